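# End-to-end model: GraphSAGE embedding -> Top-k pooling -> pair matrices ->
# stacked CNN head -> sigmoid. Parameters live in a flat named list so the
# optimizer and the gradient check can treat them uniformly. The backward
# pass mirrors the forward pass exactly; `test-acceptance.R` verifies it
# against finite differences.

# Geometry of the convolutional head for a (rows x cols) single-channel
# input. Kernel and pooling windows clip to the available extent per axis;
# the first convolution must fit unclipped along rows.
head_geometry <- function(rows, cols, config) {
  ks <- config$kernel_size
  if (rows < ks) {
    stop(sprintf(
      "configuration error: pair matrix has %d rows but the convolution kernel is %d",
      rows, ks))
  }
  channels <- if (config$cnn_layers == 3L) c(16L, 32L, 64L) else 16L
  blocks <- vector("list", config$cnn_layers)
  H <- rows
  W <- cols
  Ci <- 1L
  for (b in seq_len(config$cnn_layers)) {
    kh <- min(ks, H)
    kw <- min(ks, W)
    Hc <- H - kh + 1L
    Wc <- W - kw + 1L
    ph <- min(2L, Hc)
    pw <- min(2L, Wc)
    Ho <- Hc %/% ph
    Wo <- Wc %/% pw
    blocks[[b]] <- list(kh = kh, kw = kw, ph = ph, pw = pw,
                        Ci = Ci, Co = channels[b],
                        Hin = H, Win = W, Hc = Hc, Wc = Wc,
                        Ho = Ho, Wo = Wo,
                        seg = Ho * Wo * channels[b])
    H <- Ho
    W <- Wo
    Ci <- channels[b]
  }
  list(blocks = blocks, feat_width = sum(vapply(blocks, `[[`, 0, "seg")))
}

grn_init_params <- function(n_feat, config, seed) {
  d <- config$embed_dim
  params <- list()
  d_in <- n_feat
  for (t in seq_len(config$hops)) {
    params[[paste0("sage", t, ".W")]] <-
      glorot(2 * d_in, d, derive_seed(seed, "sageW", t),
             dims = c(2 * d_in, d))
    if (config$aggregator == "lstm") {
      lp <- lstm_init(d_in, derive_seed(seed, "sagelstm", t))
      params[[paste0("sage", t, ".lstm.Wx")]] <- lp$Wx
      params[[paste0("sage", t, ".lstm.Wh")]] <- lp$Wh
      params[[paste0("sage", t, ".lstm.b")]] <- lp$b
    }
    d_in <- d
  }
  if (config$use_topk) {
    params[["pool.p"]] <- with_seed(derive_seed(seed, "poolp"),
                                    stats::rnorm(d) / sqrt(d))
  }
  rows <- config$k_pool + 2L
  geo <- head_geometry(rows, d, config)
  bn_mean <- list()
  bn_var <- list()
  for (b in seq_along(geo$blocks)) {
    g <- geo$blocks[[b]]
    params[[paste0("cnn", b, ".bn.gamma")]] <- rep(1, g$Ci)
    params[[paste0("cnn", b, ".bn.beta")]] <- rep(0, g$Ci)
    params[[paste0("cnn", b, ".conv.K")]] <-
      glorot(g$kh * g$kw * g$Ci, g$Co, derive_seed(seed, "convK", b),
             dims = c(g$kh, g$kw, g$Ci, g$Co))
    params[[paste0("cnn", b, ".conv.b")]] <- numeric(g$Co)
    bn_mean[[b]] <- numeric(g$Ci)
    bn_var[[b]] <- rep(1, g$Ci)
  }
  params[["fc1.W"]] <- NULL  # lazy: width known at first batch
  params[["fc1.b"]] <- NULL
  params[["fc2.W"]] <- glorot(config$fc_hidden, 1, derive_seed(seed, "fc2"),
                              dims = c(config$fc_hidden, 1))
  params[["fc2.b"]] <- 0
  list(params = params,
       state = list(geo = geo, bn_mean = bn_mean, bn_var = bn_var,
                    seed = seed, n_feat = n_feat))
}

sage_stack_forward <- function(params, graph, config, lstm_seed) {
  H <- graph$features
  caches <- vector("list", config$hops)
  for (t in seq_len(config$hops)) {
    lp <- if (config$aggregator == "lstm") {
      list(Wx = params[[paste0("sage", t, ".lstm.Wx")]],
           Wh = params[[paste0("sage", t, ".lstm.Wh")]],
           b = params[[paste0("sage", t, ".lstm.b")]])
    }
    fw <- sage_layer_fwd(H, graph, params[[paste0("sage", t, ".W")]],
                         config$aggregator, lp, perm_seed = lstm_seed + t)
    caches[[t]] <- c(fw$cache, list(lstm_params = lp))
    H <- fw$H
  }
  list(X = H, caches = caches)
}

sage_stack_backward <- function(dX, caches, params, graph, config) {
  grads <- list()
  dH <- dX
  for (t in rev(seq_len(config$hops))) {
    ch <- caches[[t]]
    W <- params[[paste0("sage", t, ".W")]]
    dZ <- dH * (ch$Z > 0)
    grads[[paste0("sage", t, ".W")]] <- crossprod(cbind(ch$feats, ch$A), dZ)
    d_in <- ncol(ch$feats)
    dconcat <- dZ %*% t(W)
    dself <- dconcat[, seq_len(d_in), drop = FALSE]
    dA <- dconcat[, d_in + seq_len(d_in), drop = FALSE]
    if (t > 1 || config$aggregator == "lstm") {
      bk <- agg_backward(dA, ch$agg, graph, ch$feats, ch$lstm_params)
      if (config$aggregator == "lstm") {
        grads[[paste0("sage", t, ".lstm.Wx")]] <- bk$dWx
        grads[[paste0("sage", t, ".lstm.Wh")]] <- bk$dWh
        grads[[paste0("sage", t, ".lstm.b")]] <- bk$db
      }
      dH <- dself + bk$dfeats
    } else {
      dH <- NULL  # layer-1 input is data; no gradient needed
    }
  }
  grads
}

# Full forward pass over a batch of (i, j) node-index pairs.
grn_forward <- function(params, state, graph, pi, pj, config,
                        mode = c("train", "eval"), lstm_seed = 0L) {
  mode <- match.arg(mode)
  B <- length(pi)
  d <- config$embed_dim
  sg <- sage_stack_forward(params, graph, config, lstm_seed)
  X <- sg$X
  pool_cache <- NULL
  if (config$use_topk) {
    p <- params[["pool.p"]]
    nrm <- sqrt(sum(p^2))
    if (nrm == 0) stop("pooling projection collapsed to zero")
    pn <- p / nrm
    s_raw <- drop(X %*% pn)
    scores <- pmax(s_raw, 0)
    ord <- order(-scores, seq_along(scores))
    sel <- ord[seq_len(config$k_pool)]
    tanh_s <- tanh(scores[sel])
    gated <- if (config$gate_topk) {
      X[sel, , drop = FALSE] * tanh_s
    } else {
      X[sel, , drop = FALSE]
    }
    pool_cache <- list(pn = pn, nrm = nrm, s_raw = s_raw, scores = scores,
                       sel = sel, tanh_s = tanh_s)
  } else {
    gated <- NULL
  }
  R <- config$k_pool + 2L
  E <- array(0, c(B, R, d))
  E[, 1, ] <- X[pi, , drop = FALSE]
  E[, 2, ] <- X[pj, , drop = FALSE]
  if (config$k_pool > 0) {
    for (r in seq_len(config$k_pool)) {
      E[, 2 + r, ] <- matrix(gated[r, ], B, d, byrow = TRUE)
    }
  }
  dim(E) <- c(B, R, d, 1L)

  geo <- state$geo
  x <- E
  block_caches <- vector("list", length(geo$blocks))
  segs <- vector("list", length(geo$blocks))
  for (b in seq_along(geo$blocks)) {
    g <- geo$blocks[[b]]
    bn <- nn_bn_forward(x, params[[paste0("cnn", b, ".bn.gamma")]],
                        params[[paste0("cnn", b, ".bn.beta")]],
                        state$bn_mean[[b]], state$bn_var[[b]], mode)
    if (mode == "train") {
      state$bn_mean[[b]] <- bn$run_mean
      state$bn_var[[b]] <- bn$run_var
    }
    cz <- nn_conv_forward(bn$out, params[[paste0("cnn", b, ".conv.K")]],
                          params[[paste0("cnn", b, ".conv.b")]])
    a <- pmax(cz, 0)
    pl <- nn_pool_forward(a, g$ph, g$pw)
    block_caches[[b]] <- list(x_in = bn$out, bn_cache = bn$cache,
                              cz = cz, a_dim = dim(a), win = pl$win,
                              in_dim = dim(x))
    segs[[b]] <- matrix(pl$out, nrow = B)
    x <- pl$out
  }
  feat <- do.call(cbind, segs)

  if (is.null(params[["fc1.W"]])) {
    params[["fc1.W"]] <- glorot(ncol(feat), config$fc_hidden,
                                derive_seed(state$seed, "fc1"),
                                dims = c(ncol(feat), config$fc_hidden))
    params[["fc1.b"]] <- numeric(config$fc_hidden)
  }
  h1pre <- feat %*% params[["fc1.W"]]
  h1pre <- h1pre + rep(params[["fc1.b"]], each = nrow(h1pre))
  h1 <- pmax(h1pre, 0)
  logit <- drop(h1 %*% params[["fc2.W"]]) + params[["fc2.b"]]
  yhat <- sigmoid(logit)

  cache <- list(sage = sg$caches, X = X, pool = pool_cache, pi = pi, pj = pj,
                E_dim = dim(E), blocks = block_caches, feat = feat,
                h1pre = h1pre, h1 = h1, n = nrow(X))
  list(yhat = yhat, cache = cache, params = params, state = state)
}

# Backward pass from d(loss)/d(logit); returns gradients named like params.
grn_backward <- function(params, state, cache, dlogit, yhat, graph, config) {
  grads <- list()
  B <- length(dlogit)
  grads[["fc2.W"]] <- crossprod(cache$h1, matrix(dlogit, ncol = 1))
  grads[["fc2.b"]] <- sum(dlogit)
  dh1 <- matrix(dlogit, ncol = 1) %*% t(params[["fc2.W"]])
  dh1pre <- dh1 * (cache$h1pre > 0)
  grads[["fc1.W"]] <- crossprod(cache$feat, dh1pre)
  grads[["fc1.b"]] <- colSums(dh1pre)
  dfeat <- dh1pre %*% t(params[["fc1.W"]])

  geo <- state$geo
  nb <- length(geo$blocks)
  seg_ends <- cumsum(vapply(geo$blocks, `[[`, 0, "seg"))
  seg_starts <- c(1, utils::head(seg_ends, -1) + 1)
  dnext <- NULL
  for (b in rev(seq_len(nb))) {
    g <- geo$blocks[[b]]
    ch <- cache$blocks[[b]]
    dP <- array(dfeat[, seg_starts[b]:seg_ends[b], drop = FALSE],
                c(B, g$Ho, g$Wo, g$Co))
    if (!is.null(dnext)) dP <- dP + dnext
    da <- nn_pool_backward(dP, ch$win, ch$a_dim, g$ph, g$pw)
    dcz <- da * (ch$cz > 0)
    cb <- nn_conv_backward(ch$x_in, params[[paste0("cnn", b, ".conv.K")]], dcz)
    grads[[paste0("cnn", b, ".conv.K")]] <- cb$dK
    grads[[paste0("cnn", b, ".conv.b")]] <- cb$db
    bb <- nn_bn_backward(cb$dx, params[[paste0("cnn", b, ".bn.gamma")]],
                         ch$bn_cache)
    grads[[paste0("cnn", b, ".bn.gamma")]] <- bb$dgamma
    grads[[paste0("cnn", b, ".bn.beta")]] <- bb$dbeta
    dnext <- bb$dx
  }
  dE <- dnext
  dim(dE) <- cache$E_dim[1:3]

  d <- config$embed_dim
  n <- cache$n
  dX <- matrix(0, n, d)
  drows <- rbind(matrix(dE[, 1, ], nrow = B), matrix(dE[, 2, ], nrow = B))
  acc <- rowsum(drows, group = c(cache$pi, cache$pj))
  ridx <- as.integer(rownames(acc))
  dX[ridx, ] <- dX[ridx, , drop = FALSE] + acc

  if (config$use_topk) {
    pc <- cache$pool
    k <- config$k_pool
    dG <- matrix(0, k, d)
    for (r in seq_len(k)) {
      dG[r, ] <- colSums(matrix(dE[, 2 + r, ], nrow = B))
    }
    Xsel <- cache$X[pc$sel, , drop = FALSE]
    if (config$gate_topk) {
      dX[pc$sel, ] <- dX[pc$sel, , drop = FALSE] + dG * pc$tanh_s
      ds_sel <- rowSums(dG * Xsel) * (1 - pc$tanh_s^2)
      ds <- numeric(n)
      ds[pc$sel] <- ds_sel
      ds <- ds * (pc$s_raw > 0)
      dX <- dX + outer(ds, pc$pn)
      dpn <- drop(crossprod(cache$X, ds))
      grads[["pool.p"]] <- (dpn - pc$pn * sum(pc$pn * dpn)) / pc$nrm
    } else {
      dX[pc$sel, ] <- dX[pc$sel, , drop = FALSE] + dG
      grads[["pool.p"]] <- params[["pool.p"]] * 0
    }
  }

  c(grads, sage_stack_backward(dX, cache$sage, params, graph, config))
}

# Loss and gradients for one labeled batch; the unit the training loop and
# the finite-difference check both call.
grn_loss_grads <- function(params, state, graph, pi, pj, y, config,
                           mode = "train", lstm_seed = 0L,
                           want_grads = TRUE, eps = 1e-7) {
  fw <- grn_forward(params, state, graph, pi, pj, config, mode, lstm_seed)
  yhat <- fw$yhat
  yc <- clamp(yhat, eps, 1 - eps)
  N <- length(y)
  loss <- -mean(y * log(yc) + (1 - y) * log(1 - yc))
  out <- list(loss = loss, yhat = yhat, params = fw$params, state = fw$state)
  if (want_grads) {
    # fused sigmoid+BCE gradient: exact off the clamp boundary, and keeps a
    # recovery gradient for saturated predictions (the standard formulation)
    dlogit <- (yc - y) / N
    out$grads <- grn_backward(fw$params, fw$state, fw$cache, dlogit, yhat,
                              graph, config)
  }
  out
}
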