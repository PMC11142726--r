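# Layer primitives with hand-written backward passes. Activations are stored
# as base arrays in (batch, height, width, channel) order so per-channel
# operations reshape to a (B*H*W) x C matrix with `matrix(x, ncol = C)`.
# Nothing here is exported; the model module composes these.

# ---- 2-D convolution, stride 1, valid padding (compiled kernels) ------------

nn_conv_forward <- function(x, K, b) {
  d <- dim(x)
  kd <- dim(K)
  out <- cpp_conv_forward(x, as.integer(d), K, as.integer(kd), b)
  dim(out) <- c(d[1], d[2] - kd[1] + 1L, d[3] - kd[2] + 1L, kd[4])
  out
}

nn_conv_backward <- function(x, K, dout) {
  res <- cpp_conv_backward(x, as.integer(dim(x)), K, as.integer(dim(K)), dout)
  dim(res$dx) <- dim(x)
  dim(res$dK) <- dim(K)
  res
}

# ---- max pooling, window = stride, valid extent -----------------------------

# `win` records the winning input cell of each window as a 1-based linear
# index into x (ties to the first-visited offset), so the backward pass is
# one scatter: windows never overlap, hence winners are unique.
nn_pool_forward <- function(x, ph, pw) {
  d <- dim(x)
  res <- cpp_pool_forward(x, as.integer(d), as.integer(ph), as.integer(pw))
  dim(res$out) <- c(d[1], d[2] %/% ph, d[3] %/% pw, d[4])
  res
}

nn_pool_backward <- function(dout, win, xdim, ph, pw) {
  dx_ <- array(0, xdim)
  dx_[as.vector(win)] <- as.vector(dout)
  dx_
}

# ---- batch normalization (per channel) --------------------------------------

nn_bn_forward <- function(x, gamma, beta, run_mean, run_var,
                          mode, momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[4]
  xm <- matrix(x, ncol = C)
  N <- nrow(xm)
  if (mode == "train") {
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm^2) - mu^2, 0)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    vu <- if (N > 1) v * N / (N - 1) else v
    run_var <- (1 - momentum) * run_var + momentum * vu
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = N)) * rep(inv_sd, each = N)
  y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  list(out = array(y, dim(x)),
       cache = list(xhat = xhat, inv_sd = inv_sd, mode = mode, xdim = dim(x)),
       run_mean = run_mean, run_var = run_var)
}

nn_bn_backward <- function(dout, gamma, cache) {
  C <- cache$xdim[4]
  dy <- matrix(dout, ncol = C)
  N <- nrow(dy)
  xhat <- cache$xhat
  dbeta <- colSums(dy)
  dgamma <- colSums(dy * xhat)
  dxhat <- dy * rep(gamma, each = N)
  if (cache$mode == "train") {
    t1 <- dxhat - rep(colMeans(dxhat), each = N)
    t2 <- xhat * rep(colMeans(dxhat * xhat), each = N)
    dx <- (t1 - t2) * rep(cache$inv_sd, each = N)
  } else {
    dx <- dxhat * rep(cache$inv_sd, each = N)
  }
  list(dx = array(dx, cache$xdim), dgamma = dgamma, dbeta = dbeta)
}

# ---- LSTM over a neighbor sequence (hidden size = input size) ---------------
# Gate layout in the 4H-wide blocks: input, forget, cell, output.

nn_lstm_forward <- function(xs, Wx, Wh, b) {
  Tn <- nrow(xs)
  Hd <- ncol(Wh) / 4L  # Wh is H x 4H
  h <- numeric(Hd)
  cc <- numeric(Hd)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    h_prev <- h
    z <- drop(xs[t, ] %*% Wx + h %*% Wh) + b
    i <- sigmoid(z[1:Hd])
    f <- sigmoid(z[Hd + 1:Hd])
    g <- tanh(z[2 * Hd + 1:Hd])
    o <- sigmoid(z[3 * Hd + 1:Hd])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev,
                       cc = cc, tc = tc, h_prev = h_prev, h = h, x = xs[t, ])
  }
  list(h = h, cache = cache)
}

nn_lstm_backward <- function(dh_final, cache, Wx, Wh) {
  Tn <- length(cache)
  Hd <- length(dh_final)
  dWx <- array(0, dim(Wx))
  dWh <- array(0, dim(Wh))
  db <- numeric(4 * Hd)
  dxs <- matrix(0, Tn, nrow(Wx))
  dh <- dh_final
  dc <- numeric(Hd)
  for (t in rev(seq_len(Tn))) {
    k <- cache[[t]]
    do_ <- dh * k$tc
    dc <- dc + dh * k$o * (1 - k$tc^2)
    di <- dc * k$g
    dg <- dc * k$i
    df <- dc * k$c_prev
    dc_prev <- dc * k$f
    dz <- c(di * k$i * (1 - k$i),
            df * k$f * (1 - k$f),
            dg * (1 - k$g^2),
            do_ * k$o * (1 - k$o))
    dWx <- dWx + outer(k$x, dz)
    dWh <- dWh + outer(k$h_prev, dz)
    db <- db + dz
    dxs[t, ] <- drop(Wx %*% dz)
    dh <- drop(Wh %*% dz)
    dc <- dc_prev
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function() {
  list(m = list(), v = list(), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- params[[nm]] * 0
      opt$v[[nm]] <- params[[nm]] * 0
    }
    up <- cpp_adam_update(params[[nm]], opt$m[[nm]], opt$v[[nm]], g, lr,
                          opt$beta1, opt$beta2, bc1, bc2, opt$eps)
    dm <- dim(params[[nm]])
    if (!is.null(dm)) dim(up$p) <- dm
    params[[nm]] <- up$p
    opt$m[[nm]] <- up$m
    opt$v[[nm]] <- up$v
  }
  list(opt = opt, params = params)
}

# Rescale a gradient list so its global L2 norm is at most `max_norm`.
clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  tot <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (tot <= max_norm || tot == 0) return(grads)
  lapply(grads, function(g) g * (max_norm / tot))
}
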