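# Numerical core shared by the recurrent cells: activations, layer
# normalization (forward + backward), parameter flattening and Adam.
# Matrices are batch-major (rows = batch elements). All gradients are
# analytic; tests check them against central finite differences.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# add a row vector b to every row of matrix m
add_rowvec <- function(m, b) m + rep(b, each = nrow(m))

LN_EPS <- 1e-5

ln_forward <- function(z, gamma, beta) {
  n <- nrow(z)
  m <- ncol(z)
  mu <- .rowMeans(z, n, m)
  xc <- z - mu
  istd <- 1 / sqrt(.rowMeans(xc * xc, n, m) + LN_EPS)
  xhat <- xc * istd
  out <- add_rowvec(xhat * rep(gamma, each = n), beta)
  list(out = out, xhat = xhat, istd = istd)
}

ln_backward <- function(dout, cache, gamma) {
  n <- nrow(dout)
  m <- ncol(dout)
  xhat <- cache$xhat
  dxhat <- dout * rep(gamma, each = n)
  dz <- cache$istd *
    (dxhat - .rowMeans(dxhat, n, m) - xhat * .rowMeans(dxhat * xhat, n, m))
  list(dz = dz,
       dgamma = .colSums(dout * xhat, n, m),
       dbeta = .colSums(dout, n, m))
}

# layer norm applied independently to each of n_chunks equal column blocks
# (one block per gate), with per-feature gain/bias
ln_forward_chunks <- function(z, gamma, beta, n_chunks) {
  m <- ncol(z) %/% n_chunks
  out <- z
  caches <- vector("list", n_chunks)
  for (k in seq_len(n_chunks)) {
    idx <- ((k - 1L) * m + 1L):(k * m)
    r <- ln_forward(z[, idx, drop = FALSE], gamma[idx], beta[idx])
    out[, idx] <- r$out
    caches[[k]] <- r
  }
  list(out = out, caches = caches)
}

ln_backward_chunks <- function(dout, caches, gamma, n_chunks) {
  m <- ncol(dout) %/% n_chunks
  dz <- dout
  dgamma <- numeric(ncol(dout))
  dbeta <- numeric(ncol(dout))
  for (k in seq_len(n_chunks)) {
    idx <- ((k - 1L) * m + 1L):(k * m)
    b <- ln_backward(dout[, idx, drop = FALSE], caches[[k]], gamma[idx])
    dz[, idx] <- b$dz
    dgamma[idx] <- b$dgamma
    dbeta[idx] <- b$dbeta
  }
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# ---- parameter (un)flattening --------------------------------------------

flatten_params <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  rec <- function(s) {
    if (is.numeric(s)) {
      n <- length(s)
      out <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      attributes(out) <- attributes(s)
      return(out)
    }
    lapply(s, rec)
  }
  rec(skeleton)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(n_par) list(m = numeric(n_par), v = numeric(n_par), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
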