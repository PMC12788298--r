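# Minimal neural-network primitives with hand-derived backpropagation.
#
# Batched sequences are stored sample-major: a batch of B sequences of
# length T with C features is a (B*T) x C matrix whose rows
# (b-1)*T + 1 ... b*T hold sample b in time order. All forward functions
# return caches sufficient for the matching backward pass; gradients are
# verified against central finite differences in the test suite.

init_mat <- function(nr, nc, fan_in) {
  bound <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
}
init_vec <- function(n, fan_in) stats::runif(n, -1, 1) / sqrt(fan_in)

linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, X = X)
}
linear_bwd <- function(cache, dY, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

relu_fwd <- function(X) list(Y = pmax(X, 0), mask = X > 0)
relu_bwd <- function(cache, dY) dY * cache$mask

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}
dropout_bwd <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# Length-preserving temporal convolution (odd kernel, symmetric zero pad).
# W is a list of k matrices (C_in x C_out), one per tap; the tap loop runs
# in compiled code (src/nn_kernels.cpp).
conv1d_fwd <- function(X, W, b, T_len, B, single = TRUE, keep = TRUE) {
  .conv1d_fwd_cpp(X, W, b, T_len, B, single, keep)
}
conv1d_bwd <- function(cache, dY, W) {
  out <- .conv1d_bwd_cpp(cache$ptr, dY, W)
  list(dX = out$dX, dW = out$dW, db = as.numeric(out$db))
}

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, gamma, "*")
  Y <- sweep(Y, 2, beta, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}
layernorm_bwd <- function(cache, dY, gamma) {
  H <- ncol(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * cache$xhat)
  dX <- (dxhat - (rs1 + cache$xhat * rs2) / H) * cache$inv
  list(dX = dX, dgamma = colSums(dY * cache$xhat), dbeta = colSums(dY))
}

#' Sinusoidal positional encoding
#'
#' Standard sine/cosine encoding with geometric wavelength progression
#' (base 10000): column pairs (2k+1, 2k+2) hold `sin(t / 10000^(2k/H))`
#' and `cos(t / 10000^(2k/H))` for 0-based positions t.
#'
#' @param T_len Number of positions.
#' @param H Embedding width.
#' @return `T_len x H` matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(T_len, H) {
  stop_if(T_len < 1 || H < 1, "T and H must be >= 1")
  pos <- 0:(T_len - 1)
  pe <- matrix(0, T_len, H)
  for (k in 0:(ceiling(H / 2) - 1)) {
    ang <- pos / 10000^(2 * k / H)
    pe[, 2 * k + 1] <- sin(ang)
    if (2 * k + 2 <= H) pe[, 2 * k + 2] <- cos(ang)
  }
  pe
}
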