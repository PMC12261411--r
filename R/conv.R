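# Same-shape 2D convolution primitives (zero padding, odd kernel side).
# conv2(X, K) is the cross-correlation Y[i,j] = sum_ab K[a,b] X[i+a-c, j+b-c]
# with c the kernel center; conv2_adj is its adjoint (transpose) operator,
# and conv2_kgrad accumulates the gradient with respect to the kernel.
# All three are built from a single zero-filled shift, so the adjoint
# relationships hold exactly: <conv2(X,K), Y> == <X, conv2_adj(Y,K)> and
# <conv2(X,K), Y> == <K, conv2_kgrad(X, Y)>.

shift_mat <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  if (length(rs) && length(cs))
    out[rs - dr, cs - dc] <- x[rs, cs]
  out
}

conv2 <- function(x, k) {
  ks <- nrow(k)
  c0 <- (ks + 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(ks)) for (b in seq_len(ks)) {
    if (k[a, b] != 0)
      out <- out + k[a, b] * shift_mat(x, a - c0, b - c0)
  }
  out
}

conv2_adj <- function(y, k) {
  ks <- nrow(k)
  c0 <- (ks + 1L) %/% 2L
  out <- matrix(0, nrow(y), ncol(y))
  for (a in seq_len(ks)) for (b in seq_len(ks)) {
    if (k[a, b] != 0)
      out <- out + k[a, b] * shift_mat(y, c0 - a, c0 - b)
  }
  out
}

conv2_kgrad <- function(x, dy, ks) {
  c0 <- (ks + 1L) %/% 2L
  g <- matrix(0, ks, ks)
  for (a in seq_len(ks)) for (b in seq_len(ks)) {
    g[a, b] <- sum(dy * shift_mat(x, a - c0, b - c0))
  }
  g
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) log(expm1(y))
sigmoid <- function(x) 1 / (1 + exp(-x))
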