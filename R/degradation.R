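#' Learnable degradation operator
#'
#' The degradation operator `T` maps a high-coverage map to its degraded
#' (low-coverage) counterpart, `L = T(H) + E`. It is parameterized as a
#' small odd-sided convolution kernel plus a positive output scale: the
#' scale captures the read-depth loss (counts shrink roughly by the
#' retention fraction) and the kernel captures local blur/redistribution.
#' Degradation is read-depth degradation, not spatial shrinkage: `T`
#' preserves the matrix dimensions. The additive noise term `E` is not
#' explicitly parameterized; it is absorbed by the data term of the
#' training objective.
#'
#' @param k_side Odd kernel side (default 3).
#' @param scale_init Initial positive scale (default 0.75, a typical read
#'   retention).
#' @return A `degradation_model` with fields `kernel` (identity-initialized)
#'   and `scale_raw` (softplus pre-image of the scale).
#' @export
degradation_model <- function(k_side = 3L, scale_init = 0.75) {
  if (k_side %% 2 == 0 || k_side < 1) stop("degradation_model: k_side must be odd")
  if (scale_init <= 0) stop("degradation_model: scale_init must be > 0")
  k <- matrix(0, k_side, k_side)
  k[(k_side + 1) %/% 2, (k_side + 1) %/% 2] <- 1
  structure(list(kernel = k, scale_raw = softplus_inv(scale_init)),
            class = "degradation_model")
}

#' @rdname degradation_model
#' @param dm A `degradation_model`.
#' @export
degradation_scale <- function(dm) softplus(dm$scale_raw)

#' Apply the degradation operator
#'
#' `T(H)`: same-shape convolution with the current kernel, multiplied by
#' the positive scale, clamped at zero.
#'
#' @param dm A [degradation_model()].
#' @param h Square non-negative matrix (or [contact_map()]).
#' @return Matrix of the same dimension.
#' @export
apply_degradation <- function(dm, h) {
  stopifnot(inherits(dm, "degradation_model"))
  h <- as_mat(h)
  if (nrow(h) != ncol(h)) stop("apply_degradation: input must be square")
  pmax(degradation_scale(dm) * conv2(h, dm$kernel), 0)
}

#' Blind super-resolution objective
#'
#' `J(H, T) = ||L - T(H)||^2 + beta * P(H)`, where the squared norm is the
#' mean squared deviation (so `beta` is resolution-independent) and `P` is
#' either mean absolute value (`l1_sparsity`) or mean anisotropic total
#' variation (`total_variation`). The data term ties the simulated
#' low-coverage map to the observed one; the prior regularizes the
#' restored map.
#'
#' @param dm A [degradation_model()].
#' @param h Candidate high-coverage matrix.
#' @param l_observed Observed low-coverage matrix, same shape.
#' @param beta Non-negative regularization weight.
#' @param prior `"l1_sparsity"` or `"total_variation"`.
#' @return Scalar objective value.
#' @export
degradation_objective <- function(dm, h, l_observed, beta = 0,
                                  prior = c("l1_sparsity", "total_variation")) {
  prior <- match.arg(prior)
  h <- as_mat(h); l_observed <- as_mat(l_observed)
  if (!all(dim(h) == dim(l_observed)))
    stop("degradation_objective: shape mismatch")
  if (beta < 0) stop("degradation_objective: beta must be >= 0")
  data_term <- mean((l_observed - apply_degradation(dm, h))^2)
  data_term + beta * prior_value(h, prior)
}

prior_value <- function(h, prior) {
  if (prior == "l1_sparsity") return(mean(abs(h)))
  n <- nrow(h)
  tv <- sum(abs(h[-1, ] - h[-n, ])) + sum(abs(h[, -1] - h[, -n]))
  tv / length(h)
}

# gradient of beta * prior w.r.t. h (used by the trainer)
prior_grad <- function(h, prior, beta) {
  if (beta == 0) return(matrix(0, nrow(h), ncol(h)))
  if (prior == "l1_sparsity") return(beta * sign(h) / length(h))
  n <- nrow(h)
  g <- matrix(0, n, ncol(h))
  dv <- sign(h[-1, ] - h[-n, ])
  g[-1, ] <- g[-1, ] + dv
  g[-n, ] <- g[-n, ] - dv
  dh <- sign(h[, -1] - h[, -n])
  g[, -1] <- g[, -1] + dh
  g[, -n] <- g[, -n] - dh
  beta * g / length(h)
}
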