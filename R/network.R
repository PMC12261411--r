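#' Alternating estimator/restorer network
#'
#' A compact unrolled network for blind super-resolution of contact maps.
#' Per forward pass the observed low-coverage map is normalized, passed
#' through a convolutional feature head, and then refined by
#' `n_alternations` rounds of:
#'
#' * an *estimator*, a small MLP that maps summary statistics of the
#'   observed map and the current restored map to a kernel representation
#'   (an odd-sided degradation kernel plus a positive scale, the estimated
#'   read-retention); and
#' * a *restorer*, which combines a learned residual convolution path with
#'   a gradient step on the degradation-consistency objective
#'   `||L - T(H)||^2` under the currently estimated kernel (a
#'   Landweber-type update), clamped at zero.
#'
#' A final image tail applies a learned residual refinement, and a
#' degradation tail maps the restored map back through the estimated
#' kernel for consistency checking. All parameters are trained jointly by
#' [train_enhancer()].
#'
#' @param n_alternations Number of estimator/restorer rounds `N`
#'   (default 5, following the deep-alternating ablation this design
#'   adopts).
#' @param k_side Odd side of the estimated degradation kernel (default 3).
#' @param hidden Estimator MLP hidden width (default 8).
#' @param seed Integer seed for weight initialization.
#' @return An `alternating_network` with fields `params`, `n_alternations`,
#'   `k_side`, `hidden`, `trained`.
#' @export
alternating_network <- function(n_alternations = 5L, k_side = 3L, hidden = 8L,
                                seed = 1L) {
  if (n_alternations < 1) stop("alternating_network: n_alternations must be >= 1")
  if (k_side %% 2 == 0) stop("alternating_network: k_side must be odd")
  set.seed(seed)
  nz <- 5L
  no <- k_side^2 + 1L
  rmat <- function(r, c, sd) matrix(stats::rnorm(r * c, 0, sd), r, c)
  params <- list(
    Wh  = rmat(3, 3, 0.05), bh = 0.01,
    W1  = rmat(hidden, nz, 0.1), b1 = rep(0, hidden),
    W2  = rmat(no, hidden, 0.1), b2 = rep(0, no),
    Wr1 = rmat(3, 3, 0.05), Wr2 = rmat(3, 3, 0.05), br1 = 0.01,
    Wr3 = matrix(0, 3, 3), br3 = 0,
    g   = 0.5,
    Wt  = matrix(0, 3, 3), bt = 0)
  structure(list(params = params, n_alternations = as.integer(n_alternations),
                 k_side = as.integer(k_side), hidden = as.integer(hidden),
                 trained = FALSE),
            class = "alternating_network")
}

#' @export
print.alternating_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("alternating_network: N=%d, kernel %dx%d, %d parameters, %s\n",
              x$n_alternations, x$k_side, x$k_side, np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# constants of the estimator parameterization
.kernel_rep_scale <- 0.1
.scale_bias <- softplus_inv(0.6)
.z_eps <- 1e-6

net_norm_scale <- function(l) max(l) + 1e-8

# summary statistics feeding the estimator MLP
net_stats <- function(ln, l_raw, h_cur) {
  c(mean(ln), stats::sd(ln), mean(l_raw > 0), mean(h_cur),
    mean(ln) / (mean(h_cur) + .z_eps))
}

# estimator MLP on a statistics vector; returns kernel rep + cached nodes
estimator_eval <- function(params, z, k_side) {
  pre1 <- as.numeric(params$W1 %*% z + params$b1)
  a1 <- tanh(pre1)
  o <- as.numeric(params$W2 %*% a1 + params$b2)
  kd2 <- k_side^2
  kern <- matrix(o[1:kd2] * .kernel_rep_scale, k_side, k_side)
  kern[(k_side + 1) %/% 2, (k_side + 1) %/% 2] <-
    kern[(k_side + 1) %/% 2, (k_side + 1) %/% 2] + 1
  sc <- softplus(o[kd2 + 1] + .scale_bias)
  list(kernel = kern, scale = sc, z = z, a1 = a1, o = o)
}

# full forward pass in normalized space; keeps a tape when requested
net_forward_core <- function(params, l_raw, n_alt, k_side, keep_tape = FALSE) {
  s <- net_norm_scale(l_raw)
  ln <- l_raw / s
  gh <- conv2(ln, params$Wh) + params$bh
  f <- pmax(gh, 0)
  h <- ln
  tape <- if (keep_tape) vector("list", n_alt) else NULL
  est <- NULL
  for (k in seq_len(n_alt)) {
    z <- net_stats(ln, l_raw, h)
    est <- estimator_eval(params, z, k_side)
    v <- conv2(h, params$Wr1) + conv2(f, params$Wr2) + params$br1
    u <- pmax(v, 0)
    cc <- conv2(h, est$kernel)
    r <- ln - est$scale * cc
    m <- conv2_adj(r, est$kernel)
    b <- h + conv2(u, params$Wr3) + params$br3 + params$g * est$scale * m
    h_new <- pmax(b, 0)
    if (keep_tape)
      tape[[k]] <- list(z = z, est = est, v = v, u = u, cc = cc, r = r,
                        m = m, b = b, h_prev = h)
    h <- h_new
  }
  a <- h + conv2(h, params$Wt) + params$bt
  h_out <- pmax(a, 0)
  list(s = s, ln = ln, gh = gh, f = f, h_n = h, a = a, h_out = h_out,
       est = est, tape = tape)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# reverse pass: dh_out is the loss gradient w.r.t. h_out (normalized space).
# dk_last/dscale_last inject extra gradient into the final iteration's
# kernel representation (used by the degradation-tail consistency term).
# Returns parameter gradients. fw must come from keep_tape = TRUE.
net_backward_core <- function(params, fw, dh_out, k_side,
                              dk_last = NULL, dscale_last = 0) {
  gr <- zero_like(params)
  n_alt <- length(fw$tape)
  # image tail: h_out = relu(h_n + conv(h_n, Wt) + bt)
  da <- dh_out * (fw$a > 0)
  gr$Wt <- gr$Wt + conv2_kgrad(fw$h_n, da, 3L)
  gr$bt <- gr$bt + sum(da)
  dh <- da + conv2_adj(da, params$Wt)
  df <- matrix(0, nrow(fw$ln), ncol(fw$ln))
  npix <- length(fw$ln)
  for (k in rev(seq_len(n_alt))) {
    tp <- fw$tape[[k]]
    est <- tp$est
    db <- dh * (tp$b > 0)
    # residual + learned conv path
    dh_prev <- db
    gr$br3 <- gr$br3 + sum(db)
    gr$Wr3 <- gr$Wr3 + conv2_kgrad(tp$u, db, 3L)
    du <- conv2_adj(db, params$Wr3)
    # physics path: phys = g * scale * m
    gr$g <- gr$g + sum(db * est$scale * tp$m)
    dscale <- params$g * sum(db * tp$m)
    if (k == n_alt) dscale <- dscale + dscale_last
    dm <- params$g * est$scale * db
    # m = conv2_adj(r, K): adjoint pair of conv2
    dK <- conv2_kgrad(dm, tp$r, k_side)   # d<conv2_adj(r,K), dm>/dK
    if (k == n_alt && !is.null(dk_last)) dK <- dK + dk_last
    dr <- conv2(dm, est$kernel)
    # r = ln - scale * cc
    dscale <- dscale - sum(dr * tp$cc)
    dcc <- -est$scale * dr
    # cc = conv2(h_prev, K)
    dK <- dK + conv2_kgrad(tp$h_prev, dcc, k_side)
    dh_prev <- dh_prev + conv2_adj(dcc, est$kernel)
    # learned feature path: u = relu(conv(h_prev,Wr1) + conv(f,Wr2) + br1)
    dv <- du * (tp$v > 0)
    gr$br1 <- gr$br1 + sum(dv)
    gr$Wr1 <- gr$Wr1 + conv2_kgrad(tp$h_prev, dv, 3L)
    dh_prev <- dh_prev + conv2_adj(dv, params$Wr1)
    gr$Wr2 <- gr$Wr2 + conv2_kgrad(fw$f, dv, 3L)
    df <- df + conv2_adj(dv, params$Wr2)
    # estimator MLP backward
    kd2 <- k_side^2
    do <- numeric(kd2 + 1)
    do[1:kd2] <- as.numeric(dK) * .kernel_rep_scale
    do[kd2 + 1] <- dscale * sigmoid(est$o[kd2 + 1] + .scale_bias)
    gr$W2 <- gr$W2 + outer(do, est$a1)
    gr$b2 <- gr$b2 + do
    da1 <- as.numeric(t(params$W2) %*% do)
    dpre1 <- da1 * (1 - est$a1^2)
    gr$W1 <- gr$W1 + outer(dpre1, est$z)
    gr$b1 <- gr$b1 + dpre1
    dz <- as.numeric(t(params$W1) %*% dpre1)
    # z4 = mean(h_prev); z5 = z1 / (z4 + eps)
    z4 <- est$z[4]
    dz4 <- dz[4] - dz[5] * est$z[1] / (z4 + .z_eps)^2
    dh_prev <- dh_prev + dz4 / npix
    dh <- dh_prev
  }
  # head: f = relu(conv(ln, Wh) + bh)
  dgh <- df * (fw$gh > 0)
  gr$Wh <- gr$Wh + conv2_kgrad(fw$ln, dgh, 3L)
  gr$bh <- gr$bh + sum(dgh)
  gr
}

#' One estimator update: kernel representation from (L, current H)
#'
#' Evaluates the estimator MLP on summary statistics of the observed
#' low-coverage map and the current restored estimate, returning the
#' kernel representation (degradation kernel and positive scale, the
#' implied read retention). Deterministic for fixed weights and inputs.
#'
#' @param net An [alternating_network()].
#' @param l_observed Observed low-coverage matrix (count space).
#' @param h_current Current restored estimate (count space); defaults to
#'   `l_observed`.
#' @return List with `kernel` (`k_side x k_side`) and `scale` (scalar).
#' @export
estimator_step <- function(net, l_observed, h_current = l_observed) {
  stopifnot(inherits(net, "alternating_network"))
  l_observed <- as_mat(l_observed); h_current <- as_mat(h_current)
  if (!all(is.finite(l_observed)) || !all(is.finite(h_current)))
    stop("estimator_step: non-finite input")
  s <- net_norm_scale(l_observed)
  z <- net_stats(l_observed / s, l_observed, h_current / s)
  est <- estimator_eval(net$params, z, net$k_side)
  list(kernel = est$kernel, scale = est$scale)
}

#' One restorer update of the high-coverage estimate
#'
#' Applies a single restorer round (learned residual convolution path plus
#' a consistency gradient step under the supplied kernel representation)
#' and the non-negativity clamp. Deterministic for fixed weights/inputs.
#'
#' @param net An [alternating_network()].
#' @param l_observed Observed low-coverage matrix (count space).
#' @param kernel_rep Kernel representation from [estimator_step()].
#' @param h_current Current estimate (count space); defaults to
#'   `l_observed`.
#' @param symmetrize_output Average the result with its transpose
#'   (default `FALSE`).
#' @return Updated estimate, same shape as `l_observed`, entries >= 0.
#' @export
restorer_step <- function(net, l_observed, kernel_rep,
                          h_current = l_observed, symmetrize_output = FALSE) {
  stopifnot(inherits(net, "alternating_network"))
  l_observed <- as_mat(l_observed); h_current <- as_mat(h_current)
  if (!all(is.finite(l_observed)) || !all(is.finite(h_current)))
    stop("restorer_step: non-finite input")
  p <- net$params
  s <- net_norm_scale(l_observed)
  ln <- l_observed / s
  h <- h_current / s
  f <- pmax(conv2(ln, p$Wh) + p$bh, 0)
  u <- pmax(conv2(h, p$Wr1) + conv2(f, p$Wr2) + p$br1, 0)
  r <- ln - kernel_rep$scale * conv2(h, kernel_rep$kernel)
  m <- conv2_adj(r, kernel_rep$kernel)
  h_new <- pmax(h + conv2(u, p$Wr3) + p$br3 + p$g * kernel_rep$scale * m, 0)
  out <- s * h_new
  if (symmetrize_output) out <- symmetrize(out)
  out
}

#' Full alternating forward pass
#'
#' Runs head, `n_alternations` estimator/restorer rounds, and the image
#' tail; also applies the degradation tail (the estimated kernel applied
#' to the restored map) for consistency checking.
#'
#' @param net An [alternating_network()].
#' @param l_observed Square non-negative matrix (or [contact_map()]).
#' @param n_alternations Optional override of the network's loop count.
#' @return List with `h_hat` (restored matrix, count space), `kernel_rep`
#'   (final `kernel`/`scale`), and `l_consistency` (degradation tail
#'   output `T(h_hat)`, count space).
#' @export
alternate_forward <- function(net, l_observed,
                              n_alternations = net$n_alternations) {
  stopifnot(inherits(net, "alternating_network"))
  l_observed <- as_mat(l_observed)
  if (nrow(l_observed) != ncol(l_observed))
    stop("alternate_forward: input must be square")
  if (!all(is.finite(l_observed)) || any(l_observed < 0))
    stop("alternate_forward: input must be finite and non-negative")
  fw <- net_forward_core(net$params, l_observed, n_alternations, net$k_side)
  l_cons <- fw$s * pmax(fw$est$scale * conv2(fw$h_out, fw$est$kernel), 0)
  list(h_hat = fw$s * fw$h_out,
       kernel_rep = list(kernel = fw$est$kernel, scale = fw$est$scale),
       l_consistency = l_cons)
}
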