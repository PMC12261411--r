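as_mat <- function(x) if (is_contact_map(x)) x$matrix else as.matrix(x)

#' Peak signal-to-noise ratio between two matrices
#'
#' `PSNR = 10 * log10(MAX^2 / MSE)` in decibels, where MSE is the mean
#' squared elementwise difference. `max_value = "auto"` uses the maximum
#' over both matrices. Identical inputs (MSE = 0) return the documented
#' sentinel of 99 dB with attribute `capped = TRUE`.
#'
#' @param a,b Matrices or [contact_map()]s of equal dimension.
#' @param max_value Positive reference maximum, or `"auto"`.
#' @param cap Sentinel value returned when MSE is zero (default 99).
#' @return Scalar PSNR in dB (attribute `capped` flags the sentinel).
#' @export
psnr <- function(a, b, max_value = "auto", cap = 99) {
  a <- as_mat(a); b <- as_mat(b)
  if (!all(dim(a) == dim(b))) stop("psnr: shape mismatch")
  mx <- if (identical(max_value, "auto")) max(a, b) else max_value
  if (mx <= 0) stop("psnr: max_value must be > 0")
  mse <- mean((a - b)^2)
  if (mse == 0) return(structure(cap, capped = TRUE))
  structure(10 * log10(mx^2 / mse), capped = FALSE)
}

# population (1/N) moments of a window pair
ssim_window <- function(p, q, d1, d2) {
  mp <- mean(p); mq <- mean(q)
  vp <- mean((p - mp)^2); vq <- mean((q - mq)^2)
  cpq <- mean((p - mp) * (q - mq))
  ((2 * mp * mq + d1) * (2 * cpq + d2)) /
    ((mp^2 + mq^2 + d1) * (vp + vq + d2))
}

#' Structural similarity index between two matrices
#'
#' Windowed SSIM with stabilization constants `D1 = (alpha_c * M)^2` and
#' `D2 = (beta_c * M)^2`, where `M` is the value range. The score is the
#' mean over all sliding windows (uniform weights, stride 1, population
#' moments); matrices smaller than the window fall back to a single global
#' window, which is the plain global-statistic form of the index.
#'
#' @param a,b Matrices or [contact_map()]s of equal dimension.
#' @param max_value Value range `M`; `"auto"` uses the max over both.
#' @param alpha_c,beta_c Stabilization fractions (defaults 0.01 and 0.03).
#' @param window Square window side (default 7).
#' @return Scalar in `[-1, 1]`; 1 iff the matrices are identical.
#' @export
ssim <- function(a, b, max_value = "auto", alpha_c = 0.01, beta_c = 0.03,
                 window = 7L) {
  a <- as_mat(a); b <- as_mat(b)
  if (!all(dim(a) == dim(b))) stop("ssim: shape mismatch")
  mx <- if (identical(max_value, "auto")) max(a, b) else max_value
  if (mx <= 0) mx <- 1  # two all-zero maps: degenerate range, use 1
  d1 <- (alpha_c * mx)^2
  d2 <- (beta_c * mx)^2
  n <- nrow(a)
  w <- min(window, n)
  if (w >= n) return(ssim_window(a, b, d1, d2))
  # local moments via summed-area tables
  loc_sum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT
    cs <- t(cs)
    pad <- matrix(0, n + 1, n + 1)
    pad[2:(n + 1), 2:(n + 1)] <- cs
    k <- n - w + 1
    pad[(w + 1):(n + 1), (w + 1):(n + 1)] - pad[1:k, (w + 1):(n + 1)] -
      pad[(w + 1):(n + 1), 1:k] + pad[1:k, 1:k]
  }
  nw <- w * w
  sa <- loc_sum(a); sb <- loc_sum(b)
  saa <- loc_sum(a * a); sbb <- loc_sum(b * b); sab <- loc_sum(a * b)
  mp <- sa / nw; mq <- sb / nw
  vp <- saa / nw - mp^2; vq <- sbb / nw - mq^2
  cpq <- sab / nw - mp * mq
  vals <- ((2 * mp * mq + d1) * (2 * cpq + d2)) /
    ((mp^2 + mq^2 + d1) * (vp + vq + d2))
  mean(vals)
}

#' GenomeDISCO-style reproducibility score
#'
#' Each map is row-normalized into a random-walk transition matrix (all-zero
#' rows stay zero), raised to the power `t_steps` to smooth local structure,
#' and the score is `1 - sum|A^t - B^t| / mean(nonzero rows of A, B)`.
#' Bounded above by 1; identical maps score exactly 1.
#'
#' @param a,b [contact_map()]s (or matrices) with equal `n_bins`.
#' @param t_steps Random-walk steps (default 3).
#' @return Scalar score `<= 1`.
#' @export
genomedisco <- function(a, b, t_steps = 3L) {
  a <- as_mat(a); b <- as_mat(b)
  if (!all(dim(a) == dim(b))) stop("genomedisco: dimension mismatch")
  if (all(a == 0) && all(b == 0))
    stop("genomedisco: both maps are all-zero; score undefined")
  walk <- function(m) {
    rs <- rowSums(m)
    tm <- m / ifelse(rs == 0, 1, rs)
    tm[rs == 0, ] <- 0
    out <- tm
    for (k in seq_len(t_steps - 1)) out <- out %*% tm
    out
  }
  at <- walk(a); bt <- walk(b)
  nz <- (sum(rowSums(a) > 0) + sum(rowSums(b) > 0)) / 2
  1 - sum(abs(at - bt)) / nz
}

#' Pearson correlation coefficient
#'
#' Linear correlation between two equal-length vectors; the standard
#' product-moment definition. Rejects degenerate (zero-variance) input.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: length mismatch")
  if (length(x) < 2) stop("pearson: need at least 2 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson: zero variance; correlation undefined")
  stats::cor(x, y)
}

# Kabsch: optimal rotation mapping centered q onto centered p.
# Returns list(R, reflected). If allow_reflection, the best orthogonal
# transform (possibly det = -1) is used; otherwise a proper rotation.
kabsch_rotation <- function(p, q, weights = NULL, allow_reflection = TRUE) {
  if (is.null(weights)) weights <- rep(1, nrow(p))
  h <- t(q * weights) %*% p
  sv <- svd(h)
  r <- sv$v %*% t(sv$u)
  reflected <- det(r) < 0
  if (reflected && !allow_reflection) {
    d <- diag(c(1, 1, -1))
    r <- sv$v %*% d %*% t(sv$u)
    reflected <- FALSE
  }
  list(R = r, reflected = reflected)
}

#' Least-squares rigid superposition of two structures
#'
#' Finds the rigid transform (rotation plus translation; reflections
#' allowed by default, since contact data cannot determine chirality)
#' minimizing the RMSD between paired loci, via the SVD-based closed-form
#' solution.
#'
#' @param a,b [structure_3d()]s (or `n x 3` matrices) with equal locus
#'   counts (n >= 3). `b` is superposed onto `a`.
#' @param allow_reflection Permit an improper rotation (default `TRUE`).
#' @return List with `rmsd`, `rotation` (3 x 3), `translation` (length 3;
#'   the transform is `b %*% t(rotation) + translation`), `b_transformed`,
#'   and `reflected`.
#' @export
superpose <- function(a, b, allow_reflection = TRUE) {
  pa <- if (inherits(a, "structure_3d")) a$coords else as.matrix(a)
  pb <- if (inherits(b, "structure_3d")) b$coords else as.matrix(b)
  if (nrow(pa) != nrow(pb)) stop("superpose: locus count mismatch")
  if (nrow(pa) < 3) stop("superpose: need at least 3 loci")
  ca <- colMeans(pa); cb <- colMeans(pb)
  p <- sweep(pa, 2, ca); q <- sweep(pb, 2, cb)
  kr <- kabsch_rotation(p, q, allow_reflection = allow_reflection)
  qr_ <- q %*% t(kr$R)
  rmsd <- sqrt(mean(rowSums((p - qr_)^2)))
  translation <- as.numeric(ca - cb %*% t(kr$R))
  list(rmsd = rmsd, rotation = kr$R, translation = translation,
       b_transformed = sweep(qr_, 2, ca, `+`), reflected = kr$reflected)
}

#' Template-modeling score between two structures
#'
#' `TM = (1/L) * sum(1 / (1 + (d_i/d0)^2))` with
#' `d0 = max(1.24 * (L - 15)^(1/3) - 1.8, d0_min)`, evaluated after a
#' superposition optimized for the TM objective: starting from the
#' least-squares (Kabsch) superposition, the rotation is refined by
#' iteratively reweighted superposition with the TM weights
#' `w_i = (1 + (d_i/d0)^2)^(-2)`; the best score seen is returned.
#' Equal-length structures only; 1 for identical structures.
#'
#' @param a,b [structure_3d()]s (or `n x 3` matrices), equal length L >= 3.
#' @param d0_min Floor on `d0` for short chains (default 0.5).
#' @param allow_reflection Permit improper rotations (default `TRUE`).
#' @param max_refine Reweighting iterations (default 20).
#' @return Scalar in (0, 1].
#' @export
tm_score <- function(a, b, d0_min = 0.5, allow_reflection = TRUE,
                     max_refine = 20L) {
  pa <- if (inherits(a, "structure_3d")) a$coords else as.matrix(a)
  pb <- if (inherits(b, "structure_3d")) b$coords else as.matrix(b)
  if (nrow(pa) != nrow(pb)) stop("tm_score: length mismatch")
  L <- nrow(pa)
  if (L < 3) stop("tm_score: need at least 3 loci")
  d0 <- max(1.24 * sign(L - 15) * abs(L - 15)^(1/3) - 1.8, d0_min)
  ca <- colMeans(pa); cb <- colMeans(pb)
  p <- sweep(pa, 2, ca); q <- sweep(pb, 2, cb)
  score_of <- function(qrot) {
    d2 <- rowSums((p - qrot)^2)
    mean(1 / (1 + d2 / d0^2))
  }
  kr <- kabsch_rotation(p, q, allow_reflection = allow_reflection)
  qrot <- q %*% t(kr$R)
  best <- score_of(qrot)
  w <- NULL
  for (it in seq_len(max_refine)) {
    d2 <- rowSums((p - qrot)^2)
    w_new <- (1 + d2 / d0^2)^(-2)
    # weighted recentering + weighted Kabsch
    cw_p <- colSums(p * w_new) / sum(w_new)
    cw_q <- colSums(qrot * w_new) / sum(w_new)
    pw <- sweep(p, 2, cw_p); qw <- sweep(qrot, 2, cw_q)
    krw <- kabsch_rotation(pw, qw, weights = w_new,
                           allow_reflection = allow_reflection)
    q_new <- sweep(qw %*% t(krw$R), 2, cw_p, `+`)
    s <- score_of(q_new)
    if (s > best + 1e-12) {
      best <- s
      qrot <- q_new
    } else break
  }
  best
}

#' Insulation scores along the diagonal
#'
#' For each interior bin `i` (0-based, `window_bins <= i < n - window_bins`)
#' the mean count in the square window of upstream rows
#' `[i - w, i)` against downstream columns `(i, i + w]` is computed; scores
#' are `log2` of each value over the mean across bins. Minima mark
#' TAD-boundary-like insulation points.
#'
#' @param cm A [contact_map()].
#' @param window_bins Window half-size `w >= 1`; requires
#'   `n_bins > 2 * window_bins`.
#' @param pseudo Small pseudocount guarding `log2(0)` (default 1e-9).
#' @return Numeric vector of length `n_bins - 2 * window_bins`.
#' @export
insulation_scores <- function(cm, window_bins = 5L, pseudo = 1e-9) {
  stopifnot(is_contact_map(cm))
  w <- as.integer(window_bins)
  n <- cm$n_bins
  if (w < 1) stop("insulation_scores: window_bins must be >= 1")
  if (n <= 2 * w) stop("insulation_scores: matrix too small for window")
  m <- cm$matrix
  centers <- w:(n - w - 1)           # 0-based bins with a full window
  v <- vapply(centers, function(i) {
    rows <- (i - w + 1):i            # 1-based: bins i-w .. i-1
    cols <- (i + 2):(i + w + 1)      # 1-based: bins i+1 .. i+w
    mean(m[rows, cols])
  }, numeric(1))
  gm <- mean(v)
  log2((v + pseudo) / (gm + pseudo))
}

#' L2 distance between insulation-score profiles
#'
#' Euclidean norm of the difference of the two maps' insulation-score
#' vectors; lower values mean more consistent TAD-boundary structure.
#'
#' @param a,b [contact_map()]s with equal `n_bins`.
#' @param window_bins Window half-size passed to [insulation_scores()].
#' @return Non-negative scalar.
#' @export
insulation_l2 <- function(a, b, window_bins = 5L) {
  stopifnot(is_contact_map(a), is_contact_map(b))
  if (a$n_bins != b$n_bins) stop("insulation_l2: dimension mismatch")
  sa <- insulation_scores(a, window_bins)
  sb <- insulation_scores(b, window_bins)
  sqrt(sum((sa - sb)^2))
}

#' Full map-pair evaluation report
#'
#' Computes PSNR, SSIM, the GenomeDISCO-style score and insulation-L2 for
#' a pair of maps, recording the conventions used (reference maximum, SSIM
#' window, random-walk steps).
#'
#' @param a,b [contact_map()]s with equal `n_bins`.
#' @param max_value PSNR/SSIM reference maximum (`"auto"` by default).
#' @param window SSIM window side.
#' @param t_steps GenomeDISCO random-walk steps.
#' @param window_bins Insulation window half-size.
#' @return Data frame with one row of metrics and conventions.
#' @export
evaluate_maps <- function(a, b, max_value = "auto", window = 7L,
                          t_steps = 3L, window_bins = 5L) {
  mx <- if (identical(max_value, "auto")) max(as_mat(a), as_mat(b)) else max_value
  ins <- tryCatch(insulation_l2(a, b, window_bins), error = function(e) NA_real_)
  data.frame(
    psnr_db = as.numeric(psnr(a, b, mx)),
    ssim = ssim(a, b, mx, window = window),
    genomedisco = genomedisco(a, b, t_steps),
    insulation_l2 = ins,
    max_value = mx, ssim_window = window, disco_t = t_steps,
    insulation_window = window_bins)
}
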