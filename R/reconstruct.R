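#' Reconstruction configuration
#'
#' Settings for maximum-likelihood 3D structure inference.
#'
#' @param alpha_grid Candidate conversion exponents for [estimate_alpha()]
#'   (default `seq(0.1, 2.0, by = 0.1)`).
#' @param max_iters Maximum gradient-ascent iterations (default 3000).
#' @param learning_rate Initial step size (default 1; the optimizer adapts
#'   it by backtracking).
#' @param tol Convergence threshold on the relative likelihood change
#'   (default 1e-7).
#' @param mse_floor Positive floor on the mean squared deviation inside the
#'   log-likelihood, preventing `log(0)` at a perfect fit (default 1e-12).
#' @param ensemble_size Number of structures for [build_ensemble()]
#'   (default 20).
#' @param alpha_iters Reduced iteration budget per grid point in
#'   [estimate_alpha()] (default 600).
#' @param seed Integer master seed.
#' @return A `recon_config` list.
#' @export
recon_config <- function(alpha_grid = seq(0.1, 2.0, by = 0.1),
                         max_iters = 3000L, learning_rate = 1.0,
                         tol = 1e-7, mse_floor = 1e-12,
                         ensemble_size = 20L, alpha_iters = 600L,
                         seed = 1L) {
  if (length(alpha_grid) == 0 || any(alpha_grid <= 0))
    stop("recon_config: alpha_grid must be non-empty with positive values")
  if (mse_floor <= 0) stop("recon_config: mse_floor must be > 0")
  if (ensemble_size < 1) stop("recon_config: ensemble_size must be >= 1")
  structure(list(alpha_grid = alpha_grid, max_iters = as.integer(max_iters),
                 learning_rate = learning_rate, tol = tol,
                 mse_floor = mse_floor, ensemble_size = as.integer(ensemble_size),
                 alpha_iters = as.integer(alpha_iters), seed = as.integer(seed)),
            class = "recon_config")
}

#' Convert contact frequencies to wish distances
#'
#' Applies the reciprocal power-law convention `X_ij = IF_ij^(-alpha)` to
#' every upper-triangle pair with positive interaction frequency. Pairs
#' with zero frequency carry no distance information at the single-cell
#' level and are excluded; the likelihood's `n` counts included pairs only.
#'
#' @param cm A [contact_map()].
#' @param alpha Positive conversion exponent.
#' @return A `wish_distances` object: data frame `pairs` with 0-based
#'   columns `i`, `j` (`i < j`) and target distance `x`, plus `n_pairs`,
#'   `alpha` and `n_bins`.
#' @export
wish_distances <- function(cm, alpha) {
  stopifnot(is_contact_map(cm))
  if (alpha <= 0) stop("wish_distances: alpha must be > 0")
  m <- cm$matrix
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("wish_distances: no positive contacts in matrix")
  x <- m[idx]^(-alpha)
  structure(list(pairs = data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, x = x),
                 n_pairs = nrow(idx), alpha = alpha, n_bins = cm$n_bins),
            class = "wish_distances")
}

# pairwise distances of the scored pairs
wd_model_distances <- function(coords, wd) {
  di <- coords[wd$pairs$i + 1L, , drop = FALSE] -
        coords[wd$pairs$j + 1L, , drop = FALSE]
  sqrt(rowSums(di * di))
}

#' Log-likelihood of a structure given wish distances
#'
#' `L(S) = -n/2 - n * log(max(mean((Xs - X)^2), mse_floor))`, where `Xs`
#' are the model distances of the scored pairs and `X` the wish distances.
#' Higher is better; the floor keeps the value finite at a perfect fit.
#'
#' @param s A [structure_3d()] covering all bins referenced by `wd`.
#' @param wd A [wish_distances()] object.
#' @param mse_floor Positive floor (default 1e-12).
#' @return Scalar log-likelihood.
#' @export
structure_log_likelihood <- function(s, wd, mse_floor = 1e-12) {
  stopifnot(inherits(s, "structure_3d"), inherits(wd, "wish_distances"))
  ll_from_coords(s$coords, wd, mse_floor)
}

ll_from_coords <- function(coords, wd, mse_floor) {
  ds <- wd_model_distances(coords, wd)
  msd <- mean((ds - wd$pairs$x)^2)
  n <- wd$n_pairs
  -n / 2 - n * log(max(msd, mse_floor))
}

#' Analytic gradient of the structure log-likelihood
#'
#' Gradient of [structure_log_likelihood()] with respect to every
#' coordinate; matches central finite differences. When the mean squared
#' deviation is at or below `mse_floor` the likelihood is flat (the floor
#' is active) and the gradient is zero. Coincident scored pairs are guarded
#' by a small distance floor.
#'
#' @inheritParams structure_log_likelihood
#' @return `n_loci x 3` matrix of partial derivatives.
#' @export
likelihood_gradient <- function(s, wd, mse_floor = 1e-12) {
  stopifnot(inherits(s, "structure_3d"), inherits(wd, "wish_distances"))
  grad_from_coords(s$coords, wd, mse_floor)
}

grad_from_coords <- function(coords, wd, mse_floor) {
  n <- wd$n_pairs
  ii <- wd$pairs$i + 1L
  jj <- wd$pairs$j + 1L
  di <- coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE]
  ds <- sqrt(rowSums(di * di))
  msd <- mean((ds - wd$pairs$x)^2)
  g <- matrix(0, nrow(coords), 3)
  if (msd <= mse_floor) return(g)      # flat region: floor is active
  dsafe <- pmax(ds, 1e-9)              # coincident-pair guard
  # dL/d msd = -n/msd ; d msd/d coords = (2/n) * (ds - x) * d(ds)/d coords
  w <- (-2 / msd) * (ds - wd$pairs$x) / dsafe
  contrib <- di * w
  si <- rowsum(contrib, ii)
  g[as.integer(rownames(si)), ] <- g[as.integer(rownames(si)), ] + si
  sj <- rowsum(contrib, jj)
  g[as.integer(rownames(sj)), ] <- g[as.integer(rownames(sj)), ] - sj
  g
}

#' Infer a 3D structure by gradient ascent on the log-likelihood
#'
#' Coordinates are initialized uniformly at random in a cube whose side is
#' twice the mean wish distance (seeded), then refined by gradient ascent
#' with a backtracking step rule: a step that increases the likelihood is
#' accepted (and the step size grown slightly); a step that decreases it is
#' rejected and the step size halved. Iteration stops when the relative
#' likelihood improvement falls below `tol` or after `max_iters` proposals.
#'
#' @param wd A [wish_distances()] object.
#' @param cfg A [recon_config()].
#' @param seed Integer seed for the random initialization (default
#'   `cfg$seed`).
#' @param max_iters Optional override of `cfg$max_iters`.
#' @return List with `structure` (a [structure_3d()]), `log_likelihood`
#'   (best value seen), and `iterations` (number of proposals evaluated).
#' @export
optimize_structure <- function(wd, cfg = recon_config(), seed = cfg$seed,
                               max_iters = cfg$max_iters) {
  stopifnot(inherits(wd, "wish_distances"))
  n_loci <- wd$n_bins
  set.seed(seed)
  half_side <- mean(wd$pairs$x)
  coords <- matrix(stats::runif(n_loci * 3, -half_side, half_side), n_loci, 3)
  ll <- ll_from_coords(coords, wd, cfg$mse_floor)
  if (!is.finite(ll)) stop("optimize_structure: non-finite initial likelihood")
  step <- cfg$learning_rate
  iter <- 0L
  stall <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    g <- grad_from_coords(coords, wd, cfg$mse_floor)
    gn <- sqrt(sum(g * g))
    if (gn < 1e-12) break
    prop <- coords + step * g / gn          # normalized ascent direction
    ll_new <- ll_from_coords(prop, wd, cfg$mse_floor)
    if (!is.finite(ll_new)) stop("optimize_structure: non-finite likelihood at iteration ", iter)
    if (ll_new > ll) {
      rel <- (ll_new - ll) / (abs(ll) + 1e-12)
      coords <- prop
      ll <- ll_new
      step <- step * 1.2
      stall <- if (rel < cfg$tol) stall + 1L else 0L
      if (stall >= 5L) break
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  list(structure = structure_3d(coords, resolution_bp = 1L, chrom = "recon"),
       log_likelihood = ll, iterations = iter)
}

#' Estimate the contact-to-distance conversion exponent
#'
#' Runs a reduced-budget reconstruction for every alpha on the grid (shared
#' seed, so runs differ only through alpha) and scores each by the Pearson
#' correlation between the reconstructed distances and the wish distances
#' of the scored pairs. Correlation is used rather than raw likelihood
#' because wish-distance scales differ across alpha, making likelihoods
#' incomparable. Ties break toward the smaller alpha.
#'
#' @param cm A [contact_map()].
#' @param cfg A [recon_config()].
#' @return List with `alpha_best` and `table` (data frame of alpha, score,
#'   log-likelihood, iterations; score is `NA` for failed runs).
#' @export
estimate_alpha <- function(cm, cfg = recon_config()) {
  stopifnot(is_contact_map(cm))
  rows <- lapply(cfg$alpha_grid, function(a) {
    res <- tryCatch({
      wd <- wish_distances(cm, a)
      fit <- optimize_structure(wd, cfg, seed = cfg$seed,
                                max_iters = cfg$alpha_iters)
      ds <- wd_model_distances(fit$structure$coords, wd)
      data.frame(alpha = a, score = pearson(ds, wd$pairs$x),
                 log_likelihood = fit$log_likelihood,
                 iterations = fit$iterations)
    }, error = function(e) {
      data.frame(alpha = a, score = NA_real_, log_likelihood = NA_real_,
                 iterations = NA_integer_)
    })
    res
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$score))) stop("estimate_alpha: all grid points failed")
  best <- which(tab$score == max(tab$score, na.rm = TRUE))[1]  # ties: smaller alpha
  list(alpha_best = tab$alpha[best], table = tab)
}

#' Reconstruct an ensemble of structures
#'
#' Runs [optimize_structure()] `cfg$ensemble_size` times at a fixed alpha
#' (estimated from the map unless supplied) with distinct derived seeds.
#'
#' @param cm A [contact_map()].
#' @param cfg A [recon_config()].
#' @param alpha Conversion exponent; `NULL` (default) runs
#'   [estimate_alpha()] first.
#' @return List with `alpha`, `structures` (list of [structure_3d()]),
#'   `log_likelihoods`, and `failures` (count of failed member runs).
#' @export
build_ensemble <- function(cm, cfg = recon_config(), alpha = NULL) {
  stopifnot(is_contact_map(cm))
  if (is.null(alpha)) alpha <- estimate_alpha(cm, cfg)$alpha_best
  wd <- wish_distances(cm, alpha)
  structures <- list()
  lls <- numeric(0)
  failures <- 0L
  for (k in seq_len(cfg$ensemble_size)) {
    fit <- tryCatch(optimize_structure(wd, cfg, seed = cfg$seed + 1000L * k),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    structures[[length(structures) + 1]] <- fit$structure
    lls <- c(lls, fit$log_likelihood)
  }
  if (length(structures) == 0) stop("build_ensemble: every member run failed")
  list(alpha = alpha, structures = structures, log_likelihoods = lls,
       failures = failures)
}

#' Select a representative ensemble member
#'
#' Either the member with the best log-likelihood or the medoid under
#' pairwise TM-score (the member with the highest mean TM-score against
#' all others).
#'
#' @param ensemble Output of [build_ensemble()].
#' @param method `"best_likelihood"` or `"tm_medoid"`.
#' @return The selected [structure_3d()].
#' @export
representative_structure <- function(ensemble,
                                     method = c("best_likelihood", "tm_medoid")) {
  method <- match.arg(method)
  ss <- ensemble$structures
  if (method == "best_likelihood")
    return(ss[[which.max(ensemble$log_likelihoods)]])
  m <- length(ss)
  if (m == 1) return(ss[[1]])
  tm <- matrix(1, m, m)
  for (a in 1:(m - 1)) for (b in (a + 1):m) {
    tm[a, b] <- tm[b, a] <- tm_score(ss[[a]], ss[[b]])
  }
  ss[[which.max(rowMeans(tm))]]
}
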