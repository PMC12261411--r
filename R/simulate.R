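#' Simulation configuration
#'
#' Parameters of the synthetic single-cell Hi-C generator. The generator
#' produces a smooth polymer-like 3D chain, converts it to a contact map via
#' a power-law distance decay, optionally adds Poisson counting noise and
#' TAD-like block enrichment, and derives low-coverage counterparts by
#' binomial read thinning.
#'
#' @param n_loci Number of loci / bins (>= 4).
#' @param alpha_true Conversion exponent relating contacts and distances:
#'   the expected count is `count_scale * d^(-1/alpha_true)`, so the
#'   wish-distance rule `d = IF^(-alpha)` of the reconstruction stage
#'   inverts it exactly when `count_scale = 1` and noise is off.
#' @param count_scale Multiplier on expected counts (sets sequencing depth).
#' @param noise `"none"` for exact expected counts or `"poisson"` for
#'   Poisson-distributed counts.
#' @param thinning_range Length-2 numeric in (0, 1]: the read-retention
#'   probabilities used when generating low-coverage training inputs are
#'   drawn uniformly from this interval (default `c(0.3, 0.95)`).
#' @param tad_blocks Optional list of `c(start_bin, end_bin, enrichment)`
#'   triples (0-based, end exclusive): expected counts inside each diagonal
#'   block are multiplied by `enrichment`.
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 60L, alpha_true = 1.0, count_scale = 1.0,
                       noise = c("none", "poisson"),
                       thinning_range = c(0.3, 0.95),
                       tad_blocks = NULL, seed = 1L) {
  noise <- match.arg(noise)
  if (n_loci < 4) stop("sim_config: n_loci must be >= 4")
  if (alpha_true <= 0) stop("sim_config: alpha_true must be > 0")
  if (count_scale <= 0) stop("sim_config: count_scale must be > 0")
  if (length(thinning_range) != 2 || thinning_range[1] > thinning_range[2] ||
      any(thinning_range <= 0) || any(thinning_range > 1))
    stop("sim_config: thinning_range must be low <= high, both in (0, 1]")
  if (!is.null(tad_blocks)) {
    for (b in tad_blocks) {
      if (length(b) != 3 || b[1] < 0 || b[2] > n_loci || b[1] >= b[2] || b[3] <= 0)
        stop("sim_config: invalid tad_block (need start < end within [0, n_loci), enrichment > 0)")
    }
  }
  structure(list(n_loci = as.integer(n_loci), alpha_true = alpha_true,
                 count_scale = count_scale, noise = noise,
                 thinning_range = thinning_range, tad_blocks = tad_blocks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a smooth polymer-like 3D chain
#'
#' Builds a chain of unit steps whose direction changes by a bounded
#' turning angle at each locus, giving a smooth, locally stiff curve with
#' Hi-C-like distance structure. Deterministic for a given seed.
#'
#' @param config A [sim_config()].
#' @param max_turn_deg Maximum turning angle per step, degrees (default 35).
#' @return A [structure_3d()] with `n_loci` coordinates; consecutive loci
#'   are exactly 1 model unit apart.
#' @export
generate_structure <- function(config, max_turn_deg = 35) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_loci
  set.seed(config$seed)
  coords <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  max_turn <- max_turn_deg * pi / 180
  for (i in 2:n) {
    # perturb direction within the turning cone, then renormalize
    ang <- stats::runif(1, 0, max_turn)
    # random axis orthogonal to current direction
    r <- stats::rnorm(3)
    ax <- r - sum(r * dir) * dir
    nax <- sqrt(sum(ax^2))
    if (nax < 1e-12) ax <- c(-dir[2], dir[1], 0) else ax <- ax / nax
    dir <- cos(ang) * dir + sin(ang) * ax
    dir <- dir / sqrt(sum(dir^2))
    coords[i, ] <- coords[i - 1, ] + dir
  }
  structure_3d(coords, resolution_bp = 1L, chrom = "sim")
}

#' Convert a 3D structure to a synthetic contact map
#'
#' Expected counts follow the reciprocal power law
#' `lambda_ij = count_scale * d_ij^(-1/alpha_true)` for `i != j`
#' (diagonal 0). With `noise = "none"` the map holds the expectations
#' themselves, so the reconstruction stage's wish-distance rule
#' `d = IF^(-alpha)` at `alpha = alpha_true`, `count_scale = 1` recovers
#' the true distances exactly. With `noise = "poisson"` upper-triangle
#' counts are Poisson draws, mirrored. TAD blocks multiply `lambda`
#' inside each diagonal block by its enrichment factor.
#'
#' @param s A [structure_3d()].
#' @param config A [sim_config()].
#' @return A [contact_map()].
#' @export
structure_to_contacts <- function(s, config) {
  stopifnot(inherits(s, "structure_3d"), inherits(config, "sim_config"))
  d <- as.matrix(stats::dist(s$coords))
  n <- nrow(d)
  off <- d[upper.tri(d)]
  if (any(off <= 0)) stop("structure_to_contacts: coincident loci (zero distance)")
  lam <- matrix(0, n, n)
  lam[upper.tri(lam)] <- config$count_scale * off^(-1 / config$alpha_true)
  lam <- lam + t(lam)
  if (!is.null(config$tad_blocks)) {
    for (b in config$tad_blocks) {
      idx <- (b[1] + 1):b[2]
      blk <- lam[idx, idx] * b[3]
      diag(blk) <- 0
      lam[idx, idx] <- blk
    }
  }
  if (config$noise == "poisson") {
    set.seed(config$seed + 1L)
    up <- which(upper.tri(lam))
    cnt <- matrix(0, n, n)
    cnt[up] <- stats::rpois(length(up), lam[up])
    cnt <- cnt + t(cnt)
    lam <- cnt
  }
  contact_map(lam, resolution_bp = s$resolution_bp, chrom = s$chrom)
}

#' Binomial read thinning of a contact map
#'
#' Emulates reduced sequencing depth: each upper-triangle count `c` is
#' replaced by a `Binomial(round(c), retention)` draw and mirrored, so the
#' expected total equals `retention` times the original total.
#'
#' @param cm A [contact_map()] with (near-)integer counts; counts are
#'   rounded before thinning.
#' @param retention Read-retention probability in (0, 1].
#' @param seed Integer seed.
#' @return A thinned [contact_map()].
#' @export
thin_counts <- function(cm, retention, seed = 1L) {
  stopifnot(is_contact_map(cm))
  if (retention <= 0 || retention > 1)
    stop("thin_counts: retention must be in (0, 1]")
  m <- round(cm$matrix)
  if (retention == 1) {
    out <- m
  } else {
    set.seed(seed)
    up <- which(upper.tri(m, diag = TRUE))
    out <- matrix(0, nrow(m), ncol(m))
    out[up] <- stats::rbinom(length(up), m[up], retention)
    out <- out + t(out)
    diag(out) <- diag(out) / 2
  }
  contact_map(out, cm$resolution_bp, cm$chrom, cm$start_bp)
}

#' Build high/low-coverage training pairs
#'
#' Tiles the diagonal band of each input map into square patches (anchored
#' at `(a, a)`, so each patch is itself a symmetric contact map), then pairs
#' every high-coverage (HR) patch with a low-coverage (LR) version obtained
#' by binomial thinning at a retention drawn uniformly from
#' `config$thinning_range`. Seeded and deterministic.
#'
#' @param cms List of [contact_map()]s (the HR maps).
#' @param config A [sim_config()]; supplies `thinning_range` and `seed`.
#' @param patch_side Patch side in bins (default 40).
#' @param stride Patch anchor spacing (default `patch_side`).
#' @return List of pairs, each `list(hr, lr, retention, origin)` where `hr`
#'   and `lr` are `patch_side x patch_side` matrices.
#' @export
make_training_pairs <- function(cms, config, patch_side = 40L,
                                stride = patch_side) {
  stopifnot(length(cms) >= 1, inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  pairs <- list()
  for (cm in cms) {
    stopifnot(is_contact_map(cm))
    n <- cm$n_bins
    if (patch_side > n) stop("make_training_pairs: patch_side exceeds n_bins")
    anchors <- unique(pmin(seq(0L, max(n - patch_side, 0L) + stride - 1L,
                               by = stride), n - patch_side))
    anchors <- anchors[anchors <= n - patch_side]
    for (a in anchors) {
      idx <- (a + 1):(a + patch_side)
      retention <- stats::runif(1, config$thinning_range[1], config$thinning_range[2])
      sub_seed <- sample.int(2^30, 1)
      pcm <- contact_map(round(cm$matrix[idx, idx, drop = FALSE]))
      lr <- thin_counts(pcm, retention, seed = sub_seed)$matrix
      pairs[[length(pairs) + 1]] <-
        list(hr = pcm$matrix, lr = lr, retention = retention, origin = c(a, a))
    }
  }
  pairs
}
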