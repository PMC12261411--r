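#' Contact map objects
#'
#' A `contact_map` holds a single-chromosome Hi-C interaction-frequency
#' matrix together with its genomic binning metadata. The matrix is dense,
#' square, symmetric and non-negative; symmetry is enforced on construction
#' by averaging with the transpose.
#'
#' @param matrix Square numeric matrix of non-negative, finite counts.
#' @param resolution_bp Bin size in base pairs (positive integer).
#' @param chrom Chromosome label.
#' @param start_bp Genomic coordinate of bin 0 (non-negative integer).
#' @return An object of class `contact_map` with fields `matrix`, `n_bins`,
#'   `resolution_bp`, `chrom`, `start_bp`.
#' @examples
#' cm <- contact_map(matrix(c(0, 5, 5, 0), 2, 2))
#' cm$n_bins
#' @export
contact_map <- function(matrix, resolution_bp = 1L, chrom = "chr", start_bp = 0L) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("contact_map: 'matrix' must be a square matrix")
  if (!all(is.finite(matrix)))
    stop("contact_map: all entries must be finite")
  if (any(matrix < 0))
    stop("contact_map: all entries must be >= 0")
  if (resolution_bp <= 0) stop("contact_map: resolution_bp must be positive")
  if (start_bp < 0) stop("contact_map: start_bp must be >= 0")
  m <- symmetrize(matrix)
  structure(
    list(matrix = m, n_bins = nrow(m), resolution_bp = as.integer(resolution_bp),
         chrom = as.character(chrom), start_bp = as.numeric(start_bp)),
    class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  nz <- sum(x$matrix[upper.tri(x$matrix, diag = TRUE)] != 0)
  cat(sprintf("contact_map: %s, %d bins @ %d bp, %d nonzero upper-tri entries, total %.4g\n",
              x$chrom, x$n_bins, x$resolution_bp, nz, sum(x$matrix)))
  invisible(x)
}

is_contact_map <- function(x) inherits(x, "contact_map")

#' Symmetrize a square matrix
#'
#' Returns `(M + t(M)) / 2`. Idempotent; symmetric inputs are unchanged.
#'
#' @param m Square numeric matrix.
#' @return Symmetric matrix of the same dimension.
#' @export
symmetrize <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("symmetrize: input must be square")
  (m + t(m)) / 2
}

#' Read a contact map from sparse triplet text
#'
#' Reads whitespace-separated `bin_i bin_j count` records (0-based bins,
#' `#` comment lines ignored). Duplicate records for the same unordered pair
#' are summed, then the accumulated upper triangle is mirrored so that
#' `(i, j)` and `(j, i)` carry the same total. This accumulation rule makes
#' the round trip with [write_triplet()] exact.
#'
#' @param path Path to the triplet file.
#' @param n_bins Number of bins, or `"auto"` to infer `max index + 1`.
#' @param resolution_bp,chrom,start_bp Metadata passed to [contact_map()].
#' @return A [contact_map()].
#' @export
read_triplet <- function(path, n_bins = "auto", resolution_bp = 1L,
                         chrom = "chr", start_bp = 0L) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    if (identical(n_bins, "auto"))
      stop("read_triplet: empty file needs an explicit n_bins")
    m <- matrix(0, n_bins, n_bins)
    return(contact_map(m, resolution_bp, chrom, start_bp))
  }
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) stop("read_triplet: malformed record at line ", bad[1])
  i <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  j <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(i) || anyNA(j) || anyNA(v))
    stop("read_triplet: non-numeric field at line ",
         which(is.na(i) | is.na(j) | is.na(v))[1])
  if (any(i != floor(i)) || any(j != floor(j)))
    stop("read_triplet: non-integer bin index at line ",
         which(i != floor(i) | j != floor(j))[1])
  if (any(v < 0))
    stop("read_triplet: negative count at line ", which(v < 0)[1])
  if (any(i < 0) || any(j < 0))
    stop("read_triplet: negative bin index at line ", which(i < 0 | j < 0)[1])
  nb <- if (identical(n_bins, "auto")) as.integer(max(i, j) + 1) else as.integer(n_bins)
  if (any(i >= nb) || any(j >= nb))
    stop("read_triplet: bin index exceeds n_bins at line ",
         which(i >= nb | j >= nb)[1])
  m <- matrix(0, nb, nb)
  # accumulate on the unordered pair (upper triangle), then mirror
  lo <- pmin(i, j); hi <- pmax(i, j)
  for (k in seq_along(v)) m[lo[k] + 1, hi[k] + 1] <- m[lo[k] + 1, hi[k] + 1] + v[k]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_map(m, resolution_bp, chrom, start_bp)
}

#' Write a contact map as sparse triplet text
#'
#' Writes nonzero upper-triangle entries (including the diagonal) as
#' tab-separated `bin_i bin_j count` lines, 0-based. [read_triplet()]
#' applied to the output reproduces the matrix exactly.
#'
#' @param cm A [contact_map()].
#' @param path Output path.
#' @export
write_triplet <- function(cm, path) {
  stopifnot(is_contact_map(cm))
  m <- cm$matrix
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(idx)) {
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%.15g", idx[, 1] - 1L, idx[, 2] - 1L,
                       m[idx]), con)
  }
  invisible(NULL)
}

#' Read/write a dense whitespace-separated matrix
#'
#' Dense text interchange: one matrix row per line, whitespace separated.
#'
#' @param path File path.
#' @param resolution_bp,chrom,start_bp Metadata passed to [contact_map()].
#' @return `read_dense` returns a [contact_map()].
#' @export
read_dense <- function(path, resolution_bp = 1L, chrom = "chr", start_bp = 0L) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  contact_map(m, resolution_bp, chrom, start_bp)
}

#' @rdname read_dense
#' @param cm A [contact_map()].
#' @export
write_dense <- function(cm, path) {
  stopifnot(is_contact_map(cm))
  utils::write.table(cm$matrix, path, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Tile a contact map into square patches
#'
#' Deterministic raster-order tiling. Patch anchors along each axis are
#' `min(k * stride, n_bins - side)` for `k = 0, 1, ...`, so the final
#' row/column of patches is pulled back to cover every bin (the last patch
#' may overlap its predecessor).
#'
#' @param cm A [contact_map()].
#' @param side Patch side in bins (default 40).
#' @param stride Anchor spacing in bins (default `side`).
#' @return List of patches; each has `values` (side x side matrix) and
#'   `origin` (0-based `(row, col)` offset into the parent matrix).
#' @export
extract_patches <- function(cm, side = 40L, stride = side) {
  stopifnot(is_contact_map(cm))
  n <- cm$n_bins
  if (side > n) stop("extract_patches: side exceeds n_bins")
  if (stride < 1) stop("extract_patches: stride must be >= 1")
  anchors <- unique(pmin(seq(0L, max(n - side, 0L) + stride - 1L, by = stride),
                         n - side))
  anchors <- anchors[anchors <= n - side]
  out <- vector("list", length(anchors)^2)
  k <- 1L
  for (r in anchors) for (c in anchors) {
    out[[k]] <- list(values = cm$matrix[(r + 1):(r + side), (c + 1):(c + side),
                                        drop = FALSE],
                     origin = c(r, c))
    k <- k + 1L
  }
  out
}

#' Reassemble patches into a full matrix
#'
#' Inverse of [extract_patches()]: patch values are placed at their origins
#' and overlapping regions are averaged. Errors if any bin of the
#' `n_bins x n_bins` target is not covered by at least one patch.
#'
#' @param patches List of patches as produced by [extract_patches()].
#' @param n_bins Side of the output matrix.
#' @return Numeric `n_bins x n_bins` matrix.
#' @export
reassemble <- function(patches, n_bins) {
  acc <- matrix(0, n_bins, n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  for (p in patches) {
    s <- nrow(p$values)
    r <- p$origin[1]; c <- p$origin[2]
    if (r + s > n_bins || c + s > n_bins)
      stop("reassemble: patch exceeds target matrix")
    ri <- (r + 1):(r + s); ci <- (c + 1):(c + s)
    acc[ri, ci] <- acc[ri, ci] + p$values
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0)) stop("reassemble: uncovered bins in target matrix")
  acc / cnt
}

#' Log-scale view of a contact map
#'
#' Elementwise `log10(count + pseudocount)`, for visualization only.
#'
#' @param cm A [contact_map()].
#' @param pseudocount Positive offset added before the log (default 1).
#' @return Matrix of log10-scaled values.
#' @export
log_view <- function(cm, pseudocount = 1) {
  stopifnot(is_contact_map(cm))
  if (pseudocount <= 0) stop("log_view: pseudocount must be > 0")
  log10(cm$matrix + pseudocount)
}
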