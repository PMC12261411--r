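#' 3D chromosome structure objects
#'
#' Ordered 3D coordinates of genomic loci, one point per bin.
#'
#' @param coords Numeric `n_loci x 3` matrix of finite coordinates.
#' @param locus_bins Integer bin indices (0-based); defaults to
#'   `0:(n_loci - 1)`.
#' @param resolution_bp,chrom Provenance metadata.
#' @return An object of class `structure_3d`.
#' @export
structure_3d <- function(coords, locus_bins = NULL, resolution_bp = 1L,
                         chrom = "chr") {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3 || nrow(coords) < 2)
    stop("structure_3d: coords must be an n x 3 matrix with n >= 2")
  if (!all(is.finite(coords))) stop("structure_3d: non-finite coordinates")
  if (is.null(locus_bins)) locus_bins <- 0:(nrow(coords) - 1)
  if (length(locus_bins) != nrow(coords))
    stop("structure_3d: locus_bins length mismatch")
  structure(list(coords = coords, locus_bins = as.integer(locus_bins),
                 resolution_bp = as.integer(resolution_bp),
                 chrom = as.character(chrom)),
            class = "structure_3d")
}

#' @export
print.structure_3d <- function(x, ...) {
  cat(sprintf("structure_3d: %s, %d loci @ %d bp\n",
              x$chrom, nrow(x$coords), x$resolution_bp))
  invisible(x)
}

#' Distance between two probe regions of a structure
#'
#' Euclidean distance between the centroids of the loci in each bin range,
#' in model units. Mirrors FISH-probe distance read-outs on reconstructed
#' structures.
#'
#' @param s A [structure_3d()].
#' @param bin_a_range,bin_b_range Integer vectors of 0-based bin indices
#'   (e.g. `10:14`); must be non-empty and present in `s$locus_bins`.
#' @return Non-negative scalar distance.
#' @export
probe_distance <- function(s, bin_a_range, bin_b_range) {
  stopifnot(inherits(s, "structure_3d"))
  if (length(bin_a_range) == 0 || length(bin_b_range) == 0)
    stop("probe_distance: empty probe range")
  ia <- match(bin_a_range, s$locus_bins)
  ib <- match(bin_b_range, s$locus_bins)
  if (anyNA(ia) || anyNA(ib))
    stop("probe_distance: probe range refers to bins absent from the structure")
  ca <- colMeans(s$coords[ia, , drop = FALSE])
  cb <- colMeans(s$coords[ib, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Write a structure to PDB or XYZ text
#'
#' XYZ format is `bin x y z` per line (full double precision; round-trips
#' exactly through [read_xyz()]). PDB writes one CA pseudo-atom per locus
#' with sequential residue numbers; coordinates are scaled, if necessary,
#' so they fit the fixed-width PDB coordinate fields (the scale used is
#' recorded in a REMARK).
#'
#' @param s A [structure_3d()].
#' @param path Output path.
#' @param format `"xyz"` or `"pdb"`.
#' @export
write_structure <- function(s, path, format = c("xyz", "pdb")) {
  stopifnot(inherits(s, "structure_3d"))
  format <- match.arg(format)
  if (format == "xyz") {
    lines <- sprintf("%d %.17g %.17g %.17g", s$locus_bins,
                     s$coords[, 1], s$coords[, 2], s$coords[, 3])
    writeLines(lines, path)
  } else {
    xyz <- s$coords
    # PDB coordinate field is %8.3f: keep |x| < 9999 after scaling
    mx <- max(abs(xyz))
    scale <- if (mx > 999) 999 / mx else 1
    xyz <- xyz * scale
    n <- nrow(xyz)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("REMARK  chromosome %s resolution %d bp", s$chrom,
                         s$resolution_bp),
                 sprintf("REMARK  coordinate scale factor %.6g", scale)), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3]), con)
    # chain connectivity
    writeLines(sprintf("CONECT%5d%5d", seq_len(n - 1), 2:n), con)
    writeLines("END", con)
  }
  invisible(NULL)
}

#' Read a structure from XYZ text
#'
#' @param path Path to a `bin x y z` file written by [write_structure()].
#' @param resolution_bp,chrom Metadata for the returned object.
#' @return A [structure_3d()].
#' @export
read_xyz <- function(path, resolution_bp = 1L, chrom = "chr") {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("bin", "x", "y", "z"))
  structure_3d(as.matrix(tab[, c("x", "y", "z")]), locus_bins = tab$bin,
               resolution_bp = resolution_bp, chrom = chrom)
}
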