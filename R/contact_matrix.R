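#' Contact matrix container
#'
#' A `ContactMatrix` holds one chromosome's binned Hi-C interaction counts:
#' a symmetric, non-negative square matrix `counts` with one row/column per
#' genomic bin, the bin start coordinates and the bin size (resolution).
#' Entry `counts[i, j]` is the interaction count (or normalized intensity)
#' between bin `i` and bin `j`; the matrix is the weighted adjacency matrix
#' of the chromosome's contact graph.
#'
#' @param counts square symmetric numeric matrix of non-negative, finite
#'   interaction counts. Non-integer values are accepted (normalized
#'   matrices are valid input).
#' @param chrom chromosome name, e.g. `"chr1"`.
#' @param resolution bin size in base pairs.
#' @param starts optional vector of bin start coordinates in bp; must be
#'   strictly increasing with constant step `resolution`. Defaults to
#'   `0, resolution, 2*resolution, ...`.
#'
#' @return An object of class `"ContactMatrix"`: a list with elements
#'   `chrom`, `resolution`, `starts`, `counts`.
#' @export
#' @examples
#' cm <- contact_matrix(matrix(1, 3, 3), chrom = "chrS", resolution = 40000)
#' n_bins(cm)
contact_matrix <- function(counts, chrom, resolution, starts = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(!is.finite(counts))) stop("counts contains NaN or non-finite entries")
  if (any(counts < 0)) stop("negative count in matrix")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-6, check.attributes = FALSE)))
    stop("asymmetric counts matrix")
  resolution <- as.numeric(resolution)
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
    stop("resolution must be a single positive number")
  n <- nrow(counts)
  if (is.null(starts)) {
    starts <- (seq_len(n) - 1) * resolution
  } else {
    starts <- as.numeric(starts)
    if (length(starts) != n) stop("length(starts) must equal the number of bins")
    if (n > 1L && !isTRUE(all.equal(diff(starts), rep(resolution, n - 1L))))
      stop("starts must increase in constant steps of `resolution`")
  }
  dimnames(counts) <- NULL
  structure(
    list(chrom = as.character(chrom)[1L], resolution = resolution,
         starts = starts, counts = counts),
    class = "ContactMatrix"
  )
}

#' @rdname contact_matrix
#' @param x a `ContactMatrix`.
#' @export
n_bins <- function(x) {
  stopifnot(inherits(x, "ContactMatrix"))
  nrow(x$counts)
}

#' Bin end coordinates of a contact matrix
#' @param x a `ContactMatrix`.
#' @return numeric vector of half-open bin end coordinates (`starts + resolution`).
#' @export
bin_ends <- function(x) {
  stopifnot(inherits(x, "ContactMatrix"))
  x$starts + x$resolution
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %s bp (%s-%s)\n",
              x$chrom, n_bins(x), format(x$resolution, big.mark = ","),
              format(min(x$starts), big.mark = ","),
              format(max(bin_ends(x)), big.mark = ",")))
  cat(sprintf("  total counts: %.6g, non-zero: %.1f%%\n",
              sum(x$counts), 100 * mean(x$counts != 0)))
  invisible(x)
}

# internal: check two matrices are comparable bin-for-bin
check_compatible <- function(a, b) {
  if (a$chrom != b$chrom) stop("chromosome mismatch: ", a$chrom, " vs ", b$chrom)
  if (a$resolution != b$resolution) stop("resolution mismatch")
  if (n_bins(a) != n_bins(b)) stop("bin count mismatch")
  if (!isTRUE(all.equal(a$starts, b$starts))) stop("bin coordinate mismatch")
  invisible(TRUE)
}
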