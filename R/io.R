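#' Read a dense text contact matrix
#'
#' Reads a whitespace/tab-delimited n-by-n numeric table as a contact matrix.
#' Tables whose asymmetry is within floating-point noise (relative max
#' discrepancy below `1e-6`) are symmetrized by averaging with the transpose;
#' anything larger is rejected as a corrupt export.
#'
#' @param path path to the text file.
#' @param chrom chromosome name to attach.
#' @param resolution bin size in bp.
#' @param first_start start coordinate in bp of the first bin (default 0).
#' @return a [contact_matrix()].
#' @export
read_dense <- function(path, chrom, resolution, first_start = 0) {
  if (!file.exists(path)) stop("input file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric",
                                   comment.char = "#"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("non-square table: ", nrow(m), " x ", ncol(m))
  if (any(is.na(m))) stop("NaN entries in matrix")
  if (any(m < 0)) stop("negative count in matrix")
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) / scale > 1e-6) stop("asymmetric matrix in ", path)
  m <- (m + t(m)) / 2
  n <- nrow(m)
  contact_matrix(m, chrom = chrom, resolution = resolution,
                 starts = first_start + (seq_len(n) - 1) * resolution)
}

#' Read a sparse triplet contact matrix
#'
#' Reads a 3-column text file (`bin_i  bin_j  count`) and densifies it into a
#' symmetric contact matrix. The first two columns may be 0-based bin
#' *indices* or bin *start coordinates* in bp; coordinates are recognized
#' when any value is `>= resolution` and must then all be multiples of the
#' resolution. Absent pairs are zero. Files that store only one triangle are
#' mirrored; a stored duplicate of the same unordered pair (including a
#' conflicting mirror) is an error.
#'
#' @inheritParams read_dense
#' @param n_bins_total optional total bin count; defaults to the largest bin
#'   index seen plus one.
#' @return a [contact_matrix()].
#' @export
read_triplet <- function(path, chrom, resolution, n_bins_total = NULL,
                         first_start = 0) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  if (!any(nzchar(lines) & !startsWith(lines, "#")))
    stop("no records in ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != 3L) stop("expected 3 columns, got ", ncol(tab))
  bi <- as.numeric(tab[[1L]]); bj <- as.numeric(tab[[2L]])
  cnt <- as.numeric(tab[[3L]])
  if (any(is.na(bi) | is.na(bj) | is.na(cnt))) stop("non-numeric record in ", path)
  if (any(cnt < 0)) stop("negative count in ", path)
  coords <- any(c(bi, bj) >= resolution)
  if (coords) {
    off <- c(bi, bj) - first_start
    if (any(off %% resolution != 0))
      stop("mixed index/coordinate convention: values not multiples of resolution")
    i <- (bi - first_start) / resolution
    j <- (bj - first_start) / resolution
  } else {
    if (any(c(bi, bj) %% 1 != 0)) stop("non-integer bin indices")
    i <- bi; j <- bj
  }
  if (any(i < 0 | j < 0)) stop("negative bin index")
  n <- if (is.null(n_bins_total)) max(i, j) + 1 else n_bins_total
  if (any(i >= n | j >= n)) stop("bin index beyond matrix size")
  # duplicate unordered pairs are corrupt exports
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) stop("duplicate pair record in ", path)
  m <- matrix(0, n, n)
  m[cbind(i + 1, j + 1)] <- cnt
  m[cbind(j + 1, i + 1)] <- cnt
  contact_matrix(m, chrom = chrom, resolution = resolution,
                 starts = first_start + (seq_len(n) - 1) * resolution)
}

#' Read a coordinate-annotated contact matrix
#'
#' Reads the n-by-(n+3) dialect where the first three columns give the
#' chromosome, bin start and bin end, followed by the n-by-n numeric block.
#' The resolution is inferred from the first row's width; all rows must share
#' one chromosome and one bin width.
#'
#' @param path path to the text file.
#' @return a [contact_matrix()].
#' @export
read_coordinate_matrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != nrow(tab) + 3L)
    stop("expected n x (n+3) table, got ", nrow(tab), " x ", ncol(tab))
  chroms <- as.character(tab[[1L]])
  if (length(unique(chroms)) != 1L) stop("mixed chromosomes in ", path)
  starts <- as.numeric(tab[[2L]]); ends <- as.numeric(tab[[3L]])
  widths <- ends - starts
  if (any(widths != widths[1L])) stop("non-constant bin width in ", path)
  m <- as.matrix(tab[, -(1:3), drop = FALSE])
  dimnames(m) <- NULL
  if (any(is.na(m))) stop("NaN entries in matrix")
  if (any(m < 0)) stop("negative count in matrix")
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) / scale > 1e-6) stop("asymmetric matrix in ", path)
  m <- (m + t(m)) / 2
  contact_matrix(m, chrom = chroms[1L], resolution = widths[1L], starts = starts)
}

#' Write a dense contact matrix to text
#' @param x a `ContactMatrix`.
#' @param path output path.
#' @export
write_dense <- function(x, path) {
  stopifnot(inherits(x, "ContactMatrix"))
  utils::write.table(x$counts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED interval track
#'
#' Reads the first three columns of a BED file (chrom, start, end; 0-based
#' half-open) into an interval track data frame. Header lines starting with
#' `#`, `track` or `browser` are skipped.
#'
#' @param path path to the BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, sorted within
#'   chromosome.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  tab <- utils::read.table(text = lines, header = FALSE)
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.numeric(tab[[2L]]),
                    end = as.numeric(tab[[3L]]))
  if (any(out$start >= out$end)) stop("BED interval with start >= end")
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Write a result table as a BED-style file
#'
#' Writes any per-bin result data frame whose first three columns are
#' `chrom`, `start`, `end` (0-based half-open) as a tab-delimited file with a
#' single `#`-prefixed header line. Numeric score columns are printed with 6
#' significant digits.
#'
#' @param table a data frame; first three columns must be chrom/start/end.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (ncol(table) < 3L) stop("result table needs chrom/start/end columns")
  out <- table
  for (k in seq_along(out)) {
    if (is.double(out[[k]])) out[[k]] <- signif(out[[k]], 6)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  if (nrow(out) > 0L) {
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read back a BED-style result table written by [write_results()]
#' @param path path to the file.
#' @return data.frame with the original column names.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  header <- sub("^#", "", readLines(path, n = 1L))
  nms <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  lines <- readLines(path)[-1L]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(nms)))
    names(out) <- nms
    return(out)
  }
  tab <- utils::read.table(text = lines, header = FALSE, sep = "\t",
                           na.strings = "NA")
  names(tab) <- nms
  tab
}
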