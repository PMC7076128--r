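#' Analysis parameters for boundary comparison
#'
#' Bundles the tunable thresholds of the method with their standard
#' defaults: sliding window of 15 bins, boundary score cutoff of 3,
#' differential boundary score cutoff of 2 (two-sided standard-normal tail
#' below 0.05), shift window of 5 bins, and informative-bin fraction 0.2.
#'
#' @param w sliding window size in bins.
#' @param t_b boundary score cutoff.
#' @param t_d differential boundary score cutoff (absolute value).
#' @param s shift window: a one-sided boundary within `s` bins of a boundary
#'   in the other matrix is classified as Shifted.
#' @param frac minimum fraction of non-zero in-window interactions for a bin
#'   to be informative.
#' @param flank flank in bp added to each side of a boundary bin for
#'   colocalization testing.
#' @param n_perm number of permutations for the colocalization test.
#' @param sd_type SD convention for the log-gap fit.
#' @return list of class `"hic_params"`.
#' @export
hic_params <- function(w = 15, t_b = 3, t_d = 2, s = 5, frac = 0.2,
                       flank = 50000, n_perm = 10000,
                       sd_type = c("population", "sample")) {
  stopifnot(t_b > 0, t_d > 0, s >= 1, w >= 5, frac >= 0, frac < 1,
            flank >= 0, n_perm >= 1)
  structure(list(w = w, t_b = t_b, t_d = t_d, s = s, frac = frac,
                 flank = flank, n_perm = n_perm,
                 sd_type = match.arg(sd_type)),
            class = "hic_params")
}

#' Nominal false-positive rate of the differential threshold
#'
#' The differential boundary score is N(0, 1) when nothing changes, so
#' calling a bin differential when `|DB| >= t_d` has the two-sided
#' standard-normal tail probability as its nominal per-bin false-positive
#' rate. At the default `t_d = 2` this is about 0.0455, i.e. below 0.05.
#'
#' @param t_d differential score threshold (default 2).
#' @return the two-sided tail probability `2 * (1 - pnorm(t_d))`.
#' @export
differential_tail_prob <- function(t_d = 2) {
  2 * stats::pnorm(t_d, lower.tail = FALSE)
}

#' Differential boundary scores between two gap profiles
#'
#' With `ln(D_P) ~ N(mu_P, sigma2_P)` and `ln(D_R) ~ N(mu_R, sigma2_R)`, the
#' per-bin difference of log eigenvector gaps is normal, giving the
#' standardized differential boundary score
#' `DB_i = ((ln D_P,i - ln D_R,i) - (mu_P - mu_R)) / sqrt(sigma2_P + sigma2_R)`,
#' approximately N(0, 1) when the boundary landscape does not change. The
#' statistic is antisymmetric in its arguments. Profiles must be aligned on
#' identical retained bins (use [harmonize_masks()] first); placeholders
#' propagate as `NA`.
#'
#' @param gaps_P,gaps_R `"gap_profile"` objects (or numeric gap vectors with
#'   `NA` placeholders) for the two matrices, first argument = matrix of
#'   interest, second = reference.
#' @inheritParams scores_from_gaps
#' @return numeric vector of per-bin differential scores.
#' @export
differential_scores <- function(gaps_P, gaps_R,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  gp <- if (inherits(gaps_P, "gap_profile")) gaps_P$gaps else as.numeric(gaps_P)
  gr <- if (inherits(gaps_R, "gap_profile")) gaps_R$gaps else as.numeric(gaps_R)
  if (length(gp) != length(gr)) stop("gap profiles have different lengths")
  if (!identical(which(is.na(gp)), which(is.na(gr))))
    stop("misaligned profiles: harmonize masks before comparing")
  fp <- log_gap_fit(gp, sd_type)
  fr <- log_gap_fit(gr, sd_type)
  pooled <- fp$sigma2 + fr$sigma2
  if (pooled == 0) stop("degenerate profiles: zero pooled variance")
  db <- rep(NA_real_, length(gp))
  db[fp$defined] <- ((fp$log_gaps - fr$log_gaps) - (fp$mu - fr$mu)) / sqrt(pooled)
  db
}

# category labels, fixed order for factors
.categories <- c("Complex", "Split", "Merge", "Shifted", "StrengthChange",
                 "NonDifferential", "NonBoundary")

#' Classify per-bin boundary changes between two matrices
#'
#' Applies the five-type change taxonomy bin by bin given the two boundary
#' flag vectors and the differential scores. With
#' `is_diff = (|DB| >= t_d)`:
#'
#' 1. no boundary in either matrix: `NonBoundary`;
#' 2. boundary in both: `StrengthChange` if differential, else
#'    `NonDifferential`;
#' 3. boundary in exactly one matrix, not differential: `NonDifferential`;
#' 4. boundary in exactly one matrix and differential:
#'    (a) `Shifted` when the other matrix has a boundary at a different bin
#'    within `s` bins; (b) otherwise, when the nearest flagged bins on both
#'    sides are shared non-differential boundaries (present in both
#'    matrices), the bin is `Merge` if its boundary exists only in the
#'    reference `R` (it disappeared in `P`, merging `P`'s domains) and
#'    `Split` if it exists only in `P`; (c) otherwise `Complex`.
#'
#' Shifted takes precedence over Merge/Split/Complex; swapping the arguments
#' exchanges Merge and Split labels and leaves all other labels unchanged.
#'
#' @param flags_P,flags_R logical boundary flags for the matrix of interest
#'   `P` and the reference `R` (`NA` treated as no boundary).
#' @param diff per-bin differential boundary scores `DB` (P vs R).
#' @param params an [hic_params()] object (uses `t_d` and `s`).
#' @return character vector of per-bin categories.
#' @export
classify_pairwise <- function(flags_P, flags_R, diff, params = hic_params()) {
  n <- length(flags_P)
  if (length(flags_R) != n || length(diff) != n)
    stop("flag/score vectors have different lengths")
  fp <- !is.na(flags_P) & flags_P
  fr <- !is.na(flags_R) & flags_R
  is_diff <- !is.na(diff) & abs(diff) >= params$t_d
  any_flag <- fp | fr
  shared_nd <- fp & fr & !is_diff   # eligible flank: shared non-differential boundary

  out <- rep("NonBoundary", n)
  out[fp & fr] <- ifelse(is_diff[fp & fr], "StrengthChange", "NonDifferential")
  one_sided <- xor(fp, fr)
  out[one_sided & !is_diff] <- "NonDifferential"

  for (i in which(one_sided & is_diff)) {
    other <- if (fp[i]) fr else fp
    lo <- max(1L, i - params$s); hi <- min(n, i + params$s)
    near <- lo:hi
    near <- near[near != i]
    if (any(other[near])) {
      out[i] <- "Shifted"
      next
    }
    left <- if (i > 1L) rev(which(any_flag[seq_len(i - 1L)])) else integer()
    right <- which(any_flag) ; right <- right[right > i]
    if (length(left) && length(right) &&
        shared_nd[left[1L]] && shared_nd[right[1L]]) {
      out[i] <- if (fr[i]) "Merge" else "Split"
    } else {
      out[i] <- "Complex"
    }
  }
  out
}

#' Compare TAD boundaries between two contact matrices
#'
#' Runs the full two-matrix differential pipeline: jointly mask
#' non-informative bins, compute sliding-window eigenvector gap profiles and
#' boundary scores for each matrix, form the differential boundary score
#' `DB`, call boundaries at `t_b`, and classify every retained bin into the
#' change taxonomy (Complex, Split, Merge, Shifted, StrengthChange,
#' NonDifferential, NonBoundary). The first argument `P` is the matrix of
#' interest and the second `R` the reference: `Split` means a boundary
#' present only in `P`, `Merge` a boundary present only in `R`.
#'
#' @param P,R `ContactMatrix` objects on the same chromosome, resolution and
#'   bins.
#' @param params an [hic_params()] object.
#' @return object of class `"tad_comparison"`: list with `table` (per-bin
#'   data.frame: chrom, start, end, gap_P, gap_R, score_P, score_R,
#'   diff_score, boundary_P, boundary_R, category), `params`, and the two
#'   fitted `"boundary_scores"` objects.
#' @export
#' @examples
#' spec <- simulation_spec(n = 60, boundaries = c(20, 40), seed = 1)
#' P <- simulate_matrix(spec)
#' cmp <- tad_compare(P, P)
#' summary(cmp)
tad_compare <- function(P, R, params = hic_params()) {
  check_compatible(P, R)
  mask <- harmonize_masks(informative_mask(P, w = params$w, frac = params$frac),
                          informative_mask(R, w = params$w, frac = params$frac))
  gp <- windowed_gap_profile(P, mask = mask, w = params$w)
  gr <- windowed_gap_profile(R, mask = mask, w = params$w)
  sp <- scores_from_gaps(gp, sd_type = params$sd_type)
  sr <- scores_from_gaps(gr, sd_type = params$sd_type)
  db <- differential_scores(gp, gr, sd_type = params$sd_type)
  flags_P <- call_boundaries(sp, params$t_b)
  flags_R <- call_boundaries(sr, params$t_b)
  category <- classify_pairwise(flags_P, flags_R, db, params)
  category[!mask] <- NA_character_

  keep <- which(mask)
  table <- data.frame(
    chrom = P$chrom,
    start = P$starts[keep],
    end = P$starts[keep] + P$resolution,
    bin = keep,
    gap_P = gp$gaps[keep], gap_R = gr$gaps[keep],
    score_P = sp$scores[keep], score_R = sr$scores[keep],
    diff_score = db[keep],
    boundary_P = flags_P[keep], boundary_R = flags_R[keep],
    category = category[keep],
    stringsAsFactors = FALSE
  )
  structure(list(table = table, params = params, scores_P = sp, scores_R = sr,
                 mask = mask),
            class = "tad_comparison")
}

#' @export
print.tad_comparison <- function(x, ...) {
  tab <- x$table
  cat(sprintf("tad_comparison: %s, %d retained bins\n", tab$chrom[1], nrow(tab)))
  counts <- table(factor(tab$category, levels = .categories))
  print(counts)
  invisible(x)
}

#' @export
summary.tad_comparison <- function(object, ...) {
  tab <- object$table
  counts <- table(factor(tab$category, levels = .categories))
  n_bound <- sum(tab$boundary_P | tab$boundary_R)
  diff_cats <- c("Complex", "Split", "Merge", "Shifted", "StrengthChange")
  n_diff <- sum(tab$category %in% diff_cats)
  out <- list(chrom = tab$chrom[1], n_bins = nrow(tab), counts = counts,
              n_boundaries = n_bound, n_differential = n_diff,
              prop_differential = if (n_bound > 0) n_diff / n_bound else NA_real_,
              params = object$params)
  class(out) <- "summary.tad_comparison"
  out
}

#' @export
print.summary.tad_comparison <- function(x, ...) {
  cat(sprintf("Differential boundary analysis (%s): %d retained bins\n",
              x$chrom, x$n_bins))
  cat(sprintf("  boundaries in at least one matrix: %d\n", x$n_boundaries))
  cat(sprintf("  differential boundaries: %d (%.1f%% of boundaries)\n",
              x$n_differential, 100 * x$prop_differential))
  print(x$counts)
  invisible(x)
}

#' @export
plot.tad_comparison <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$start, tab$score_P, type = "l", col = "steelblue",
                 xlab = "bin start (bp)", ylab = "boundary score",
                 main = "Boundary scores", ...)
  graphics::lines(tab$start, tab$score_R, col = "darkorange")
  graphics::abline(h = x$params$t_b, lty = 2)
  graphics::legend("topright", c("P", "R"), col = c("steelblue", "darkorange"),
                   lty = 1, bty = "n")
  diff_cats <- c("Complex", "Split", "Merge", "Shifted", "StrengthChange")
  hit <- tab$category %in% diff_cats
  graphics::plot(tab$start, tab$diff_score, type = "h",
                 col = ifelse(hit, "red", "grey50"),
                 xlab = "bin start (bp)", ylab = "differential score",
                 main = "Differential boundary score")
  graphics::abline(h = c(-x$params$t_d, x$params$t_d), lty = 2)
  invisible(x)
}

#' Result table of a comparison as a BED-compatible data frame
#'
#' @param x a `"tad_comparison"`, `"tad_consensus"` or `"tad_timecourse"`
#'   object.
#' @param ... unused.
#' @return data.frame whose first three columns are chrom/start/end, ready
#'   for [write_results()].
#' @export
as.data.frame.tad_comparison <- function(x, ...) x$table
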