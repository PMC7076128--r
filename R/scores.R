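# internal: fit the log-normal location/scale of a gap profile.
# Zero gaps cannot be logged; they are floored to the smallest positive
# defined gap (with a warning) so the fit stays defined.
log_gap_fit <- function(gaps, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  defined <- which(!is.na(gaps))
  g <- gaps[defined]
  if (any(g == 0)) {
    pos <- g[g > 0]
    if (length(pos) == 0L) stop("degenerate profile: all gaps are zero")
    warning(sum(g == 0), " zero gap(s) floored to the minimum positive gap")
    g[g == 0] <- min(pos)
  }
  if (length(g) < 3L) stop("need at least 3 defined positive gaps")
  lg <- log(g)
  mu <- mean(lg)
  var <- if (sd_type == "population") mean((lg - mu)^2) else stats::var(lg)
  if (var == 0) stop("degenerate profile: zero variance of log gaps")
  list(log_gaps = lg, defined = defined, mu = mu, sigma2 = var,
       sigma = sqrt(var), sd_type = sd_type)
}

#' Boundary scores from an eigenvector gap profile
#'
#' Eigenvector gaps are well approximated by a log-normal distribution, so
#' the natural log of the gaps is standardized into a Z-score: the boundary
#' score `B_i = (ln(gap_i) - mu) / sigma`, where `mu` and `sigma` are the
#' location and scale of the log gaps fitted on this profile. Scores are
#' approximately N(0, 1); a large positive score marks a likely domain
#' boundary and its magnitude is directly interpretable as boundary
#' strength.
#'
#' Zero gaps (identical consecutive projected eigenvector rows) are floored
#' to the smallest positive gap before taking logs, with a warning.
#'
#' @param profile a `"gap_profile"` from [windowed_gap_profile()], or a
#'   plain numeric gap vector (`NA` = placeholder).
#' @param sd_type `"population"` (divide by N; the default — scores are
#'   descriptive standardizations) or `"sample"` (divide by N-1).
#' @return object of class `"boundary_scores"`: list with `scores` (numeric,
#'   `NA` propagated from placeholders), `gaps`, `mu`, `sigma`, `sd_type`,
#'   and the profile's coordinates when available.
#' @export
#' @examples
#' sc <- scores_from_gaps(c(NA, exp(0), exp(1), exp(2)))
#' sc$scores
scores_from_gaps <- function(profile, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (inherits(profile, "gap_profile")) {
    gaps <- profile$gaps
    meta <- profile[c("chrom", "starts", "resolution", "mask", "w")]
  } else {
    gaps <- as.numeric(profile)
    meta <- NULL
  }
  fit <- log_gap_fit(gaps, sd_type)
  scores <- rep(NA_real_, length(gaps))
  scores[fit$defined] <- (fit$log_gaps - fit$mu) / fit$sigma
  structure(
    c(list(scores = scores, gaps = gaps, mu = fit$mu, sigma = fit$sigma,
           sd_type = sd_type), meta),
    class = "boundary_scores"
  )
}

#' Call boundaries from boundary scores
#'
#' A bin is a boundary when its boundary score is at least `t_b` (default 3).
#' The call is one-sided: boundaries are bins with unusually *large*
#' eigenvector gaps; large negative scores mean a very smooth contact
#' pattern, never a boundary. `NA` scores (placeholders, masked bins) are
#' never boundaries.
#'
#' @param scores a `"boundary_scores"` object or numeric score vector.
#' @param t_b boundary score cutoff (default 3).
#' @return logical vector of per-bin boundary flags.
#' @export
call_boundaries <- function(scores, t_b = 3) {
  s <- if (inherits(scores, "boundary_scores")) scores$scores else as.numeric(scores)
  flag <- !is.na(s) & s >= t_b
  flag
}

#' Boundary scores for one contact matrix
#'
#' Convenience wrapper running the full single-matrix pipeline: informative
#' bin masking, sliding-window eigenvector gaps and log-normal
#' standardization into boundary scores.
#'
#' @param C a `ContactMatrix`.
#' @param w sliding window size in bins (default 15).
#' @param frac informative-bin threshold (default 0.2).
#' @param mask optional externally harmonized mask.
#' @inheritParams scores_from_gaps
#' @return a `"boundary_scores"` object.
#' @export
boundary_scores <- function(C, w = 15, frac = 0.2, mask = NULL,
                            sd_type = c("population", "sample")) {
  if (is.null(mask)) mask <- informative_mask(C, w = w, frac = frac)
  scores_from_gaps(windowed_gap_profile(C, mask = mask, w = w),
                   sd_type = match.arg(sd_type))
}

#' @export
print.boundary_scores <- function(x, ...) {
  n <- length(x$scores)
  cat(sprintf("boundary_scores: %d bins, %d scored; log-gap fit mu=%.4f sigma=%.4f (%s SD)\n",
              n, sum(!is.na(x$scores)), x$mu, x$sigma, x$sd_type))
  cat(sprintf("  boundaries at cutoff 3: %d\n", sum(call_boundaries(x))))
  invisible(x)
}

#' @export
summary.boundary_scores <- function(object, t_b = 3, ...) {
  s <- object$scores
  out <- list(
    n_bins = length(s), n_scored = sum(!is.na(s)),
    mu = object$mu, sigma = object$sigma,
    score_range = range(s, na.rm = TRUE),
    n_boundaries = sum(call_boundaries(object, t_b)), t_b = t_b
  )
  class(out) <- "summary.boundary_scores"
  out
}

#' @export
print.summary.boundary_scores <- function(x, ...) {
  cat(sprintf("Boundary score summary: %d/%d bins scored\n", x$n_scored, x$n_bins))
  cat(sprintf("  log-gap fit: mu=%.4f sigma=%.4f\n", x$mu, x$sigma))
  cat(sprintf("  score range: [%.3f, %.3f]\n", x$score_range[1], x$score_range[2]))
  cat(sprintf("  boundaries (score >= %g): %d\n", x$t_b, x$n_boundaries))
  invisible(x)
}

#' @export
plot.boundary_scores <- function(x, t_b = 3, ...) {
  pos <- if (!is.null(x$starts)) x$starts else seq_along(x$scores) - 1
  graphics::plot(pos, x$scores, type = "h", xlab = "bin start (bp)",
                 ylab = "boundary score", ...)
  graphics::abline(h = t_b, col = "red", lty = 2)
  hits <- which(call_boundaries(x, t_b))
  if (length(hits)) graphics::points(pos[hits], x$scores[hits], col = "red", pch = 19)
  invisible(x)
}
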