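#' Per-time-point boundary presence from replicated scores
#'
#' For each ordered time point, replicate boundary scores collapse to their
#' per-bin median (the consensus boundary score); a boundary is present at
#' that time point when the median is at least `t_b`. Needs at least 3 time
#' points; all score vectors must be aligned on a joint mask.
#'
#' @param scores_by_timepoint time-ordered list; each element is a list of
#'   one or more aligned replicate score vectors (or `"boundary_scores"`
#'   objects) for that time point.
#' @param t_b boundary score cutoff (default 3).
#' @return list with `presence` (bins x time points logical matrix) and
#'   `consensus` (bins x time points numeric matrix of median scores).
#' @export
presence_matrix <- function(scores_by_timepoint, t_b = 3) {
  if (!is.list(scores_by_timepoint) || length(scores_by_timepoint) < 3L)
    stop("need at least 3 time points")
  cons <- lapply(scores_by_timepoint, function(reps) {
    if (!is.list(reps)) reps <- list(reps)
    if (length(reps) == 1L) {
      v <- reps[[1L]]
      if (inherits(v, "boundary_scores")) v$scores else as.numeric(v)
    } else {
      consensus_scores(reps)
    }
  })
  len <- lengths(cons)
  if (length(unique(len)) != 1L) stop("misaligned score vectors across time points")
  cmat <- do.call(cbind, cons)
  colnames(cmat) <- paste0("t", seq_len(ncol(cmat)))
  pres <- !is.na(cmat) & cmat >= t_b
  list(presence = pres, consensus = cmat)
}

# exact 4-time-point lookup (Table-style taxonomy): keys are presence
# strings, values the temporal pattern. Patterns not listed are Dynamic.
.temporal_lookup4 <- c(
  "1111" = "HighlyCommon", "1011" = "HighlyCommon",
  "0111" = "EarlyAppearing",
  "1000" = "EarlyDisappearing",
  "0011" = "LateAppearing", "0001" = "LateAppearing",
  "1100" = "LateDisappearing", "1110" = "LateDisappearing"
)

#' Classify a temporal boundary-presence pattern
#'
#' Maps a boundary's presence/absence vector over ordered time points to
#' one of six temporal patterns: `HighlyCommon`, `EarlyAppearing`,
#' `EarlyDisappearing`, `LateAppearing`, `LateDisappearing` or `Dynamic`.
#' For exactly 4 time points the published exact lookup is used (1111 and
#' 1011 are highly common; any 4-point pattern not in the lookup, e.g. 1010
#' or 1101, is `Dynamic`). For other lengths the general rules apply, tried
#' in order: highly common = present at the first and last time point and in
#' at least `T - 1` time points overall; early appearing = absent at t1 then
#' present from t2 on; early disappearing = present at t1 only; late
#' appearing = presence starting only at the last or second-to-last time
#' point; late disappearing = presence ending at the second-to-last or
#' third-to-last time point; anything else is dynamic.
#'
#' @param presence logical (or 0/1) vector of length >= 3 with at least one
#'   `TRUE` entry.
#' @return a single pattern string.
#' @export
#' @examples
#' classify_temporal(c(0, 1, 1, 1))  # "EarlyAppearing"
#' classify_temporal(c(1, 0, 1, 0))  # "Dynamic"
classify_temporal <- function(presence) {
  p <- as.logical(presence)
  T_ <- length(p)
  if (T_ < 3L) stop("need at least 3 time points")
  if (any(is.na(p))) stop("presence vector contains NA")
  if (!any(p)) stop("all-absent pattern is not a union boundary")
  if (T_ == 4L) {
    key <- paste(as.integer(p), collapse = "")
    hit <- .temporal_lookup4[key]
    return(if (is.na(hit)) "Dynamic" else unname(hit))
  }
  first_on <- which(p)[1L]
  last_on <- which(p)[sum(p)]
  contiguous_on <- all(p[first_on:last_on])
  if (p[1L] && p[T_] && sum(p) >= T_ - 1L) return("HighlyCommon")
  if (!p[1L] && first_on == 2L && contiguous_on && last_on == T_)
    return("EarlyAppearing")
  if (p[1L] && sum(p) == 1L) return("EarlyDisappearing")
  if (first_on >= T_ - 1L && contiguous_on && last_on == T_)
    return("LateAppearing")
  if (first_on == 1L && contiguous_on &&
      last_on >= T_ - 2L && last_on <= T_ - 1L)
    return("LateDisappearing")
  "Dynamic"
}

#' Time-course analysis of boundary dynamics
#'
#' Tracks boundary-score trajectories across ordered time points (each
#' possibly replicated), takes the union of boundaries over time points, and
#' classifies each union boundary's presence trajectory into one of the six
#' temporal patterns. All matrices are jointly masked so bins compare
#' one-to-one across the course.
#'
#' @param matrices_by_timepoint time-ordered list (length >= 3); each
#'   element a `ContactMatrix` or a list of replicate `ContactMatrix`
#'   objects for that time point.
#' @param params an [hic_params()] object.
#' @return object of class `"tad_timecourse"`: list with `table` (one row
#'   per union-boundary bin: chrom, start, end, bin, per-time-point
#'   consensus scores, presence string, pattern), `consensus` and
#'   `presence` matrices over all retained bins, `params`, `mask`.
#' @export
tad_timecourse <- function(matrices_by_timepoint, params = hic_params()) {
  if (!is.list(matrices_by_timepoint) || length(matrices_by_timepoint) < 3L)
    stop("need at least 3 time points")
  tps <- lapply(matrices_by_timepoint, function(x)
    if (inherits(x, "ContactMatrix")) list(x) else x)
  all_m <- unlist(tps, recursive = FALSE)
  for (m in all_m[-1L]) check_compatible(all_m[[1L]], m)
  masks <- lapply(all_m, informative_mask, w = params$w, frac = params$frac)
  mask <- harmonize_masks(masks)
  if (sum(mask) < params$w)
    stop("joint mask leaves fewer bins than the window size")

  scores_by_tp <- lapply(tps, function(reps)
    lapply(reps, boundary_scores, w = params$w, mask = mask,
           sd_type = params$sd_type))
  pm <- presence_matrix(scores_by_tp, t_b = params$t_b)

  ref <- all_m[[1L]]
  union_bins <- which(rowSums(pm$presence) > 0)
  pattern <- vapply(union_bins, function(i)
    classify_temporal(pm$presence[i, ]), character(1L))
  cmat <- pm$consensus[union_bins, , drop = FALSE]
  colnames(cmat) <- paste0("score_", colnames(pm$presence))
  table <- data.frame(
    chrom = ref$chrom, start = ref$starts[union_bins],
    end = ref$starts[union_bins] + ref$resolution, bin = union_bins,
    cmat,
    presence = apply(pm$presence[union_bins, , drop = FALSE], 1L,
                     function(z) paste(as.integer(z), collapse = "")),
    pattern = pattern,
    stringsAsFactors = FALSE
  )
  rownames(table) <- NULL
  structure(list(table = table, consensus = pm$consensus,
                 presence = pm$presence, params = params, mask = mask),
            class = "tad_timecourse")
}

#' @export
print.tad_timecourse <- function(x, ...) {
  cat(sprintf("tad_timecourse: %d time points, %d union boundaries\n",
              ncol(x$presence), nrow(x$table)))
  lv <- c("HighlyCommon", "EarlyAppearing", "EarlyDisappearing",
          "LateAppearing", "LateDisappearing", "Dynamic")
  print(table(factor(x$table$pattern, levels = lv)))
  invisible(x)
}

#' @export
as.data.frame.tad_timecourse <- function(x, ...) x$table

#' @export
plot.tad_timecourse <- function(x, ...) {
  lv <- c("HighlyCommon", "EarlyAppearing", "EarlyDisappearing",
          "LateAppearing", "LateDisappearing", "Dynamic")
  pat <- factor(x$table$pattern, levels = lv)
  cols <- grep("^score_t", names(x$table))
  avg <- stats::aggregate(x$table[cols], by = list(pattern = pat), FUN = mean,
                          drop = FALSE)
  tmat <- as.matrix(avg[, -1L, drop = FALSE])
  graphics::matplot(t(tmat), type = "b", pch = 19, lty = 1,
                    xlab = "time point", ylab = "mean consensus score", ...)
  graphics::abline(h = x$params$t_b, lty = 2, col = "red")
  graphics::legend("topleft", legend = avg$pattern, col = seq_len(nrow(avg)),
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
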