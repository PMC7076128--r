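#' Consensus boundary scores across replicates
#'
#' The consensus boundary score of a bin is the median of its boundary
#' scores across replicate Hi-C matrices; a high consensus score marks a
#' boundary supported by evidence from multiple replicates, in contrast to
#' the union, where boundaries detected in any single replicate are pooled.
#' An even number of replicates uses the midpoint median. `NA` propagates:
#' bins must be aligned on a joint mask.
#'
#' @param score_vectors list (one element per replicate, >= 2) of aligned
#'   per-bin score vectors, or of `"boundary_scores"` objects.
#' @return numeric vector of per-bin median scores.
#' @export
#' @examples
#' consensus_scores(list(c(3, 1), c(2, 2), c(1, 1)))  # 2, 1
consensus_scores <- function(score_vectors) {
  mat <- score_matrix(score_vectors, min_k = 2L)
  apply(mat, 1L, stats::median)
}

# internal: bind replicate score vectors into a bins x replicates matrix
score_matrix <- function(score_vectors, min_k = 1L) {
  if (!is.list(score_vectors)) stop("score_vectors must be a list")
  vecs <- lapply(score_vectors, function(v) {
    if (inherits(v, "boundary_scores")) v$scores else as.numeric(v)
  })
  if (length(vecs) < min_k) stop("need at least ", min_k, " replicates")
  len <- lengths(vecs)
  if (length(unique(len)) != 1L) stop("misaligned score vectors")
  do.call(cbind, vecs)
}

#' Union boundaries across replicates
#'
#' A bin is a union boundary when it is called a boundary (score >= `t_b`)
#' in at least one replicate.
#'
#' @inheritParams consensus_scores
#' @param t_b boundary score cutoff (default 3).
#' @return logical vector of per-bin union flags.
#' @export
union_boundaries <- function(score_vectors, t_b = 3) {
  mat <- score_matrix(score_vectors)
  apply(mat, 1L, function(s) any(!is.na(s) & s >= t_b))
}

#' Consensus boundaries from consensus scores
#'
#' A bin is a consensus boundary when its consensus (median) score is at
#' least `t_b` (default 3). Consensus boundaries are always a subset of
#' union boundaries at the same cutoff.
#'
#' @param consensus numeric vector of per-bin consensus (median) scores.
#' @param t_b boundary score cutoff (default 3).
#' @return logical vector.
#' @export
consensus_boundaries <- function(consensus, t_b = 3) {
  !is.na(consensus) & consensus >= t_b
}

#' Consensus boundary analysis of replicate contact matrices
#'
#' Jointly masks all replicates, computes each replicate's boundary scores,
#' and summarizes them per bin as the consensus (median) score with union
#' and consensus boundary flags.
#'
#' @param matrices list of >= 2 `ContactMatrix` replicates on identical
#'   bins.
#' @param params an [hic_params()] object.
#' @return object of class `"tad_consensus"`: list with `table` (chrom,
#'   start, end, bin, per-replicate scores, consensus, union_boundary,
#'   consensus_boundary), `params`, `mask`.
#' @export
tad_consensus <- function(matrices, params = hic_params()) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("need a list of at least 2 matrices")
  for (m in matrices[-1L]) check_compatible(matrices[[1L]], m)
  masks <- lapply(matrices, informative_mask, w = params$w, frac = params$frac)
  mask <- harmonize_masks(masks)
  scores <- lapply(matrices, function(m)
    boundary_scores(m, w = params$w, mask = mask, sd_type = params$sd_type))
  cons <- consensus_scores(scores)
  uni <- union_boundaries(scores, t_b = params$t_b)
  cb <- consensus_boundaries(cons, t_b = params$t_b)

  keep <- which(mask)
  ref <- matrices[[1L]]
  smat <- score_matrix(scores)[keep, , drop = FALSE]
  colnames(smat) <- paste0("score_rep", seq_along(matrices))
  table <- data.frame(
    chrom = ref$chrom, start = ref$starts[keep],
    end = ref$starts[keep] + ref$resolution, bin = keep,
    smat,
    consensus = cons[keep],
    union_boundary = uni[keep],
    consensus_boundary = cb[keep],
    stringsAsFactors = FALSE
  )
  structure(list(table = table, params = params, mask = mask, scores = scores),
            class = "tad_consensus")
}

#' @export
print.tad_consensus <- function(x, ...) {
  tab <- x$table
  cat(sprintf("tad_consensus: %s, %d retained bins, %d replicates\n",
              tab$chrom[1], nrow(tab), length(x$scores)))
  cat(sprintf("  union boundaries: %d; consensus boundaries: %d\n",
              sum(tab$union_boundary), sum(tab$consensus_boundary)))
  invisible(x)
}

#' @export
as.data.frame.tad_consensus <- function(x, ...) x$table

#' Compare boundaries between two groups of replicate matrices
#'
#' Extends the two-matrix comparison to replicated groups. All matrices are
#' jointly masked; within each group, the per-bin median of log eigenvector
#' gaps forms a consensus pseudo-gap profile (alternatively, with
#' `aggregate = "score"`, replicate Z-scores are medianed and mapped back
#' onto the gap scale of the first replicate's fit). The log-normal
#' location/scale are refitted on each group's consensus profile, and the
#' differential score, boundary calls and change classification proceed as
#' in [tad_compare()]. With single-matrix groups the result reduces exactly
#' to [tad_compare()].
#'
#' @param groupA,groupB non-empty lists of `ContactMatrix` replicates;
#'   `groupA` is the group of interest, `groupB` the reference.
#' @param params an [hic_params()] object.
#' @param aggregate `"gap"` (default; median of log gaps) or `"score"`.
#' @return a `"tad_comparison"` object (per-bin table on the consensus
#'   profiles).
#' @export
compare_groups <- function(groupA, groupB, params = hic_params(),
                           aggregate = c("gap", "score")) {
  aggregate <- match.arg(aggregate)
  if (!is.list(groupA) || length(groupA) == 0L) stop("groupA is empty")
  if (!is.list(groupB) || length(groupB) == 0L) stop("groupB is empty")
  all_m <- c(groupA, groupB)
  for (m in all_m[-1L]) check_compatible(all_m[[1L]], m)
  masks <- lapply(all_m, informative_mask, w = params$w, frac = params$frac)
  mask <- harmonize_masks(masks)

  group_gaps <- function(group) {
    profs <- lapply(group, windowed_gap_profile, mask = mask, w = params$w)
    gm <- do.call(cbind, lapply(profs, `[[`, "gaps"))
    if (aggregate == "gap") {
      cons <- exp(apply(log(gm), 1L, stats::median))
    } else {
      sc <- lapply(profs, scores_from_gaps, sd_type = params$sd_type)
      med <- consensus_scores(if (length(sc) > 1L) sc else c(sc, sc))
      fit1 <- sc[[1L]]
      cons <- exp(med * fit1$sigma + fit1$mu)
    }
    ref <- profs[[1L]]
    ref$gaps <- cons
    ref
  }
  gA <- group_gaps(groupA)
  gB <- group_gaps(groupB)

  sA <- scores_from_gaps(gA, sd_type = params$sd_type)
  sB <- scores_from_gaps(gB, sd_type = params$sd_type)
  db <- differential_scores(gA, gB, sd_type = params$sd_type)
  flags_A <- call_boundaries(sA, params$t_b)
  flags_B <- call_boundaries(sB, params$t_b)
  category <- classify_pairwise(flags_A, flags_B, db, params)
  category[!mask] <- NA_character_

  ref <- groupA[[1L]]
  keep <- which(mask)
  table <- data.frame(
    chrom = ref$chrom, start = ref$starts[keep],
    end = ref$starts[keep] + ref$resolution, bin = keep,
    gap_P = gA$gaps[keep], gap_R = gB$gaps[keep],
    score_P = sA$scores[keep], score_R = sB$scores[keep],
    diff_score = db[keep],
    boundary_P = flags_A[keep], boundary_R = flags_B[keep],
    category = category[keep],
    stringsAsFactors = FALSE
  )
  structure(list(table = table, params = params, scores_P = sA, scores_R = sB,
                 mask = mask),
            class = "tad_comparison")
}
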