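# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as naive element-wise procedures, not
# shared with the package internals.

oracle_laplacian <- function(C) {
  n <- nrow(C)
  d <- numeric(n)
  for (j in 1:n) d[j] <- sum(C[, j])
  L <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) L[i, j] <- C[i, j] / sqrt(d[i] * d[j])
  L
}

oracle_gaps <- function(V) {
  # step-by-step: column norm scaling, row unit-circle projection, distances
  k <- nrow(V)
  Vh <- V
  for (j in 1:2) {
    nrm <- sqrt(sum(V[, j]^2))
    Vh[, j] <- V[, j] / nrm
  }
  Z <- Vh
  for (i in 1:k) {
    r <- sqrt(Vh[i, 1]^2 + Vh[i, 2]^2)
    Z[i, ] <- Vh[i, ] / r
  }
  out <- numeric(k - 1)
  for (i in 2:k) {
    out[i - 1] <- sqrt((Z[i, 1] - Z[i - 1, 1])^2 + (Z[i, 2] - Z[i - 1, 2])^2)
  }
  out
}

oracle_mean_overlap <- function(regions, track) {
  # quadratic all-pairs half-open overlap count
  total <- 0
  for (i in seq_len(nrow(regions))) {
    cnt <- 0
    for (j in seq_len(nrow(track))) {
      if (regions$chrom[i] == track$chrom[j] &&
          regions$start[i] < track$end[j] &&
          track$start[j] < regions$end[i]) {
        cnt <- cnt + 1
      }
    }
    total <- total + cnt
  }
  total / nrow(regions)
}

# Independent per-bin rule table for the pairwise change taxonomy.
# States: flags in P and R, |DB| >= t_d, shift search, flank search.
oracle_classify <- function(fp, fr, diff, t_d = 2, s = 5) {
  n <- length(fp)
  isd <- !is.na(diff) & abs(diff) >= t_d
  res <- character(n)
  for (i in 1:n) {
    in_p <- isTRUE(fp[i]); in_r <- isTRUE(fr[i])
    if (!in_p && !in_r) { res[i] <- "NonBoundary"; next }
    if (in_p && in_r) {
      res[i] <- if (isd[i]) "StrengthChange" else "NonDifferential"
      next
    }
    if (!isd[i]) { res[i] <- "NonDifferential"; next }
    # one-sided differential boundary: shift first
    other <- if (in_p) fr else fp
    shifted <- FALSE
    for (j in 1:n) {
      if (j != i && abs(j - i) <= s && isTRUE(other[j])) shifted <- TRUE
    }
    if (shifted) { res[i] <- "Shifted"; next }
    # shared non-differential flanks on both sides?
    flank_ok <- function(idx_range) {
      for (j in idx_range) {
        if (isTRUE(fp[j]) || isTRUE(fr[j])) {
          return(isTRUE(fp[j]) && isTRUE(fr[j]) && !isd[j])
        }
      }
      FALSE
    }
    left_ok <- if (i > 1) flank_ok((i - 1):1) else FALSE
    right_ok <- if (i < n) flank_ok((i + 1):n) else FALSE
    if (left_ok && right_ok) {
      res[i] <- if (in_r) "Merge" else "Split"
    } else {
      res[i] <- "Complex"
    }
  }
  res
}

# Exact published 4-time-point lookup for temporal patterns; anything not
# listed is Dynamic.
oracle_temporal4 <- function(p) {
  key <- paste(as.integer(p), collapse = "")
  tab <- list(
    HighlyCommon = c("1111", "1011"),
    EarlyAppearing = "0111",
    EarlyDisappearing = "1000",
    LateAppearing = c("0011", "0001"),
    LateDisappearing = c("1100", "1110"),
    Dynamic = c("1010", "1001")
  )
  for (nm in names(tab)) if (key %in% tab[[nm]]) return(nm)
  "Dynamic"
}

# small helper: ContactMatrix from a plain symmetric matrix
cm_of <- function(m, chrom = "chrS", resolution = 40000) {
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

# random symmetric positive matrix
rand_sym <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 5), n, n)
  (m + t(m)) / 2
}
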