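#' Specification of a synthetic Hi-C contact matrix
#'
#' Describes a planted-domain contact matrix: `n` bins at a given
#' resolution, domain boundaries at interior bin indices (boundary `b`
#' separates bins `b - 1` and `b`; bin `b` opens the new domain), a
#' power-law decay of expected counts with genomic distance, and a
#' between-domain attenuation applied once per boundary crossed. Expected
#' counts are
#' `E[C_ij] = base * (|i - j| + 1)^(-alpha) * prod(beta_b over boundaries crossed)`.
#' Optional Poisson count noise and a sparsity knob (fraction of
#' off-diagonal bin pairs zeroed symmetrically) emulate shallow sequencing.
#'
#' @param n number of bins.
#' @param boundaries ordered interior bin indices in `2:(n - 1)`.
#' @param resolution bin size in bp (default 40000).
#' @param base within-domain base intensity at distance 0 (default 100).
#' @param alpha distance-decay exponent, > 0 (default 1, the canonical
#'   contact-frequency decay).
#' @param beta between-domain attenuation in (0, 1); scalar or one value
#'   per boundary (default 0.5).
#' @param noise `"none"` or `"poisson"`.
#' @param sparsity fraction in `[0, 1)` of off-diagonal bin pairs set to 0.
#' @param seed integer seed; required whenever `noise != "none"` or
#'   `sparsity > 0`.
#' @param chrom chromosome name for the simulated matrix.
#' @return list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n, boundaries = integer(), resolution = 40000,
                            base = 100, alpha = 1, beta = 0.5,
                            noise = c("none", "poisson"), sparsity = 0,
                            seed = NULL, chrom = "chrS") {
  noise <- match.arg(noise)
  boundaries <- as.integer(sort(boundaries))
  if (anyDuplicated(boundaries)) stop("duplicate boundary positions")
  if (length(boundaries) && (min(boundaries) < 2L || max(boundaries) > n - 1L))
    stop("boundaries must be interior bin indices in 2:(n-1)")
  if (alpha <= 0) stop("alpha must be positive")
  beta <- rep_len(as.numeric(beta), max(1L, length(boundaries)))
  if (any(beta <= 0 | beta >= 1)) stop("beta must lie in (0, 1)")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")
  if (is.null(seed) && (noise != "none" || sparsity > 0))
    stop("a seed is required for stochastic simulation")
  structure(list(n = as.integer(n), boundaries = boundaries,
                 resolution = resolution, base = base, alpha = alpha,
                 beta = beta, noise = noise, sparsity = sparsity,
                 seed = seed, chrom = chrom),
            class = "simulation_spec")
}

# internal: expected-count matrix of a spec (no noise, no sparsity)
expected_counts <- function(spec) {
  n <- spec$n
  idx <- seq_len(n)
  decay <- (abs(outer(idx, idx, "-")) + 1)^(-spec$alpha)
  # cumulative log-attenuation: S[i] = sum of log(beta_b) over boundaries b <= i
  S <- numeric(n)
  if (length(spec$boundaries)) {
    lb <- log(spec$beta[seq_along(spec$boundaries)])
    for (k in seq_along(spec$boundaries)) {
      S[spec$boundaries[k]:n] <- S[spec$boundaries[k]:n] + lb[k]
    }
  }
  atten <- exp(S[outer(idx, idx, pmax)] - S[outer(idx, idx, pmin)])
  spec$base * decay * atten
}

#' Simulate a contact matrix with planted domain boundaries
#'
#' Realizes a [simulation_spec()] as a symmetric `ContactMatrix`. With
#' `noise = "poisson"`, counts on the upper triangle are drawn
#' independently as Poisson with the spec's expected values and mirrored;
#' a `sparsity` fraction of off-diagonal bin pairs is then zeroed
#' symmetrically. All randomness is local to the given seed, so a fixed
#' seed reproduces the matrix bit for bit.
#'
#' @param spec a `"simulation_spec"`.
#' @param seed optional seed overriding `spec$seed` (e.g. for replicates).
#' @return a [contact_matrix()].
#' @export
#' @examples
#' cm <- simulate_matrix(simulation_spec(n = 60, boundaries = c(20, 40)))
simulate_matrix <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(seed)) seed <- spec$seed
  E <- expected_counts(spec)
  n <- spec$n
  stochastic <- spec$noise == "poisson" || spec$sparsity > 0
  if (stochastic) {
    if (is.null(seed)) stop("a seed is required for stochastic simulation")
    E <- with_seed(seed, {
      M <- E
      up <- upper.tri(M, diag = TRUE)
      if (spec$noise == "poisson") M[up] <- stats::rpois(sum(up), E[up])
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      if (spec$sparsity > 0) {
        off <- which(upper.tri(M, diag = FALSE))
        drop <- sample(off, floor(spec$sparsity * length(off)))
        M[drop] <- 0
        M <- pmin(M, t(M))  # mirror the zeros symmetrically
      }
      M
    })
  }
  contact_matrix(E, chrom = spec$chrom, resolution = spec$resolution)
}

#' Boundary-change scenario between two simulated matrices
#'
#' Derives a changed spec from a base spec according to one of the five
#' change types and records per-bin ground truth. The change is applied to
#' the *first* matrix `P` of the pair; the base spec plays the reference
#' `R`, so `tad_compare(P, R)` is expected to recover the planted label:
#'
#' * `merge`: the boundary is deleted in `P` (its flanking boundaries stay),
#'   so `P`'s two domains merge relative to `R` — planted label `Merge`;
#' * `split`: a new boundary is inserted in `P` — planted label `Split`;
#' * `shift`: the boundary moves by `k` bins in `P` — planted label
#'   `Shifted` at the new position;
#' * `strength`: the boundary's attenuation in `P` is multiplied by
#'   `gamma` — planted label `StrengthChange`;
#' * `complex`: the boundary is replaced in `P` by two new non-adjacent
#'   boundaries — planted label `Complex` at the removed bin.
#'
#' @param base a `"simulation_spec"` (the reference).
#' @param type one of `"merge"`, `"split"`, `"shift"`, `"strength"`,
#'   `"complex"`.
#' @param boundary the affected boundary bin (must exist in `base` except
#'   for `split`, where it must not).
#' @param k shift in bins (for `shift`; may be negative).
#' @param gamma attenuation multiplier (for `strength`); `beta * gamma`
#'   must stay in (0, 1).
#' @param new_boundaries two interior bins (for `complex`), each
#'   non-adjacent to the other and distinct from the removed boundary.
#' @return list of class `"change_scenario"` with `spec_P`, `spec_R`,
#'   `type`, and `truth` (data.frame of `bin`, `label`).
#' @export
change_scenario <- function(base, type = c("merge", "split", "shift",
                                           "strength", "complex"),
                            boundary, k = 2, gamma = 0.5,
                            new_boundaries = NULL) {
  stopifnot(inherits(base, "simulation_spec"))
  type <- match.arg(type)
  b <- as.integer(boundary)
  has_b <- b %in% base$boundaries
  mod <- base
  if (type == "split") {
    if (has_b) stop("split: boundary already present at bin ", b)
    if (b < 2L || b > base$n - 1L) stop("split: boundary outside interior")
    ord <- order(c(mod$boundaries, b))
    mod$beta <- c(mod$beta[seq_along(mod$boundaries)], mod$beta[1L])[ord]
    mod$boundaries <- sort(c(mod$boundaries, b))
    truth <- data.frame(bin = b, label = "Split")
  } else {
    if (!has_b) stop(type, ": no boundary at bin ", b)
    pos <- match(b, base$boundaries)
    if (type == "merge") {
      mod$boundaries <- base$boundaries[-pos]
      mod$beta <- base$beta[seq_along(base$boundaries)][-pos]
      truth <- data.frame(bin = b, label = "Merge")
    } else if (type == "shift") {
      nb <- b + as.integer(k)
      if (nb < 2L || nb > base$n - 1L || nb %in% base$boundaries)
        stop("shift: new position collides or leaves the interior")
      mod$boundaries[pos] <- nb
      ord <- order(mod$boundaries)
      mod$beta <- mod$beta[seq_along(mod$boundaries)][ord]
      mod$boundaries <- mod$boundaries[ord]
      truth <- data.frame(bin = nb, label = "Shifted")
    } else if (type == "strength") {
      newbeta <- base$beta[pos] * gamma
      if (newbeta <= 0 || newbeta >= 1)
        stop("strength: beta * gamma must stay in (0, 1)")
      mod$beta[pos] <- newbeta
      truth <- data.frame(bin = b, label = "StrengthChange")
    } else { # complex
      nb <- sort(as.integer(new_boundaries))
      if (length(nb) != 2L) stop("complex: give exactly two new boundaries")
      if (any(nb < 2L | nb > base$n - 1L)) stop("complex: boundaries outside interior")
      if (diff(nb) < 2L) stop("complex: new boundaries must be non-adjacent")
      if (any(nb %in% base$boundaries) || b %in% nb)
        stop("complex: new boundaries collide with existing ones")
      keep <- base$boundaries[-pos]
      keepb <- base$beta[seq_along(base$boundaries)][-pos]
      ord <- order(c(keep, nb))
      mod$boundaries <- sort(c(keep, nb))
      mod$beta <- c(keepb, rep(base$beta[1L], 2L))[ord]
      truth <- data.frame(bin = b, label = "Complex")
    }
  }
  structure(list(spec_P = mod, spec_R = base, type = type, truth = truth),
            class = "change_scenario")
}

#' Realize a change scenario as a pair of matrices
#'
#' Simulates the changed matrix `P` and the reference matrix `R` from a
#' [change_scenario()], with independent noise when the specs are
#' stochastic.
#'
#' @param scenario a `"change_scenario"`.
#' @param seed optional base seed; `P` uses `seed`, `R` uses `seed + 1`.
#'   Defaults to the base spec's seed.
#' @return list with `P`, `R` (`ContactMatrix`) and `truth`.
#' @export
apply_change <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "change_scenario"))
  if (is.null(seed)) seed <- scenario$spec_R$seed
  stochastic <- scenario$spec_R$noise != "none" || scenario$spec_R$sparsity > 0
  sP <- if (stochastic) seed else NULL
  sR <- if (stochastic) seed + 1L else NULL
  list(P = simulate_matrix(scenario$spec_P, seed = sP),
       R = simulate_matrix(scenario$spec_R, seed = sR),
       truth = scenario$truth)
}

#' Simulate a boundary time course
#'
#' Generates `timepoints` ordered sets of replicate matrices from a base
#' spec with boundaries appearing or disappearing at scheduled times, and
#' the true temporal pattern of every planted boundary. An `"appear"` event
#' makes the boundary present from its time point onward; a `"disappear"`
#' event removes it from its time point onward. Boundaries of the base spec
#' without an event are present throughout. Replicates get independent
#' noise via derived seeds.
#'
#' @param base a `"simulation_spec"` whose boundaries are present at time 1
#'   unless an `"appear"` event introduces them later.
#' @param events list of `list(time =, action = "appear"|"disappear",
#'   boundary =)`; appearing boundaries need not be in `base$boundaries`.
#'   Alternatively an event may give an explicit presence schedule,
#'   `list(boundary =, pattern = logical vector over time points)`, e.g. to
#'   plant a dynamic on/off trajectory.
#' @param timepoints number of time points, >= 3 (default 4).
#' @param reps replicates per time point (default 1).
#' @param seed base seed (defaults to `base$seed`); required when the spec
#'   is stochastic.
#' @return list with `matrices` (list over time points of lists of
#'   `ContactMatrix`), `truth` (data.frame `bin`, `pattern`), and
#'   `schedule` (boundaries x time points logical matrix).
#' @export
simulate_timecourse <- function(base, events = list(), timepoints = 4,
                                reps = 1, seed = NULL) {
  stopifnot(inherits(base, "simulation_spec"))
  if (timepoints < 3L) stop("need at least 3 time points")
  if (is.null(seed)) seed <- base$seed
  all_b <- sort(unique(c(base$boundaries,
                         vapply(events, function(e) as.integer(e$boundary),
                                integer(1L)))))
  sched <- matrix(FALSE, nrow = length(all_b), ncol = timepoints,
                  dimnames = list(all_b, NULL))
  sched[match(base$boundaries, all_b), ] <- TRUE
  for (e in events) {
    row <- match(as.integer(e$boundary), all_b)
    if (!is.null(e$pattern)) {
      if (length(e$pattern) != timepoints) stop("pattern length must equal timepoints")
      sched[row, ] <- as.logical(e$pattern)
      next
    }
    t0 <- as.integer(e$time)
    if (t0 < 1L || t0 > timepoints) stop("event at invalid time ", t0)
    if (e$action == "appear") {
      sched[row, ] <- seq_len(timepoints) >= t0
    } else if (e$action == "disappear") {
      sched[row, ] <- seq_len(timepoints) < t0
    } else stop("unknown event action: ", e$action)
  }
  if (any(rowSums(sched) == 0L)) stop("a scheduled boundary is never present")

  beta1 <- base$beta[1L]
  stochastic <- base$noise != "none" || base$sparsity > 0
  if (stochastic && is.null(seed)) stop("a seed is required for stochastic simulation")
  matrices <- lapply(seq_len(timepoints), function(t0) {
    spec_t <- base
    spec_t$boundaries <- all_b[sched[, t0]]
    spec_t$beta <- rep_len(beta1, max(1L, length(spec_t$boundaries)))
    lapply(seq_len(reps), function(r) {
      s <- if (stochastic) seed + 1000L * t0 + r else NULL
      simulate_matrix(spec_t, seed = s)
    })
  })
  truth <- data.frame(
    bin = all_b,
    pattern = apply(sched, 1L, classify_temporal)
  )
  list(matrices = matrices, truth = truth, schedule = sched)
}
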