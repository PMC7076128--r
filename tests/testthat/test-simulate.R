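test_that("the expected-count model plants decay and attenuation", {
  spec <- simulation_spec(n = 6, boundaries = 4, base = 100, alpha = 1, beta = 0.5)
  cm <- simulate_matrix(spec)
  m <- cm$counts
  # within-domain: pure power-law decay
  expect_equal(m[1, 2], 100 * 2^-1)
  expect_equal(m[1, 3], 100 * 3^-1)
  # crossing the boundary between bins 3 and 4 applies the attenuation once
  expect_equal(m[3, 4], 100 * 2^-1 * 0.5)
  expect_equal(m[1, 6], 100 * 6^-1 * 0.5)
  expect_equal(m, t(m))
})

test_that("a boundary-free spec is a deterministic Toeplitz decay", {
  spec <- simulation_spec(n = 12, base = 50, alpha = 1.2)
  cm <- simulate_matrix(spec)
  d <- abs(outer(1:12, 1:12, "-"))
  expect_equal(cm$counts, 50 * (d + 1)^-1.2)
})

test_that("stochastic simulation is reproducible and sparsity thins pairs", {
  spec <- simulation_spec(n = 40, boundaries = 20, beta = 0.3, noise = "poisson",
                          sparsity = 0.3, seed = 99)
  a <- simulate_matrix(spec); b <- simulate_matrix(spec)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, simulate_matrix(spec, seed = 100)$counts))
  # about 30% of off-diagonal pairs zeroed (some already zero by Poisson)
  off <- a$counts[upper.tri(a$counts)]
  expect_gte(mean(off == 0), 0.3)
  expect_equal(a$counts, t(a$counts))
  expect_error(simulation_spec(n = 40, boundaries = 20, noise = "poisson"),
               "seed")
})

test_that("boundary contrast vanishes as the attenuation approaches one", {
  spec0 <- simulation_spec(n = 60, base = 100, alpha = 1)
  ref <- windowed_gap_profile(simulate_matrix(spec0))$gaps[30]
  gaps <- vapply(c(0.5, 0.7, 0.9, 0.99), function(b) {
    sp <- simulation_spec(n = 60, boundaries = 30, base = 100, alpha = 1, beta = b)
    windowed_gap_profile(simulate_matrix(sp))$gaps[30]
  }, numeric(1))
  # junction gap decreases toward the boundary-free value
  expect_true(all(diff(gaps) < 0))
  expect_equal(gaps[4], ref, tolerance = 0.1)
})

test_that("deepening the contrast never decreases the junction gap", {
  gaps <- vapply(seq(0.8, 0.1, by = -0.1), function(b) {
    sp <- simulation_spec(n = 60, boundaries = 30, base = 100, alpha = 1, beta = b)
    windowed_gap_profile(simulate_matrix(sp))$gaps[30]
  }, numeric(1))
  expect_true(all(diff(gaps) >= 0))
})

test_that("simulation specs validate their fields", {
  expect_error(simulation_spec(n = 50, boundaries = 1), "interior")
  expect_error(simulation_spec(n = 50, boundaries = 50), "interior")
  expect_error(simulation_spec(n = 50, boundaries = 25, beta = 1), "beta")
  expect_error(simulation_spec(n = 50, boundaries = 25, alpha = 0), "alpha")
  expect_error(simulation_spec(n = 50, boundaries = 25, sparsity = 1), "sparsity")
})

test_that("change scenarios modify the first spec and keep ground truth", {
  base <- simulation_spec(n = 100, boundaries = c(30, 60), beta = 0.3)
  sc <- change_scenario(base, "merge", boundary = 60)
  expect_equal(sc$spec_P$boundaries, 30L)
  expect_equal(sc$spec_R$boundaries, c(30L, 60L))
  expect_equal(sc$truth, data.frame(bin = 60, label = "Merge"))

  sc <- change_scenario(base, "split", boundary = 45)
  expect_equal(sc$spec_P$boundaries, c(30L, 45L, 60L))

  sc <- change_scenario(base, "shift", boundary = 60, k = -3)
  expect_equal(sc$spec_P$boundaries, c(30L, 57L))
  expect_equal(sc$truth$bin, 57)

  sc <- change_scenario(base, "strength", boundary = 30, gamma = 0.5)
  expect_equal(sc$spec_P$beta, c(0.15, 0.3))

  sc <- change_scenario(base, "complex", boundary = 60, new_boundaries = c(50, 70))
  expect_equal(sc$spec_P$boundaries, c(30L, 50L, 70L))

  expect_error(change_scenario(base, "merge", boundary = 10), "no boundary")
  expect_error(change_scenario(base, "split", boundary = 30), "already present")
  expect_error(change_scenario(base, "shift", boundary = 30, k = 30), "collides")
  expect_error(change_scenario(base, "complex", boundary = 30,
                               new_boundaries = c(50, 51)), "non-adjacent")
})

test_that("a mild strength change stays non-differential", {
  base <- simulation_spec(n = 150, boundaries = seq(15, 135, 15), beta = 0.3)
  pr <- apply_change(change_scenario(base, "strength", boundary = 75, gamma = 0.9))
  cmp <- tad_compare(pr$P, pr$R)
  row <- cmp$table[cmp$table$bin == 75, ]
  expect_lt(abs(row$diff_score), 2)
  expect_false(row$category == "StrengthChange")
})

test_that("recall does not improve as matrices get sparser", {
  bnd <- c(50, 100)
  recall_at <- function(sparsity) {
    hits <- vapply(1:20, function(s) {
      spec <- simulation_spec(n = 150, boundaries = bnd, beta = 0.2, base = 30,
                              noise = "poisson", sparsity = sparsity, seed = s)
      bs <- suppressWarnings(boundary_scores(simulate_matrix(spec)))
      sum(bs$scores[bnd] >= 2, na.rm = TRUE)
    }, numeric(1))
    sum(hits) / (20 * length(bnd))
  }
  r <- vapply(c(0, 0.3, 0.6), recall_at, numeric(1))
  expect_true(all(diff(r) <= 0))
})

test_that("simulated time courses honour their event schedules", {
  base <- simulation_spec(n = 100, boundaries = c(30, 60), beta = 0.2)
  tc <- simulate_timecourse(
    base,
    events = list(list(time = 2, action = "appear", boundary = 80),
                  list(boundary = 30, pattern = c(TRUE, FALSE, TRUE, FALSE))),
    timepoints = 4, reps = 2, seed = NULL
  )
  expect_equal(dim(tc$schedule), c(3L, 4L))
  expect_equal(unname(tc$schedule["80", ]), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(tc$schedule["30", ]), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tc$truth$pattern[tc$truth$bin == 80], "EarlyAppearing")
  expect_equal(tc$truth$pattern[tc$truth$bin == 30], "Dynamic")
  expect_length(tc$matrices, 4L)
  expect_length(tc$matrices[[1]], 2L)
})
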