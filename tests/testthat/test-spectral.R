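test_that("normalized Laplacian matches its closed form", {
  expect_equal(normalized_laplacian(matrix(1, 2, 2)), matrix(0.5, 2, 2))
  expect_equal(normalized_laplacian(diag(c(3, 7))), diag(2))
  for (seed in 1:20) {
    C <- rand_sym(5, seed)
    expect_equal(normalized_laplacian(C), oracle_laplacian(C), tolerance = 1e-12)
  }
  expect_error(normalized_laplacian(matrix(c(0, 0, 0, 1), 2, 2)), "zero row sum")
})

test_that("leading spectrum returns the two largest-magnitude eigenpairs", {
  for (seed in 1:10) {
    L <- normalized_laplacian(rand_sym(10, seed + 50))
    sp <- leading_spectrum(L)
    # residual check
    for (k in 1:2) {
      expect_lt(max(abs(L %*% sp$vectors[, k] - sp$values[k] * sp$vectors[, k])), 1e-8)
    }
    # ordering against the full decomposition
    full <- eigen(L, symmetric = TRUE)$values
    expect_equal(abs(sp$values), sort(abs(full), decreasing = TRUE)[1:2])
  }
})

test_that("leading spectrum has a deterministic sign and block structure", {
  # two disconnected equal-weight 3-bin cliques
  blk <- matrix(1, 3, 3)
  C <- rbind(cbind(blk, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), blk))
  sp <- leading_spectrum(normalized_laplacian(C))
  V <- sp$vectors
  for (k in 1:2) {
    expect_equal(V[1, k], V[2, k], tolerance = 1e-10)
    expect_equal(V[4, k], V[5, k], tolerance = 1e-10)
    expect_gte(V[which.max(abs(V[, k])), k], 0)  # sign convention
  }
})

test_that("eigenvector gaps follow the projection formula", {
  # identical consecutive rows -> gap 0
  V <- matrix(c(1, 1, 2, 2), 2, 2)
  expect_equal(eigenvector_gaps(V), 0)
  # antipodal projected rows -> gap 2
  V <- matrix(c(1, -1, 1, -1), 2, 2)
  expect_equal(eigenvector_gaps(V), 2)
  for (seed in 1:20) {
    set.seed(seed)
    V <- matrix(rnorm(12), 6, 2)
    g <- eigenvector_gaps(V)
    expect_equal(g, oracle_gaps(V), tolerance = 1e-12)
    expect_true(all(g >= 0 & g <= 2))
    # invariance under global sign flips of either column
    expect_equal(eigenvector_gaps(V %*% diag(c(-1, 1))), g)
    expect_equal(eigenvector_gaps(V %*% diag(c(1, -1))), g)
  }
  V <- matrix(c(1, 0, 1, 1, 0, 1), 3, 2)
  expect_error(eigenvector_gaps(V), "bin\\(s\\) 2")
})

test_that("informative mask flags sparse bins within the window band", {
  m <- rand_sym(20, 5)
  expect_true(all(informative_mask(cm_of(m), w = 15)))
  m[3, ] <- 0; m[, 3] <- 0
  expect_false(informative_mask(cm_of(m), w = 15)[3])
  # hand count: bin 1 at w = 7 sees entries 1..8; 1 non-zero of 8 = 0.125 < 0.2
  m2 <- matrix(0, 20, 20); diag(m2) <- 1
  m2[1, 2] <- m2[2, 1] <- 0  # bin 1: only the diagonal entry non-zero
  msk <- informative_mask(m2, w = 7, frac = 0.2)
  expect_false(msk[1])
  # 2 of 8 = 0.25 >= 0.2 -> informative
  m2[1, 5] <- m2[5, 1] <- 3
  expect_true(informative_mask(m2, w = 7, frac = 0.2)[1])
})

test_that("mask harmonization is the element-wise AND", {
  expect_equal(harmonize_masks(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)),
               c(TRUE, FALSE, FALSE))
  a <- c(TRUE, FALSE, TRUE); expect_equal(harmonize_masks(a, a), a)
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(c(TRUE, FALSE), 12, TRUE); y <- sample(c(TRUE, FALSE), 12, TRUE)
    expect_equal(harmonize_masks(x, y), harmonize_masks(y, x))
  }
  expect_error(harmonize_masks(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("windowed profile reduces to the dense decomposition at full radius", {
  cm <- cm_of(rand_sym(24, 77) + diag(24))
  gp <- windowed_gap_profile(cm, w = 24)
  dense <- eigenvector_gaps(leading_spectrum(normalized_laplacian(cm$counts)))
  expect_equal(gp$gaps[-1], dense, tolerance = 1e-10)
  expect_true(is.na(gp$gaps[1]))
})

test_that("windowed profile respects masks and placeholder conventions", {
  spec <- simulation_spec(n = 60, boundaries = c(20, 40), beta = 0.3)
  cm <- simulate_matrix(spec)
  mask <- rep(TRUE, 60); mask[c(5, 31)] <- FALSE
  gp <- windowed_gap_profile(cm, mask = mask, w = 15)
  expect_true(all(is.na(gp$gaps[c(5, 31)])))
  expect_true(is.na(gp$gaps[1]))   # first retained bin placeholder
  expect_equal(sum(is.na(gp$gaps)), 3L)
  expect_true(all(gp$gaps >= 0 & gp$gaps <= 2, na.rm = TRUE))
  expect_error(windowed_gap_profile(cm, mask = rep(c(TRUE, FALSE), 30), w = 40),
               "retained")
})

test_that("planted junctions are strict local maxima of the gap profile", {
  spec <- simulation_spec(n = 100, boundaries = c(25, 50, 75), beta = 0.3)
  gp <- windowed_gap_profile(simulate_matrix(spec))
  g <- gp$gaps
  for (b in c(25, 50, 75)) {
    expect_gt(g[b], g[b - 1]); expect_gt(g[b], g[b + 1])
  }
  # and globally the three junctions dominate everything else
  expect_equal(sort(order(g, decreasing = TRUE)[1:3]), c(25, 50, 75))
})

test_that("boundary scores standardize log gaps", {
  sc <- scores_from_gaps(c(NA, exp(0), exp(1), exp(2)))
  expect_equal(sc$scores[-1], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_true(is.na(sc$scores[1]))
  sc2 <- scores_from_gaps(c(NA, exp(0), exp(1), exp(2)), sd_type = "sample")
  expect_equal(sc2$scores[-1], c(-1, 0, 1))

  # gap equal to the geometric mean scores 0
  g <- c(0.2, 0.8, sqrt(0.2 * 0.8))
  expect_equal(scores_from_gaps(g)$scores[3], 0, tolerance = 1e-12)

  # standardization identity on its own data
  set.seed(1)
  g <- exp(rnorm(50))
  sc <- scores_from_gaps(g)
  expect_lt(abs(mean(sc$scores)), 1e-9)
  expect_lt(abs(sqrt(mean(sc$scores^2)) - 1), 1e-9)
})

test_that("degenerate gap profiles are floored or rejected", {
  expect_warning(sc <- scores_from_gaps(c(0, 0.5, 1, 2)), "floored")
  expect_true(all(is.finite(sc$scores)))
  expect_error(scores_from_gaps(c(1, 1, 1)), "degenerate")
  expect_error(scores_from_gaps(c(0.5, 2)), "at least 3")
})

test_that("boundary calling uses the >= convention, one-sided", {
  expect_equal(call_boundaries(rep(0, 4)), rep(FALSE, 4))
  expect_equal(call_boundaries(c(2.9, 3.0, 3.1)), c(FALSE, TRUE, TRUE))
  expect_equal(call_boundaries(c(-5, NA, 4)), c(FALSE, FALSE, TRUE))
})

test_that("zero-noise planted domains yield exactly the junction boundaries", {
  spec <- simulation_spec(n = 100, boundaries = c(33, 66), beta = 0.3)
  bs <- boundary_scores(simulate_matrix(spec))
  expect_identical(which(call_boundaries(bs)), c(33L, 66L))
})
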