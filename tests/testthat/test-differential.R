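diff_cats <- c("Complex", "Split", "Merge", "Shifted", "StrengthChange")

test_that("identical gap profiles give zero differential scores", {
  set.seed(4)
  g <- c(NA, exp(rnorm(30)))
  expect_equal(differential_scores(g, g), c(NA, rep(0, 30)))
})

test_that("the two printed forms of the differential score agree", {
  # second form uses boundary scores defined with a variance denominator
  for (seed in 1:20) {
    set.seed(seed)
    gp <- exp(rnorm(40, -2, 0.8)); gr <- exp(rnorm(40, -1.5, 1.2))
    db1 <- differential_scores(gp, gr)
    lp <- log(gp); lr <- log(gr)
    s2p <- mean((lp - mean(lp))^2); s2r <- mean((lr - mean(lr))^2)
    Bp <- (lp - mean(lp)) / s2p; Br <- (lr - mean(lr)) / s2r
    db2 <- (s2p * Bp - s2r * Br) / sqrt(s2p + s2r)
    expect_equal(db1, db2, tolerance = 1e-12)
  }
})

test_that("differential scores are antisymmetric and need aligned profiles", {
  set.seed(9)
  gp <- c(NA, exp(rnorm(25))); gr <- c(NA, exp(rnorm(25)))
  expect_equal(differential_scores(gp, gr), -differential_scores(gr, gp))
  expect_error(differential_scores(gp, gr[-2]), "length")
  bad <- gr; bad[5] <- NA
  expect_error(differential_scores(gp, bad), "misaligned")
})

test_that("pairwise classification follows the documented decision procedure", {
  p <- hic_params()
  # identical flags, nothing differential
  f <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  out <- classify_pairwise(f, f, rep(0, 5), p)
  expect_true(all(out %in% c("NonBoundary", "NonDifferential")))

  # constructed split: shared non-differential flanks at 1 and 13 (outside
  # the shift window), differential boundary only in P at 7
  fp <- rep(FALSE, 13); fp[c(1, 7, 13)] <- TRUE
  fr <- rep(FALSE, 13); fr[c(1, 13)] <- TRUE
  d <- rep(0, 13); d[7] <- 2.5
  expect_equal(classify_pairwise(fp, fr, d, p)[7], "Split")
  # same configuration with the boundary only in R is a merge
  expect_equal(classify_pairwise(fr, fp, -d, p)[7], "Merge")
  # a shared flank inside the shift window wins as Shifted instead
  fp2 <- rep(FALSE, 13); fp2[c(4, 7, 13)] <- TRUE
  fr2 <- rep(FALSE, 13); fr2[c(4, 13)] <- TRUE
  expect_equal(classify_pairwise(fp2, fr2, d, p)[7], "Shifted")

  # a nearby boundary in the other matrix wins as Shifted
  fp <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  fr <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  d <- c(0, 0, 2.5, 0, -2.5, 0, 0)
  out <- classify_pairwise(fp, fr, d, p)
  expect_equal(out[3], "Shifted"); expect_equal(out[5], "Shifted")

  # no flanks at all: complex
  fp <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  fr <- rep(FALSE, 7)
  d <- c(0, 0, 0, 3, 0, 0, 0)
  expect_equal(classify_pairwise(fp, fr, d, p)[4], "Complex")

  # one-sided boundary below the differential threshold stays non-differential
  d2 <- c(0, 0, 0, 1.5, 0, 0, 0)
  expect_equal(classify_pairwise(fp, fr, d2, p)[4], "NonDifferential")
})

test_that("classification matches the rule-table oracle on random configurations", {
  p <- hic_params()
  set.seed(123)
  for (rep in 1:400) {
    n <- sample(5:9, 1)
    fp <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.4, 0.6))
    fr <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.4, 0.6))
    d <- sample(c(0, 1, 2.5, -3), n, TRUE)
    expect_identical(classify_pairwise(fp, fr, d, p),
                     oracle_classify(fp, fr, d, p$t_d, p$s))
  }
})

test_that("comparing a matrix with itself yields no differential boundaries", {
  cm <- simulate_matrix(simulation_spec(n = 80, boundaries = c(27, 54), beta = 0.3))
  cmp <- tad_compare(cm, cm)
  expect_true(all(cmp$table$diff_score == 0, na.rm = TRUE))
  expect_false(any(cmp$table$category %in% diff_cats))
  expect_true(all(cmp$table$category[cmp$table$boundary_P] == "NonDifferential"))
})

test_that("compare rejects incompatible matrices", {
  a <- simulate_matrix(simulation_spec(n = 60, boundaries = 30, beta = 0.3))
  b <- simulate_matrix(simulation_spec(n = 60, boundaries = 30, beta = 0.3,
                                       resolution = 10000))
  expect_error(tad_compare(a, b), "resolution")
  d <- simulate_matrix(simulation_spec(n = 60, boundaries = 30, beta = 0.3,
                                       chrom = "chr9"))
  expect_error(tad_compare(a, d), "chromosome")
})

test_that("a planted merge is labelled at the planted bin and swaps to split", {
  base <- simulation_spec(n = 150, boundaries = seq(15, 135, 15), beta = 0.15)
  pr <- apply_change(change_scenario(base, "merge", boundary = 75))
  cmp <- tad_compare(pr$P, pr$R)
  expect_equal(cmp$table$category[cmp$table$bin == 75], "Merge")
  swapped <- tad_compare(pr$R, pr$P)
  expect_equal(swapped$table$category[swapped$table$bin == 75], "Split")
  # swap exchanges merge and split everywhere, fixes the other labels
  a <- cmp$table$category; b <- swapped$table$category
  expect_identical(a == "Merge", b == "Split")
  expect_identical(a == "Split", b == "Merge")
  expect_identical(a %in% c("Shifted", "StrengthChange", "Complex"),
                   b %in% c("Shifted", "StrengthChange", "Complex"))
  expect_equal(cmp$table$diff_score, -swapped$table$diff_score)
})

test_that("a strengthened boundary maximizes |DB| at the modified bin", {
  # start from a weak boundary at bin 75 so its junction gap is far from
  # saturation, then strengthen it five-fold
  bnd <- seq(15, 135, 15)
  beta <- ifelse(bnd == 75, 0.7, 0.15)
  base <- simulation_spec(n = 150, boundaries = bnd, beta = beta)
  pr <- apply_change(change_scenario(base, "strength", boundary = 75, gamma = 0.2))
  cmp <- tad_compare(pr$P, pr$R)
  tab <- cmp$table
  expect_equal(tab$bin[which.max(abs(tab$diff_score))], 75)
  expect_gt(tab$diff_score[tab$bin == 75], 0)  # boundary strengthened in P
})

test_that("the nominal differential false-positive rate is below 0.05", {
  expect_equal(differential_tail_prob(2), 2 * (1 - pnorm(2)))
  expect_lt(differential_tail_prob(2), 0.05)
})
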