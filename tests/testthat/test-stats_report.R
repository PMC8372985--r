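test_that("descriptives use the sample (n-1) standard deviation", {
  d <- descriptives(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(descriptives(rep(4.2, 5))$sd, 0)
  expect_error(descriptives(numeric(0)), "empty")
  expect_true(is.na(descriptives(3)$sd))

  # two-pass oracle on random data
  set.seed(8)
  x <- rnorm(200, 5, 2)
  d2 <- descriptives(x)
  m <- sum(x) / length(x)
  s2 <- sum((x - m)^2) / (length(x) - 1)
  expect_equal(d2$mean, m, tolerance = 1e-12)
  expect_equal(d2$sd, sqrt(s2), tolerance = 1e-12)
  expect_true(d2$min <= d2$mean && d2$mean <= d2$max)
})

test_that("exact Mann-Whitney matches wilcox.test on tie-free samples", {
  set.seed(19)
  for (i in 1:12) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    ours <- mann_whitney_exact(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    # symmetry under group exchange
    expect_equal(mann_whitney_exact(y, x)$p_value, ours$p_value,
                 tolerance = 1e-12)
    expect_true(ours$statistic >= 0 && ours$statistic <= n1 * n2)
  }
})

test_that("identical samples give p = 1 and ties use midranks", {
  x <- c(3, 5, 5, 8)
  expect_equal(mann_whitney_exact(x, x)$p_value, 1)
  res <- mann_whitney_exact(c(1, 1), c(1, 2))
  expect_equal(res$method, "exact")
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("complete separation at n = 7 per group hits the 2/3432 floor", {
  p <- mann_whitney_exact(1:7, 8:14)$p_value
  expect_equal(p, 2 / 3432, tolerance = 1e-12)
  # no arrangement can do better: the floor is the doubled probability of
  # the single most extreme assignment among choose(14, 7)
  expect_equal(p, 2 / choose(14, 7), tolerance = 1e-15)
})

test_that("large samples fall back to the normal approximation", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15, 1)
  res <- mann_whitney_exact(x, y)
  expect_equal(res$method, "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("ICC mean squares agree with a two-way ANOVA decomposition", {
  set.seed(23)
  n <- 12; k <- 3
  ratings <- matrix(rnorm(n * k, 10), n, k) + rnorm(n, 0, 3)
  res <- icc_agreement(ratings)
  df <- data.frame(y = as.numeric(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(lm(y ~ subj + rater, df))[["Mean Sq"]]
  expect_equal(res$msr, ms[1], tolerance = 1e-9)
  expect_equal(res$msc, ms[2], tolerance = 1e-9)
  expect_equal(res$mse, ms[3], tolerance = 1e-9)
})

test_that("ICC is 1 for perfect agreement and errors without variance", {
  subj <- c(1, 5, 9, 14, 20)
  expect_equal(icc_agreement(cbind(subj, subj))$icc, 1)
  expect_error(icc_agreement(matrix(3, 4, 2)), "between-subject")
})

test_that("planted variance components are recovered", {
  set.seed(77)
  n <- 100
  subj <- rnorm(n, 0, 10)             # subject variance 100
  ratings <- cbind(subj + rnorm(n, 0, 1), subj + rnorm(n, 0, 1))
  res <- icc_agreement(ratings)
  expect_lt(abs(res$icc - 100 / 101), 0.02)
  # consistency form on the same data
  expect_lt(abs(icc_agreement(ratings, "ICC3")$icc - 100 / 101), 0.02)
})

test_that("report tables have the study layout", {
  cohort <- synthetic_cohort(radii = c(29, 33, 37), seed = 5)
  res <- run_pipeline(cohort, seed = 5)
  tabs <- build_tables(res)
  expect_equal(nrow(tabs$comparisons), 4 * 4) # parameters x slices
  pcols <- grep("^p_", names(tabs$comparisons), value = TRUE)
  expect_length(pcols, choose(4, 2))
  expect_setequal(pcols, c("p_0vs6", "p_0vs9", "p_0vs12",
                           "p_6vs9", "p_6vs12", "p_9vs12"))
  expect_equal(nrow(tabs$descriptives), 4 * 4 * 4)
  expect_true(all(tabs$descriptives$n == 3))
})

test_that("simulated repeat segmentations agree closely", {
  cohort <- synthetic_cohort(radii = c(27, 31, 35, 39), seed = 6)
  study <- simulate_rater_study(cohort, noise_sd = 0.2, seed = 6)
  expect_equal(nrow(study), 4 * 4)
  agr <- agreement_table(study)
  expect_equal(nrow(agr), 8)
  expect_true(all(agr$icc > 0.9))
})
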