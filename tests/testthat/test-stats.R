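test_that("repeated-measures F agrees with the explicit sum-of-squares decomposition", {
  # oracle: subject x treatment decomposition computed by hand arithmetic
  set.seed(21)
  n <- 4; k <- 3
  y <- matrix(rnorm(n * k) + rep(c(0, 0.5, 1.2), each = n), n, k)
  d <- data.frame(subject = rep(1:n, k), level = rep(1:k, each = n),
                  y = as.numeric(y))
  gm <- mean(y)
  ss_treat <- n * sum((colMeans(y) - gm)^2)
  resid <- y - outer(rowMeans(y), rep(1, k)) -
    outer(rep(1, n), colMeans(y)) + gm
  ss_err <- sum(resid^2)
  F_oracle <- (ss_treat / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))

  av <- suppressWarnings(rm_anova(d, "y", "level"))
  expect_equal(av$F, F_oracle, tolerance = 1e-9)
  expect_equal(av$df1, k - 1)
  expect_equal(av$df2, (n - 1) * (k - 1))
  p_oracle <- stats::pf(F_oracle, k - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  expect_equal(av$p, p_oracle, tolerance = 1e-9)
})

test_that("two-level repeated-measures F is the square of the paired t", {
  set.seed(22)
  a <- rnorm(9); b <- rnorm(9, 0.4)
  d <- data.frame(subject = rep(1:9, 2), cond = rep(1:2, each = 9), y = c(a, b))
  av <- suppressWarnings(rm_anova(d, "y", "cond"))
  tt <- paired_t(a, b)
  expect_equal(av$F, tt$t^2, tolerance = 1e-9)
  expect_equal(av$p, tt$p, tolerance = 1e-9)
})

test_that("two-way repeated-measures ANOVA reports GG-corrected inference", {
  set.seed(23)
  d <- expand.grid(subject = 1:8, depth = c("deep", "middle", "superficial"),
                   theta = c(90, 15, 0))
  d$y <- rnorm(nrow(d)) + as.numeric(d$depth == "superficial") * 0.8
  av <- suppressWarnings(rm_anova(d, "y", c("depth", "theta")))
  expect_identical(av$effect, c("depth", "theta", "depth:theta"))
  expect_true(all(av$gg_epsilon <= 1 + 1e-9))
  expect_true(all(av$gg_epsilon >= 0.5 - 1e-9))  # >= 1/(k-1) for k = 3
  expect_true(all(is.finite(av$p_gg)))
  # equal condition means per subject give F = 0
  d0 <- expand.grid(subject = 1:5, f = 1:3)
  d0$y <- rep(rnorm(5), 3)
  av0 <- suppressWarnings(rm_anova(d0, "y", "f"))
  expect_equal(av0$F, 0, tolerance = 1e-12)
  expect_error(rm_anova(d0[-1, ], "y", "f"), "balanced")
})

test_that("paired t and Pearson r match hand arithmetic and flag degeneracy", {
  x <- c(5, 3, 8)
  tt <- paired_t(x + c(1, 2, 3), x)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(tt$df, 2)
  expect_identical(paired_t(x, x)$t, 0)
  expect_true(paired_t(x, x)$degenerate)

  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5, tolerance = 1e-12)
  expect_true(pearson_r(c(1, 1, 1), c(1, 2, 3))$degenerate)
})

test_that("the max-statistic permutation test matches exhaustive enumeration", {
  set.seed(31)
  behav <- rnorm(5)
  fmri <- matrix(rnorm(15), 5, 3)
  res <- permutation_fwe(behav, fmri, exhaustive = TRUE)
  expect_identical(res$n_perm, 120L)

  # independent oracle: enumerate all 120 assignments and recompute max |r|
  null_max <- vapply(perms_oracle(5), function(p) {
    max(abs(cor(behav[p], fmri)))
  }, numeric(1))
  p_oracle <- vapply(abs(res$observed_r),
                     function(r) mean(null_max >= r - 1e-12), numeric(1))
  expect_equal(unname(res$p_fwe), p_oracle, tolerance = 1e-12)
  expect_equal(sort(res$null_max_r), sort(null_max), tolerance = 1e-12)

  # one ROI reduces to the standard permutation p for that correlation
  one <- permutation_fwe(behav, fmri[, 1], exhaustive = TRUE)
  p_one <- mean(vapply(perms_oracle(5),
                       function(p) abs(cor(behav[p], fmri[, 1])),
                       numeric(1)) >= abs(cor(behav, fmri[, 1])) - 1e-12)
  expect_equal(unname(one$p_fwe), p_one, tolerance = 1e-12)

  expect_error(permutation_fwe(rep(1, 5), fmri), "degenerate")
  expect_identical(permutation_fwe(behav, fmri, n_perm = 500, seed = 4)$p_fwe,
                   permutation_fwe(behav, fmri, n_perm = 500, seed = 4)$p_fwe)
})

test_that("Holm adjustment sits between unadjusted and Bonferroni", {
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  expect_identical(holm_correct(0.3), 0.3)
  expect_identical(holm_correct(c(1, 1, 1)), c(1, 1, 1))
  set.seed(41)
  p <- runif(10)
  h <- holm_correct(p)
  expect_true(all(h >= p - 1e-15))
  expect_true(all(h <= pmin(1, length(p) * p) + 1e-15))
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
})

test_that("BCEA matches its closed form and is rotation invariant", {
  # build samples with exact unit SDs and zero correlation
  set.seed(51)
  x0 <- rnorm(2000); y0 <- rnorm(2000)
  x <- as.numeric(scale(x0))
  y <- as.numeric(scale(stats::resid(lm(y0 ~ x0))))
  tr <- fake_trace(x, y)
  b <- bcea(tr, preprocess = FALSE)
  expect_equal(b$area, pi * qchisq(0.95, 2), tolerance = 1e-9)

  # rotation leaves the area unchanged (depends on the covariance determinant)
  th <- 0.7
  tr_rot <- fake_trace(cos(th) * x - sin(th) * y, sin(th) * x + cos(th) * y)
  expect_equal(bcea(tr_rot, preprocess = FALSE)$area, b$area, tolerance = 1e-9)

  idle <- fake_trace(rep(0.3, 200), rep(-0.1, 200))
  bi <- bcea(idle, preprocess = FALSE)
  expect_true(bi$degenerate)
  expect_identical(bi$area, 0)
  expect_error(bcea(fake_trace(rnorm(50), rnorm(50)), preprocess = FALSE),
               "at least 100")
})

test_that("BCEA of a simulated trace recovers the generating parameters", {
  g <- simulate_gaze(60, 0.3, 0.2, 0.1, blink_rate_hz = 0.2, seed = 2)
  b <- bcea(g, preprocess = TRUE)
  closed <- pi * qchisq(0.95, 2) * 0.3 * 0.2 * sqrt(1 - 0.1^2)
  expect_lt(abs(b$area - closed) / closed, 0.10)
  expect_equal(b$P, 0.95)
})

test_that("gaze preprocessing interpolates blinks and recenters blocks", {
  tl <- std_timeline()
  g <- simulate_gaze(60, 0.3, 0.2, 0, blink_rate_hz = 0.5, seed = 8,
                     timeline = tl)
  clean <- preprocess_gaze(g)
  expect_true(all(clean$samples$valid))
  expect_true(all(is.finite(clean$samples$x)))
  # per-block means are removed
  cond <- ifelse(is.na(clean$samples$condition), -1, clean$samples$condition)
  blocks <- split(clean$samples$x, cumsum(c(1, diff(cond) != 0)))
  expect_true(all(abs(vapply(blocks, mean, numeric(1))) < 1e-9))
})

test_that("below-fixation gaze fractions follow the sample distribution", {
  sym <- fake_trace(rnorm(5000), rnorm(5000))
  f <- gaze_below_fixation_fraction(sym)
  expect_lt(abs(f$fraction[f$condition == "all"] - 0.5), 0.05)

  down <- fake_trace(rnorm(200), rep(-1, 200), condition = 90)
  fd <- gaze_below_fixation_fraction(down)
  expect_identical(fd$fraction[fd$condition == "90"], 1)

  up <- fake_trace(rnorm(5000), rnorm(5000) + 1)
  fu <- gaze_below_fixation_fraction(up)
  expect_lt(fu$fraction[fu$condition == "all"], 0.5)

  # the analysis window restricts the samples considered
  wide <- fake_trace(c(-5, 5, 0.1, -0.1), c(-1, -1, 1, -1))
  fw <- gaze_below_fixation_fraction(wide, region = list(x = c(-1, 1)))
  expect_identical(fw$fraction[fw$condition == "all"], 0.5)
})
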