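test_that("BOCO maps equal series to zero and is scale invariant", {
  const <- fake_run(matrix(500, 3, 10), matrix(500, 3, 10))
  out <- boco_correct(const)
  expect_true(all(abs(out$data) < 1e-12))
  expect_equal(out$tr, 5.02 / 2)

  tl <- std_timeline()
  ph <- generate_laminar_phantom(20, "v1_like", 1, 50, seed = 2)
  run <- simulate_paired_vaso_run(ph, tl, seed = 4)
  scaled <- run
  scaled$nulled <- run$nulled * 3.7
  scaled$not_nulled <- run$not_nulled * 3.7
  expect_equal(boco_correct(run)$data, boco_correct(scaled)$data)

  one <- fake_run(matrix(500, 3, 1), matrix(500, 3, 1))
  expect_error(boco_correct(one), "at least 2")
  neg <- fake_run(matrix(500, 3, 10), matrix(c(-1, rep(500, 29)), 3, 10))
  expect_error(boco_correct(neg), "positive")
})

test_that("BOCO removes the BOLD-like component shared by both series", {
  tl <- std_timeline()
  ph <- generate_laminar_phantom(60, "v1_like", 1, 50, seed = 3,
                                 noise_sd = 0, drift_amplitude = 0)
  run0 <- simulate_paired_vaso_run(ph, tl, cbv_gain = 1, bold_gain = 0, seed = 5)
  runb <- simulate_paired_vaso_run(ph, tl, cbv_gain = 1, bold_gain = 0.5, seed = 5)
  b0 <- fit_block_glm(boco_correct(run0), tl)$betas[, "theta90"]
  bb <- fit_block_glm(boco_correct(runb), tl)$betas[, "theta90"]
  bold_amp <- 0.5 * (ph$W %*% ph$B_true)[, "90"]
  # residual contamination after division is under 5% of the BOLD amplitude
  expect_lt(max(abs(bb - b0) / bold_amp), 0.05)
})

test_that("BOCO equals sign-inverted nulled PSC up to centering and interpolation", {
  tl <- std_timeline(isi = 300)
  ph <- generate_laminar_phantom(30, "v1_like", 1, 50, seed = 3,
                                 noise_sd = 0, drift_amplitude = 0)
  run <- simulate_paired_vaso_run(ph, tl, cbv_gain = 1, bold_gain = 0, seed = 5)
  out <- boco_correct(run)
  psc <- -percent_signal_change(run$nulled)
  shared <- out$data[, seq(1, ncol(out$data), by = 2)]
  d <- shared - psc
  d <- sweep(d, 1, rowMeans(d))  # remove the median-vs-mean centering offset
  amp <- (ph$W %*% ph$B_true)[, "90"]
  expect_lt(max(abs(sweep(d, 1, amp, "/"))), 0.01)
})

test_that("percent signal change is exact per-run arithmetic", {
  expect_true(all(percent_signal_change(matrix(7, 2, 5)) == 0))
  expect_equal(as.numeric(percent_signal_change(c(99, 101))), c(-1, 1))
  two <- matrix(c(99, 101, 199, 201, 202, 197), 1)
  out <- percent_signal_change(two, run_lengths = c(2, 4))
  expect_equal(mean(out[1, 1:2]), 0)
  expect_equal(mean(out[1, 3:6]), 0)
  expect_warning(percent_signal_change(rbind(c(0, 0), c(1, 1))), "zero mean")
})

test_that("the block GLM is an exact linear estimator with rank checking", {
  tl <- std_timeline()
  times <- seq(0, 269, by = 2.51)
  X <- lamsal:::build_condition_regressors(tl, times)
  ts <- matrix(1.5 * X[, "theta90"], 1)
  fit <- fit_block_glm(ts, tl, tr = 2.51)
  expect_equal(unname(fit$betas[1, "theta90"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(fit$betas[1, c("theta15", "theta0")]), c(0, 0),
               tolerance = 1e-9)

  # linearity: scaling the data scales the betas
  set.seed(8)
  noisy <- matrix(rnorm(3 * length(times)), 3) + 2 * rep(X[, "theta15"], each = 3)
  f1 <- fit_block_glm(noisy, tl, tr = 2.51)
  f3 <- fit_block_glm(3 * noisy, tl, tr = 2.51)
  expect_equal(f3$betas, 3 * f1$betas, tolerance = 1e-9)

  # duplicated condition column is reported as collinear
  expect_error(fit_block_glm(noisy, tl, nuisance = X[, "theta90", drop = FALSE],
                             tr = 2.51), "collinear")
})

test_that("end-to-end GLM + unmixing recovers the phantom truth within 2 SE", {
  tl <- std_timeline()
  B <- matrix(NA_real_, 5, 10)
  truth <- NULL
  for (i in seq_len(10)) {
    ph <- generate_laminar_phantom(200, "v1_like", 1, 50, seed = 5 + i,
                                   noise_sd = 0.5)
    truth <- ph$B_true[, "90"]
    run <- simulate_paired_vaso_run(ph, tl, cbv_gain = 1, bold_gain = 0.5,
                                    seed = 5 + i)
    fit <- fit_block_glm(boco_correct(run), tl)
    B[, i] <- unmix_layers(fit$betas[, "theta90"], ph$W)$B
  }
  se_mean <- apply(B, 1, sd) / sqrt(ncol(B))
  expect_true(all(abs(rowMeans(B) - truth) <= 2 * se_mean))
})

test_that("tSNR and CNR follow their definitions and flag degenerate voxels", {
  tl <- std_timeline()
  times <- seq(0, 269, by = 2.51)
  stim <- !is.na(lamsal:::condition_at_time(tl, times))
  set.seed(9)
  # voxel 1: contrast 2 over noise sd 1; voxel 2: constant
  data <- rbind(100 + 2 * stim + rnorm(length(times)),
                rep(100, length(times)))
  m <- snr_metrics(raw = data, ts = data, timeline = tl, tr = 2.51)
  expect_true(m$flagged[2])
  expect_true(is.na(m$tsnr[2]))
  expect_equal(m$cnr[1], 2, tolerance = 0.5)
  expect_equal(m$tsnr[1], mean(data[1, ]) / sd(data[1, ]))

  # pure noise: mean CNR compatible with zero
  noise <- matrix(rnorm(1000 * length(times)), 1000)
  mn <- snr_metrics(noise, noise, tl, tr = 2.51)
  expect_lt(abs(mean(mn$cnr)), 3 * sd(mn$cnr) / sqrt(1000))
})
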