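test_that("block design reproduces the session arithmetic and invariants", {
  tl <- std_timeline(seed = 1)
  expect_identical(tl$run_duration, 270)
  expect_identical(nrow(tl$blocks), 6L)
  expect_identical(as.integer(table(tl$events$block)), rep(60L, 6))
  # balanced conditions over blocks
  expect_identical(as.integer(sort(table(tl$blocks$condition))), rep(2L, 3))
  for (b in seq_len(6)) {
    ev <- tl$events[tl$events$block == b, ]
    expect_true(all(ev$onset >= tl$blocks$start[b] - 1e-9))
    expect_true(all(ev$onset + ev$duration <= tl$blocks$end[b] + 1e-9))
    expect_true(all(ev$condition == tl$blocks$condition[b]))
    expect_true(all(diff(ev$onset) >= ev$duration[-60] - 1e-9))
  }
  # blocks followed by fixation gaps, non-overlapping
  expect_true(all(diff(tl$blocks$start) == 45))
  expect_identical(tl$run_duration, tl$blocks$end[6] + 15)
})

test_that("fixed 300-ms ISI tiles a block so the last slot ends at its boundary", {
  tl <- generate_block_design(2, 30, 15, 200, 300, 60, c(90, 15), seed = 7)
  for (b in 1:2) {
    ev <- tl$events[tl$events$block == b, ]
    expect_equal(ev$duration + ev$isi, rep(0.5, 60))
    expect_equal(ev$onset[60] + ev$duration[60] + ev$isi[60], tl$blocks$end[b])
  }
})

test_that("degenerate and invalid block designs are handled", {
  tl0 <- generate_block_design(0, 30, 15, 200, 300, 60, c(90, 15, 0), seed = 1)
  expect_identical(tl0$run_duration, 0)
  expect_identical(nrow(tl0$events), 0L)
  expect_error(generate_block_design(6, -1, 15, 200, 300, 60, c(90), seed = 1),
               "positive")
  expect_error(generate_block_design(6, 30, 15, 200, 300, 60, numeric(), seed = 1),
               "non-empty")
  expect_error(generate_block_design(5, 30, 15, 200, 300, 60, c(90, 15, 0), seed = 1),
               "multiple")
})

test_that("phantom weights are simplex rows and truth encodes the laminar effect", {
  ph <- generate_laminar_phantom(1000, "v1_like", 1.0, 50, seed = 3)
  expect_true(all(abs(rowSums(ph$W) - 1) < 1e-12))
  expect_true(all(ph$W >= 0))
  expect_equal(ph$B_true["superficial", "90"] - ph$B_true["superficial", "15"], 1.0)
  # the generating laminar contrast peaks at the superficial compartment
  contrast <- ph$B_true[, "90"] - ph$B_true[, "15"]
  expect_identical(names(which.max(contrast)), "superficial")
  expect_true(all(ph$B_true[c("wm", "csf"), ] == 0))

  flat <- generate_laminar_phantom(100, "flat", 0, 50, seed = 3)
  expect_true(all(flat$B_true[2:4, ] == flat$B_true[2, 1]))

  ips <- generate_laminar_phantom(100, "ips_like", 1.0, 50, seed = 3)
  ips_contrast <- ips$B_true[2:4, "90"] - ips$B_true[2:4, "15"]
  expect_identical(names(which.max(ips_contrast)), "middle")

  expect_error(generate_laminar_phantom(3, "v1_like", 1, 50, seed = 1), ">= 5")
  expect_error(generate_laminar_phantom(100, "v9_like", 1, 50, seed = 1))
})

test_that("paired VASO simulation respects the sign convention and determinism", {
  tl <- std_timeline()
  ph <- generate_laminar_phantom(100, "v1_like", 1, 50, seed = 3,
                                 noise_sd = 0.5)
  r1 <- simulate_paired_vaso_run(ph, tl, cbv_gain = 1, bold_gain = 0, seed = 5)
  r2 <- simulate_paired_vaso_run(ph, tl, cbv_gain = 1, bold_gain = 0, seed = 5)
  expect_identical(r1, r2)
  expect_identical(dim(r1$nulled), dim(r1$not_nulled))
  expect_true(all(r1$baseline > 0))

  # nulled dips during 90-degree blocks for superficial-weighted voxels
  sup <- which(ph$W[, "superficial"] > 0.8)
  lab <- lamsal:::condition_at_time(tl, r1$t_nulled)
  in90 <- !is.na(lab) & lab == 90
  fix <- is.na(lab)
  for (v in head(sup, 5)) {
    expect_lt(mean(r1$nulled[v, in90]), mean(r1$nulled[v, fix]))
  }
})

test_that("a silent phantom yields exactly constant baselines", {
  tl <- std_timeline()
  ph <- generate_laminar_phantom(20, "flat", 0, 50, seed = 2,
                                 noise_sd = 0, drift_amplitude = 0)
  r <- simulate_paired_vaso_run(ph, tl, cbv_gain = 0, bold_gain = 0, seed = 5)
  expect_identical(r$nulled, matrix(r$baseline, 20, ncol(r$nulled)))
  expect_identical(r$not_nulled, matrix(r$baseline, 20, ncol(r$not_nulled)))
})

test_that("synthetic pRF node tables anchor the localizer peak and floor sigma", {
  one <- generate_prf_nodes(1, "left", 120, 4, 0.2, seed = 1)
  expect_equal(one$A, 120)
  expect_equal(one$E, 4)
  many <- generate_prf_nodes(500, "right", 120, 4, 0.2, seed = 1)
  expect_equal(c(many$A[1], many$E[1]), c(120, 4))
  expect_true(all(many$sigma >= 0.1))
  expect_true(all(many$A >= 0 & many$A <= 180))
  expect_true(all(many$E >= 0.5 - 1e-9 & many$E <= 10 + 1e-9))
  expect_error(generate_prf_nodes(10, "left", 190, 4, 0.2, seed = 1), "Am")
})

test_that("gaze traces have the requested moments and blink structure", {
  g <- simulate_gaze(10, 0.2, 0.2, 0, blink_rate_hz = 0, seed = 2)
  expect_identical(nrow(g$samples), 10000L)
  expect_true(all(g$samples$valid))
  expect_identical(simulate_gaze(10, 0.2, 0.2, 0, 0, seed = 2),
                   simulate_gaze(10, 0.2, 0.2, 0, 0, seed = 2))

  g2 <- simulate_gaze(60, 0.3, 0.2, 0.1, blink_rate_hz = 0.2, seed = 2)
  ok <- g2$samples$valid
  expect_lt(abs(sd(g2$samples$x[ok]) - 0.3) / 0.3, 0.1)
  expect_lt(abs(sd(g2$samples$y[ok]) - 0.2) / 0.2, 0.1)

  g3 <- simulate_gaze(1, 0.2, 0.2, 0, blink_rate_hz = 1000, seed = 1)
  expect_lt(mean(g3$samples$valid), 0.05)

  expect_error(simulate_gaze(10, -0.1, 0.2, 0, 0, seed = 1), "positive")
  expect_error(simulate_gaze(10, 0.2, 0.2, 1.2, 0, seed = 1), "rho")
})
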