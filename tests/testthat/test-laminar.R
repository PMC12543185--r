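test_that("unmixing is exact on pure and noiseless designs", {
  # pure voxels: one voxel fully in each compartment
  X <- diag(5)
  Y <- c(0.1, 1.2, 0.7, 2.0, -0.3)
  expect_equal(unname(unmix_layers(Y, X)$B), Y)

  set.seed(4)
  ph <- generate_laminar_phantom(50, "flat", 0, 20, seed = 4)
  truth <- c(0, 1, 2, 3, 0)
  Y2 <- as.numeric(ph$W %*% truth)
  expect_equal(unname(unmix_layers(Y2, ph$W)$B), truth, tolerance = 1e-9)

  expect_error(unmix_layers(c(1, 2, 3), diag(5)[1:3, ]), "fewer voxels|same number")
  Xdef <- cbind(ph$W[, 1:4], ph$W[, 4])
  expect_error(unmix_layers(Y2, Xdef), "rank deficient")
})

test_that("unmixing agrees with the normal-equations oracle and recovers truth", {
  truth <- c(0, 0.4, 0.6, 1.0, 0)
  B <- matrix(NA_real_, 5, 20)
  for (i in seq_len(20)) {
    ph <- generate_laminar_phantom(500, "flat", 0, 50, seed = 100 + i)
    set.seed(200 + i)
    Y <- as.numeric(ph$W %*% truth) + rnorm(500, sd = 0.5)
    est <- unmix_layers(Y, ph$W)
    # independent oracle: explicit normal equations
    oracle <- solve(t(ph$W) %*% ph$W, t(ph$W) %*% Y)
    expect_equal(unname(est$B), as.numeric(oracle), tolerance = 1e-8)
    B[, i] <- est$B
  }
  se_mean <- apply(B, 1, sd) / sqrt(ncol(B))
  expect_true(all(abs(rowMeans(B) - truth) <= 2 * se_mean + 1e-12))
})

test_that("response normalization preserves per-subject shape and group scale", {
  # single subject: normalization is the identity
  r1 <- array(rnorm(9, 1), c(1, 3, 3),
              dimnames = list(NULL, NULL, c("90", "15", "0")))
  p1 <- normalize_responses(r1)
  expect_equal(p1$S, r1, ignore_attr = TRUE)

  # a rescaled subject gets the same normalized profile
  set.seed(5)
  base <- matrix(rnorm(9, 1), 3, 3)
  r2 <- array(NA_real_, c(2, 3, 3), dimnames = list(NULL, NULL, c("90", "15", "0")))
  r2[1, , ] <- base
  r2[2, , ] <- 2 * base
  p2 <- normalize_responses(r2)
  expect_equal(p2$S[1, , ], p2$S[2, , ])

  # constant-response subject collapses to signed r_bar
  r3 <- array(NA_real_, c(2, 3, 3), dimnames = list(NULL, NULL, c("90", "15", "0")))
  r3[1, , ] <- -0.7
  r3[2, , ] <- base
  p3 <- normalize_responses(r3)
  expect_equal(unname(p3$S[1, 1, 1]), -p3$r_bar)

  r4 <- r3
  r4[1, , ] <- 0
  expect_error(normalize_responses(r4), "all-zero")
})

test_that("the per-subject RMS of normalized responses equals the group mean normalizer", {
  set.seed(11)
  for (rep in 1:10) {
    r <- array(rnorm(8 * 3 * 3, mean = 1), c(8, 3, 3),
               dimnames = list(NULL, NULL, c("90", "15", "0")))
    p <- normalize_responses(r)
    rms <- apply(p$S, 1, function(m) sqrt(mean(m^2)))
    expect_true(all(abs(rms - p$r_bar) < 1e-9))
  }
  # a 5-compartment array is reduced to its cortical layers
  r5 <- array(rnorm(2 * 5 * 3, 1), c(2, 5, 3),
              dimnames = list(NULL, c("wm", "deep", "middle", "superficial", "csf"),
                              c("90", "15", "0")))
  p5 <- normalize_responses(r5)
  expect_identical(dim(p5$S)[2], 3L)
})

test_that("saliency contrasts are the defined condition differences", {
  S <- array(NA_real_, c(1, 3, 3),
             dimnames = list(NULL, c("deep", "middle", "superficial"),
                             c("90", "15", "0")))
  S[1, , "90"] <- 1.2
  S[1, , "15"] <- 0.8
  S[1, , "0"] <- 0.9
  prof <- structure(list(S = S), class = "layer_profile")
  cc <- saliency_contrasts(prof)
  expect_equal(unname(cc$SS[1, ]), rep(0.4, 3))
  expect_equal(unname(cc$alt[1, ]), rep(0.3, 3))
  expect_equal(unname(cc$suppression[1, ]), rep(0.1, 3), tolerance = 1e-12)

  S[1, , ] <- 1
  cc0 <- saliency_contrasts(structure(list(S = S), class = "layer_profile"))
  expect_true(all(cc0$SS == 0 & cc0$alt == 0 & cc0$suppression == 0))

  Sm <- S[, , 1:2, drop = FALSE]
  expect_error(saliency_contrasts(structure(list(S = Sm), class = "layer_profile")),
               "missing condition")
})

test_that("SNR normalization divides elementwise and validates inputs", {
  SS <- matrix(c(1, 2, 3), 1)
  expect_equal(unname(snr_normalized_saliency(SS, c(1, 2, 3))),
               matrix(1, 1, 3))
  # common factor leaves laminar ordering unchanged
  SS2 <- matrix(rnorm(15), 5)
  out <- snr_normalized_saliency(SS2, c(2, 2, 2))
  expect_equal(apply(out, 1, which.max), apply(SS2, 1, which.max))
  expect_error(snr_normalized_saliency(SS, c(1, 0, 3)), "positive")
})

test_that("v1-like phantoms give superficial-peaked saliency end to end", {
  tl <- std_timeline()
  peaks <- vapply(1:10, function(i) {
    ph <- generate_laminar_phantom(500, "v1_like", 1.0, 50, seed = 300 + i,
                                   noise_sd = 0.5)
    run <- simulate_paired_vaso_run(ph, tl, seed = 400 + i)
    fit <- fit_block_glm(boco_correct(run), tl)
    ss <- unmix_layers(fit$betas[, "theta90"], ph$W)$B[2:4] -
      unmix_layers(fit$betas[, "theta15"], ph$W)$B[2:4]
    which.max(ss)
  }, integer(1))
  expect_gte(mean(peaks == 3), 0.9)
})
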