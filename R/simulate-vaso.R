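#' Simulate a paired nulled/not-nulled VASO run
#'
#' Generates alternating blood-nulled and not-nulled timeseries for every
#' voxel of a laminar phantom under a block-design timeline. The neural
#' regressor of each condition is the block boxcar convolved with the
#' canonical HRF (unit plateau). A voxel's CBV response amplitude is its layer
#' weights times the phantom's ground-truth layer amplitudes. Following the
#' VASO sign convention the nulled signal *decreases* when CBV rises; both
#' series carry a common positive BOLD-like component scaled by `bold_gain`
#' (the contamination that BOLD correction must remove):
#' nulled = baseline * (1 + (bold - cbv)/100), not-nulled = baseline *
#' (1 + bold/100). Nulled volumes are sampled at multiples of the paired TR,
#' not-nulled volumes half a TR later. Additive Gaussian noise (`noise_sd` of
#' the phantom, percent) and a linear drift (`drift_amplitude` percent over
#' the run, random sign per series) complete the model.
#'
#' @param phantom A `laminar_phantom`.
#' @param timeline A `stimulus_timeline`; its `paired_tr` sets the sampling.
#' @param cbv_gain Scale of the CBV response (1 = phantom amplitudes as-is).
#' @param bold_gain Scale of the BOLD-like contamination relative to the CBV
#'   amplitude.
#' @param seed Integer seed; runs are bit-identical given the seed.
#' @return A `paired_vaso_run`: list with `nulled`, `not_nulled` (n_voxels x
#'   n_pairs), `paired_tr`, `baseline`, and the acquisition times
#'   `t_nulled`, `t_not_nulled`.
#' @export
simulate_paired_vaso_run <- function(phantom, timeline, cbv_gain = 1,
                                     bold_gain = 0.5, seed = 1) {
  tr <- timeline$paired_tr
  if (timeline$run_duration < 2 * tr) {
    stop_invalid("run_duration (%.1f s) must be at least two paired TRs", timeline$run_duration)
  }
  set.seed(seed)
  n_pairs <- floor(timeline$run_duration / tr)
  t_nulled <- (seq_len(n_pairs) - 1) * tr
  t_not_nulled <- t_nulled + tr / 2
  n_vox <- nrow(phantom$W)

  conds <- colnames(phantom$B_true)
  # per-condition neural responses at both sampling grids
  resp_n <- resp_nn <- matrix(0, n_pairs, length(conds))
  for (j in seq_along(conds)) {
    blocks <- timeline$blocks[timeline$blocks$condition == as.numeric(conds[j]), , drop = FALSE]
    if (nrow(blocks) == 0) next
    resp_n[, j] <- convolve_blocks_hrf(blocks$start, blocks$end, t_nulled,
                                       timeline$run_duration)
    resp_nn[, j] <- convolve_blocks_hrf(blocks$start, blocks$end, t_not_nulled,
                                        timeline$run_duration)
  }

  amp <- phantom$W %*% phantom$B_true            # n_vox x n_cond, percent
  cbv_n <- cbv_gain * amp %*% t(resp_n)          # n_vox x n_pairs
  cbv_nn <- cbv_gain * amp %*% t(resp_nn)
  bold_n <- bold_gain * amp %*% t(resp_n)
  bold_nn <- bold_gain * amp %*% t(resp_nn)

  baseline <- rlnorm(n_vox, meanlog = log(1000), sdlog = 0.1)

  drift_ramp <- seq(-0.5, 0.5, length.out = n_pairs)
  drift_n <- phantom$drift_amplitude * sample(c(-1, 1), 1) *
    matrix(drift_ramp, n_vox, n_pairs, byrow = TRUE)
  drift_nn <- phantom$drift_amplitude * sample(c(-1, 1), 1) *
    matrix(drift_ramp, n_vox, n_pairs, byrow = TRUE)

  noise_n <- if (phantom$noise_sd > 0) {
    matrix(rnorm(n_vox * n_pairs, sd = phantom$noise_sd), n_vox, n_pairs)
  } else 0
  noise_nn <- if (phantom$noise_sd > 0) {
    matrix(rnorm(n_vox * n_pairs, sd = phantom$noise_sd), n_vox, n_pairs)
  } else 0

  nulled <- baseline * (1 + (bold_n - cbv_n + drift_n + noise_n) / 100)
  not_nulled <- baseline * (1 + (bold_nn + drift_nn + noise_nn) / 100)

  structure(list(nulled = nulled, not_nulled = not_nulled, paired_tr = tr,
                 baseline = baseline, t_nulled = t_nulled,
                 t_not_nulled = t_not_nulled),
            class = "paired_vaso_run")
}

#' @export
print.paired_vaso_run <- function(x, ...) {
  cat(sprintf("<paired_vaso_run> %d voxels x %d pairs, paired TR %.2f s\n",
              nrow(x$nulled), ncol(x$nulled), x$paired_tr))
  invisible(x)
}
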