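#' Canonical double-gamma haemodynamic response function
#'
#' Standard double-gamma HRF with a response peak at 6 s, an undershoot peaking
#' at 16 s and a peak-to-undershoot ratio of 1/6, normalized so its maximum is
#' 1. Used both to generate synthetic block responses and to build GLM
#' regressors, so block betas read directly in percent signal change.
#'
#' @param t Time in seconds (vector).
#' @return HRF values at `t`, unit peak.
#' @export
canonical_hrf <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  # unit-peak normalization on a fine reference grid so scaling does not
  # depend on the sampling of t
  ref <- seq(0, 32, by = 0.01)
  peak <- max(dgamma(ref, shape = 6, rate = 1) - dgamma(ref, shape = 16, rate = 1) / 6)
  h / peak
}

# Convolve a condition boxcar (defined by block start/end times) with the
# canonical HRF and sample at the requested acquisition times. Computed on a
# fine internal grid (dt seconds) then linearly interpolated.
convolve_blocks_hrf <- function(block_start, block_end, sample_times,
                                run_duration, hrf = canonical_hrf, dt = 0.1) {
  grid <- seq(0, max(run_duration, max(sample_times, 0)) + dt, by = dt)
  box <- rep(0, length(grid))
  for (i in seq_along(block_start)) {
    box[grid >= block_start[i] & grid < block_end[i]] <- 1
  }
  kern <- hrf(seq(0, 32, by = dt))
  resp <- stats::convolve(box, rev(kern), type = "open")[seq_along(grid)] * dt
  # unit-peak scale the *block* response so a beta of 1 means 1% signal change
  # at plateau
  peak <- max(resp)
  if (peak > 0) resp <- resp / peak
  approx(grid, resp, xout = sample_times, rule = 2)$y
}
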