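#' BOLD-correct a paired VASO run (BOCO)
#'
#' Both series are temporally upsampled by a factor of two and the not-nulled
#' series is shifted by half a paired TR so the two contrasts are co-registered
#' on a common grid; the nulled series is then divided by the not-nulled
#' series to cancel the common BOLD-like component. The ratio is converted to
#' percent change about its per-voxel median and sign-inverted so that a CBV
#' *increase* is a *positive* response.
#'
#' @param run A `paired_vaso_run`.
#' @param interpolation `"linear"` (default) or `"sinc"` (Whittaker-Shannon on
#'   the regular paired grid).
#' @return A `cbv_timeseries`: list with `data` (n_voxels x 2*n_pairs, percent
#'   signal change, CBV-positive), `tr` (= paired_tr / 2), `times`.
#' @export
boco_correct <- function(run, interpolation = c("linear", "sinc")) {
  interpolation <- match.arg(interpolation)
  n_pairs <- ncol(run$nulled)
  if (n_pairs < 2) stop_invalid("need at least 2 pairs to interpolate")
  if (any(run$not_nulled <= 0)) stop_invalid("not-nulled signal must be strictly positive")
  tr_out <- run$paired_tr / 2
  t_out <- (seq_len(2 * n_pairs) - 1) * tr_out

  interp_row <- function(tin, x) {
    if (interpolation == "linear") {
      approx(tin, x, xout = t_out, rule = 2)$y
    } else {
      sinc_interp(tin, x, t_out)
    }
  }
  nulled_up <- t(apply(run$nulled, 1, function(x) interp_row(run$t_nulled, x)))
  nn_up <- t(apply(run$not_nulled, 1, function(x) interp_row(run$t_not_nulled, x)))

  ratio <- nulled_up / nn_up
  med <- apply(ratio, 1, median)
  data <- -100 * (ratio - med) / med

  structure(list(data = data, tr = tr_out, times = t_out,
                 native_times = run$t_nulled),
            class = "cbv_timeseries")
}

# Whittaker-Shannon interpolation for a uniformly sampled series; evaluation
# clamped to the sampled range (sinc extrapolation diverges)
sinc_interp <- function(tin, x, t_out) {
  dt <- tin[2] - tin[1]
  t_eval <- pmin(pmax(t_out, min(tin)), max(tin))
  s <- outer(t_eval, tin, function(a, b) {
    u <- (a - b) / dt
    ifelse(u == 0, 1, sin(pi * u) / (pi * u))
  })
  # normalize rows so a constant series interpolates to itself
  as.numeric((s %*% x) / rowSums(s))
}

#' Scale a timeseries to percent signal change
#'
#' Per voxel (row) and per run segment: `100 * (x - mean) / mean`. Voxels with
#' zero mean cannot be scaled; they are returned as `NA` with a warning.
#'
#' @param ts Matrix n_voxels x n_timepoints (or a vector).
#' @param run_lengths Optional integer vector partitioning the columns into
#'   runs; each run is scaled independently.
#' @return Matrix of the same shape, percent signal change (mean 0 per run).
#' @export
percent_signal_change <- function(ts, run_lengths = NULL) {
  if (is.vector(ts)) ts <- matrix(ts, nrow = 1)
  if (is.null(run_lengths)) run_lengths <- ncol(ts)
  if (sum(run_lengths) != ncol(ts)) stop_invalid("run_lengths must partition the columns")
  out <- ts
  stops <- cumsum(run_lengths)
  starts <- c(1, head(stops, -1) + 1)
  for (r in seq_along(run_lengths)) {
    idx <- starts[r]:stops[r]
    m <- rowMeans(ts[, idx, drop = FALSE])
    bad <- m == 0
    if (any(bad)) {
      warning(sprintf("%d voxel(s) with zero mean excluded from scaling", sum(bad)))
      m[bad] <- NA_real_
    }
    out[, idx] <- 100 * (ts[, idx, drop = FALSE] - m) / m
  }
  out
}

# condition regressors: per-condition block boxcars convolved with the
# canonical HRF, unit-plateau scaled. When the analyzed series was temporally
# upsampled from a coarser native grid (BOCO output), the regressors are
# sampled at the native grid and passed through the same linear upsampling,
# so interpolation attenuates model and data identically and betas stay
# unbiased.
build_condition_regressors <- function(timeline, times, hrf = canonical_hrf,
                                       native_times = NULL) {
  conds <- unique(timeline$blocks$condition)
  conds <- conds[order(-conds)]
  X <- sapply(conds, function(th) {
    blocks <- timeline$blocks[timeline$blocks$condition == th, , drop = FALSE]
    if (is.null(native_times)) {
      convolve_blocks_hrf(blocks$start, blocks$end, times,
                          timeline$run_duration, hrf = hrf)
    } else {
      r <- convolve_blocks_hrf(blocks$start, blocks$end, native_times,
                               timeline$run_duration, hrf = hrf)
      approx(native_times, r, xout = times, rule = 2)$y
    }
  })
  colnames(X) <- paste0("theta", conds)
  X
}

#' Fit a block-design GLM to a CBV (or BOLD) timeseries
#'
#' Ordinary least squares per voxel. Condition regressors are block boxcars
#' convolved with the canonical HRF and scaled to unit plateau, so betas read
#' as percent signal change from baseline. Nuisance regressors are Legendre
#' polynomials up to order 2 (baseline, linear and quadratic drift) plus any
#' user-supplied columns (e.g. motion estimates).
#'
#' @param ts A `cbv_timeseries`, or a matrix (then `tr` must be given).
#' @param timeline A `stimulus_timeline`.
#' @param nuisance Optional matrix of extra nuisance columns.
#' @param tr Sampling interval when `ts` is a bare matrix.
#' @return A `glm_result`: list with `betas` (n_voxels x n_regressors),
#'   `residual_sd`, `regressor_names`, `design`, `residuals`.
#' @export
fit_block_glm <- function(ts, timeline, nuisance = NULL, tr = NULL) {
  if (inherits(ts, "cbv_timeseries")) {
    data <- ts$data
    times <- ts$times
    native_times <- ts$native_times
  } else {
    if (is.null(tr)) stop_invalid("tr required when ts is a bare matrix")
    data <- ts
    times <- (seq_len(ncol(ts)) - 1) * tr
    native_times <- NULL
  }
  Xc <- build_condition_regressors(timeline, times, native_times = native_times)
  Xn <- legendre_drift(length(times), 2L)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (is.null(colnames(nuisance))) colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    Xn <- cbind(Xn, nuisance)
  }
  X <- cbind(Xc, Xn)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(X, t(data))
  betas <- t(fit$coefficients)
  resid <- t(fit$residuals)
  dfres <- ncol(data) - ncol(X)
  residual_sd <- sqrt(rowSums(resid^2) / dfres)

  structure(list(betas = betas, residual_sd = residual_sd,
                 regressor_names = colnames(X), design = X,
                 residuals = resid, condition_names = colnames(Xc)),
            class = "glm_result")
}

#' Temporal SNR and contrast-to-noise ratio per voxel
#'
#' tSNR is the mean of the raw (unscaled) series divided by its SD. CNR is the
#' stimulus-minus-fixation mean difference of the analyzed series divided by
#' the GLM residual SD.
#'
#' @param raw Matrix n_voxels x n_timepoints of raw signal (pre scaling).
#' @param ts A `cbv_timeseries` (analyzed series) or matrix aligned with
#'   `timeline` at `tr`.
#' @param timeline A `stimulus_timeline`.
#' @param tr Sampling interval when `ts` is a matrix.
#' @return Tibble with `voxel`, `tsnr`, `cnr`; constant voxels carry `NA` and
#'   a `flagged` mark.
#' @export
snr_metrics <- function(raw, ts, timeline, tr = NULL) {
  if (inherits(ts, "cbv_timeseries")) {
    data <- ts$data
    times <- ts$times
  } else {
    if (is.null(tr)) stop_invalid("tr required when ts is a bare matrix")
    data <- ts
    times <- (seq_len(ncol(ts)) - 1) * tr
  }
  stim <- !is.na(condition_at_time(timeline, times))
  if (sum(stim) < 2 || sum(!stim) < 2) {
    stop_invalid("need at least 2 stimulus and 2 fixation timepoints")
  }
  sd_raw <- apply(raw, 1, sd)
  flagged <- sd_raw == 0
  tsnr <- rowMeans(raw) / ifelse(flagged, NA_real_, sd_raw)

  fit <- fit_block_glm(if (inherits(ts, "cbv_timeseries")) ts else data,
                       timeline, tr = tr)
  rsd <- fit$residual_sd
  cnr <- (rowMeans(data[, stim, drop = FALSE]) -
            rowMeans(data[, !stim, drop = FALSE])) /
    ifelse(rsd == 0, NA_real_, rsd)
  tibble::tibble(voxel = seq_len(nrow(data)), tsnr = tsnr, cnr = cnr,
                 flagged = flagged | rsd == 0)
}
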