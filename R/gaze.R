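#' Simulate a fixational gaze trace at 1000 Hz
#'
#' Gaze positions are a bivariate AR(1) process (lag-1 coefficient `phi`)
#' whose stationary covariance matches the requested `sigma_x`, `sigma_y` and
#' `rho`, so downstream fixation-stability estimators face realistic temporal
#' autocorrelation. Blinks arrive as a Poisson process with rate
#' `blink_rate_hz` and exponentially distributed durations (mean 100 ms);
#' samples inside a blink are flagged invalid.
#'
#' @param duration_s Trace duration, seconds.
#' @param sigma_x,sigma_y Stationary SDs, degrees of visual angle.
#' @param rho Stationary correlation between x and y, |rho| < 1.
#' @param blink_rate_hz Blink rate, per second.
#' @param seed Integer seed.
#' @param phi AR(1) lag-1 coefficient.
#' @param timeline Optional `stimulus_timeline`; when given, each sample is
#'   labelled with the condition of the block covering it.
#' @return A `gaze_trace`: tibble-backed list with `t` (ms), `x`, `y`
#'   (degrees), `valid` (logical), `condition`, plus `blink_intervals`
#'   (tibble: start, end in ms).
#' @export
simulate_gaze <- function(duration_s, sigma_x, sigma_y, rho = 0,
                          blink_rate_hz = 0.2, seed = 1, phi = 0.95,
                          timeline = NULL) {
  if (abs(rho) >= 1) stop_invalid("|rho| must be < 1")
  if (sigma_x <= 0 || sigma_y <= 0) stop_invalid("sigmas must be positive")
  if (duration_s <= 0) stop_invalid("duration must be positive")
  set.seed(seed)
  n <- round(duration_s * 1000)
  t_ms <- seq_len(n)

  # innovations scaled so the AR(1) stationary covariance is the target
  Sigma <- matrix(c(sigma_x^2, rho * sigma_x * sigma_y,
                    rho * sigma_x * sigma_y, sigma_y^2), 2, 2)
  Sinn <- Sigma * (1 - phi^2)
  L <- chol(Sinn)
  innov <- matrix(rnorm(2 * n), n, 2) %*% L
  xy <- matrix(0, n, 2)
  xy[1, ] <- rnorm(2) %*% chol(Sigma)
  for (i in 2:n) xy[i, ] <- phi * xy[i - 1, ] + innov[i, ]

  # blinks: Poisson arrivals, exponential durations (mean 100 ms)
  n_blinks <- rpois(1, blink_rate_hz * duration_s)
  if (n_blinks > 0) {
    starts <- sort(runif(n_blinks, 0, duration_s * 1000))
    durs <- rexp(n_blinks, rate = 1 / 100)
    blink_intervals <- tibble::tibble(start = starts,
                                      end = pmin(starts + durs, duration_s * 1000))
  } else {
    blink_intervals <- tibble::tibble(start = numeric(), end = numeric())
  }
  valid <- rep(TRUE, n)
  for (i in seq_len(nrow(blink_intervals))) {
    valid[t_ms >= blink_intervals$start[i] & t_ms <= blink_intervals$end[i]] <- FALSE
  }

  condition <- if (!is.null(timeline)) {
    condition_at_time(timeline, (t_ms - 1) / 1000)
  } else rep(NA_real_, n)

  structure(list(
    samples = tibble::tibble(t = t_ms, x = xy[, 1], y = xy[, 2],
                             valid = valid, condition = condition),
    blink_intervals = blink_intervals
  ), class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d samples (%.1f s), %d blinks, %.1f%% valid\n",
              nrow(x$samples), nrow(x$samples) / 1000,
              nrow(x$blink_intervals), 100 * mean(x$samples$valid)))
  invisible(x)
}
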