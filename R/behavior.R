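#' Michelson contrast of bars against a uniform background
#'
#' @param L_bar Bar luminance, cd/m^2.
#' @param L0 Background luminance, cd/m^2. Bars darker than the background are
#'   not modelled.
#' @return `(L_bar - L0) / (L_bar + L0)`, in [0, 1).
#' @examples
#' michelson_contrast(78.9, 43.8) # staircase ceiling of the behavioral session
#' @export
michelson_contrast <- function(L_bar, L0) {
  if (any(L_bar <= 0) || any(L0 <= 0)) stop_invalid("luminances must be positive")
  if (any(L_bar < L0)) stop_invalid("L_bar must be >= L0 (darker bars not modelled)")
  (L_bar - L0) / (L_bar + L0)
}

#' Weibull psychometric function
#'
#' `p(correct | C) = gamma + (1 - gamma - lambda) * (1 - exp(-(C/alpha)^beta))`
#' for a 2AFC detection task (guess rate `gamma`, lapse rate `lambda`).
#'
#' @param C Michelson contrast (vector).
#' @param alpha Contrast scale of the Weibull.
#' @param beta Slope.
#' @param gamma Guess rate (0.5 for 2AFC).
#' @param lambda Lapse rate.
#' @export
weibull_p <- function(C, alpha, beta, gamma = 0.5, lambda = 0.01) {
  gamma + (1 - gamma - lambda) * (1 - exp(-(C / alpha)^beta))
}

# contrast at which the Weibull reaches raw accuracy p (closed form)
weibull_threshold <- function(alpha, beta, p = 0.80, gamma = 0.5, lambda = 0.01) {
  q <- (p - gamma) / (1 - gamma - lambda)
  if (q <= 0 || q >= 1) stop_invalid("accuracy %.2f unreachable for gamma=%.2f, lambda=%.3f", p, gamma, lambda)
  alpha * (-log(1 - q))^(1 / beta)
}

#' One step of an n-down-1-up staircase
#'
#' After `rule_down` consecutive correct responses the contrast is divided by
#' `1 + step_fraction` and the counter resets; after any error it is
#' multiplied by `1 + step_fraction` (counter resets). Geometric steps keep
#' contrast positive; the result is clipped to at most 1.
#'
#' @param contrast Current Michelson contrast.
#' @param counter Consecutive-correct counter before this trial.
#' @param last_correct Was the response correct?
#' @param step_fraction Step size as a fraction (default 0.15).
#' @param rule_down Correct responses required before a step down.
#' @return List with `contrast` (next trial) and `counter`.
#' @export
staircase_step <- function(contrast, counter, last_correct,
                           step_fraction = 0.15, rule_down = 3) {
  if (step_fraction <= 0 || step_fraction >= 1) stop_invalid("step_fraction must be in (0, 1)")
  if (last_correct) {
    counter <- counter + 1
    if (counter >= rule_down) {
      contrast <- contrast / (1 + step_fraction)
      counter <- 0
    }
  } else {
    contrast <- contrast * (1 + step_fraction)
    counter <- 0
  }
  list(contrast = min(contrast, 1), counter = counter)
}

#' Simulate interleaved 3-down-1-up staircase sessions
#'
#' Runs `n_staircases` independent staircases of `trials_each` trials against
#' a Weibull observer, with trial order randomly interleaved across staircases
#' as in blocked psychophysical sessions. Responses are Bernoulli draws from
#' the observer's psychometric function at the presented contrast.
#'
#' @param observer List with `alpha`, `beta`, and optionally `gamma`
#'   (default 0.5) and `lambda` (default 0.01).
#' @param n_staircases Number of staircases (default 4).
#' @param trials_each Trials per staircase (>= 10; default 60).
#' @param start_contrast Initial contrast (default 0.2863).
#' @param step_fraction Staircase step (default 0.15).
#' @param seed Integer seed.
#' @param condition Condition label attached to the record.
#' @return A tibble (class `staircase_record`) with columns `trial`,
#'   `staircase`, `contrast`, `correct`, `reversal`, `condition`.
#' @export
run_staircase_session <- function(observer, n_staircases = 4, trials_each = 60,
                                  start_contrast = 0.2863, step_fraction = 0.15,
                                  seed = 1, condition = NA_real_) {
  if (trials_each < 10) stop_invalid("trials_each must be >= 10")
  gamma <- if (is.null(observer$gamma)) 0.5 else observer$gamma
  lambda <- if (is.null(observer$lambda)) 0.01 else observer$lambda
  set.seed(seed)

  # interleave: random order over the pooled trial slots
  order <- sample(rep(seq_len(n_staircases), trials_each))
  contrast <- rep(start_contrast, n_staircases)
  counter <- rep(0L, n_staircases)
  last_dir <- rep(0L, n_staircases)   # -1 down, +1 up, 0 none yet

  n_total <- n_staircases * trials_each
  out <- tibble::tibble(trial = seq_len(n_total), staircase = order,
                        contrast = NA_real_, correct = NA,
                        reversal = FALSE, condition = condition)
  for (i in seq_len(n_total)) {
    s <- order[i]
    C <- contrast[s]
    p <- weibull_p(C, observer$alpha, observer$beta, gamma, lambda)
    corr <- runif(1) < p
    nxt <- staircase_step(C, counter[s], corr, step_fraction)
    dir <- sign(nxt$contrast - C)
    rev <- dir != 0 && last_dir[s] != 0 && dir != last_dir[s]
    if (dir != 0) last_dir[s] <- dir
    out$contrast[i] <- C
    out$correct[i] <- corr
    out$reversal[i] <- rev
    contrast[s] <- nxt$contrast
    counter[s] <- nxt$counter
  }
  class(out) <- c("staircase_record", class(out))
  out
}

#' Fit a Weibull psychometric function by maximum likelihood
#'
#' Estimates (`alpha`, `beta`) with guess and lapse rates fixed, maximizing
#' the Bernoulli likelihood on (log alpha, log beta) from five starting points
#' to avoid local optima. The threshold is the contrast at `threshold_p` raw
#' accuracy on the fitted curve, and sensitivity is its reciprocal.
#'
#' @param records A `staircase_record` tibble (or anything with `contrast` and
#'   `correct` columns); pooled across staircases.
#' @param gamma Fixed guess rate (default 0.5).
#' @param lambda Fixed lapse rate (default 0.01).
#' @param threshold_p Raw accuracy defining the threshold (default 0.80).
#' @return A `psychometric_fit`: list with `alpha_hat`, `beta_hat`,
#'   `C_threshold`, `S`, `loglik`, `n_trials`.
#' @export
fit_weibull <- function(records, gamma = 0.5, lambda = 0.01, threshold_p = 0.80) {
  C <- records$contrast
  y <- as.numeric(records$correct)
  if (length(unique(C)) < 2 || all(y == 1) || all(y == 0)) {
    stop_invalid("psychometric fit is not identifiable: need >= 2 contrast levels with both outcomes")
  }
  nll <- function(par) {
    p <- weibull_p(C, exp(par[1]), exp(par[2]), gamma, lambda)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  starts <- list(
    c(log(median(C)), log(3)),
    c(log(median(C) / 2), log(2)),
    c(log(median(C) * 2), log(4)),
    c(log(unname(quantile(C, 0.25))), log(1.5)),
    c(log(unname(quantile(C, 0.75))), log(6))
  )
  fits <- lapply(starts, function(s) {
    tryCatch(optim(s, nll, method = "Nelder-Mead"), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop_invalid("psychometric fit failed to converge")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  alpha_hat <- exp(best$par[1])
  beta_hat <- exp(best$par[2])
  C_thr <- weibull_threshold(alpha_hat, beta_hat, threshold_p, gamma, lambda)
  structure(list(alpha_hat = alpha_hat, beta_hat = beta_hat,
                 C_threshold = C_thr, S = 1 / C_thr,
                 gamma = gamma, lambda = lambda,
                 loglik = -best$value, n_trials = length(y)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> alpha %.4f, beta %.2f, C_threshold %.4f, S %.2f (%d trials)\n",
              x$alpha_hat, x$beta_hat, x$C_threshold, x$S, x$n_trials))
  invisible(x)
}

#' Behavioral saliency score from two contrast sensitivities
#'
#' The normalized sensitivity difference between the high and low
#' orientation-contrast conditions:
#' `SS = (S90 - S15) / ((S90 + S15) / 2)`.
#'
#' @param S90 Sensitivity (1/threshold contrast) at 90 degrees orientation
#'   contrast.
#' @param S15 Sensitivity at 15 degrees.
#' @return List with `S90`, `S15`, `SS_behavior`.
#' @examples
#' behavioral_saliency(18.719, 9.720)
#' @export
behavioral_saliency <- function(S90, S15) {
  if (any(S90 <= 0) || any(S15 <= 0)) stop_invalid("sensitivities must be positive")
  list(S90 = S90, S15 = S15,
       SS_behavior = (S90 - S15) / ((S90 + S15) / 2))
}
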