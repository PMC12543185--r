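#' Repeated-measures ANOVA with sphericity diagnostics
#'
#' One- or two-way within-subject ANOVA on a complete balanced long table.
#' Univariate F tests per effect with Mauchly's sphericity test and the
#' Greenhouse-Geisser epsilon and corrected p value (reported whenever the
#' effect has more than one numerator df).
#'
#' @param data Long data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of 1 or 2 within-subject factor columns.
#' @param subject Name of the subject column.
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`, `F`, `p`,
#'   `gg_epsilon`, `p_gg`, `mauchly_p`.
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  data <- as.data.frame(data)
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])

  cells <- interaction(data[within], drop = FALSE)
  tab <- table(data[[subject]], cells)
  if (any(tab != 1)) stop_invalid("within-subject table must be complete and balanced (one observation per subject per cell)")

  # wide subject x cell matrix, cells in a fixed factor order
  lev <- expand.grid(lapply(rev(within), function(w) levels(data[[w]])),
                     stringsAsFactors = FALSE)
  lev <- lev[, rev(seq_along(within)), drop = FALSE]
  names(lev) <- within
  key_data <- do.call(paste, c(data[within], sep = "\r"))
  key_lev <- do.call(paste, c(lev, sep = "\r"))
  subjects <- levels(data[[subject]])
  wide <- matrix(NA_real_, length(subjects), nrow(lev))
  for (i in seq_along(subjects)) {
    rows <- data[[subject]] == subjects[i]
    wide[i, ] <- data[[dv]][rows][match(key_lev, key_data[rows])]
  }

  idata <- as.data.frame(lapply(lev, factor))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  mlm <- lm(wide ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  # HF epsilon is not reported here; silence its clipping note
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })

  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  gg <- s$pval.adjustments
  sph <- s$sphericity.tests
  out <- lapply(effects, function(e) {
    Fe <- unname(ut[e, "F value"])
    pe <- unname(ut[e, "Pr(>F)"])
    # a zero effect sum of squares means F = 0 even when the error SS also
    # vanishes (0/0 in the ratio)
    if (ut[e, "Sum Sq"] < 1e-12) {
      Fe <- 0
      pe <- 1
    }
    tibble::tibble(
      effect = e,
      df1 = unname(ut[e, "num Df"]),
      df2 = unname(ut[e, "den Df"]),
      F = Fe,
      p = pe,
      gg_epsilon = if (!is.null(gg) && e %in% rownames(gg)) unname(gg[e, "GG eps"]) else NA_real_,
      p_gg = if (!is.null(gg) && e %in% rownames(gg)) unname(gg[e, "Pr(>F[GG])"]) else NA_real_,
      mauchly_p = if (!is.null(sph) && e %in% rownames(sph)) unname(sph[e, "p-value"]) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Paired t test
#'
#' @param a,b Paired numeric vectors.
#' @return List with `t`, `df`, `p`, `mean_diff`; a `degenerate` flag when the
#'   differences have zero variance.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) stop_invalid("a and b must be paired vectors of length >= 2")
  d <- a - b
  if (sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1, p = NA_real_, mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Numeric vectors (length >= 3, non-degenerate).
#' @return List with `r`, `p`, `df`; `degenerate` flag on zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop_invalid("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, df = length(x) - 2, degenerate = TRUE))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), degenerate = FALSE)
}

#' Max-statistic permutation test for FWE-corrected correlations
#'
#' Correlates a behavioral score with each of several ROI measures. Each
#' permutation shuffles the behavioral vector, recomputes all ROI
#' correlations, and records the largest absolute r; the family-wise p value
#' of each ROI is the add-one-corrected fraction of null maxima at least as
#' large as its observed |r|. With `exhaustive = TRUE` all n! assignments are
#' enumerated (exact test; feasible for n <= 7).
#'
#' @param behav Behavioral vector (n subjects).
#' @param fmri Matrix n x n_rois (a vector is treated as one ROI).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return A `permutation_result`: list with `observed_r`, `null_max_r`,
#'   `fwe_threshold` (95th percentile of the null maxima), `p_fwe`, `n_perm`.
#' @export
permutation_fwe <- function(behav, fmri, n_perm = 10000, seed = 1,
                            exhaustive = FALSE) {
  fmri <- as.matrix(fmri)
  n <- length(behav)
  if (n != nrow(fmri)) stop_invalid("behav and fmri must have the same number of subjects")
  if (n < 5) stop_invalid("need at least 5 subjects")
  if (!exhaustive && n_perm < 100) stop_invalid("n_perm must be >= 100")
  if (sd(behav) == 0 || any(apply(fmri, 2, sd) == 0)) {
    stop_invalid("degenerate input: zero variance in behav or an fmri column")
  }

  observed_r <- as.numeric(cor(behav, fmri))
  names(observed_r) <- colnames(fmri)

  # r for all permutations at once: scale columns, then crossproduct
  Z <- scale(fmri) / sqrt(n - 1)
  if (exhaustive) {
    perms <- all_permutations(n)
    B <- matrix(scale(behav)[perms], nrow(perms), n) / sqrt(n - 1)
    null_r <- B %*% Z
    null_max <- apply(abs(null_r), 1, max)
    p_fwe <- vapply(abs(observed_r),
                    function(r) mean(null_max >= r - 1e-12), numeric(1))
    n_eff <- nrow(perms)
  } else {
    set.seed(seed)
    bz <- as.numeric(scale(behav)) / sqrt(n - 1)
    B <- t(vapply(seq_len(n_perm), function(i) bz[sample.int(n)], numeric(n)))
    null_r <- B %*% Z
    null_max <- apply(abs(null_r), 1, max)
    p_fwe <- vapply(abs(observed_r),
                    function(r) (1 + sum(null_max >= r)) / (n_perm + 1),
                    numeric(1))
    n_eff <- n_perm
  }
  structure(list(observed_r = observed_r, null_max_r = null_max,
                 fwe_threshold = unname(quantile(null_max, 0.95)),
                 p_fwe = p_fwe, n_perm = n_eff, exhaustive = exhaustive),
            class = "permutation_result")
}

# all n! permutations of 1..n as a matrix (rows); recursion, n <= 7
all_permutations <- function(n) {
  if (n > 7) stop_invalid("exhaustive enumeration limited to n <= 7")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Holm step-down multiple-comparison adjustment
#'
#' @param pvals Vector of p values in [0, 1].
#' @return Holm-adjusted p values (same order as input).
#' @export
holm_correct <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop_invalid("p values must lie in [0, 1]")
  p.adjust(pvals, method = "holm")
}

#' Bivariate contour ellipse area of fixation
#'
#' Quantifies fixation stability as the area of the ellipse covering a
#' fraction `P` of gaze samples under a bivariate-normal model:
#' `BCEA = pi * chi2_2(P) * sigma_x * sigma_y * sqrt(1 - rho^2)`, with
#' `chi2_2(0.95) = 5.9915`. Preprocessing (on by default) mirrors standard
#' eye-tracking cleanup: blink intervals extended by 200 ms on both sides,
#' linear interpolation across removed samples, linear detrend of x and y,
#' and per-stimulus-block baseline (mean) subtraction.
#'
#' @param trace A `gaze_trace`.
#' @param P Coverage fraction (default 0.95).
#' @param preprocess Apply the cleanup pipeline before estimating moments.
#' @param const Ellipse scale constant; defaults to the chi-square quantile
#'   `qchisq(P, 2)`. Supply e.g. `2 * k` to use a k-factor parameterization.
#' @return A `bcea_result`: list with `sigma_x`, `sigma_y`, `rho`, `area`
#'   (degrees squared), `P`, `n_valid`, `degenerate`.
#' @export
bcea <- function(trace, P = 0.95, preprocess = TRUE, const = qchisq(P, 2)) {
  s <- if (preprocess) preprocess_gaze(trace)$samples else trace$samples
  ok <- s$valid
  if (sum(ok) < 100) stop_invalid("need at least 100 valid samples, have %d", sum(ok))
  sx <- sd(s$x[ok]); sy <- sd(s$y[ok]); rho <- if (sx > 0 && sy > 0) cor(s$x[ok], s$y[ok]) else 0
  degenerate <- sx == 0 || sy == 0
  area <- if (degenerate) 0 else pi * const * sx * sy * sqrt(1 - rho^2)
  structure(list(sigma_x = sx, sigma_y = sy, rho = rho, area = area, P = P,
                 n_valid = sum(ok), degenerate = degenerate),
            class = "bcea_result")
}

#' Preprocess a gaze trace for fixation analysis
#'
#' Extends every blink interval by 200 ms on both sides, linearly interpolates
#' x and y across the removed stretches, removes a linear trend from each
#' coordinate, and subtracts the per-stimulus-block mean (blocks identified
#' from the condition labels; unlabelled stretches form their own segments).
#' All samples are valid after interpolation unless a coordinate could not be
#' interpolated at the trace edge.
#'
#' @param trace A `gaze_trace`.
#' @param blink_pad_ms Padding added around blinks (default 200).
#' @return A `gaze_trace` with cleaned samples.
#' @export
preprocess_gaze <- function(trace, blink_pad_ms = 200) {
  s <- trace$samples
  valid <- s$valid
  for (i in seq_len(nrow(trace$blink_intervals))) {
    a <- trace$blink_intervals$start[i] - blink_pad_ms
    b <- trace$blink_intervals$end[i] + blink_pad_ms
    valid[s$t >= a & s$t <= b] <- FALSE
  }
  if (!any(valid)) stop_invalid("no valid samples remain after blink removal")
  interp <- function(v) {
    if (all(valid)) return(v)
    approx(s$t[valid], v[valid], xout = s$t, rule = 2)$y
  }
  x <- interp(s$x); y <- interp(s$y)
  # linear detrend
  tt <- s$t
  x <- x - stats::fitted(lm(x ~ tt))
  y <- y - stats::fitted(lm(y ~ tt))
  # per-block baseline: contiguous runs of equal condition label
  cond <- ifelse(is.na(s$condition), -1, s$condition)
  block_id <- cumsum(c(1, diff(cond) != 0))
  x <- x - stats::ave(x, block_id)
  y <- y - stats::ave(y, block_id)

  out <- trace
  out$samples <- tibble::tibble(t = s$t, x = x, y = y, valid = TRUE,
                                condition = s$condition)
  out
}

#' Fraction of gaze samples below the fixation center
#'
#' Among valid samples inside an optional analysis window, the fraction with
#' `y < 0`, computed per stimulus condition (and overall).
#'
#' @param trace A `gaze_trace` (preprocess first if desired).
#' @param region Optional list with `x = c(min, max)` and/or `y = c(min, max)`
#'   bounds restricting the samples analyzed.
#' @return Tibble with `condition` (including `"all"`) and `fraction`.
#' @export
gaze_below_fixation_fraction <- function(trace, region = NULL) {
  s <- trace$samples
  keep <- s$valid
  if (!is.null(region$x)) keep <- keep & s$x >= region$x[1] & s$x <= region$x[2]
  if (!is.null(region$y)) keep <- keep & s$y >= region$y[1] & s$y <= region$y[2]
  s <- s[keep, , drop = FALSE]
  conds <- sort(unique(s$condition[!is.na(s$condition)]), decreasing = TRUE)
  rows <- lapply(conds, function(th) {
    sub <- s[!is.na(s$condition) & s$condition == th, , drop = FALSE]
    tibble::tibble(condition = as.character(th),
                   fraction = if (nrow(sub) == 0) NA_real_ else mean(sub$y < 0))
  })
  rows <- c(rows, list(tibble::tibble(condition = "all",
                                      fraction = if (nrow(s) == 0) NA_real_ else mean(s$y < 0))))
  do.call(rbind, rows)
}
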