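#' Build a deconvolution-free gPPI design
#'
#' The seed timeseries is z-scored over the run. For each condition a stimulus
#' boxcar is sampled at the series' TR; the psychophysiological interaction
#' regressor is the elementwise product of the boxcar *shifted by one TR* (to
#' account for the haemodynamic delay, without deconvolution) and the z-scored
#' seed.
#'
#' @param seed_ts Seed timeseries (e.g. depth-averaged BOLD of V1
#'   superficial), length matching the timeline sampled at `tr`.
#' @param timeline A `stimulus_timeline`.
#' @param tr Sampling interval of the series, seconds.
#' @param shift_trs Boxcar shift in TRs of the analyzed series (default 1).
#' @param nuisance Optional extra nuisance columns (e.g. motion).
#' @return A `ppi_design`: list with `seed_z`, `stim` (matrix, one boxcar per
#'   condition), `ppi` (matrix, one interaction per condition), `nuisance`.
#' @export
build_ppi_design <- function(seed_ts, timeline, tr, shift_trs = 1L,
                             nuisance = NULL) {
  n <- length(seed_ts)
  expected <- floor(timeline$run_duration / tr)
  if (n != expected) {
    stop_invalid("seed length %d does not match timeline sampled at tr=%.3f (expected %d)",
                 n, tr, expected)
  }
  if (sd(seed_ts) == 0) stop_invalid("seed timeseries has zero variance")
  seed_z <- as.numeric(scale(seed_ts))

  times <- (seq_len(n) - 1) * tr
  conds <- unique(timeline$blocks$condition)
  conds <- conds[order(-conds)]
  box <- sapply(conds, function(th) {
    blocks <- timeline$blocks[timeline$blocks$condition == th, , drop = FALSE]
    out <- rep(0, n)
    for (i in seq_len(nrow(blocks))) {
      out[times >= blocks$start[i] & times < blocks$end[i]] <- 1
    }
    out
  })
  colnames(box) <- paste0("theta", conds)

  shifted <- rbind(matrix(0, shift_trs, ncol(box)),
                   box[seq_len(n - shift_trs), , drop = FALSE])
  ppi <- shifted * seed_z
  colnames(ppi) <- paste0("ppi_", colnames(box))

  drift <- legendre_drift(n, 2L)
  if (!is.null(nuisance)) drift <- cbind(drift, as.matrix(nuisance))

  structure(list(seed_z = seed_z, stim = box, ppi = ppi, nuisance = drift,
                 conditions = conds, tr = tr),
            class = "ppi_design")
}

#' Fit a gPPI model to a target timeseries
#'
#' OLS regression of the target on the seed timecourse, the per-condition
#' stimulus boxcars, the per-condition PPI interaction terms, and nuisance
#' regressors. The saliency-dependent connectivity is the difference of the
#' PPI betas between the 90 and 15 degree conditions.
#'
#' @param target_ts Target timeseries (same length as the design).
#' @param design A `ppi_design`.
#' @return A `connectivity_result`: list with `beta_ppi` (named per
#'   condition), `beta_seed`, `beta_stim`, `delta` (= ppi 90 minus ppi 15).
#' @export
fit_gppi <- function(target_ts, design) {
  X <- cbind(seed = design$seed_z, design$stim, design$ppi, design$nuisance)
  if (length(target_ts) != nrow(X)) stop_invalid("target length does not match design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_invalid("gPPI design is rank deficient")
  beta <- qr.coef(qrX, target_ts)
  ppi_names <- colnames(design$ppi)
  beta_ppi <- setNames(beta[ppi_names], sub("^ppi_theta", "", ppi_names))
  delta <- if (all(c("90", "15") %in% names(beta_ppi))) {
    unname(beta_ppi["90"] - beta_ppi["15"])
  } else NA_real_
  structure(list(beta_ppi = beta_ppi, beta_seed = unname(beta["seed"]),
                 beta_stim = beta[colnames(design$stim)], delta = delta),
            class = "connectivity_result")
}

#' Layer-dependent pathway analysis between V1 and IPS
#'
#' Runs the gPPI model for the two hypothesized pathways — feedforward (seed
#' V1 superficial, target IPS middle) and feedback (seed IPS deep, target V1
#' deep) — separately per hemisphere, then averages betas across hemispheres.
#' Also returns the full 3 x 3 depth-pair delta matrix (V1 seed depth x IPS
#' target depth, feedforward direction).
#'
#' @param hemis Named list (`left`, `right`, or one of them) of lists with
#'   elements `v1` and `ips`: matrices n_timepoints x 3 with columns named
#'   `deep`, `middle`, `superficial`.
#' @param timeline A `stimulus_timeline`.
#' @param tr Sampling interval, seconds.
#' @param shift_trs Boxcar shift passed to [build_ppi_design()].
#' @return List with `feedforward` and `feedback` (each: `beta_ppi`, `delta`,
#'   averaged over hemispheres), `depth_matrix` (3 x 3 deltas), and
#'   `per_hemisphere` details.
#' @export
pathway_analysis <- function(hemis, timeline, tr, shift_trs = 1L) {
  if (length(hemis) == 0) stop_invalid("at least one hemisphere required")
  for (h in names(hemis)) {
    for (roi in c("v1", "ips")) {
      m <- hemis[[h]][[roi]]
      if (is.null(m) || !all(CORTICAL_LAYERS %in% colnames(m))) {
        stop_invalid("hemisphere %s is missing depth series for %s", h, roi)
      }
    }
  }
  one_hemi <- function(hd) {
    ff_design <- build_ppi_design(hd$v1[, "superficial"], timeline, tr, shift_trs)
    ff <- fit_gppi(hd$ips[, "middle"], ff_design)
    fb_design <- build_ppi_design(hd$ips[, "deep"], timeline, tr, shift_trs)
    fb <- fit_gppi(hd$v1[, "deep"], fb_design)
    dm <- matrix(NA_real_, 3, 3, dimnames = list(v1 = CORTICAL_LAYERS,
                                                 ips = CORTICAL_LAYERS))
    for (i in CORTICAL_LAYERS) {
      d_i <- build_ppi_design(hd$v1[, i], timeline, tr, shift_trs)
      for (j in CORTICAL_LAYERS) {
        dm[i, j] <- fit_gppi(hd$ips[, j], d_i)$delta
      }
    }
    list(feedforward = ff, feedback = fb, depth_matrix = dm)
  }
  per_h <- lapply(hemis, one_hemi)

  avg_result <- function(field) {
    bp <- Reduce(`+`, lapply(per_h, function(p) p[[field]]$beta_ppi)) / length(per_h)
    list(beta_ppi = bp, delta = unname(bp["90"] - bp["15"]))
  }
  list(
    feedforward = avg_result("feedforward"),
    feedback = avg_result("feedback"),
    depth_matrix = Reduce(`+`, lapply(per_h, `[[`, "depth_matrix")) / length(per_h),
    per_hemisphere = per_h
  )
}
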