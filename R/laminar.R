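#' Unmix voxel responses into layer responses by spatial regression
#'
#' Solves the partial-volume model `Y = X B + U` by ordinary least squares,
#' where `Y` holds per-voxel response estimates (betas) and `X` the voxel
#' layer-weight matrix over the five compartments (WM, deep, middle,
#' superficial, CSF). Standard errors come from the residual variance and
#' `(X'X)^-1`.
#'
#' @param Y Numeric vector of per-voxel betas (length n_voxels), or a matrix
#'   n_voxels x k to unmix several response maps at once.
#' @param X Layer-weight matrix n_voxels x 5 (rows sum to 1).
#' @return A list with `B` (length-5 vector or 5 x k matrix of layer betas),
#'   `se` (same shape), `sigma` (residual SD per column), `df`.
#' @export
unmix_layers <- function(Y, X) {
  X <- as.matrix(X)
  Ymat <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1)
  if (nrow(Ymat) != nrow(X)) stop_invalid("Y and X must have the same number of voxels")
  if (nrow(X) < ncol(X)) stop_invalid("fewer voxels (%d) than compartments (%d)", nrow(X), ncol(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_invalid("layer-weight matrix is rank deficient (rank %d < %d)", qrX$rank, ncol(X))

  fit <- lm.fit(X, Ymat)
  B <- as.matrix(fit$coefficients)
  resid <- Ymat - X %*% B
  df <- nrow(X) - ncol(X)
  sigma <- sqrt(colSums(resid^2) / df)
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(xtx_inv)) %o% sigma

  nm <- colnames(X)
  if (is.null(nm)) nm <- COMPARTMENTS[seq_len(ncol(X))]
  rownames(B) <- rownames(se) <- nm
  if (!is.matrix(Y)) {
    B <- setNames(as.numeric(B), nm)
    se <- setNames(as.numeric(se), nm)
  }
  list(B = B, se = se, sigma = sigma, df = df)
}

#' Normalize laminar responses across subjects
#'
#' Scales each subject's layer-by-condition response array by its root mean
#' square over the 3 cortical layers x 3 conditions (9 cells) and multiplies
#' by the group mean of these normalizers, removing individual differences in
#' overall response amplitude while keeping the group scale in percent signal
#' change: `S(s,l,theta) = r(s,l,theta) / r_norm(s) * r_bar`.
#'
#' @param r Array subjects x layers x conditions. The layer dimension may have
#'   3 (cortical layers) or 5 (all compartments; the middle three are used for
#'   normalization and returned).
#' @return A `layer_profile`: list with `S` (subjects x 3 layers x
#'   conditions), `r` (raw cortical-layer responses), `r_norm` (per subject),
#'   `r_bar`.
#' @export
normalize_responses <- function(r) {
  if (length(dim(r)) != 3) stop_invalid("r must be a 3-d array (subjects x layers x conditions)")
  if (dim(r)[2] == 5) r <- r[, 2:4, , drop = FALSE]
  if (dim(r)[2] != 3) stop_invalid("layer dimension must have 3 (or 5) entries")
  n_sub <- dim(r)[1]
  r_norm <- apply(r, 1, function(m) sqrt(mean(m^2)))
  zero <- r_norm == 0
  if (any(zero)) stop_invalid("subject(s) %s have all-zero responses",
                              paste(which(zero), collapse = ", "))
  r_bar <- mean(r_norm)
  S <- r
  for (s in seq_len(n_sub)) S[s, , ] <- r[s, , ] / r_norm[s] * r_bar
  if (is.null(dimnames(S)[[2]])) dimnames(S)[[2]] <- CORTICAL_LAYERS
  structure(list(S = S, r = r, r_norm = r_norm, r_bar = r_bar),
            class = "layer_profile")
}

#' Saliency contrasts across cortical depth
#'
#' From a normalized layer profile, computes per subject and layer the
#' saliency-sensitive response `SS = S(90) - S(15)`, the alternative contrast
#' `S(90) - S(0)`, and the background-suppression contrast
#' `(S(90) + S(15))/2 - S(0)`.
#'
#' @param profile A `layer_profile` whose condition dimension is named
#'   `"90"`, `"15"`, `"0"` (in any order).
#' @return List of subjects x layers matrices: `SS`, `alt`, `suppression`.
#' @export
saliency_contrasts <- function(profile) {
  S <- profile$S
  cn <- dimnames(S)[[3]]
  if (is.null(cn)) cn <- c("90", "15", "0")
  need <- c("90", "15", "0")
  if (!all(need %in% cn)) {
    stop_invalid("missing condition(s): %s", paste(setdiff(need, cn), collapse = ", "))
  }
  slice <- function(i) {
    matrix(S[, , i], dim(S)[1], dim(S)[2],
           dimnames = list(dimnames(S)[[1]], dimnames(S)[[2]]))
  }
  s90 <- slice(which(cn == "90"))
  s15 <- slice(which(cn == "15"))
  s0 <- slice(which(cn == "0"))
  list(SS = s90 - s15, alt = s90 - s0, suppression = (s90 + s15) / 2 - s0)
}

#' SNR-normalize a laminar saliency contrast
#'
#' Divides the per-layer saliency contrast by the per-layer SNR (tSNR or CNR)
#' to check that laminar ordering is not driven by depth-dependent
#' signal-to-noise differences.
#'
#' @param SS Matrix subjects x layers of saliency contrasts.
#' @param snr Positive per-layer SNR: a length-`n_layers` vector or a matrix
#'   matching `SS`.
#' @return Matrix of `SS / snr`, same shape as `SS`.
#' @export
snr_normalized_saliency <- function(SS, snr) {
  SS <- as.matrix(SS)
  if (is.vector(snr)) snr <- matrix(snr, nrow(SS), ncol(SS), byrow = TRUE)
  if (any(snr <= 0)) stop_invalid("snr must be strictly positive")
  if (!all(dim(snr) == dim(SS))) stop_invalid("snr dimensions must match SS")
  SS / snr
}
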