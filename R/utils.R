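#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor cor.test dgamma lm lm.fit median optim qchisq
#'   quantile rexp rgamma rlnorm rnorm runif sd setNames t.test p.adjust rpois
#' @importFrom utils head
NULL

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Derive a per-component random seed from a global seed
#'
#' Expands one global seed into independent per-component streams by hashing
#' the seed with a stream offset. Results stay below 2^31 so they are valid R
#' integer seeds.
#'
#' @param seed Global integer seed.
#' @param stream Integer stream index (component number).
#' @return An integer seed for `set.seed()`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  # multiplicative LCG hash (Park-Miller constants), kept in double precision
  x <- (as.double(seed) %% 2147483647) + 1
  for (k in seq_len(stream + 1)) {
    x <- (x * 48271) %% 2147483647
  }
  as.integer(x)
}

# Legendre polynomial drift basis on [-1, 1], orders 0..degree, one column each.
legendre_drift <- function(n_timepoints, degree = 2L) {
  x <- seq(-1, 1, length.out = n_timepoints)
  cols <- lapply(0:degree, function(d) {
    switch(as.character(d),
      "0" = rep(1, n_timepoints),
      "1" = x,
      "2" = 0.5 * (3 * x^2 - 1),
      "3" = 0.5 * (5 * x^3 - 3 * x),
      stop_invalid("Legendre drift supports degree <= 3, got %d", d)
    )
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("drift", 0:degree)
  m
}

# canonical compartment names, white matter to CSF
COMPARTMENTS <- c("wm", "deep", "middle", "superficial", "csf")
CORTICAL_LAYERS <- c("deep", "middle", "superficial")
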