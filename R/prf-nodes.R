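#' Generate a synthetic population receptive field node table
#'
#' Synthetic stand-in for an atlas-derived pRF map of one hemisphere: polar
#' angles uniform on [0, 180] degrees (within-hemisphere convention, 0 = upper
#' vertical meridian), eccentricities log-uniform on [0.5, 10] degrees, and
#' pRF sizes growing linearly with eccentricity, floored at 0.1 degrees. Node
#' 1 is always the anchor node at exactly (`Am`, `Em`) — the localizer-peak
#' vertex used to correct the map.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param hemisphere `"left"` or `"right"`.
#' @param Am Anchor polar angle, degrees in (0, 180).
#' @param Em Anchor eccentricity, degrees (> 0).
#' @param sigma_slope pRF size per degree of eccentricity.
#' @param seed Integer seed.
#' @return A tibble with columns `node`, `hemisphere`, `A`, `E`, `sigma`.
#' @export
generate_prf_nodes <- function(n_nodes, hemisphere = c("left", "right"),
                               Am = 127.88, Em = 4.28, sigma_slope = 0.2,
                               seed = 1) {
  hemisphere <- match.arg(hemisphere)
  if (!(Am > 0 && Am < 180)) stop_invalid("Am must be in (0, 180)")
  if (Em <= 0) stop_invalid("Em must be positive")
  if (n_nodes < 1) stop_invalid("n_nodes must be >= 1")
  set.seed(seed)
  A <- c(Am, runif(n_nodes - 1, 0, 180))
  E <- c(Em, exp(runif(n_nodes - 1, log(0.5), log(10))))
  tibble::tibble(
    node = seq_len(n_nodes),
    hemisphere = hemisphere,
    A = A,
    E = E,
    sigma = pmax(0.1, sigma_slope * E)
  )
}
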