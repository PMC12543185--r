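#' Correct pRF coordinates by aligning the localizer peak to the stimulus
#'
#' Piecewise-linear transform that maps the localizer-peak polar angle `Am`
#' onto the stimulus polar angle (127.88 degrees) while pinning the vertical
#' meridians (0 and 180 degrees), and rescales eccentricity so `Em` maps onto
#' the stimulus eccentricity (4.28 degrees):
#' \deqn{Ac = A/Am \cdot 127.88 \; (A \le Am); \quad
#'       Ac = 180 - (180-A)/(180-Am) \cdot (180-127.88) \; (A > Am); \quad
#'       Ec = E/Em \cdot 4.28.}
#'
#' @param A Polar angle, degrees in [0, 180] (within-hemisphere convention).
#' @param E Eccentricity, degrees (>= 0).
#' @param Am,Em Localizer-peak coordinates (Am in (0, 180), Em > 0).
#' @param A_target,E_target Stimulus location; defaults 127.88 and 4.28
#'   degrees.
#' @return List with `Ac` and `Ec` (vectors like `A`, `E`).
#' @export
correct_prf <- function(A, E, Am, Em, A_target = 127.88, E_target = 4.28) {
  if (Am <= 0 || Am >= 180) stop_invalid("Am must lie strictly inside (0, 180)")
  if (Em <= 0) stop_invalid("Em must be positive")
  if (any(A < 0 | A > 180)) stop_invalid("A must lie in [0, 180]")
  if (any(E < 0)) stop_invalid("E must be non-negative")
  Ac <- ifelse(A <= Am,
               A / Am * A_target,
               180 - (180 - A) / (180 - Am) * (180 - A_target))
  Ec <- E / Em * E_target
  list(Ac = Ac, Ec = Ec)
}

#' Default visual-field grid for map reconstruction
#'
#' Covers the lower visual field where the texture stimulus is shown:
#' x in [-8, 8], y in [-8, 0] degrees, 0.1-degree step.
#'
#' @param x_range,y_range Extent in degrees.
#' @param step Grid step in degrees.
#' @return List with `x`, `y` (cell-center coordinates) and `step`.
#' @export
field_grid <- function(x_range = c(-8, 8), y_range = c(-8, 0), step = 0.1) {
  list(x = seq(x_range[1], x_range[2], by = step),
       y = seq(y_range[1], y_range[2], by = step),
       step = step)
}

# Cartesian visual-field position of a corrected pRF center. Polar angle runs
# from the upper vertical meridian (0) to the lower vertical meridian (180)
# within a hemisphere; the left hemisphere represents the right hemifield.
prf_center_xy <- function(Ac, Ec, hemisphere) {
  sgn <- ifelse(hemisphere == "left", 1, -1)
  list(x = sgn * Ec * sin(Ac * pi / 180),
       y = Ec * cos(Ac * pi / 180))
}

#' Evaluate a node's pRF as a unit-volume Gaussian on the field grid
#'
#' Isotropic Gaussian of SD `sigma` centered at the Cartesian position of the
#' corrected coordinates (`Ac`, `Ec`), scaled so its mass (sum times cell
#' area) is 1 for centers well inside the grid. If the center lies outside the
#' grid extent a warning reports the truncated mass.
#'
#' @param node One row of a pRF node table: needs `Ac`, `Ec`, `sigma`,
#'   `hemisphere`.
#' @param grid A grid from [field_grid()].
#' @return Matrix length(y) x length(x) of Gaussian weights (density units).
#' @export
node_prf_image <- function(node, grid = field_grid()) {
  if (node$sigma <= 0) stop_invalid("sigma must be positive")
  ctr <- prf_center_xy(node$Ac, node$Ec, node$hemisphere)
  gx <- exp(-(grid$x - ctr$x)^2 / (2 * node$sigma^2))
  gy <- exp(-(grid$y - ctr$y)^2 / (2 * node$sigma^2))
  img <- (gy %o% gx) / (2 * pi * node$sigma^2)
  if (ctr$x < min(grid$x) || ctr$x > max(grid$x) ||
      ctr$y < min(grid$y) || ctr$y > max(grid$y)) {
    mass <- sum(img) * grid$step^2
    warning(sprintf("pRF center (%.2f, %.2f) outside grid; %.0f%% of mass truncated",
                    ctr$x, ctr$y, 100 * (1 - mass)))
  }
  img
}

#' Back-project node responses into visual-field saliency maps
#'
#' For each cortical depth, sums every node's response times its corrected
#' pRF image, then divides *all* depths by the single maximum across depths so
#' laminar differences survive normalization; the across-depth maximum is
#' exactly 1. If maps from several subjects are supplied they are averaged
#' after normalization.
#'
#' @param nodes A tibble with columns `Ac`, `Ec`, `sigma`, `hemisphere`,
#'   `depth` (factor/character over layers), and `response` — or `response`
#'   supplied separately via `responses`.
#' @param responses Optional vector of per-node responses overriding
#'   `nodes$response`.
#' @param grid A grid from [field_grid()].
#' @return A `field_map`: list with `maps` (named list of matrices per
#'   depth), `normalizer` (the across-depth max before scaling), `grid`.
#' @export
reconstruct_field_map <- function(nodes, responses = NULL, grid = field_grid()) {
  if (nrow(nodes) == 0) stop_invalid("node set is empty")
  if (!is.null(responses)) nodes$response <- responses
  if (is.null(nodes$response)) stop_invalid("node responses are required")
  if (is.null(nodes$depth)) nodes$depth <- "all"

  depths <- unique(nodes$depth)
  maps <- lapply(depths, function(d) {
    sub <- nodes[nodes$depth == d, , drop = FALSE]
    acc <- matrix(0, length(grid$y), length(grid$x))
    for (i in seq_len(nrow(sub))) {
      acc <- acc + sub$response[i] * node_prf_image(sub[i, ], grid)
    }
    acc
  })
  names(maps) <- depths

  normalizer <- max(vapply(maps, max, numeric(1)))
  degenerate <- normalizer <= 0
  if (!degenerate) maps <- lapply(maps, function(m) m / normalizer)

  structure(list(maps = maps, normalizer = normalizer, grid = grid,
                 degenerate = degenerate),
            class = "field_map")
}

#' Average normalized field maps across subjects
#'
#' @param map_list List of `field_map` objects with identical depth names and
#'   grids.
#' @return A `field_map` with per-depth averages of the normalized maps.
#' @export
average_field_maps <- function(map_list) {
  if (length(map_list) == 0) stop_invalid("no maps to average")
  depths <- names(map_list[[1]]$maps)
  maps <- lapply(depths, function(d) {
    Reduce(`+`, lapply(map_list, function(m) m$maps[[d]])) / length(map_list)
  })
  names(maps) <- depths
  structure(list(maps = maps, normalizer = NA_real_,
                 grid = map_list[[1]]$grid, degenerate = FALSE),
            class = "field_map")
}
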