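#' Vertical column grid
#'
#' Builds the vertical layer geometry used by every other component: layer
#' thicknesses, cumulative interface depths (layer bottoms), layer mid-depths,
#' and a nominal horizontal cell area.
#'
#' @param thicknesses numeric vector of layer thicknesses in metres, surface
#'   layer first. All must be strictly positive.
#' @param area nominal horizontal area of the column in m^2 (default 1).
#'
#' @return An object of class `column_grid`: a list with `thickness`,
#'   `interface_depth` (depth of each layer bottom, m), `mid_depth`,
#'   `n_layers`, `bottom_depth` and `area`.
#' @examples
#' g <- column_grid(c(50, 80))
#' g$interface_depth  # 50, 130
#' @export
column_grid <- function(thicknesses, area = 1) {
  thicknesses <- as.numeric(thicknesses)
  if (length(thicknesses) == 0L)
    stop("grid needs at least one layer", call. = FALSE)
  if (any(!is.finite(thicknesses)) || any(thicknesses <= 0))
    stop("all layer thicknesses must be finite and > 0", call. = FALSE)
  if (!is.numeric(area) || length(area) != 1L || area <= 0)
    stop("`area` must be a single positive number", call. = FALSE)
  iface <- cumsum(thicknesses)
  structure(list(
    thickness       = thicknesses,
    interface_depth = iface,
    mid_depth       = iface - thicknesses / 2,
    n_layers        = length(thicknesses),
    bottom_depth    = iface[length(iface)],
    area            = area
  ), class = "column_grid")
}

#' @export
print.column_grid <- function(x, ...) {
  cat(sprintf("<column_grid> %d layers, bottom %.0f m (surface layer %.0f m)\n",
              x$n_layers, x$bottom_depth, x$thickness[1]))
  invisible(x)
}

#' Default 19-layer grid
#'
#' The default vertical grid: a 50 m surface layer, an 80 m second layer (so
#' the second interface sits at 130 m, the depth at which export diagnostics
#' are evaluated), and the remaining layers geometrically increasing in
#' thickness down to an abyssal bottom.
#'
#' @param bottom_depth total column depth in metres (default 5000).
#' @param n_layers total number of layers (default 19).
#' @param area nominal column area, m^2.
#' @return A [column_grid()].
#' @export
default_grid <- function(bottom_depth = 5000, n_layers = 19, area = 1) {
  if (n_layers < 3)
    stop("default grid needs at least 3 layers", call. = FALSE)
  if (bottom_depth <= 130)
    stop("`bottom_depth` must exceed 130 m", call. = FALSE)
  n_deep <- n_layers - 2L
  remaining <- bottom_depth - 130
  # deep layers: 80 * r, 80 * r^2, ... summing to the remaining depth
  f <- function(r) 80 * r * (r^n_deep - 1) / (r - 1) - remaining
  if (f(1 + 1e-9) > 0) {
    # shallower than a uniform continuation: fall back to equal deep layers
    thick <- c(50, 80, rep(remaining / n_deep, n_deep))
  } else {
    r <- stats::uniroot(f, c(1 + 1e-9, 3), tol = 1e-12)$root
    thick <- c(50, 80, 80 * r^seq_len(n_deep))
    thick[n_layers] <- thick[n_layers] + (bottom_depth - sum(thick))  # absorb rounding
  }
  column_grid(thick, area = area)
}

#' Column integral of a per-layer field
#'
#' @param field per-layer concentration (e.g. particles m^-3).
#' @param grid a [column_grid()].
#' @return areal inventory (field units times m).
#' @export
column_integral <- function(field, grid) {
  stopifnot(inherits(grid, "column_grid"))
  if (length(field) != grid$n_layers)
    stop("`field` length must equal the number of layers", call. = FALSE)
  sum(field * grid$thickness)
}

#' Depth-bracket inventories
#'
#' Integrates a per-layer concentration over depth brackets (e.g. 0-100 m,
#' 100-500 m, below 500 m). Bracket edges may split a layer; the layer's
#' contribution is pro-rated linearly by the thickness fraction inside the
#' bracket.
#'
#' @param field per-layer concentration (particles m^-3 or mmol N m^-3).
#' @param grid a [column_grid()].
#' @param brackets a list of length-2 numeric vectors `c(z_top, z_bottom)` in
#'   metres, or a 2-column matrix with one bracket per row.
#' @return numeric vector of areal inventories, one per bracket.
#' @examples
#' g <- column_grid(c(50, 80))
#' depth_bracket_inventory(rep(1, 2), g, list(c(0, 100)))  # 100
#' @export
depth_bracket_inventory <- function(field, grid, brackets) {
  stopifnot(inherits(grid, "column_grid"))
  if (length(field) != grid$n_layers)
    stop("`field` length must equal the number of layers", call. = FALSE)
  if (is.matrix(brackets)) brackets <- asplit(brackets, 1)
  z_bot <- grid$interface_depth
  z_top <- c(0, z_bot[-grid$n_layers])
  vapply(brackets, function(b) {
    b <- as.numeric(b)
    if (length(b) != 2L || !all(is.finite(b)))
      stop("each bracket must be c(z_top, z_bottom)", call. = FALSE)
    if (b[1] >= b[2])
      stop(sprintf("inverted bracket (%g >= %g)", b[1], b[2]), call. = FALSE)
    if (b[1] < 0 || b[2] > grid$bottom_depth + 1e-9)
      stop("bracket must lie within [0, bottom_depth]", call. = FALSE)
    overlap <- pmax(0, pmin(z_bot, b[2]) - pmax(z_top, b[1]))
    sum(field * overlap)
  }, numeric(1))
}

#' Standard analysis brackets
#'
#' The three depth brackets used for inventory maps: 0-100 m, 100-500 m, and
#' 500 m to the column bottom.
#' @param grid a [column_grid()].
#' @return list of brackets for [depth_bracket_inventory()].
#' @export
standard_brackets <- function(grid) {
  list(c(0, 100), c(100, 500), c(500, grid$bottom_depth))
}
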