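#' Annual plastic waste generation
#'
#' Total global plastic waste generation: 2 million metric tonnes per year in
#' 1950, compounding at 8.4 % per year thereafter. Years before the start
#' year return 0.
#'
#' @param year calendar year (vectorised).
#' @param base_tonnes generation in the start year, tonnes yr^-1.
#' @param growth_rate annual fractional growth (default 0.084).
#' @param start_year onset year (default 1950).
#' @return tonnes yr^-1.
#' @examples
#' waste_generation(1950)  # 2e6
#' waste_generation(1951)  # 2.168e6
#' @export
waste_generation <- function(year, base_tonnes = 2e6, growth_rate = 0.084,
                             start_year = 1950) {
  ifelse(year < start_year, 0,
         base_tonnes * (1 + growth_rate)^(year - start_year))
}

#' Per-column microplastic emission rate
#'
#' The global microplastic input is `F_T` times the annual waste generation,
#' converted from tonnes to particles, and distributed over columns by a
#' non-negative weight vector that sums to 1. All emission enters the surface
#' layer of the receiving column.
#'
#' @param year calendar year.
#' @param params an [mp_parameters()] object (uses `F_T` and the
#'   mass-to-particle conversion).
#' @param weights per-column emission weights; must be non-negative and sum
#'   to 1 (within `tol`).
#' @param base_tonnes,growth_rate,start_year passed to [waste_generation()].
#' @param tol tolerance on the weight sum (default 1e-8).
#' @return particles yr^-1 per column.
#' @export
mp_emission <- function(year, params, weights = 1,
                        base_tonnes = 2e6, growth_rate = 0.084,
                        start_year = 1950, tol = 1e-8) {
  if (any(weights < 0))
    stop("emission weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > tol)
    stop(sprintf("emission weights must sum to 1 (got %.6g)", sum(weights)),
         call. = FALSE)
  global <- params$F_T *
    waste_generation(year, base_tonnes, growth_rate, start_year) *
    particles_per_tonne(params)
  weights * global
}

#' Tabulate the forcing time series
#'
#' @param years integer vector of calendar years.
#' @param params an [mp_parameters()] object.
#' @param base_tonnes,growth_rate,start_year passed to [waste_generation()].
#' @return data.frame with `year`, `waste_tonnes` and `mp_particles` (global
#'   annual input after applying `F_T` and the mass conversion).
#' @export
forcing_series <- function(years, params = mp_parameters(F_T = 1),
                           base_tonnes = 2e6, growth_rate = 0.084,
                           start_year = 1950) {
  w <- waste_generation(years, base_tonnes, growth_rate, start_year)
  data.frame(year = years, waste_tonnes = w,
             mp_particles = params$F_T * w * particles_per_tonne(params))
}

#' Idealised column temperature profile
#'
#' A mixed layer at the surface temperature over the top `mld` metres, then
#' an exponential relaxation towards the deep temperature with e-folding
#' scale `decay_m`. Temperatures are clamped to the valid ocean range
#' \[-2, 35\] degC.
#'
#' @param grid a [column_grid()].
#' @param surface_C mixed-layer temperature, degC.
#' @param deep_C abyssal temperature, degC (default 2).
#' @param mld mixed-layer depth, m (default 50).
#' @param decay_m thermocline e-folding scale, m (default 200).
#' @return per-layer temperature at layer mid-depths, degC.
#' @export
temperature_profile <- function(grid, surface_C, deep_C = 2, mld = 50,
                                decay_m = 200) {
  z <- grid$mid_depth
  t <- deep_C + (surface_C - deep_C) * exp(-pmax(z - mld, 0) / decay_m)
  pmin(pmax(t, -2), 35)
}

#' Prescribed temperature scenario
#'
#' Wraps per-column base profiles with an idealised linear warming trend
#' applied after a reference year (default 2000), decaying with depth to
#' represent surface-intensified warming. This stands in for a coupled
#' high-emissions climate response, which is outside this model's scope.
#'
#' @param profiles a list of per-layer base temperature profiles (one per
#'   column), or a single numeric profile.
#' @param trend_C_per_century surface warming rate after `trend_start_year`,
#'   degC per century (default 0).
#' @param trend_start_year year the trend switches on (default 2000).
#' @param trend_decay_m e-folding depth of the warming signal, m (default 300).
#' @param grid the [column_grid()] the profiles live on.
#' @return An object of class `temperature_scenario`.
#' @export
temperature_scenario <- function(profiles, grid, trend_C_per_century = 0,
                                 trend_start_year = 2000,
                                 trend_decay_m = 300) {
  if (is.numeric(profiles)) profiles <- list(profiles)
  lapply(profiles, function(p) {
    if (length(p) != grid$n_layers)
      stop("each profile must have one value per layer", call. = FALSE)
    if (any(p < -2 - 1e-9) || any(p > 35 + 1e-9))
      stop("temperatures must lie in [-2, 35] degC", call. = FALSE)
  })
  structure(list(profiles = profiles, grid = grid,
                 trend_C_per_century = trend_C_per_century,
                 trend_start_year = trend_start_year,
                 trend_decay_m = trend_decay_m),
            class = "temperature_scenario")
}

#' Evaluate a temperature scenario
#'
#' @param scenario a [temperature_scenario()].
#' @param year calendar year.
#' @param column column index (default 1).
#' @return per-layer temperature, degC.
#' @export
temperature_at <- function(scenario, year, column = 1) {
  stopifnot(inherits(scenario, "temperature_scenario"))
  base <- scenario$profiles[[column]]
  dy <- max(0, year - scenario$trend_start_year)
  if (dy == 0 || scenario$trend_C_per_century == 0) return(base)
  z <- scenario$grid$mid_depth
  warming <- scenario$trend_C_per_century * (dy / 100) *
    exp(-z / scenario$trend_decay_m)
  pmin(pmax(base + warming, -2), 35)
}
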