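#' Microplastic export efficiency
#'
#' The export flux of bound microplastic past the diagnostic depth (130 m by
#' default, the bottom of the second model layer) divided by the integrated
#' gross microplastic uptake rate above that depth, both averaged over the
#' same period. Defined as 0 where the integrated uptake is 0 (e.g. high
#' latitudes with no plastic).
#'
#' @param flux export flux, particles m^-2 per period (>= 0).
#' @param uptake integrated uptake above the export depth, particles m^-2
#'   per period (>= 0).
#' @return dimensionless efficiency (vectorised).
#' @export
mp_export_efficiency <- function(flux, uptake) {
  if (any(flux < 0) || any(uptake < 0))
    stop("flux and uptake must be >= 0", call. = FALSE)
  ifelse(uptake > 0, flux / uptake, 0)
}

#' Particulate organic nitrogen export efficiency
#'
#' Detrital export at the diagnostic depth divided by the integrated
#' production above it: net primary production for the marine snow class,
#' grazing for the faecal pellet class. Shares the 0/0 -> 0 convention with
#' [mp_export_efficiency()]. Values above 1 are possible when material is
#' imported from elsewhere rather than produced locally.
#'
#' @param export detrital export flux, mmol N m^-2 per period.
#' @param production integrated production above the export depth,
#'   mmol N m^-2 per period.
#' @return dimensionless efficiency (vectorised).
#' @export
pon_export_efficiency <- function(export, production) {
  if (any(export < 0) || any(production < 0))
    stop("export and production must be >= 0", call. = FALSE)
  ifelse(production > 0, export / production, 0)
}

#' Missing surface microplastic fraction
#'
#' The share of the total column microplastic inventory (all three
#' compartments) residing below the surface layer: the model analogue of
#' surface plastic that a neuston net would not find. 0 when the column
#' holds no plastic.
#'
#' @param state a [tracer_state()].
#' @param grid a [column_grid()].
#' @return dimensionless fraction in \[0, 1\].
#' @export
missing_fraction <- function(state, grid) {
  tot_field <- state$MP + state$MP_A + state$MP_Z
  total <- column_integral(tot_field, grid)
  if (total <= 0) return(0)
  surface <- tot_field[1] * grid$thickness[1]
  1 - surface / total
}

#' Classify the shape of a free microplastic profile
#'
#' Flags the profile features used by the ensemble plausibility filter:
#' a surface or sub-surface local minimum, a sub-surface local maximum below
#' that minimum (the signature of release of plastic from sinking organic
#' carriers), and the goodness of a power-law fit (log-log linear
#' regression) on the tail below the minimum.
#'
#' @param profile free microplastic concentration per layer, surface first.
#' @param grid a [column_grid()].
#' @param r2_threshold minimum R-squared for the power-law flag
#'   (default 0.95).
#' @param min_points minimum number of strictly positive tail points for the
#'   power-law fit (default 4).
#' @return list with `has_minimum`, `has_subsurface_maximum`,
#'   `power_law` (logical) and `power_law_r2` (NA when not estimable).
#' @export
classify_profile <- function(profile, grid, r2_threshold = 0.95,
                             min_points = 4) {
  n <- length(profile)
  if (n != grid$n_layers)
    stop("`profile` length must equal the number of layers", call. = FALSE)
  has_min <- FALSE; min_idx <- NA_integer_
  if (n >= 2) {
    interior_min <- which(diff(sign(diff(profile))) > 0) + 1L
    if (profile[1] < profile[2]) interior_min <- c(1L, interior_min)
    if (length(interior_min) > 0) {
      has_min <- TRUE
      min_idx <- interior_min[1]
    }
  }
  has_max <- FALSE
  if (has_min && min_idx < n) {
    below <- profile[min_idx:n]
    im <- which.max(below)
    has_max <- im > 1 && im < length(below) &&
      below[im] > below[im - 1] && below[im] >= below[im + 1]
  }
  # power-law fit on the decaying tail (below the shallowest maximum)
  start <- if (has_min) min_idx else 1L
  peak <- start - 1L + which.max(profile[start:n])
  tail_idx <- seq(peak, n)
  z <- grid$mid_depth[tail_idx]; c_ <- profile[tail_idx]
  keep <- c_ > 0 & z > 0
  r2 <- NA_real_
  if (sum(keep) >= min_points && stats::sd(log(c_[keep])) > 0) {
    # R^2 of the log-log linear fit (squared correlation)
    r2 <- stats::cor(log(z[keep]), log(c_[keep]))^2
  }
  list(has_minimum = has_min,
       has_subsurface_maximum = has_max,
       power_law = isTRUE(r2 >= r2_threshold),
       power_law_r2 = r2)
}

#' Summarise a simulation for analysis and filtering
#'
#' Per column: the final-year diagnostic record plus the profile-shape
#' classification of the final-year annual-mean free microplastic profile,
#' and run-level metrics used by the ensemble plausibility filter.
#'
#' @param run an `mpsink_run` from [run_simulation()].
#' @param year calendar year to summarise (default: last simulated year).
#' @return data.frame, one row per column, joining the diagnostic record
#'   with `has_minimum`, `has_subsurface_maximum`, `power_law` and
#'   `power_law_r2`.
#' @export
summarize_run <- function(run, year = NULL) {
  stopifnot(inherits(run, "mpsink_run"))
  d <- run$diagnostics
  if (is.null(year)) year <- max(d$year)
  rows <- d[d$year == year, , drop = FALSE]
  grid <- run$config$grid
  shape <- lapply(seq_len(nrow(rows)), function(i) {
    pr <- run$profiles[[rows$column[i]]]
    yi <- match(year, pr$years)
    if (is.na(yi)) return(list(has_minimum = NA, has_subsurface_maximum = NA,
                               power_law = NA, power_law_r2 = NA_real_))
    classify_profile(pr$MP[yi, ], grid)
  })
  cbind(rows,
        has_minimum = vapply(shape, function(s) isTRUE(s$has_minimum), logical(1)),
        has_subsurface_maximum =
          vapply(shape, function(s) isTRUE(s$has_subsurface_maximum), logical(1)),
        power_law = vapply(shape, function(s) isTRUE(s$power_law), logical(1)),
        power_law_r2 = vapply(shape, function(s)
          if (is.numeric(s$power_law_r2)) s$power_law_r2 else NA_real_, numeric(1)))
}
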