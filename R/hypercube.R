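#' Screened parameter ranges
#'
#' The ranges over which the seven microplastic parameters are screened:
#' F_T and F_A and F_B in \[0, 1\], F_R in \[0, 0.1\], k_P in \[0, 1000\]
#' particles m^-3, psi_MP in \[0.1, 0.3\], R_F_MP in \[0.5, 1.5\].
#'
#' @return named list of `c(min, max)` ranges.
#' @export
default_ranges <- function() {
  list(F_T = c(0, 1), F_R = c(0, 0.1), F_A = c(0, 1), k_P = c(0, 1000),
       F_B = c(0, 1), psi_MP = c(0.1, 0.3), R_F_MP = c(0.5, 1.5))
}

#' Latin hypercube design for the microplastic parameter space
#'
#' @param n_samples number of ensemble members (the full published protocol
#'   uses 700; 30 is a practical desk-scale default).
#' @param seed integer seed making the design reproducible.
#' @param stage model complexity stage: `"no_bio"` (physical parameters
#'   only), `"snow_only"` (adds marine snow aggregation), `"full"` (adds
#'   zooplankton grazing of plastic).
#' @param ranges per-parameter ranges (default [default_ranges()]).
#' @param k_P_strata list of k_P sub-ranges sampled separately so the
#'   strongly nonlinear uptake coefficient is covered across decades
#'   (default `(0,1)`, `(1,100)`, `(100,1000)`); used in the snow_only and
#'   full stages.
#' @param sd_frac the sampling distribution within each range is a normal
#'   truncated to the range, centred at the midpoint with
#'   `sd = sd_frac * range width` (default 0.25).
#' @return An object of class `hypercube_design`.
#' @export
hypercube_design <- function(n_samples = 30, seed = 1,
                             stage = c("full", "snow_only", "no_bio"),
                             ranges = default_ranges(),
                             k_P_strata = list(c(0, 1), c(1, 100), c(100, 1000)),
                             sd_frac = 0.25) {
  stage <- match.arg(stage)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] >= r[2])
      stop(sprintf("invalid range for %s", nm), call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 stage = stage, ranges = ranges, k_P_strata = k_P_strata,
                 sd_frac = sd_frac),
            class = "hypercube_design")
}

#' Active parameters of a model complexity stage
#'
#' The incremental screening protocol: `no_bio` varies only the physical
#' parameters (F_T, F_R) with biological uptake disabled; `snow_only` adds
#' the marine snow pathway (F_A, k_P, F_B); `full` adds zooplankton grazing
#' (psi_MP, R_F_MP).
#'
#' @param stage one of `"no_bio"`, `"snow_only"`, `"full"`.
#' @return character vector of active parameter names.
#' @export
configure_stage <- function(stage = c("full", "snow_only", "no_bio")) {
  stage <- match.arg(stage)
  switch(stage,
         no_bio = c("F_T", "F_R"),
         snow_only = c("F_T", "F_R", "F_A", "k_P", "F_B"),
         full = c("F_T", "F_R", "F_A", "k_P", "F_B", "psi_MP", "R_F_MP"))
}

# quantile of a normal truncated to [a, b], centred mid-range
qtnorm_range <- function(u, a, b, sd_frac) {
  mu <- (a + b) / 2
  sd <- sd_frac * (b - a)
  pa <- stats::pnorm(a, mu, sd); pb <- stats::pnorm(b, mu, sd)
  stats::qnorm(pa + u * (pb - pa), mu, sd)
}

# one-parameter LHS draw: n equal-probability strata, one sample per
# stratum, stratum order permuted
lhs_column <- function(n, a, b, sd_frac) {
  u <- (sample.int(n) - stats::runif(n)) / n
  qtnorm_range(u, a, b, sd_frac)
}

#' Sample a Latin hypercube of parameter sets
#'
#' Stratified sampling: each active parameter's range is cut into
#' `n_samples` equal-probability strata under a truncated normal centred at
#' mid-range, one sample is drawn per stratum, and strata are permuted
#' independently per parameter. `k_P` is additionally split across its
#' sub-ranges with an (approximately) equal number of members per sub-range,
#' each sub-range sampled with its own Latin layout. Deterministic given the
#' design seed.
#'
#' @param design a [hypercube_design()].
#' @return data.frame with one row per member: `sample` id and the seven
#'   parameter columns (inactive parameters are fixed at their stage
#'   defaults: 0 for F_A/psi_MP/F_B, 1 for k_P/R_F_MP).
#' @export
sample_hypercube <- function(design) {
  stopifnot(inherits(design, "hypercube_design"))
  n <- design$n_samples
  active <- configure_stage(design$stage)
  set.seed(design$seed)
  out <- data.frame(sample = seq_len(n))
  fixed <- list(F_T = 0, F_R = 0, F_A = 0, k_P = 1, F_B = 0,
                psi_MP = 0, R_F_MP = 1)
  for (nm in c("F_T", "F_R", "F_A", "k_P", "F_B", "psi_MP", "R_F_MP")) {
    if (!nm %in% active) {
      out[[nm]] <- fixed[[nm]]
    } else if (nm == "k_P" && length(design$k_P_strata) > 1) {
      ns <- length(design$k_P_strata)
      grp <- rep(seq_len(ns), length.out = n)  # round-robin allocation
      x <- numeric(n)
      for (g in seq_len(ns)) {
        idx <- which(grp == g)
        r <- design$k_P_strata[[g]]
        x[idx] <- lhs_column(length(idx), r[1], r[2], design$sd_frac)
      }
      out[[nm]] <- x
    } else {
      r <- design$ranges[[nm]]
      out[[nm]] <- lhs_column(n, r[1], r[2], design$sd_frac)
    }
  }
  out
}

#' Default plausibility-filter thresholds
#'
#' The published screening criteria are stated qualitatively ("roughly",
#' "generously"); the bands here are deliberately generous defaults and are
#' fully configurable.
#'
#' @param F_T_band plausible band on the ocean-entry fraction. About 4 % of
#'   plastic waste is estimated to enter the ocean; the default allows a
#'   10-fold guard above that (and a 10-fold guard below 4 % of that
#'   estimate).
#' @param inventory_band_global plausible band on the total ocean
#'   microplastic inventory at the filter year, particles.
#' @param agg_band plausible band on the annual-mean surface marine snow
#'   aggregate formation rate, aggregates m^-3 d^-1.
#' @param require_profile require a sub-surface particle maximum below a
#'   local minimum in the free microplastic profile.
#' @param filter_year year at which inventory criteria are evaluated
#'   (default 2010).
#' @return named list of thresholds.
#' @export
default_filter_thresholds <- function(F_T_band = c(0.004, 0.4),
                                      inventory_band_global = c(1e12, 1e18),
                                      agg_band = c(0.1, 1e5),
                                      require_profile = TRUE,
                                      filter_year = 2010) {
  list(F_T_band = F_T_band, inventory_band_global = inventory_band_global,
       agg_band = agg_band, require_profile = require_profile,
       filter_year = filter_year)
}

#' Plausibility filter for an ensemble member
#'
#' Six boolean criteria: (1) the run is numerically stable; (2) the total
#' microplastic inventory does not exceed the time-integrated pollution
#' input; (3) the implied annual ocean pollution rate (F_T) lies in a band
#' around the independent ~4 % ocean-entry estimate; (4) the mean surface
#' aggregation rate lies in a (generous) band around independently measured
#' marine snow aggregation rates; (5) the inventory at the filter year lies
#' in an agreement band around an independent estimate; (6) the free
#' microplastic profile shows a sub-surface maximum below a local minimum.
#' An unstable run fails all criteria.
#'
#' @param member one-row data.frame (or list) with `stable`, `F_T`,
#'   `total_inventory` (particles m^-2), `cum_emission` (particles m^-2),
#'   `agg_formation_surface`, `has_minimum`, `has_subsurface_maximum`.
#' @param thresholds see [default_filter_thresholds()].
#' @param ocean_area_m2 area converting per-m^2 column inventories to global
#'   totals (default 3.61e14).
#' @return named logical vector of the six criteria plus `plausible` (all
#'   six true).
#' @export
plausibility_filter <- function(member,
                                thresholds = default_filter_thresholds(),
                                ocean_area_m2 = 3.61e14) {
  th <- thresholds
  if (!isTRUE(member$stable)) {
    v <- stats::setNames(rep(FALSE, 7),
                         c("stable", "below_cumulative_input", "pollution_rate",
                           "aggregation_rate", "inventory_2010", "profile_shape",
                           "plausible"))
    return(v)
  }
  inv_global <- member$total_inventory * ocean_area_m2
  v <- c(
    stable = TRUE,
    below_cumulative_input =
      member$total_inventory <= member$cum_emission * (1 + 1e-9),
    pollution_rate =
      member$F_T >= th$F_T_band[1] && member$F_T <= th$F_T_band[2],
    aggregation_rate =
      member$agg_formation_surface >= th$agg_band[1] &&
      member$agg_formation_surface <= th$agg_band[2],
    inventory_2010 =
      inv_global >= th$inventory_band_global[1] &&
      inv_global <= th$inventory_band_global[2],
    profile_shape = !isTRUE(th$require_profile) ||
      (isTRUE(member$has_minimum) && isTRUE(member$has_subsurface_maximum))
  )
  c(v, plausible = all(v))
}

#' Run a parameter ensemble
#'
#' Samples the hypercube, runs every member through [run_simulation()] under
#' a shared base configuration, and applies the plausibility filter to the
#' filter-year summary of each run. Member failures are recorded as
#' unstable; the ensemble continues. Fully reproducible given the design
#' seed.
#'
#' @param design a [hypercube_design()].
#' @param base_config a [run_config()] supplying everything except the
#'   microplastic parameters (grid, years, columns, ecosystem, transport,
#'   forcing).
#' @param thresholds filter thresholds (see [default_filter_thresholds()]).
#' @return data.frame, one row per member: parameters, summary metrics and
#'   filter verdicts.
#' @export
run_ensemble <- function(design, base_config = run_config(),
                         thresholds = default_filter_thresholds()) {
  samples <- sample_hypercube(design)
  ocean_area <- base_config$forcing$ocean_area_m2
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    member <- list(sample = s$sample, F_T = s$F_T, F_R = s$F_R, F_A = s$F_A,
                   k_P = max(s$k_P, 1e-12), F_B = s$F_B, psi_MP = s$psi_MP,
                   R_F_MP = s$R_F_MP)
    res <- tryCatch({
      cfg <- base_config
      cfg$params <- mp_parameters(F_T = member$F_T, F_R = member$F_R,
                                  F_A = member$F_A, k_P = member$k_P,
                                  F_B = member$F_B, psi_MP = member$psi_MP,
                                  R_F_MP = member$R_F_MP)
      run <- run_simulation(cfg)
      fy <- min(thresholds$filter_year, max(run$diagnostics$year))
      sm <- summarize_run(run, year = fy)
      sm <- sm[1, ]  # filter on the first (reference) column
      sm$stable <- all(run$stable) && sm$stable
      sm
    }, error = function(e) NULL)
    if (is.null(res)) {
      res <- data.frame(stable = FALSE, total_inventory = NA_real_,
                        cum_emission = NA_real_,
                        agg_formation_surface = NA_real_,
                        has_minimum = NA, has_subsurface_maximum = NA,
                        surface_MP_total = NA_real_,
                        uptake_export_ratio = NA_real_,
                        missing_fraction = NA_real_)
    }
    verdict <- plausibility_filter(
      c(member, as.list(res)), thresholds, ocean_area)
    data.frame(sample = member$sample, F_T = member$F_T, F_R = member$F_R,
               F_A = member$F_A, k_P = s$k_P, F_B = member$F_B,
               psi_MP = member$psi_MP, R_F_MP = member$R_F_MP,
               stable = isTRUE(res$stable),
               total_inventory = res$total_inventory,
               cum_emission = res$cum_emission,
               surface_MP_total = res$surface_MP_total,
               uptake_export_ratio = res$uptake_export_ratio,
               missing_fraction = res$missing_fraction,
               agg_formation_surface = res$agg_formation_surface,
               t(as.matrix(verdict)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
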