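# Operator-split column step:
#   (1) ecosystem source/sink tendencies (positivity-limited),
#   (2) microplastic exchange tendencies + surface emission,
#   (3) vertical transport: sinking (detritus, MP_A, MP_Z), buoyant rise of
#       free MP (sub-cycled), diffusion of all tracers,
#   (4) seafloor exchange (detritus N returned; MP split by F_B).
# Sources before transport keeps the particle budget identity exact per step.
column_step <- function(state, grid, T_C, light, dt, params, eco, prefs,
                        w, kappa_md, emis_conc, k_exp) {
  nz <- grid$n_layers
  dz <- grid$thickness

  mp_as_N <- mp_to_nitrogen(state$MP, params)
  fl <- eco_fluxes(state, T_C, light, eco, prefs, mp_as_N)
  fl <- limit_fluxes(fl, state, dt)
  td <- eco_tendencies(fl, eco)

  mp_raw <- list(
    A_upt = aggregation_uptake(state$MP, td$src_DET_A, params),
    A_rel = fl$mu_D * state$MP_A,
    P_upt = nitrogen_to_mp(fl$G_MP_N, params),
    P_rel = fl$mu_D * state$MP_Z)
  mp_lim <- limit_mp_fluxes(mp_raw, state, dt)
  emis_vec <- c(emis_conc, rep(0, nz - 1L))
  mp_td <- mp_tendencies(mp_lim, emis_vec)

  state$N     <- state$N     + dt * td$dN
  state$PH    <- state$PH    + dt * td$dPH
  state$CO    <- state$CO    + dt * td$dCO
  state$DZ    <- state$DZ    + dt * td$dDZ
  state$Z     <- state$Z     + dt * td$dZ
  state$DET_A <- state$DET_A + dt * td$dDET_A
  state$DET_Z <- state$DET_Z + dt * td$dDET_Z
  state$MP    <- state$MP    + dt * mp_td$dMP
  state$MP_A  <- state$MP_A  + dt * mp_td$dMP_A
  state$MP_Z  <- state$MP_Z  + dt * mp_td$dMP_Z

  # sinking (flux-form upwind); record the flux at the export interface
  fx_DA <- w * state$DET_A
  fx_DZ <- w * state$DET_Z
  fx_MA <- w * state$MP_A
  fx_MZ <- w * state$MP_Z
  shift <- function(fx) c(0, fx[-nz])
  state$DET_A <- state$DET_A + dt * (shift(fx_DA) - fx_DA) / dz
  state$DET_Z <- state$DET_Z + dt * (shift(fx_DZ) - fx_DZ) / dz
  state$MP_A  <- state$MP_A  + dt * (shift(fx_MA) - fx_MA) / dz
  state$MP_Z  <- state$MP_Z  + dt * (shift(fx_MZ) - fx_MZ) / dz

  # seafloor: detrital N is remineralised into the bottom layer (a closed
  # nitrogen budget stand-in for sediment exchange); bound MP splits by F_B
  state$N[nz] <- state$N[nz] + dt * (fx_DA[nz] + fx_DZ[nz]) / dz[nz]
  sf <- seafloor_exchange(fx_MA[nz], fx_MZ[nz], params$F_B)
  state$MP[nz] <- state$MP[nz] + dt * sf$returned / dz[nz]

  state$MP <- apply_rise(state$MP, params$F_R, params$w_p_ms * 86400, grid, dt)

  for (nm in names(state))
    state[[nm]] <- diffuse(state[[nm]], kappa_md, grid, dt)

  above <- seq_len(k_exp)
  diag <- c(
    upt_A_above  = sum(mp_lim$A_upt[above] * dz[above]),
    upt_Z_above  = sum(mp_lim$P_upt[above] * dz[above]),
    exp_MPA      = fx_MA[k_exp],
    exp_MPZ      = fx_MZ[k_exp],
    exp_DET_A    = fx_DA[k_exp],
    exp_DET_Z    = fx_DZ[k_exp],
    npp_above    = sum(td$NPP[above] * dz[above]),
    graz_above   = sum(td$G_food[above] * dz[above]),
    sf_lost      = sf$lost,
    sf_returned  = sf$returned,
    emitted      = emis_conc * dz[1],
    agg_formation_surface = aggregate_count(td$src_DET_A[1], params))

  list(state = state, diag = diag,
       fluxes = list(eco = td, mp = mp_lim))
}

#' Advance the full column model one time step
#'
#' One operator-split step: ecosystem sources/sinks, microplastic exchange
#' and emission, vertical transport (sinking, sub-cycled buoyant rise,
#' mixing), and seafloor exchange. All tracers remain non-negative; the
#' microplastic particle budget (emission minus inventory change minus
#' permanent seafloor loss) closes exactly up to floating-point error.
#'
#' @param state a [tracer_state()].
#' @param grid a [column_grid()].
#' @param T_C per-layer temperature, degC.
#' @param dt time step, days (must satisfy the sinking CFL condition).
#' @param params an [mp_parameters()] object.
#' @param eco an [eco_parameters()] object.
#' @param tcfg a [transport_config()].
#' @param emission surface-layer emission rate, particles m^-3 d^-1.
#' @param light optional per-layer light factor (defaults to
#'   [light_profile()]).
#' @param export_depth depth (m) of the interface at which export fluxes are
#'   recorded (default 130).
#' @return list with the updated `state`, per-step `diag` scalars
#'   (integrated uptake above the export depth, export fluxes, seafloor
#'   loss/return, emission), and the limited `fluxes`.
#' @export
step_column <- function(state, grid, T_C, dt, params,
                        eco = eco_parameters(), tcfg = transport_config(),
                        emission = 0, light = NULL, export_depth = 130) {
  w <- sinking_speed(grid, tcfg)
  check_cfl(w, grid, dt)
  if (is.null(light)) light <- light_profile(grid, eco)
  kappa_md <- kappa_interfaces(grid, tcfg)
  prefs <- renormalise_preferences(params$psi_MP)
  k_exp <- which.min(abs(grid$interface_depth - export_depth))
  column_step(state, grid, T_C, light, dt, params, eco, prefs,
              w, kappa_md, emission, k_exp)
}

#' Assemble a run configuration
#'
#' Collects everything a simulation needs: the grid, the microplastic
#' parameter set (or the name of a packaged fixture), ecosystem and
#' transport constants, the emission forcing, the column definitions and the
#' temperature scenario.
#'
#' Each column is a named list with `name`, `surface_C` (mixed-layer
#' temperature), optional `deep_C`, `weight` (share of the global emission
#' and of the represented ocean area; weights must sum to 1) and
#' `emission_factor` (local emission flux relative to the global mean).
#'
#' @param params an [mp_parameters()] object, a fixture name (see
#'   [fixture_parameters()]), or a named list of parameter overrides.
#' @param grid a [column_grid()] (default [default_grid()]).
#' @param columns list of column definitions (default: one tropical column,
#'   surface 28 degC).
#' @param years length-2 vector, first and last simulated calendar year.
#' @param spinup_years ecosystem spin-up years before the start year
#'   (no emission), default 30.
#' @param dt time step in days (default 0.5; rounded so a 365-day year holds
#'   an integer number of steps).
#' @param eco an [eco_parameters()] object or a list of overrides.
#' @param transport a [transport_config()] or a list of overrides.
#' @param forcing list of forcing constants: `base_tonnes`, `growth_rate`,
#'   `start_year`, `ocean_area_m2` (total ocean area shared by the columns,
#'   default 3.61e14).
#' @param scenario list: `warming_C_per_century`, `trend_start_year`,
#'   `trend_decay_m`.
#' @param export_depth diagnostic export depth, m (default 130: the bottom
#'   of the second layer of the default grid).
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = "test_med", grid = default_grid(),
                       columns = list(list(name = "tropics", surface_C = 28)),
                       years = c(1950, 2020), spinup_years = 30, dt = 0.5,
                       eco = eco_parameters(), transport = transport_config(),
                       forcing = list(), scenario = list(),
                       export_depth = 130) {
  if (is.character(params)) params <- fixture_parameters(params)
  if (!inherits(params, "mp_parameters")) params <- do.call(mp_parameters, params)
  if (!inherits(eco, "eco_parameters")) eco <- do.call(eco_parameters, eco)
  if (!inherits(transport, "transport_config"))
    transport <- do.call(transport_config, transport)
  stopifnot(inherits(grid, "column_grid"))
  if (length(years) != 2L || years[2] < years[1])
    stop("`years` must be c(first, last)", call. = FALSE)
  f_def <- list(base_tonnes = 2e6, growth_rate = 0.084, start_year = 1950,
                ocean_area_m2 = 3.61e14)
  forcing <- utils::modifyList(f_def, forcing)
  s_def <- list(warming_C_per_century = 0, trend_start_year = 2000,
                trend_decay_m = 300)
  scenario <- utils::modifyList(s_def, scenario)
  ncol <- length(columns)
  columns <- lapply(seq_along(columns), function(i) {
    cdef <- list(name = paste0("column", i), surface_C = 28, deep_C = 2,
                 mld = 50, decay_m = 200,
                 weight = 1 / ncol, emission_factor = 1)
    utils::modifyList(cdef, columns[[i]])
  })
  wsum <- sum(vapply(columns, `[[`, numeric(1), "weight"))
  if (abs(wsum - 1) > 1e-8)
    stop("column weights must sum to 1", call. = FALSE)
  structure(list(params = params, grid = grid, columns = columns,
                 years = years, spinup_years = spinup_years, dt = dt,
                 eco = eco, transport = transport, forcing = forcing,
                 scenario = scenario, export_depth = export_depth),
            class = "run_config")
}

# annual emission rate into one column's surface layer, particles m^-3 d^-1
emission_conc_rate <- function(year, cfg, col_idx) {
  weights <- vapply(cfg$columns, `[[`, numeric(1), "weight")
  rate <- mp_emission(year, cfg$params, weights,
                      base_tonnes = cfg$forcing$base_tonnes,
                      growth_rate = cfg$forcing$growth_rate,
                      start_year = cfg$forcing$start_year)[col_idx]
  area <- weights[col_idx] * cfg$forcing$ocean_area_m2
  cfg$columns[[col_idx]]$emission_factor * rate /
    (area * cfg$grid$thickness[1] * 365)
}

# simulate one column over the configured span; annual diagnostics
run_column <- function(cfg, col_idx, scenario_obj) {
  grid <- cfg$grid; params <- cfg$params; eco <- cfg$eco; tcfg <- cfg$transport
  nz <- grid$n_layers; dz <- grid$thickness
  w <- sinking_speed(grid, tcfg)
  check_cfl(w, grid, cfg$dt)
  kappa_md <- kappa_interfaces(grid, tcfg)
  light <- light_profile(grid, eco)
  prefs <- renormalise_preferences(params$psi_MP)
  k_exp <- which.min(abs(grid$interface_depth - cfg$export_depth))
  spy <- max(1L, round(365 / cfg$dt))
  dt <- 365 / spy
  yrs <- seq(cfg$years[1], cfg$years[2])
  brackets <- standard_brackets(grid)

  state <- initial_state(grid)
  base_T <- scenario_obj$profiles[[col_idx]]
  for (i in seq_len(cfg$spinup_years * spy))
    state <- column_step(state, grid, base_T, light, dt, params, eco, prefs,
                         w, kappa_md, 0, k_exp)$state
  n_total0 <- column_integral(state$N + state$PH + state$CO + state$DZ +
                                state$Z + state$DET_A + state$DET_Z, grid)

  rows <- vector("list", length(yrs))
  prof_MP <- matrix(NA_real_, length(yrs), nz)
  prof_MPA <- prof_MP; prof_MPZ <- prof_MP
  cum_emit <- 0; cum_lost <- 0
  stable <- TRUE

  for (yi in seq_along(yrs)) {
    year <- yrs[yi]
    T_C <- temperature_at(scenario_obj, year, col_idx)
    emis <- emission_conc_rate(year, cfg, col_idx)
    acc <- NULL
    pMP <- numeric(nz); pMPA <- numeric(nz); pMPZ <- numeric(nz)
    surf_tot <- 0; surf_free <- 0
    for (s in seq_len(spy)) {
      st <- column_step(state, grid, T_C, light, dt, params, eco, prefs,
                        w, kappa_md, emis, k_exp)
      state <- st$state
      acc <- if (is.null(acc)) st$diag else acc + st$diag
      pMP <- pMP + state$MP; pMPA <- pMPA + state$MP_A; pMPZ <- pMPZ + state$MP_Z
      surf_free <- surf_free + state$MP[1]
      surf_tot <- surf_tot + state$MP[1] + state$MP_A[1] + state$MP_Z[1]
    }
    if (any(!is.finite(unlist(state, use.names = FALSE)))) {
      stable <- FALSE
    }
    m <- acc / spy
    cum_emit <- cum_emit + acc[["emitted"]] * dt
    cum_lost <- cum_lost + acc[["sf_lost"]] * dt
    pMP <- pMP / spy; pMPA <- pMPA / spy; pMPZ <- pMPZ / spy
    prof_MP[yi, ] <- pMP; prof_MPA[yi, ] <- pMPA; prof_MPZ[yi, ] <- pMPZ
    tot_prof <- pMP + pMPA + pMPZ
    inv <- if (stable) depth_bracket_inventory(tot_prof, grid, brackets)
           else rep(NA_real_, 3)
    total_inv <- column_integral(state$MP + state$MP_A + state$MP_Z, grid)
    n_total <- column_integral(state$N + state$PH + state$CO + state$DZ +
                                 state$Z + state$DET_A + state$DET_Z, grid)
    exp_mp <- m[["exp_MPA"]] + m[["exp_MPZ"]]
    upt_mp <- m[["upt_A_above"]] + m[["upt_Z_above"]]
    rows[[yi]] <- data.frame(
      column = cfg$columns[[col_idx]]$name, year = year,
      surface_MP_total = surf_tot / spy, surface_MP_free = surf_free / spy,
      uptake_A = m[["upt_A_above"]], uptake_Z = m[["upt_Z_above"]],
      export_MPA = m[["exp_MPA"]], export_MPZ = m[["exp_MPZ"]],
      eff_MPA = mp_export_efficiency(m[["exp_MPA"]], m[["upt_A_above"]]),
      eff_MPZ = mp_export_efficiency(m[["exp_MPZ"]], m[["upt_Z_above"]]),
      uptake_export_ratio = if (exp_mp > 0) upt_mp / exp_mp else NA_real_,
      export_PON_A = m[["exp_DET_A"]], export_PON_Z = m[["exp_DET_Z"]],
      npp_above = m[["npp_above"]], grazing_above = m[["graz_above"]],
      eff_PON_A = pon_export_efficiency(m[["exp_DET_A"]], m[["npp_above"]]),
      eff_PON_Z = pon_export_efficiency(m[["exp_DET_Z"]], m[["graz_above"]]),
      inv_0_100 = inv[1], inv_100_500 = inv[2], inv_500_bottom = inv[3],
      total_inventory = total_inv,
      missing_fraction = missing_fraction(state, grid),
      cum_emission = cum_emit, cum_seafloor_loss = cum_lost,
      budget_rel_err = if (cum_emit > 0)
        abs(cum_emit - total_inv - cum_lost) / cum_emit else 0,
      N_rel_drift = abs(n_total - n_total0) / n_total0,
      agg_formation_surface = m[["agg_formation_surface"]],
      stable = stable,
      stringsAsFactors = FALSE)
    if (!stable) break
  }
  done <- !vapply(rows, is.null, logical(1))
  list(diagnostics = do.call(rbind, rows[done]),
       profiles = list(MP = prof_MP[done, , drop = FALSE],
                       MP_A = prof_MPA[done, , drop = FALSE],
                       MP_Z = prof_MPZ[done, , drop = FALSE],
                       years = yrs[done]),
       final_state = state, stable = stable)
}

#' Run a full simulation
#'
#' Spins the ecosystem up to a quasi-steady annual cycle, then integrates
#' the coupled ecosystem + microplastic column(s) over the configured year
#' span with annually updated emission and temperature forcing, recording
#' annual-mean diagnostics (export efficiencies, depth-bracket inventories,
#' surface concentrations, conservation audit) and annual-mean microplastic
#' profiles.
#'
#' @param config a [run_config()].
#' @return An object of class `mpsink_run`: list with `diagnostics` (one row
#'   per column-year), `profiles` (per column: annual-mean profile matrices
#'   for the three microplastic tracers), `final_states`, `stable` (per
#'   column), `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scen <- temperature_scenario(
    lapply(config$columns, function(cl)
      temperature_profile(config$grid, cl$surface_C, cl$deep_C,
                          cl$mld, cl$decay_m)),
    config$grid,
    trend_C_per_century = config$scenario$warming_C_per_century,
    trend_start_year = config$scenario$trend_start_year,
    trend_decay_m = config$scenario$trend_decay_m)
  res <- lapply(seq_along(config$columns), function(i)
    run_column(config, i, scen))
  names(res) <- vapply(config$columns, `[[`, character(1), "name")
  structure(list(
    diagnostics = do.call(rbind, lapply(res, `[[`, "diagnostics")),
    profiles = lapply(res, `[[`, "profiles"),
    final_states = lapply(res, `[[`, "final_state"),
    stable = vapply(res, `[[`, logical(1), "stable"),
    config = config
  ), class = "mpsink_run")
}

#' @export
print.mpsink_run <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<mpsink_run> %d column(s), years %d-%d%s\n",
              length(x$profiles), min(d$year), max(d$year),
              if (all(x$stable)) "" else " [UNSTABLE]"))
  last <- d[d$year == max(d$year), ]
  for (i in seq_len(nrow(last)))
    cat(sprintf(
      "  %s %d: surface MP %.3g m^-3, uptake:export %.2f, missing fraction %.2f\n",
      last$column[i], last$year[i], last$surface_MP_total[i],
      last$uptake_export_ratio[i], last$missing_fraction[i]))
  invisible(x)
}
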