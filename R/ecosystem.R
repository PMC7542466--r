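#' Ecosystem rate constants
#'
#' Constants of the minimal nutrient-phytoplankton-zooplankton-detritus
#' (NPZD) ecosystem that supplies the biological fluxes the microplastic
#' equations consume: marine snow (free detritus) production, faecal pellet
#' production, temperature-dependent remineralisation, and Holling type II
#' grazing. Three phytoplankton classes are carried (mixed phytoplankton PH,
#' small phytoplankton/calcifiers CO, diazotrophs DZ) so that the grazing
#' preference structure of the host biogeochemistry is preserved; their
#' growth is light- and nutrient-limited with Eppley-style temperature
#' scaling.
#'
#' All rates are per day; concentrations are mmol N m^-3.
#'
#' @param mu_Z0 zooplankton maximum grazing rate at 0 degC, d^-1.
#' @param b_T Eppley temperature base (rate multiplies by `b_T` per degC).
#' @param T_cap temperature (degC) above which the zooplankton maximum
#'   growth rate stops increasing (default 20).
#' @param k_Z grazing half-saturation constant, mmol N m^-3.
#' @param j0_PH,j0_CO,j0_DZ phytoplankton maximum growth rates at 0 degC.
#' @param k_N_PH,k_N_CO,k_N_DZ nutrient half-saturation constants.
#' @param m_P phytoplankton linear mortality, d^-1 (routed to free detritus).
#' @param m_Z zooplankton linear mortality, d^-1 (particulate loss).
#' @param e_Z zooplankton excretion, d^-1 (dissolved loss).
#' @param gamma zooplankton assimilation efficiency; the unassimilated
#'   fraction of grazed food is a particulate loss.
#' @param mu_D0 detrital remineralisation rate at 0 degC, d^-1.
#' @param q10_remin remineralisation rate multiplier per 10 degC.
#' @param pellet_fraction fraction of zooplankton particulate losses diverted
#'   to the faecal-pellet detritus class (default 0.5).
#' @param k_light attenuation coefficient of photosynthetically available
#'   light, m^-1.
#' @return An object of class `eco_parameters`.
#' @export
eco_parameters <- function(mu_Z0 = 0.6, b_T = 1.066, T_cap = 20, k_Z = 0.15,
                           j0_PH = 0.6, j0_CO = 0.5, j0_DZ = 0.25,
                           k_N_PH = 0.7, k_N_CO = 0.3, k_N_DZ = 0.5,
                           m_P = 0.05, m_Z = 0.06, e_Z = 0.03, gamma = 0.7,
                           mu_D0 = 0.048, q10_remin = 1.4,
                           pellet_fraction = 0.5, k_light = 0.03) {
  p <- as.list(environment())
  if (any(!vapply(p, is.finite, logical(1))))
    stop("all ecosystem constants must be finite", call. = FALSE)
  if (pellet_fraction < 0 || pellet_fraction > 1)
    stop("`pellet_fraction` must lie in [0, 1]", call. = FALSE)
  pos <- setdiff(names(p), "pellet_fraction")
  if (any(unlist(p[pos]) <= 0))
    stop("ecosystem rate constants must be positive", call. = FALSE)
  structure(p, class = "eco_parameters")
}

#' Renormalised grazing preferences
#'
#' Grazing preferences must sum to 1. When the microplastic preference
#' `psi_MP` is varied, the diazotroph preference is pinned at 0.1 (a poor
#' food source) and the remainder `1 - 0.1 - psi_MP` is split equally among
#' the other four prey classes (CO, PH, total detritus, Z).
#'
#' @param psi_MP microplastic grazing preference, in \[0, 0.9\].
#' @return list with `psi_CO`, `psi_PH`, `psi_DZ`, `psi_Detr`, `psi_Z`,
#'   `psi_MP`; the six entries sum to 1.
#' @examples
#' renormalise_preferences(0)$psi_PH    # 0.225
#' renormalise_preferences(0.193)$psi_PH  # 0.17675
#' @export
renormalise_preferences <- function(psi_MP) {
  if (!is.finite(psi_MP) || psi_MP < 0 || psi_MP > 0.9)
    stop("`psi_MP` must lie in [0, 0.9] (psi_DZ is fixed at 0.1)",
         call. = FALSE)
  rest <- (1 - 0.1 - psi_MP) / 4
  list(psi_CO = rest, psi_PH = rest, psi_DZ = 0.1,
       psi_Detr = rest, psi_Z = rest, psi_MP = psi_MP)
}

#' Temperature-dependent remineralisation rate
#'
#' `mu_D(T) = mu_D0 * q10_remin^(T/10)`: detritus (and therefore the
#' microplastic bound in it) is remineralised faster in warm water.
#'
#' @param T_C temperature, degC (vectorised).
#' @param eco an [eco_parameters()] object.
#' @return rate, d^-1.
#' @export
remin_rate <- function(T_C, eco = eco_parameters()) {
  eco$mu_D0 * eco$q10_remin^(T_C / 10)
}

#' Zooplankton maximum growth/grazing rate
#'
#' Eppley-type increase with temperature, capped above `T_cap` (default
#' 20 degC) to represent metabolic limitation of growth in very warm water.
#'
#' @param T_C temperature, degC (vectorised).
#' @param eco an [eco_parameters()] object.
#' @return rate, d^-1.
#' @export
max_growth <- function(T_C, eco = eco_parameters()) {
  eco$mu_Z0 * eco$b_T^pmin(T_C, eco$T_cap)
}

# phytoplankton maximum growth (uncapped Eppley curve)
phyto_max_growth <- function(T_C, j0, eco) j0 * eco$b_T^T_C

#' Layer-mean light limitation factor
#'
#' Exponentially attenuated surface light, averaged analytically over each
#' layer.
#'
#' @param grid a [column_grid()].
#' @param eco an [eco_parameters()] object (uses `k_light`).
#' @param surface light at the surface (dimensionless, default 1).
#' @return per-layer dimensionless factor in (0, 1].
#' @export
light_profile <- function(grid, eco = eco_parameters(), surface = 1) {
  k <- eco$k_light
  z_bot <- grid$interface_depth
  z_top <- c(0, z_bot[-grid$n_layers])
  surface * (exp(-k * z_top) - exp(-k * z_bot)) / (k * grid$thickness)
}

#' Construct an ecosystem + microplastic tracer state
#'
#' Per-layer concentrations of the seven ecosystem tracers (mmol N m^-3) and
#' the three microplastic tracers (particles m^-3). Scalars are recycled
#' across layers.
#'
#' @param grid a [column_grid()].
#' @param N,PH,CO,DZ,Z,DET_A,DET_Z ecosystem tracers, mmol N m^-3.
#' @param MP,MP_A,MP_Z microplastic tracers, particles m^-3.
#' @return An object of class `tracer_state` (list of per-layer vectors).
#' @export
tracer_state <- function(grid, N = 10, PH = 0.1, CO = 0.1, DZ = 0.02,
                         Z = 0.1, DET_A = 0.01, DET_Z = 0.01,
                         MP = 0, MP_A = 0, MP_Z = 0) {
  nz <- grid$n_layers
  s <- lapply(list(N = N, PH = PH, CO = CO, DZ = DZ, Z = Z,
                   DET_A = DET_A, DET_Z = DET_Z,
                   MP = MP, MP_A = MP_A, MP_Z = MP_Z),
              function(v) {
                v <- as.numeric(v)
                if (length(v) == 1L) v <- rep(v, nz)
                if (length(v) != nz)
                  stop("tracer fields must be scalar or one value per layer",
                       call. = FALSE)
                if (any(v < 0)) stop("tracer concentrations must be >= 0",
                                     call. = FALSE)
                v
              })
  structure(s, class = "tracer_state")
}

# default pre-spin-up initial condition: nutrient-rich at depth
initial_state <- function(grid) {
  tracer_state(grid,
               N = 2 + 28 * (1 - exp(-grid$mid_depth / 400)),
               PH = 0.1, CO = 0.1, DZ = 0.02, Z = 0.1,
               DET_A = 0.01, DET_Z = 0.01)
}

#' Holling type II grazing rates, extended with a microplastic prey term
#'
#' For each prey class X the grazing rate is
#' `G_X = max_growth(T) * Z * psi_X * X / (sum_i psi_i * prey_i + k_Z)`,
#' where the prey sum runs over CO, PH, DZ, total detritus, Z itself, and the
#' nitrogen-currency value of free microplastic. A positive microplastic term
#' enlarges the shared denominator, so ingesting plastic reduces the uptake
#' of every real food source.
#'
#' @param state a [tracer_state()] (or any list with `PH`, `CO`, `DZ`, `Z`,
#'   `DET_A`, `DET_Z` vectors).
#' @param prefs a preference set from [renormalise_preferences()].
#' @param T_C temperature per layer, degC.
#' @param mp_as_N free microplastic in nitrogen currency, mmol N m^-3
#'   (default 0; see [mp_to_nitrogen()]).
#' @param eco an [eco_parameters()] object.
#' @return list of per-layer grazing rates (mmol N m^-3 d^-1): `G_CO`,
#'   `G_PH`, `G_DZ`, `G_Detr`, `G_Z`, `G_MP_N`, plus the shared `denominator`.
#' @export
grazing_rates <- function(state, prefs, T_C, mp_as_N = 0,
                          eco = eco_parameters()) {
  detr_tot <- state$DET_A + state$DET_Z
  denom <- prefs$psi_CO * state$CO + prefs$psi_PH * state$PH +
    prefs$psi_DZ * state$DZ + prefs$psi_Detr * detr_tot +
    prefs$psi_Z * state$Z + prefs$psi_MP * mp_as_N + eco$k_Z
  g <- max_growth(T_C, eco) * state$Z / denom
  list(G_CO    = g * prefs$psi_CO * state$CO,
       G_PH    = g * prefs$psi_PH * state$PH,
       G_DZ    = g * prefs$psi_DZ * state$DZ,
       G_Detr  = g * prefs$psi_Detr * detr_tot,
       G_Z     = g * prefs$psi_Z * state$Z,
       G_MP_N  = g * prefs$psi_MP * mp_as_N,
       denominator = denom)
}

# All local (non-transport) ecosystem fluxes, per layer, per day.
# Each flux has a single source pool; this is what makes the one-pass
# positivity limiter in limit_fluxes() conservative.
eco_fluxes <- function(state, T_C, light, eco, prefs, mp_as_N = 0) {
  gr <- grazing_rates(state, prefs, T_C, mp_as_N, eco)
  nlim <- function(kn) state$N / (kn + state$N)
  npp_PH <- phyto_max_growth(T_C, eco$j0_PH, eco) * light * nlim(eco$k_N_PH) * state$PH
  npp_CO <- phyto_max_growth(T_C, eco$j0_CO, eco) * light * nlim(eco$k_N_CO) * state$CO
  npp_DZ <- phyto_max_growth(T_C, eco$j0_DZ, eco) * light * nlim(eco$k_N_DZ) * state$DZ
  detr_tot <- state$DET_A + state$DET_Z
  share_A <- ifelse(detr_tot > 0, state$DET_A / detr_tot, 0)
  mu_D <- remin_rate(T_C, eco)
  list(npp_PH = npp_PH, npp_CO = npp_CO, npp_DZ = npp_DZ,
       G_CO = gr$G_CO, G_PH = gr$G_PH, G_DZ = gr$G_DZ,
       G_Detr_A = gr$G_Detr * share_A, G_Detr_Z = gr$G_Detr * (1 - share_A),
       G_Z = gr$G_Z, G_MP_N = gr$G_MP_N,
       mort_PH = eco$m_P * state$PH, mort_CO = eco$m_P * state$CO,
       mort_DZ = eco$m_P * state$DZ,
       mort_Z = eco$m_Z * state$Z, excr_Z = eco$e_Z * state$Z,
       remin_A = mu_D * state$DET_A, remin_Z = mu_D * state$DET_Z,
       mu_D = mu_D)
}

# positivity factor: scales a pool's combined sinks so they cannot remove
# more than the pool holds within dt
sink_factor <- function(pool, sink, dt) {
  s <- pmax(sink, 0)
  f <- rep(1, length(pool))
  hot <- s * dt > pool
  f[hot] <- pool[hot] / (s[hot] * dt)
  f
}

# Scale every flux by its source pool's positivity factor so that no pool's
# combined sinks can exceed the pool within dt. Scaling only shrinks sinks,
# so downstream pools cannot be driven negative either; mass is conserved
# exactly because tendencies are rebuilt from the scaled fluxes. The plastic
# pools have their own limiter in the stepper: grazed plastic carries no
# nitrogen into the food web (it is egested, not assimilated), so the two
# systems decouple.
limit_fluxes <- function(fl, state, dt) {
  fac <- function(pool, sink) sink_factor(pool, sink, dt)
  f_N  <- fac(state$N,  fl$npp_PH + fl$npp_CO + fl$npp_DZ)
  f_PH <- fac(state$PH, fl$G_PH + fl$mort_PH)
  f_CO <- fac(state$CO, fl$G_CO + fl$mort_CO)
  f_DZ <- fac(state$DZ, fl$G_DZ + fl$mort_DZ)
  f_Z  <- fac(state$Z,  fl$G_Z + fl$mort_Z + fl$excr_Z)
  f_DA <- fac(state$DET_A, fl$remin_A + fl$G_Detr_A)
  f_DD <- fac(state$DET_Z, fl$remin_Z + fl$G_Detr_Z)
  fl$npp_PH <- fl$npp_PH * f_N; fl$npp_CO <- fl$npp_CO * f_N
  fl$npp_DZ <- fl$npp_DZ * f_N
  fl$G_PH <- fl$G_PH * f_PH; fl$mort_PH <- fl$mort_PH * f_PH
  fl$G_CO <- fl$G_CO * f_CO; fl$mort_CO <- fl$mort_CO * f_CO
  fl$G_DZ <- fl$G_DZ * f_DZ; fl$mort_DZ <- fl$mort_DZ * f_DZ
  fl$G_Z <- fl$G_Z * f_Z; fl$mort_Z <- fl$mort_Z * f_Z
  fl$excr_Z <- fl$excr_Z * f_Z
  fl$remin_A <- fl$remin_A * f_DA; fl$G_Detr_A <- fl$G_Detr_A * f_DA
  fl$remin_Z <- fl$remin_Z * f_DD; fl$G_Detr_Z <- fl$G_Detr_Z * f_DD
  fl
}

# dt-aware limiter for the microplastic exchange fluxes
limit_mp_fluxes <- function(mp_fl, state, dt) {
  f_MP <- sink_factor(state$MP,   mp_fl$A_upt + mp_fl$P_upt, dt)
  f_MA <- sink_factor(state$MP_A, mp_fl$A_rel, dt)
  f_MZ <- sink_factor(state$MP_Z, mp_fl$P_rel, dt)
  mp_fl$A_upt <- mp_fl$A_upt * f_MP
  mp_fl$P_upt <- mp_fl$P_upt * f_MP
  mp_fl$A_rel <- mp_fl$A_rel * f_MA
  mp_fl$P_rel <- mp_fl$P_rel * f_MZ
  mp_fl
}

# Assemble ecosystem tendencies (mmol N m^-3 d^-1) from limited fluxes.
# Returns tendencies plus the derived fluxes the microplastic equations and
# diagnostics consume.
eco_tendencies <- function(fl, eco) {
  G_food <- fl$G_CO + fl$G_PH + fl$G_DZ + fl$G_Detr_A + fl$G_Detr_Z + fl$G_Z
  z_part <- (1 - eco$gamma) * G_food + fl$mort_Z
  pf <- eco$pellet_fraction
  src_DET_A <- fl$mort_PH + fl$mort_CO + fl$mort_DZ + (1 - pf) * z_part
  src_DET_Z <- pf * z_part
  npp <- fl$npp_PH + fl$npp_CO + fl$npp_DZ
  list(
    dN  = fl$remin_A + fl$remin_Z + fl$excr_Z - npp,
    dPH = fl$npp_PH - fl$mort_PH - fl$G_PH,
    dCO = fl$npp_CO - fl$mort_CO - fl$G_CO,
    dDZ = fl$npp_DZ - fl$mort_DZ - fl$G_DZ,
    dZ  = eco$gamma * G_food - fl$G_Z - fl$mort_Z - fl$excr_Z,
    dDET_A = src_DET_A - fl$remin_A - fl$G_Detr_A,
    dDET_Z = src_DET_Z - fl$remin_Z - fl$G_Detr_Z,
    src_DET_A = src_DET_A, src_DET_Z = src_DET_Z,
    pellet_production = src_DET_Z,
    NPP = npp, G_food = G_food, mu_D = fl$mu_D
  )
}

#' Advance the ecosystem one time step (no transport)
#'
#' Explicit Euler update of the local ecosystem source/sink terms with a
#' conservative positivity limiter (sinks of a pool are scaled down so they
#' cannot remove more than the pool holds within `dt`). Nitrogen is conserved
#' exactly by construction. Vertical transport is handled separately by the
#' column stepper.
#'
#' @param state a [tracer_state()].
#' @param T_C per-layer temperature, degC.
#' @param light per-layer light factor (see [light_profile()]).
#' @param dt time step, days.
#' @param eco an [eco_parameters()] object.
#' @param prefs preferences from [renormalise_preferences()].
#' @param mp_as_N free microplastic in nitrogen currency (mmol N m^-3);
#'   affects the grazing denominator but the plastic pools themselves are
#'   not updated here.
#' @return list with the updated `state` and `fluxes` (the limited per-layer
#'   fluxes plus `src_DET_A`, `pellet_production`, `NPP`, `mu_D`).
#' @export
step_ecosystem <- function(state, T_C, light, dt, eco = eco_parameters(),
                           prefs = renormalise_preferences(0), mp_as_N = 0) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  fl <- eco_fluxes(state, T_C, light, eco, prefs, mp_as_N)
  fl <- limit_fluxes(fl, state, dt)
  td <- eco_tendencies(fl, eco)
  state$N     <- state$N     + dt * td$dN
  state$PH    <- state$PH    + dt * td$dPH
  state$CO    <- state$CO    + dt * td$dCO
  state$DZ    <- state$DZ    + dt * td$dDZ
  state$Z     <- state$Z     + dt * td$dZ
  state$DET_A <- state$DET_A + dt * td$dDET_A
  state$DET_Z <- state$DET_Z + dt * td$dDET_Z
  list(state = state, fluxes = td)
}
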