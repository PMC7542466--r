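#' Marine snow aggregate formation rate
#'
#' Converts a detritus production rate (the marine snow formation rate, in
#' nitrogen units) into a number of newly forming aggregates, assuming every
#' aggregate has the carbon content of a diatom aggregate (8.8 ug C). The
#' nitrogen flux is converted to carbon at Redfield stoichiometry
#' (C:N = 106:16) and then to micrograms of carbon (12.011 ug per umol C).
#'
#' @param det_source marine snow production rate, mmol N m^-3 d^-1.
#' @param params an [mp_parameters()] object.
#' @return aggregates m^-3 d^-1.
#' @examples
#' aggregate_count(1)  # about 9042 aggregates per mmol N
#' @export
aggregate_count <- function(det_source, params = mp_parameters()) {
  if (any(det_source < 0))
    stop("`det_source` must be >= 0", call. = FALSE)
  det_source * params$redfield_CN * 12.011e3 / params$c_agg_ugC
}

#' Microplastic uptake by newly forming marine snow
#'
#' A Monod (saturating) function of the free microplastic concentration,
#' applied to the aggregate formation rate: at saturation at most a fraction
#' `F_A` of newly forming aggregates each capture one particle, so the
#' uptake is bounded above by `F_A * aggregate_count(det_source)`.
#'
#' @param MP free microplastic, particles m^-3.
#' @param det_source marine snow production, mmol N m^-3 d^-1.
#' @param params an [mp_parameters()] object (uses `k_P` and `F_A`).
#' @return uptake rate, particles m^-3 d^-1. Zero where `MP` is zero (also
#'   in the `k_P = 0` limit).
#' @export
aggregation_uptake <- function(MP, det_source, params) {
  if (any(MP < 0) || any(det_source < 0))
    stop("inputs must be non-negative", call. = FALSE)
  sat <- ifelse(MP > 0, MP / (params$k_P + MP), 0)
  sat * aggregate_count(det_source, params) * params$F_A
}

#' Release of microplastic from marine snow
#'
#' Bound particles are released at the detrital remineralisation rate:
#' `A_rel = mu_D * MP_A`.
#'
#' @param MP_A aggregate-bound microplastic, particles m^-3.
#' @param mu_D remineralisation rate, d^-1 (see [remin_rate()]).
#' @return release rate, particles m^-3 d^-1.
#' @export
aggregate_release <- function(MP_A, mu_D) {
  if (any(MP_A < 0) || any(mu_D < 0))
    stop("inputs must be non-negative", call. = FALSE)
  mu_D * MP_A
}

#' Release of microplastic from faecal pellets
#'
#' Pellet-bound particles are released at the same remineralisation rate as
#' aggregates: `P_rel = mu_D * MP_Z`. All grazed microplastic is egested to
#' the pellet pool (none is retained or metabolised), so pellet release is
#' the only loss from `MP_Z` besides sinking.
#'
#' @param MP_Z pellet-bound microplastic, particles m^-3.
#' @param mu_D remineralisation rate, d^-1.
#' @return release rate, particles m^-3 d^-1.
#' @export
pellet_release <- function(MP_Z, mu_D) {
  if (any(MP_Z < 0) || any(mu_D < 0))
    stop("inputs must be non-negative", call. = FALSE)
  mu_D * MP_Z
}

#' Zooplankton ingestion of microplastic
#'
#' Free microplastic enters the Holling type II grazing response as an
#' additional prey: particles are converted to the nitrogen currency of the
#' food they displace (see [mp_to_nitrogen()]), grazed with preference
#' `psi_MP`, and the resulting nitrogen-unit grazing rate is converted back
#' to particles.
#'
#' @param MP free microplastic, particles m^-3.
#' @param state a [tracer_state()] supplying the food prey fields.
#' @param prefs preference set from [renormalise_preferences()].
#' @param T_C temperature, degC.
#' @param params an [mp_parameters()] object.
#' @param eco an [eco_parameters()] object.
#' @return list with `P_upt` (particles m^-3 d^-1) and `G_MP_N`
#'   (mmol N m^-3 d^-1).
#' @export
mp_grazing <- function(MP, state, prefs, T_C, params,
                       eco = eco_parameters()) {
  if (any(MP < 0)) stop("`MP` must be >= 0", call. = FALSE)
  mp_as_N <- mp_to_nitrogen(MP, params)
  gr <- grazing_rates(state, prefs, T_C, mp_as_N, eco)
  list(P_upt = nitrogen_to_mp(gr$G_MP_N, params), G_MP_N = gr$G_MP_N)
}

# raw (un-limited) microplastic exchange fluxes, per layer per day
mp_fluxes <- function(state, src_DET_A, mu_D, prefs, T_C, params, eco) {
  A_upt <- aggregation_uptake(state$MP, src_DET_A, params)
  gz <- mp_grazing(state$MP, state, prefs, T_C, params, eco)
  list(A_upt = A_upt,
       A_rel = aggregate_release(state$MP_A, mu_D),
       P_upt = gz$P_upt,
       P_rel = pellet_release(state$MP_Z, mu_D))
}

#' Local microplastic tendencies (sources and sinks only)
#'
#' Assembles the per-layer source-minus-sink tendencies of the three
#' microplastic compartments from the exchange fluxes and the surface
#' emission. Exchange terms cancel pairwise, so the summed tendency of the
#' three compartments equals the emission exactly (local particle
#' conservation before transport).
#'
#' @param mp_fl list of exchange fluxes `A_upt`, `A_rel`, `P_upt`, `P_rel`
#'   (particles m^-3 d^-1), e.g. limited fluxes from the stepper.
#' @param emission per-layer emission rate, particles m^-3 d^-1 (non-zero
#'   only in the surface layer during normal runs).
#' @return list of tendencies `dMP`, `dMP_A`, `dMP_Z` (particles m^-3 d^-1).
#' @export
mp_tendencies <- function(mp_fl, emission = 0) {
  n <- length(mp_fl$A_upt)
  emission <- if (length(emission) == 1L) rep(emission, n) else emission
  if (any(vapply(mp_fl[c("A_rel", "P_upt", "P_rel")], length, 1L) != n) ||
      length(emission) != n)
    stop("flux and emission vectors must share the layer count", call. = FALSE)
  list(dMP   = emission - mp_fl$A_upt - mp_fl$P_upt + mp_fl$A_rel + mp_fl$P_rel,
       dMP_A = mp_fl$A_upt - mp_fl$A_rel,
       dMP_Z = mp_fl$P_upt - mp_fl$P_rel)
}
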