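#' Vertical transport configuration
#'
#' Sinking of aggregates, pellets and detritus follows a prescribed linear
#' increase with depth, `w_D(z) = w_D0 + m_w * z`; the buoyant sub-population
#' of free microplastic rises at `w_p`; all tracers are mixed vertically with
#' a constant background diffusivity, enhanced within the surface mixed
#' layer. The background value is an effective diffusivity standing in for
#' the vertical nutrient supply a 3-D circulation would provide.
#'
#' @param w_D0 sinking speed at the surface, m d^-1 (default 7).
#' @param m_w linear depth increase of the sinking speed, d^-1 (default 0.04).
#' @param kappa_bg_m2s background vertical diffusivity, m^2 s^-1
#'   (default 1e-4).
#' @param kappa_ml_m2s mixed-layer diffusivity, m^2 s^-1 (default 1e-3).
#' @param ml_depth_m mixed-layer depth for the enhanced diffusivity, m.
#' @param dt time step, days (default 0.5). Must satisfy the sinking CFL
#'   condition on the grid in use; the rise transport is sub-cycled
#'   internally so it does not constrain `dt`.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(w_D0 = 7, m_w = 0.04,
                             kappa_bg_m2s = 1e-4, kappa_ml_m2s = 1e-3,
                             ml_depth_m = 50, dt = 0.5) {
  if (w_D0 < 0 || m_w < 0) stop("sinking speeds must be >= 0", call. = FALSE)
  if (kappa_bg_m2s < 0 || kappa_ml_m2s < 0)
    stop("diffusivities must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(w_D0 = w_D0, m_w = m_w,
                 kappa_bg_m2s = kappa_bg_m2s, kappa_ml_m2s = kappa_ml_m2s,
                 ml_depth_m = ml_depth_m, dt = dt),
            class = "transport_config")
}

# per-layer sinking speed (m/d) evaluated at layer mid-depths
sinking_speed <- function(grid, tcfg) tcfg$w_D0 + tcfg$m_w * grid$mid_depth

# error if the explicit sinking update could empty a layer in one step
check_cfl <- function(w, grid, dt) {
  courant <- dt * w / grid$thickness
  if (any(courant > 1)) {
    i <- which.max(courant)
    stop(sprintf(
      "CFL violation in layer %d: w = %.2f m/d, dz = %.1f m, dt = %.3g d",
      i, w[i], grid$thickness[i], dt), call. = FALSE)
  }
  invisible(TRUE)
}

#' First-order upwind sinking fluxes
#'
#' Downward flux across the bottom interface of each layer: the layer's own
#' concentration times its sinking speed. The surface (top) interface carries
#' no flux. The last element is the flux onto the seafloor.
#'
#' @param conc per-layer concentration (particles m^-3 or mmol N m^-3).
#' @param w per-layer sinking speed, m d^-1 (>= 0).
#' @param grid a [column_grid()].
#' @return flux at each layer's bottom interface (conc units x m d^-1).
#' @export
sinking_flux <- function(conc, w, grid) {
  if (length(conc) != grid$n_layers || length(w) != grid$n_layers)
    stop("`conc` and `w` must have one value per layer", call. = FALSE)
  if (any(w < 0)) stop("sinking speeds must be >= 0 (downward)", call. = FALSE)
  w * conc
}

# explicit flux-form sinking update; returns updated conc and seafloor flux
apply_sinking <- function(conc, w, grid, dt) {
  fl <- w * conc
  nz <- grid$n_layers
  conc <- conc + dt * (c(0, fl[-nz]) - fl) / grid$thickness
  list(conc = conc, bottom_flux = fl[nz])
}

#' Upward rise fluxes of buoyant free microplastic
#'
#' A fraction `F_R` of the free microplastic in each layer below the surface
#' rises at speed `w_p`. The flux across the interface above layer `i`
#' (`i >= 2`) is `F_R * w_p * MP[i]`. Nothing leaves through the sea
#' surface: particles arriving in the surface layer stay there.
#'
#' @param MP free microplastic, particles m^-3.
#' @param F_R buoyant fraction, in \[0, 1\].
#' @param w_p_md rise speed, m d^-1.
#' @param grid a [column_grid()].
#' @return upward flux across the interface above each layer (element 1,
#'   the sea surface, is always 0).
#' @export
rise_flux <- function(MP, F_R, w_p_md, grid) {
  if (F_R < 0 || F_R > 1) stop("`F_R` must lie in [0, 1]", call. = FALSE)
  up <- F_R * w_p_md * MP
  up[1] <- 0
  up
}

# sub-cycled explicit rise update (the rise CFL, not the user dt, sets the
# internal number of sub-steps)
apply_rise <- function(MP, F_R, w_p_md, grid, dt) {
  if (F_R == 0 || w_p_md == 0) return(MP)
  nz <- grid$n_layers
  if (nz == 1L) return(MP)
  n_sub <- max(1L, ceiling(dt * F_R * w_p_md / min(grid$thickness[-1])))
  dts <- dt / n_sub
  for (s in seq_len(n_sub)) {
    up <- rise_flux(MP, F_R, w_p_md, grid)
    # up[i] leaves layer i upward and enters layer i-1
    MP <- MP + dts * (c(up[-1], 0) - up) / grid$thickness
  }
  MP
}

# interface diffusivities (m^2/d), enhanced inside the mixed layer
kappa_interfaces <- function(grid, tcfg) {
  iface <- grid$interface_depth[-grid$n_layers]
  k <- rep(tcfg$kappa_bg_m2s, length(iface))
  k[iface <= tcfg$ml_depth_m + 1e-9] <- tcfg$kappa_ml_m2s
  k * 86400
}

# conservative explicit vertical diffusion of one tracer
diffuse <- function(conc, kappa_md, grid, dt) {
  nz <- grid$n_layers
  if (nz == 1L) return(conc)
  dzc <- diff(grid$mid_depth)
  j <- kappa_md * (conc[-nz] - conc[-1]) / dzc  # downward-positive flux
  conc[-nz] <- conc[-nz] - dt * j / grid$thickness[-nz]
  conc[-1]  <- conc[-1]  + dt * j / grid$thickness[-1]
  conc
}

#' Seafloor exchange of ballasted microplastic
#'
#' Particles reaching the seafloor inside aggregates or pellets are split: a
#' fraction `F_B` is returned to the bottom layer as free microplastic
#' (released from its organic matrix), the rest is permanently buried.
#'
#' @param flux_A,flux_Z seafloor fluxes of aggregate- and pellet-bound
#'   microplastic, particles m^-2 d^-1 (>= 0).
#' @param F_B return fraction, in \[0, 1\].
#' @return list with `returned` and `lost` (particles m^-2 d^-1), plus the
#'   per-tracer breakdown.
#' @export
seafloor_exchange <- function(flux_A, flux_Z, F_B) {
  if (any(c(flux_A, flux_Z) < 0))
    stop("seafloor fluxes must be >= 0", call. = FALSE)
  if (F_B < 0 || F_B > 1) stop("`F_B` must lie in [0, 1]", call. = FALSE)
  tot <- flux_A + flux_Z
  list(returned = F_B * tot, lost = (1 - F_B) * tot,
       returned_A = F_B * flux_A, returned_Z = F_B * flux_Z,
       lost_A = (1 - F_B) * flux_A, lost_Z = (1 - F_B) * flux_Z)
}
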