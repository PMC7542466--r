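#' Microplastic model parameters
#'
#' Bundles the seven screened microplastic parameters together with the fixed
#' physical conversion constants. Particle mass is set by the bulk conversion
#' 236e3 tonnes of microplastic = 51.2e12 particles; food mass is converted to
#' nitrogen via Redfield organic matter (C106 H263 O110 N16 P, 222.08 g per
#' mol N).
#'
#' @param F_T fraction of total annual plastic waste generation entering the
#'   ocean as microplastic (dimensionless, 0-1).
#' @param F_R fraction of the free microplastic pool assigned a fast rise
#'   rate (0-0.1 in the screening design).
#' @param F_A fraction of newly forming marine snow aggregates that capture a
#'   microplastic particle at saturation (0-1).
#' @param k_P half-saturation constant of microplastic capture by marine
#'   snow, particles m^-3 (0-1000).
#' @param F_B fraction of particles reaching the seafloor in aggregates or
#'   pellets that is returned to the bottom water-column layer (0-1).
#' @param psi_MP zooplankton grazing preference for microplastic (0.1-0.3 in
#'   the screening design; 0 disables plastic grazing).
#' @param R_F_MP food substitution ratio, grams of food displaced per gram of
#'   microplastic ingested (0.5-1.5).
#' @param w_p_ms rise speed of the buoyant sub-population, m s^-1
#'   (default 0.019).
#' @param mp_mass_tonnes,mp_count bulk mass-to-particle calibration: `mp_count`
#'   particles weigh `mp_mass_tonnes` tonnes (defaults 236e3 t = 51.2e12).
#' @param R_N_F mol N per gram of food at Redfield stoichiometry
#'   (default 1/222.078).
#' @param c_agg_ugC carbon content of one marine snow aggregate, micrograms C
#'   (default 8.8, diatom aggregates).
#' @param redfield_CN molar C:N ratio of organic matter (default 106/16).
#'
#' @return An object of class `mp_parameters` (a named list).
#' @seealso [fixture_parameters()] for the published sample parameterisations.
#' @export
mp_parameters <- function(F_T = 0, F_R = 0, F_A = 0, k_P = 1, F_B = 0,
                          psi_MP = 0, R_F_MP = 1,
                          w_p_ms = 0.019,
                          mp_mass_tonnes = 236e3, mp_count = 51.2e12,
                          R_N_F = 1 / 222.078,
                          c_agg_ugC = 8.8,
                          redfield_CN = 106 / 16) {
  p <- list(F_T = F_T, F_R = F_R, F_A = F_A, k_P = k_P, F_B = F_B,
            psi_MP = psi_MP, R_F_MP = R_F_MP,
            w_p_ms = w_p_ms,
            mp_mass_tonnes = mp_mass_tonnes, mp_count = mp_count,
            R_N_F = R_N_F, c_agg_ugC = c_agg_ugC, redfield_CN = redfield_CN)
  for (f in c("F_T", "F_A", "F_B")) {
    v <- p[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must lie in [0, 1]", f), call. = FALSE)
  }
  if (!is.finite(p$F_R) || p$F_R < 0 || p$F_R > 1)
    stop("`F_R` must lie in [0, 1]", call. = FALSE)
  if (!is.finite(p$psi_MP) || p$psi_MP < 0 || p$psi_MP > 0.9)
    stop("`psi_MP` must lie in [0, 0.9]", call. = FALSE)
  if (!is.finite(p$k_P) || p$k_P < 0)
    stop("`k_P` must be >= 0", call. = FALSE)
  if (!is.finite(p$R_F_MP) || p$R_F_MP <= 0)
    stop("`R_F_MP` must be > 0", call. = FALSE)
  structure(p, class = "mp_parameters")
}

#' @export
print.mp_parameters <- function(x, ...) {
  cat("<mp_parameters>\n")
  cat(sprintf("  F_T=%.3f F_R=%.3f F_A=%.3f k_P=%.3f F_B=%.3f psi_MP=%.3f R_F:MP=%.3f\n",
              x$F_T, x$F_R, x$F_A, x$k_P, x$F_B, x$psi_MP, x$R_F_MP))
  invisible(x)
}

# grams of plastic per particle (236e9 g / 51.2e12 particles by default)
mp_particle_mass_g <- function(params) {
  params$mp_mass_tonnes * 1e6 / params$mp_count
}

#' Particles per tonne of microplastic
#' @param params an [mp_parameters()] object.
#' @return particles per metric tonne.
#' @export
particles_per_tonne <- function(params = mp_parameters()) {
  params$mp_count / params$mp_mass_tonnes
}

#' Convert microplastic mass to particle count (and back)
#'
#' Uses the bulk calibration that 236e3 tonnes of microplastic corresponds to
#' 51.2e12 particles. `particles_to_mass()` is the exact inverse.
#'
#' @param mass_tonnes microplastic mass, metric tonnes (>= 0).
#' @param particles particle count (>= 0).
#' @param params an [mp_parameters()] object.
#' @return particle count, or mass in tonnes.
#' @examples
#' mass_to_particles(236e3)  # 5.12e13
#' @export
mass_to_particles <- function(mass_tonnes, params = mp_parameters()) {
  if (any(!is.finite(mass_tonnes)) || any(mass_tonnes < 0))
    stop("`mass_tonnes` must be non-negative", call. = FALSE)
  mass_tonnes * particles_per_tonne(params)
}

#' @rdname mass_to_particles
#' @export
particles_to_mass <- function(particles, params = mp_parameters()) {
  if (any(!is.finite(particles)) || any(particles < 0))
    stop("`particles` must be non-negative", call. = FALSE)
  particles / particles_per_tonne(params)
}

# mmol N per particle for the grazing currency: particle mass (g) x food
# substitution ratio (g food per g MP) x mol N per g food x 1000 mmol/mol.
mp_nitrogen_conversion <- function(params) {
  mp_particle_mass_g(params) * params$R_F_MP * params$R_N_F * 1000
}

#' Convert free microplastic concentration to its nitrogen-currency value
#'
#' For the grazing calculation microplastic is expressed as the nitrogen
#' equivalent of the food it displaces: particles are converted to grams of
#' plastic, multiplied by the food substitution ratio `R_F_MP`, and converted
#' to mmol N at Redfield stoichiometry.
#'
#' @param mp particles m^-3 (vectorised).
#' @param mmol_N mmol N m^-3 (vectorised).
#' @param params an [mp_parameters()] object.
#' @return mmol N m^-3, or particles m^-3 for the inverse.
#' @export
mp_to_nitrogen <- function(mp, params) mp * mp_nitrogen_conversion(params)

#' @rdname mp_to_nitrogen
#' @export
nitrogen_to_mp <- function(mmol_N, params) mmol_N / mp_nitrogen_conversion(params)

# Published sample parameterisations (fixtures)
.fixture_table <- function() {
  data.frame(
    name   = c("no_bio", "test_lo", "test_hi", "test_med"),
    F_T    = c(0.260, 0.137, 0.329, 0.276),
    F_R    = c(0.033, 0.003, 0.074, 0.011),
    F_B    = c(0,     0.132, 0.888, 0.528),
    F_A    = c(0,     0.003, 0.098, 0.092),
    k_P    = c(1,     0.424, 833.290, 615.508),
    psi_MP = c(0,     0.260, 0.132, 0.193),
    R_F_MP = c(1,     1.029, 1.489, 0.993),
    stringsAsFactors = FALSE
  )
}

#' Published sample parameterisations
#'
#' Returns one of the four packaged parameter fixtures: `"no_bio"` (physical
#' transport only; biological uptake disabled), and the low / high / moderate
#' surface-concentration configurations `"test_lo"`, `"test_hi"`,
#' `"test_med"`. In `no_bio` the aggregation fraction and grazing preference
#' are zero, so the biological pathway parameters are inert placeholders.
#'
#' @param name fixture name.
#' @return An [mp_parameters()] object.
#' @examples
#' fixture_parameters("test_med")$k_P  # 615.508
#' @export
fixture_parameters <- function(name = c("no_bio", "test_lo", "test_hi", "test_med")) {
  name <- match.arg(name)
  tb <- .fixture_table()
  r <- tb[tb$name == name, ]
  mp_parameters(F_T = r$F_T, F_R = r$F_R, F_A = r$F_A, k_P = r$k_P,
                F_B = r$F_B, psi_MP = r$psi_MP, R_F_MP = r$R_F_MP)
}

#' List the packaged parameter fixtures
#' @return data.frame of fixture names and parameter values.
#' @export
list_fixtures <- function() .fixture_table()
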