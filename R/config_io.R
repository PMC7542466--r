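#' Load a run configuration from YAML
#'
#' Reads a YAML configuration, validates it against the known schema
#' (unknown top-level keys are rejected), fills defaults, and returns a
#' [run_config()]. An empty file yields the all-defaults configuration.
#'
#' Recognised top-level keys: `run` (`years`, `spinup_years`, `dt_days`),
#' `grid` (`thicknesses_m` or `bottom_depth_m`/`n_layers`), `parameters`
#' (a fixture name or a map of the seven microplastic parameters),
#' `forcing`, `columns`, `scenario`, `ecosystem`, `transport`,
#' `export_depth_m`.
#'
#' @param path path to a YAML file.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("run", "grid", "parameters", "forcing", "columns", "scenario",
             "ecosystem", "transport", "export_depth_m")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop(sprintf("unknown configuration keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)

  g <- raw$grid
  grid <- if (!is.null(g$thicknesses_m)) {
    column_grid(unlist(g$thicknesses_m))
  } else {
    default_grid(bottom_depth = g$bottom_depth_m %||% 5000,
                 n_layers = g$n_layers %||% 19)
  }
  params <- raw$parameters %||% "test_med"
  if (is.list(params)) params <- do.call(mp_parameters, params)

  args <- list(
    params = params, grid = grid,
    years = unlist(raw$run$years %||% c(1950, 2020)),
    spinup_years = raw$run$spinup_years %||% 30,
    dt = raw$run$dt_days %||% 0.5,
    forcing = raw$forcing %||% list(),
    scenario = raw$scenario %||% list(),
    eco = do.call(eco_parameters, raw$ecosystem %||% list()),
    transport = do.call(transport_config, raw$transport %||% list()),
    export_depth = raw$export_depth_m %||% 130)
  if (!is.null(raw$columns)) args$columns <- raw$columns
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation outputs
#'
#' Writes tidy CSV outputs next to each other in `dir`: `diagnostics.csv`
#' (one row per column-year), `profiles.csv` (one row per
#' column-year-layer for the three microplastic tracers), and
#' `provenance.yaml` echoing the resolved configuration. Identical runs
#' produce byte-identical files.
#'
#' @param run an `mpsink_run` from [run_simulation()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "mpsink_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_diag <- file.path(dir, "diagnostics.csv")
  utils::write.csv(run$diagnostics, p_diag, row.names = FALSE)

  grid <- run$config$grid
  prof <- do.call(rbind, lapply(names(run$profiles), function(cn) {
    pr <- run$profiles[[cn]]
    ny <- length(pr$years)
    data.frame(column = cn,
               year = rep(pr$years, each = grid$n_layers),
               layer = rep(seq_len(grid$n_layers), ny),
               mid_depth_m = rep(grid$mid_depth, ny),
               MP = as.vector(t(pr$MP)),
               MP_A = as.vector(t(pr$MP_A)),
               MP_Z = as.vector(t(pr$MP_Z)),
               stringsAsFactors = FALSE)
  }))
  p_prof <- file.path(dir, "profiles.csv")
  utils::write.csv(prof, p_prof, row.names = FALSE)

  cfg <- run$config
  p_prov <- file.path(dir, "provenance.yaml")
  yaml::write_yaml(list(
    package = "mpsink",
    parameters = unclass(cfg$params)[c("F_T", "F_R", "F_A", "k_P", "F_B",
                                       "psi_MP", "R_F_MP")],
    grid = list(thicknesses_m = grid$thickness),
    years = cfg$years, spinup_years = cfg$spinup_years, dt_days = cfg$dt,
    forcing = cfg$forcing, scenario = cfg$scenario,
    columns = cfg$columns,
    stable = as.list(run$stable)), p_prov)
  invisible(c(diagnostics = p_diag, profiles = p_prof, provenance = p_prov))
}
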