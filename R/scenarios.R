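#' Trade-off parameter sweep
#'
#' Runs the food web over a grid of omnivore trade-off parameters
#' (`f_PM` x `f_FC`) and reports pool means and the within-/between-year
#' variability decomposition for every cell, alongside the control solution
#' (behavioral model off) computed once with the same configuration. Cells
#' are independent; their order does not affect the results. A failing cell
#' is recorded with `NA` values and the sweep continues.
#'
#' @param cfg Base configuration.
#' @param f_PM_grid,f_FC_grid Grid values in \[0, 1\].
#' @param years Simulated years per cell.
#' @return A data frame with one row per (cell, pool): `f_PM`, `f_FC`,
#'   `control` (logical), `pool`, `mean`, `within_cv`, `between_cv`.
#' @export
tradeoff_sweep <- function(cfg = default_config(),
                           f_PM_grid = seq(0.2, 1, by = 0.2),
                           f_FC_grid = seq(0.2, 1, by = 0.2),
                           years = cfg$run$years) {
  cfg <- validate_config(cfg)
  if (any(f_PM_grid < 0 | f_PM_grid > 1) || any(f_FC_grid < 0 | f_FC_grid > 1))
    stop("grid values must lie in [0, 1]", call. = FALSE)
  cell <- function(cfg_i, fpm, ffc, control) {
    res <- tryCatch(foodweb_run(cfg_i, years = years), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(f_PM = fpm, f_FC = ffc, control = control,
                        pool = .POOLS, mean = NA_real_,
                        within_cv = NA_real_, between_cv = NA_real_))
    }
    s <- scenario_summary(res)$pools
    data.frame(f_PM = fpm, f_FC = ffc, control = control, s)
  }
  rows <- list()
  ctl <- cfg
  ctl$omnivore$obm <- FALSE
  ctl$predator$obm <- FALSE
  rows[[1]] <- cell(ctl, NA_real_, NA_real_, TRUE)
  for (fpm in f_PM_grid) for (ffc in f_FC_grid) {
    ci <- cfg
    ci$omnivore$obm <- TRUE
    ci$omnivore$tradeoff$f_PM <- fpm
    ci$omnivore$tradeoff$f_FC <- ffc
    rows[[length(rows) + 1]] <- cell(ci, fpm, ffc, FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nutrient-loading scenario ladder
#'
#' Runs the food web across a ladder of nutrient-load multipliers, with and
#' without the behavioral model, and returns the seasonal metrics of
#' [scenario_metrics()] for every scenario. The omnivore biomass index is
#' normalized to the maximum across the two configurations.
#'
#' @param cfg Base configuration (its trade-off parameters are used for the
#'   behavior-on runs).
#' @param scales Load multipliers; the default ladder is 25 %, 50 %,
#'   100 %, 200 % and 400 % of the baseline load.
#' @param years Simulated years per scenario.
#' @return A data frame with columns `load_scale`, `obm`, `metric`,
#'   `value`; the metric `august_omnivore_index` is added (normalized
#'   biomass).
#' @export
loading_ladder <- function(cfg = default_config(),
                           scales = c(0.25, 0.5, 1, 2, 4),
                           years = cfg$run$years) {
  cfg <- validate_config(cfg)
  if (any(scales <= 0)) stop("`scales` must be > 0", call. = FALSE)
  rows <- list()
  for (obm in c(TRUE, FALSE)) {
    ci <- cfg
    ci$omnivore$obm <- obm
    ci$predator$obm <- obm
    for (sc in scales) {
      ci$forcing$load_scale <- sc
      res <- foodweb_run(ci, years = years)
      m <- scenario_metrics(res)
      rows[[length(rows) + 1]] <- data.frame(load_scale = sc, obm = obm, m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  omn <- out[out$metric == "august_omnivore_biomass", ]
  idx <- transform(omn, metric = "august_omnivore_index",
                   value = value / max(value))
  rbind(out, idx)
}

#' Emergent functional-response curves for a scenario pair
#'
#' Convenience wrapper around [functional_response()] computing the curve
#' at two ambient predation levels over a shared availability grid.
#'
#' @param tp A [tradeoff_params()].
#' @param m_pred_low,m_pred_high Smoothed predation mortalities (d^-1) for
#'   the two curves.
#' @param R_grid Availability grid (g m^-3).
#' @param env Template [feeding_env()] (its `R` and `m_pred_s` are
#'   replaced).
#' @return Data frame: the [functional_response()] columns plus
#'   `predation` (`"low"`/`"high"`).
#' @export
response_curves <- function(tp = tradeoff_params(1, 1, 0.3),
                            m_pred_low = 0.001, m_pred_high = 0.01,
                            R_grid = seq(0, 20, length.out = 201),
                            env = feeding_env(R = 1, c = 0.05, I_max = 0.05,
                                              a = 0.7, u = 0.005,
                                              m_nat = 5e-4)) {
  out <- list()
  for (lev in c(low = m_pred_low, high = m_pred_high)) {
    e <- env
    e$m_pred_s <- lev
    fr <- functional_response(e, tp, R_grid)
    fr$predation <- if (lev == m_pred_low) "low" else "high"
    out[[length(out) + 1]] <- fr
  }
  do.call(rbind, out)
}

#' Search for a cycling reference calibration
#'
#' Deterministically scans a small grid of predator clearance and omnivore
#' maximum-consumption values around the default configuration and returns
#' the first calibration (in a seed-shuffled but reproducible order) whose
#' control run (behavioral model off) shows multiyear oscillation of
#' omnivorous fish biomass -- between-year CV above `floor` -- and whose
#' behavior-on run (`f_PM = f_FC = 1`) reduces the between-year CV of both
#' fish groups. The frozen copy of the fixture found by this search ships
#' with the package (see [cycling_fixture()]).
#'
#' @param seed Integer seed controlling only the order in which grid cells
#'   are tried; the returned fixture for a given seed is always identical.
#' @param years Simulated years per trial run.
#' @param floor Required between-year CV of omnivore biomass in the control
#'   run.
#' @param c_p_grid,Im_o_grid Candidate predator clearance rates and
#'   omnivore maximum consumption rates.
#' @param predator_energetics Overrides applied to the predator before the
#'   search: multiyear cycles need a predator whose decline during prey
#'   scarcity is slow relative to prey growth, so the search starts from a
#'   low-turnover predator rather than the fast default.
#' @return A list with `cfg` (the calibration), `floor`, and `diagnostics`
#'   (data frame of all evaluated cells). Errors with the grid diagnostics
#'   if no cell qualifies.
#' @export
make_cycling_fixture <- function(seed = 1L, years = 60,
                                 floor = 0.25,
                                 c_p_grid = c(0.1, 0.15, 0.25),
                                 Im_o_grid = c(0.06, 0.08),
                                 predator_energetics = list(
                                   I_max = 0.025, u = 0.003, m_nat = 7.5e-4)) {
  base <- validate_config(default_config())
  base$omnivore$tradeoff <- list(f_PM = 1, f_FC = 1, f_RF = base$omnivore$tradeoff$f_RF)
  base$predator[names(predator_energetics)] <- predator_energetics
  grid <- expand.grid(c_p = c_p_grid, Im_o = Im_o_grid)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  grid <- grid[sample(nrow(grid)), , drop = FALSE]
  diag <- list()
  for (k in seq_len(nrow(grid))) {
    cfg <- base
    cfg$predator$c <- grid$c_p[k]
    cfg$omnivore$I_max <- grid$Im_o[k]
    off <- cfg
    off$omnivore$obm <- FALSE
    off$predator$obm <- FALSE
    r_off <- tryCatch(foodweb_run(off, years = years), error = function(e) NULL)
    cv_off_o <- cv_off_p <- cv_on_o <- cv_on_p <- NA_real_
    ok <- FALSE
    if (!is.null(r_off)) {
      cv_off_o <- tryCatch(between_year_cv(analysis_series(r_off, "omnivore")),
                           error = function(e) NA_real_)
      cv_off_p <- tryCatch(between_year_cv(analysis_series(r_off, "predator")),
                           error = function(e) NA_real_)
      if (isTRUE(cv_off_o >= floor)) {
        r_on <- tryCatch(foodweb_run(cfg, years = years), error = function(e) NULL)
        if (!is.null(r_on)) {
          cv_on_o <- tryCatch(between_year_cv(analysis_series(r_on, "omnivore")),
                              error = function(e) NA_real_)
          cv_on_p <- tryCatch(between_year_cv(analysis_series(r_on, "predator")),
                              error = function(e) NA_real_)
          ok <- isTRUE(cv_on_o < cv_off_o) && isTRUE(cv_on_p < cv_off_p)
        }
      }
    }
    diag[[k]] <- data.frame(c_p = grid$c_p[k], Im_o = grid$Im_o[k],
                            cv_off_omn = cv_off_o, cv_off_prd = cv_off_p,
                            cv_on_omn = cv_on_o, cv_on_prd = cv_on_p,
                            qualifies = ok)
    if (ok) {
      return(list(cfg = cfg, floor = floor,
                  diagnostics = do.call(rbind, diag)))
    }
  }
  dd <- do.call(rbind, diag)
  stop("no calibration on the search grid qualifies as cycling; diagnostics:\n",
       paste(utils::capture.output(print(dd)), collapse = "\n"), call. = FALSE)
}

#' The frozen cycling reference calibration
#'
#' Loads the calibration shipped with the package: a configuration whose
#' control run (behavioral model off) exhibits multiyear fish-biomass
#' cycles (between-year CV of omnivorous fish above the declared floor)
#' and whose behavior-on run damps them. Found once by
#' [make_cycling_fixture()] and frozen.
#'
#' @return A list with `cfg`, `floor` and `provenance` fields.
#' @export
cycling_fixture <- function() {
  path <- system.file("extdata", "cycling_fixture.yaml", package = "lakeOBM",
                      mustWork = TRUE)
  fx <- yaml::read_yaml(path)
  fx$cfg <- validate_config(fx$cfg)
  fx
}
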