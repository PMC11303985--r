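# ---------------------------------------------------------------------------
# Zero-dimensional lake food web:
#   nutrient -> phytoplankton -> zooplankton -> omnivorous fish -> predator
#   detritus (sediment POM) <- mortality + egestion; zoobenthos feeds on it;
#   mineralization closes the loop back to nutrient.
# Single mass currency (nutrient-equivalent biomass, g m^-3); every flux is
# a transfer between pools, so a closed configuration conserves total mass
# exactly up to floating-point rounding.

.STATE_NAMES <- c(.POOLS, "mps_omnivore", "mps_predator",
                  "clipped", "exported", "loaded")
.CLIP_FLOOR <- 1e-12

# flatten a validated config into plain vectors for the inner loop
.fw_params <- function(cfg) {
  om <- cfg$omnivore
  prey <- om$prey
  list(
    mu_max = cfg$phytoplankton$mu_max, K_N = cfg$phytoplankton$K_N,
    resp_phy = cfg$phytoplankton$resp, mort_phy = cfg$phytoplankton$mort,
    c_z = cfg$zooplankton$c, Im_z = cfg$zooplankton$I_max,
    fg_z = cfg$zooplankton$f_gut, a_z = cfg$zooplankton$a,
    u_z = cfg$zooplankton$u, mn_z = cfg$zooplankton$m_nat,
    c_b = cfg$zoobenthos$c, Im_b = cfg$zoobenthos$I_max,
    fg_b = cfg$zoobenthos$f_gut, a_b = cfg$zoobenthos$a,
    u_b = cfg$zoobenthos$u, mn_b = cfg$zoobenthos$m_nat,
    obm_o = isTRUE(om$obm), Im_o = om$I_max, u_o = om$u, mn_o = om$m_nat,
    fveg_o = om$f_veg,
    fPM_o = om$tradeoff$f_PM, fFC_o = om$tradeoff$f_FC, fRF_o = om$tradeoff$f_RF,
    prey_id = vapply(prey, `[[`, character(1), "id"),
    prey_mode = vapply(prey, `[[`, character(1), "mode"),
    prey_c = vapply(prey, `[[`, numeric(1), "c"),
    prey_fg = vapply(prey, `[[`, numeric(1), "f_gut"),
    prey_a = vapply(prey, `[[`, numeric(1), "a"),
    obm_p = isTRUE(cfg$predator$obm), Im_p = cfg$predator$I_max,
    u_p = cfg$predator$u, mn_p = cfg$predator$m_nat,
    fveg_p = cfg$predator$f_veg, c_p = cfg$predator$c,
    fg_p = cfg$predator$f_gut, a_p = cfg$predator$a,
    fPM_p = cfg$predator$tradeoff$f_PM, fFC_p = cfg$predator$tradeoff$f_FC,
    fRF_p = cfg$predator$tradeoff$f_RF,
    flushing = cfg$physics$flushing, burial = cfg$physics$burial,
    miner = cfg$physics$mineralization,
    q10 = c(phy = cfg$phytoplankton$q10, zoo = cfg$zooplankton$q10,
            ben = cfg$zoobenthos$q10, omn = om$q10, prd = cfg$predator$q10,
            min = 2)
  )
}

# fixed-activity (control) solution: maximal feeding, no mitigation
.control_solution <- function(Re, G, I_max, a, u, m_nat, m_pred_s, f_RF) {
  F_lev <- if (I_max + G > 0) G / (I_max + G) else 0
  g <- if (I_max + G > 0) a * Re * I_max / (I_max + G) else 0
  list(p_star = 0, f_feed = 1, F = F_lev, g = g, u_tot = (1 + f_RF) * u,
       m_tot = m_nat + m_pred_s, W = NA_real_, regime = 1L,
       g_pot = g, u_pot = (1 + f_RF) * u)
}

# one explicit-Euler day; st is the numeric state vector, fT the per-group
# temperature factors for this day
.fw_step_core <- function(st, light, load, fT, P, dt) {
  nut <- st[1]; phy <- st[2]; zoo <- st[3]; ben <- st[4]; det <- st[5]
  omn <- st[6]; prd <- st[7]; mps_o <- st[8]; mps_p <- st[9]

  # --- lower food web -------------------------------------------------------
  upt <- P$mu_max * fT[1] * light * nut / (P$K_N + nut) * phy
  resp_phy <- P$resp_phy * fT[1] * phy
  mort_phy <- P$mort_phy * phy

  Im_z <- P$Im_z * fT[2]
  Qz <- P$c_z * P$fg_z * phy
  cap_z <- P$c_z * phy * (Im_z / (Im_z + Qz)) * zoo   # = c*phy*(1-F)*Z
  resp_z <- P$u_z * fT[2] * zoo
  mort_z <- P$mn_z * zoo

  Im_b <- P$Im_b * fT[3]
  Qb <- P$c_b * P$fg_b * det
  cap_b <- P$c_b * det * (Im_b / (Im_b + Qb)) * ben
  resp_b <- P$u_b * fT[3] * ben
  mort_b <- P$mn_b * ben

  # --- omnivorous fish: diet + behavior ------------------------------------
  Rv <- c(zoo, ben, det)[match(P$prey_id,
                               c("zooplankton", "zoobenthos", "detritus"))]
  Im_o <- P$Im_o * fT[4]; u_o <- P$u_o * fT[4]
  if (P$obm_o) {
    dd <- .diet_then_behavior(Rv, P$prey_c, P$prey_fg, P$prey_a, P$prey_mode,
                              Im_o, u_o, P$mn_o, mps_o, P$fveg_o,
                              P$fPM_o, P$fFC_o, P$fRF_o)
    cap_o <- dd$capture          # specific capture per prey, d^-1
    sol_o <- dd$sol
  } else {
    dd <- .diet_then_behavior(Rv, P$prey_c, P$prey_fg, P$prey_a, P$prey_mode,
                              Im_o, u_o, P$mn_o, mps_o, P$fveg_o,
                              1, 0, P$fRF_o)   # f_FC = 0 keeps f_feed = 1
    # control model: feed maximally regardless of fitness
    e <- numeric(length(Rv))
    e[dd$sel] <- dd$mode_weights[P$prey_mode[dd$sel]] * P$prey_c[dd$sel] * Rv[dd$sel]
    CR <- sum(e)
    sol_o <- .control_solution(P$fveg_o * CR,
                               P$fveg_o * sum(e * P$prey_fg), Im_o,
                               if (CR > 0) sum(e * P$prey_a) / CR else 0,
                               u_o, P$mn_o, mps_o, P$fRF_o)
    cap_o <- P$fveg_o * e * (1 - sol_o$F)
  }
  assim_o <- sum(P$prey_a * cap_o) * omn
  egest_o <- sum((1 - P$prey_a) * cap_o) * omn
  resp_o <- sol_o$u_tot * omn
  mort_o <- P$mn_o * omn
  cap_o_tot <- cap_o * omn       # flux removed from each prey pool

  # --- predator fish -------------------------------------------------------
  avail <- (1 - sol_o$p_star * P$fPM_o) * omn
  Im_p <- P$Im_p * fT[5]; u_p <- P$u_p * fT[5]
  Re_p <- P$fveg_p * P$c_p * avail
  if (P$obm_p) {
    sol_p <- .obm_solve(Re_p, Re_p * P$fg_p, Im_p, P$a_p, u_p,
                        P$mn_p, mps_p, P$fPM_p, P$fFC_p, P$fRF_p)
  } else {
    sol_p <- .control_solution(Re_p, Re_p * P$fg_p, Im_p, P$a_p, u_p,
                               P$mn_p, mps_p, P$fRF_p)
  }
  cap_p <- sol_p$f_feed * P$fveg_p * P$c_p * avail * (1 - sol_p$F)  # specific
  cap_p_tot <- cap_p * prd
  resp_p <- sol_p$u_tot * prd
  mort_p <- P$mn_p * prd

  miner <- P$miner * fT[6] * det
  flush_nut <- P$flushing * nut
  flush_phy <- P$flushing * phy
  bury <- P$burial * det

  # --- availability limitation: scale every outflow of an over-drawn pool --
  lim <- function(pool, out) if (out > 0 && out * dt > pool) pool / (out * dt) else 1
  cap_o_zoo <- cap_o_tot[P$prey_id == "zooplankton"]
  cap_o_ben <- cap_o_tot[P$prey_id == "zoobenthos"]
  cap_o_det <- cap_o_tot[P$prey_id == "detritus"]
  cap_o_zoo <- if (length(cap_o_zoo)) sum(cap_o_zoo) else 0
  cap_o_ben <- if (length(cap_o_ben)) sum(cap_o_ben) else 0
  cap_o_det <- if (length(cap_o_det)) sum(cap_o_det) else 0

  l_nut <- lim(nut, upt + flush_nut)
  l_phy <- lim(phy, resp_phy + mort_phy + cap_z + flush_phy)
  l_zoo <- lim(zoo, resp_z + mort_z + cap_o_zoo)
  l_ben <- lim(ben, resp_b + mort_b + cap_o_ben)
  l_det <- lim(det, cap_b + cap_o_det + miner + bury)
  l_omn <- lim(omn, resp_o + mort_o + cap_p_tot)
  l_prd <- lim(prd, resp_p + mort_p)

  upt <- upt * l_nut; flush_nut <- flush_nut * l_nut
  resp_phy <- resp_phy * l_phy; mort_phy <- mort_phy * l_phy
  cap_z <- cap_z * l_phy; flush_phy <- flush_phy * l_phy
  resp_z <- resp_z * l_zoo; mort_z <- mort_z * l_zoo; cap_o_zoo <- cap_o_zoo * l_zoo
  resp_b <- resp_b * l_ben; mort_b <- mort_b * l_ben; cap_o_ben <- cap_o_ben * l_ben
  cap_b <- cap_b * l_det; cap_o_det <- cap_o_det * l_det
  miner <- miner * l_det; bury <- bury * l_det
  resp_o <- resp_o * l_omn; mort_o <- mort_o * l_omn; cap_p_tot <- cap_p_tot * l_omn
  resp_p <- resp_p * l_prd; mort_p <- mort_p * l_prd

  # recompute assimilation/egestion from the availability-scaled captures
  caps <- c(zooplankton = cap_o_zoo, zoobenthos = cap_o_ben, detritus = cap_o_det)
  a_by_id <- stats::setNames(P$prey_a, P$prey_id)   # prey ids are unique
  caps <- caps[names(a_by_id)]                      # only pools on the menu
  assim_o <- sum(a_by_id * caps)
  egest_o <- sum((1 - a_by_id) * caps)

  # --- balances ------------------------------------------------------------
  d_nut <- load + resp_phy + resp_z + resp_b + resp_o + resp_p + miner -
    upt - flush_nut
  d_phy <- upt - resp_phy - mort_phy - cap_z - flush_phy
  d_zoo <- P$a_z * cap_z - resp_z - mort_z - cap_o_zoo
  d_ben <- P$a_b * cap_b - resp_b - mort_b - cap_o_ben
  d_det <- mort_phy + mort_z + mort_b + mort_o + mort_p +
    (1 - P$a_z) * cap_z + (1 - P$a_b) * cap_b + egest_o +
    (1 - P$a_p) * cap_p_tot - cap_b - cap_o_det - miner - bury
  d_omn <- assim_o - resp_o - mort_o - cap_p_tot
  d_prd <- P$a_p * cap_p_tot - resp_p - mort_p

  new <- c(nut + dt * d_nut, phy + dt * d_phy, zoo + dt * d_zoo,
           ben + dt * d_ben, det + dt * d_det, omn + dt * d_omn,
           prd + dt * d_prd)
  old <- st[1:7]
  clipped <- st[10]
  low <- new < .CLIP_FLOOR
  if (any(low)) {
    fix <- low & (old > 0)
    clipped <- clipped + sum(.CLIP_FLOOR - new[fix])
    new[fix] <- .CLIP_FLOOR
    new[low & !fix] <- pmax(new[low & !fix], 0)
  }

  m_pred_inst <- sol_p$f_feed * P$fveg_p * P$c_p * (1 - sol_p$F) * prd
  st_new <- c(new,
              (mps_o + 0.25 * m_pred_inst) / 1.25,
              mps_p,                       # top predator: risk stays zero
              clipped,
              st[11] + dt * (flush_nut + flush_phy + bury),
              st[12] + dt * load)
  list(state = st_new,
       diag = c(p_omn = sol_o$p_star, feed_omn = sol_o$f_feed,
                regime_omn = as.numeric(sol_o$regime),
                cons_omn = if (omn > 0)
                  (cap_o_zoo + cap_o_ben + cap_o_det) / omn else 0,
                p_prd = sol_p$p_star, feed_prd = sol_p$f_feed,
                regime_prd = as.numeric(sol_p$regime),
                cons_prd = cap_p_tot / max(prd, .CLIP_FLOOR)))
}

#' Initial food-web state
#'
#' @param cfg Validated configuration list.
#' @return Named numeric state vector: the seven pools (g m^-3), the
#'   smoothed predation risk of each fish group (d^-1), and three ledger
#'   entries (`clipped`, `exported`, `loaded` cumulative masses, g m^-3).
#' @export
foodweb_init <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  st <- c(unlist(cfg$init[.POOLS]), 0, 0, 0, 0, 0)
  names(st) <- .STATE_NAMES
  st
}

#' Advance the food web by one time step
#'
#' Explicit-Euler update of all source-minus-sink balances. Fish groups
#' with the behavioral model enabled first choose diet and feeding-mode
#' allocation, then the mitigation level `p*` (using the smoothed predation
#' risk carried in the state); the predator sees only the unmitigated
#' fraction `(1 - p* f_PM)` of omnivore biomass. Every ingestion appears as
#' a loss on the prey pool; unassimilated ingestion and mortality route to
#' the detritus pool; respiration is remineralized to the nutrient pool.
#' Outflows of a pool that would overdraw it within the step are scaled
#' down proportionally; pools are floored at `1e-12` g m^-3 (the clipped
#' mass is accumulated in the `clipped` ledger entry).
#'
#' @param state Named state vector from [foodweb_init()] or a previous step.
#' @param forcing One-row data frame from [seasonal_forcing()].
#' @param cfg Validated configuration.
#' @param dt Time step (days).
#' @return A list with `state` (updated vector) and `diag` (named vector:
#'   `p_omn`, `feed_omn`, `regime_omn`, `cons_omn`, and the predator
#'   equivalents; regimes coded 1 = normal, 2 = starvation_feed,
#'   3 = starvation_stop).
#' @export
foodweb_step <- function(state, forcing, cfg = default_config(), dt = 1) {
  cfg <- validate_config(cfg)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite state: simulation diverged", call. = FALSE)
  P <- .fw_params(cfg)
  fT <- unname(P$q10^((forcing$temperature - 20) / 10))
  out <- .fw_step_core(unname(state), forcing$light_factor,
                       forcing$nutrient_load, fT, P, dt)
  names(out$state) <- .STATE_NAMES
  out
}

#' Run the food-web simulation with looped annual forcing
#'
#' Simulates `years` model years at daily resolution, looping one identical
#' 365-day forcing cycle (no interannual environmental variability), and
#' returns the daily series together with the analysis window over which
#' statistics are computed (by default the last half of the run, mirroring
#' a spin-up-then-analyze protocol).
#'
#' @param cfg Configuration list (validated and merged over defaults).
#' @param years Number of simulated years (>= 2); defaults to
#'   `cfg$run$years`.
#' @param seed Optional integer recorded in the result (the model itself is
#'   deterministic).
#' @return An object of class `"scenario_result"`: list with `series`
#'   (data frame, one row per day: `day`, `year`, `doy`, the seven pools,
#'   ledgers and behavioral diagnostics), `cfg`, `years`, `analysis_years`
#'   (integer vector of years in the analysis window), and `seed`.
#' @examples
#' res <- foodweb_run(default_config(), years = 3)
#' head(res$series)
#' @export
foodweb_run <- function(cfg = default_config(), years = NULL, seed = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(years)) years <- cfg$run$years
  if (years < 2) stop("`years` must be >= 2", call. = FALSE)
  dt <- cfg$run$dt
  P <- .fw_params(cfg)
  fp <- forcing_params(cfg$forcing$temperature, cfg$forcing$light,
                       cfg$forcing$load)
  frc <- seasonal_forcing(1:365, fp, load_scale = cfg$forcing$load_scale)
  fTd <- outer(frc$temperature, rep(1, length(P$q10)))
  for (j in seq_along(P$q10)) fTd[, j] <- P$q10[j]^((frc$temperature - 20) / 10)

  ndays <- years * 365L
  series <- matrix(NA_real_, nrow = ndays, ncol = length(.STATE_NAMES) + 8L)
  st <- unname(foodweb_init(cfg))
  i <- 0L
  for (yr in seq_len(years)) {
    for (doy in 1:365) {
      i <- i + 1L
      out <- .fw_step_core(st, frc$light_factor[doy], frc$nutrient_load[doy],
                           fTd[doy, ], P, dt)
      st <- out$state
      if (any(!is.finite(st)))
        stop(sprintf("non-finite state on day %d: simulation diverged", i),
             call. = FALSE)
      series[i, ] <- c(st, out$diag)
    }
  }
  df <- as.data.frame(series)
  names(df) <- c(.STATE_NAMES, "p_omn", "feed_omn", "regime_omn", "cons_omn",
                 "p_prd", "feed_prd", "regime_prd", "cons_prd")
  df <- cbind(day = seq_len(ndays),
              year = rep(seq_len(years), each = 365L),
              doy = rep(1:365, times = years), df)
  n_analysis <- max(1L, ceiling(years * cfg$run$analysis_fraction))
  structure(list(series = df, cfg = cfg, years = years, dt = dt,
                 analysis_years = seq.int(years - n_analysis + 1L, years),
                 seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Food-web scenario: %d years (analysis window: years %d-%d)\n",
              x$years, min(x$analysis_years), max(x$analysis_years)))
  last <- x$series[nrow(x$series), .POOLS]
  cat("Final pools (g m^-3):\n")
  print(round(unlist(last), 4))
  invisible(x)
}

#' Extract the analysis-window daily series of one pool
#'
#' @param result A `"scenario_result"` from [foodweb_run()].
#' @param pool Column name in the daily series.
#' @return Numeric vector of daily values over the analysis window.
#' @export
analysis_series <- function(result, pool) {
  stopifnot(inherits(result, "scenario_result"))
  if (!pool %in% names(result$series)) stop("unknown series: ", pool, call. = FALSE)
  result$series[result$series$year %in% result$analysis_years, pool]
}

#' Total mass ledger of a run
#'
#' Total currency currently in the pools, plus exported (outflow + burial)
#' and minus loaded and clipped mass. In a closed configuration (zero load,
#' flushing and burial) this quantity is conserved.
#'
#' @param state Named state vector.
#' @return Total ledgered mass (g m^-3).
#' @export
mass_ledger <- function(state) {
  sum(state[.POOLS]) + state[["exported"]] - state[["loaded"]] -
    state[["clipped"]]
}
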