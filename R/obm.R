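# regime codes used by the internal solver
.REGIMES <- c("normal", "starvation_feed", "starvation_stop")

# absolute tolerance for comparisons of specific rates (d^-1) against
# regime thresholds
.RATE_TOL <- 1e-12

.check_scalar <- function(x, name, lower = 0, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  as.numeric(x)
}

#' Behavioral trade-off parameters
#'
#' Bundles the three constants that set the strength of a fish group's
#' feeding-predation trade-off along the behavioral gradient `p` (0 =
#' maximal feeding, 1 = maximal risk mitigation).
#'
#' @param f_PM Predation mitigation efficiency in \[0, 1\]: the fraction of
#'   predation mortality removed at full mitigation (`p = 1`).
#' @param f_FC Feeding cost of predation mitigation in \[0, 1\]: the fraction
#'   of feeding activity given up at full mitigation.
#' @param f_RF Extra metabolic cost of active feeding, relative to the basal
#'   metabolic rate (non-negative scalar; feeding at full activity costs
#'   `(1 + f_RF)` times basal metabolism).
#'
#' @return An object of class `"tradeoff_params"`.
#' @examples
#' tradeoff_params(f_PM = 0.9, f_FC = 0.675, f_RF = 0.3)
#' @export
tradeoff_params <- function(f_PM = 1, f_FC = 1, f_RF = 0) {
  out <- list(
    f_PM = .check_scalar(f_PM, "f_PM", 0, 1),
    f_FC = .check_scalar(f_FC, "f_FC", 0, 1),
    f_RF = .check_scalar(f_RF, "f_RF", 0, Inf)
  )
  structure(out, class = "tradeoff_params")
}

#' @export
print.tradeoff_params <- function(x, ...) {
  cat(sprintf("Trade-off parameters: f_PM = %g, f_FC = %g, f_RF = %g\n",
              x$f_PM, x$f_FC, x$f_RF))
  invisible(x)
}

#' Ambient feeding environment of a fish group
#'
#' The state a fish group perceives when choosing its behavior: prey
#' availability, its own (temperature-scaled) rate constants, and the
#' smoothed predation risk. All rates are biomass-specific (d^-1), biomass
#' concentrations in g m^-3, and clearance in m^3 g^-1 d^-1.
#'
#' @param R Prey availability (biomass concentration, g m^-3).
#' @param c Maximum clearance rate toward the prey (m^3 g^-1 d^-1).
#' @param f_gut Gut occupation factor (dimensionless, >= 0); higher for prey
#'   of low digestibility or energy density.
#' @param f_veg Vegetation catchability factor in \[0, 1\] (1 = no refuge
#'   effect; supplied externally, no macrophyte dynamics here).
#' @param I_max Maximum (gut-limited) consumption rate (d^-1), already scaled
#'   to ambient temperature.
#' @param a Assimilation efficiency in \[0, 1\].
#' @param u Basal metabolic rate (d^-1), already scaled to temperature.
#' @param m_nat Background natural mortality (d^-1). Must be strictly
#'   positive for the behavioral optimization (Gilliam ratio denominator).
#' @param m_pred_s Smoothed maximum predation mortality (d^-1), i.e. the
#'   risk experienced at `p = 0`.
#'
#' @return An object of class `"feeding_env"`.
#' @seealso [optimal_behavior()], [smooth_predation()]
#' @examples
#' feeding_env(R = 1, c = 0.5, I_max = 0.04, a = 0.7, u = 0.004,
#'             m_nat = 5e-4, m_pred_s = 0.01)
#' @export
feeding_env <- function(R, c, f_gut = 1, f_veg = 1, I_max, a, u,
                        m_nat, m_pred_s = 0) {
  out <- list(
    R = .check_scalar(R, "R"),
    c = .check_scalar(c, "c"),
    f_gut = .check_scalar(f_gut, "f_gut"),
    f_veg = .check_scalar(f_veg, "f_veg", 0, 1),
    I_max = .check_scalar(I_max, "I_max"),
    a = .check_scalar(a, "a", 0, 1),
    u = .check_scalar(u, "u"),
    m_nat = .check_scalar(m_nat, "m_nat"),
    m_pred_s = .check_scalar(m_pred_s, "m_pred_s")
  )
  structure(out, class = "feeding_env")
}

#' Encountered prey
#'
#' The encounter rate term `R_e = R * c * f_veg` (d^-1 per unit gut factor):
#' prey availability times clearance times catchability.
#'
#' @param env A [feeding_env()].
#' @return Encountered prey (specific rate, d^-1).
#' @export
encountered_prey <- function(env) {
  stopifnot(inherits(env, "feeding_env"))
  env$R * env$c * env$f_veg
}

#' Feeding activity at mitigation level p
#'
#' The fraction of maximal feeding activity retained when a fraction `p` of
#' effort goes to predation mitigation: `f_feed = 1 - p * f_FC`.
#'
#' @param p Mitigation level in \[0, 1\].
#' @param f_FC Feeding cost of mitigation in \[0, 1\].
#' @return Feeding activity in \[1 - f_FC, 1\]. Vectorized over `p`.
#' @export
feeding_activity <- function(p, f_FC) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  f_FC <- .check_scalar(f_FC, "f_FC", 0, 1)
  1 - p * f_FC
}

#' Gut-limited feeding level
#'
#' Satiation of the fish: the fraction of gut capacity occupied,
#' `F = Q / (I_max + Q)` with gut-weighted encounter
#' `Q = f_feed * f_veg * c * f_gut * R`. `F = 0` is an empty gut; `F -> 1`
#' full satiation.
#'
#' @inheritParams encountered_prey
#' @param f_feed Feeding activity in \[0, 1\].
#' @return Feeding level in \[0, 1). Vectorized over `f_feed`.
#' @export
feeding_level <- function(env, f_feed) {
  stopifnot(inherits(env, "feeding_env"))
  if (any(f_feed < 0) || any(f_feed > 1))
    stop("`f_feed` must lie in [0, 1]", call. = FALSE)
  Q <- f_feed * env$f_veg * env$c * env$f_gut * env$R
  if (env$I_max == 0) {
    if (any(Q > 0))
      stop("degenerate environment: I_max = 0 with positive prey encounter",
           call. = FALSE)
    return(rep(0, length(Q)))
  }
  Q / (env$I_max + Q)
}

#' Specific assimilation (ingestion) rate
#'
#' Encountered-and-caught prey times the hunger level `(1 - F)` times the
#' assimilation efficiency:
#' `g = a * f_feed * f_veg * c * R * (1 - F)`. At `f_feed = 1` this is
#' exactly a Holling type II response with handling time `f_gut / I_max`
#' and attack rate `c * f_veg`.
#'
#' @inheritParams feeding_level
#' @return Assimilation rate (d^-1, biomass-specific). Vectorized over
#'   `f_feed`.
#' @export
ingestion <- function(env, f_feed) {
  if (any(f_feed < 0) || any(f_feed > 1))
    stop("`f_feed` must lie in [0, 1]", call. = FALSE)
  Q <- f_feed * env$f_veg * env$c * env$f_gut * env$R
  if (env$I_max == 0) {
    if (any(Q > 0))
      stop("degenerate environment: I_max = 0 with positive prey encounter",
           call. = FALSE)
    return(env$a * f_feed * env$f_veg * env$c * env$R)
  }
  # hunger level 1 - F written as I_max / (I_max + Q) for conditioning
  env$a * f_feed * env$f_veg * env$c * env$R * env$I_max / (env$I_max + Q)
}

#' Total mortality at mitigation level p
#'
#' `m_tot = m_nat + (1 - p * f_PM) * m_pred_s`: mitigation removes up to a
#' fraction `f_PM` of the predation term, never the background mortality.
#'
#' @inheritParams feeding_activity
#' @param f_PM Predation mitigation efficiency in \[0, 1\].
#' @param m_nat Background natural mortality (d^-1).
#' @param m_pred_s Smoothed maximum predation mortality (d^-1).
#' @return Total mortality (d^-1). Vectorized over `p`.
#' @export
total_mortality <- function(p, f_PM, m_nat, m_pred_s) {
  if (any(p < 0) || any(p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  f_PM <- .check_scalar(f_PM, "f_PM", 0, 1)
  m_nat <- .check_scalar(m_nat, "m_nat")
  m_pred_s <- .check_scalar(m_pred_s, "m_pred_s")
  m_nat + (1 - p * f_PM) * m_pred_s
}

#' Predation-risk smoothing filter
#'
#' First-order recursive smoother applied to instantaneous predation
#' mortality to prevent erratic step-to-step switching of predator and prey
#' feeding efforts: `m_pred_s = (m_pred_s_prev + 0.25 * m_pred) / 1.25`.
#' The filter has its fixed point at the input value and relaxes toward a
#' constant input geometrically with per-step factor 0.8.
#'
#' @param m_pred_s_prev Smoothed predation mortality of the previous step
#'   (d^-1).
#' @param m_pred Current instantaneous predation mortality (d^-1).
#' @return Updated smoothed predation mortality (d^-1). Vectorized.
#' @export
smooth_predation <- function(m_pred_s_prev, m_pred) {
  if (any(m_pred_s_prev < 0) || any(m_pred < 0))
    stop("predation rates must be non-negative", call. = FALSE)
  (m_pred_s_prev + 0.25 * m_pred) / 1.25
}

#' Total metabolic rate at a feeding activity
#'
#' Basal metabolism plus the extra cost of the feeding process:
#' `u_tot = (1 + f_RF * f_feed) * u`.
#'
#' @param u Basal metabolic rate (d^-1).
#' @param f_RF Extra metabolic cost of feeding (non-negative scalar).
#' @param f_feed Feeding activity in \[0, 1\].
#' @return Total metabolic rate (d^-1). Vectorized over `f_feed`.
#' @export
total_metabolism <- function(u, f_RF, f_feed) {
  u <- .check_scalar(u, "u")
  f_RF <- .check_scalar(f_RF, "f_RF")
  (1 + f_RF * f_feed) * u
}

#' Fitness along the behavioral gradient
#'
#' Gilliam's-rule fitness of mitigation level `p`. When the potential net
#' energy gain at maximal feeding is non-negative
#' (`g_pot - u_pot >= 0`, both evaluated at `p = 0`), fitness is net energy
#' gain over mortality, `W = (g - u_tot) / m_tot` (dimensionless; equal to
#' lifetime reproductive output in a stable environment). When the potential
#' net gain is negative, starvation dominates and fitness is the net gain
#' itself, `W = g - u_tot` (d^-1), predation being disregarded.
#'
#' @inheritParams feeding_level
#' @param p Mitigation level(s) in \[0, 1\]; vectorized.
#' @param tp A [tradeoff_params()].
#' @return Numeric vector of fitness values with attribute `"regime"`, one
#'   of `"normal"` (ratio branch) or `"starvation"` (net-gain branch).
#' @export
fitness <- function(p, env, tp) {
  stopifnot(inherits(env, "feeding_env"), inherits(tp, "tradeoff_params"))
  if (any(p < 0) || any(p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  f_feed <- 1 - p * tp$f_FC
  g <- ingestion(env, f_feed)
  u_tot <- (1 + tp$f_RF * f_feed) * env$u
  g_pot <- ingestion(env, 1)
  u_pot <- (1 + tp$f_RF) * env$u
  if (g_pot - u_pot >= 0) {
    m_tot <- env$m_nat + (1 - p * tp$f_PM) * env$m_pred_s
    if (any(m_tot <= 0))
      stop("total mortality is zero in the Gilliam ratio; `m_nat` must be > 0",
           call. = FALSE)
    W <- (g - u_tot) / m_tot
    regime <- "normal"
  } else {
    W <- g - u_tot
    regime <- "starvation"
  }
  attr(W, "regime") <- regime
  W
}

# ---------------------------------------------------------------------------
# Internal scalar solver.
#
# Works on aggregate encounter terms so the multi-prey module can reuse it:
#   Re = f_veg * sum(c_i R_i)        (encountered prey)
#   G  = f_veg * sum(c_i f_gut_i R_i) (gut-weighted encounter)
#   a  = encounter-weighted mean assimilation efficiency
#
# In the normal regime, dW/dp = 0 is a quadratic A2 p^2 + A1 p + A0 = 0
# (derived symbolically from the Gilliam ratio with the linear trade-off
# substituted); the optimum is the best of the real roots in (0, 1) and the
# endpoints. Ties flat to within ~1e-12 resolve to the largest p (mortality
# weakly decreases in p).
.obm_solve <- function(Re, G, I_max, a, u, m_nat, m_pred_s,
                       f_PM, f_FC, f_RF) {
  g_pot <- if (I_max + G > 0) a * Re * I_max / (I_max + G) else 0
  u_pot <- (1 + f_RF) * u
  net <- g_pot - u_pot

  if (net <= -u + .RATE_TOL) {
    # feeding cannot pay its own marginal cost: stop feeding, mitigate fully
    return(list(p_star = 1, f_feed = 0, F = 0, g = 0, u_tot = u,
                m_tot = m_nat + (1 - f_PM) * m_pred_s,
                W = -u, regime = 3L, g_pot = g_pot, u_pot = u_pot))
  }
  if (net < 0) {
    # negative net gain but feeding beats not feeding: maximize time to
    # starvation by feeding maximally
    return(list(p_star = 0, f_feed = 1, F = G / (I_max + G), g = g_pot,
                u_tot = u_pot, m_tot = m_nat + m_pred_s,
                W = net, regime = 2L, g_pot = g_pot, u_pot = u_pot))
  }

  # normal regime: Gilliam ratio, closed-form stationary points
  mm <- m_nat + m_pred_s
  K <- f_FC * f_RF * u * mm - f_PM * u * m_pred_s * (1 + f_RF)
  M <- I_max * Re * a * f_PM * m_pred_s
  A2 <- G * f_FC^2 * (G * K + M)
  A1 <- -2 * G * f_FC * (G * K + M + I_max * K)
  A0 <- (G + I_max)^2 * K + (G + I_max) * M - I_max^2 * Re * a * f_FC * mm

  cand <- c(0, 1)
  if (is.finite(A2) && is.finite(A1) && is.finite(A0)) {
    if (A2 != 0) {
      disc <- A1^2 - 4 * A2 * A0
      if (disc >= 0) {
        # numerically stable quadratic roots
        q <- -(A1 + sign(A1 + (A1 == 0)) * sqrt(disc)) / 2
        r <- c(q / A2, if (q != 0) A0 / q else -A1 / A2)
        cand <- c(cand, r[is.finite(r) & r > 0 & r < 1])
      }
    } else if (A1 != 0) {
      r <- -A0 / A1
      if (is.finite(r) && r > 0 && r < 1) cand <- c(cand, r)
    }
  } else {
    # degenerate coefficients: numerical fallback on the fitness curve
    warning(warningCondition(
      "non-finite stationary-point coefficients; falling back to numerical maximization",
      class = "lakeOBM_numeric_fallback"))
    opt <- stats::optimize(function(p) {
      ff <- 1 - p * f_FC
      g <- a * ff * Re * I_max / (I_max + ff * G)
      (g - (1 + f_RF * ff) * u) / (m_nat + (1 - p * f_PM) * m_pred_s)
    }, c(0, 1), maximum = TRUE, tol = 1e-12)
    cand <- c(cand, opt$maximum)
  }

  ff <- 1 - cand * f_FC
  g <- a * ff * Re * I_max / (I_max + ff * G)
  ut <- (1 + f_RF * ff) * u
  mt <- m_nat + (1 - cand * f_PM) * m_pred_s
  W <- (g - ut) / mt
  w_max <- max(W)
  flat <- W >= w_max - 1e-12 * max(1, abs(w_max))
  p_star <- max(cand[flat])
  i <- which(cand == p_star)[1]

  list(p_star = p_star, f_feed = ff[i],
       F = if (I_max + ff[i] * G > 0) ff[i] * G / (I_max + ff[i] * G) else 0,
       g = g[i], u_tot = ut[i], m_tot = mt[i], W = W[i],
       regime = 1L, g_pot = g_pot, u_pot = u_pot)
}

.as_behavior_solution <- function(sol) {
  sol$regime <- .REGIMES[sol$regime]
  structure(sol, class = "behavior_solution")
}

#' Optimal behavior of a fish group
#'
#' Solves for the fitness-maximizing mitigation level `p*` given the ambient
#' environment and the trade-off parameters. Three regimes are
#' distinguished:
#' \describe{
#'   \item{`normal`}{Potential net energy gain at maximal feeding is
#'     non-negative; `p*` maximizes the Gilliam ratio
#'     `(g - u_tot) / m_tot`. The stationary condition is solved in closed
#'     form (quadratic in `p`), clamped to \[0, 1\] by endpoint comparison.}
#'   \item{`starvation_feed`}{Net gain is negative but feeding still beats
#'     fasting (`g_pot - u_pot > -u`): the fish feeds maximally, `p* = 0`.}
#'   \item{`starvation_stop`}{Feeding cannot pay its own metabolic cost
#'     (`g_pot - u_pot <= -u`, i.e. `g_pot <= f_RF * u`): the fish stops
#'     feeding (`f_feed = 0`) and is free to mitigate fully, `p* = 1`.}
#' }
#'
#' @inheritParams fitness
#' @return A `"behavior_solution"`: list with elements `p_star`, `f_feed`,
#'   `F` (feeding level), `g` (assimilation, d^-1), `u_tot` (d^-1), `m_tot`
#'   (d^-1), `W` (fitness), `regime`, `g_pot`, `u_pot` (potential rates at
#'   `p = 0`).
#' @examples
#' env <- feeding_env(R = 2, c = 0.5, I_max = 0.04, a = 0.7, u = 0.004,
#'                    m_nat = 5e-4, m_pred_s = 0.01)
#' optimal_behavior(env, tradeoff_params(1, 1, 0.3))
#' @export
optimal_behavior <- function(env, tp) {
  stopifnot(inherits(env, "feeding_env"), inherits(tp, "tradeoff_params"))
  if (env$m_nat <= 0)
    stop("`m_nat` must be > 0 for the behavioral optimization", call. = FALSE)
  sol <- .obm_solve(Re = encountered_prey(env), G = encountered_prey(env) * env$f_gut,
                    I_max = env$I_max, a = env$a, u = env$u,
                    m_nat = env$m_nat, m_pred_s = env$m_pred_s,
                    f_PM = tp$f_PM, f_FC = tp$f_FC, f_RF = tp$f_RF)
  .as_behavior_solution(sol)
}

#' @export
print.behavior_solution <- function(x, ...) {
  cat(sprintf("Optimal behavior [%s]\n", x$regime))
  cat(sprintf("  p* = %.6g, f_feed = %.6g, feeding level F = %.6g\n",
              x$p_star, x$f_feed, x$F))
  cat(sprintf("  g = %.6g d^-1, u_tot = %.6g d^-1, m_tot = %.6g d^-1, W = %.6g\n",
              x$g, x$u_tot, x$m_tot, x$W))
  invisible(x)
}

#' Emergent functional response
#'
#' Sweeps prey availability and solves the optimal behavior at each level,
#' returning the consumption that emerges after optimization. With a costly
#' trade-off (`f_FC = 1`) the curve resembles a Holling type III response;
#' at submaximal cost (`f_FC < 1`) and high predation it can decrease over
#' an intermediate range of availability. Consumption is zero below the
#' resource threshold at which feeding metabolism exceeds the energy gained
#' from feeding.
#'
#' @param env A [feeding_env()] used as template; its `R` is replaced by
#'   each value of `R_grid`.
#' @param tp A [tradeoff_params()].
#' @param R_grid Increasing vector of prey availabilities (g m^-3).
#' @return A data frame with one row per availability: `R`,
#'   `scaled_availability` (gut-weighted encounter over `I_max`), `p_star`,
#'   `f_feed`, `regime`, `consumption` (biomass intake, d^-1) and
#'   `scaled_consumption` (intake over the maximum possible intake
#'   `I_max / f_gut`).
#' @export
functional_response <- function(env, tp, R_grid) {
  stopifnot(inherits(env, "feeding_env"), inherits(tp, "tradeoff_params"))
  if (is.unsorted(R_grid)) stop("`R_grid` must be sorted ascending", call. = FALSE)
  n <- length(R_grid)
  p_star <- f_feed <- cons <- numeric(n)
  regime <- character(n)
  for (i in seq_len(n)) {
    e <- env
    e$R <- R_grid[i]
    sol <- optimal_behavior(e, tp)
    p_star[i] <- sol$p_star
    f_feed[i] <- sol$f_feed
    regime[i] <- sol$regime
    # biomass intake before assimilation
    cons[i] <- sol$f_feed * e$f_veg * e$c * e$R * (1 - sol$F)
  }
  data.frame(
    R = R_grid,
    scaled_availability = R_grid * env$c * env$f_veg * env$f_gut / env$I_max,
    p_star = p_star, f_feed = f_feed, regime = regime,
    consumption = cons,
    scaled_consumption = cons * env$f_gut / env$I_max
  )
}
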