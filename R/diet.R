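#' One prey type on a fish menu
#'
#' @param id Character label.
#' @param R Availability (biomass concentration, g m^-3).
#' @param c Clearance rate toward this prey (m^3 g^-1 d^-1).
#' @param f_gut Gut occupation factor (>= 0); higher for prey of low
#'   digestibility or energy density.
#' @param a Assimilation efficiency in \[0, 1\].
#' @param mode Feeding mode, one of `"pelagic"`, `"benthic"`,
#'   `"piscivorous"`. Modes are mutually exclusive in space/time; effort is
#'   allocated among them by [allocate_modes()].
#' @return An object of class `"prey_item"`.
#' @export
prey_item <- function(id, R, c, f_gut = 1, a = 1,
                      mode = c("pelagic", "benthic", "piscivorous")) {
  mode <- match.arg(mode)
  structure(list(
    id = as.character(id),
    R = .check_scalar(R, "R"),
    c = .check_scalar(c, "c"),
    f_gut = .check_scalar(f_gut, "f_gut"),
    a = .check_scalar(a, "a", 0, 1),
    mode = mode
  ), class = "prey_item")
}

.prey_fields <- function(prey) {
  stopifnot(all(vapply(prey, inherits, logical(1), "prey_item")))
  list(
    id = vapply(prey, `[[`, character(1), "id"),
    R = vapply(prey, `[[`, numeric(1), "R"),
    c = vapply(prey, `[[`, numeric(1), "c"),
    f_gut = vapply(prey, `[[`, numeric(1), "f_gut"),
    a = vapply(prey, `[[`, numeric(1), "a"),
    mode = vapply(prey, `[[`, character(1), "mode")
  )
}

#' Aggregate feeding level over a multi-prey menu
#'
#' Shared gut saturation over all prey in the diet:
#' `F = Q / (I_max + Q)` with
#' `Q = sum_i f_feed * f_veg * c_i * f_gut_i * R_i`. Reduces to the
#' single-prey [feeding_level()] for one prey item.
#'
#' @param prey List of [prey_item()]s (possibly empty).
#' @param I_max Maximum gut-limited consumption (d^-1).
#' @param f_feed Feeding activity in \[0, 1\].
#' @param f_veg Vegetation catchability factor in \[0, 1\].
#' @return Aggregate feeding level in \[0, 1); 0 for an empty menu.
#' @export
aggregate_feeding_level <- function(prey, I_max, f_feed = 1, f_veg = 1) {
  if (length(prey) == 0) return(0)
  pf <- .prey_fields(prey)
  Q <- sum(f_feed * f_veg * pf$c * pf$f_gut * pf$R)
  if (I_max == 0) {
    if (Q > 0) stop("I_max = 0 with positive prey encounter", call. = FALSE)
    return(0)
  }
  Q / (I_max + Q)
}

# Greedy diet-breadth on plain vectors. Rank prey by profitability
# a_i / f_gut_i (assimilated energy per unit of gut capacity, the binding
# constraint in a gut-limited model; f_gut = 0 ranks first), ties broken by
# larger encounter c_i * R_i; include the prefix that maximizes total
# assimilation. Because a prey raises total assimilation iff its
# profitability exceeds the current scaled intake g(S)/I_max, the greedy
# prefix is the exact subset optimum.
.optimal_diet_idx <- function(R, cc, f_gut, a, I_max, f_veg) {
  enc <- cc * R
  active <- which(enc > 0)
  if (length(active) == 0) return(integer(0))
  prof <- ifelse(f_gut[active] > 0, a[active] / f_gut[active], Inf)
  ord <- active[order(-prof, -enc[active])]
  A_cum <- cumsum(f_veg * a[ord] * enc[ord])
  Q_cum <- cumsum(f_veg * f_gut[ord] * enc[ord])
  g_cum <- if (I_max > 0) A_cum * I_max / (I_max + Q_cum) else
    ifelse(Q_cum > 0, NA_real_, A_cum)
  if (anyNA(g_cum)) stop("I_max = 0 with positive prey encounter", call. = FALSE)
  k <- which.max(g_cum)
  ord[seq_len(k)]
}

#' Optimal diet breadth within a feeding mode
#'
#' Selects the subset of prey that maximizes total assimilated energy at
#' maximal feeding (`f_feed = 1`), per the two-step decision order in which
#' diet is chosen before the behavioral optimization. Abundant prey of low
#' quality (high `f_gut`) may be excluded because they occupy gut capacity
#' that more profitable prey could use.
#'
#' @inheritParams aggregate_feeding_level
#' @return The selected sublist of `prey`, with attribute `"assimilation"`
#'   (total assimilation rate of the selected diet at `f_feed = 1`, d^-1).
#' @export
optimal_diet <- function(prey, I_max, f_veg = 1) {
  if (length(prey) == 0) {
    return(structure(list(), assimilation = 0))
  }
  pf <- .prey_fields(prey)
  idx <- .optimal_diet_idx(pf$R, pf$c, pf$f_gut, pf$a, I_max, f_veg)
  sel <- prey[idx]
  A <- sum(f_veg * pf$a[idx] * pf$c[idx] * pf$R[idx])
  Q <- sum(f_veg * pf$f_gut[idx] * pf$c[idx] * pf$R[idx])
  g <- if (length(idx) == 0) 0 else if (I_max > 0) A * I_max / (I_max + Q) else A
  structure(sel, assimilation = g)
}

#' Allocate feeding effort among feeding modes
#'
#' Feeding time is split among available modes as a weighted average of the
#' relative current ingestion rates achievable in each mode; if no mode
#' yields any ingestion, effort is spread uniformly.
#'
#' @param mode_ingestion Named numeric vector of per-mode ingestion rates
#'   (d^-1), all non-negative.
#' @return Named weights, non-negative and summing to 1.
#' @export
allocate_modes <- function(mode_ingestion) {
  if (length(mode_ingestion) == 0) stop("no feeding modes given", call. = FALSE)
  if (any(mode_ingestion < 0)) stop("ingestion rates must be >= 0", call. = FALSE)
  tot <- sum(mode_ingestion)
  if (tot > 0) mode_ingestion / tot
  else stats::setNames(rep(1 / length(mode_ingestion), length(mode_ingestion)),
                       names(mode_ingestion))
}

#' Base environment for the multi-prey behavioral decision
#'
#' The prey-independent part of a [feeding_env()]: the fish's own
#' temperature-scaled rates, mortality terms and catchability.
#'
#' @inheritParams feeding_env
#' @return An object of class `"base_env"`.
#' @export
base_env <- function(I_max, u, m_nat, m_pred_s = 0, f_veg = 1) {
  structure(list(
    I_max = .check_scalar(I_max, "I_max"),
    u = .check_scalar(u, "u"),
    m_nat = .check_scalar(m_nat, "m_nat"),
    m_pred_s = .check_scalar(m_pred_s, "m_pred_s"),
    f_veg = .check_scalar(f_veg, "f_veg", 0, 1)
  ), class = "base_env")
}

# fast kernel used by the food-web step: vectors in, plain list out
.diet_then_behavior <- function(R, cc, f_gut, a, mode,
                                I_max, u, m_nat, m_pred_s, f_veg,
                                f_PM, f_FC, f_RF) {
  modes <- unique(mode)
  n <- length(R)
  sel <- logical(n)
  g_mode <- numeric(length(modes))
  names(g_mode) <- modes
  for (j in seq_along(modes)) {
    in_m <- which(mode == modes[j])
    idx <- .optimal_diet_idx(R[in_m], cc[in_m], f_gut[in_m], a[in_m],
                             I_max, f_veg)
    idx <- in_m[idx]
    sel[idx] <- TRUE
    A <- sum(f_veg * a[idx] * cc[idx] * R[idx])
    Q <- sum(f_veg * f_gut[idx] * cc[idx] * R[idx])
    g_mode[j] <- if (length(idx) == 0) 0 else A * I_max / (I_max + Q)
  }
  w <- if (sum(g_mode) > 0) g_mode / sum(g_mode) else
    rep(1 / length(modes), length(modes))
  names(w) <- modes

  # effective (time-weighted) encounter of each selected prey
  e <- numeric(n)
  e[sel] <- w[mode[sel]] * cc[sel] * R[sel]
  CR <- sum(e)
  if (CR > 0) {
    Qg <- sum(e * f_gut)        # gut-weighted
    A <- sum(e * a)             # assimilation-weighted
    sol <- .obm_solve(Re = f_veg * CR, G = f_veg * Qg, I_max = I_max,
                      a = A / CR, u = u, m_nat = m_nat, m_pred_s = m_pred_s,
                      f_PM = f_PM, f_FC = f_FC, f_RF = f_RF)
  } else {
    sol <- .obm_solve(Re = 0, G = 0, I_max = I_max, a = 0, u = u,
                      m_nat = m_nat, m_pred_s = m_pred_s,
                      f_PM = f_PM, f_FC = f_FC, f_RF = f_RF)
  }
  capture <- sol$f_feed * f_veg * e * (1 - sol$F)  # biomass removed per prey
  list(sel = sel, mode_weights = w, capture = capture,
       ingestion = a * capture, sol = sol)
}

#' Two-step diet and behavior decision
#'
#' Implements the decision order of the feeding algorithm: first the diet
#' composition ([optimal_diet()]) and feeding-mode allocation
#' ([allocate_modes()]) are computed for all modes assuming maximized
#' feeding (no predation mitigation); then the selected multi-prey menu is
#' collapsed into aggregate encounter and quality terms (time-weighted
#' encounter `sum w_m c_i R_i`, encounter-weighted mean `f_gut` and `a`) and
#' the single-prey behavioral optimization is solved on the aggregates.
#' Realized ingestion is distributed over prey in proportion to their
#' contribution to encounter.
#'
#' @param prey List of [prey_item()]s over all modes.
#' @param env_base A [base_env()].
#' @param tp A [tradeoff_params()].
#' @return A list with components `diet` (class `"diet_solution"`: selected
#'   ids per mode, `mode_weights`, `F_agg`, `g_pot_agg`,
#'   `per_prey_ingestion`, `per_prey_capture`) and `behavior` (a
#'   `"behavior_solution"`, see [optimal_behavior()]).
#' @export
diet_then_behavior <- function(prey, env_base, tp) {
  stopifnot(inherits(env_base, "base_env"), inherits(tp, "tradeoff_params"))
  if (env_base$m_nat <= 0)
    stop("`m_nat` must be > 0 for the behavioral optimization", call. = FALSE)
  pf <- .prey_fields(prey)
  res <- .diet_then_behavior(pf$R, pf$c, pf$f_gut, pf$a, pf$mode,
                             env_base$I_max, env_base$u, env_base$m_nat,
                             env_base$m_pred_s, env_base$f_veg,
                             tp$f_PM, tp$f_FC, tp$f_RF)
  included <- split(pf$id[res$sel], pf$mode[res$sel])
  diet <- structure(list(
    included = included,
    mode_weights = res$mode_weights,
    F_agg = res$sol$F,
    g_pot_agg = res$sol$g_pot,
    per_prey_ingestion = stats::setNames(res$ingestion, pf$id),
    per_prey_capture = stats::setNames(res$capture, pf$id)
  ), class = "diet_solution")
  list(diet = diet, behavior = .as_behavior_solution(res$sol))
}

#' @export
print.diet_solution <- function(x, ...) {
  cat("Diet solution\n")
  for (m in names(x$included))
    cat(sprintf("  %s (w = %.3f): %s\n", m, x$mode_weights[[m]],
                paste(x$included[[m]], collapse = ", ")))
  cat(sprintf("  aggregate feeding level = %.4f, potential assimilation = %.6g d^-1\n",
              x$F_agg, x$g_pot_agg))
  invisible(x)
}
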