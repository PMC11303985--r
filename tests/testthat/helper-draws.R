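# random draws of environments and trade-off parameters over plausible
# ranges (rates log-uniform), used by the property-style tests

draw_env <- function(m_pred_s = 10^runif(1, -5, -1)) {
  feeding_env(
    R = 10^runif(1, -3, 2),
    c = 10^runif(1, -3, 1),
    f_gut = 10^runif(1, -1, 1),
    f_veg = runif(1, 0.2, 1),
    I_max = 10^runif(1, -3, 0),
    a = runif(1, 0.1, 1),
    u = 10^runif(1, -4, -1),
    m_nat = 10^runif(1, -5, -2),
    m_pred_s = m_pred_s
  )
}

draw_tp <- function() {
  tradeoff_params(f_PM = runif(1, 0.01, 1), f_FC = runif(1, 0.01, 1),
                  f_RF = runif(1, 0, 1))
}

draw_prey <- function(n, modes = "pelagic") {
  lapply(seq_len(n), function(i) {
    prey_item(paste0("prey", i),
              R = 10^runif(1, -2, 1.5),
              c = 10^runif(1, -2, 0.5),
              f_gut = 10^runif(1, -1, 1),
              a = runif(1, 0.05, 1),
              mode = sample(modes, 1))
  })
}

# dense-grid + local-refinement maximizer of the fitness curve, independent
# of the closed-form path
grid_oracle_W <- function(env, tp, n = 10001) {
  p <- seq(0, 1, length.out = n)
  W <- fitness(p, env, tp)
  i <- which.max(W)
  lo <- p[max(1, i - 1)]
  hi <- p[min(n, i + 1)]
  opt <- stats::optimize(function(q) fitness(q, env, tp), c(lo, hi),
                         maximum = TRUE, tol = 1e-14)
  max(opt$objective, W[i])
}

# exhaustive best-subset assimilation for small menus
exhaustive_diet_g <- function(prey, I_max, f_veg = 1) {
  n <- length(prey)
  best <- 0
  for (m in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    A <- sum(vapply(prey[idx], function(p) p$a * p$c * p$R, numeric(1)))
    Q <- sum(vapply(prey[idx], function(p) p$f_gut * p$c * p$R, numeric(1)))
    g <- f_veg * A * I_max / (I_max + f_veg * Q)
    if (g > best) best <- g
  }
  best
}

# a small fast closed configuration for conservation-style tests
closed_config <- function() {
  cfg <- default_config()
  cfg$physics$flushing <- 0
  cfg$physics$burial <- 0
  cfg$forcing$load$base <- 0
  cfg$forcing$load$amplitude <- 0
  cfg
}
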