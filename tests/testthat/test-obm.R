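test_that("feeding activity is the linear trade-off and rejects bad input", {
  expect_equal(feeding_activity(0, 1), 1)
  expect_equal(feeding_activity(1, 1), 0)
  expect_equal(feeding_activity(0.5, 0.675), 0.6625)
  expect_equal(feeding_activity(c(0, 0.25, 1), 0.4), c(1, 0.9, 0.6))
  expect_error(feeding_activity(1.2, 0.5), "0, 1")
  expect_error(feeding_activity(0.5, -0.1))
})

test_that("feeding level saturates the gut and handles degenerate I_max", {
  env <- feeding_env(R = 0, c = 1, I_max = 1, a = 1, u = 0, m_nat = 1e-3)
  expect_equal(feeding_level(env, 1), 0)
  env <- feeding_env(R = 1, c = 1, f_gut = 1, I_max = 1, a = 1, u = 0,
                     m_nat = 1e-3)
  expect_equal(feeding_level(env, 1), 0.5)       # half-saturation
  env$R <- 9
  expect_equal(feeding_level(env, 1), 0.9)
  env$I_max <- 0
  expect_error(feeding_level(env, 1), "degenerate")
})

test_that("ingestion reduces to the Holling type II form at full feeding", {
  env <- feeding_env(R = 1, c = 1, f_gut = 1, I_max = 1, a = 1, u = 0,
                     m_nat = 1e-3)
  expect_equal(ingestion(env, 1), 0.5)
  env$R <- 0
  expect_equal(ingestion(env, 1), 0)
  set.seed(11)
  for (k in 1:200) {
    e <- draw_env()
    holling2 <- e$a * e$c * e$f_veg * e$R * e$I_max /
      (e$I_max + e$c * e$f_veg * e$f_gut * e$R)
    expect_equal(ingestion(e, 1), holling2, tolerance = 1e-12)
  }
})

test_that("total mortality interpolates between full and mitigated risk", {
  expect_equal(total_mortality(1, 1, 0.001, 0.5), 0.001)
  expect_equal(total_mortality(0, 1, 0.001, 0.5), 0.501)
  expect_equal(total_mortality(0.5, 0.9, 0, 1), 0.55)
  p <- seq(0, 1, by = 0.1)
  m <- total_mortality(p, 0.8, 0.01, 0.2)
  expect_true(all(diff(m) < 0))
  expect_true(all(m >= 0.01 & m <= 0.21 + 1e-12))
})

test_that("predation smoothing has the exact fixed point and 0.8 geometric decay", {
  expect_equal(smooth_predation(0.37, 0.37), 0.37)
  expect_equal(smooth_predation(0, 1.25), 0.25)
  x <- 0
  for (n in 1:40) {
    x <- smooth_predation(x, 1)
    expect_equal(x, 1 - 0.8^n, tolerance = 1e-15)
  }
})

test_that("total metabolism adds the feeding surcharge linearly", {
  expect_equal(total_metabolism(0.02, 0.5, 0), 0.02)
  expect_equal(total_metabolism(0.02, 0, 1), 0.02)
  expect_equal(total_metabolism(0.01, 0.5, 1), 0.015)
})

test_that("fitness uses the Gilliam ratio when potential net gain is non-negative", {
  env <- feeding_env(R = 10, c = 1, I_max = 1, a = 1, u = 0.4, m_nat = 1e-3,
                     m_pred_s = 0)
  tp <- tradeoff_params(1, 1, 0)
  # g_pot = 10/11, u = 0.4 -> W(0) = (10/11 - 0.4)/1e-3
  expect_equal(as.numeric(fitness(0, env, tp)), (10 / 11 - 0.4) / 1e-3)
  expect_identical(attr(fitness(0, env, tp), "regime"), "normal")
  # scarce food: net-gain branch, W = -u at full mitigation (no feeding)
  env2 <- feeding_env(R = 1e-6, c = 1e-3, I_max = 1, a = 0.5, u = 0.01,
                      m_nat = 1e-3, m_pred_s = 0.1)
  W <- fitness(c(0, 1), env2, tp)
  expect_identical(attr(W, "regime"), "starvation")
  expect_equal(as.numeric(W[2]), -0.01, tolerance = 1e-6)
  # zero m_nat makes the ratio branch ill-posed
  env3 <- feeding_env(R = 10, c = 1, I_max = 1, a = 1, u = 0, m_nat = 0,
                      m_pred_s = 0)
  expect_error(fitness(0.5, env3, tp), "m_nat")
})

test_that("closed-form optimum matches the dense-grid oracle across random draws", {
  set.seed(101)
  n_draws <- 400
  checked <- 0
  for (k in seq_len(n_draws)) {
    env <- draw_env()
    tp <- draw_tp()
    sol <- optimal_behavior(env, tp)
    if (sol$regime != "normal") next
    checked <- checked + 1
    W_oracle <- grid_oracle_W(env, tp)
    expect_lte(abs(sol$W - W_oracle) / max(abs(W_oracle), 1e-300), 1e-6)
  }
  expect_gte(checked, 50)
})

test_that("starvation regimes assign branches and never lose fitness", {
  tp <- tradeoff_params(1, 1, 0.5)
  # far below the stop threshold
  env <- feeding_env(R = 1e-8, c = 1e-3, I_max = 0.1, a = 0.5, u = 0.01,
                     m_nat = 1e-3, m_pred_s = 0.05)
  sol <- optimal_behavior(env, tp)
  expect_identical(sol$regime, "starvation_stop")
  expect_equal(sol$f_feed, 0)
  expect_equal(sol$p_star, 1)
  expect_equal(sol$m_tot, env$m_nat + (1 - tp$f_PM) * env$m_pred_s)
  expect_equal(sol$W, -env$u)
  # straddle the threshold g_pot = f_RF * u: scale R around the crossing
  set.seed(202)
  for (k in 1:200) {
    env <- draw_env()
    tp <- draw_tp()
    # find R where g_pot = f_RF * u, then test both sides
    g1 <- ingestion(env, 1) / env$R   # g_pot is linear in R only at low R
    if (!is.finite(g1) || g1 <= 0) next
    target <- tp$f_RF * env$u
    if (target <= 0) next
    # solve a*c*fveg*R*Imax/(Imax+c*fveg*fgut*R) = target for R
    k1 <- env$a * env$c * env$f_veg * env$I_max
    k2 <- env$c * env$f_veg * env$f_gut
    denom <- k1 - target * k2
    if (denom <= 0) next                 # threshold unreachable
    R_star <- target * env$I_max / denom
    for (fac in c(0.95, 1.05)) {
      e <- env
      e$R <- R_star * fac
      sol <- optimal_behavior(e, tp)
      W_feed <- ingestion(e, 1) - (1 + tp$f_RF) * e$u    # feed maximally
      W_stop <- -e$u                                     # fast fully
      if (sol$regime == "starvation_stop") {
        expect_gte(W_stop, W_feed - 1e-12)
        expect_equal(sol$f_feed, 0)
        expect_equal(sol$p_star, 1)
      } else if (sol$regime == "starvation_feed") {
        expect_gte(W_feed, W_stop - 1e-12)
        expect_equal(sol$p_star, 0)
      }
    }
  }
})

test_that("p* is trivial when mitigation has no benefit and no cost saving", {
  env <- feeding_env(R = 5, c = 0.5, I_max = 0.5, a = 0.8, u = 0.01,
                     m_nat = 1e-3, m_pred_s = 0)
  sol <- optimal_behavior(env, tradeoff_params(f_PM = 1, f_FC = 0.7, f_RF = 0))
  expect_identical(sol$regime, "normal")
  expect_equal(sol$p_star, 0)
})

test_that("p* increases with predation risk and solution stays in bounds", {
  tp <- tradeoff_params(1, 1, 0.3)
  env <- feeding_env(R = 2, c = 0.5, I_max = 0.08, a = 0.7, u = 0.005,
                     m_nat = 5e-4, m_pred_s = 0)
  risks <- c(0, 1e-4, 1e-3, 5e-3, 0.02, 0.1)
  p_prev <- -1
  for (m in risks) {
    env$m_pred_s <- m
    sol <- optimal_behavior(env, tp)
    expect_gte(sol$p_star, p_prev - 1e-9)
    expect_true(sol$p_star >= 0 && sol$p_star <= 1)
    expect_true(sol$f_feed >= 0 && sol$f_feed <= 1)
    expect_true(all(c(sol$g, sol$u_tot, sol$m_tot) >= 0))
    p_prev <- sol$p_star
  }
})

test_that("random draws keep p* in bounds with non-negative rates", {
  set.seed(303)
  for (k in 1:300) {
    tp <- draw_tp()
    sol <- optimal_behavior(draw_env(), tp)
    expect_true(sol$p_star >= 0 && sol$p_star <= 1)
    expect_true(sol$f_feed >= 0 && sol$f_feed <= 1)
    expect_true(all(c(sol$g, sol$u_tot, sol$m_tot) >= 0))
    if (sol$regime == "starvation_stop") {
      expect_equal(sol$f_feed, 0)
      expect_equal(sol$p_star, 1)
    } else {
      if (sol$regime == "starvation_feed") expect_equal(sol$p_star, 0)
      expect_equal(sol$f_feed, 1 - sol$p_star * tp$f_FC)
    }
  }
})
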