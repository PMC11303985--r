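test_that("aggregate feeding level reduces to the single-prey form and is linear in encounter", {
  p1 <- prey_item("z", R = 3, c = 0.4, f_gut = 1.2, a = 0.7)
  env <- feeding_env(R = 3, c = 0.4, f_gut = 1.2, I_max = 0.05, a = 0.7,
                     u = 0.005, m_nat = 1e-3)
  expect_equal(aggregate_feeding_level(list(p1), I_max = 0.05),
               feeding_level(env, 1))
  # two identical prey at R/2 equal one prey at R
  halves <- list(prey_item("a", R = 1.5, c = 0.4, f_gut = 1.2, a = 0.7),
                 prey_item("b", R = 1.5, c = 0.4, f_gut = 1.2, a = 0.7))
  expect_equal(aggregate_feeding_level(halves, I_max = 0.05),
               aggregate_feeding_level(list(p1), I_max = 0.05))
  expect_equal(aggregate_feeding_level(list(), I_max = 0.05), 0)
  expect_error(aggregate_feeding_level(list(p1), I_max = 0), "I_max")
})

test_that("optimal diet equals the exhaustive subset optimum on random menus", {
  set.seed(404)
  for (k in 1:500) {
    n <- sample(1:5, 1)
    prey <- draw_prey(n)
    I_max <- 10^runif(1, -2, 0)
    sel <- optimal_diet(prey, I_max)
    expect_equal(attr(sel, "assimilation"), exhaustive_diet_g(prey, I_max),
                 tolerance = 1e-12)
  }
})

test_that("diet selection excludes abundant low-quality prey and keeps free prey", {
  good <- prey_item("good", R = 5, c = 0.5, f_gut = 1, a = 0.9)
  ballast <- prey_item("ballast", R = 50, c = 0.5, f_gut = 500, a = 0.1)
  sel <- optimal_diet(list(good, ballast), I_max = 0.1)
  expect_identical(vapply(sel, `[[`, character(1), "id"), "good")
  # f_gut = 0 prey cost nothing and are always included
  free <- prey_item("free", R = 0.01, c = 0.01, f_gut = 0, a = 0.2)
  sel2 <- optimal_diet(list(good, ballast, free), I_max = 0.1)
  expect_setequal(vapply(sel2, `[[`, character(1), "id"), c("good", "free"))
  # single prey is always included
  sel3 <- optimal_diet(list(ballast), I_max = 0.1)
  expect_identical(vapply(sel3, `[[`, character(1), "id"), "ballast")
})

test_that("mode weights follow relative ingestion with a uniform degenerate rule", {
  expect_equal(allocate_modes(c(pelagic = 0.02, benthic = 0.01)),
               c(pelagic = 2 / 3, benthic = 1 / 3))
  expect_equal(allocate_modes(c(pelagic = 0.05)), c(pelagic = 1))
  expect_equal(allocate_modes(c(pelagic = 0, benthic = 0)),
               c(pelagic = 0.5, benthic = 0.5))
  expect_error(allocate_modes(c(a = -1)))
})

test_that("two-step decision reduces to the single-prey behavioral model", {
  set.seed(505)
  for (k in 1:100) {
    env <- draw_env()
    tp <- draw_tp()
    prey <- list(prey_item("only", R = env$R, c = env$c, f_gut = env$f_gut,
                           a = env$a))
    eb <- base_env(I_max = env$I_max, u = env$u, m_nat = env$m_nat,
                   m_pred_s = env$m_pred_s, f_veg = env$f_veg)
    two <- diet_then_behavior(prey, eb, tp)
    one <- optimal_behavior(env, tp)
    expect_equal(two$behavior$p_star, one$p_star, tolerance = 1e-12)
    expect_equal(two$behavior$g, one$g, tolerance = 1e-12)
    expect_identical(two$behavior$regime, one$regime)
  }
})

test_that("mode with no available prey receives no effort", {
  prey <- list(
    prey_item("z", R = 2, c = 0.5, f_gut = 1, a = 0.7, mode = "pelagic"),
    prey_item("b", R = 0, c = 0.3, f_gut = 1.5, a = 0.6, mode = "benthic")
  )
  eb <- base_env(I_max = 0.05, u = 0.005, m_nat = 1e-3)
  out <- diet_then_behavior(prey, eb, tradeoff_params(1, 1, 0.3))
  expect_equal(unname(out$diet$mode_weights["pelagic"]), 1)
  expect_equal(unname(out$diet$mode_weights["benthic"]), 0)
})

test_that("per-prey ingestion sums to the behavioral solution's assimilation", {
  set.seed(606)
  for (k in 1:100) {
    prey <- draw_prey(sample(2:6, 1), modes = c("pelagic", "benthic"))
    eb <- base_env(I_max = 10^runif(1, -2, 0), u = 10^runif(1, -4, -2),
                   m_nat = 10^runif(1, -5, -2), m_pred_s = 10^runif(1, -4, -1))
    tp <- draw_tp()
    out <- diet_then_behavior(prey, eb, tp)
    expect_equal(sum(out$diet$per_prey_ingestion), out$behavior$g,
                 tolerance = 1e-12)
    expect_true(all(out$diet$per_prey_ingestion >= 0))
    w <- out$diet$mode_weights
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1)
    # mitigation can only lower realized assimilation below the potential
    expect_lte(out$behavior$g, out$diet$g_pot_agg + 1e-12)
  }
})
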