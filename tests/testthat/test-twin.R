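state_with <- function(...) {
  C <- c(glc = 10, gln = 2, asn = 1, lac = 5, nh4 = 1, ala = 0.5)
  over <- c(...)
  C[names(over)] <- over
  reactor_state(t = 0, V = 2, Xv = 1, Xd = 0.1, C = C, P = 10)
}

test_that("growth rate saturates, vanishes on depletion and halves per factor", {
  p <- nominal_parameters()
  sat <- state_with(glc = 1e9, gln = 1e9, asn = 1e9, lac = 0, nh4 = 0)
  expect_equal(growth_rate(sat, p), p$mu_max, tolerance = 1e-6)
  expect_equal(growth_rate(state_with(glc = 0), p), 0)
  expect_equal(growth_rate(state_with(gln = 0), p), 0)
  expect_equal(growth_rate(state_with(asn = 0), p), 0)
  # all five factors at half saturation/inhibition: mu = mu_max / 32
  half <- state_with(glc = p$K_glc, gln = p$K_gln, asn = p$K_asn,
                     lac = p$KI_lac, nh4 = p$KI_amm)
  expect_equal(growth_rate(half, p), p$mu_max / 32, tolerance = 1e-12)
  expect_lte(growth_rate(state_with(), p), p$mu_max)
})

test_that("death rate is basal plus linear in ammonia", {
  p <- nominal_parameters()
  expect_equal(death_rate(state_with(nh4 = 0), p), p$kd0)
  d1 <- death_rate(state_with(nh4 = 2), p) - p$kd0
  d2 <- death_rate(state_with(nh4 = 4), p) - p$kd0
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_equal(death_rate(state_with(nh4 = 5), p), p$kd0 + 5 * p$kd_amm,
               tolerance = 1e-12)
})

test_that("specific rates follow the closed forms and the sign convention", {
  p <- nominal_parameters()
  s <- state_with()
  q <- specific_rates(s, p)
  expect_named(q, twin_species())
  mu <- growth_rate(s, p)
  qg <- mu / p$Y_xg + p$m_glc * s$C[["glc"]] / (p$K_mglc + s$C[["glc"]])
  qq <- mu / p$Y_xgln + p$m_gln * s$C[["gln"]] / (p$K_mgln + s$C[["gln"]])
  sw <- plogis((s$C[["glc"]] - p$glc_switch) / p$switch_width)
  expect_equal(q[["glc"]], -qg, tolerance = 1e-12)
  expect_equal(q[["gln"]], -qq, tolerance = 1e-12)
  expect_equal(q[["asn"]],
               -p$q_asn_max * s$C[["asn"]] / (p$K_asn_up + s$C[["asn"]]),
               tolerance = 1e-12)
  expect_equal(q[["lac"]],
               sw * p$Y_lg * qg -
                 (1 - sw) * p$q_lac_max * s$C[["lac"]] / (p$K_lac + s$C[["lac"]]),
               tolerance = 1e-12)
  expect_equal(q[["nh4"]], p$Y_ag * qq, tolerance = 1e-12)
  expect_equal(q[["ala"]], p$Y_ala * qq, tolerance = 1e-12)
  # uptakes negative, secretions positive
  expect_lt(q[["glc"]], 0); expect_lt(q[["gln"]], 0); expect_lt(q[["asn"]], 0)
  expect_gt(q[["nh4"]], 0); expect_gt(q[["ala"]], 0)
})

test_that("lactate shifts from secretion to uptake across the glucose switch", {
  p <- nominal_parameters()
  expect_gt(specific_rates(state_with(glc = 20, lac = 10), p)[["lac"]], 0)
  expect_lt(specific_rates(state_with(glc = 0.05, lac = 10), p)[["lac"]], 0)
})

test_that("all rates vanish on an empty medium", {
  p <- nominal_parameters()
  empty <- state_with(glc = 0, gln = 0, asn = 0, lac = 0, nh4 = 0, ala = 0)
  expect_equal(unname(specific_rates(empty, p)), rep(0, 6))
  expect_equal(antibody_rate(empty, p), 0)
})

test_that("rhs mass balances behave at the degenerate corners", {
  p <- nominal_parameters()
  pol0 <- feed_policy(c(0, 100), 0, 0, 0)
  # no cells, no flow: everything frozen
  x <- reactor_state(t = 0, V = 1, Xv = 0, Xd = 0,
                     C = c(glc = 5, gln = 1, asn = 1, lac = 1, nh4 = 1, ala = 1),
                     P = 3)
  d <- twin_rhs(x, pol0, p)
  expect_equal(unname(d), rep(0, length(d)))
  # equal in/out flow: chemostat-like volume
  polf <- feed_policy(c(0, 100), C_feed_glc = 100, F_in = 0.3, F_out = 0.3)
  d2 <- twin_rhs(state_with(), polf, p)
  expect_equal(d2[["V"]], 0)
  expect_error(twin_rhs(reactor_state(t = 500, V = 1, Xv = 0, Xd = 0,
                                      C = x$C, P = 0), pol0, p),
               "policy undefined")
})

test_that("compiled integrator agrees with an explicit Euler step of the R rhs", {
  p <- nominal_parameters()
  x0 <- nominal_state()
  pol <- baseline_policy()
  dt <- 1e-3
  d <- twin_rhs(x0, pol, p)
  y_euler <- fluxmpc:::pack_state(x0) + dt * d
  traj <- simulate_twin(x0, pol, p, t_end = dt, output_dt = dt)
  y_int <- unlist(traj$states[nrow(traj$states),
                              c("V", "Xv", "Xd", twin_species(), "P", "glc_fed")])
  expect_equal(unname(y_int), unname(y_euler), tolerance = 1e-6)
})

test_that("batch simulation matches the independent RK4 oracle", {
  p <- nominal_parameters()
  x0 <- nominal_state()
  pol <- no_feed_policy(72)
  traj <- simulate_twin(x0, pol, p, t_end = 72)
  y_oracle <- oracle_rk4(x0, pol, p, t_end = 72, dt = 0.01)
  y_pkg <- unlist(traj$states[nrow(traj$states),
                              c("V", "Xv", "Xd", twin_species(), "P")])
  expect_equal(unname(y_pkg), unname(y_oracle[1:10]), tolerance = 1e-4)
  # antibody mass specifically
  expect_equal(traj$totals$antibody_mass, y_oracle[["P"]] * y_oracle[["V"]],
               tolerance = 1e-4)
})

test_that("trajectories are insensitive to the output grid", {
  p <- nominal_parameters()
  x0 <- nominal_state()
  t1 <- simulate_twin(x0, baseline_policy(), p, t_end = 100, output_dt = 2)
  t2 <- simulate_twin(x0, baseline_policy(), p, t_end = 100, output_dt = 1)
  f1 <- unlist(t1$states[nrow(t1$states), c("V", "Xv", twin_species(), "P")])
  f2 <- unlist(t2$states[nrow(t2$states), c("V", "Xv", twin_species(), "P")])
  expect_equal(f1, f2, tolerance = 1e-7)
})

test_that("zero-cell zero-feed cultures stay constant", {
  p <- nominal_parameters()
  x0 <- reactor_state(t = 0, V = 5, Xv = 0, Xd = 0,
                      C = c(glc = 10, gln = 5, asn = 2, lac = 1, nh4 = 1,
                            ala = 0.1), P = 7)
  traj <- simulate_twin(x0, feed_policy(c(0, 50), 0, 0, 0), p, t_end = 50)
  for (col in c("V", "Xv", "Xd", twin_species(), "P"))
    expect_equal(diff(range(traj$states[[col]])), 0, tolerance = 1e-9)
  expect_equal(unname(observed_fluxes(traj)),
               matrix(0, nrow(traj$states), 7), ignore_attr = TRUE)
})

test_that("volume balance integrates the flows for random policies", {
  p <- nominal_parameters()
  x0 <- nominal_state()
  set.seed(0)
  for (i in 1:20) {
    kn <- sort(c(0, runif(4, 1, 99), 100))
    pol <- feed_policy(kn, C_feed_glc = runif(6, 0, 1000),
                       F_in = runif(6, 0.06, 5), F_out = runif(6, 0, 1),
                       C_feed_other = nominal_feed_medium())
    traj <- simulate_twin(x0, pol, p, t_end = 100, output_dt = 5)
    # piecewise-linear flows: exact quadrature on a fine grid of knots
    tt <- sort(unique(c(kn, seq(0, 100, by = 0.25))))
    u <- policy_at(pol, tt)
    expected_dV <- oracle_trapz(tt, u$F_in - u$F_out)
    got_dV <- traj$states$V[nrow(traj$states)] - x0$V
    expect_equal(got_dV, expected_dV, tolerance = 1e-6)
    expect_gte(min(traj$states$glc_fed), 0)
    expect_true(all(diff(traj$states$glc_fed) >= -1e-9))
  }
})

test_that("no state component goes materially negative", {
  p <- nominal_parameters()
  traj <- simulate_twin(nominal_state(), no_feed_policy(), p, t_end = 360)
  sm <- as.matrix(traj$states[c("V", "Xv", "Xd", twin_species(), "P")])
  expect_gte(min(sm), -1e-9)
})

test_that("richer glucose feed never reduces cumulative glucose fed", {
  p <- nominal_parameters()
  x0 <- nominal_state()
  base_c <- c(100, 300, 200, 400)
  pol1 <- feed_policy(c(0, 40, 80, 120), C_feed_glc = base_c, F_in = 0.5)
  pol2 <- feed_policy(c(0, 40, 80, 120), C_feed_glc = base_c + 50, F_in = 0.5)
  t1 <- simulate_twin(x0, pol1, p, t_end = 120)
  t2 <- simulate_twin(x0, pol2, p, t_end = 120)
  expect_gt(t2$totals$glucose_fed, t1$totals$glucose_fed)
})

test_that("observed fluxes carry the target-table schema and re-evaluate", {
  traj <- simulate_twin(nominal_state(), baseline_policy(), nominal_parameters(),
                        t_end = 48, output_dt = 4)
  z <- observed_fluxes(traj)
  expect_identical(colnames(z), tracked_fluxes(fx_targets))
  p <- nominal_parameters()
  for (i in c(1, 5, nrow(traj$states))) {
    C <- unlist(traj$states[i, twin_species()])
    expect_equal(unname(z[i, "glc"]), unname(specific_rates(C, p)["glc"]),
                 tolerance = 1e-12)
    expect_equal(unname(z[i, "biomass"]), unname(growth_rate(C, p)),
                 tolerance = 1e-12)
  }
})

test_that("closed reactor with inert kinetics conserves every species amount", {
  # all rate constants zeroed out: amounts V*C must stay constant
  p0 <- kinetic_parameters(mu_max = 1e-12, kd0 = 0, kd_amm = 0, m_glc = 0,
                           m_gln = 0, q_lac_max = 0, q_asn_max = 0,
                           alpha = 0, beta = 0)
  x0 <- nominal_state()
  traj <- simulate_twin(x0, no_feed_policy(100), p0, t_end = 100)
  for (sp in twin_species()) {
    amounts <- traj$states[[sp]] * traj$states$V
    expect_equal(diff(range(amounts)) / max(amounts, 1), 0, tolerance = 1e-7)
  }
})
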