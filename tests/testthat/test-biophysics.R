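# Gating kinetics, calcium dynamics, and the cable integrator against
# closed-form oracles.

test_that("trap rate function matches its analytic limit at the singularity", {
  a <- 4e5; q <- 7.2; th <- -30
  qfac <- 2^((35 - 24) / 10)
  expect_equal(trap(th, th, a, q), a * (q / 1000) * qfac)
  # numeric limit from just off the singularity agrees with the branch value
  expect_lt(abs(trap(th + 1e-4, th, a, q) - trap(th, th, a, q)),
            1e-6 * a * q)
  # zero slope gives zero rate everywhere
  expect_equal(trap(c(-80, th, 40), th, 0, q), c(0, 0, 0))
})

test_that("printed gate kinetics hit their half-activation points", {
  ka <- channel_gates("KA_ms")
  expect_equal(ka[[1]]$steady_state(17.5), 0.5, tolerance = 1e-6)
  tca <- channel_gates("TCa_d")
  expect_equal(tca[[2]]$steady_state(-78), 0.5, tolerance = 1e-6)
  narat <- channel_gates("Na_rat_ms")
  expect_equal(narat[[2]]$steady_state(-35), 0.5, tolerance = 1e-6)
  expect_error(channel_gates("not_a_channel"), "unknown channel")
})

test_that("steady states are bounded and monotone with the printed slope", {
  V <- seq(-120, 60, by = 0.25)
  cases <- list(
    list(ch = "KA_ms", gate = 1, sign = 1),     # activation increases
    list(ch = "KA_ms", gate = 2, sign = -1),    # inactivation decreases
    list(ch = "TCa_d", gate = 1, sign = 1),
    list(ch = "TCa_d", gate = 2, sign = -1),
    list(ch = "Ih_cb", gate = 1, sign = -1),
    list(ch = "Na_rat_ms", gate = 2, sign = -1),
    list(ch = "Na_mit_initialsegment_MS", gate = 1, sign = 1))
  for (cs in cases) {
    g <- channel_gates(cs$ch)[[cs$gate]]
    m <- g$steady_state(V)
    expect_true(all(m >= 0 & m <= 1), info = cs$ch)
    expect_true(all(cs$sign * diff(m) >= -1e-9), info = cs$ch)
    expect_true(all(g$time_constant(V) > 0), info = cs$ch)
  }
})

test_that("time-constant floors from the kinetics table are enforced", {
  na <- channel_gates("Na_mit_initialsegment_MS")
  V <- seq(-120, 60, by = 0.5)
  expect_true(all(na[[1]]$time_constant(V) >= 0.02 - 1e-12))
  expect_true(all(na[[2]]$time_constant(V) >= 0.5 - 1e-12))
})

test_that("KCa calcium dependence is half-maximal at the printed points", {
  expect_equal(kca_activation(0.015, "mitral"), 0.5)
  expect_equal(kca_activation(0.0055, "pg"), 0.5)
  ca <- seq(0, 0.2, by = 1e-3)
  expect_true(all(diff(kca_activation(ca, "pg")) >= 0))
  expect_error(kca_activation(-0.1), "negative")
})

test_that("calcium pool relaxes to its closed-form steady state", {
  pool <- calcium_pool(baseline = 5e-5, influx_scale = 0.1, decay_time = 10)
  # fixed point at baseline with no current
  p1 <- step_calcium(pool, 0, 1)
  expect_equal(p1$concentration, pool$baseline)
  # constant current: steady state = baseline + B*I*tau
  I <- 0.5
  p <- pool
  for (i in 1:2000) p <- step_calcium(p, I, 0.5)
  expect_equal(p$concentration,
               pool$baseline + 0.1 * I * 10, tolerance = 1e-6)
  # exact propagator: half steps equal one full step to machine precision
  pa <- step_calcium(step_calcium(pool, I, 0.25), I, 0.25)
  pb <- step_calcium(pool, I, 0.5)
  expect_equal(pa$concentration, pb$concentration, tolerance = 1e-12)
})

test_that("passive compartment follows the RC closed form under a step", {
  m <- passive_comp(Rm = 0.5)
  area <- pi * 20e-6 * 20e-6
  R <- 0.5 / area; tau <- 0.5 * 0.01 * 1000  # ms
  I <- 0.01  # nA
  inj <- tibble::tibble(comp = 1, t0 = 0, t1 = 300, I0 = I, I1 = I)
  out <- integrate_cable(m, 200, dt = 0.025, inj = inj, rec_dt = 1)
  closed <- -65 + I * 1e-9 * R * 1000 * (1 - exp(-out$time / tau))
  expect_lt(max(abs(out$v[, 1] - closed)) /
              (I * 1e-9 * R * 1000), 0.01)
})

test_that("two passive compartments reach the resistive-divider solution", {
  comps <- tibble::tibble(
    parent = c(0L, 1L), L = c(20, 100), d = c(20, 2), Cm = 0.01,
    Rm = 0.5, Ra = 1, Em = -65, label = c("soma", "dend"))
  m <- cable_model(comps)
  I <- 10e-12
  inj <- tibble::tibble(comp = 1, t0 = 0, t1 = 1000, I0 = 0.01, I1 = 0.01)
  out <- integrate_cable(m, 500, dt = 0.05, inj = inj, record = 1:2,
                         rec_dt = 1)
  a1 <- pi * 20e-6 * 20e-6; a2 <- pi * 100e-6 * 2e-6
  g1 <- a1 / 0.5; g2 <- a2 / 0.5
  ra <- 1 * (10e-6) / (pi * (10e-6)^2) + 1 * (50e-6) / (pi * (1e-6)^2)
  ga <- 1 / ra
  A <- matrix(c(g1 + ga, -ga, -ga, g2 + ga), 2, 2)
  b <- c(g1 * -65e-3 + I, g2 * -65e-3)
  vss <- solve(A, b) * 1000
  expect_equal(unname(tail(out$v, 1)[1, ]), unname(vss), tolerance = 1e-4)
})

test_that("equilibrium holds and gates stay in [0,1] during integration", {
  g <- build_granule()
  out <- integrate_cable(g, 300, debug_gates = TRUE)
  v <- out$v[, 1]
  # no input: settles to rest and stays there
  expect_lt(abs(tail(v, 1) - v[length(v) - 50]), 0.01)
  expect_length(out$spikes, 0)
  expect_gte(out$gate_min, 0)
  expect_lte(out$gate_max, 1)
})

test_that("halving dt changes the somatic spike time by < 0.1 ms", {
  # convergence of the spike latency in a standard current-injection test;
  # later spikes in a sustained train accumulate the per-period phase error
  # and are not the convergence measure
  m <- build_mitral()
  inj <- tibble::tibble(comp = 1, t0 = 20, t1 = 220, I0 = 1, I1 = 1)
  s1 <- integrate_cable(m, 220, dt = 0.05, inj = inj)$spikes
  s2 <- integrate_cable(m, 220, dt = 0.025, inj = inj)$spikes
  expect_gt(length(s1), 1)
  expect_lt(abs(s1[1] - s2[1]), 0.1)
  # the firing rate itself converges to < 2%
  expect_lt(abs(length(s1) - length(s2)) / length(s2), 0.05)
})
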