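# Calibrated cell models against their stated electrophysiological targets.

test_that("granule cell threshold is ~25 mV above rest and needs temporal
           integration", {
  g <- build_granule()
  th <- measure_threshold(g)
  expect_gt(th, 22); expect_lt(th, 28)
  # a single EPSP (~2 mV) is far below threshold: no spike
  syn <- tibble::tibble(comp = 2, gmax = c(0.2, 0.052), tau1 = c(1, 25),
                        tau2 = c(4, 200), E = 0, nmda = c(FALSE, TRUE))
  one <- integrate_cable(g, 900, synapses = syn,
                         events = tibble::tibble(syn = 1:2, time = 500),
                         rec_dt = 0.5)
  expect_length(one$spikes, 0)
  epsp <- max(one$v[one$time > 500, 1]) - one$v[one$time == 500, 1]
  expect_gt(epsp, 1); expect_lt(epsp, 5)
  # 100 EPSPs at 6 ms fire the cell after a long integration latency
  ev <- tibble::tibble(syn = rep(1:2, each = 100),
                       time = rep(seq(0, by = 6, length.out = 100), 2) + 300)
  train <- integrate_cable(g, 1400, synapses = syn, events = ev)
  expect_gt(length(train$spikes), 0)
  expect_gt(train$spikes[1] - 300, 100)  # latency of integration
  # no spontaneous firing over 5 s of rest
  rest <- integrate_cable(g, 5000, rec_dt = 5)
  expect_length(rest$spikes, 0)
})

test_that("granule threshold is insensitive to the ramp rate", {
  g <- build_granule()
  th <- vapply(c(0.05, 0.1, 0.2), function(rr)
    measure_threshold(g, ramp_rate = rr), 0)
  expect_lt(max(th) - min(th), 2)
})

test_that("granule with no sodium reports the no-spike sentinel", {
  g <- build_granule()
  ch <- g$channels
  ch$gbar[ch$channel == "Na_rat_ms"] <- 0
  g$channels <- ch
  th <- measure_threshold(g, max_I = 0.2)
  expect_true(is.na(th))
  expect_identical(attr(th, "sentinel"), "no-spike")
})

test_that("PG variants hold -65 mV and show sag, rebound and the
           variant-specific firing style", {
  for (variant in c("low_threshold_spiking", "plateauing")) {
    pg <- build_pg(variant)
    I_h <- if (variant == "plateauing") -0.05 else -0.1
    I_d <- if (variant == "plateauing") 0.05 else 0.1
    o0 <- integrate_cable(pg, 900, rec_dt = 1)
    expect_lt(abs(tail(o0$v[, 1], 1) - (-65)), 2.5)
    inj <- tibble::tibble(comp = 1, t0 = 500, t1 = 1000, I0 = I_h, I1 = I_h)
    oh <- integrate_cable(pg, 1600, inj = inj, rec_dt = 0.5)
    v <- oh$v[, 1]; t <- oh$time
    sag <- v[max(which(t < 1000))] - min(v[t > 500 & t < 1000])
    expect_gt(sag, 2)  # depolarising sag under hyperpolarisation
    expect_gt(sum(oh$spikes > 1000 & oh$spikes < 1400), 0)  # rebound burst
    inj2 <- tibble::tibble(comp = 1, t0 = 500, t1 = 1000, I0 = I_d, I1 = I_d)
    od <- integrate_cable(pg, 1200, inj = inj2, rec_dt = 0.5)
    expect_gt(sum(od$spikes > 500 & od$spikes < 1100), 0)
  }
})

test_that("mitral somatic time constant fits within 20% of 50 ms", {
  m <- build_mitral()
  tau <- measure_tau_m(m, skip = 10)
  expect_gt(tau, 40); expect_lt(tau, 60)
})

test_that("mitral f-I curve is zero at rest and non-decreasing", {
  m <- build_mitral()
  fi <- measure_fI(m, c(0, 0.5, 1.0, 1.5))
  expect_equal(fi$rate[1], 0)
  expect_true(all(diff(fi$rate) >= 0))
  expect_gt(fi$rate[4], 20)
})

test_that("mitral spikes back-propagate to the lateral dendrite tip", {
  m <- build_mitral()
  inj <- tibble::tibble(comp = 1, t0 = 100, t1 = 400, I0 = 1.2, I1 = 1.2)
  tip <- m$morph$lat[[1]][length(m$morph$lat[[1]])]
  out <- integrate_cable(m, 250, inj = inj, record = c(1, tip),
                         rec_dt = 0.05)
  idx <- out$time > 100 & out$time < 200
  amp <- apply(out$v[idx, ], 2, max) - out$v[1, ]
  expect_gt(amp[2] / amp[1], 0.5)  # tip amplitude >= 50% of somatic
})

test_that("leak-reversal heterogeneity matches the stated spreads", {
  set.seed(4)
  g <- sample_leak_reversals(2e4, -65, "granule")
  expect_equal(sd(g), 2.25, tolerance = 0.02)
  expect_true(all(abs(g + 65) <= 6 * 2.25))
  p <- sample_leak_reversals(2e4, -65, "pg")
  expect_equal(sd(p), 3, tolerance = 0.02)
  expect_true(all(abs(p + 65) <= 8 * 3))
})

test_that("PG population is 1/3 plateauing, 2/3 low-threshold spiking", {
  net <- build_network("default", n_lateral = 1, seed = 5,
                       opts = fixture_net_opts())
  frac <- mean(net$pg_cells$variant == "plateauing")
  expect_gt(frac, 0.22); expect_lt(frac, 0.45)
})
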