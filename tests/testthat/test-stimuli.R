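# ORN kernels, pulse trains, respiration, logistic non-linearity, Poisson
# trains and background drive.

test_that("ORN kernels start at zero, peak at t_p, and land in the stated
           post-convolution ranges", {
  set.seed(10)
  k <- make_orn_kernel("odor")
  expect_equal(k$values[1], 0)
  expect_equal(orn_kernel_fun(k$t_p, k$k_p, k$t_p, k$sigma_p), k$k_p)
  resp <- respiration(seq(0, 1999))
  pks <- replicate(40, {
    ko <- make_orn_kernel("odor")
    r <- rate_from_stimulus(odor_series = resp, odor_kernel = ko,
                            baseline = 0)
    max(r$rate)
  })
  expect_true(all(pks >= 2.3 & pks <= 9.1))
  pka <- replicate(40, {
    ka <- make_orn_kernel("air")
    r <- rate_from_stimulus(air_series = resp, air_kernel = ka,
                            baseline = 0)
    max(r$rate)
  })
  expect_true(all(pka >= 0.75 & pka <= 3.05))
})

test_that("respiration waveform is periodic, non-negative, and matches a
           fine-grid evaluation of its printed form", {
  t <- seq(0, 499, by = 0.5)
  w <- respiration(t)
  expect_true(all(w >= 0))
  expect_equal(respiration(t), respiration(t + 500))
  expect_equal(respiration(t), respiration(t + 5 * 500))
  # independent fine-grid oracle for the within-cycle maximum
  Tp <- 0.5
  de <- function(x, a, b) (exp(-x / a) - exp(-x / b)) / (a - b)
  tt <- seq(0, Tp, by = 1e-5)
  ref <- pmax(0.6 * de(tt, 0.06 * Tp, 0.05 * Tp) +
                0.5 * de(tt, 0.3 * Tp, 0.1 * Tp) -
                0.1 * de(Tp - tt, 0.03 * Tp, 0.025 * Tp), 0)
  expect_equal(max(w), max(ref), tolerance = 1e-3)
  expect_lt(abs(t[which.max(w)] / 1000 - tt[which.max(ref)]), 1e-3)
})

test_that("m-sequence series uses 7 x 50 ms bits and the 40 ms valve filter", {
  ms <- msequence_concentration(1, duration_ms = 700, rotate = FALSE)
  # step response reaches 1 - e^-1 of the plateau at 40 ms into a pulse
  on_start <- which(diff(c(0, ms$conc > 0.01)) == 1)[1]
  expect_equal(ms$conc[on_start + 40 - 1], 1 - exp(-1), tolerance = 0.02)
  # sequence period: 350 ms
  expect_equal(ms$conc[1:350], ms$conc[351:700], tolerance = 0.05)
  # all-zero bits: pedestal-only
  ms0 <- msequence_concentration(1, duration_ms = 350, bits = rep(0L, 7),
                                 rotate = FALSE)
  expect_true(all(ms0$conc == 0))
  expect_true(all(ms0$air > 0))
  # m-sequence property: 4 ones, 3 zeros in one period
  ms1 <- msequence_concentration(1, duration_ms = 350, rotate = FALSE)
  on_frac <- mean(ms1$conc > 0.5)
  expect_equal(on_frac, 4 / 7, tolerance = 0.1)
})

test_that("logistic non-linearity matches its printed values", {
  expect_equal(orn_logistic(7.2), 9)
  expect_equal(orn_logistic(1e3), 18)
  expect_equal(orn_logistic(0), 18 / (1 + exp(7.2)))
  expect_equal(orn_logistic(0), 0.0134, tolerance = 0.01)
})

test_that("rate generator is linear in concentration without the
           non-linearity", {
  set.seed(11)
  ko <- make_orn_kernel("odor")
  conc <- respiration(seq(0, 999))
  r1 <- rate_from_stimulus(odor_series = conc, odor_kernel = ko,
                           baseline = 0.5)
  r2 <- rate_from_stimulus(odor_series = 2 * conc, odor_kernel = ko,
                           baseline = 0.5)
  expect_equal(r2$rate - 0.5, 2 * (r1$rate - 0.5), tolerance = 1e-10)
})

test_that("Poisson trains obey the dead-time-corrected rate and refractory
           constraint", {
  set.seed(12)
  sp <- poisson_spikes(35, n_trains = 50, duration_ms = 20000)
  emp <- nrow(sp) / 50 / 20
  expect_equal(emp, 35 / (1 + 0.001 * 35), tolerance = 0.02)
  isis <- unlist(lapply(split(sp$time, sp$train), function(x) diff(sort(x))))
  expect_true(all(isis >= 1))
  # zero rate: empty train
  none <- poisson_spikes(0, n_trains = 3, duration_ms = 1000)
  expect_equal(nrow(none), 0)
})

test_that("background trains hit their nominal rates and are uncorrelated", {
  set.seed(13)
  bv <- background_trains("in_vitro", n_cells = 30, duration_ms = 60000)
  expect_equal(nrow(bv) / 30 / 60, 3.45, tolerance = 0.1 / 3.45)
  bi <- background_trains("in_vivo", n_cells = 30, duration_ms = 30000)
  expect_equal(nrow(bi) / 30 / 30, 35 * (1 / (1 + 0.035)),
               tolerance = 1 / 35)
  # two cells' trains are uncorrelated at 10 ms resolution
  t1 <- bi$time[bi$train == 1]; t2 <- bi$time[bi$train == 2]
  br <- seq(0, 30000, by = 10)
  c1 <- as.numeric(table(cut(t1, br))); c2 <- as.numeric(table(cut(t2, br)))
  # remove the shared respiratory modulation before testing independence
  phase <- rep(seq_len(50), length.out = length(c1))
  r <- cor(c1 - ave(c1, phase), c2 - ave(c2, phase))
  expect_lt(abs(r), 0.05)
})

test_that("mixed-polarity kernels produce rectified rates", {
  set.seed(14)
  k <- make_orn_kernel("odor", polarity = "mixed")
  conc <- respiration(seq(0, 1999))
  r <- rate_from_stimulus(odor_series = conc, odor_kernel = k, baseline = 0)
  expect_true(all(r$rate >= 0))
  # the raw convolution (pre-flooring) does go negative for mixed kernels
  raw <- stats::convolve(conc, rev(k$values), type = "open")[
    seq_along(conc)] / 1000
  expect_lt(min(raw), 0)
})
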