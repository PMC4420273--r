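# Kernel fitting, two-odor prediction, residual/noise, correlations,
# morph-model fitting and scaled-pulse metrics, against brute-force oracles.

make_conv_response <- function(kernel, conc, baseline = 0) {
  nb <- length(conc)
  out <- rep(baseline, nb)
  for (j in seq_along(kernel)) {
    idx <- seq_len(nb - j + 1)
    out[idx + j - 1] <- out[idx + j - 1] + kernel[j] * conc[idx]
  }
  out
}

test_that("kernel fitting exactly recovers a known kernel from noiseless
           convolutions", {
  set.seed(20)
  true_k <- dual_exp_g(seq(0, 39) * 50, 5, 100, 400) -
    dual_exp_g(seq(0, 39) * 50, 2, 300, 800)
  conc1 <- as.numeric(msequence_concentration(1, 4000)$conc[seq(1, 4000, 50)])
  conc2 <- as.numeric(msequence_concentration(1, 4000)$conc[seq(1, 4000, 50)])
  y1 <- make_conv_response(true_k, conc1, baseline = 2)
  y2 <- make_conv_response(true_k, conc2, baseline = 2)
  fit <- fit_linear_kernel(list(y1, y2), list(conc1, conc2), baseline = 2)
  expect_lt(max(abs(fit$kernel$value - true_k)), 1e-6)
  expect_false(fit$rank_deficient)
  # constant response at baseline -> kernel ~ 0
  fit0 <- fit_linear_kernel(rep(2, 80), conc1, baseline = 2)
  expect_lt(max(abs(fit0$kernel$value)), 1e-8)
})

test_that("tidy and glance expose the kernel fit", {
  conc <- runif(80)
  y <- make_conv_response(c(1, 0.5, rep(0, 38)), conc)
  fit <- fit_linear_kernel(y, conc)
  td <- tidy(fit)
  expect_equal(nrow(td), 40)
  expect_named(td, c("lag", "value"))
  gl <- glance(fit)
  expect_equal(gl$n_taps, 40)
})

test_that("two-odor prediction is the rectified sum of single-odor parts", {
  set.seed(21)
  kA <- c(3, 2, 1, rep(0, 37)); kB <- c(1, 2, 0.5, rep(0, 37))
  concA <- runif(60); concB <- runif(60)
  yA <- make_conv_response(kA, concA); yB <- make_conv_response(kB, concB)
  fitA <- fit_linear_kernel(yA, concA)
  fitB <- fit_linear_kernel(yB, concB)
  # C_B = 0 reduces to the single-odor fit
  p0 <- predict_two_odor(fitA, fitB, concA, rep(0, 60))
  expect_equal(p0, pmax(yA, 0), tolerance = 1e-8)
  # doubling both concentrations doubles the pre-rectification deviation
  p1 <- predict_two_odor(fitA, fitB, concA, concB)
  p2 <- predict_two_odor(fitA, fitB, 2 * concA, 2 * concB)
  expect_equal(p2, pmax(2 * (yA + yB), 0), tolerance = 1e-8)
  expect_equal(p1, pmax(yA + yB, 0), tolerance = 1e-8)
})

test_that("residual/noise reproduces a hand-computed worked example", {
  # 3 bins, 2 trials, worked by direct arithmetic
  trials <- rbind(c(1, 2, 3), c(3, 2, 5))
  m <- c(2, 2, 4)
  pred <- c(2, 3, 4)
  # residual = mean((pred - m)^2) = (0 + 1 + 0)/3
  # noise = mean(var per bin) = (2 + 0 + 2)/3
  q <- residual_over_noise(pred, trials)
  expect_equal(q$residual, 1 / 3)
  expect_equal(q$noise, 4 / 3)
  expect_equal(q$ratio, 0.25)
  # prediction equal to the mean: ratio 0
  expect_equal(residual_over_noise(m, trials)$ratio, 0)
  # identical trials with an off prediction: infinite sentinel, flagged
  qi <- residual_over_noise(c(1, 1, 1), rbind(m, m))
  expect_true(is.infinite(qi$ratio))
  expect_true(qi$infinite)
  expect_error(residual_over_noise(pred, trials[1, , drop = FALSE]),
               "single trial")
})

test_that("residual/noise is scale-invariant", {
  set.seed(22)
  trials <- matrix(rnorm(40, 10, 2), nrow = 4)
  pred <- colMeans(trials) + rnorm(10, 0, 0.5)
  r1 <- residual_over_noise(pred, trials)$ratio
  r2 <- residual_over_noise(3.7 * pred, 3.7 * trials)$ratio
  expect_equal(r1, r2)
})

test_that("residual/noise approaches 1 for a prediction equal to the true
           mean under iid noise", {
  set.seed(23)
  truth <- seq(5, 20, length.out = 40)
  ratios <- replicate(30, {
    trials <- t(replicate(60, truth + rnorm(40, 0, 2)))
    residual_over_noise(truth, trials)$ratio * 60  # residual of mean ~ sigma^2/n
  })
  # E[residual of the sample mean] = sigma^2 / n_trials, so ratio*n ~ 1
  expect_equal(mean(ratios), 1, tolerance = 0.15)
})

test_that("phase correlation handles identity, anti-correlation and
           exclusions", {
  a <- c(1, 5, 3, 2, 4)
  expect_equal(phase_correlation(a, a)$r, 1)
  expect_equal(phase_correlation(a, 10 - a)$r, -1)
  ex <- phase_correlation(a, rep(0, 5))
  expect_true(ex$excluded)
  expect_true(is.na(ex$r))
  # permuting bins identically in both sisters leaves r unchanged
  b <- c(2, 1, 4, 5, 3)
  perm <- sample(5)
  expect_equal(phase_correlation(a, b)$r,
               phase_correlation(a[perm], b[perm])$r)
})

test_that("delta-rate correlation matches its definition", {
  d <- tidyr::expand_grid(instance = 1:5, odor = c("A", "B"))
  set.seed(24)
  d$s1 <- rnorm(10)
  deltas <- dplyr::bind_rows(
    tibble::tibble(instance = d$instance, odor = d$odor, sister = 1,
                   delta = d$s1),
    tibble::tibble(instance = d$instance, odor = d$odor, sister = 2,
                   delta = d$s1))
  expect_equal(delta_rate_correlation(deltas), 1)
  deltas$delta[deltas$sister == 2] <- -deltas$delta[deltas$sister == 2]
  expect_equal(delta_rate_correlation(deltas), -1)
  expect_error(delta_rate_correlation(deltas[c(1, 11), ]), "at least 2")
})

test_that("morph model recovers data generated from itself", {
  set.seed(25)
  nb <- 9
  rmax <- 30
  Fair <- rnorm(nb, -0.5, 0.2)
  FA <- rnorm(nb, 0.3, 0.4); FB <- rnorm(nb, 0.2, 0.4)
  wA <- c(0.3, 0.6, 0.85); wB <- c(0.35, 0.65, 0.9)
  lvA <- c(0.2, 0.4, 0.8); lvB <- c(0.2, 0.6, 0.8)
  conc <- tibble::tibble(cA = c(lvA, 0.0), cB = c(0.2, 0.6, 0.2, 0.8))
  conc$cB <- c(lvB[1], lvB[2], lvB[1], lvB[3])
  f <- morph_sigmoid
  responses <- list(
    air = rmax * f(Fair), A = rmax * f(FA), B = rmax * f(FB),
    morphs = lapply(seq_len(4), function(i) {
      wa <- if (conc$cA[i] == 0) 0 else wA[match(conc$cA[i], lvA)]
      wb <- if (conc$cB[i] == 0) 0 else wB[match(conc$cB[i], lvB)]
      rmax * f(wa * FA + wb * FB + Fair)
    }))
  fit <- fit_morph_model(responses, conc, n_starts = 4)
  expect_lt(fit$sse / sum(unlist(responses)^2), 1e-4)
  # weights are monotone by construction
  expect_true(all(diff(fit$par$wA) >= 0))
  expect_true(all(diff(fit$par$wB) >= 0))
  # printed sigmoid passes through 0.5 at zero
  expect_equal(morph_sigmoid(0), 0.5)
})

test_that("rectifier-mode morph model uses concentrations as weights", {
  nb <- 9
  FA <- seq(0.1, 0.9, length.out = nb); FB <- rev(FA)
  Fair <- rep(0.05, nb); rmax <- 20
  conc <- tibble::tibble(cA = c(1, 0.5), cB = c(0, 0.5))
  responses <- list(
    air = rmax * pmax(Fair, 0), A = rmax * pmax(FA, 0),
    B = rmax * pmax(FB, 0),
    morphs = list(rmax * pmax(1 * FA + 0 * FB + Fair, 0),
                  rmax * pmax(0.5 * FA + 0.5 * FB + Fair, 0)))
  fit <- fit_morph_model(responses, conc, mode = "linear_weights_rectifier",
                         n_starts = 3)
  expect_equal(fit$par$wA, c(0.5, 1))
  expect_lt(fit$sse / sum(unlist(responses)^2), 1e-3)
})

test_that("scaled-pulse metrics normalise latencies and correlate against
           the reference concentration", {
  h1 <- c(0, 1, 4, 2, 1, 0)
  resp <- tibble::tibble(
    cell = 1, conc = c(1 / 3, 1, 5),
    first_spike = c(120, 100, 80),
    hist = list(h1 * 0.5, h1, c(4, 2, 1, 0, 0, 0)))
  m <- scaled_pulse_metrics(resp)
  expect_equal(m$norm_latency_spike, c(120, 100, 80) / 100)
  expect_equal(m$r_vs_ref[m$conc == 1], 1)
  expect_equal(m$r_vs_ref[m$conc == 1 / 3], 1)  # scaled copy correlates fully
  expect_lt(m$r_vs_ref[m$conc == 5], 1)
  # single concentration: normalised latency is identically 1
  single <- scaled_pulse_metrics(resp[2, ])
  expect_equal(single$norm_latency_spike, 1)
})
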