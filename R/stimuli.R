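# Synthetic ORN drive: odor/air kernels, pulse-train and respiration
# concentration series, the logistic output non-linearity, inhomogeneous
# Poisson spike trains, and granule background input.
#
# Rate series live on a 1 ms grid.  Kernels are Gaussians in time,
# pre-multiplied so they start from zero:
#   k(t) = k_p * (t/t_p)^(t_p/(2*sigma_p)) * exp(-(t - t_p)^2 / (2*sigma_p^2))
# with latency-to-peak t_p ~ U(150, 350) ms and width sigma_p ~ U(250, 450)
# ms; k_p is scaled so the respiration-convolved peak falls in 0.8-3 Hz for
# air and 2.4-9 Hz for odor.

RATE_DT <- 1  # ms grid for rate series

#' Evaluate an ORN kernel
#'
#' @param t time, ms (vectorised)
#' @param k_p peak amplitude
#' @param t_p latency to peak, ms
#' @param sigma_p width, ms
#' @return kernel values; \code{k(0) = 0} and \code{k(t_p) = k_p}
#' @export
orn_kernel_fun <- function(t, k_p, t_p, sigma_p) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- k_p * (t[pos] / t_p)^(t_p / (2 * sigma_p)) *
    exp(-(t[pos] - t_p)^2 / (2 * sigma_p^2))
  out
}

#' Draw an ORN kernel
#'
#' Parameters are drawn uniformly from the stated ranges and the amplitude
#' is scaled so that, after convolution with the half-rectified respiration
#' waveform, the peak firing rate lies in 0.8-3 Hz for air kernels and
#' 2.4-9 Hz for odor kernels.  \code{polarity = "mixed"} returns a weighted
#' difference of two time-displaced Gaussians (an excitatory-inhibitory
#' kernel); the resulting rate is floored at zero downstream.
#'
#' @param kind \code{"air"} or \code{"odor"}
#' @param polarity \code{"excitatory"} or \code{"mixed"}
#' @param duration kernel support, ms
#' @return list with fields \code{kind, k_p, t_p, sigma_p, values} (on the
#'   1 ms grid) and \code{peak_rate} (respiration-convolved peak, Hz)
#' @export
make_orn_kernel <- function(kind = c("odor", "air"),
                            polarity = c("excitatory", "mixed"),
                            duration = 1500) {
  kind <- match.arg(kind)
  polarity <- match.arg(polarity)
  t_p <- runif(1, 150, 350)
  sigma_p <- runif(1, 250, 450)
  peak_target <- if (kind == "air") runif(1, 0.8, 3) else runif(1, 2.4, 9)
  tt <- seq(0, duration, by = RATE_DT)
  base <- orn_kernel_fun(tt, 1, t_p, sigma_p)
  if (polarity == "mixed") {
    t_p2 <- t_p + runif(1, 50, 150)
    w2 <- runif(1, 0.3, 0.7)
    base <- base - w2 * orn_kernel_fun(tt, 1, t_p2, sigma_p)
  }
  # scale so that the respiration-convolved peak equals peak_target
  resp <- respiration(seq(0, 4 * 500 - RATE_DT, by = RATE_DT))
  conv <- stats::convolve(rep(resp, 2), rev(base), type = "open")[
    seq_len(2 * length(resp))] * RATE_DT / 1000
  k_p <- peak_target / max(conv)
  list(kind = kind, polarity = polarity, k_p = k_p, t_p = t_p,
       sigma_p = sigma_p, t = tt, values = k_p * base,
       peak_rate = peak_target)
}

#' Periodic respiration waveform
#'
#' Three dual-exponential terms, half-rectified, with period T = 0.5 s:
#' \code{0.6 dualexp(t, .06T, .05T) + 0.5 dualexp(t, .3T, .1T)
#' - 0.1 dualexp(T - t, .03T, .025T)} where
#' \code{dualexp(t, a, b) = (exp(-t/a) - exp(-t/b)) / (a - b)}.
#'
#' @param t time, ms (vectorised); evaluated modulo the period
#' @param period_ms respiration period, ms (default 500)
#' @return non-negative flow values (arbitrary units)
#' @export
respiration <- function(t, period_ms = 500) {
  Tp <- period_ms / 1000
  tc <- (t / 1000) %% Tp
  dualexp <- function(x, a, b) (exp(-x / a) - exp(-x / b)) / (a - b)
  w <- 0.6 * dualexp(tc, 0.06 * Tp, 0.05 * Tp) +
    0.5 * dualexp(tc, 0.3 * Tp, 0.1 * Tp) -
    0.1 * dualexp(Tp - tc, 0.03 * Tp, 0.025 * Tp)
  pmax(w, 0)
}

#' Binary m-sequence odor-concentration series
#'
#' A 7-bit maximal-length binary sequence (3-stage LFSR, taps config-fixed)
#' gates 50 ms odor pulses; the full 350 ms sequence repeats to the
#' requested duration.  The binary valve train is convolved with a decaying
#' exponential of time constant 40 ms (valve opening/closing) and scaled so
#' the pulse plateau equals \code{peak_conc}.  A constant air pedestal at
#' one third of the freely-breathing respiration peak is returned alongside.
#'
#' @param peak_conc odor pulse concentration, percent saturated vapor
#' @param duration_ms series length, ms
#' @param bit_ms pulse duration per bit (default 50)
#' @param valve_tau valve filter time constant, ms (default 40)
#' @param bits optional explicit bit vector (default: the LFSR sequence
#'   1110100, freshly permuted by rotation for each call through the RNG)
#' @param rotate if TRUE (default), rotate the sequence by a random offset,
#'   giving distinct pulse trains per draw
#' @return tibble with columns \code{t} (ms), \code{conc} (odor), and
#'   \code{air} (pedestal flow, units of the respiration waveform)
#' @export
msequence_concentration <- function(peak_conc, duration_ms = 3500,
                                    bit_ms = 50, valve_tau = 40,
                                    bits = NULL, rotate = TRUE) {
  stopifnot(peak_conc >= 0)
  if (is.null(bits)) {
    # length-7 maximal sequence of the 3-stage LFSR x^3 + x + 1, seed 111
    reg <- c(1L, 1L, 1L)
    bits <- integer(7)
    for (i in 1:7) {
      bits[i] <- reg[3]
      reg <- c(xor(reg[1], reg[3]), reg[1], reg[2])
    }
  }
  if (rotate) {
    off <- sample.int(length(bits), 1) - 1L
    if (off > 0) bits <- c(bits[-seq_len(off)], bits[seq_len(off)])
  }
  tt <- seq(0, duration_ms - RATE_DT, by = RATE_DT)
  bit_idx <- (floor(tt / bit_ms) %% length(bits)) + 1L
  valve <- bits[bit_idx]
  # valve filter: first-order low-pass, exact exponential update
  a <- exp(-RATE_DT / valve_tau)
  filt <- stats::filter(valve * (1 - a), a, method = "recursive")
  conc <- as.numeric(filt) * peak_conc
  pedestal <- max(respiration(seq(0, 499, by = RATE_DT))) / 3
  tibble(t = tt, conc = conc, air = rep(pedestal, length(tt)))
}

#' Logistic output non-linearity of the ORN population
#'
#' \code{18 / (1 + exp(-(x - 7.2)))}: centred at 7.2 Hz with 1 Hz
#' steepness, saturating at 18 Hz.
#'
#' @param x input firing rate, Hz
#' @export
orn_logistic <- function(x) 18 / (1 + exp(-(x - 7.2)))

#' ORN firing-rate series from stimulus series and kernels
#'
#' Convolves the odor concentration series with the odor kernel and the air
#' flow series with the air kernel, sums them with a constant 0.5 Hz
#' baseline, optionally applies the logistic non-linearity, and floors the
#' result at zero.
#'
#' @param odor_series odor concentration on the 1 ms grid (or NULL)
#' @param air_series air flow on the 1 ms grid (or NULL)
#' @param odor_kernel,air_kernel kernels from [make_orn_kernel()]
#' @param nonlinearity \code{"none"} or \code{"logistic"}
#' @param baseline constant background rate, Hz (default 0.5)
#' @return tibble with \code{t} (ms) and \code{rate} (Hz >= 0)
#' @export
rate_from_stimulus <- function(odor_series = NULL, air_series = NULL,
                               odor_kernel = NULL, air_kernel = NULL,
                               nonlinearity = c("none", "logistic"),
                               baseline = 0.5) {
  nonlinearity <- match.arg(nonlinearity)
  n <- max(length(odor_series), length(air_series))
  if (!is.null(odor_series) && !is.null(air_series) &&
      length(odor_series) != length(air_series))
    stop("odor and air series must share a time base", call. = FALSE)
  rate <- rep(baseline, n)
  convo <- function(series, kernel) {
    stats::convolve(series, rev(kernel$values), type = "open")[
      seq_along(series)] * RATE_DT / 1000
  }
  if (!is.null(odor_series)) rate <- rate + convo(odor_series, odor_kernel)
  if (!is.null(air_series)) rate <- rate + convo(air_series, air_kernel)
  if (nonlinearity == "logistic") rate <- orn_logistic(rate)
  tibble(t = seq(0, n - 1) * RATE_DT, rate = pmax(rate, 0))
}

#' Inhomogeneous Poisson spike trains with refractory period
#'
#' Thinning of a homogeneous Poisson process at the maximum rate, followed
#' by a 1 ms dead time.  Under a constant rate r the realised rate is the
#' renewal-corrected r/(1 + r*refrac).
#'
#' @param rate a rate series: tibble with \code{t} (ms) and \code{rate}
#'   (Hz), or a single number (constant rate) with \code{duration}
#' @param n_trains number of independent trains
#' @param duration_ms needed when \code{rate} is scalar
#' @param refractory_ms dead time (default 1 ms)
#' @return tibble with \code{train} and \code{time} (ms), sorted
#' @export
poisson_spikes <- function(rate, n_trains = 1, duration_ms = NULL,
                           refractory_ms = 1) {
  if (is.numeric(rate) && length(rate) == 1) {
    stopifnot(!is.null(duration_ms))
    rate <- tibble(t = seq(0, duration_ms - RATE_DT, by = RATE_DT),
                   rate = rate)
  }
  stopifnot(all(rate$rate >= 0))
  rmax <- max(rate$rate)
  dur <- max(rate$t) + RATE_DT
  if (rmax <= 0)
    return(tibble(train = integer(), time = numeric()))
  # homogeneous candidates at rmax across all trains at once: per-train
  # Poisson counts, then uniform event times (order statistics)
  n_cand <- stats::rpois(n_trains, rmax * dur / 1000)
  train <- rep.int(seq_len(n_trains), n_cand)
  tt <- runif(sum(n_cand)) * dur
  ord <- order(train, tt)
  train <- train[ord]; tt <- tt[ord]
  # thin by the local rate
  loc <- rate$rate[pmin(length(rate$rate), floor(tt / RATE_DT) + 1L)]
  keep <- runif(length(tt)) < loc / rmax
  train <- train[keep]; tt <- tt[keep]
  # dead time within each train
  if (length(tt)) {
    k2 <- .dead_time_filter(train, tt, refractory_ms)
    train <- train[k2]; tt <- tt[k2]
  }
  tibble(train = train, time = tt)
}

#' Background spike trains for granule cells
#'
#' Proxy for the unmodelled mitral population: independent Poisson trains
#' per granule cell at 3.45 Hz (in vitro) or 35 Hz (in vivo); the in-vivo
#' version is modulated proportionally to the respiration waveform around
#' the 35 Hz mean (default modulation depth 50%).
#'
#' @param context \code{"in_vitro"} or \code{"in_vivo"}
#' @param n_cells number of granule cells
#' @param duration_ms train length
#' @param modulation_depth fractional respiratory modulation (in vivo)
#' @return tibble with \code{train} (granule index) and \code{time} (ms)
#' @export
background_trains <- function(context = c("in_vivo", "in_vitro"), n_cells,
                              duration_ms, modulation_depth = 0.25) {
  context <- match.arg(context)
  if (context == "in_vitro") {
    return(poisson_spikes(3.45, n_cells, duration_ms))
  }
  tt <- seq(0, duration_ms - RATE_DT, by = RATE_DT)
  w <- respiration(tt)
  w <- w / mean(w)  # unit-mean modulation
  r <- 35 * (1 + modulation_depth * (w - 1))
  poisson_spikes(tibble(t = tt, rate = pmax(r, 0)), n_cells, duration_ms)
}
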