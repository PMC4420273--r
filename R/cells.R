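# The three cell models: mitral (reduced morphology), granule (2 compartments)
# and periglomerular (3 compartments, plateauing and low-threshold-spiking
# variants).  Channel densities below are the frozen result of a scripted
# calibration against the stated physiological targets: granule spike
# threshold ~25 mV above rest with long-latency integration of EPSP trains;
# PG resting potential -65 mV with sag / rebound burst / low-threshold spike
# or plateau; mitral somatic membrane time constant ~50 ms with soma-first
# spike initiation for weak tuft input and tuft-first for strong input.

# --- frozen density tables (S/m^2) -------------------------------------------

granule_params <- function() {
  list(
    soma = list(L = 8, d = 8),
    dend = list(L = 350, d = 2),
    Cm = 0.01, Rm = 5.0, Ra = 1.0, Em = -64,
    dens = list(
      soma = c(Na_rat_ms = 4000, K2_mit_usb = 250, KA_ms = 20),
      dend = c(Na_rat_ms = 40, K2_mit_usb = 20, KA_ms = 5)
    )
  )
}

pg_params <- function(variant) {
  base <- list(
    soma = list(L = 8, d = 8),
    dend = list(L = 150, d = 2),
    Cm = 0.01, Rm = 0.5, Ra = 1.0,
    ca = list(tau = 25, base = 5e-5, B = 2e-4)
  )
  if (variant == "plateauing") {
    base$Em <- -78
    base$dens <- list(
      soma = c(Na_rat_ms = 3200, K2_mit_usb = 250, KA_bsg_yka = 40,
               TCa_d = 60, Ih_cb = 2, Kca_mit_usb_pg = 10),
      dend = c(TCa_d = 50, Ih_cb = 4, KA_bsg_yka = 20, Kca_mit_usb_pg = 5)
    )
  } else {
    base$Em <- -73
    base$dens <- list(
      soma = c(Na_rat_ms = 1500, K2_mit_usb = 500, KA_bsg_yka = 150,
               TCa_d = 8, Ih_cb = 1.5, Kca_mit_usb_pg = 40),
      dend = c(TCa_d = 60, Ih_cb = 3, KA_bsg_yka = 60, Kca_mit_usb_pg = 15)
    )
  }
  base
}

mitral_params <- function() {
  list(
    soma = list(L = 25, d = 25),
    iseg = list(L = 30, d = 1.5),
    prim = list(L = 350, d = 6, nseg = 7),
    tuft = list(n_branch = 16, br_nseg = 3, seg_len = 25, d = 1),
    lat = list(L = 425, d = 2.5, nseg = 17, n = 4),
    Cm = 0.01, Rm = 6.0, Ra = 0.8, Em = -65,
    ca = list(tau = 12, base = 5e-5, B = 1e-4),
    dens = list(
      soma = c(Na_mit_usb = 1200, K2_mit_usb = 300, K_mit_usb = 500,
               KA_bsg_yka = 40, LCa3_mit_usb = 8, Kca_mit_usb = 120),
      iseg = c(Na_mit_initialsegment_MS = 10000, K_mit_usb = 800),
      prim = c(Na_mit_usb = 400, K2_mit_usb = 100, K_mit_usb = 160),
      tuft = c(Na_mit_usb = 800, K2_mit_usb = 60, K_mit_usb = 100),
      lat = c(Na_mit_usb = 350, K2_mit_usb = 80, K_mit_usb = 140)
    )
  )
}

.dens_rows <- function(comp_ids, dens) {
  if (!length(dens)) return(NULL)
  tibble(comp = rep(comp_ids, each = length(dens)),
         channel = rep(names(dens), length(comp_ids)),
         gbar = rep(unname(dens), length(comp_ids)))
}

#' Build the two-compartment granule cell model
#'
#' Soma plus a single lumped dendritic compartment carrying Na, K and A-type
#' K channels, calibrated so the cell has a spike threshold of about 25 mV
#' above rest and fires only after temporal integration of a dense EPSP
#' train.  K reversal is -80 mV.
#'
#' @param Em leak reversal, mV (population spread is applied by the network
#'   builder)
#' @return a [cable_model()]
#' @export
build_granule <- function(Em = NULL) {
  p <- granule_params()
  if (is.null(Em)) Em <- p$Em
  comps <- tibble(
    parent = c(0L, 1L),
    L = c(p$soma$L, p$dend$L), d = c(p$soma$d, p$dend$d),
    Cm = p$Cm, Rm = p$Rm, Ra = p$Ra, Em = Em,
    label = c("soma", "dend"))
  ch <- bind_rows(.dens_rows(1L, p$dens$soma), .dens_rows(2L, p$dens$dend))
  ch$E <- ifelse(grepl("^Na", ch$channel), NA_real_, -80)
  cable_model(comps, ch, soma = 1L)
}

#' Build a periglomerular cell model
#'
#' Three compartments (soma and two dendritic shafts), with Na, K, A-type K,
#' T-type Ca, h-current and Ca-activated K channels plus a somatic/dendritic
#' calcium pool.  Two variants reproduce the reported firing styles:
#' \code{"plateauing"} (burst with plateau at +50 pA; sag at -50 pA) and
#' \code{"low_threshold_spiking"} (low-threshold spike at +100 pA; sag at
#' -100 pA).  Resting potential is -65 mV.
#'
#' @param variant \code{"plateauing"} or \code{"low_threshold_spiking"}
#' @param Em leak reversal, mV
#' @return a [cable_model()]
#' @export
build_pg <- function(variant = c("plateauing", "low_threshold_spiking"),
                     Em = NULL) {
  variant <- match.arg(variant)
  p <- pg_params(variant)
  if (is.null(Em)) Em <- p$Em
  comps <- tibble(
    parent = c(0L, 1L, 1L),
    L = c(p$soma$L, p$dend$L, p$dend$L),
    d = c(p$soma$d, p$dend$d, p$dend$d),
    Cm = p$Cm, Rm = p$Rm, Ra = p$Ra, Em = Em,
    label = c("soma", "dend1", "dend2"))
  ch <- bind_rows(.dens_rows(1L, p$dens$soma),
                  .dens_rows(2:3, p$dens$dend))
  ch$E <- ifelse(ch$channel %in% c("K2_mit_usb", "KA_bsg_yka"), -80, NA_real_)
  pools <- tibble(comp = 1:3, tau = p$ca$tau, base = p$ca$base, B = p$ca$B)
  cable_model(comps, ch, pools, soma = 1L)
}

#' Build the reduced mitral cell model
#'
#' Reduced morphology: soma, an initial segment bearing a dedicated fast Na
#' channel, a primary dendrite ending in a tuft cable, and four lateral
#' (secondary) dendrites of 425 um half-span discretised in 25 um segments.
#' Passive parameters give a somatic membrane time constant of ~50 ms
#' (Rm*Cm = 50 ms).  The tuft and primary dendrite are more excitable than
#' the laterals so that strong tuft input initiates the spike in the tuft
#' and weak input at the soma.
#'
#' @param n_lateral number of lateral dendrites (default 4)
#' @param Em leak reversal, mV
#' @return a [cable_model()]; compartment labels identify soma, initial
#'   segment (\code{iseg}), primary segments (\code{prim_i}), tuft segments
#'   (\code{tuft_i}) and lateral segments (\code{lat<j>_<i>})
#' @export
build_mitral <- function(n_lateral = 4, Em = -65) {
  p <- mitral_params()
  rows <- list(tibble(parent = 0L, L = p$soma$L, d = p$soma$d, label = "soma"))
  nxt <- 2L
  # initial segment off the soma
  rows <- c(rows, list(tibble(parent = 1L, L = p$iseg$L, d = p$iseg$d,
                              label = "iseg")))
  iseg_id <- nxt; nxt <- nxt + 1L
  # primary dendrite
  prim_ids <- integer(p$prim$nseg)
  par <- 1L
  for (i in seq_len(p$prim$nseg)) {
    rows <- c(rows, list(tibble(parent = par, L = p$prim$L / p$prim$nseg,
                                d = p$prim$d, label = paste0("prim_", i))))
    prim_ids[i] <- nxt; par <- nxt; nxt <- nxt + 1L
  }
  prim_end <- par
  # tuft: several thin branches off the primary so glomerular input is
  # distributed rather than concentrated on one cable
  tuft_ids <- integer(0); tuft_branch <- integer(0)
  for (b in seq_len(p$tuft$n_branch)) {
    par <- prim_end
    for (i in seq_len(p$tuft$br_nseg)) {
      rows <- c(rows, list(tibble(parent = par, L = p$tuft$seg_len,
                                  d = p$tuft$d,
                                  label = paste0("tuft", b, "_", i))))
      tuft_ids <- c(tuft_ids, nxt); tuft_branch <- c(tuft_branch, b)
      par <- nxt; nxt <- nxt + 1L
    }
  }
  lat_ids <- vector("list", n_lateral)
  for (j in seq_len(n_lateral)) {
    par <- 1L
    ids <- integer(p$lat$nseg)
    for (i in seq_len(p$lat$nseg)) {
      rows <- c(rows, list(tibble(parent = par, L = p$lat$L / p$lat$nseg,
                                  d = p$lat$d,
                                  label = paste0("lat", j, "_", i))))
      ids[i] <- nxt; par <- nxt; nxt <- nxt + 1L
    }
    lat_ids[[j]] <- ids
  }
  comps <- bind_rows(rows)
  comps$Cm <- p$Cm; comps$Rm <- p$Rm; comps$Ra <- p$Ra; comps$Em <- Em
  ch <- bind_rows(
    .dens_rows(1L, p$dens$soma),
    .dens_rows(iseg_id, p$dens$iseg),
    .dens_rows(prim_ids, p$dens$prim),
    .dens_rows(tuft_ids, p$dens$tuft),
    .dens_rows(unlist(lat_ids), p$dens$lat))
  pools <- tibble(comp = 1L, tau = p$ca$tau, base = p$ca$base, B = p$ca$B)
  m <- cable_model(comps, ch, pools, soma = 1L)
  m$morph <- list(iseg = iseg_id, prim = prim_ids, tuft = tuft_ids,
                  tuft_branch = tuft_branch, lat = lat_ids,
                  seg_len = p$lat$L / p$lat$nseg,
                  prim_len = p$prim$L, lat_len = p$lat$L,
                  soma_d = p$soma$d, lat_d = p$lat$d, prim_d = p$prim$d)
  m
}

#' Measure spike threshold under a slow current ramp
#'
#' Applies a slow depolarising somatic ramp and reports the membrane
#' potential at spike initiation (the voltage at the time the ramp first
#' produces a spike, read just before the fast upstroke), minus the resting
#' potential.
#'
#' @param cell a [cable_model()]
#' @param ramp_rate ramp slope, pA/ms (default 0.1)
#' @param max_I maximum ramp current, nA
#' @param dt time step, ms
#' @return threshold in mV above rest, or the sentinel \code{"no-spike"}
#'   (as \code{NA} with attribute) if the ramp never elicits a spike
#' @export
measure_threshold <- function(cell, ramp_rate = 0.1, max_I = 0.5, dt = 0.025) {
  dur <- max_I * 1000 / ramp_rate  # ms
  inj <- tibble(comp = cell$soma, t0 = 0, t1 = dur, I0 = 0, I1 = max_I)
  out <- integrate_cable(cell, duration = dur, dt = dt, inj = inj,
                         rec_dt = dt)
  rest <- out$v[1, 1]
  if (!length(out$spikes)) {
    res <- NA_real_
    attr(res, "sentinel") <- "no-spike"
    return(res)
  }
  t1 <- out$spikes[1]
  # threshold: voltage where dV/dt first exceeds 10 mV/ms before first spike
  idx <- which(out$time <= t1)
  v <- out$v[idx, 1]
  dv <- c(0, diff(v)) / dt
  th_i <- which(dv > 10)[1]
  if (is.na(th_i)) th_i <- length(v)
  unname(v[th_i] - rest)
}

#' Somatic membrane time constant from a hyperpolarising step
#'
#' Injects a small step (default -100 pA, 500 ms), fits a single exponential
#' to the charging transient (discarding the first 5 ms dominated by fast
#' equalising components) and returns the fitted time constant.
#'
#' @param cell a [cable_model()]
#' @param I step amplitude, nA
#' @param duration step length, ms
#' @param skip initial window to exclude from the fit, ms
#' @return fitted membrane time constant, ms
#' @export
measure_tau_m <- function(cell, I = -0.1, duration = 500, skip = 5) {
  inj <- tibble(comp = cell$soma, t0 = 0, t1 = duration, I0 = I, I1 = I)
  out <- integrate_cable(cell, duration = duration, dt = 0.05, inj = inj,
                         rec_dt = 0.5)
  v <- out$v[, 1]; t <- out$time
  keep <- t >= skip
  v <- v[keep]; t <- t[keep]
  vinf <- tail(v, 1); v0 <- v[1]
  # linearised exponential fit on log(v - vinf)
  dvr <- (v - vinf) / (v0 - vinf)
  ok <- dvr > 0.02
  fit <- lm(log(dvr[ok]) ~ t[ok])
  -1 / unname(coef(fit)[2])
}

#' Firing rate versus injected current
#'
#' @param cell a [cable_model()]
#' @param currents injected currents, nA
#' @param duration injection window, ms (>= 400)
#' @param settle settling time before the injection, ms
#' @param dt time step, ms
#' @return tibble with \code{I} (nA) and \code{rate} (Hz)
#' @export
measure_fI <- function(cell, currents, duration = 400, settle = 100,
                       dt = 0.025) {
  stopifnot(duration >= 400)
  rates <- vapply(currents, function(I) {
    inj <- tibble(comp = cell$soma, t0 = settle, t1 = settle + duration,
                  I0 = I, I1 = I)
    out <- integrate_cable(cell, duration = settle + duration, dt = dt,
                           inj = inj, rec_dt = 1)
    sum(out$spikes >= settle & out$spikes < settle + duration) /
      (duration / 1000)
  }, 0)
  tibble(I = currents, rate = rates)
}

#' Sample heterogeneous leak reversal potentials
#'
#' Granule-cell leak reversals are spread normally with SD 2.25 mV truncated
#' at 6 SD; PG reversals with SD 3 mV truncated at 8 SD.
#'
#' @param n number of cells
#' @param mean mean leak reversal, mV
#' @param type \code{"granule"} or \code{"pg"}
#' @export
sample_leak_reversals <- function(n, mean = -65, type = c("granule", "pg")) {
  type <- match.arg(type)
  sdv <- if (type == "granule") 2.25 else 3
  lim <- if (type == "granule") 6 else 8
  x <- rnorm(n, 0, sdv)
  while (any(bad <- abs(x) > lim * sdv))
    x[bad] <- rnorm(sum(bad), 0, sdv)
  mean + x
}
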