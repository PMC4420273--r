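# Synaptic conductance models, delays, weight spread, and distance scaling.
#
# All synapses are dual-exponential conductances
#   g(t) = A * gmax * (exp(-t/tau1) - exp(-t/tau2)) / (tau1 - tau2)
# with A chosen so the peak equals gmax; tau1 = tau2 is the alpha-function
# limit gmax * (t/tau) * exp(1 - t/tau).  Excitatory reversal 0 mV,
# inhibitory -78 mV.  Delays: ORN input 0 ms, excitatory 1.8 ms, inhibitory
# 0.6 ms; mitral->PG delays uniform 0-40 ms, PG-|mitral exponential mean
# 160 ms, aggregated-granule synapses exponential with SD 160 ms.

E_EXC <- 0
E_INH <- -78

#' Dual-exponential synaptic conductance
#'
#' Peak-normalised: the maximum over time equals \code{gmax} exactly, attained
#' at \code{t* = tau1*tau2*log(tau1/tau2)/(tau1 - tau2)}.  Negative times give
#' zero.  Equal time constants are handled as the alpha-function limit.
#'
#' @param t time since event, ms (vectorised)
#' @param gmax peak conductance, nS
#' @param tau1,tau2 time constants, ms
#' @return conductance, nS
#' @export
dual_exp_g <- function(t, gmax, tau1, tau2) {
  g <- numeric(length(t))
  pos <- t >= 0
  if (!any(pos)) return(g)
  tp <- t[pos]
  if (abs(tau1 - tau2) < 1e-9 * max(tau1, tau2)) {
    tau <- (tau1 + tau2) / 2
    g[pos] <- gmax * (tp / tau) * exp(1 - tp / tau)
  } else {
    raw <- exp(-tp / tau1) - exp(-tp / tau2)
    tstar <- tau1 * tau2 * log(tau1 / tau2) / (tau1 - tau2)
    peak <- exp(-tstar / tau1) - exp(-tstar / tau2)
    g[pos] <- gmax * raw / peak
  }
  g
}

#' Peak time of the dual-exponential
#' @inheritParams dual_exp_g
#' @export
dualexp_peak_time <- function(tau1, tau2) {
  ifelse(abs(tau1 - tau2) < 1e-9 * pmax(tau1, tau2),
         (tau1 + tau2) / 2,
         tau1 * tau2 * log(tau1 / tau2) / (tau1 - tau2))
}

# Engine event weight giving peak conductance gmax (nS -> S).  The engine's
# unit impulse response is (exp(-t/taud) - exp(-t/taur)) / (1/taur - 1/taud)
# (cascade form), so we divide gmax by its peak.
dualexp_event_weight <- function(gmax_nS, tau1, tau2) {
  if (!length(gmax_nS)) return(numeric())
  taur <- pmin(tau1, tau2) / 1000
  taud <- pmax(tau1, tau2) / 1000
  eq <- abs(taur - taud) < 1e-9 * taud
  peak <- ifelse(eq, taur * exp(-1),
                 {
                   tstar <- ifelse(eq, taur, taur * taud * log(taud / taur) /
                                             (taud - taur))
                   (exp(-tstar / taud) - exp(-tstar / taur)) /
                     (1 / taur - 1 / taud)
                 })
  gmax_nS * 1e-9 / peak
}

#' Jahr-Stevens magnesium block of the NMDA conductance
#'
#' Sigmoidal voltage dependence \code{1/(1 + [Mg]/3.57 * exp(-0.062 V))} with
#' extracellular magnesium in mM (default 1 mM).  Monotone increasing in V.
#'
#' @param V membrane potential, mV (vectorised)
#' @param mg extracellular magnesium, mM
#' @export
mg_block <- function(V, mg = 1) {
  1 / (1 + (mg / 3.57) * exp(-0.062 * V))
}

#' NMDA conductance at time t and voltage V
#'
#' Dual-exponential envelope (tau1 = 25 ms, tau2 = 200 ms by convention of the
#' mitral-to-granule synapse) multiplied by the magnesium block.
#'
#' @inheritParams dual_exp_g
#' @param V membrane potential, mV
#' @param mg extracellular magnesium, mM
#' @export
nmda_g <- function(t, gmax, V, tau1 = 25, tau2 = 200, mg = 1) {
  dual_exp_g(t, gmax, tau1, tau2) * mg_block(V, mg)
}

#' Distance-dependent scaling of granule-to-mitral inhibition
#'
#' Exponential decay with length constant 100 um along the primary dendrite
#' and 150 um along secondary (lateral) dendrites, additionally scaled by the
#' local/somatic diameter ratio.
#'
#' @param x path distance from the soma, um (vectorised, >= 0)
#' @param dendrite \code{"primary"} or \code{"secondary"}
#' @param diameter_ratio local diameter over somatic diameter
#' @return multiplier in (0, 1]
#' @export
distance_decay <- function(x, dendrite = c("primary", "secondary"),
                           diameter_ratio = 1) {
  dendrite <- match.arg(dendrite)
  stopifnot(all(x >= 0))
  lambda <- if (dendrite == "primary") 100 else 150
  exp(-x / lambda) * diameter_ratio
}

#' Synaptic delays by connection kind
#'
#' Fixed delays for the standard kinds (ORN input 0 ms, excitatory 1.8 ms,
#' inhibitory 0.6 ms); mitral->PG delays uniform on 0-40 ms; PG-|mitral
#' static latencies exponential with mean 160 ms; aggregated-granule synapse
#' delays exponential with SD (= mean) 160 ms.
#'
#' @param kind one of \code{"orn"}, \code{"excitatory"}, \code{"inhibitory"},
#'   \code{"mitral_to_pg"}, \code{"pg_to_mitral"}, \code{"aggregated"}
#' @param n number of delays to draw
#' @return delays in ms
#' @export
assign_delays <- function(kind, n = 1) {
  switch(kind,
    orn = rep(0, n),
    excitatory = rep(1.8, n),
    inhibitory = rep(0.6, n),
    mitral_to_pg = runif(n, 0, 40),
    pg_to_mitral = 0.6 + rexp(n, rate = 1 / 160),
    aggregated = 0.6 + rexp(n, rate = 1 / 160),
    stop("unknown delay kind: ", kind, call. = FALSE))
}

#' Log-normal synaptic weight spread
#'
#' Samples weights log-normally around a putative mean with a relative
#' standard deviation of 25%.
#'
#' @param mean putative mean conductance, nS (vectorised)
#' @param n number of draws (ignored if \code{mean} has length > 1)
#' @param rel_sd relative standard deviation (default 0.25)
#' @export
sample_weights <- function(mean, n = length(mean), rel_sd = 0.25) {
  if (length(mean) == 1) mean <- rep(mean, n)
  sig2 <- log(1 + rel_sd^2)
  mu <- log(mean) - sig2 / 2
  rlnorm(length(mean), meanlog = mu, sdlog = sqrt(sig2))
}

#' Reference synaptic parameters
#'
#' The glomerular and dendro-dendritic synapse constants used throughout the
#' model: peak conductances, dual-exponential time constants, reversals and
#' delay kinds, one row per synapse class.
#'
#' @return tibble with columns \code{kind, gmax, tau1, tau2, E, delay_kind,
#'   nmda}
#' @export
synapse_params <- function() {
  tibble(
    kind = c("orn_mitral", "orn_pg_plateau", "orn_pg_lts",
             "mitral_pg_plateau", "mitral_pg_lts", "pg_mitral",
             "mitral_granule_ampa", "mitral_granule_nmda",
             "granule_mitral", "granule_mitral_directed", "auto_inhib",
             "background_granule_ampa", "background_granule_nmda"),
    gmax = c(6, 0.45, 1.25, 0.45, 1.25, 1, 0.2, 0.2 * 0.26,
             1, 1.5, 0.005, 0.2, 0.2 * 0.26),
    tau1 = c(1, 1, 1, 1, 1, 1, 1, 25, 1, 1, 1, 1, 25),
    tau2 = c(1, 1, 1, 1, 1, 1, 4, 200, 20, 20, 20, 4, 200),
    E = c(E_EXC, E_EXC, E_EXC, E_EXC, E_EXC, E_INH, E_EXC, E_EXC,
          E_INH, E_INH, E_INH, E_EXC, E_EXC),
    delay_kind = c("orn", "orn", "orn", "mitral_to_pg", "mitral_to_pg",
                   "pg_to_mitral", "excitatory", "excitatory",
                   "inhibitory", "inhibitory", "inhibitory", "orn", "orn"),
    nmda = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
             FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}
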