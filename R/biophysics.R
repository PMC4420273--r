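# Gating kinetics, calcium dynamics, and the compartmental cable interface.
#
# Interface units: mV, ms, nA, nS, um, mM.  The C++ engine works in SI; the
# wrappers here convert.  Kinetics are evaluated at T = 35 C throughout.

TEMP_C <- 35

#' Singularity-safe linoid rate function
#'
#' Rate function of the form \code{a*(V - th) / (1 - exp(-(V - th)/q))} with a
#' temperature factor \code{2^((T - 24)/10)}, used by the sodium channel rate
#' constants of the mitral initial-segment and granule/PG sodium channels.
#' At the removable singularity \code{V = th} the analytic limit
#' \code{a*q*2^((T-24)/10)} is returned; the guard band is |V - th| <= 1e-3 mV
#' (1 uV).
#'
#' @param V membrane potential, mV (vectorised)
#' @param th half-activation offset, mV
#' @param a rate slope, 1/(s*V)
#' @param q slope factor, mV
#' @param temperature temperature in degrees C (default 35)
#' @return rate in 1/s
#' @export
trap <- function(V, th, a, q, temperature = TEMP_C) {
  stopifnot(q != 0)
  qfac <- 2^((temperature - 24) / 10)
  x <- (V - th) / 1000  # V
  qv <- q / 1000
  out <- ifelse(abs(V - th) <= 1e-3,
                a * qv,
                a * x / (1 - exp(-x / qv)))
  out * qfac
}

# internal channel registry ---------------------------------------------------
# type ids must match src/engine.cpp
.channel_types <- c(
  Na_mit_usb = 0L, K2_mit_usb = 1L, K_mit_usb = 2L, LCa3_mit_usb = 3L,
  KA_bsg_yka = 4L, Kca_mit_usb = 5L, Na_mit_initialsegment_MS = 6L,
  Na_rat_ms = 7L, KA_ms = 8L, TCa_d = 9L, Ih_cb = 10L, Kca_mit_usb_pg = 5L
)

.channel_defaults <- list(
  # name = list(E_mV, gates = n, powers)
  Na_mit_usb = list(E = 50, kd = 0),
  K2_mit_usb = list(E = -70, kd = 0),
  K_mit_usb = list(E = -70, kd = 0),
  LCa3_mit_usb = list(E = 70, kd = 0),
  KA_bsg_yka = list(E = -70, kd = 0),
  Kca_mit_usb = list(E = -70, kd = 0.015),
  Na_mit_initialsegment_MS = list(E = 50, kd = 0),
  Na_rat_ms = list(E = 60, kd = 0),
  KA_ms = list(E = -90, kd = 0),
  TCa_d = list(E = 120, kd = 0),
  Ih_cb = list(E = -30, kd = 0),
  Kca_mit_usb_pg = list(E = -80, kd = 0.0055)
)

#' Channel gate kinetics
#'
#' Returns the gating-variable descriptions of a named channel: for each gate,
#' a steady-state function of voltage, a time-constant function of voltage,
#' and the gate exponent.  Printed kinetic rows (the initial-segment and
#' granule/PG sodium channels, the granule A-type channel, the PG low-threshold
#' calcium and h-current channels) follow their published closed forms at
#' 35 C; the remaining channels of the mitral-cell family are re-derived
#' externally-sourced rate functions, calibrated downstream against stated
#' physiological targets.
#'
#' @param channel channel name, e.g. \code{"KA_ms"}
#' @return list of gates; each gate has \code{steady_state(V_mV)},
#'   \code{time_constant(V_mV)} (ms), and \code{exponent}
#' @export
channel_gates <- function(channel) {
  if (!channel %in% names(.channel_types))
    stop("unknown channel name: ", channel, call. = FALSE)
  type <- .channel_types[[channel]]
  ng <- if (type %in% c(2L, 3L, 5L, 10L)) 1L else 2L
  powers <- switch(as.character(type),
    "0" = c(3L, 1L), "1" = c(2L, 1L), "2" = 2L, "3" = 1L,
    "4" = c(1L, 1L), "5" = 1L, "6" = c(3L, 1L), "7" = c(3L, 1L),
    "8" = c(1L, 1L), "9" = c(2L, 1L), "10" = 1L)
  lapply(seq_len(ng), function(g) {
    structure(list(
      steady_state = function(V) {
        tab <- .engine_gate_table(type, V / 1000)
        tab[[g]]$inf
      },
      time_constant = function(V) {
        tab <- .engine_gate_table(type, V / 1000)
        tab[[g]]$tau * 1000
      },
      exponent = powers[[g]],
      channel = channel,
      gate = g
    ), class = "gate_kinetics")
  })
}

#' Evaluate a gate at a voltage
#'
#' @param kin a gate from [channel_gates()]
#' @param V membrane potential, mV
#' @return named vector \code{c(inf = ..., tau_ms = ...)}
#' @export
evaluate_gate <- function(kin, V) {
  stopifnot(inherits(kin, "gate_kinetics"), is.finite(V))
  c(inf = kin$steady_state(V), tau_ms = kin$time_constant(V))
}

#' Calcium-dependence factor of the Ca-activated K channel
#'
#' Saturating dependence \code{Ca/(Ca + Kd)}, half-maximal at 0.015 mM for the
#' mitral variant and at 0.0055 mM for the PG variant.
#'
#' @param Ca calcium concentration, mM (vectorised, must be >= 0)
#' @param variant \code{"mitral"} or \code{"pg"}
#' @return activation factor in [0, 1]
#' @export
kca_activation <- function(Ca, variant = c("mitral", "pg")) {
  variant <- match.arg(variant)
  if (any(Ca < 0)) stop("negative calcium concentration", call. = FALSE)
  kd <- if (variant == "pg") 0.0055 else 0.015
  Ca / (Ca + kd)
}

#' Create a single-pool calcium buffer
#'
#' First-order pool: \code{dCa/dt = B*I_Ca - (Ca - base)/tau}.
#'
#' @param baseline resting concentration, mM
#' @param influx_scale B, mM per nA per ms
#' @param decay_time tau, ms
#' @param concentration initial concentration, mM (default baseline)
#' @export
calcium_pool <- function(baseline = 5e-5, influx_scale = 0.1,
                         decay_time = 10, concentration = baseline) {
  structure(list(concentration = concentration, baseline = baseline,
                 influx_scale = influx_scale, decay_time = decay_time),
            class = "calcium_pool")
}

#' Advance a calcium pool by one step
#'
#' Exact exponential update of the linear pool ODE over \code{dt} under a
#' constant calcium current; the steady state under constant current is
#' \code{baseline + influx_scale * I_Ca * decay_time}.
#'
#' @param pool a [calcium_pool()]
#' @param I_Ca calcium current, nA (inward positive)
#' @param dt time step, ms
#' @export
step_calcium <- function(pool, I_Ca, dt) {
  stopifnot(dt > 0)
  ss <- pool$baseline + pool$influx_scale * I_Ca * pool$decay_time
  e <- exp(-dt / pool$decay_time)
  pool$concentration <- max(0, ss + (pool$concentration - ss) * e)
  pool
}

# cable model ------------------------------------------------------------------

#' Construct a compartmental cable model
#'
#' @param comps tibble with one row per compartment: \code{parent} (0 for the
#'   root), \code{L} and \code{d} (um), \code{Cm} (F/m^2), \code{Rm} (ohm m^2),
#'   \code{Ra} (ohm m), \code{Em} (mV), and a \code{label}
#' @param channels tibble: \code{comp}, \code{channel} (registry name),
#'   \code{gbar} (S/m^2), optional \code{E} (mV) and \code{kd} (mM) overrides
#' @param pools tibble: \code{comp}, \code{tau} (ms), \code{base} (mM),
#'   \code{B} (mM per nA per ms)
#' @param soma index of the somatic compartment (spike detection site)
#' @return object of class \code{cable_model}
#' @export
cable_model <- function(comps, channels = NULL, pools = NULL, soma = 1L) {
  comps <- as_tibble(comps)
  stopifnot(all(c("parent", "L", "d", "Cm", "Rm", "Ra", "Em") %in% names(comps)))
  if (!"label" %in% names(comps)) comps$label <- paste0("comp", seq_len(nrow(comps)))
  if (any(comps$L <= 0) || any(comps$d <= 0))
    stop("compartment length and diameter must be positive", call. = FALSE)
  p <- comps$parent
  if (sum(p == 0) != 1) stop("exactly one root compartment required", call. = FALSE)
  if (any(p >= seq_len(nrow(comps)) & p != 0))
    stop("compartments must be ordered parent-before-child", call. = FALSE)
  if (is.null(channels))
    channels <- tibble(comp = integer(), channel = character(), gbar = numeric())
  channels <- as_tibble(channels)
  if (!nrow(channels)) {
    channels$E <- numeric()
    channels$kd <- numeric()
  } else {
    bad <- setdiff(channels$channel, names(.channel_types))
    if (length(bad)) stop("unknown channel name: ", bad[1], call. = FALSE)
    if (!"E" %in% names(channels))
      channels$E <- vapply(channels$channel, function(ch) .channel_defaults[[ch]]$E, 0)
    if (!"kd" %in% names(channels))
      channels$kd <- vapply(channels$channel, function(ch) .channel_defaults[[ch]]$kd, 0)
    channels$E <- ifelse(is.na(channels$E),
                         vapply(channels$channel, function(ch) .channel_defaults[[ch]]$E, 0),
                         channels$E)
  }
  if (is.null(pools))
    pools <- tibble(comp = integer(), tau = numeric(), base = numeric(), B = numeric())
  structure(list(comps = comps, channels = as_tibble(channels),
                 pools = as_tibble(pools), soma = as.integer(soma)),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat("<cable_model> ", nrow(x$comps), " compartments, ",
      nrow(x$channels), " channel instances, soma = ",
      x$comps$label[x$soma], "\n", sep = "")
  invisible(x)
}

# flatten one cable model into engine arrays (internal)
.flatten_cell <- function(model) {
  cm <- model$comps
  list(parent = as.integer(cm$parent - 1L),
       L = cm$L * 1e-6, d = cm$d * 1e-6,
       Cm = cm$Cm, Rm = cm$Rm, Ra = cm$Ra, Em = cm$Em / 1000,
       chan_comp = as.integer(model$channels$comp - 1L),
       chan_type = unname(.channel_types[model$channels$channel]),
       chan_gbar = model$channels$gbar,
       chan_E = model$channels$E / 1000,
       chan_kd = model$channels$kd,
       pool_comp = as.integer(model$pools$comp - 1L),
       pool_tau = model$pools$tau / 1000,
       pool_base = model$pools$base,
       pool_B = model$pools$B * 1e9 * 1e3,  # mM/(nA ms) -> mM/(A s)
       soma = model$soma - 1L)
}

#' Integrate a single cable model
#'
#' Implicit (backward-Euler by default, Hines-ordered) integration of the
#' voltage tree with exponential-Euler gate updates.  Spike times are upward
#' crossings of 0 mV at the soma with a 1 ms refractory.
#'
#' @param model a [cable_model()]
#' @param duration simulation length, ms
#' @param dt time step, ms (default 0.025)
#' @param inj current injections: tibble \code{comp, t0, t1, I0, I1} (ms, nA);
#'   current ramps linearly from I0 at t0 to I1 at t1
#' @param synapses synapse table: tibble \code{comp, gmax} (nS), \code{tau1},
#'   \code{tau2} (ms), \code{E} (mV), \code{nmda} (logical)
#' @param events synaptic events: tibble \code{syn} (row of \code{synapses}),
#'   \code{time} (ms), optional \code{scale}
#' @param record compartments to record (default soma)
#' @param rec_dt recording interval, ms
#' @param theta implicitness (1 = backward Euler, 0.5 = Crank-Nicolson)
#' @param debug_gates also return the min/max of all gate variables
#' @return list with \code{time} (ms), \code{v} (mV matrix, one column per
#'   recorded compartment), \code{spikes} (ms)
#' @export
integrate_cable <- function(model, duration, dt = 0.025, inj = NULL,
                            synapses = NULL, events = NULL,
                            record = NULL, rec_dt = 0.5,
                            theta = 1.0, debug_gates = FALSE) {
  stopifnot(inherits(model, "cable_model"), duration > 0, dt > 0)
  fl <- .flatten_cell(model)
  if (is.null(record)) record <- model$soma
  if (is.null(synapses))
    synapses <- tibble(comp = integer(), gmax = numeric(), tau1 = numeric(),
                       tau2 = numeric(), E = numeric(), nmda = logical())
  synapses <- as_tibble(synapses)
  if (!"nmda" %in% names(synapses)) synapses$nmda <- FALSE
  wnorm <- dualexp_event_weight(synapses$gmax, synapses$tau1, synapses$tau2)
  if (is.null(events)) events <- tibble(syn = integer(), time = numeric())
  events <- as_tibble(events)
  if (!"scale" %in% names(events)) events$scale <- 1
  events <- events[order(events$time), ]
  net <- list(parent = fl$parent, cell = rep(0L, length(fl$parent)),
              L = fl$L, d = fl$d, Cm = fl$Cm, Rm = fl$Rm, Ra = fl$Ra,
              Em = fl$Em, soma_comp = fl$soma,
              chan_comp = fl$chan_comp, chan_type = fl$chan_type,
              chan_gbar = fl$chan_gbar, chan_E = fl$chan_E,
              chan_kd = fl$chan_kd,
              pool_comp = fl$pool_comp, pool_tau = fl$pool_tau,
              pool_base = fl$pool_base, pool_B = fl$pool_B,
              syn_comp = as.integer(synapses$comp - 1L),
              syn_taur = pmin(synapses$tau1, synapses$tau2) / 1000,
              syn_taud = pmax(synapses$tau1, synapses$tau2) / 1000,
              syn_E = synapses$E / 1000,
              syn_nmda = as.integer(synapses$nmda),
              conn_src_cell = integer(), conn_pool = integer(),
              conn_w = numeric(), conn_delay = numeric(),
              n_cells = 1L, mg_mM = 1.0)
  if (is.null(inj))
    inj <- tibble(comp = integer(), t0 = numeric(), t1 = numeric(),
                  I0 = numeric(), I1 = numeric())
  stim <- list(time = events$time / 1000,
               pool = as.integer(events$syn - 1L),
               w = wnorm[events$syn] * events$scale,
               inj_comp = as.integer(inj$comp - 1L),
               inj_t0 = inj$t0 / 1000, inj_t1 = inj$t1 / 1000,
               inj_I0 = inj$I0 * 1e-9, inj_I1 = inj$I1 * 1e-9)
  out <- .engine_run(net, stim, duration / 1000, dt / 1000,
                     as.integer(record - 1L), rec_dt / 1000,
                     0.0, 1e-3, debug_gates, theta)
  res <- list(time = out$time * 1000,
              v = out$v * 1000,
              spikes = out$spike_t * 1000)
  colnames(res$v) <- model$comps$label[record]
  if (debug_gates) {
    res$gate_min <- out$gate_min
    res$gate_max <- out$gate_max
  }
  res
}
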