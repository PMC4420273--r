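# Orchestrated replications of the simulated experiments: nerve shock,
# activity-dependent inhibition in vitro (slice) and in vivo, pulse-train
# linearity, freely-breathing respiration responses, and scaled pulses.
#
# An "instance" bundles one network with one set of per-glomerulus ORN
# kernels (air + two odors), the analogue of one animal; the same kernels
# serve the pulse-train (tracheotomized) and respiration (freely-breathing)
# protocols.

# Input-strength calibration: multiplier on the ORN->mitral conductance
# that brings freely-breathing mean central-mitral rates to ~14 Hz for
# odor at 1% saturated vapor and ~8 Hz for air (frozen from the scripted
# calibration).
ORN_MITRAL_GAIN <- 0.7

# Inhibitory-strength calibration: multiplier on granule/PG/auto-inhibitory
# conductances onto mitral cells so that unitary IPSP amplitudes match the
# parent model's simulated values (~-0.9 mV proximal granule-|mitral,
# ~-0.2 mV PG-|mitral) on the reduced morphology.
GABA_MITRAL_GAIN <- 0.15

#' Create a simulation instance (network + ORN kernels)
#'
#' @param seed instance seed (drives connectivity and kernel draws)
#' @param scheme connectivity scheme
#' @param n_lateral lateral glomeruli
#' @param opts network size overrides (fixtures)
#' @param compile compile for simulation (default TRUE)
#' @param ... passed to [build_network()]
#' @return list: \code{net}, \code{cmp} (compiled, or NULL),
#'   \code{kernels}: per glomerulus a list \code{air}, \code{odorA},
#'   \code{odorB}
#' @export
make_instance <- function(seed, scheme = "default", n_lateral = 2,
                          opts = list(), compile = TRUE, ...) {
  net <- build_network(scheme, n_lateral = n_lateral, seed = seed,
                       opts = opts, ...)
  net <- aggregate_singles(net)
  set.seed(seed + 500009L)
  kernels <- lapply(seq_len(n_lateral + 1), function(g)
    list(air = make_orn_kernel("air"),
         odorA = make_orn_kernel("odor"),
         odorB = make_orn_kernel("odor")))
  names(kernels) <- as.character(seq_len(n_lateral + 1))
  cmp <- if (compile) compile_network(net) else NULL
  list(net = net, cmp = cmp, kernels = kernels, seed = seed)
}

# per-glomerulus ORN rate series for a freely-breathing stimulus
.fb_rates <- function(inst, stimulus, duration_ms, conc = 1,
                      nonlinearity = "none") {
  tt <- seq(0, duration_ms - 1, by = 1)
  resp <- respiration(tt)
  lapply(inst$kernels, function(ks) {
    odor <- switch(stimulus,
      air = NULL,
      odorA = resp * conc,
      odorB = resp * conc,
      morph = resp * conc)
    okern <- switch(stimulus,
      air = ks$odorA,  # unused when odor series is NULL
      odorA = ks$odorA, odorB = ks$odorB, morph = ks$odorA)
    rate_from_stimulus(odor_series = odor, air_series = resp,
                       odor_kernel = okern, air_kernel = ks$air,
                       nonlinearity = nonlinearity)
  })
}

#' Olfactory-nerve shock protocol
#'
#' Activates a fraction of the ORN synapses of mitral cell A's glomerulus
#' over 4 ms (weak: 33/400 mitral, 4/50 per PG; strong: 66/400, 8/50) and
#' records voltage at the soma, the tuft base (primary-dendrite end) and a
#' tuft branch.  The initiation site is read from the order in which the
#' full-height action potential (threshold +20 mV, above the synaptic
#' envelope) appears at the soma versus the tuft.
#'
#' @param inst an instance from [make_instance()] (any scheme; uses mitral
#'   cell 1's glomerulus)
#' @param strength \code{"weak"} or \code{"strong"}
#' @param seed trial seed
#' @param t_shock shock onset, ms
#' @return list: \code{traces} (tibble t, site, v), \code{onset} (named
#'   times of +20 mV crossing), \code{initiation} ("soma" or "tuft")
#' @export
run_nerve_shock <- function(inst, strength = c("weak", "strong"), seed = 1,
                            t_shock = 100) {
  strength <- match.arg(strength)
  cmp <- inst$cmp
  set.seed(seed)
  o <- inst$net$opts
  n_mit_syn <- if (strength == "weak") ceiling(o$orn_per_mitral * 33 / 400)
    else ceiling(o$orn_per_mitral * 66 / 400)
  n_pg_syn <- if (strength == "weak") ceiling(o$orn_per_pg * 4 / 50)
    else ceiling(o$orn_per_pg * 8 / 50)
  glomA <- inst$net$mitral$glom[1]
  ext <- cmp$ext
  # mitral A's ORN synapses
  mit_syn <- which(ext$kind == "orn_mitral" & ext$cell == 1L)
  pick_m <- sample(mit_syn, min(n_mit_syn, length(mit_syn)))
  # per-PG ORN synapses of the same glomerulus
  pg_rows <- ext[ext$kind == "orn_pg" & ext$glom == glomA, ]
  pick_p <- unlist(lapply(split(seq_len(nrow(pg_rows)), pg_rows$cell),
                          function(ix) sample(ix, min(n_pg_syn, length(ix)))))
  ev <- tibble(
    pool = c(ext$pool[pick_m], pg_rows$pool[pick_p]),
    time = t_shock + runif(length(pick_m) + length(pick_p), 0, 4),
    w = c(ext$w_eng[pick_m], pg_rows$w_eng[pick_p]))
  m <- cmp$models[[1]]
  rec <- tibble(cell = 1L,
                comp = c(1L, m$morph$prim[length(m$morph$prim)],
                         m$morph$tuft[2]))
  res <- simulate_network(cmp, t_shock + 60, orn_rates = list(),
                          background = "none", record = rec, seed = seed,
                          rec_dt = 0.05, events = ev)
  sites <- c("soma", "tuft_base", "tuft")
  colnames(res$v) <- sites
  onset <- apply(res$v, 2, function(v) {
    i <- which(v > 20)[1]
    if (is.na(i)) NA_real_ else res$time[i]
  })
  traces <- as_tibble(res$v) %>%
    mutate(t = res$time) %>%
    tidyr::pivot_longer(-"t", names_to = "site", values_to = "v")
  initiation <- if (is.na(onset["tuft"]) ||
                    (!is.na(onset["soma"]) && onset["soma"] < onset["tuft"]))
    "soma" else "tuft"
  list(traces = traces, onset = onset, initiation = initiation)
}

#' Activity-dependent inhibition in vitro (slice)
#'
#' Paired f-I curves of mitral cell A with and without simultaneous 1.2 nA
#' injection into mitral cell B (50 um apart in a slice), across network
#' seeds; the most-inhibiting half of the pairs is selected and the mean
#' rate reduction is reported against A's control rate.
#'
#' @param currents_A somatic currents for A, nA
#' @param I_B current in B, nA (default 1.2)
#' @param n_seeds number of slice instances (default 10)
#' @param n_select most-inhibiting pairs kept (default half)
#' @param inj_ms injection duration (400 ms, starting at 250 ms; B starts
#'   5 ms earlier)
#' @param opts network size overrides
#' @param base_seed first instance seed
#' @return list: \code{curves} (tibble seed, I, rate_alone, rate_with_B),
#'   \code{selected} seeds, \code{summary} (tibble rate_alone bins vs mean
#'   reduction)
#' @export
run_adi_invitro <- function(currents_A = seq(0.25, 1.5, by = 0.25),
                            I_B = 1.2, n_seeds = 10, n_select = 5,
                            inj_ms = 400, opts = list(), base_seed = 1) {
  res <- purrr::map_dfr(seq_len(n_seeds), function(s) {
    seed <- base_seed + s - 1
    net <- build_network("default", n_lateral = 1, seed = seed,
                         separations = 50, two_mitral = TRUE, opts = opts)
    net <- make_slice(net, separation_um = 50)
    net <- aggregate_singles(net)
    cmp <- compile_network(net)
    t0 <- 250; t1 <- t0 + inj_ms
    purrr::map_dfr(currents_A, function(I) {
      inj_a <- tibble(cell = 1L, comp = 1L, t0 = t0, t1 = t1, I0 = I, I1 = I)
      inj_b <- tibble(cell = 2L, comp = 1L, t0 = t0 - 5, t1 = t1,
                      I0 = I_B, I1 = I_B)
      r0 <- simulate_network(cmp, t1 + 20, background = "in_vitro",
                             inj = inj_a, seed = seed * 101 + round(I * 100),
                             dt = 0.05)
      r1 <- simulate_network(cmp, t1 + 20, background = "in_vitro",
                             inj = bind_rows(inj_a, inj_b),
                             seed = seed * 101 + round(I * 100),
                             dt = 0.05)
      rate_of <- function(r) sum(r$spikes$cell == 1L &
                                   r$spikes$time >= t0 &
                                   r$spikes$time < t1) / (inj_ms / 1000)
      tibble(seed = seed, I = I, rate_alone = rate_of(r0),
             rate_with_B = rate_of(r1))
    })
  })
  peak_red <- res %>%
    group_by(.data$seed) %>%
    summarise(peak_reduction = max(.data$rate_alone - .data$rate_with_B),
              .groups = "drop")
  selected <- peak_red %>%
    arrange(desc(.data$peak_reduction)) %>%
    slice(seq_len(n_select)) %>%
    pull(.data$seed)
  summary <- res %>%
    filter(.data$seed %in% selected) %>%
    mutate(reduction = .data$rate_with_B - .data$rate_alone) %>%
    group_by(.data$I) %>%
    summarise(rate_alone = mean(.data$rate_alone),
              mean_reduction = mean(.data$reduction),
              sem = sd(.data$reduction) / sqrt(n()), .groups = "drop")
  list(curves = res, selected = selected, summary = summary)
}

#' Activity-dependent inhibition in vivo
#'
#' Two mitral cells A (central) and B (lateral, super-inhibiting A in the
#' default scheme) at a given separation; constant-rate ORN Poisson input
#' replaces current injection, with the 35 Hz in-vivo granule background.
#' A's firing is averaged over a 400 ms window after 100 ms settling, for a
#' range of input rates to A, without and with input to B; the mean
#' point-wise difference between the uninhibited and the 10 Hz-B curves
#' summarises the inhibition.
#'
#' @param scheme connectivity scheme
#' @param separation_um A-B separation
#' @param rates_A ORN input rates to A's glomerulus, Hz
#' @param rates_B ORN rates for B's glomerulus (default 0, 5, 10)
#' @param n_instances instances averaged (default 10)
#' @param direction \code{"B_on_A"} or \code{"A_on_B"} (cells swapped)
#' @param opts,base_seed as elsewhere
#' @param dt integration step, ms
#' @return list: \code{curves} (instance x rate_A x rate_B -> rate),
#'   \code{mean_inhibition} (scalar: mean reduction due to 10 Hz B)
#' @export
run_adi_invivo <- function(scheme = "default", separation_um = 400,
                           rates_A = seq(0, 16, by = 4),
                           rates_B = c(0, 10), n_instances = 10,
                           direction = c("B_on_A", "A_on_B"),
                           opts = list(), base_seed = 1, dt = 0.05) {
  direction <- match.arg(direction)
  probe <- if (direction == "B_on_A") 1L else 2L  # cell whose rate is read
  other <- 3L - probe
  curves <- purrr::map_dfr(seq_len(n_instances), function(s) {
    seed <- base_seed + s - 1
    net <- build_network(scheme, n_lateral = 1, seed = seed,
                         separations = separation_um, two_mitral = TRUE,
                         opts = opts)
    net <- aggregate_singles(net)
    cmp <- compile_network(net)
    glA <- as.character(net$mitral$glom[probe])
    glB <- as.character(net$mitral$glom[other])
    purrr::map_dfr(rates_A, function(ra) purrr::map_dfr(rates_B, function(rb) {
      rates <- setNames(list(ra, rb), c(glA, glB))
      r <- simulate_network(cmp, 500, orn_rates = rates,
                            background = "in_vivo",
                            seed = seed * 7919 + ra * 13 + rb,
                            dt = dt)
      rate <- sum(r$spikes$cell == probe & r$spikes$time >= 100 &
                    r$spikes$time < 500) / 0.4
      tibble(instance = seed, rate_A_in = ra, rate_B_in = rb, rate = rate)
    }))
  })
  mcurve <- curves %>%
    group_by(.data$rate_A_in, .data$rate_B_in) %>%
    summarise(rate = mean(.data$rate), .groups = "drop")
  r0 <- mcurve$rate[mcurve$rate_B_in == 0]
  r10 <- mcurve$rate[mcurve$rate_B_in == max(rates_B)]
  list(curves = curves, mean_curves = mcurve,
       mean_inhibition = mean(r0 - r10))
}

#' Freely-breathing respiration protocol
#'
#' Runs trials of 2 respiratory cycles (0.5 s each) of air or odor drive on
#' an instance, bins the second-cycle response of each central sister into
#' 5 bins, and averages over trials.
#'
#' @param inst instance from [make_instance()]
#' @param stimulus \code{"air"}, \code{"odorA"}, \code{"odorB"}
#' @param conc odor concentration (1 = 1% saturated vapor)
#' @param trials number of trials (default 8)
#' @param cycles respiratory cycles per trial (default 2)
#' @param n_bins bins per cycle (default 5)
#' @param analysis_cycle which cycle is analysed (default 2)
#' @param nonlinearity ORN output non-linearity
#' @param base_seed trial seed offset
#' @param dt integration step, ms (0.05 production; coarser for scaled CI runs)
#' @return list: \code{binned} (tibble sister, trial, bin, rate),
#'   \code{mean_cycle} (sister x bin), \code{mean_rate} (per sister, Hz,
#'   over the analysis cycle), \code{spikes}
#' @export
run_freely_breathing <- function(inst, stimulus = "odorA", conc = 1,
                                 trials = 8, cycles = 2, n_bins = 5,
                                 analysis_cycle = 2,
                                 nonlinearity = "none", base_seed = 1,
                                 dt = 0.05) {
  cmp <- inst$cmp
  period <- 500
  dur <- cycles * period
  rates <- .fb_rates(inst, stimulus, dur, conc, nonlinearity)
  sisters <- which(inst$net$mitral$glom == 1L)
  spikes_all <- list()
  binned <- purrr::map_dfr(seq_len(trials), function(tr) {
    r <- simulate_network(cmp, dur, orn_rates = rates,
                          background = "in_vivo",
                          seed = inst$net$dynamical_seed + base_seed * 6007 +
                            tr, dt = dt)
    spikes_all[[tr]] <<- r$spikes %>% mutate(trial = tr)
    t0 <- (analysis_cycle - 1) * period
    purrr::map_dfr(seq_along(sisters), function(si) {
      st <- r$spikes$time[r$spikes$cell == sisters[si]]
      st <- st[st >= t0 & st < t0 + period] - t0
      sb <- floor(st / (period / n_bins)) + 1L
      counts <- tabulate(sb, nbins = n_bins)
      tibble(sister = si, trial = tr, bin = seq_len(n_bins),
             rate = counts / (period / n_bins / 1000))
    })
  })
  mean_cycle <- binned %>%
    group_by(.data$sister, .data$bin) %>%
    summarise(rate = mean(.data$rate), .groups = "drop")
  mean_rate <- binned %>%
    group_by(.data$sister) %>%
    summarise(rate = mean(.data$rate), .groups = "drop")
  list(binned = binned, mean_cycle = mean_cycle, mean_rate = mean_rate,
       spikes = bind_rows(spikes_all))
}

#' Pulse-train (tracheotomized) linearity protocol
#'
#' Runs m-sequence random pulse-train stimuli: 2 per odor for each of two
#' odors, plus 1 two-odor overlapping pulse train (5 stimuli), with several
#' trials each; central-sister responses are binned at 50 ms and
#' trial-averaged.
#'
#' @param inst instance
#' @param conc pulse concentration (%% saturated vapor)
#' @param trials trials per stimulus (default 9)
#' @param duration_ms stimulus length (default 3500)
#' @param bin_ms bin width (default 50)
#' @param base_seed seed offset
#' @param dt integration step, ms
#' @return list: \code{stimuli} (tibble stim, odor set, concentration
#'   series), \code{responses} (tibble stim, sister, trial, bin, rate),
#'   \code{binned_conc} (per stim, binned concentration series per odor)
#' @export
run_linearity_protocol <- function(inst, conc = 1, trials = 9,
                                   duration_ms = 3500, bin_ms = 50,
                                   base_seed = 1, dt = 0.05) {
  cmp <- inst$cmp
  sisters <- which(inst$net$mitral$glom == 1L)
  set.seed(inst$seed + 77003L + base_seed)
  stim_def <- tibble(
    stim = 1:5,
    odorA_on = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    odorB_on = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  ms_list <- lapply(1:5, function(i)
    list(A = msequence_concentration(conc, duration_ms),
         B = msequence_concentration(conc, duration_ms)))
  n_bins <- duration_ms / bin_ms
  responses <- purrr::map_dfr(1:5, function(si) {
    msA <- ms_list[[si]]$A; msB <- ms_list[[si]]$B
    concA <- if (stim_def$odorA_on[si]) msA$conc else rep(0, duration_ms)
    concB <- if (stim_def$odorB_on[si]) msB$conc else rep(0, duration_ms)
    air <- msA$air
    rates <- lapply(inst$kernels, function(ks) {
      rA <- rate_from_stimulus(odor_series = concA, air_series = air,
                               odor_kernel = ks$odorA, air_kernel = ks$air)
      rB <- rate_from_stimulus(odor_series = concB, air_series = NULL,
                               odor_kernel = ks$odorB, air_kernel = ks$air,
                               baseline = 0)
      tibble(t = rA$t, rate = pmax(rA$rate + rB$rate, 0))
    })
    purrr::map_dfr(seq_len(trials), function(tr) {
      r <- simulate_network(cmp, duration_ms, orn_rates = rates,
                            background = "in_vivo",
                            seed = inst$net$dynamical_seed + base_seed +
                              si * 1009 + tr, dt = dt)
      purrr::map_dfr(seq_along(sisters), function(ss) {
        st <- r$spikes$time[r$spikes$cell == sisters[ss]]
        sb <- floor(st / bin_ms) + 1L
        counts <- tabulate(sb[sb <= n_bins], nbins = n_bins)
        tibble(stim = si, sister = ss, trial = tr, bin = seq_len(n_bins),
               rate = counts / (bin_ms / 1000))
      })
    })
  })
  bin_series <- function(x) {
    colMeans(matrix(x, nrow = bin_ms))
  }
  binned_conc <- purrr::map_dfr(1:5, function(si) {
    tibble(stim = si, bin = seq_len(n_bins),
           concA = if (stim_def$odorA_on[si])
             bin_series(ms_list[[si]]$A$conc) else rep(0, n_bins),
           concB = if (stim_def$odorB_on[si])
             bin_series(ms_list[[si]]$B$conc) else rep(0, n_bins))
  })
  list(stimuli = stim_def, responses = responses, binned_conc = binned_conc,
       bin_ms = bin_ms)
}

#' Scaled-pulse protocol
#'
#' 200 ms odor pulses at a range of concentrations (default 0, 1/3, 2/3, 1,
#' 2, 5 %% saturated vapor), several trials each; responses are binned into
#' 50 ms histograms over 1.7 s after odor onset and the mean air (0%%)
#' response is subtracted.
#'
#' @param inst instance
#' @param concs concentrations (%% saturated vapor)
#' @param trials trials per concentration (default 9)
#' @param pulse_ms pulse duration (default 200)
#' @param onset_ms odor onset (default 300)
#' @param hist_ms histogram length after onset (default 1700)
#' @param bin_ms bin width (default 50)
#' @param base_seed seed offset
#' @param dt integration step, ms
#' @return tibble: \code{cell}, \code{conc}, \code{first_spike} (ms after
#'   onset, trial-averaged), list-column \code{hist} (air-subtracted mean
#'   histogram)
#' @export
run_scaled_pulses <- function(inst, concs = c(0, 1/3, 2/3, 1, 2, 5),
                              trials = 9, pulse_ms = 200, onset_ms = 300,
                              hist_ms = 1700, bin_ms = 50, base_seed = 1,
                              dt = 0.05) {
  cmp <- inst$cmp
  sisters <- which(inst$net$mitral$glom == 1L)
  dur <- onset_ms + hist_ms
  n_bins <- hist_ms / bin_ms
  valve_tau <- 40
  tt <- seq(0, dur - 1)
  pedestal <- max(respiration(seq(0, 499))) / 3
  raw <- purrr::map_dfr(seq_along(concs), function(ci) {
    cc <- concs[ci]
    valve <- as.numeric(tt >= onset_ms & tt < onset_ms + pulse_ms)
    a <- exp(-1 / valve_tau)
    conc_series <- as.numeric(stats::filter(valve * (1 - a), a,
                                            method = "recursive")) * cc
    rates <- lapply(inst$kernels, function(ks)
      rate_from_stimulus(odor_series = conc_series,
                         air_series = rep(pedestal, dur),
                         odor_kernel = ks$odorA, air_kernel = ks$air))
    purrr::map_dfr(seq_len(trials), function(tr) {
      r <- simulate_network(cmp, dur, orn_rates = rates,
                            background = "in_vivo",
                            seed = inst$net$dynamical_seed + base_seed +
                              ci * 333 + tr, dt = dt)
      purrr::map_dfr(seq_along(sisters), function(ss) {
        st <- r$spikes$time[r$spikes$cell == sisters[ss]] - onset_ms
        st <- st[st >= 0 & st < hist_ms]
        sb <- floor(st / bin_ms) + 1L
        tibble(cell = ss, conc = cc, trial = tr,
               first_spike = if (length(st)) min(st) else NA_real_,
               hist = list(tabulate(sb, nbins = n_bins) / (bin_ms / 1000)))
      })
    })
  })
  per <- raw %>%
    group_by(.data$cell, .data$conc) %>%
    summarise(first_spike = mean(.data$first_spike, na.rm = TRUE),
              hist = list(Reduce(`+`, .data$hist) / length(.data$hist)),
              .groups = "drop")
  air <- per %>% filter(.data$conc == 0) %>%
    select("cell", air_hist = "hist")
  per %>%
    left_join(air, by = "cell") %>%
    mutate(hist = purrr::map2(.data$hist, .data$air_hist, `-`)) %>%
    select(-"air_hist")
}
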