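# Assembling a network instance into the C++ engine's flat arrays and
# running trials on it.
#
# compile_network() does the expensive, anatomy-determined part once per
# instance (cell models, receptor pools, spike-triggered connection lists,
# ORN synapse placement); simulate_network() adds trial-specific inputs
# (ORN and background Poisson events, current injections) and integrates.

#' Compile a network instance for simulation
#'
#' Instantiates cell models (mitral cells; shared granule cells and
#' aggregates -- the network must have been through [aggregate_singles()]
#' unless \code{all_granules = TRUE}; connected PG cells), merges synapses
#' into receptor pools, and builds the spike-triggered connection table.
#' Auto-inhibitory 5 pS synapses are created at every reciprocal
#' mitral-granule site, merged per compartment, and triggered by the host
#' mitral cell's own spike.
#'
#' @param net a [build_network()] (+ [aggregate_singles()]) result
#' @param all_granules keep singly-connected granules as individual cells
#'   (only sensible for small fixture networks)
#' @param orn_gain multiplier on the ORN-to-mitral conductance; the default
#'   is the documented input-strength calibration that brings the
#'   freely-breathing mean mitral rates to ~14 Hz (odor, 1% saturated
#'   vapor) and ~8 Hz (air)
#' @param gaba_gain multiplier on all inhibitory conductances onto mitral
#'   cells; the default matches the simulated unitary IPSP amplitudes of
#'   the parent model (~-0.9 mV proximal granule, ~-0.2 mV PG) on this
#'   reduced morphology, whose input resistance is higher
#' @return a \code{bulbnet_compiled} object
#' @export
compile_network <- function(net, all_granules = FALSE,
                            orn_gain = ORN_MITRAL_GAIN,
                            gaba_gain = GABA_MITRAL_GAIN) {
  stopifnot(inherits(net, "bulbnet_network"))
  if (!net$aggregated && !all_granules)
    stop("network must be aggregated (see aggregate_singles) unless ",
         "all_granules = TRUE", call. = FALSE)
  set.seed(net$seed + 13L)  # structural stream for placement choices below
  sp <- synapse_params()
  prm <- function(kind, col) sp[[col]][sp$kind == kind]

  mits <- net$mitral$mit
  shared_keys <- net$granules$granule_key[net$granules$n_mitral >= 2L]
  if (all_granules) {
    gran_tbl <- net$granules
  } else {
    gran_tbl <- net$granules %>% filter(.data$granule_key %in% shared_keys)
  }
  n_mit <- length(mits)
  n_gran <- nrow(gran_tbl)
  agg_tbl <- if (net$aggregated) net$aggregates else
    tibble(agg_id = character())
  n_agg <- nrow(agg_tbl)
  pg_tbl <- net$pg_cells
  n_pg <- nrow(pg_tbl)

  # global cell ids: mitral, granule, aggregate, pg
  cells <- bind_rows(
    tibble(cell = seq_len(n_mit), type = "mitral",
           key = as.character(mits)),
    tibble(cell = n_mit + seq_len(n_gran), type = "granule",
           key = gran_tbl$granule_key),
    if (n_agg) tibble(cell = n_mit + n_gran + seq_len(n_agg),
                      type = "aggregate", key = agg_tbl$agg_id),
    if (n_pg) tibble(cell = n_mit + n_gran + n_agg + seq_len(n_pg),
                     type = "pg",
                     key = paste0(pg_tbl$glom, ":", pg_tbl$pg)))
  mit_cell <- setNames(seq_len(n_mit), as.character(mits))
  gran_cell <- setNames(n_mit + seq_len(n_gran), gran_tbl$granule_key)
  agg_cell <- if (n_agg) setNames(n_mit + n_gran + seq_len(n_agg),
                                  agg_tbl$agg_id) else c()
  pg_cell <- if (n_pg) setNames(n_mit + n_gran + n_agg + seq_len(n_pg),
                                paste0(pg_tbl$glom, ":", pg_tbl$pg)) else c()

  # cell models from cached templates (identical anatomy, per-cell Em)
  t_mit <- build_mitral()
  t_gran <- build_granule()
  t_pg <- list(plateauing = build_pg("plateauing"),
               low_threshold_spiking = build_pg("low_threshold_spiking"))
  models <- vector("list", nrow(cells))
  cell_em <- rep(NA_real_, nrow(cells))
  for (i in seq_len(n_mit)) models[[i]] <- t_mit
  gEms <- gran_tbl$Em
  for (i in seq_len(n_gran)) {
    models[[n_mit + i]] <- t_gran; cell_em[n_mit + i] <- gEms[i]
  }
  if (n_agg) {
    agg_em <- sample_leak_reversals(n_agg, granule_params()$Em, "granule")
    for (i in seq_len(n_agg)) {
      models[[n_mit + n_gran + i]] <- t_gran
      cell_em[n_mit + n_gran + i] <- agg_em[i]
    }
  }
  if (n_pg) for (i in seq_len(n_pg)) {
    ci <- n_mit + n_gran + n_agg + i
    models[[ci]] <- t_pg[[pg_tbl$variant[i]]]
    cell_em[ci] <- pg_tbl$Em[i]
  }

  ncomp_per <- vapply(models, function(m) nrow(m$comps), 0L)
  offset <- cumsum(c(0L, ncomp_per))[seq_along(models)]

  fl_t <- list(mitral = .flatten_cell(t_mit),
               granule = .flatten_cell(t_gran),
               plateauing = .flatten_cell(t_pg$plateauing),
               low_threshold_spiking =
                 .flatten_cell(t_pg$low_threshold_spiking))
  fl <- lapply(seq_along(models), function(i) {
    f <- switch(cells$type[i],
                mitral = fl_t$mitral,
                granule = fl_t$granule, aggregate = fl_t$granule,
                pg = fl_t[[pg_tbl$variant[i - n_mit - n_gran - n_agg]]])
    if (!is.na(cell_em[i])) f$Em <- rep(cell_em[i] / 1000, length(f$Em))
    f
  })
  eng <- list(
    parent = unlist(lapply(seq_along(fl), function(i)
      ifelse(fl[[i]]$parent < 0, -1L, fl[[i]]$parent + offset[i]))),
    cell = rep(seq_along(fl) - 1L, ncomp_per),
    L = unlist(lapply(fl, `[[`, "L")),
    d = unlist(lapply(fl, `[[`, "d")),
    Cm = unlist(lapply(fl, `[[`, "Cm")),
    Rm = unlist(lapply(fl, `[[`, "Rm")),
    Ra = unlist(lapply(fl, `[[`, "Ra")),
    Em = unlist(lapply(fl, `[[`, "Em")),
    soma_comp = vapply(seq_along(fl), function(i)
      fl[[i]]$soma + offset[i], 0L),
    chan_comp = unlist(lapply(seq_along(fl), function(i)
      fl[[i]]$chan_comp + offset[i])),
    chan_type = unlist(lapply(fl, `[[`, "chan_type")),
    chan_gbar = unlist(lapply(fl, `[[`, "chan_gbar")),
    chan_E = unlist(lapply(fl, `[[`, "chan_E")),
    chan_kd = unlist(lapply(fl, `[[`, "chan_kd")),
    pool_comp = unlist(lapply(seq_along(fl), function(i)
      fl[[i]]$pool_comp + offset[i])),
    pool_tau = unlist(lapply(fl, `[[`, "pool_tau")),
    pool_base = unlist(lapply(fl, `[[`, "pool_base")),
    pool_B = unlist(lapply(fl, `[[`, "pool_B")),
    n_cells = length(models), mg_mM = 1.0)
  for (nm in c("chan_comp", "chan_type")) eng[[nm]] <- as.integer(eng[[nm]])
  eng$pool_comp <- as.integer(eng$pool_comp)
  eng$parent <- as.integer(eng$parent)
  eng$cell <- as.integer(eng$cell)
  eng$soma_comp <- as.integer(eng$soma_comp)

  # ---- synapse site lists (global comp, kinetics) -------------------------
  syn_rows <- list()
  conn_rows <- list()
  ext_rows <- list()   # external synapse definitions (train -> pool)
  add_syn <- function(comp, tau1, tau2, E, nmda) {
    syn_rows[[length(syn_rows) + 1]] <<-
      tibble(comp = comp, tau1 = tau1, tau2 = tau2, E = E, nmda = nmda)
  }

  gran_dend_comp <- function(cell_id) offset[cell_id] + 2L - 1L  # 0-based
  # 1. reciprocal mitral<->granule synapses (shared granules)
  rs <- net$synapses %>% filter(.data$granule_key %in% names(gran_cell))
  if (nrow(rs)) {
    gcell <- gran_cell[rs$granule_key]
    mcell <- mit_cell[as.character(rs$mit)]
    mcomp <- offset[mcell] + rs$comp - 1L
    gcomp <- gran_dend_comp(gcell)
    # mitral -> granule AMPA + NMDA at the granule dendrite
    add_syn(gcomp, 1, 4, 0, FALSE)
    conn_rows[[length(conn_rows) + 1]] <- tibble(
      src = mcell, comp = gcomp, tau1 = 1, tau2 = 4, E = 0, nmda = FALSE,
      w = rs$gmax_ampa, delay = rs$delay_exc)
    add_syn(gcomp, 25, 200, 0, TRUE)
    conn_rows[[length(conn_rows) + 1]] <- tibble(
      src = mcell, comp = gcomp, tau1 = 25, tau2 = 200, E = 0, nmda = TRUE,
      w = rs$gmax_nmda, delay = rs$delay_exc)
    # granule -> mitral GABA at the mitral compartment
    add_syn(mcomp, 1, 20, E_INH, FALSE)
    conn_rows[[length(conn_rows) + 1]] <- tibble(
      src = gcell, comp = mcomp, tau1 = 1, tau2 = 20, E = E_INH,
      nmda = FALSE, w = gaba_gain * rs$gmax_gaba, delay = rs$delay_gaba)
  }
  # 2. aggregates: one excitatory input, 10 staggered inhibitory outputs
  if (n_agg && !all_granules) {
    ai <- net$aggregate_input
    acell <- agg_cell[ai$agg_id]
    mcell <- mit_cell[as.character(ai$mit)]
    gcomp <- gran_dend_comp(acell)
    add_syn(gcomp, 1, 4, 0, FALSE)
    conn_rows[[length(conn_rows) + 1]] <- tibble(
      src = mcell, comp = gcomp, tau1 = 1, tau2 = 4, E = 0, nmda = FALSE,
      w = ai$gmax_ampa, delay = ai$delay_exc)
    add_syn(gcomp, 25, 200, 0, TRUE)
    conn_rows[[length(conn_rows) + 1]] <- tibble(
      src = mcell, comp = gcomp, tau1 = 25, tau2 = 200, E = 0, nmda = TRUE,
      w = ai$gmax_nmda, delay = ai$delay_exc)
    as_ <- net$aggregate_syn
    acell2 <- agg_cell[as_$agg_id]
    mcell2 <- mit_cell[as.character(as_$mit)]
    mcomp2 <- offset[mcell2] + as_$comp - 1L
    add_syn(mcomp2, 1, 20, E_INH, FALSE)
    conn_rows[[length(conn_rows) + 1]] <- tibble(
      src = acell2, comp = mcomp2, tau1 = 1, tau2 = 20, E = E_INH,
      nmda = FALSE, w = gaba_gain * as_$gmax_gaba, delay = as_$delay)
  }
  # 3. auto-inhibitory 5 pS synapses at every reciprocal site (merged per
  #    compartment), triggered by the host mitral cell's own spike
  auto <- net$synapses %>%
    count(.data$mit, .data$comp, name = "n_sites")
  mcellA <- mit_cell[as.character(auto$mit)]
  mcompA <- offset[mcellA] + auto$comp - 1L
  add_syn(mcompA, 1, 20, E_INH, FALSE)
  conn_rows[[length(conn_rows) + 1]] <- tibble(
    src = mcellA, comp = mcompA, tau1 = 1, tau2 = 20, E = E_INH,
    nmda = FALSE,
    w = gaba_gain * prm("auto_inhib", "gmax") * auto$n_sites,
    delay = rep(0.6, nrow(auto)))
  # 4. PG circuitry
  if (n_pg) {
    ps <- net$pg_synapses
    pcell <- pg_cell[paste0(ps$glom, ":", ps$pg)]
    variant <- pg_tbl$variant[pcell - (n_mit + n_gran + n_agg)]
    g_exc <- ifelse(variant == "plateauing",
                    prm("mitral_pg_plateau", "gmax"),
                    prm("mitral_pg_lts", "gmax"))
    mcellP <- mit_cell[as.character(ps$mit)]
    pcomp <- offset[pcell] + ps$pg_dend - 1L
    # mitral -> PG excitatory
    add_syn(pcomp, 1, 1, 0, FALSE)
    conn_rows[[length(conn_rows) + 1]] <- tibble(
      src = mcellP, comp = pcomp, tau1 = 1, tau2 = 1, E = 0, nmda = FALSE,
      w = sample_weights(g_exc), delay = ps$delay_exc)
    # PG -> mitral inhibitory at the reciprocal tuft site
    rec <- ps$recip
    if (any(rec)) {
      mcompP <- offset[mcellP[rec]] + ps$tuft_comp[rec] - 1L
      add_syn(mcompP, 1, 20, E_INH, FALSE)
      conn_rows[[length(conn_rows) + 1]] <- tibble(
        src = pcell[rec], comp = mcompP, tau1 = 1, tau2 = 20, E = E_INH,
        nmda = FALSE,
        w = gaba_gain * sample_weights(rep(prm("pg_mitral", "gmax"),
                                           sum(rec))),
        delay = ps$delay_inh[rec])
    }
  }
  # 5. external synapses: ORN -> mitral tuft, ORN -> PG, background -> granule
  o <- net$opts
  orn_mit <- purrr::map_dfr(seq_len(n_mit), function(i) {
    m <- models[[i]]
    tibble(kind = "orn_mitral", glom = net$mitral$glom[i], cell = i,
           comp = offset[i] + sample(m$morph$tuft, o$orn_per_mitral,
                                     replace = TRUE) - 1L,
           tau1 = 1, tau2 = 1, E = 0, nmda = FALSE,
           w = orn_gain * sample_weights(rep(prm("orn_mitral", "gmax"),
                                             o$orn_per_mitral)))
  })
  orn_pg <- if (n_pg) purrr::map_dfr(seq_len(n_pg), function(i) {
    ci <- n_mit + n_gran + n_agg + i
    gmx <- if (pg_tbl$variant[i] == "plateauing")
      prm("orn_pg_plateau", "gmax") else prm("orn_pg_lts", "gmax")
    tibble(kind = "orn_pg", glom = pg_tbl$glom[i], cell = ci,
           comp = offset[ci] + sample(2:3, o$orn_per_pg, replace = TRUE) - 1L,
           tau1 = 1, tau2 = 1, E = 0, nmda = FALSE,
           w = sample_weights(rep(gmx, o$orn_per_pg)))
  }) else NULL
  bg_cells <- c(n_mit + seq_len(n_gran), if (n_agg) n_mit + n_gran + seq_len(n_agg))
  bg_gran <- tibble(kind = "background", glom = NA_integer_,
                    cell = bg_cells,
                    comp = offset[bg_cells] + 2L - 1L,
                    tau1 = 1, tau2 = 4, E = 0, nmda = FALSE,
                    w = prm("background_granule_ampa", "gmax"))
  bg_nmda <- bg_gran %>%
    mutate(tau1 = 25, tau2 = 200, nmda = TRUE,
           w = prm("background_granule_nmda", "gmax"))
  ext <- bind_rows(orn_mit, orn_pg, bg_gran, bg_nmda)
  add_syn(ext$comp, ext$tau1, ext$tau2, ext$E, ext$nmda)

  # ---- merge into pools ---------------------------------------------------
  sites <- bind_rows(syn_rows)
  pools <- sites %>%
    distinct(.data$comp, .data$tau1, .data$tau2, .data$E, .data$nmda) %>%
    mutate(pool = seq_len(n()) - 1L)
  pool_of <- function(df) {
    df %>% left_join(pools, by = c("comp", "tau1", "tau2", "E", "nmda")) %>%
      pull(.data$pool)
  }
  conns <- bind_rows(conn_rows)
  conns$pool <- pool_of(conns)
  ext$pool <- pool_of(ext)

  eng$syn_comp <- as.integer(pools$comp)
  eng$syn_taur <- pmin(pools$tau1, pools$tau2) / 1000
  eng$syn_taud <- pmax(pools$tau1, pools$tau2) / 1000
  eng$syn_E <- pools$E / 1000
  eng$syn_nmda <- as.integer(pools$nmda)
  eng$conn_src_cell <- as.integer(conns$src - 1L)
  eng$conn_pool <- as.integer(conns$pool)
  eng$conn_w <- dualexp_event_weight(conns$w, conns$tau1, conns$tau2)
  eng$conn_delay <- pmin(conns$delay, 999) / 1000

  ext$w_eng <- dualexp_event_weight(ext$w, ext$tau1, ext$tau2)

  structure(list(net = net, eng = eng, cells = cells, models = models,
                 offset = offset, ext = ext,
                 n_mit = n_mit, n_gran = n_gran, n_agg = n_agg,
                 n_pg = n_pg),
            class = "bulbnet_compiled")
}

#' @export
print.bulbnet_compiled <- function(x, ...) {
  cat("<bulbnet_compiled> cells=", nrow(x$cells),
      " (mitral ", x$n_mit, ", granule ", x$n_gran,
      ", aggregate ", x$n_agg, ", pg ", x$n_pg, ")",
      " comps=", length(x$eng$parent),
      " pools=", length(x$eng$syn_comp),
      " conns=", length(x$eng$conn_w), "\n", sep = "")
  invisible(x)
}

#' Simulate a compiled network
#'
#' Generates trial-specific Poisson input (per-glomerulus ORN rate series
#' driving every ORN synapse independently; granule background trains) and
#' integrates the network.
#'
#' @param comp a [compile_network()] result
#' @param duration_ms simulation length
#' @param orn_rates named list mapping glomerulus id (as character) to a
#'   rate tibble (\code{t}, \code{rate} in Hz) or a single constant rate;
#'   glomeruli absent from the list receive no ORN input
#' @param background \code{"in_vivo"} (35 Hz respiratory-modulated),
#'   \code{"in_vitro"} (3.45 Hz), or \code{"none"}
#' @param inj current injections: tibble \code{cell} (global id),
#'   \code{comp} (within-cell), \code{t0,t1,I0,I1} (ms, nA)
#' @param record tibble \code{cell}, \code{comp} to record voltages from
#'   (default: mitral somas)
#' @param seed dynamical seed for this trial
#' @param dt time step, ms
#' @param rec_dt recording interval, ms
#' @param events extra pre-scheduled external events (tibble \code{pool},
#'   \code{time} ms, \code{w} engine weight), e.g. shock activations
#' @return list: \code{spikes} (tibble cell, type, time), \code{time},
#'   \code{v} (mV), \code{cells}
#' @export
simulate_network <- function(comp, duration_ms, orn_rates = list(),
                             background = c("in_vivo", "in_vitro", "none"),
                             inj = NULL, record = NULL, seed = 1,
                             dt = 0.025, rec_dt = 1, events = NULL) {
  stopifnot(inherits(comp, "bulbnet_compiled"))
  background <- match.arg(background)
  set.seed(seed)
  ext <- comp$ext
  ev_list <- if (is.null(events)) list() else list(events)
  # ORN events: one independent train per ORN synapse of each glomerulus
  for (gl in names(orn_rates)) {
    r <- orn_rates[[gl]]
    sub <- ext %>% filter(.data$kind %in% c("orn_mitral", "orn_pg"),
                          .data$glom == as.integer(gl))
    if (!nrow(sub)) next
    if (is.numeric(r) && length(r) == 1) {
      tr <- poisson_spikes(r, n_trains = nrow(sub),
                           duration_ms = duration_ms)
    } else {
      tr <- poisson_spikes(r, n_trains = nrow(sub))
    }
    ev_list[[length(ev_list) + 1]] <- tibble(
      pool = sub$pool[tr$train], time = tr$time, w = sub$w_eng[tr$train])
  }
  # granule background: one train per granule/aggregate, deposited into the
  # AMPA and NMDA background pools together
  if (background != "none") {
    bg <- ext %>% filter(.data$kind == "background", !.data$nmda)
    bgN <- ext %>% filter(.data$kind == "background", .data$nmda)
    if (nrow(bg)) {
      tr <- background_trains(if (background == "in_vivo") "in_vivo"
                              else "in_vitro",
                              n_cells = nrow(bg), duration_ms = duration_ms)
      ev_list[[length(ev_list) + 1]] <- tibble(
        pool = bg$pool[tr$train], time = tr$time, w = bg$w_eng[tr$train])
      ev_list[[length(ev_list) + 1]] <- tibble(
        pool = bgN$pool[tr$train], time = tr$time, w = bgN$w_eng[tr$train])
    }
  }
  ev <- if (length(ev_list)) bind_rows(ev_list) else
    tibble(pool = integer(), time = numeric(), w = numeric())
  ev <- ev[order(ev$time), ]

  if (is.null(record))
    record <- tibble(cell = seq_len(comp$n_mit), comp = 1L)
  rec_global <- comp$offset[record$cell] + record$comp - 1L

  if (is.null(inj))
    inj <- tibble(cell = integer(), comp = integer(), t0 = numeric(),
                  t1 = numeric(), I0 = numeric(), I1 = numeric())
  stim <- list(time = ev$time / 1000, pool = as.integer(ev$pool), w = ev$w,
               inj_comp = as.integer(comp$offset[inj$cell] + inj$comp - 1L),
               inj_t0 = inj$t0 / 1000, inj_t1 = inj$t1 / 1000,
               inj_I0 = inj$I0 * 1e-9, inj_I1 = inj$I1 * 1e-9)
  out <- .engine_run(comp$eng, stim, duration_ms / 1000, dt / 1000,
                     as.integer(rec_global), rec_dt / 1000,
                     0.0, 1e-3, FALSE, 1.0)
  sp <- tibble(cell = out$spike_cell + 1L, time = out$spike_t * 1000)
  sp$type <- comp$cells$type[sp$cell]
  list(spikes = sp, time = out$time * 1000, v = out$v * 1000,
       cells = comp$cells, record = record)
}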