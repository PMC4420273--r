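# Seeded stochastic construction of olfactory-bulb network instances.
#
# Geometry lives in a 2D plane (um).  Glomeruli sit in an 850 x 850 um^2
# field around a central glomerulus; each glomerulus has 2 mitral cells
# (somas just below it), 1000 PG cells, and the granule-cell layer is a
# 2 um lattice (2500 cells per (100 um)^2).  Each mitral cell forms 10^4
# reciprocal synapses with granule cells (80 on the soma, the rest uniform
# along the primary and four lateral dendrites); for each synapse the
# granule is drawn uniformly from the 100 x 100 um window around the
# synapse location.  Schemes: "random" (all dendrites randomly rotated),
# "directed" (one lateral mitral per glomerulus aims a dendrite at a
# central sister), "default" (directed plus super-inhibition: 100 extra
# shared granules proximal to the target, granule-|mitral x4 and distal
# mitral->granule x3 for the pair, and x4 granule columns around lateral
# mitral cells), and "slice" (default-derived two-cell in-vitro prep).

GRANULE_SPACING <- 2       # um lattice spacing -> 2500 per (100 um)^2
GRANULE_WINDOW <- 100      # um granule dendritic extent (square window)
PROXIMAL_CUTOFF <- 100     # um path distance bounding "proximal"

.default_net_opts <- function() {
  list(
    syn_per_mitral = 10000L,  # reciprocal mitral|->granule synapses
    soma_syn = 80L,           # of which on the soma
    pg_per_glom = 1000L,
    pg_recip_per_mitral = 100L,  # reciprocal mitral|->PG synapses
    pg_syn_target = 25L,         # mitral->PG synapses per PG after top-up
    orn_per_mitral = 400L,
    orn_per_pg = 50L,
    n_extra_shared = 100L,    # super-inhibition granules per directed pair
    directed_offset = 20L,    # um: aimed dendrite passes this close to target
    super_gaba_factor = 4,
    super_nmda_factor = 3,
    super_scope = "added",   # "pair": x4/x3 for all shared granules of a
                              # super pair; "added": only the 100 added
                              # granules (see methods vignette)
    field = 850,              # um glomerular field edge
    min_glom_dist = 300,      # um minimum spacing of odor-activated glomeruli
    mitral_offset = 50        # um between sister somas
  )
}

# Anatomical lateral arbor: the electrical model reduces the secondary
# dendrites to 4 cables, but synapse placement uses a fuller anatomical
# arbor -- 4 trunks at right angles that each trifurcate at TRUNK_LEN into
# three sub-branches (+/- SPLIT_ANGLE and straight ahead), all reaching the
# same 425 um half-span.  Anatomical trunk/branch k maps onto electrical
# cable k at the same path distance.  This reproduces the parent
# morphology's total secondary-dendrite length (~4 mm), on which the
# granule-sharing statistics depend.
N_TRUNKS <- 4L
ANAT_SPAN <- 850  # um anatomical half-span of the secondary-dendrite arbor

# Anatomical arbor piece table: each of 4 trunks (0-150 um) trifurcates at
# 150 um (+/-25 deg) and each daughter bifurcates again at 450 um
# (+/-10 deg), giving 4 + 12 + 24 strands and ~13.8 mm of secondary
# dendrite -- the scale of the parent morphology, which the granule-sharing
# statistics depend on.  Pieces: id, cable (electrical lateral 1..4),
# radial interval [r0, r1], and the cumulative turn angles.
.arbor_pieces <- function() {
  rows <- list()
  id <- 0L
  for (k in seq_len(N_TRUNKS)) {
    base <- (k - 1) * 2 * pi / N_TRUNKS
    id <- id + 1L
    rows[[length(rows) + 1]] <- tibble(
      piece = id, cable = k, r0 = 0, r1 = 150,
      a1 = base, a2 = base, a3 = base)
    for (s in -1:1) {
      a2 <- base + s * 25 * pi / 180
      id <- id + 1L
      rows[[length(rows) + 1]] <- tibble(
        piece = id, cable = k, r0 = 150, r1 = 450,
        a1 = base, a2 = a2, a3 = a2)
      for (t in c(-1, 1)) {
        a3 <- a2 + t * 10 * pi / 180
        id <- id + 1L
        rows[[length(rows) + 1]] <- tibble(
          piece = id, cable = k, r0 = 450, r1 = ANAT_SPAN,
          a1 = base, a2 = a2, a3 = a3)
      }
    }
  }
  out <- bind_rows(rows)
  .arbor_env$pieces <- out
  out
}
.arbor_env <- new.env(parent = emptyenv())
.arbor_get <- function() {
  if (is.null(.arbor_env$pieces)) .arbor_pieces() else .arbor_env$pieces
}

# synapse placement along one mitral cell's arbor (vectorised over
# synapses).  dend coding: 0 soma; 1 primary; >= 2: arbor piece dend - 1.
# Anatomical path distances beyond the electrical cable length are clamped
# to the cable tip when mapping to compartments; granule-to-mitral weights
# still use the true path distance, at which the inhibitory decay
# (length constant 150 um) has made them negligible.
.place_mitral_synapses <- function(n_syn, soma_syn, morph) {
  ap <- .arbor_get()
  lens <- c(morph$prim_len, ap$r1 - ap$r0)
  n_rest <- n_syn - soma_syn
  piece <- sample(seq_along(lens), n_rest, replace = TRUE, prob = lens)
  arc <- runif(n_rest) * lens[piece] +
    c(0, ap$r0)[piece]  # path distance from the soma
  tibble(
    dend = c(rep(0L, soma_syn), piece),
    arc = c(rep(0, soma_syn), arc))
}

# planar offsets of a synapse site relative to the soma
.arbor_xy <- function(dend, arc, angle0) {
  n <- length(dend)
  dx <- dy <- numeric(n)
  cable <- integer(n)
  ap <- .arbor_get()
  lat <- dend >= 2L
  if (any(lat)) {
    pc <- dend[lat] - 1L
    a1 <- angle0[lat] + ap$a1[pc]
    a2 <- angle0[lat] + ap$a2[pc]
    a3 <- angle0[lat] + ap$a3[pc]
    r <- arc[lat]
    l1 <- pmin(r, 150)
    l2 <- pmin(pmax(r - 150, 0), 300)
    l3 <- pmax(r - 450, 0)
    dx[lat] <- l1 * cos(a1) + l2 * cos(a2) + l3 * cos(a3)
    dy[lat] <- l1 * sin(a1) + l2 * sin(a2) + l3 * sin(a3)
    cable[lat] <- ap$cable[pc]
  }
  list(dx = dx, dy = dy, cable = cable)
}

# compartment index for a synapse site on the mitral model
.mitral_syn_comp <- function(dend, arc, cable, morph) {
  nseg_p <- length(morph$prim)
  seg_p <- pmin(nseg_p, floor(arc / (morph$prim_len / nseg_p)) + 1L)
  nseg_l <- length(morph$lat[[1]])
  seg_l <- pmin(nseg_l, floor(pmin(arc, morph$lat_len - 1e-9) /
                                (morph$lat_len / nseg_l)) + 1L)
  out <- integer(length(dend))
  out[dend == 0L] <- 1L
  pidx <- dend == 1L
  out[pidx] <- morph$prim[seg_p[pidx]]
  for (j in seq_along(morph$lat)) {
    lidx <- dend >= 2L & cable == j
    out[lidx] <- morph$lat[[j]][seg_l[lidx]]
  }
  out
}

.snap_lattice <- function(x) round(x / GRANULE_SPACING) * GRANULE_SPACING

#' Build a network instance
#'
#' Seeded stochastic construction of one network: glomerulus layout, mitral
#' placement and rotation, reciprocal mitral-granule and mitral-PG synapses,
#' ORN input synapses, and (for \code{default}) super-inhibitory edges.
#' Weights carry the distance-dependent decay of granule-to-mitral
#' inhibition, scheme strengthening factors and a log-normal 25% spread;
#' delays follow [assign_delays()].
#'
#' @param scheme \code{"random"}, \code{"directed"} or \code{"default"}
#'   (use [make_slice()] for the slice preparation)
#' @param n_lateral number of lateral glomeruli, 0..6
#' @param seed structural random seed (connectivity); the instance also
#'   stores a derived dynamical seed for inputs
#' @param opts named list overriding the physiological counts (fixtures use
#'   smaller networks); see the methods vignette
#' @param separations optional numeric vector of lateral-glomerulus
#'   distances from the centre, um (default: random within reach)
#' @param two_mitral if TRUE, keep only mitral cells A (central) and B (one
#'   lateral), as in the paired in-vivo probes
#' @return object of class \code{bulbnet_network}
#' @export
build_network <- function(scheme = c("default", "random", "directed"),
                          n_lateral = 2, seed = 1, opts = list(),
                          separations = NULL, two_mitral = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(n_lateral >= 0, n_lateral <= 6)
  o <- utils::modifyList(.default_net_opts(), opts)
  set.seed(seed)

  morph <- build_mitral()$morph
  reach <- ANAT_SPAN

  # --- glomeruli and mitral cells -----------------------------------------
  n_glom <- 1L + n_lateral
  gx <- gy <- numeric(n_glom)
  for (j in seq_len(n_lateral)) {
    if (!is.null(separations)) {
      th <- runif(1, 0, 2 * pi)
      gx[j + 1] <- separations[j] * cos(th)
      gy[j + 1] <- separations[j] * sin(th)
    } else {
      # odor-activated glomeruli are sparse, hence far apart on average:
      # enforce a minimum spacing between all activated glomeruli
      repeat {
        px <- runif(1, -o$field / 2, o$field / 2)
        py <- runif(1, -o$field / 2, o$field / 2)
        dists <- sqrt((px - gx[seq_len(j)])^2 + (py - gy[seq_len(j)])^2)
        if (sqrt(px^2 + py^2) <= reach * 0.95 &&
            all(dists >= o$min_glom_dist)) break
      }
      gx[j + 1] <- px; gy[j + 1] <- py
    }
  }
  glomeruli <- tibble(glom = seq_len(n_glom), x = gx, y = gy,
                      central = c(TRUE, rep(FALSE, n_lateral)))

  n_mit <- 2L * n_glom
  mitral <- tibble(
    mit = seq_len(n_mit),
    glom = rep(seq_len(n_glom), each = 2),
    sister = rep(1:2, n_glom))
  mitral$x <- glomeruli$x[mitral$glom] +
    ifelse(mitral$sister == 1, -o$mitral_offset, o$mitral_offset)
  mitral$y <- glomeruli$y[mitral$glom]
  mitral$angle <- runif(n_mit, 0, 2 * pi)
  # directed rotation: in directed/default, one mitral per lateral glomerulus
  # aims a lateral dendrite near alternating central sisters
  mitral$directed_to <- NA_integer_
  if (scheme %in% c("directed", "default") && n_lateral > 0) {
    for (j in seq_len(n_lateral)) {
      src <- 2L * j + 1L             # first mitral of lateral glomerulus j
      tgt <- if (j %% 2 == 1) 1L else 2L
      dx <- mitral$x[tgt] - mitral$x[src]
      dy <- mitral$y[tgt] - mitral$y[src]
      # aim so the dendrite passes within directed_offset of the target soma
      d <- sqrt(dx^2 + dy^2)
      ang <- atan2(dy, dx) + asin(min(1, o$directed_offset / max(d, 1))) *
        sample(c(-1, 1), 1)
      mitral$angle[src] <- ang       # lateral dendrite 1 points along `ang`
      mitral$directed_to[src] <- tgt
    }
  }
  if (two_mitral) {
    keep_mit <- c(1L, 3L)
  } else {
    keep_mit <- mitral$mit
  }

  # --- reciprocal mitral|->granule synapses --------------------------------
  syn <- purrr::map_dfr(keep_mit, function(mi) {
    pl <- .place_mitral_synapses(o$syn_per_mitral, o$soma_syn, morph)
    pl$mit <- mi
    pl
  })
  ang0 <- mitral$angle[syn$mit]
  axy <- .arbor_xy(syn$dend, syn$arc, ang0)
  syn$x <- mitral$x[syn$mit] + axy$dx
  syn$y <- mitral$y[syn$mit] + axy$dy
  syn$cable <- axy$cable
  syn$comp <- .mitral_syn_comp(syn$dend, syn$arc, syn$cable, morph)
  syn$path <- ifelse(syn$dend == 0L, 0, syn$arc)
  # granule choice within the 100x100 um window
  syn$ggx <- .snap_lattice(syn$x + runif(nrow(syn), -GRANULE_WINDOW / 2,
                                         GRANULE_WINDOW / 2))
  syn$ggy <- .snap_lattice(syn$y + runif(nrow(syn), -GRANULE_WINDOW / 2,
                                         GRANULE_WINDOW / 2))
  syn$granule_key <- paste0(syn$ggx, "_", syn$ggy)
  syn$super <- FALSE

  # --- super-inhibition edges (default scheme) ----------------------------
  super_edges <- tibble(src_mit = integer(), tgt_mit = integer())
  if (scheme == "default" && n_lateral > 0) {
    for (j in seq_len(n_lateral)) {
      src <- 2L * j + 1L
      tgt <- mitral$directed_to[src]
      if (!(src %in% keep_mit) || !(tgt %in% keep_mit)) next
      super_edges <- bind_rows(super_edges,
                               tibble(src_mit = src, tgt_mit = tgt))
      # granules connected only to tgt, proximal on tgt
      tally <- syn %>% group_by(.data$granule_key) %>%
        summarise(n_mit = n_distinct(.data$mit), .groups = "drop")
      singles <- tally$granule_key[tally$n_mit == 1L]
      cand <- syn %>%
        filter(.data$mit == tgt, .data$path <= PROXIMAL_CUTOFF,
               .data$granule_key %in% singles) %>%
        distinct(.data$granule_key, .keep_all = TRUE)
      n_pick <- min(o$n_extra_shared, nrow(cand))
      pick <- cand[sample(nrow(cand), n_pick), ]
      # connect each picked granule to the closest segment of the directed
      # dendrite (dendrite 1) of the source mitral cell
      th <- mitral$angle[src]
      relx <- pick$ggx - mitral$x[src]; rely <- pick$ggy - mitral$y[src]
      arc <- pmin(pmax(relx * cos(th) + rely * sin(th), 0), ANAT_SPAN)
      # straight path along trunk 1: trunk piece, its middle daughter, and
      # that branch's first grand-daughter (dend = piece id + 1)
      dcode <- ifelse(arc <= 150, 2L, ifelse(arc <= 450, 6L, 7L))
      new <- tibble(dend = dcode, arc = arc, mit = src,
                    x = mitral$x[src] + arc * cos(th),
                    y = mitral$y[src] + arc * sin(th),
                    cable = 1L,
                    comp = .mitral_syn_comp(dcode, arc, rep(1L, n_pick),
                                            morph),
                    path = arc,
                    ggx = pick$ggx, ggy = pick$ggy,
                    granule_key = pick$granule_key,
                    super = TRUE)
      syn <- bind_rows(syn, new)
    }
  }

  # --- weights and factors -------------------------------------------------
  gaba_base <- if (scheme %in% c("random", "directed")) 1.5 else 1.0
  dec <- ifelse(syn$dend == 1L,
                distance_decay(syn$path, "primary"),
                ifelse(syn$dend >= 2L,
                       distance_decay(syn$path, "secondary"), 1))
  # shared granules of each super-inhibitory pair: x4 GABA, x3 distal NMDA/AMPA
  syn$pair_super <- FALSE
  if (nrow(super_edges)) {
    for (k in seq_len(nrow(super_edges))) {
      pair <- c(super_edges$src_mit[k], super_edges$tgt_mit[k])
      if (identical(o$super_scope, "added")) {
        shared_keys <- unique(syn$granule_key[syn$super &
                                                syn$mit == pair[1]])
      } else {
        keys1 <- unique(syn$granule_key[syn$mit == pair[1]])
        keys2 <- unique(syn$granule_key[syn$mit == pair[2]])
        shared_keys <- intersect(keys1, keys2)
      }
      syn$pair_super <- syn$pair_super |
        (syn$granule_key %in% shared_keys & syn$mit %in% pair)
    }
  }
  # granule "columns": proximal granule-|mitral strengthening around lateral
  # mitral cells, in lieu of unmodelled super-inhibitors onto them
  col_boost <- rep(FALSE, nrow(syn))
  if (scheme == "default") {
    lat_mits <- mitral$mit[mitral$glom != 1L & mitral$mit %in% keep_mit]
    col_boost <- syn$mit %in% lat_mits & syn$path <= PROXIMAL_CUTOFF
  }
  gaba_factor <- ifelse(syn$pair_super | col_boost, o$super_gaba_factor, 1)
  exc_factor <- ifelse(syn$pair_super & syn$path > PROXIMAL_CUTOFF,
                       o$super_nmda_factor, 1)
  syn$gmax_gaba <- sample_weights(gaba_base * dec * gaba_factor)
  sp <- synapse_params()
  ampa <- sp$gmax[sp$kind == "mitral_granule_ampa"]
  syn$gmax_ampa <- sample_weights(ampa * exc_factor)
  syn$gmax_nmda <- syn$gmax_ampa * 0.26
  syn$delay_gaba <- assign_delays("inhibitory", nrow(syn))
  syn$delay_exc <- assign_delays("excitatory", nrow(syn))

  # --- granule table -------------------------------------------------------
  granules <- syn %>%
    group_by(.data$granule_key) %>%
    summarise(x = first(.data$ggx), y = first(.data$ggy),
              n_mitral = n_distinct(.data$mit), n_syn = n(),
              .groups = "drop")
  granules$Em <- sample_leak_reversals(nrow(granules),
                                       granule_params()$Em, "granule")

  # --- PG cells ------------------------------------------------------------
  keep_glom <- unique(mitral$glom[mitral$mit %in% keep_mit])
  pg_recip <- purrr::map_dfr(intersect(seq_len(n_glom), keep_glom),
                             function(gl) {
    mits <- mitral$mit[mitral$glom == gl & mitral$mit %in% keep_mit]
    purrr::map_dfr(mits, function(mi) {
      tibble(mit = mi, glom = gl,
             pg = sample.int(o$pg_per_glom, o$pg_recip_per_mitral,
                             replace = TRUE))
    })
  })
  # top up chosen PG cells to pg_syn_target mitral->PG synapses
  pg_extra <- pg_recip %>%
    count(.data$glom, .data$pg, name = "n_have") %>%
    mutate(n_need = pmax(0L, o$pg_syn_target - .data$n_have))
  extra <- pg_extra[rep(seq_len(nrow(pg_extra)), pg_extra$n_need), ] %>%
    select("glom", "pg")
  if (nrow(extra)) {
    extra$mit <- vapply(extra$glom, function(gl) {
      mits <- mitral$mit[mitral$glom == gl & mitral$mit %in% keep_mit]
      mits[sample.int(length(mits), 1)]
    }, 0L)
    extra$recip <- FALSE
  }
  pg_recip$recip <- TRUE
  pg_syn <- bind_rows(pg_recip, extra)
  pg_cells <- pg_syn %>% distinct(.data$glom, .data$pg)
  pg_cells$variant <- ifelse(runif(nrow(pg_cells)) < 1 / 3,
                             "plateauing", "low_threshold_spiking")
  pg_cells$Em <- sample_leak_reversals(
    nrow(pg_cells), 0, "pg") +
    ifelse(pg_cells$variant == "plateauing",
           pg_params("plateauing")$Em, pg_params("low_threshold_spiking")$Em)
  pg_syn$delay_exc <- assign_delays("mitral_to_pg", nrow(pg_syn))
  pg_syn$delay_inh <- assign_delays("pg_to_mitral", nrow(pg_syn))
  pg_syn$tuft_comp <- sample(morph$tuft, nrow(pg_syn), replace = TRUE)
  pg_syn$pg_dend <- sample(2:3, nrow(pg_syn), replace = TRUE)

  structure(list(
    scheme = scheme, seed = seed, dynamical_seed = seed + 1000003L,
    n_lateral = n_lateral, opts = o,
    glomeruli = glomeruli,
    mitral = mitral[mitral$mit %in% keep_mit, ],
    granules = granules,
    synapses = as_tibble(syn),
    pg_cells = pg_cells, pg_synapses = as_tibble(pg_syn),
    super_edges = super_edges,
    aggregated = FALSE, morph = morph
  ), class = "bulbnet_network")
}

#' @export
print.bulbnet_network <- function(x, ...) {
  cat("<bulbnet_network> scheme=", x$scheme, " seed=", x$seed,
      " glomeruli=", nrow(x$glomeruli),
      " mitral=", nrow(x$mitral),
      " granules=", nrow(x$granules),
      " (shared ", sum(x$granules$n_mitral >= 2), ")",
      " pg=", nrow(x$pg_cells),
      if (x$aggregated) " [aggregated]", "\n", sep = "")
  invisible(x)
}

#' Aggregate singly-connected granule cells
#'
#' Granule cells connected to two or more mitral cells are kept 1:1.
#' Singly-connected granule cells are aggregated \code{ratio}:1 per mitral
#' cell: each aggregate keeps one mitral-to-granule input synapse and emits
#' its inhibition as 10 staggered synapses whose summed strength equals the
#' group's total (conductance-time integral conserved), with exponentially
#' distributed delays of SD 160 ms.
#'
#' @param net a [build_network()] result
#' @param ratio aggregation ratio (default 100)
#' @return the network with an \code{aggregates} table and aggregation
#'   bookkeeping
#' @export
aggregate_singles <- function(net, ratio = 100) {
  stopifnot(inherits(net, "bulbnet_network"), ratio > 0)
  set.seed(net$seed + 7L)
  gr <- net$granules
  shared_keys <- gr$granule_key[gr$n_mitral >= 2L]
  singles <- net$synapses %>%
    filter(!(.data$granule_key %in% shared_keys))
  # group singles per mitral cell into batches of `ratio` granules
  agg <- singles %>%
    distinct(.data$mit, .data$granule_key) %>%
    group_by(.data$mit) %>%
    mutate(grp = (sample.int(n()) - 1L) %/% as.integer(ratio)) %>%
    ungroup()
  singles <- singles %>%
    left_join(agg, by = c("mit", "granule_key"))
  agg_tbl <- singles %>%
    group_by(.data$mit, .data$grp) %>%
    summarise(n_members = n_distinct(.data$granule_key),
              total_gaba = sum(.data$gmax_gaba),
              x = mean(.data$ggx), y = mean(.data$ggy),
              keep_key = first(.data$granule_key),
              .groups = "drop") %>%
    mutate(agg_id = paste0("agg", .data$mit, "_", .data$grp))
  # 10 inhibitory synapses per aggregate, targets sampled from member sites,
  # each carrying total_gaba / 10 so the conductance integral is conserved
  n_out <- 10L
  agg_syn <- purrr::map_dfr(seq_len(nrow(agg_tbl)), function(i) {
    mem <- singles %>% filter(.data$mit == agg_tbl$mit[i],
                              .data$grp == agg_tbl$grp[i])
    idx <- sample.int(nrow(mem), n_out, replace = nrow(mem) < n_out)
    tibble(agg_id = agg_tbl$agg_id[i], mit = agg_tbl$mit[i],
           comp = mem$comp[idx],
           gmax_gaba = rep(agg_tbl$total_gaba[i] / n_out, n_out),
           delay = assign_delays("aggregated", n_out))
  })
  # the aggregate keeps a single excitatory input synapse (the kept member's)
  keep_in <- singles %>%
    group_by(.data$mit, .data$grp) %>%
    slice(1) %>% ungroup() %>%
    left_join(agg_tbl %>% select("mit", "grp", "agg_id"),
              by = c("mit", "grp"))
  net$aggregates <- agg_tbl
  net$aggregate_syn <- agg_syn
  net$aggregate_input <- keep_in
  net$aggregate_ratio <- ratio
  net$aggregated <- TRUE
  net
}

#' Carve an in-vitro slice from a default-style network
#'
#' Two mitral cells A (central) and B (lateral) at a given separation;
#' granule cells farther than 100 um from the line through the two somas
#' (the plane containing the primary dendrites) are discarded; both cells'
#' dendrites are randomly rotated, keeping the granule columns.
#'
#' @param net a default-scheme network with exactly 1 lateral glomerulus,
#'   built with \code{two_mitral = TRUE} and \code{separations} equal to the
#'   slice separation
#' @param separation_um distance between A and B somas (must match the
#'   network's layout; default 50)
#' @param slab_halfwidth_um half-width of the retained slab (default 100)
#' @return pruned network (class unchanged)
#' @export
make_slice <- function(net, separation_um = 50, slab_halfwidth_um = 100) {
  stopifnot(inherits(net, "bulbnet_network"), separation_um > 0)
  mits <- net$mitral$mit
  stopifnot(length(mits) == 2L)
  a <- c(net$mitral$x[1], net$mitral$y[1])
  b <- c(net$mitral$x[2], net$mitral$y[2])
  u <- (b - a) / sqrt(sum((b - a)^2))
  # distance of each granule from the A-B line
  rel <- cbind(net$granules$x - a[1], net$granules$y - a[2])
  dist_line <- abs(rel[, 1] * (-u[2]) + rel[, 2] * u[1])
  keep <- net$granules$granule_key[dist_line <= slab_halfwidth_um]
  net$granules <- net$granules[dist_line <= slab_halfwidth_um, ]
  net$synapses <- net$synapses %>% filter(.data$granule_key %in% keep)
  net$granules <- net$granules %>%
    filter(.data$granule_key %in% unique(net$synapses$granule_key))
  # recompute sharing after pruning
  tal <- net$synapses %>% group_by(.data$granule_key) %>%
    summarise(n_mitral = n_distinct(.data$mit), n_syn = n(),
              .groups = "drop")
  net$granules <- net$granules %>%
    select(-"n_mitral", -"n_syn") %>%
    left_join(tal, by = "granule_key")
  net$slice <- list(separation = separation_um,
                    slab_halfwidth = slab_halfwidth_um)
  net$scheme <- "slice"
  net
}

#' Connectivity arithmetic report
#'
#' Reproduces the disynaptic-path arithmetic for super-inhibitory
#' connections: proximal granule-mitral contacts per mitral times spines per
#' granule gives disynaptic paths; dividing by the contacts required for one
#' super-inhibitory connection bounds the number of possible
#' super-inhibitors; comparing with the number of reachable mitral/tufted
#' cells gives the sparsity bound and the fan-in estimate.
#'
#' @param net optional network instance; when supplied, the measured
#'   proximal contact count per mitral is included alongside the reference
#'   arithmetic
#' @param proximal_contacts proximal granule-|mitral contacts per mitral
#'   (reference value 400)
#' @param spines_per_granule reciprocal spines per granule cell (100)
#' @param required_contacts proximal shared contacts required for one
#'   super-inhibitory connection (100)
#' @param n_glomeruli_reach glomeruli within dendritic reach (175)
#' @param mt_per_glomerulus M/T cells per glomerulus (75)
#' @param odor_active_inhibitors effective odor-activated super-inhibitors
#'   (2) and \code{odor_active_glomeruli} (17) for the tighter estimate
#' @param odor_active_glomeruli see above
#' @return tibble of named quantities
#' @export
connectivity_report <- function(net = NULL, proximal_contacts = 400,
                                spines_per_granule = 100,
                                required_contacts = 100,
                                n_glomeruli_reach = 175,
                                mt_per_glomerulus = 75,
                                odor_active_inhibitors = 2,
                                odor_active_glomeruli = 17) {
  paths <- proximal_contacts * spines_per_granule
  max_super <- paths / required_contacts
  reachable <- n_glomeruli_reach * mt_per_glomerulus
  upper_one_in <- reachable / max_super
  sparsity_denom <- odor_active_glomeruli * mt_per_glomerulus /
    odor_active_inhibitors
  fan_in <- round(reachable, -3) / round(sparsity_denom, -1)
  out <- tibble(
    quantity = c("disynaptic_paths", "max_super_inhibitors",
                 "reachable_mt", "upper_bound_one_in", "fan_in"),
    value = c(paths, max_super, reachable, upper_one_in, fan_in))
  if (!is.null(net)) {
    prox <- net$synapses %>%
      filter(.data$path <= PROXIMAL_CUTOFF) %>%
      count(.data$mit) %>%
      summarise(m = mean(.data$n)) %>% pull(.data$m)
    out <- bind_rows(out, tibble(quantity = "measured_proximal_contacts",
                                 value = prox))
  }
  out
}
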