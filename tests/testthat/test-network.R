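# Stochastic network construction, aggregation, slice carving and the
# connectivity report.  Fixture-sized networks keep runtimes small; the
# full-scale statistics are exercised by the acceptance suite.

test_that("network construction is deterministic given a seed", {
  n1 <- build_network("default", n_lateral = 1, seed = 7,
                      opts = fixture_net_opts())
  n2 <- build_network("default", n_lateral = 1, seed = 7,
                      opts = fixture_net_opts())
  expect_identical(n1$synapses, n2$synapses)
  expect_identical(n1$granules, n2$granules)
  n3 <- build_network("default", n_lateral = 1, seed = 8,
                      opts = fixture_net_opts())
  expect_false(identical(n1$synapses$granule_key, n3$synapses$granule_key))
})

test_that("stated per-cell synapse counts hold", {
  o <- fixture_net_opts()
  net <- build_network("default", n_lateral = 1, seed = 9, opts = o)
  counts <- dplyr::count(dplyr::filter(net$synapses, !net$synapses$super),
                         .data$mit)
  expect_true(all(counts$n == o$syn_per_mitral))
  soma <- dplyr::count(dplyr::filter(net$synapses, .data$dend == 0), .data$mit)
  expect_true(all(soma$n == o$soma_syn))
  # each PG has pg_syn_target mitral->PG synapses after top-up
  pg_counts <- dplyr::count(net$pg_synapses, .data$glom, .data$pg)
  expect_true(all(pg_counts$n == o$pg_syn_target))
})

test_that("granules lie within the selection window of their synapses", {
  net <- build_network("default", n_lateral = 1, seed = 10,
                       opts = fixture_net_opts())
  s <- dplyr::filter(net$synapses, !net$synapses$super)
  expect_true(all(abs(s$ggx - s$x) <= 51))
  expect_true(all(abs(s$ggy - s$y) <= 51))
})

test_that("random scheme has no super-inhibition edges; default does", {
  nr <- build_network("random", n_lateral = 1, seed = 11,
                      opts = fixture_net_opts())
  expect_equal(nrow(nr$super_edges), 0)
  expect_true(all(!nr$synapses$super))
  nd <- build_network("default", n_lateral = 1, seed = 11,
                      opts = fixture_net_opts())
  expect_gt(nrow(nd$super_edges), 0)
  expect_gt(sum(nd$synapses$super), 0)
  # directedness: strengthening applies on the B->A pair only, and the
  # extra granules were connected to the directed lateral dendrite
  extra <- dplyr::filter(nd$synapses, nd$synapses$super)
  expect_true(all(extra$mit %in% nd$super_edges$src_mit))
})

test_that("synapse placement is uniform along the dendritic length", {
  net <- build_network("random", n_lateral = 0, seed = 12,
                       opts = list(syn_per_mitral = 4000L, soma_syn = 0L,
                                   pg_per_glom = 10L,
                                   pg_recip_per_mitral = 5L,
                                   pg_syn_target = 2L,
                                   orn_per_mitral = 10L, orn_per_pg = 2L))
  # placement is uniform per unit dendritic length; within each arbor piece
  # the relative position must be uniform
  lat <- dplyr::filter(net$synapses, net$synapses$dend >= 2, net$synapses$mit == 1)
  r0 <- ifelse(lat$arc > 450, 450, ifelse(lat$arc > 150, 150, 0))
  r1 <- ifelse(lat$arc > 450, 850, ifelse(lat$arc > 150, 450, 150))
  rel <- (lat$arc - r0) / (r1 - r0)
  ks <- suppressWarnings(stats::ks.test(rel, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("aggregation preserves shared granules and conserves the
           inhibitory conductance integral", {
  net <- build_network("default", n_lateral = 1, seed = 13,
                       opts = fixture_net_opts())
  agg <- aggregate_singles(net, ratio = 20)
  shared_keys <- net$granules$granule_key[net$granules$n_mitral >= 2]
  # shared granule synapses untouched
  expect_identical(
    dplyr::filter(net$synapses, net$synapses$granule_key %in% shared_keys),
    dplyr::filter(agg$synapses, agg$synapses$granule_key %in% shared_keys))
  # total inhibitory weight onto each mitral conserved within 1%
  singles_w <- net$synapses %>%
    dplyr::filter(!(.data$granule_key %in% shared_keys)) %>%
    dplyr::group_by(.data$mit) %>%
    dplyr::summarise(w = sum(.data$gmax_gaba))
  agg_w <- agg$aggregate_syn %>%
    dplyr::group_by(.data$mit) %>%
    dplyr::summarise(w = sum(.data$gmax_gaba))
  expect_equal(agg_w$w, singles_w$w, tolerance = 0.01)
  # each aggregate emits 10 synapses and keeps one input
  expect_true(all(dplyr::count(agg$aggregate_syn, .data$agg_id)$n == 10))
  expect_equal(nrow(agg$aggregate_input), nrow(agg$aggregates))
  # ratio 1 keeps one granule per aggregate (pure bookkeeping)
  a1 <- aggregate_singles(net, ratio = 1)
  expect_true(all(a1$aggregates$n_members == 1))
})

test_that("slice carving removes out-of-slab granules and shrinks the
           network", {
  net <- build_network("default", n_lateral = 1, seed = 14,
                       separations = 50, two_mitral = TRUE,
                       opts = fixture_net_opts())
  sl <- make_slice(net, separation_um = 50)
  expect_lt(nrow(sl$granules), nrow(net$granules))
  # geometric audit: all surviving granule somas within 100 um of the A-B line
  a <- c(net$mitral$x[1], net$mitral$y[1])
  b <- c(net$mitral$x[2], net$mitral$y[2])
  u <- (b - a) / sqrt(sum((b - a)^2))
  rel <- cbind(sl$granules$x - a[1], sl$granules$y - a[2])
  d <- abs(rel[, 1] * (-u[2]) + rel[, 2] * u[1])
  expect_true(all(d <= 100))
  # somata separation as requested
  expect_equal(sqrt(sum((b - a)^2)), 50, tolerance = 1e-6)
})

test_that("connectivity report reproduces the disynaptic-path arithmetic", {
  rep <- connectivity_report()
  val <- function(q) rep$value[rep$quantity == q]
  expect_equal(val("disynaptic_paths"), 400 * 100)
  expect_equal(val("max_super_inhibitors"), 40000 / 100)
  expect_equal(val("reachable_mt"), 175 * 75)
  expect_equal(val("upper_bound_one_in"), 13125 / 400)
  expect_equal(val("fan_in"), 13000 / 640)
})

test_that("weights carry distance decay and scheme strengthening", {
  net <- build_network("default", n_lateral = 1, seed = 15,
                       opts = fixture_net_opts())
  s <- net$synapses
  prox <- s$gmax_gaba[s$path <= 10 & s$mit == 1]
  dist <- s$gmax_gaba[s$path > 400 & s$mit == 1 & !s$pair_super]
  expect_gt(mean(prox), 5 * mean(dist))
  # random/directed base strength is 1.5 nS (no super synapses)
  nr <- build_network("random", n_lateral = 1, seed = 15,
                      opts = fixture_net_opts())
  prox_r <- nr$synapses$gmax_gaba[nr$synapses$path <= 10]
  expect_equal(mean(prox_r), 1.5, tolerance = 0.1)
})
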