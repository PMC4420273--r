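# Network compilation and simulation on fixture-sized instances.

test_that("compiled network accounts for every cell class and pool merge", {
  net <- build_network("default", n_lateral = 1, seed = 30,
                       opts = fixture_net_opts())
  net <- aggregate_singles(net, ratio = 20)
  cmp <- compile_network(net)
  expect_s3_class(cmp, "bulbnet_compiled")
  expect_equal(cmp$n_mit, nrow(net$mitral))
  expect_equal(cmp$n_gran, sum(net$granules$n_mitral >= 2))
  expect_equal(cmp$n_agg, nrow(net$aggregates))
  expect_equal(cmp$n_pg, nrow(net$pg_cells))
  # pools are unique (comp, kinetics, reversal) combinations
  pools <- tibble::tibble(comp = cmp$eng$syn_comp, taur = cmp$eng$syn_taur,
                          taud = cmp$eng$syn_taud, E = cmp$eng$syn_E,
                          nmda = cmp$eng$syn_nmda)
  expect_equal(nrow(pools), nrow(dplyr::distinct(pools)))
  # an unaggregated network is refused unless asked for explicitly
  raw <- build_network("default", n_lateral = 1, seed = 30,
                       opts = fixture_net_opts())
  expect_error(compile_network(raw), "aggregated")
  expect_s3_class(compile_network(raw, all_granules = TRUE),
                  "bulbnet_compiled")
})

test_that("identical seeds give identical spike output", {
  inst <- fixture_instance(seed = 31)
  r1 <- simulate_network(inst$cmp, 400, orn_rates = list("1" = 8, "2" = 8),
                         background = "in_vivo", seed = 5, dt = 0.05)
  r2 <- simulate_network(inst$cmp, 400, orn_rates = list("1" = 8, "2" = 8),
                         background = "in_vivo", seed = 5, dt = 0.05)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- simulate_network(inst$cmp, 400, orn_rates = list("1" = 8, "2" = 8),
                         background = "in_vivo", seed = 6, dt = 0.05)
  expect_false(identical(r1$spikes$time, r3$spikes$time))
})

test_that("ORN drive raises mitral firing above the undriven condition", {
  inst <- fixture_instance(seed = 32)
  r0 <- simulate_network(inst$cmp, 600, orn_rates = list(),
                         background = "none", seed = 2, dt = 0.05)
  r1 <- simulate_network(inst$cmp, 600,
                         orn_rates = list("1" = 30, "2" = 30),
                         background = "none", seed = 2, dt = 0.05)
  m0 <- sum(r0$spikes$type == "mitral")
  m1 <- sum(r1$spikes$type == "mitral")
  expect_gt(m1, m0)
  expect_gt(m1, 3)
})

test_that("voltage recording returns the requested compartments", {
  inst <- fixture_instance(seed = 33)
  rec <- tibble::tibble(cell = c(1L, 1L), comp = c(1L, 3L))
  r <- simulate_network(inst$cmp, 100, orn_rates = list(),
                        background = "none", record = rec, seed = 1,
                        dt = 0.05, rec_dt = 0.5)
  expect_equal(ncol(r$v), 2)
  expect_true(all(abs(r$v[1, ] + 65) < 1))
})
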