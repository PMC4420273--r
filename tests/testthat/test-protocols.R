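# Protocol orchestration on fixture-sized instances: shapes, determinism and
# the qualitative behaviours the full-scale experiments rely on.

test_that("nerve shock: weak input initiates at the soma, strong at the
           tuft", {
  # full-size single glomerulus so the shock fractions are faithful
  inst <- make_instance(seed = 40, scheme = "random", n_lateral = 0,
                        opts = list(pg_per_glom = 200L))
  weak <- run_nerve_shock(inst, "weak", seed = 1)
  strong <- run_nerve_shock(inst, "strong", seed = 1)
  expect_identical(weak$initiation, "soma")
  expect_identical(strong$initiation, "tuft")
  expect_true(all(c("soma", "tuft_base", "tuft") %in% weak$traces$site))
})

test_that("freely-breathing protocol bins the second cycle into 5 bins per
           sister and is reproducible", {
  inst <- fixture_instance(seed = 41)
  fb <- run_freely_breathing(inst, "odorA", trials = 2)
  expect_setequal(unique(fb$binned$bin), 1:5)
  expect_setequal(unique(fb$binned$sister), 1:2)
  expect_equal(nrow(fb$binned), 2 * 2 * 5)
  fb2 <- run_freely_breathing(inst, "odorA", trials = 2)
  expect_identical(fb$binned, fb2$binned)
})

test_that("linearity protocol produces 5 stimuli with the requested trials
           and 50 ms bins", {
  inst <- fixture_instance(seed = 42)
  lin <- run_linearity_protocol(inst, trials = 2, duration_ms = 700)
  expect_setequal(unique(lin$responses$stim), 1:5)
  expect_equal(max(lin$responses$trial), 2)
  expect_equal(max(lin$responses$bin), 700 / 50)
  expect_equal(lin$bin_ms, 50)
  # two-odor stimulus has both concentration series active
  bc <- dplyr::filter(lin$binned_conc, lin$binned_conc$stim == 5)
  expect_gt(max(bc$concA), 0)
  expect_gt(max(bc$concB), 0)
})

test_that("scaled-pulse protocol covers all concentrations and subtracts
           air", {
  inst <- fixture_instance(seed = 43)
  sp <- run_scaled_pulses(inst, concs = c(0, 1, 2), trials = 2,
                          hist_ms = 800)
  expect_setequal(unique(sp$conc), c(0, 1, 2))
  # the 0% level reproduces the air-only response: zero after subtraction
  zero <- dplyr::filter(sp, sp$conc == 0)
  expect_true(all(vapply(zero$hist, function(h) all(h == 0), TRUE)))
})

test_that("in-vivo paired probe reports no inhibition without drive to B", {
  r <- run_adi_invivo(scheme = "default", separation_um = 300,
                      rates_A = c(5, 10), rates_B = c(0, 0.001),
                      n_instances = 1, opts = fixture_net_opts(),
                      base_seed = 44)
  expect_lt(abs(r$mean_inhibition), 3)
})

test_that("in-vitro paired slice probe runs, selects pairs and reports the
           reduction summary", {
  r <- run_adi_invitro(currents_A = c(0.5, 1.0), I_B = 1.2, n_seeds = 2,
                       n_select = 1, opts = fixture_net_opts(),
                       base_seed = 46)
  expect_equal(nrow(r$curves), 2 * 2)
  expect_length(r$selected, 1)
  expect_true(all(c("rate_alone", "mean_reduction") %in% names(r$summary)))
  expect_true(all(r$curves$rate_alone >= 0))
})
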