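# Shared fixtures: small networks and canned stimuli built in code.

fixture_net_opts <- function() {
  list(syn_per_mitral = 400L, soma_syn = 10L, pg_per_glom = 40L,
       pg_recip_per_mitral = 15L, pg_syn_target = 5L,
       orn_per_mitral = 40L, orn_per_pg = 8L, n_extra_shared = 15L)
}

fixture_instance <- function(seed = 3, scheme = "default", n_lateral = 1,
                             ...) {
  make_instance(seed = seed, scheme = scheme, n_lateral = n_lateral,
                opts = fixture_net_opts(), ...)
}

# a passive single-compartment model for integrator oracles
passive_comp <- function(L = 20, d = 20, Rm = 0.5, Em = -65) {
  cable_model(tibble::tibble(parent = 0L, L = L, d = d, Cm = 0.01,
                             Rm = Rm, Ra = 1, Em = Em, label = "soma"))
}
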