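# Shared fixtures for the suite. F1 is defined in the package (it is itself
# a tested module); helpers here only assemble derived objects.

f1 <- fixture_formulary_f1()

# All supported continuous (non-transdermal) drug/route pairs of F1.
f1_continuous <- local({
  dr <- f1$drug_routes
  dr[dr$supported & dr$route != "transdermal", c("drug", "route")]
})

# Mutations of the F1 file structure that each break exactly one formulary
# invariant; validation must reject every one and name the invariant.
f1_raw <- yaml::read_yaml(system.file("extdata", "formulary-f1.yaml",
                                      package = "omeconvert"))

mutate_f1 <- function(mutator) {
  x <- f1_raw
  mutator(x)
}

# A small deterministic log: n_conv drug-to-drug conversions and n_bt
# breakthrough calculations replayed through the engine.
small_log <- function(n_conv = 10, n_bt = 3, seed = 11) {
  n <- n_conv + n_bt
  spec <- fixture_spec(seed, n, frac_no_equivalence = 0, frac_border = 0,
                       frac_unsupported = 0, frac_breakthrough = n_bt / n)
  replay_requests(f1, generate_requests(spec))
}
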