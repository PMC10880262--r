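# Shared fixtures: one synthetic consensus library per test run (seeded,
# deterministic) and small convenience builders.

test_lib <- synthetic_consensus_library(seed = 101L)

mi120 <- library_unit(test_lib, "MiSat120")
masat <- library_unit(test_lib, "MaSat")

make_read <- function(sat_class, n, divergence = 0, seed = 1L, ...) {
  simulate_array_read(
    array_spec(sat_class, n, divergence = divergence, seed = seed, ...),
    test_lib, read_id = sprintf("%s_%d", sat_class, seed)
  )
}

random_read <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
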