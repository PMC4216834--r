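# Small networks reused across tests. Suppress the heavy-tail draw notes
# that rcauchy occasionally triggers.
quiet <- function(expr) suppressMessages(expr)

tiny_two_pop <- function(k_tc = 5, k_ct = 1.2, n = 200, ...) {
  two_population_network(k_tc, k_ct, n = n, ...)
}

# reduced parameters of the default minimal model at given couplings
minimal_params <- function(k_tc = 5.5, k_ct = 1.2) {
  as_oa_params(two_population_network(k_tc, k_ct))
}

# a synthetic sli_series with prescribed values (for duration logic tests)
fake_series <- function(times, values, offset = 50) {
  structure(list(times_ms = times,
                 sli = matrix(values, ncol = 1,
                              dimnames = list(NULL, "theta")),
                 stimulus = stimulus_spec(100, 0, offset),
                 n_oscillators = 1000),
            class = "sli_series")
}
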