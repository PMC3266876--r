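# Shared fixtures: everything is generated in code at test time.

ref_params <- function(k_d = 0.01)
  kinetic_params(k_g = 10, k_s = 0.1, k_o = 0.001, k_d = k_d)

# Small random parameter sets for property-style loops.
random_params <- function(n, seed = 101) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    kinetic_params(k_g = runif(1, 2, 15), k_s = runif(1, 0.05, 0.5),
                   k_o = runif(1, 5e-4, 5e-3), k_d = runif(1, 0, 0.5)))
}

# Protocol without destructive sampling: cheap brood-only cohorts.
brood_proto <- function(n = 30)
  observation_protocol(n_per_dense = 0, n_longitudinal = n)
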