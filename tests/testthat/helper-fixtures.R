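# Shared fixture builders; everything is generated in code under fixed seeds.

random_spd <- function(n, seed = 1, T_eff = 4 * n) {
  set.seed(seed)
  X <- matrix(rnorm(T_eff * n), T_eff, n)
  crossprod(X) / T_eff
}

# a small two-group cohort used by several suites
tiny_cohort <- function(seed = 1, n_per_group = 3, n_networks = 6,
                        n_volumes = 120) {
  spec <- synthetic_spec(n_subjects_per_group = n_per_group,
                         n_networks = n_networks, n_volumes = n_volumes,
                         groups = c("A", "B"), seed = seed)
  generate_cohort(spec)
}

# quadrature sinusoid pair at a resolvable frequency
quadrature_pair <- function(T = 290, f = 0.05, tr = 2.072) {
  tt <- (seq_len(T) - 1) * tr
  cbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))
}
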