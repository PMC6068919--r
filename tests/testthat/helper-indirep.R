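# Shared fixtures: the reference parameter set used throughout the
# analyses, and a reproducible sample of random simplex states.

printed_params <- function() {
  game_parameters(N = 100, pi = 1e6, c = 0.5e6, theta = 0.75, p = 0.5)
}

random_simplex_states <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(3 * n), ncol = 3)
  m / rowSums(m)
}

as_state <- function(row) population_state(row[1], row[2], row[3])
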