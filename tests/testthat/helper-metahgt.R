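# Generators for property-style tests. Callers fix the RNG seed.

random_state <- function(max_classes = 6L, max_char = 15L, max_count = 1000L) {
  k <- sample.int(max_classes, 1L)
  metapop(y = sample.int(max_char + 1L, k, replace = TRUE) - 1L,
          z = sample.int(max_char + 1L, k, replace = TRUE) - 1L,
          count = sample.int(max_count, k, replace = TRUE))
}

random_params <- function() {
  hgt_params(p_plus = stats::runif(1, 0, 5e-3),
             p_minus = stats::runif(1, 0, 1e-4),
             delta = stats::runif(1, 1e-3, 0.05),
             s = stats::runif(1, 0.05, 0.5),
             beta = stats::runif(1, 0, 0.1),
             n_max = sample(c(1e3, 1e4), 1L))
}

# mean z (or y) of a metapop state
state_mean <- function(state, coordinate) {
  m <- metapop_means(state)
  unname(if (coordinate == "z") m["mean_z"] else m["mean_y"])
}
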