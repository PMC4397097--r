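# small graphs built in code

star_network <- function(n_leaves = 10) {
  n <- n_leaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- 1
  a[2:n, 1] <- 1
  osc_network(a)
}

ring_network <- function(n = 8) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    a[i, j] <- a[j, i] <- 1
  }
  osc_network(a)
}

triangle_network <- function() {
  osc_network(matrix(1, 3, 3) - diag(3))
}

complete_network <- function(n) {
  osc_network(matrix(1, n, n) - diag(n))
}

# quick noise-free star run used by several tests; long enough that the
# symmetric leaf-leaf phase differences decay below the dPLI tie band
star_run <- function(n_samples = 40000, noise_sd = 0, S = 1.5, seed = 5) {
  cfg <- sim_config(S = S, delays = 0.010, omega_sd_hz = 0,
                    noise_sd = noise_sd, n_samples = n_samples, seed = seed)
  simulate_stuart_landau(star_network(), cfg)
}
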