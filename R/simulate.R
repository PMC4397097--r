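#' Simulation configuration
#'
#' Collects every oscillator, coupling, delay, noise, perturbation and
#' integration parameter for [simulate_stuart_landau()] and
#' [simulate_kuramoto()].
#'
#' @param S global coupling strength (dimensionless).
#' @param delays a `delay_matrix` from [build_delay_matrix()], or a single
#'   delay in seconds applied to every edge at simulation time.
#' @param lambda amplitude parameter, identical across nodes; default 2, so
#'   the uncoupled limit cycle has radius `sqrt(2)`.
#' @param omega_mean_hz,omega_sd_hz mean and sd (Hz) of the Gaussian natural
#'   frequencies; defaults 10 and 1, the alpha band.
#' @param noise_sd standard deviation of the additive Gaussian white noise
#'   applied to each of the amplitude and phase equations (Kuramoto: phase
#'   only); increments scale with `sqrt(dt)`. Default 2.
#' @param gamma hub-perturbation exponent: each node's coupling prefactor is
#'   `S / degree^gamma`. 0 leaves the network intact, 1 homogenizes the
#'   effective coupling. Default 0.
#' @param fs output sampling rate in Hz; the Euler step is `1/fs` divided by
#'   `substeps`. Default 1000.
#' @param n_samples total output samples including the initial state;
#'   default 10000.
#' @param burn_in_fraction fraction of samples discarded as transient by the
#'   analysis functions; default 0.5 (the retained window is the latter half).
#' @param seed optional integer seed covering frequencies, initial phases
#'   and noise.
#' @param model `"stuart_landau"` or `"kuramoto"`.
#' @param substeps integer integration substeps per output sample, for
#'   step-size convergence checks; default 1.
#' @param noise_mode `"polar"` (independent increments on amplitude and
#'   phase) or `"complex"` (additive complex increment).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(S, delays, lambda = 2, omega_mean_hz = 10,
                       omega_sd_hz = 1, noise_sd = 2, gamma = 0, fs = 1000,
                       n_samples = 10000, burn_in_fraction = 0.5,
                       seed = NULL, model = c("stuart_landau", "kuramoto"),
                       substeps = 1L, noise_mode = c("polar", "complex")) {
  model <- match.arg(model)
  noise_mode <- match.arg(noise_mode)
  stopifnot(fs > 0, n_samples >= 2, burn_in_fraction >= 0,
            burn_in_fraction < 1, noise_sd >= 0, gamma >= 0, substeps >= 1)
  structure(
    list(S = S, delays = delays, lambda = lambda,
         omega_mean_hz = omega_mean_hz, omega_sd_hz = omega_sd_hz,
         noise_sd = noise_sd, gamma = gamma, fs = fs,
         n_samples = as.integer(n_samples),
         burn_in_fraction = burn_in_fraction, seed = seed, model = model,
         substeps = as.integer(substeps), noise_mode = noise_mode),
    class = "sim_config")
}

#' Draw natural frequencies for a set of oscillators
#'
#' Frequencies are Gaussian in Hz and returned in rad/s.
#'
#' @param n number of oscillators.
#' @param omega_mean_hz,omega_sd_hz mean and sd in Hz.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`, rad/s.
#' @export
draw_natural_frequencies <- function(n, omega_mean_hz = 10, omega_sd_hz = 1,
                                     seed = NULL) {
  stopifnot(omega_sd_hz >= 0)
  with_seed(seed, 2 * pi * stats::rnorm(n, omega_mean_hz, omega_sd_hz))
}

delay_values <- function(delays, net) {
  if (inherits(delays, "delay_matrix")) return(delays$values)
  if (is.matrix(delays)) return(delays)
  net$adjacency * delays
}

run_simulation <- function(net, cfg) {
  n <- net$n_nodes
  a <- net$adjacency
  tau <- delay_values(cfg$delays, net)
  if (!all(dim(tau) == c(n, n))) stop("delay matrix does not match network")
  dt <- 1 / cfg$fs
  dtf <- dt / cfg$substeps

  # CSR neighbour structure with per-directed-edge lags in fine steps
  ptr <- integer(n + 1)
  idx <- integer(0)
  lag <- integer(0)
  nbrs <- lapply(seq_len(n), function(j) which(a[j, ] > 0))
  lags <- lapply(seq_len(n), function(j) as.integer(round(tau[j, nbrs[[j]]] / dtf)))
  ptr <- c(0L, cumsum(vapply(nbrs, length, 1L)))
  idx <- as.integer(unlist(nbrs) - 1L)
  lag <- as.integer(unlist(lags))

  run <- function() {
    omegas <- draw_natural_frequencies(n, cfg$omega_mean_hz, cfg$omega_sd_hz)
    theta0 <- stats::runif(n, -pi, pi)
    r0 <- rep(sqrt(cfg$lambda), n)
    pref <- cfg$S / pmax(net$degrees, 1)^cfg$gamma
    out <- sim_oscillators_cpp(
      ptr, idx, lag, pref, omegas, cfg$lambda, cfg$noise_sd, dt,
      cfg$n_samples, cfg$substeps, r0, theta0,
      if (cfg$model == "kuramoto") 1L else 0L,
      if (cfg$noise_mode == "complex") 1L else 0L)
    structure(
      list(r = out$r, theta = out$theta, fs = cfg$fs,
           retained_from = floor(cfg$burn_in_fraction * cfg$n_samples) + 1L,
           omegas = omegas, model = cfg$model, config = cfg),
      class = "trajectory_set")
  }
  with_seed(cfg$seed, run())
}

#' Simulate delay-coupled Stuart-Landau oscillators on a network
#'
#' Integrates the complex-state oscillator
#' `dz_j/dt = (lambda + i w_j - |z_j|^2) z_j + (S/g_j^gamma) sum_k K_jk
#' z_k(t - tau_jk)` plus noise with a stochastic Euler scheme at step
#' `1/(fs * substeps)`, reading delayed states from a ring-buffer history
#' (held at the initial state for t < 0). Initial amplitudes start on the
#' uncoupled limit cycle `r = sqrt(lambda)` with phases uniform on
#' `(-pi, pi]`, so any systematic phase-lead/lag structure in the output
#' must emerge from the network.
#'
#' @param net an [osc_network].
#' @param cfg a [sim_config] (its `model` field is overridden).
#' @return a `trajectory_set`: amplitude matrix `r` (n x T), unwrapped phase
#'   matrix `theta` (n x T, radians), `fs`, `retained_from` (first
#'   post-burn-in sample), realized `omegas` (rad/s).
#' @export
simulate_stuart_landau <- function(net, cfg) {
  cfg$model <- "stuart_landau"
  run_simulation(net, cfg)
}

#' Simulate delay-coupled Kuramoto oscillators on a network
#'
#' The phase-only limit of the Stuart-Landau network with all amplitudes
#' pinned at 1:
#' `dtheta_j/dt = w_j + (S/g_j^gamma) sum_k K_jk sin(theta_k(t - tau_jk)
#' - theta_j)` plus phase noise.
#'
#' @inheritParams simulate_stuart_landau
#' @return a `trajectory_set` with `r` identically 1.
#' @export
simulate_kuramoto <- function(net, cfg) {
  cfg$model <- "kuramoto"
  run_simulation(net, cfg)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %s: %d nodes x %d samples at %g Hz\n",
              x$model, nrow(x$r), ncol(x$r), x$fs))
  cat(sprintf("  retained window: samples %d..%d\n",
              x$retained_from, ncol(x$r)))
  invisible(x)
}

#' Retained (post burn-in) sample window of a trajectory set
#'
#' @param traj a `trajectory_set`.
#' @return integer vector `c(from, to)`, 1-based inclusive.
#' @export
retained_window <- function(traj) {
  c(traj$retained_from, ncol(traj$theta))
}
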