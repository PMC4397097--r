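#' Generate a brain-like network with posterior hubs
#'
#' Degrees are drawn from a truncated power law with exponential cutoff,
#' `P(k) ~ k^(-exponent) * exp(-k / cutoff_scale)` on
#' `[min_degree, n - 1]`, and a uniform connected simple realization is
#' sampled (Viger-Latapy). The defaults emulate the density of published
#' 78-region cortical DTI networks (mean degree around 7-8, largest hubs
#' around 20-25, no leaf nodes).
#'
#' Nodes are then placed on a synthetic anterior-posterior axis: sorted by
#' degree, the highest-degree nodes receive the most negative y coordinate
#' ("posterior") on a regular grid from -60 to +60 mm with small jitter,
#' and x/z are uniform in +/- 20 mm. This is a 1-D positional convention,
#' not anatomy: it guarantees by construction that hubs sit posterior of
#' peripheral nodes, mirroring the posterior-parietal hub concentration of
#' real cortical networks. Distances are Euclidean in mm.
#'
#' @param n number of nodes; default 78.
#' @param exponent power-law slope magnitude; default 1.
#' @param cutoff_scale exponential cutoff scale in degree units; default 8.
#' @param seed optional integer seed.
#' @param min_degree smallest allowed degree; default 3.
#' @return an [osc_network] with coordinates, distances and a
#'   `truth` attribute: data frame of per-node degree, y coordinate and
#'   anterior/central/posterior group (y terciles).
#' @export
make_brainlike_network <- function(n = 78, exponent = 1, cutoff_scale = 8,
                                   seed = NULL, min_degree = 3) {
  if (n < 20) stop("n must be at least 20")
  # continuous power law with exponential cutoff on [min_degree, n-1],
  # rounded to integer degrees; as cutoff_scale -> Inf with min_degree 1
  # this is exactly the law behind generate_scale_free()
  draw_degrees <- function() {
    lo <- min_degree; hi <- n - 1
    k <- numeric(n); need <- n
    while (need > 0) {
      u <- stats::runif(need)
      x <- if (abs(exponent - 1) < 1e-12) {
        lo * exp(u * log(hi / lo))
      } else {
        a <- exponent - 1
        (lo^(-a) - u * (lo^(-a) - hi^(-a)))^(-1 / a)
      }
      acc <- stats::runif(need) < exp(-(x - lo) / cutoff_scale)
      got <- x[acc]
      if (length(got)) {
        k[(n - need + 1):(n - need + length(got))] <- got
        need <- need - length(got)
      }
    }
    pmin(round(k), hi)
  }
  with_seed(seed, {
    g <- NULL
    for (i in 1:10000) {
      k <- draw_degrees()
      if (sum(k) %% 2 != 0 || sum(k) < 2 * (n - 1)) next
      g <- try(suppressWarnings(igraph::sample_degseq(k, method = "vl")),
               silent = TRUE)
      if (!inherits(g, "try-error")) break
      g <- NULL
    }
    if (is.null(g))
      stop("generation failure: no connected realization of the cutoff law")
    a <- unname(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
    deg <- rowSums(a)
    # posterior (negative y) band for the high-degree tercile, anterior
    # (positive y) band for the low-degree tercile, overlapping central
    # band between; this pins hubs posterior of peripherals without making
    # inter-node distance a monotone function of degree
    rk <- rank(-deg, ties.method = "first")
    band <- cut(rk, 3, labels = FALSE)
    y <- numeric(n)
    y[band == 1] <- stats::runif(sum(band == 1), -60, -10)
    y[band == 2] <- stats::runif(sum(band == 2), -35, 35)
    y[band == 3] <- stats::runif(sum(band == 3), 10, 60)
    coords <- cbind(x = stats::runif(n, -30, 30), y = y,
                    z = stats::runif(n, -25, 25))
    net <- osc_network(a, coordinates = coords)
    terc <- cut(y, stats::quantile(y, c(0, 1 / 3, 2 / 3, 1)),
                labels = c("posterior", "central", "anterior"),
                include.lowest = TRUE)
    attr(net, "truth") <- data.frame(node = seq_len(n), degree = deg,
                                     y = y, group = as.character(terc))
    net
  })
}

#' Simulate two-state multichannel recordings (intact vs hub-perturbed)
#'
#' Runs the Stuart-Landau network twice with identical frequencies, initial
#' conditions and noise stream: once with the intact topology
#' (`gamma = 0`, "wake-like") and once with degree-normalized coupling
#' (`gamma = 1`, "anesthesia-like", emulating preferential hub
#' disruption). The real part of each oscillator, `r cos(theta)`, over the
#' post-burn-in window is emitted as the channel signal, decimated from the
#' native 1000 Hz to the recording rate.
#'
#' Delays are a constant 10 ms per edge by default (the convention for
#' model networks); `delay_mode = "distance"` derives them from the node
#' coordinates at propagation speed `speed_m_s` instead.
#'
#' @param net an [osc_network], e.g. from [make_brainlike_network()].
#' @param duration_s recorded duration per state in seconds; default 300.
#' @param fs recording sampling rate; must divide 1000. Default 500.
#' @param seed optional integer seed shared by both states.
#' @param S coupling strength; default 3.
#' @param delay_mode `"constant"` (10 ms per edge) or `"distance"`.
#' @param speed_m_s conduction speed for distance delays; default 6.
#' @param noise_sd oscillator noise; default 2.
#' @param burn_s simulated transient discarded before recording; default 10.
#' @return list of class `brainlike_fixture`: `network`, `fs`,
#'   `states` (list of channels x samples matrices `wake`, `anesthesia`),
#'   `truth` (per-node degree and group data frame).
#' @export
make_two_state_recordings <- function(net, duration_s = 300, fs = 500,
                                      seed = NULL, S = 3,
                                      delay_mode = c("constant", "distance"),
                                      speed_m_s = 6, noise_sd = 2,
                                      burn_s = 10) {
  delay_mode <- match.arg(delay_mode)
  if (duration_s < 30) stop("duration must be at least 30 s")
  sim_fs <- 1000
  if (sim_fs %% fs != 0)
    stop("fs must divide the native simulation rate of 1000 Hz")
  dec <- sim_fs %/% fs
  delays <- if (delay_mode == "distance")
    suppressWarnings(build_delay_matrix(net, "distance", speed_m_s))
  else build_delay_matrix(net, "constant", 0.010)
  n_samples <- (duration_s + burn_s) * sim_fs
  one_state <- function(gamma) {
    cfg <- sim_config(S = S, delays = delays, gamma = gamma,
                      noise_sd = noise_sd, fs = sim_fs,
                      n_samples = n_samples,
                      burn_in_fraction = burn_s / (duration_s + burn_s),
                      seed = seed)
    traj <- simulate_stuart_landau(net, cfg)
    w <- retained_window(traj)
    keep <- seq(w[1], w[2], by = dec)
    sig <- traj$r[, keep, drop = FALSE] * cos(traj$theta[, keep, drop = FALSE])
    sig
  }
  truth <- attr(net, "truth")
  if (is.null(truth))
    truth <- data.frame(node = seq_len(net$n_nodes), degree = net$degrees)
  structure(list(network = net, fs = fs,
                 states = list(wake = one_state(0),
                               anesthesia = one_state(1)),
                 truth = truth),
            class = "brainlike_fixture")
}
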