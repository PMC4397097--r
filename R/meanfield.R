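#' Steady-state and mean-field summary of a trajectory set
#'
#' Over the retained window this computes per-node steady amplitudes
#' `r_star` (time means of `r_j`), the population mean field
#' `Z(t) = mean_j z_j(t)` whose time-averaged magnitude is the order
#' parameter `R_tilde` and whose argument is the mean phase `Phi(t)`, and
#' per-node steady relative phases `phi_star` (circular mean of
#' `theta_j - Phi(t)`). When the network and coupling strength are
#' supplied, the per-node effective coupling `K = degree * S` and the
#' delay phase `beta = mean(omega) * mean edge delay` are attached.
#'
#' A warning is attached (field `stationary = FALSE`) when the first- and
#' second-half amplitude means differ by more than 10%, indicating the
#' window still contains transient drift.
#'
#' @param traj a `trajectory_set`.
#' @param net optional [osc_network] the trajectories were simulated on.
#' @param S optional coupling strength used in the simulation.
#' @return list of class `meanfield_state` with fields `r_star`,
#'   `phi_star`, `R_tilde`, `Phi`, `K`, `beta`, `stationary`.
#' @export
meanfield_state <- function(traj, net = NULL, S = NULL) {
  w <- retained_window(traj)
  idx <- w[1]:w[2]
  if (length(idx) < 20 * traj$fs / mean(traj$omegas / (2 * pi)))
    warning("retained window covers fewer than 20 mean cycles")
  r <- traj$r[, idx, drop = FALSE]
  th <- traj$theta[, idx, drop = FALSE]

  r_star <- rowMeans(r)
  half <- floor(ncol(r) / 2)
  r1 <- rowMeans(r[, 1:half, drop = FALSE])
  r2 <- rowMeans(r[, (half + 1):ncol(r), drop = FALSE])
  stationary <- all(abs(r1 - r2) <= 0.10 * pmax(r_star, .Machine$double.eps))
  if (!stationary)
    warning("non-stationary drift: first/second-half amplitudes differ > 10%")

  z <- r * exp(1i * th)
  Z <- colMeans(z)
  R_tilde <- mean(Mod(Z))
  Phi <- Arg(Z)
  rel <- exp(1i * sweep(th, 2, Phi, `-`))
  phi_star <- Arg(rowMeans(rel))

  K <- beta <- NULL
  if (!is.null(net) && !is.null(S)) {
    K <- net$degrees * S
    cfg <- traj$config
    tau <- delay_values(cfg$delays, net)
    edge_tau <- tau[net$adjacency > 0]
    if (length(edge_tau)) beta <- mean(traj$omegas) * mean(edge_tau)
  }
  structure(list(r_star = r_star, phi_star = phi_star, R_tilde = R_tilde,
                 Phi = Phi, K = K, beta = beta, stationary = stationary),
            class = "meanfield_state")
}

#' Check the monotone coupling-amplitude relation
#'
#' The mean-field analysis predicts that `(K_j * R_tilde)^2` increases
#' monotonically with the squared steady amplitude `(r_star_j)^2`. This
#' reports the Spearman correlation between the two, the fraction of
#' variance captured by an isotonic (monotone nondecreasing) fit, and a
#' pass flag at `rho > 0.9` (an implementer-chosen acceptance constant,
#' not a theoretical bound).
#'
#' @param state a `meanfield_state` carrying `K` (supply `net` and `S` to
#'   [meanfield_state()]).
#' @return list with `rho`, `isotonic_R2`, `pass`, or `applicable = FALSE`
#'   when fewer than 3 distinct `K` values exist.
#' @export
check_amplitude_monotonicity <- function(state) {
  if (is.null(state$K)) stop("state carries no effective coupling K")
  x <- (state$K * state$R_tilde)^2
  y <- state$r_star^2
  if (length(unique(state$K)) < 3)
    return(list(applicable = FALSE, rho = NA_real_, isotonic_R2 = NA_real_,
                pass = NA))
  rho <- spearman_cor(x, y)$rho
  o <- order(x)
  iso <- stats::isoreg(x[o], y[o])
  ss_res <- sum((y[o] - iso$yf)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(applicable = TRUE, rho = rho,
       isotonic_R2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       pass = rho > 0.9)
}

wrap_pi <- function(d) {
  w <- d %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Check the degree-amplitude-phase orderings
#'
#' For every node pair with strictly different degrees this tallies how
#' often the higher-degree node has (a) the larger steady amplitude and
#' (b) the smaller steady relative phase, i.e. lags. The phase comparison
#' is restricted to nodes whose `phi_star + beta` lies inside
#' `(-pi/2, pi/2)`, the band where the mean-field tangent relation is
#' monotone. Group-level node-dPLI means for hubs and peripherals are
#' reported alongside.
#'
#' @param net an [osc_network].
#' @param state a `meanfield_state`.
#' @param dpli_node per-node average dPLI (see [node_dpli()]).
#' @param peripheral_rule passed to [classify_nodes()].
#' @return list with `frac_amplitude`, `frac_phase`, `n_pairs`,
#'   `n_phase_pairs`, `hub_mean_dpli`, `peripheral_mean_dpli`.
#' @export
check_orderings <- function(net, state, dpli_node,
                            peripheral_rule = "degree_one") {
  k <- net$degrees
  n <- length(k)
  pr <- t(utils::combn(n, 2))
  diff_deg <- k[pr[, 1]] != k[pr[, 2]]
  pr <- pr[diff_deg, , drop = FALSE]
  hi <- ifelse(k[pr[, 1]] > k[pr[, 2]], pr[, 1], pr[, 2])
  lo <- ifelse(k[pr[, 1]] > k[pr[, 2]], pr[, 2], pr[, 1])

  frac_amp <- mean(state$r_star[hi] > state$r_star[lo])

  beta <- if (is.null(state$beta)) 0 else state$beta
  phi <- wrap_pi(state$phi_star)
  eligible <- abs(wrap_pi(phi + beta)) < pi / 2
  ok <- eligible[hi] & eligible[lo]
  frac_phase <- if (any(ok)) mean(phi[hi[ok]] < phi[lo[ok]]) else NA_real_

  cls <- classify_nodes(net, peripheral_rule = peripheral_rule)
  list(frac_amplitude = frac_amp, frac_phase = frac_phase,
       n_pairs = nrow(pr), n_phase_pairs = sum(ok),
       hub_mean_dpli = if (length(cls$hubs)) mean(dpli_node[cls$hubs])
                       else NA_real_,
       peripheral_mean_dpli = if (length(cls$peripherals))
         mean(dpli_node[cls$peripherals]) else NA_real_)
}
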