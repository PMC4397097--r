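test_that("natural frequency draws have the requested moments", {
  w <- draw_natural_frequencies(5, 10, 0, seed = 1)
  expect_equal(w, rep(20 * pi, 5))
  w2 <- draw_natural_frequencies(10000, 10, 1, seed = 2)
  se <- 2 * pi * 1 / sqrt(10000)
  expect_lt(abs(mean(w2) - 20 * pi), 3 * se)
  expect_identical(w2, draw_natural_frequencies(10000, 10, 1, seed = 2))
})

test_that("uncoupled noise-free oscillators sit on the limit cycle", {
  net <- complete_network(5)
  cfg <- sim_config(S = 0, delays = 0.010, noise_sd = 0, seed = 7)
  tr <- simulate_stuart_landau(net, cfg)
  w <- retained_window(tr)
  expect_lt(max(abs(tr$r[, w[1]:w[2]] - sqrt(2))), 1e-3)
  # phase velocity equals the natural frequency
  slope <- (tr$theta[, 10000] - tr$theta[, 5000]) / 5
  expect_lt(max(abs(slope - tr$omegas)), 1e-6)
})

test_that("two coupled identical oscillators synchronize in phase", {
  net <- osc_network(matrix(c(0, 1, 1, 0), 2))
  cfg <- sim_config(S = 1.5, delays = 1e-9, omega_sd_hz = 0, noise_sd = 0,
                    seed = 3)
  tr <- simulate_stuart_landau(net, cfg)
  d <- tr$theta[1, 10000] - tr$theta[2, 10000]
  expect_lt(abs(atan2(sin(d), cos(d))), 1e-6)
})

test_that("star-graph center gains amplitude and phase-lags every leaf", {
  tr <- star_run()
  st <- meanfield_state(tr, star_network(), 1.5)
  expect_true(all(st$r_star[1] > st$r_star[-1]))
  cm <- connectivity_matrices(tr)
  expect_lt(cm$node_dpli[1], 0)
  expect_true(all(cm$node_dpli[-1] > 0))
  # fine-step oracle: 10x smaller step preserves orderings and amplitudes
  cfgf <- tr$config; cfgf$substeps <- 10L
  trf <- simulate_stuart_landau(star_network(), cfgf)
  stf <- meanfield_state(trf, star_network(), 1.5)
  expect_true(all(stf$r_star[1] > stf$r_star[-1]))
  expect_lt(abs(stf$r_star[1] - st$r_star[1]) / st$r_star[1], 0.02)
  cmf <- connectivity_matrices(trf)
  expect_lt(cmf$node_dpli[1], 0)
})

test_that("identical configuration and seed give bit-identical trajectories", {
  net <- generate_scale_free(40, 2.2, seed = 1)
  cfg <- sim_config(S = 1.5, delays = 0.010, seed = 42, n_samples = 2000)
  t1 <- simulate_stuart_landau(net, cfg)
  t2 <- simulate_stuart_landau(net, cfg)
  expect_identical(t1$r, t2$r)
  expect_identical(t1$theta, t2$theta)
})

test_that("Kuramoto model keeps unit amplitude and locks at strong coupling", {
  net <- complete_network(8)
  cfg <- sim_config(S = 50, delays = 1e-9, omega_sd_hz = 1, noise_sd = 0,
                    seed = 4, n_samples = 4000)
  tr <- simulate_kuramoto(net, cfg)
  expect_true(all(tr$r == 1))
  pc <- phase_coherence(tr$theta, retained_window(tr))
  expect_gt(min(pc), 0.99)
})

test_that("uncoupled Kuramoto rotators show no consistent lead/lag", {
  net <- complete_network(6)
  # default noise: phase diffusion decorrelates even near-degenerate
  # frequency pairs; the window must cover many diffusion mixing times
  # (~1/8 s here) for every pairwise estimate to settle near zero
  cfg <- sim_config(S = 0, delays = 1e-9, omega_sd_hz = 1, seed = 5,
                    n_samples = 400000)
  tr <- simulate_kuramoto(net, cfg)
  d <- dpli(tr$theta, retained_window(tr))
  expect_lt(max(abs(d)), 0.1)
})

test_that("Stuart-Landau phase increments reduce to Kuramoto at equal amplitudes", {
  # both models start with r = sqrt(lambda) everywhere, so the first-step
  # phase increments must agree to O(dt^2)
  net <- ring_network(6)
  cfg <- sim_config(S = 1, delays = 1e-9, noise_sd = 0, seed = 6,
                    n_samples = 2)
  tsl <- simulate_stuart_landau(net, cfg)
  tku <- simulate_kuramoto(net, cfg)
  diff1 <- max(abs((tsl$theta[, 2] - tsl$theta[, 1]) -
                   (tku$theta[, 2] - tku$theta[, 1])))
  expect_lt(diff1, 1e-3)
  # first-order agreement: substepping shrinks the discrepancy
  cfg5 <- cfg; cfg5$substeps <- 5L
  t5s <- simulate_stuart_landau(net, cfg5)
  t5k <- simulate_kuramoto(net, cfg5)
  diff5 <- max(abs((t5s$theta[, 2] - t5s$theta[, 1]) -
                   (t5k$theta[, 2] - t5k$theta[, 1])))
  expect_lt(diff5, diff1 / 2)
})

test_that("degree-normalized coupling (gamma = 1) homogenizes amplitudes", {
  star <- star_network()
  run <- function(gamma) {
    cfg <- sim_config(S = 1.5, delays = 0.010, omega_sd_hz = 0, noise_sd = 0,
                      gamma = gamma, seed = 8)
    st <- meanfield_state(simulate_stuart_landau(star, cfg))
    st$r_star[1] - mean(st$r_star[-1])  # hub-peripheral amplitude gap
  }
  gap0 <- run(0); gap1 <- run(1)
  expect_lt(abs(gap1) / abs(gap0), 0.3)
})

test_that("hub lag on the star is robust to moderate noise", {
  # at noise sd 1 the ~0.4 rad center lag angle stays well above the phase
  # fluctuation; at sd 2 only the amplitude ordering remains reliable on a
  # graph this small (11 nodes)
  ok <- vapply(1:100, function(s) {
    cfg <- sim_config(S = 1.5, delays = 0.010, omega_sd_hz = 0, noise_sd = 1,
                      seed = s, n_samples = 10000)
    tr <- simulate_stuart_landau(star_network(), cfg)
    nd <- node_dpli(dpli(tr$theta, retained_window(tr)))
    rs <- rowMeans(tr$r[, tr$retained_from:10000])
    nd[1] < 0 && rs[1] == max(rs)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  ok2 <- vapply(1:20, function(s) {
    cfg <- sim_config(S = 1.5, delays = 0.010, omega_sd_hz = 0, noise_sd = 2,
                      seed = 200 + s, n_samples = 10000)
    tr <- simulate_stuart_landau(star_network(), cfg)
    rs <- rowMeans(tr$r[, tr$retained_from:10000])
    rs[1] == max(rs)
  }, logical(1))
  expect_gte(mean(ok2), 0.95)
})

test_that("phase-lag orderings are invariant across sub-quarter-cycle delays", {
  net <- make_brainlike_network(seed = 31)
  signs <- vapply(c(0.002, 0.005, 0.010, 0.020), function(tau) {
    cfg <- sim_config(S = 3, delays = tau, noise_sd = 0, seed = 32)
    tr <- simulate_stuart_landau(net, cfg)
    nd <- node_dpli(dpli(tr$theta, retained_window(tr)))
    sign(spearman_cor(net$degrees, nd)$rho)
  }, numeric(1))
  expect_true(all(signs == -1))
})

test_that("blow-ups are reported as integration failures", {
  net <- complete_network(4)
  # absurdly strong coupling with a long step drives the state non-finite
  cfg <- sim_config(S = 1e8, delays = 1e-9, noise_sd = 0, seed = 1,
                    n_samples = 200)
  expect_error(simulate_stuart_landau(net, cfg), "integration failure")
})
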