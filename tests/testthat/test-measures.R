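test_that("Hilbert phase recovers tones and constant lags", {
  fs <- 1000; t <- seq(0, 2, by = 1 / fs)
  x <- rbind(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t - pi / 4))
  ph <- instantaneous_phase(x, fs)
  interior <- 200:1800
  slope <- diff(ph[1, interior])
  slope <- atan2(sin(slope), cos(slope)) * fs
  expect_lt(max(abs(slope - 2 * pi * 10)), 1e-2 * 2 * pi * 10)
  d <- ph[1, interior] - ph[2, interior]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - pi / 4)), 0.02)
  expect_error(instantaneous_phase(rbind(x[1, ], 0 * t), fs), "degenerate")
})

test_that("analytic signal matches an independent FFT quadrature construction", {
  set.seed(1)
  fs <- 500
  x <- as.numeric(stats::filter(rnorm(2048), rep(1, 10), sides = 1))
  x[is.na(x)] <- 0
  x <- x - mean(x)
  ph <- instantaneous_phase(rbind(x), fs)[1, ]
  # independent oracle: quadrature by explicit spectral rotation -i*sign(f)
  X <- stats::fft(x); n <- length(x)
  freqs <- c(0, rep(1, n / 2 - 1), 0, rep(-1, n / 2 - 1))
  q <- Re(stats::fft(X * (-1i * freqs), inverse = TRUE) / n)
  ph2 <- atan2(q, x)
  expect_lt(max(abs(atan2(sin(ph - ph2), cos(ph - ph2)))), 1e-6)
})

test_that("phase coherence honors its analytic limits", {
  t <- seq(0, 5, by = 1e-3)
  base <- 2 * pi * 10 * t
  ph <- rbind(base, base, base + 0.7)
  pc <- phase_coherence(ph)
  expect_equal(pc[1, 2], 1)
  expect_equal(pc[1, 3], 1)  # constant lag still coheres fully
  set.seed(2)
  T <- 5000
  ph2 <- rbind(runif(T, -pi, pi), rep(0, T))
  pc2 <- phase_coherence(ph2)
  expect_lt(pc2[1, 2], 3 / sqrt(T))
})

test_that("dPLI and PLI follow the sign contract", {
  T <- 1000
  lead <- rbind(rep(0.3, T), rep(0, T))      # constant positive lag
  d <- dpli(lead)
  expect_equal(d[1, 2], 1)
  expect_equal(pli(lead)[1, 2], 1)
  same <- rbind(rep(1, T), rep(1, T))
  expect_equal(dpli(same)[1, 2], 0)
  # half leads, half lags: brute-force sign tally says zero
  eps <- 0.01
  mixed <- rbind(c(rep(eps, T / 2), rep(-eps, T / 2)), rep(0, T))
  expect_equal(dpli(mixed)[1, 2], 0)
  tally <- mean(sign(mixed[1, ] - mixed[2, ]))
  expect_equal(dpli(mixed)[1, 2], tally)
})

test_that("measure identities hold on arbitrary phase matrices", {
  set.seed(3)
  for (i in 1:5) {
    ph <- matrix(cumsum(rnorm(6 * 500, 0.06, 0.05)), 6, 500)
    d <- dpli(ph); p <- pli(ph); pc <- phase_coherence(ph)
    expect_equal(p, abs(d))
    expect_equal(d, -t(d))
    expect_equal(diag(d), rep(0, 6))
    expect_true(all(pc >= 0 & pc <= 1))
    expect_true(all(d >= -1 & d <= 1))
    expect_equal(pc, t(pc))
  }
})

test_that("node_dpli averages rows and sums to zero", {
  m <- matrix(c(0, -0.6, 0.6, 0), 2)  # node 1 leads node 2 by 0.6
  expect_equal(node_dpli(m), c(0.6, -0.6))
  set.seed(4)
  u <- matrix(rnorm(25), 5); a <- u - t(u); diag(a) <- 0
  nd <- node_dpli(a)
  expect_lt(abs(sum(nd)), 1e-12)
  # brute-force loop oracle
  oracle <- sapply(1:5, function(i) mean(a[i, -i]))
  expect_equal(nd, oracle)
  expect_error(node_dpli(matrix(0, 1, 1)), "at least 2")
})

test_that("zero-phase band-pass keeps in-band tones and kills out-of-band ones", {
  fs <- 500; t <- seq(0, 4, by = 1 / fs)
  alpha <- band_presets()$alpha
  tone10 <- sin(2 * pi * 10 * t)
  tone50 <- sin(2 * pi * 50 * t)
  f10 <- bandpass_filter(tone10, fs, alpha)
  f50 <- bandpass_filter(tone50, fs, alpha)
  mid <- 500:1500
  expect_lt(abs(sd(f10[mid]) / sd(tone10[mid]) - 1), 0.05)
  expect_lt(20 * log10(sd(f50[mid]) / sd(tone50[mid])), -40)
  # zero phase: cross-correlation of an in-band tone peaks at lag 0
  cc <- stats::ccf(f10[mid], tone10[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass_filter(tone10, fs, band_spec("bad", 10, 400)),
               "Nyquist")
})

test_that("band amplitude scales with power and tracks oscillator amplitude", {
  fs <- 500; t <- seq(0, 10, by = 1 / fs)
  alpha <- band_presets()$alpha
  a1 <- band_amplitude(rbind(sin(2 * pi * 10 * t)), fs, alpha)
  a2 <- band_amplitude(rbind(2 * sin(2 * pi * 10 * t)), fs, alpha)
  expect_equal(unname(a2 / a1), 4, tolerance = 1e-6)
  # white noise: flat spectrum, alpha mean PSD matches broadband mean
  set.seed(5)
  ratios <- replicate(100, {
    x <- rnorm(4 * fs)
    sp_a <- band_amplitude(rbind(x), fs, alpha)
    sp_w <- band_amplitude(rbind(x), fs, band_spec("bb", 0.5, 249))
    sp_a / sp_w
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
  # simulated star: band amplitude ranks like the model amplitude r
  tr <- star_run(n_samples = 10000)
  w <- retained_window(tr); idx <- w[1]:w[2]
  sig <- tr$r[, idx] * cos(tr$theta[, idx])
  amp <- band_amplitude(sig, 1000, alpha)
  rbar <- rowMeans(tr$r[, idx])
  expect_equal(order(amp), order(rbar))
})

test_that("symbolic transfer entropy detects directional forcing", {
  set.seed(6)
  x <- rnorm(3000)
  y <- c(rnorm(5), x[1:2995])  # y is a lagged copy of x
  s_xy <- symbolic_transfer_entropy(y, x, prediction_times = 1:10)  # x -> y
  s_yx <- symbolic_transfer_entropy(x, y, prediction_times = 1:10)
  expect_gt(s_xy, s_yx)
  # independent pair: below a shuffle-null bound
  a <- rnorm(3000); b <- rnorm(3000)
  s_ab <- symbolic_transfer_entropy(b, a, prediction_times = 1:10)
  null <- replicate(100,
    symbolic_transfer_entropy(sample(b), a, prediction_times = 1:10))
  expect_lt(s_ab, quantile(null, 0.99) + 1e-9)
  expect_error(symbolic_transfer_entropy(rnorm(50), rnorm(50)), "too short")
})

test_that("Granger causality separates driver from follower", {
  set.seed(7)
  n <- 3000
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  y <- numeric(n)
  for (t in 2:n) y[t] <- 0.4 * y[t - 1] + 0.5 * x[t - 1] + rnorm(1)
  g <- granger_causality(x, y)
  expect_gt(g$gc_xy, g$gc_yx)
  expect_gt(g$gc_xy, 0.05)
  # independent AR(1) pair: both directions below the shuffle null
  a <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  b <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  g0 <- granger_causality(a, b)
  null <- replicate(50, {
    gs <- granger_causality(a, sample(b))
    max(gs$gc_xy, gs$gc_yx)
  })
  expect_lt(max(g0$gc_xy, g0$gc_yx), quantile(null, 0.95) + 0.01)
})
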