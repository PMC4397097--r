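#' Frequency band specification
#'
#' @param name band label.
#' @param lo_hz,hi_hz band edges in Hz, `0 < lo < hi`.
#' @return list of class `band_spec`.
#' @export
band_spec <- function(name, lo_hz, hi_hz) {
  stopifnot(lo_hz > 0, hi_hz > lo_hz)
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_spec")
}

#' Standard EEG analysis bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-25, gamma 25-55 and the
#' whole band 0.5-55 Hz.
#'
#' @return named list of [band_spec] objects.
#' @export
band_presets <- function() {
  list(delta = band_spec("delta", 0.5, 4),
       theta = band_spec("theta", 4, 8),
       alpha = band_spec("alpha", 8, 13),
       beta  = band_spec("beta", 13, 25),
       gamma = band_spec("gamma", 25, 55),
       whole = band_spec("whole", 0.5, 55))
}

# analytic signal of one real series via the one-sided FFT construction
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase by Hilbert transform
#'
#' Channels are de-meaned, the analytic signal is formed per channel and its
#' argument returned (wrapped phase).
#'
#' @param signals channels x samples real matrix.
#' @param fs sampling rate in Hz (attached to the result as an attribute).
#' @return channels x samples matrix of phases in radians, attribute `fs`.
#' @export
instantaneous_phase <- function(signals, fs) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 64) stop("need at least 64 samples per channel")
  flat <- which(apply(signals, 1, function(x) stats::sd(x) == 0))
  if (length(flat))
    stop("constant (degenerate) channel(s): ", paste(flat, collapse = ", "))
  ph <- t(apply(signals, 1, function(x) Arg(analytic_signal(x - mean(x)))))
  attr(ph, "fs") <- fs
  ph
}

resolve_window <- function(phases, window) {
  T <- ncol(phases)
  if (is.null(window)) return(c(1L, T))
  w <- as.integer(window[c(1, length(window))])
  if (w[1] < 1 || w[2] > T || w[1] > w[2]) stop("invalid sample window")
  w
}

#' Mean phase coherence (PC)
#'
#' `PC_jk = |mean_t exp(i (theta_j - theta_k))|`: 1 for complete phase
#' synchronization (including any constant lag), near 0 for independent
#' phases.
#'
#' @param phases channels x samples phase matrix (radians).
#' @param window `c(from, to)` sample range, or `NULL` for all samples.
#' @return symmetric n x n matrix in `[0, 1]` with unit diagonal.
#' @export
phase_coherence <- function(phases, window = NULL) {
  w <- resolve_window(phases, window)
  phase_pair_stats_cpp(phases, w[1], w[2], 0, TRUE)$pc
}

#' Directed phase lag index (dPLI)
#'
#' The time average of the sign of the phase difference
#' `theta_i - theta_j`, wrapped to `(-pi, pi]`. Positive values mean
#' channel `i` consistently leads channel `j`, negative that it lags;
#' values near zero mean no consistent lead/lag relation.
#'
#' Wrapped differences smaller in magnitude than `tie_tol` count as ties
#' (sign 0). The default tolerance, 1e-8 rad, is far below any physically
#' resolvable phase difference and only matters for the degenerate case of
#' exactly symmetric noise-free oscillators, whose phase differences decay
#' to numerical rounding noise with an arbitrary persistent sign.
#'
#' @inheritParams phase_coherence
#' @param tie_tol tie band in radians; 0 restores the literal sign rule.
#' @return antisymmetric n x n matrix in `[-1, 1]`, zero diagonal.
#' @export
dpli <- function(phases, window = NULL, tie_tol = 1e-8) {
  w <- resolve_window(phases, window)
  phase_pair_stats_cpp(phases, w[1], w[2], tie_tol, FALSE)$dpli
}

#' Phase lag index (PLI)
#'
#' The magnitude of [dpli()]: near 1 when one channel's phase is
#' consistently ahead of the other's, near 0 when lead and lag alternate.
#'
#' @inheritParams dpli
#' @return symmetric n x n matrix in `[0, 1]`, zero diagonal.
#' @export
pli <- function(phases, window = NULL, tie_tol = 1e-8) {
  abs(dpli(phases, window, tie_tol))
}

#' Per-node average dPLI
#'
#' Averages each node's dPLI with respect to all other nodes. Nodes with
#' negative values lag the rest of the network on average (directional
#' sinks); the vector sums to zero by antisymmetry.
#'
#' @param dpli_matrix antisymmetric dPLI matrix.
#' @return numeric vector of length n.
#' @export
node_dpli <- function(dpli_matrix) {
  n <- nrow(dpli_matrix)
  if (n < 2) stop("need at least 2 nodes")
  if (max(abs(dpli_matrix + t(dpli_matrix))) > 1e-12)
    stop("dpli matrix must be antisymmetric")
  rowSums(dpli_matrix) / (n - 1)
}

#' All pairwise connectivity matrices of a trajectory set
#'
#' Computes PC, PLI and dPLI from the model phases over the retained
#' (post burn-in) window, plus the per-node average dPLI.
#'
#' @param traj a `trajectory_set`.
#' @param window sample range; defaults to the retained window.
#' @return list with `pc`, `pli`, `dpli`, `node_dpli`.
#' @export
connectivity_matrices <- function(traj, window = retained_window(traj)) {
  w <- resolve_window(traj$theta, window)
  st <- phase_pair_stats_cpp(traj$theta, w[1], w[2], 1e-8, TRUE)
  list(pc = st$pc, pli = abs(st$dpli), dpli = st$dpli,
       node_dpli = node_dpli(st$dpli))
}

#' Zero-phase Butterworth band-pass filter
#'
#' A fifth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), cancelling the filter's phase shift; the effective
#' magnitude response is the squared single-pass response.
#'
#' @param signals channels x samples matrix (or vector).
#' @param fs sampling rate, Hz.
#' @param band a [band_spec].
#' @param order single-pass filter order; default 5.
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(signals, fs, band, order = 5) {
  if (band$hi_hz >= fs / 2)
    stop("band edge must be below the Nyquist frequency")
  bf <- signal::butter(order, c(band$lo_hz, band$hi_hz) / (fs / 2),
                       type = "pass")
  one <- function(x) signal::filtfilt(bf, x)
  if (is.matrix(signals)) t(apply(signals, 1, one)) else one(signals)
}

# Hamming-windowed Welch PSD (one-sided), segments of seg_len samples with
# 50% overlap, mean of modified periodograms
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1))
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    half <- p[1:nf]
    if (seg_len %% 2 == 0) half[2:(nf - 1)] <- 2 * half[2:(nf - 1)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1) * fs / seg_len, psd = acc / length(starts))
}

#' Band amplitude from the mean power spectral density
#'
#' The Welch-averaged modified periodogram (Hamming window, 2-s segments,
#' 50% overlap) is computed per channel, and the amplitude is the mean PSD
#' over the frequency bins inside the band.
#'
#' @param signals channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param band a [band_spec].
#' @param seg_seconds Welch segment length in seconds; default 2.
#' @return numeric vector of per-channel band amplitudes.
#' @export
band_amplitude <- function(signals, fs, band, seg_seconds = 2) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 2 * fs)
    stop("need at least 2 s of signal")
  seg_len <- round(seg_seconds * fs)
  apply(signals, 1, function(x) {
    sp <- welch_psd(x, fs, seg_len)
    sel <- sp$freq >= band$lo_hz & sp$freq <= band$hi_hz
    if (!any(sel)) stop("band contains no FFT bins at this resolution")
    mean(sp$psd[sel])
  })
}

# ordinal-pattern symbols of embedding dimension 3 (6 patterns), codes 1..6
ordinal_symbols3 <- function(x) {
  n <- length(x) - 2
  a <- x[1:n]; b <- x[2:(n + 1)]; c <- x[3:(n + 2)]
  code <- integer(n)
  code[a <= b & b <= c] <- 1L
  code[a <= c & c <  b] <- 2L
  code[b <  a & a <= c] <- 3L
  code[b <= c & c <  a] <- 4L
  code[c <  a & a <= b] <- 5L
  code[c <  b & b <  a] <- 6L
  code
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Symbolic transfer entropy (STE)
#'
#' Both series are symbolized into ordinal patterns of embedding dimension 3
#' and the transfer entropy `STE(y -> x) = H(x+ | x) - H(x+ | x, y)` is
#' estimated from pattern counts, where `x+` is the symbol of `x` a
#' prediction time ahead. The prediction time is scanned over
#' `prediction_times` and the maximum taken.
#'
#' @param x,y numeric series of equal length (direction measured: `y` to
#'   `x`).
#' @param embedding_dim ordinal pattern length; only 3 is implemented.
#' @param prediction_times candidate prediction horizons in samples.
#' @return scalar STE estimate (nats), >= 0 up to estimation noise;
#'   attribute `prediction_time` holds the maximizing horizon.
#' @export
symbolic_transfer_entropy <- function(x, y, embedding_dim = 3,
                                      prediction_times = 1:50) {
  if (embedding_dim != 3) stop("only embedding dimension 3 is implemented")
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 20 * max(prediction_times))
    stop("series too short for the requested prediction times")
  sx <- ordinal_symbols3(x)
  sy <- ordinal_symbols3(y)
  n <- length(sx)
  best <- -Inf; best_d <- NA_integer_
  for (d in prediction_times) {
    m <- n - d
    xf <- sx[(1 + d):n]; xp <- sx[1:m]; yp <- sy[1:m]
    c_xfx  <- tabulate(xf + 6L * (xp - 1L), 36)
    c_x    <- tabulate(xp, 6)
    c_xfxy <- tabulate(xf + 6L * (xp - 1L) + 36L * (yp - 1L), 216)
    c_xy   <- tabulate(xp + 6L * (yp - 1L), 36)
    te <- (entropy_counts(c_xfx) - entropy_counts(c_x)) -
          (entropy_counts(c_xfxy) - entropy_counts(c_xy))
    if (te > best) { best <- te; best_d <- d }
  }
  structure(best, prediction_time = best_d)
}

#' Pairwise linear Granger causality
#'
#' Fits autoregressive models of the given order by ordinary least squares
#' and returns the log ratio of restricted to full residual variances in
#' each direction: `gc_xy` measures `x -> y`, `gc_yx` measures `y -> x`.
#'
#' @param x,y numeric series of equal length.
#' @param order autoregressive model order; default 12.
#' @return list with `gc_xy` and `gc_yx`.
#' @export
granger_causality <- function(x, y, order = 12) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n <= 10 * order) stop("series too short for this model order")
  lagmat <- function(v) {
    m <- stats::embed(v, order + 1)
    m[, -1, drop = FALSE]  # columns are lags 1..order
  }
  lx <- lagmat(x); ly <- lagmat(y)
  tx <- x[(order + 1):n]; ty <- y[(order + 1):n]
  rss <- function(yv, X) {
    f <- stats::.lm.fit(cbind(1, X), yv)
    sum(f$residuals^2)
  }
  gc_one <- function(target, own, other) {
    r_restricted <- rss(target, own)
    r_full <- rss(target, cbind(own, other))
    if (r_full <= 0) stop("numerical failure: singular full-model fit")
    log(r_restricted / r_full)
  }
  list(gc_xy = gc_one(ty, ly, lx), gc_yx = gc_one(tx, lx, ly))
}
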