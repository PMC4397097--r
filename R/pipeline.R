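#' Split a multichannel recording into non-overlapping epochs
#'
#' @param signals channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param epoch_seconds epoch length in seconds; default 10 (a
#'   pseudo-stationary window for resting EEG).
#' @return list of channels x epoch-samples matrices; a trailing remainder
#'   shorter than one epoch is dropped.
#' @export
segment_epochs <- function(signals, fs, epoch_seconds = 10) {
  signals <- as.matrix(signals)
  len <- round(epoch_seconds * fs)
  n_ep <- floor(ncol(signals) / len)
  if (n_ep < 1) stop("recording is shorter than one epoch")
  lapply(seq_len(n_ep), function(i)
    signals[, ((i - 1) * len + 1):(i * len), drop = FALSE])
}

epoch_pli <- function(epoch, fs, band) {
  ph <- instantaneous_phase(bandpass_filter(epoch, fs, band), fs)
  pli(ph)
}

#' Build a PLI-thresholded functional network
#'
#' Per epoch, each channel is band-pass filtered, Hilbert phases extracted
#' and the pairwise PLI computed; the PLI matrices are averaged over epochs
#' and the `retained_fraction` of channel pairs with the largest mean PLI
#' become the edges of a binary functional graph. The edge quota is
#' `ceiling(retained_fraction * n(n-1)/2)`; ties at the cutoff are resolved
#' deterministically in lexicographic pair order.
#'
#' @param epochs list of channels x samples matrices (see
#'   [segment_epochs()]).
#' @param fs sampling rate, Hz.
#' @param band [band_spec] used for filtering.
#' @param retained_fraction fraction of pairs kept; default 0.30.
#' @return list of class `functional_network`: binary `adjacency`,
#'   `degrees`, `mean_pli`, `band`, `retained_fraction`.
#' @export
build_functional_network <- function(epochs, fs, band,
                                     retained_fraction = 0.30) {
  stopifnot(length(epochs) >= 1, retained_fraction > 0,
            retained_fraction <= 1)
  mp <- Reduce(`+`, lapply(epochs, epoch_pli, fs = fs, band = band)) /
    length(epochs)
  n <- nrow(mp)
  iu <- which(upper.tri(mp), arr.ind = TRUE)
  quota <- ceiling(retained_fraction * n * (n - 1) / 2)
  ord <- order(-mp[iu], iu[, 1], iu[, 2])
  keep <- iu[ord[seq_len(quota)], , drop = FALSE]
  a <- matrix(0, n, n)
  a[keep] <- 1
  a <- a + t(a)
  structure(list(adjacency = a, degrees = as.integer(rowSums(a)),
                 mean_pli = mp, band = band,
                 retained_fraction = retained_fraction),
            class = "functional_network")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are used for ties; the two-sided p-value comes from the
#' large-sample t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of at least 3 values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

#' Per-node functional summary of a multichannel recording
#'
#' The EEG-style analysis: node degree comes from the PLI-thresholded
#' functional network built in `band_network` (default the whole band),
#' while the per-node mean dPLI and band amplitude are computed per epoch
#' in `band_analysis` (default alpha) and averaged over epochs. Spearman
#' correlations among degree, dPLI and amplitude are attached.
#'
#' @param epochs list of channels x samples matrices.
#' @param fs sampling rate, Hz.
#' @param band_network band for the functional graph.
#' @param band_analysis band for dPLI and amplitude.
#' @param retained_fraction PLI threshold fraction; default 0.30.
#' @return list of class `node_summary`: data frame `nodes` (degree,
#'   mean_dpli, amplitude), `correlations` (rho and p for each pair),
#'   `network` (the functional network), `n_epochs`.
#' @export
summarize_nodes <- function(epochs, fs,
                            band_network = band_presets()$whole,
                            band_analysis = band_presets()$alpha,
                            retained_fraction = 0.30) {
  fnet <- build_functional_network(epochs, fs, band_network,
                                   retained_fraction)
  per_epoch <- lapply(epochs, function(ep) {
    ph <- instantaneous_phase(bandpass_filter(ep, fs, band_analysis), fs)
    list(nd = node_dpli(dpli(ph)),
         amp = band_amplitude(ep, fs, band_analysis))
  })
  nd <- rowMeans(sapply(per_epoch, `[[`, "nd"))
  amp <- rowMeans(sapply(per_epoch, `[[`, "amp"))
  deg <- fnet$degrees
  correlations <- list(
    degree_dpli = spearman_cor(deg, nd),
    degree_amplitude = spearman_cor(deg, amp),
    dpli_amplitude = spearman_cor(nd, amp))
  structure(list(
    nodes = data.frame(node = seq_along(deg), degree = deg,
                       mean_dpli = nd, amplitude = amp),
    correlations = correlations, network = fnet,
    n_epochs = length(epochs)), class = "node_summary")
}

#' @export
print.node_summary <- function(x, ...) {
  cat(sprintf("<node_summary> %d nodes, %d epochs\n",
              nrow(x$nodes), x$n_epochs))
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("  %s: rho = %+.3f (p = %.3g)\n", nm, co$rho, co$p))
  }
  invisible(x)
}
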