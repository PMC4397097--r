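#' Oscillator network objects
#'
#' An `osc_network` is an undirected, unweighted graph on which oscillators
#' are placed: a symmetric binary adjacency matrix with zero diagonal,
#' per-node degrees, and optionally node coordinates (mm), a Euclidean
#' distance matrix (mm) and node labels.
#'
#' @param adjacency square symmetric binary matrix with zero diagonal.
#' @param coordinates optional n x 3 matrix of node positions in mm.
#' @param labels optional character vector of node names.
#' @param distances optional n x n symmetric non-negative matrix in mm;
#'   computed from `coordinates` when those are given and this is `NULL`.
#' @return an object of class `osc_network` with fields `n_nodes`,
#'   `adjacency`, `degrees`, and optionally `coordinates`, `distances`,
#'   `labels`.
#' @export
osc_network <- function(adjacency, coordinates = NULL, labels = NULL,
                        distances = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n)
    stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency must be binary (0/1)")
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  storage.mode(adjacency) <- "double"

  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n || ncol(coordinates) != 3)
      stop("coordinates must be an n x 3 matrix")
    if (is.null(distances))
      distances <- as.matrix(stats::dist(coordinates))
  }
  if (!is.null(distances)) {
    distances <- as.matrix(distances)
    if (nrow(distances) != n || ncol(distances) != n)
      stop("distances must be n x n")
    if (any(distances < 0) || any(diag(distances) != 0) ||
        !isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)))
      stop("distances must be symmetric and non-negative with zero diagonal")
    dimnames(distances) <- NULL
  }
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per node")

  structure(
    list(n_nodes = n, adjacency = unname(adjacency),
         degrees = as.integer(rowSums(adjacency)),
         coordinates = if (is.null(coordinates)) NULL else unname(coordinates),
         distances = distances, labels = labels),
    class = "osc_network")
}

#' @export
print.osc_network <- function(x, ...) {
  k <- x$degrees
  cat(sprintf("<osc_network> %d nodes, %d edges\n", x$n_nodes, sum(k) / 2))
  cat(sprintf("  degrees: mean %.2f, range [%d, %d]\n",
              mean(k), min(k), max(k)))
  if (!is.null(x$coordinates)) cat("  coordinates: yes (mm)\n")
  invisible(x)
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Generate a connected Gilbert random network
#'
#' Each unordered node pair is linked independently with probability
#' `p = (1 + epsilon) * log(n) / n`, just above the connectivity threshold
#' `log(n)/n`; the draw is repeated until the graph is connected.
#'
#' @param n number of nodes (>= 2).
#' @param epsilon small positive margin above the connectivity threshold;
#'   default 0.1.
#' @param seed optional integer seed for reproducibility.
#' @param max_tries resampling cap before giving up.
#' @return an [osc_network].
#' @export
generate_random_gilbert <- function(n, epsilon = 0.1, seed = NULL,
                                    max_tries = 10000L) {
  if (n < 2) stop("n must be at least 2")
  if (epsilon <= 0) stop("epsilon must be positive")
  p <- (1 + epsilon) * log(n) / n
  if (p >= 1) stop("edge probability (1+epsilon)*log(n)/n is >= 1")
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      u <- matrix(0, n, n)
      u[upper.tri(u)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
      a <- u + t(u)
      net <- osc_network(a)
      if (is_connected_adjacency(a)) return(net)
    }
    stop("failed to draw a connected Gilbert graph in ", max_tries, " tries")
  })
}

is_connected_adjacency <- function(a) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::is_connected(g)
}

# Draw one integer degree sequence from a continuous power law x^(-exponent)
# on [1, n-1], rounded to the nearest integer.  Rounding the continuous law
# (rather than sampling the discrete zeta law) keeps the printed slope while
# giving the degree-one mass and occasional large hubs seen in reference
# realizations of this generator class.
draw_powerlaw_degrees <- function(n, exponent) {
  a <- exponent - 1
  x <- (1 - stats::runif(n) * (1 - (n - 1)^(-a)))^(-1 / a)
  pmin(round(x), n - 1L)
}

#' Generate a connected scale-free network (configuration model)
#'
#' Node degrees are drawn from a power law with density slope `-exponent`,
#' then a uniform simple connected realization of the sequence is sampled
#' with the Viger-Latapy algorithm. Sequences whose total stub count cannot
#' support a connected graph (fewer than `n - 1` edges) are redrawn, as are
#' odd-sum sequences.
#'
#' @param n number of nodes (>= 10).
#' @param exponent power-law slope magnitude (> 2); default 2.2.
#' @param seed optional integer seed.
#' @param max_tries redraw cap before failing.
#' @return an [osc_network].
#' @export
generate_scale_free <- function(n, exponent = 2.2, seed = NULL,
                                max_tries = 10000L) {
  if (n < 10) stop("n must be at least 10")
  if (exponent <= 2) stop("exponent must exceed 2")
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      k <- draw_powerlaw_degrees(n, exponent)
      if (sum(k) %% 2 != 0 || sum(k) < 2 * (n - 1)) next
      g <- try(suppressWarnings(igraph::sample_degseq(k, method = "vl")),
               silent = TRUE)
      if (inherits(g, "try-error")) next
      a <- unname(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
      return(osc_network(a))
    }
    stop("scale-free generation failed: no connected realization in ",
         max_tries, " tries")
  })
}

#' Classify nodes into hubs and peripherals by degree
#'
#' Hubs are nodes whose degree strictly exceeds `mean(k) + sd(k)`.
#' Peripherals are nodes with degree 1 (`"degree_one"`) or with degree
#' strictly below `mean(k) - sd(k)` (`"mean_minus_sd"`).
#'
#' @param net an [osc_network].
#' @param hub_rule currently only `"mean_plus_sd"`.
#' @param peripheral_rule `"degree_one"` or `"mean_minus_sd"`.
#' @return list with integer node indices `hubs` and `peripherals`.
#' @export
classify_nodes <- function(net, hub_rule = "mean_plus_sd",
                           peripheral_rule = c("degree_one", "mean_minus_sd")) {
  hub_rule <- match.arg(hub_rule)
  peripheral_rule <- match.arg(peripheral_rule)
  k <- net$degrees
  s <- stats::sd(k)
  if (s == 0) {
    warning("all degrees equal; hub set is empty")
    hubs <- integer(0)
  } else {
    hubs <- which(k > mean(k) + s)
  }
  peripherals <- switch(peripheral_rule,
    degree_one = which(k == 1L),
    mean_minus_sd = which(k < mean(k) - s))
  list(hubs = hubs, peripherals = setdiff(peripherals, hubs))
}

#' Build a per-edge conduction delay matrix
#'
#' Constant mode assigns the same delay to every edge; distance mode divides
#' the inter-node distance (mm) by a propagation speed (m/s). A warning is
#' emitted when any delay exceeds a quarter period of the reference
#' oscillation frequency, the regime beyond which delay-coupled phase
#' relations are no longer expected to be stable.
#'
#' @param net an [osc_network].
#' @param mode `"constant"` or `"distance"`.
#' @param value delay in seconds (constant mode) or propagation speed in m/s
#'   (distance mode).
#' @param reference_hz oscillation frequency used for the quarter-period
#'   check; default 10.
#' @return list of class `delay_matrix`: `values` (n x n seconds, nonzero on
#'   edges only), `mode`, `speed` (m/s, distance mode only).
#' @export
build_delay_matrix <- function(net, mode = c("constant", "distance"), value,
                               reference_hz = 10) {
  mode <- match.arg(mode)
  if (value <= 0) stop("value must be positive")
  if (mode == "constant") {
    tau <- net$adjacency * value
    speed <- NULL
  } else {
    if (is.null(net$distances))
      stop("distance mode requires node distances on the network")
    tau <- net$adjacency * (net$distances / 1000) / value  # mm -> m, /(m/s)
    speed <- value
  }
  quarter <- 1 / (4 * reference_hz)
  if (max(tau) > quarter)
    warning(sprintf(
      "some delays exceed a quarter period at %g Hz (%.0f ms); phase-lag %s",
      reference_hz, 1000 * quarter,
      "orderings are only expected below that"))
  structure(list(values = unname(tau), mode = mode, speed = speed),
            class = "delay_matrix")
}

#' Read a network from an edge list or adjacency file
#'
#' Edge lists are two- or three-column whitespace- or comma-separated files
#' of 0-based node ids (a third column is ignored); square numeric tables
#' are read as adjacency matrices. An optional coordinates CSV
#' (`id,x,y,z` in mm, 0-based ids) attaches node positions.
#'
#' @param path network file.
#' @param coordinates_path optional coordinates CSV.
#' @param n_nodes optional node count for edge lists whose highest id is not
#'   present in any edge.
#' @return an [osc_network].
#' @export
load_network <- function(path, coordinates_path = NULL, n_nodes = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           comment.char = "#")
  if (ncol(tab) <= 3 && nrow(tab) != ncol(tab)) {
    e <- as.matrix(tab[, 1:2])
    if (any(e != floor(e)) || any(e < 0))
      stop("edge list must contain non-negative integer 0-based node ids")
    n <- if (is.null(n_nodes)) max(e) + 1 else n_nodes
    a <- matrix(0, n, n)
    a[e + 1] <- 1
    a[e[, 2:1] + 1] <- 1
    diag(a) <- 0
  } else {
    a <- as.matrix(tab)
    if (nrow(a) != ncol(a)) stop("adjacency table must be square")
    if (!isTRUE(all.equal(unname(a), unname(t(a)))))
      stop("adjacency is not symmetric")
    if (any(diag(a) != 0)) stop("adjacency has a nonzero diagonal")
  }
  coords <- NULL
  if (!is.null(coordinates_path)) {
    cc <- utils::read.csv(coordinates_path)
    coords <- as.matrix(cc[order(cc[[1]]), 2:4])
  }
  osc_network(a, coordinates = coords)
}

#' Write a network as an edge list (and optional coordinates sidecar)
#'
#' @param net an [osc_network].
#' @param path output edge-list file (0-based ids, comma-separated).
#' @param coordinates_path optional output CSV for coordinates.
#' @export
save_network <- function(net, path, coordinates_path = NULL) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency > 0, arr.ind = TRUE)
  utils::write.table(cbind(idx[, 1] - 1L, idx[, 2] - 1L), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(coordinates_path)) {
    if (is.null(net$coordinates)) stop("network has no coordinates")
    utils::write.csv(
      data.frame(id = seq_len(net$n_nodes) - 1L,
                 x = net$coordinates[, 1], y = net$coordinates[, 2],
                 z = net$coordinates[, 3]),
      coordinates_path, row.names = FALSE)
  }
  invisible(path)
}
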