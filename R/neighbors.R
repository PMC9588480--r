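#' k-nearest-neighbour distance profile
#'
#' Exact Euclidean distances from every point to its 1st..kth nearest
#' neighbour (kd-tree search; results identical to exhaustive pairwise
#' comparison), with per-k mean, SD and standard error.
#'
#' @param pattern A [soma_pattern()] with n >= k + 1 points.
#' @param k Number of neighbours (default 10).
#' @return A `knn_dist3d` list: `dist` (n x k matrix, um) and `summary`
#'   (data frame with `k`, `mean_um`, `sd_um`, `se_um`).
#' @export
knn_distances <- function(pattern, k = 10) {
  n <- npoints(pattern)
  if (n <= k)
    stop_somaspat("need more than k = ", k, " points (have ", n, ")",
                  class = "somaspat_input_error")
  d <- FNN::get.knn(pattern$coords, k = k)$nn.dist
  structure(list(dist = d,
                 summary = data.frame(k = seq_len(k),
                                      mean_um = colMeans(d),
                                      sd_um = apply(d, 2, stats::sd),
                                      se_um = apply(d, 2, stats::sd) /
                                        sqrt(n))),
            class = "knn_dist3d")
}

#' @export
print.knn_dist3d <- function(x, ...) {
  cat("k-NN distance profile, n =", nrow(x$dist), "points\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

# Nearest neighbour of every point with deterministic lowest-index
# tie-break (relevant for lattice fixtures; ties are measure-zero for
# empirical coordinates).
nn_index <- function(coords) {
  n <- nrow(coords)
  kk <- min(n - 1L, 26L)
  nn <- FNN::get.knn(coords, k = kk)
  idx <- integer(n)
  dist1 <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- nn$nn.dist[i, 1]
    tied <- nn$nn.index[i, nn$nn.dist[i, ] == d1]
    idx[i] <- min(tied)
    dist1[i] <- d1
  }
  list(index = idx, dist = dist1)
}

#' Undirected nearest-neighbour graph and its clusters
#'
#' Adds the undirected edge `{i, NN(i)}` for every point (union of directed
#' nearest-neighbour choices, deduplicated) and partitions the graph into
#' connected components -- the "clusters". Every node has degree >= 1, so the
#' minimum cluster size is 2. Exact distance ties are resolved to the lowest
#' point index.
#'
#' @param pattern A [soma_pattern()] with n >= 2 points.
#' @return An `nn_graph3d` list: `edges` (2-column matrix), `nn` (per-point
#'   nearest-neighbour index), `nn_dist_um`, `membership` (component id per
#'   point), `sizes` (component sizes), `histogram` (table: size ->
#'   number of clusters).
#' @export
nn_graph <- function(pattern) {
  n <- npoints(pattern)
  if (n < 2)
    stop_somaspat("need at least 2 points", class = "somaspat_input_error")
  nn <- nn_index(pattern$coords)
  e <- cbind(pmin(seq_len(n), nn$index), pmax(seq_len(n), nn$index))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  structure(list(edges = e, nn = nn$index, nn_dist_um = nn$dist,
                 membership = comp$membership, sizes = comp$csize,
                 histogram = table(comp$csize)),
            class = "nn_graph3d")
}

#' @export
print.nn_graph3d <- function(x, ...) {
  cat("nearest-neighbour graph:", length(x$membership), "somata in",
      length(x$sizes), "clusters\n")
  cat("  cluster-size histogram:\n")
  print(x$histogram)
  invisible(x)
}

#' @param x An `nn_graph3d`.
#' @param ... Passed to [graphics::barplot()].
#' @rdname nn_graph
#' @export
plot.nn_graph3d <- function(x, ...) {
  graphics::barplot(as.vector(x$histogram),
                    names.arg = names(x$histogram),
                    xlab = "cluster size (cells)", ylab = "frequency", ...)
  invisible(x)
}

#' Observed vs CSR mean k-NN distances with Monte Carlo envelopes
#'
#' Compares the observed mean distance to the 1st..kth nearest neighbour
#' against uniform simulations with the same number of points in the same
#' region (same Monte Carlo band convention as [csr_envelope()]). An
#' observed mean below the band indicates clustering, above the band
#' regularity.
#'
#' @param pattern Observed [soma_pattern()].
#' @param region The [region3d] to simulate in.
#' @param n_sims Number of CSR simulations (default 1000).
#' @param k Number of neighbours (default 10).
#' @param honor_exclusions Exclude simulated points from exclusion zones?
#' @param seed Optional master seed.
#' @return An `nnenv3d` data frame: `k`, `obs_mean_um`, `sim_mean_um`,
#'   `lo_um`, `hi_um`, with attribute `sims`.
#' @export
nn_compare_to_csr <- function(pattern, region, n_sims = 1000, k = 10,
                              honor_exclusions = FALSE, seed = NULL) {
  stopifnot(n_sims >= 2)
  n <- npoints(pattern)
  obs <- colMeans(knn_distances(pattern, k)$dist)
  sims <- matrix(NA_real_, n_sims, k)
  for (s in seq_len(n_sims)) {
    sim <- sample_uniform(region, n, honor_exclusions = honor_exclusions,
                          seed = derive_seed(seed, s))
    sims[s, ] <- colMeans(knn_distances(sim, k)$dist)
  }
  m <- envelope_rank(n_sims)
  structure(data.frame(k = seq_len(k), obs_mean_um = obs,
                       sim_mean_um = colMeans(sims),
                       lo_um = apply(sims, 2, function(v) sort(v)[m]),
                       hi_um = apply(sims, 2, function(v)
                         sort(v, decreasing = TRUE)[m])),
            sims = sims, n = n,
            class = c("nnenv3d", "data.frame"))
}

#' @export
print.nnenv3d <- function(x, ...) {
  cat("mean k-NN distances vs CSR,", nrow(attr(x, "sims")), "simulations, n =",
      attr(x, "n"), "\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Total-variation distance between two cluster-size histograms
#'
#' Histograms (as returned in `nn_graph()$histogram`) are normalised to
#' frequency distributions over cluster size before comparison.
#'
#' @param h1,h2 Tables mapping cluster size to frequency.
#' @return TV distance in `[0, 1]`.
#' @export
histogram_tv <- function(h1, h2) {
  sizes <- sort(unique(c(as.integer(names(h1)), as.integer(names(h2)))))
  p <- as.vector(h1[match(sizes, as.integer(names(h1)))]); p[is.na(p)] <- 0
  q <- as.vector(h2[match(sizes, as.integer(names(h2)))]); q[is.na(q)] <- 0
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}

#' Robustness of the cluster-size histogram to coordinate noise
#'
#' Adds isotropic Gaussian noise of standard deviation `sd_um` to the
#' coordinates, rebuilds the nearest-neighbour graph, and reports the
#' total-variation distance between the original and perturbed cluster-size
#' frequency distributions, once per replicate.
#'
#' @param pattern A [soma_pattern()].
#' @param sd_um Noise SD in micrometres (>= 0).
#' @param n_reps Number of replicates (default 20).
#' @param seed Optional master seed.
#' @return Numeric vector of TV distances (one per replicate), with the
#'   reference histogram as attribute `reference`.
#' @export
noise_robustness <- function(pattern, sd_um, n_reps = 20, seed = NULL) {
  stopifnot(sd_um >= 0, n_reps >= 1)
  ref <- nn_graph(pattern)$histogram
  out <- vapply(seq_len(n_reps), function(r) {
    pert <- with_seed(derive_seed(seed, r),
                      pattern$coords +
                        matrix(stats::rnorm(3 * npoints(pattern), 0, sd_um),
                               ncol = 3))
    histogram_tv(ref, nn_graph(soma_pattern(pert, check = FALSE))$histogram)
  }, numeric(1))
  attr(out, "reference") <- ref
  out
}
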