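# Independent brute-force oracles (plain base R, no spatial indexing) used to
# validate the package estimators on small instances.

unit_box <- function() region_box(c(0, 0, 0), c(1000, 1000, 1000))

# K(r) by the O(n^2) double loop over the full distance matrix.
brute_k <- function(coords, volume_mm3, radii_um) {
  n <- nrow(coords)
  if (n < 2) return(rep(0, length(radii_um)))
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  vapply(radii_um, function(r) volume_mm3 * sum(d <= r) / n^2, numeric(1))
}

# K_inhom(r) by the double loop with supplied per-point intensities.
brute_kinhom <- function(coords, lambda, radii_um) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  w <- outer(1 / lambda, 1 / lambda)
  vapply(radii_um, function(r) sum(w[d <= r]), numeric(1))
}

# k-NN distances by full sort of the distance matrix.
brute_knn <- function(coords, k) {
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  t(apply(d, 1, function(row) sort(row)[seq_len(k)]))
}

# nearest neighbour with lowest-index tie-break, and connected components of
# the symmetrised NN graph by breadth-first search
brute_nn_components <- function(coords) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nn <- unname(apply(d, 1, function(row) which(row == min(row))[1]))
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- union(adj[[i]], nn[i])
    adj[[nn[i]]] <- union(adj[[nn[i]]], i)
  }
  comp <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cid <- cid + 1
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (comp[u] == 0) { comp[u] <- cid; queue <- c(queue, u) }
    }
  }
  list(nn = nn, membership = comp)
}

# Voronoi cell volumes by chunked nearest-generator labelling of voxel
# centres (no kd-tree), on the same grid the implementation uses.
brute_voxel_voronoi <- function(coords, lo, hi, voxel_size_um) {
  nv <- pmax(1L, ceiling((hi - lo) / voxel_size_um))
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(nv[k]) - 0.5) * voxel_size_um)
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  n <- nrow(coords)
  lab <- integer(nrow(grid))
  chunk <- 20000L
  for (s in seq(1, nrow(grid), by = chunk)) {
    e <- min(s + chunk - 1, nrow(grid))
    g <- grid[s:e, , drop = FALSE]
    d2 <- matrix(0, nrow(g), n)
    for (j in seq_len(n))
      d2[, j] <- (g[, 1] - coords[j, 1])^2 + (g[, 2] - coords[j, 2])^2 +
        (g[, 3] - coords[j, 3])^2
    lab[s:e] <- max.col(-d2, ties.method = "first")
  }
  tabulate(lab, nbins = n) * voxel_size_um^3 / 1e9
}

# canonical partition signature for comparing component structures
partition_signature <- function(membership) {
  groups <- split(seq_along(membership), membership)
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","), "")),
        collapse = ";")
}

# latitude-longitude triangulated sphere mesh (watertight)
sphere_mesh <- function(center, radius, n_lat = 24, n_lon = 48) {
  th <- seq(0, pi, length.out = n_lat + 1)
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  verts <- rbind(center + c(0, 0, radius))
  idx <- matrix(0L, n_lat + 1, n_lon)
  idx[1, ] <- 1L
  for (i in 2:n_lat) {
    for (j in seq_len(n_lon)) {
      verts <- rbind(verts, center + radius *
                       c(sin(th[i]) * cos(ph[j]), sin(th[i]) * sin(ph[j]),
                         cos(th[i])))
      idx[i, j] <- nrow(verts)
    }
  }
  verts <- rbind(verts, center + c(0, 0, -radius))
  idx[n_lat + 1, ] <- nrow(verts)
  faces <- NULL
  for (i in 1:n_lat) {
    for (j in seq_len(n_lon)) {
      jn <- if (j == n_lon) 1L else j + 1L
      a <- idx[i, j]; b <- idx[i, jn]; c2 <- idx[i + 1, j]; d <- idx[i + 1, jn]
      if (i == 1) faces <- rbind(faces, c(a, c2, d))
      else if (i == n_lat) faces <- rbind(faces, c(a, b, c2))
      else faces <- rbind(faces, c(a, c2, d), c(a, d, b))
    }
  }
  region_mesh(verts, faces)
}
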