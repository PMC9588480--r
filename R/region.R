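#' Bounded 3D regions
#'
#' A `region3d` represents the bounded domain a soma pattern is observed in:
#' an analytic box, ellipsoid or sphere, a boolean voxel mask, a watertight
#' triangle mesh, or the union of Delaunay tetrahedra produced by
#' [build_region()]. All regions support an exact volume ([region_volume()],
#' mm^3), a deterministic membership test ([contains()], boundary points count
#' as inside), a bounding box, and uniform sampling ([sample_uniform()]).
#' Optional exclusion zones (axonal-bundle models, see [tube_exclusions()])
#' can be attached to any region with [set_exclusions()].
#'
#' @name region3d
NULL

new_region <- function(type, fields, name = NULL) {
  structure(c(fields, list(name = name, exclusions = NULL)),
            class = c(paste0("region_", type), "region3d"))
}

#' @param lo,hi Numeric length-3 lower/upper corners in micrometres.
#' @param name Optional region label.
#' @rdname region3d
#' @export
region_box <- function(lo, hi, name = NULL) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo))
  new_region("box", list(lo = lo, hi = hi), name)
}

#' @param center Numeric length-3 centre in micrometres.
#' @param semiaxes Numeric length-3 semi-axis lengths in micrometres.
#' @rdname region3d
#' @export
region_ellipsoid <- function(center, semiaxes, name = NULL) {
  center <- as.numeric(center); semiaxes <- as.numeric(semiaxes)
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0))
  new_region("ellipsoid", list(center = center, semiaxes = semiaxes), name)
}

#' @param radius_um Sphere radius in micrometres.
#' @rdname region3d
#' @export
region_sphere <- function(center, radius_um, name = NULL) {
  region_ellipsoid(center, rep(radius_um, 3), name)
}

#' @param mask 3D logical array of voxel occupancy.
#' @param voxel_size_um Edge length of the cubic voxels, micrometres.
#' @param origin_um Lower corner of voxel `[1,1,1]`, micrometres.
#' @rdname region3d
#' @export
region_voxel <- function(mask, voxel_size_um, origin_um = c(0, 0, 0),
                         name = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, voxel_size_um > 0)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop_somaspat("empty voxel mask",
                                class = "somaspat_empty_region_error")
  new_region("voxel", list(mask = mask, voxel_size_um = voxel_size_um,
                           origin_um = as.numeric(origin_um)), name)
}

#' @param vertices Numeric v x 3 matrix of mesh vertices (micrometres).
#' @param faces Integer f x 3 matrix of 1-based triangle vertex indices.
#' @rdname region3d
#' @export
region_mesh <- function(vertices, faces, name = NULL) {
  vertices <- as_coord_matrix(vertices)
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(faces) == 3, min(faces) >= 1, max(faces) <= nrow(vertices))
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  closed <- all(table(key) == 2L)
  new_region("mesh", list(vertices = vertices, faces = faces, closed = closed),
             name)
}

new_region_tets <- function(vertices, tets, circumradius_um, alpha_um, name) {
  r <- new_region("tets", list(vertices = vertices, tets = tets,
                               circumradius_um = circumradius_um,
                               alpha_um = alpha_um), name)
  r
}

#' @export
format.region3d <- function(x, ...) {
  type <- sub("^region_", "", class(x)[1])
  sprintf("%s region%s, volume %.4g mm^3%s",
          type,
          if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
          region_volume(x),
          if (is.null(x$exclusions)) "" else " (+exclusion zones)")
}

#' @export
print.region3d <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# ---- bounding boxes ---------------------------------------------------------

#' Axis-aligned bounding box of a region
#' @param region A [region3d].
#' @return List with `lo` and `hi` (micrometres).
#' @export
bounding_box <- function(region) UseMethod("bounding_box")

#' @export
bounding_box.region_box <- function(region) list(lo = region$lo, hi = region$hi)

#' @export
bounding_box.region_ellipsoid <- function(region)
  list(lo = region$center - region$semiaxes,
       hi = region$center + region$semiaxes)

#' @export
bounding_box.region_voxel <- function(region)
  list(lo = region$origin_um,
       hi = region$origin_um + dim(region$mask) * region$voxel_size_um)

#' @export
bounding_box.region_mesh <- function(region)
  list(lo = apply(region$vertices, 2, min), hi = apply(region$vertices, 2, max))

#' @export
bounding_box.region_tets <- function(region)
  list(lo = apply(region$vertices, 2, min), hi = apply(region$vertices, 2, max))

# ---- volume -----------------------------------------------------------------

#' Region volume in cubic millimetres
#'
#' Mesh and tetrahedral regions use signed-tetrahedron sums, voxel regions
#' voxel counting, analytic regions the closed form. By default the volume
#' includes any attached exclusion zones (bundles are part of the anatomical
#' structure); set `exclude_zones = TRUE` to subtract the admissible-volume
#' complement (estimated deterministically by fixed-seed Monte Carlo for
#' analytic exclusion shapes).
#'
#' @param region A [region3d].
#' @param exclude_zones Subtract exclusion-zone volume?
#' @return Volume in mm^3.
#' @export
region_volume <- function(region, exclude_zones = FALSE) {
  v <- region_volume_raw(region)
  if (exclude_zones && !is.null(region$exclusions))
    v <- v * (1 - excluded_fraction(region))
  v
}

region_volume_raw <- function(region) UseMethod("region_volume_raw")

#' @export
region_volume_raw.region_box <- function(region)
  prod(region$hi - region$lo) / UM3_PER_MM3

#' @export
region_volume_raw.region_ellipsoid <- function(region)
  4 / 3 * pi * prod(region$semiaxes) / UM3_PER_MM3

#' @export
region_volume_raw.region_voxel <- function(region)
  sum(region$mask) * region$voxel_size_um^3 / UM3_PER_MM3

#' @export
region_volume_raw.region_mesh <- function(region) {
  if (!region$closed)
    stop_somaspat("mesh is not watertight; volume undefined",
                  class = "somaspat_geometry_error")
  v <- region$vertices
  f <- region$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det6)) / 6 / UM3_PER_MM3
}

#' @export
region_volume_raw.region_tets <- function(region) {
  sum(abs(cpp_tet_volumes(region$vertices[, 1], region$vertices[, 2],
                          region$vertices[, 3], region$tets))) / UM3_PER_MM3
}

# ---- membership -------------------------------------------------------------

#' Point-in-region membership test
#'
#' Deterministic membership test; points on the boundary count as inside.
#' With `honor_exclusions = TRUE` points inside any attached exclusion zone
#' are rejected.
#'
#' @param region A [region3d].
#' @param points n x 3 matrix (micrometres) or length-3 vector.
#' @param honor_exclusions Reject points inside exclusion zones?
#' @return Logical vector of length n.
#' @export
contains <- function(region, points, honor_exclusions = FALSE) {
  points <- as_coord_matrix(points)
  ok <- region_inside(region, points)
  if (honor_exclusions && !is.null(region$exclusions)) {
    for (ex in region$exclusions) ok <- ok & !in_exclusion(ex, points)
  }
  ok
}

region_inside <- function(region, points) UseMethod("region_inside")

#' @export
region_inside.region_box <- function(region, points) {
  points[, 1] >= region$lo[1] & points[, 1] <= region$hi[1] &
  points[, 2] >= region$lo[2] & points[, 2] <= region$hi[2] &
  points[, 3] >= region$lo[3] & points[, 3] <= region$hi[3]
}

#' @export
region_inside.region_ellipsoid <- function(region, points) {
  u <- sweep(points, 2, region$center)
  u <- sweep(u, 2, region$semiaxes, "/")
  rowSums(u * u) <= 1 + 1e-12
}

#' @export
region_inside.region_voxel <- function(region, points) {
  idx <- floor(sweep(points, 2, region$origin_um) / region$voxel_size_um) + 1
  d <- dim(region$mask)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- logical(nrow(points))
  if (any(ok))
    out[ok] <- region$mask[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  out
}

#' @export
region_inside.region_mesh <- function(region, points) {
  cpp_point_in_mesh(points, region$vertices, region$faces)
}

#' @export
region_inside.region_tets <- function(region, points) {
  cpp_point_in_tets(points, region$vertices[, 1], region$vertices[, 2],
                    region$vertices[, 3], region$tets)
}

# ---- exclusion zones --------------------------------------------------------

#' Tube-shaped exclusion zones
#'
#' Models axonal fibre bundles as a union of cylinders running parallel to
#' the anterior-posterior (Y) axis, each defined by its (x, z) centre line
#' and radius. Somata are excluded from these tubes in constrained null
#' simulations.
#'
#' @param x_um,z_um Tube centre-line coordinates, micrometres.
#' @param radius_um Tube radii (recycled), micrometres.
#' @return An `exclusion_tubes` object.
#' @export
tube_exclusions <- function(x_um, z_um, radius_um) {
  stopifnot(length(x_um) == length(z_um), all(radius_um > 0))
  structure(list(x_um = as.numeric(x_um), z_um = as.numeric(z_um),
                 radius_um = rep_len(as.numeric(radius_um), length(x_um))),
            class = c("exclusion_tubes", "exclusion3d"))
}

#' Voxel-mask exclusion zones
#'
#' @param mask,voxel_size_um,origin_um As in [region_voxel()]; `TRUE` voxels
#'   are forbidden.
#' @return An `exclusion_voxels` object.
#' @export
voxel_exclusions <- function(mask, voxel_size_um, origin_um = c(0, 0, 0)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, voxel_size_um > 0)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, voxel_size_um = voxel_size_um,
                 origin_um = as.numeric(origin_um)),
            class = c("exclusion_voxels", "exclusion3d"))
}

#' Test whether points fall inside an exclusion zone
#' @param exclusion An `exclusion3d` object.
#' @param points n x 3 matrix, micrometres.
#' @return Logical vector.
#' @export
in_exclusion <- function(exclusion, points) UseMethod("in_exclusion")

#' @export
in_exclusion.exclusion_tubes <- function(exclusion, points) {
  points <- as_coord_matrix(points)
  out <- logical(nrow(points))
  for (i in seq_along(exclusion$x_um)) {
    dx <- points[, 1] - exclusion$x_um[i]
    dz <- points[, 3] - exclusion$z_um[i]
    out <- out | (dx * dx + dz * dz <= exclusion$radius_um[i]^2)
  }
  out
}

#' @export
in_exclusion.exclusion_voxels <- function(exclusion, points) {
  points <- as_coord_matrix(points)
  region_inside.region_voxel(exclusion, points)
}

#' Attach exclusion zones to a region
#'
#' Validates that the zones lie inside the region boundary (by fixed-seed
#' Monte Carlo membership of zone points).
#'
#' @param region A [region3d].
#' @param ... One or more `exclusion3d` objects (or a list of them).
#' @param validate Check that voxel-mask zones lie inside the region
#'   boundary (occupied voxel centres must pass [contains()]).
#' @return The region with exclusions attached.
#' @export
set_exclusions <- function(region, ..., validate = TRUE) {
  ex <- list(...)
  if (length(ex) == 1L && is.list(ex[[1]]) && !inherits(ex[[1]], "exclusion3d"))
    ex <- ex[[1]]
  stopifnot(all(vapply(ex, inherits, TRUE, "exclusion3d")))
  if (validate) {
    for (e in ex) {
      if (inherits(e, "exclusion_voxels")) {
        occ <- which(e$mask, arr.ind = TRUE)
        if (nrow(occ) > 0) {
          ctr <- sweep((occ - 0.5) * e$voxel_size_um, 2, e$origin_um, "+")
          out <- !region_inside(region, ctr)
          if (any(out))
            stop_somaspat(sum(out), " exclusion voxel(s) outside the region ",
                          "boundary (mismatched extents?)",
                          class = "somaspat_mask_error")
        }
      }
    }
  }
  region$exclusions <- ex
  region
}

# Deterministic Monte Carlo estimate of the volume fraction occupied by the
# exclusion zones (fixed internal seed; ~0.1% standard error at n = 2e5).
#' Fraction of region volume occupied by exclusion zones
#' @param region A [region3d] with exclusions attached.
#' @param n_mc Number of fixed-seed Monte Carlo points.
#' @return Fraction in `[0, 1]`.
#' @export
excluded_fraction <- function(region, n_mc = 2e5) {
  if (is.null(region$exclusions)) return(0)
  pts <- with_seed(171717L, sample_uniform_core(region, n_mc))
  excl <- logical(nrow(pts))
  for (ex in region$exclusions) excl <- excl | in_exclusion(ex, pts)
  mean(excl)
}

# ---- uniform sampling -------------------------------------------------------

# n uniform points inside the boundary, ignoring exclusions; advances RNG.
sample_uniform_core <- function(region, n) {
  if (n == 0) return(as_coord_matrix(matrix(numeric(0), ncol = 3)))
  bb <- bounding_box(region)
  out <- matrix(NA_real_, 0, 3)
  proposed <- 0
  batch <- max(1000L, ceiling(2.5 * n))
  repeat {
    cand <- cbind(runif(batch, bb$lo[1], bb$hi[1]),
                  runif(batch, bb$lo[2], bb$hi[2]),
                  runif(batch, bb$lo[3], bb$hi[3]))
    keep <- region_inside(region, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
    proposed <- proposed + batch
    if (nrow(out) >= n) break
    if (proposed >= 2e6 && nrow(out) / proposed < 1e-6)
      stop_somaspat("admissible volume fraction below 1e-6 of bounding box",
                    class = "somaspat_sampling_error")
    batch <- max(batch, ceiling((n - nrow(out)) * proposed /
                                  max(nrow(out), 1) * 1.3))
    batch <- min(batch, 2e6)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample points uniformly inside a region
#'
#' Rejection sampling from the region's bounding box; returns exactly `n`
#' points, all passing [contains()]. Deterministic given `seed`.
#'
#' @param region A [region3d].
#' @param n Number of points.
#' @param honor_exclusions Also reject points inside exclusion zones?
#' @param seed Optional integer seed.
#' @return A [soma_pattern()] with the region attached.
#' @export
sample_uniform <- function(region, n, honor_exclusions = TRUE, seed = NULL) {
  stopifnot(n >= 0)
  coords <- with_seed(seed, {
    if (honor_exclusions && !is.null(region$exclusions)) {
      got <- matrix(NA_real_, 0, 3)
      tries <- 0
      while (nrow(got) < n) {
        m <- max(1000L, ceiling(1.6 * (n - nrow(got))))
        cand <- sample_uniform_core(region, m)
        keep <- !Reduce(`|`, lapply(region$exclusions, in_exclusion,
                                    points = cand),
                        accumulate = FALSE, init = logical(m))
        got <- rbind(got, cand[keep, , drop = FALSE])
        tries <- tries + 1
        if (tries > 200)
          stop_somaspat("admissible volume fraction too small",
                        class = "somaspat_sampling_error")
      }
      got[seq_len(n), , drop = FALSE]
    } else {
      sample_uniform_core(region, n)
    }
  })
  soma_pattern(coords, region_label = region$name, region = region,
               check = FALSE)
}

# ---- hull / alpha-complex construction --------------------------------------

#' Build a region from point coordinates
#'
#' Constructs the region occupied by a point cloud as the union of Delaunay
#' tetrahedra with circumradius at most `alpha_um` (an alpha-complex); with
#' `alpha_um = Inf` this is the convex hull. The volume is the sum of the
#' retained tetrahedra and the boundary is the set of triangle faces used by
#' exactly one retained tetrahedron.
#'
#' A deterministic symbolic jitter of 1e-8 of the cloud diameter is applied
#' before tetrahedralisation to break exact cosphericality (grids, cube
#' corners); reported volumes are affected at a relative 1e-7 level.
#'
#' @param points A [soma_pattern()] or n x 3 coordinate matrix (micrometres),
#'   n >= 4, not all coplanar.
#' @param alpha_um Circumradius threshold in micrometres, or `Inf` for the
#'   convex hull.
#' @param name Optional region label.
#' @return A `region_tets` [region3d].
#' @examples
#' cube <- as.matrix(expand.grid(c(0, 1000), c(0, 1000), c(0, 1000)))
#' region_volume(build_region(cube))  # 1 mm^3
#' @export
build_region <- function(points, alpha_um = Inf, name = NULL) {
  if (inherits(points, "soma_pattern")) points <- points$coords
  points <- as_coord_matrix(points)
  if (nrow(points) < 4)
    stop_somaspat("need at least 4 points", class = "somaspat_geometry_error")
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop_somaspat("points are coplanar or collinear; no 3D region",
                  class = "somaspat_geometry_error")
  scale <- max(apply(points, 2, function(v) diff(range(v))))
  jit <- with_seed(987654L,
                   matrix(runif(length(points), -1, 1), ncol = 3) * 1e-8 * scale)
  pj <- points + jit
  dl <- cpp_delaunay3d(pj[, 1], pj[, 2], pj[, 3])
  keep <- dl$circumradius_um <= alpha_um
  if (!any(keep))
    stop_somaspat("alpha too small: no tetrahedron survives",
                  class = "somaspat_empty_region_error")
  new_region_tets(pj, dl$tets[keep, , drop = FALSE],
                  dl$circumradius_um[keep], alpha_um, name)
}

#' Boundary surface of a tetrahedral region
#'
#' @param region A `region_tets` region from [build_region()].
#' @return A `region_mesh` holding the boundary triangles (faces used by
#'   exactly one tetrahedron).
#' @export
boundary_mesh <- function(region) {
  stopifnot(inherits(region, "region_tets"))
  t4 <- region$tets
  faces <- rbind(t4[, c(2, 3, 4)], t4[, c(1, 3, 4)],
                 t4[, c(1, 2, 4)], t4[, c(1, 2, 3)])
  opposite <- c(t4[, 1], t4[, 2], t4[, 3], t4[, 4])
  sorted <- t(apply(faces, 1, sort))
  key <- paste(sorted[, 1], sorted[, 2], sorted[, 3])
  keep <- key %in% names(which(table(key) == 1L))
  bf <- faces[keep, , drop = FALSE]
  opp <- opposite[keep]
  # orient each face so its normal points away from the opposite vertex
  v <- region$vertices
  for (i in seq_len(nrow(bf))) {
    a <- v[bf[i, 1], ]; b <- v[bf[i, 2], ]; cc <- v[bf[i, 3], ]
    nrm <- crossprod_3(b - a, cc - a)
    if (sum(nrm * (v[opp[i], ] - a)) > 0) bf[i, 2:3] <- bf[i, 3:2]
  }
  used <- sort(unique(as.vector(bf)))
  remap <- match(bf, used)
  dim(remap) <- dim(bf)
  region_mesh(v[used, , drop = FALSE], remap, name = region$name)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- voxelisation -----------------------------------------------------------

#' Voxelise a region
#'
#' Boolean occupancy grid over the bounding box: a voxel is occupied when its
#' centre passes [contains()].
#'
#' @param region A [region3d].
#' @param voxel_size_um Voxel edge length, micrometres.
#' @param honor_exclusions Carve exclusion zones out of the mask?
#' @return A `region_voxel` [region3d].
#' @export
voxelize <- function(region, voxel_size_um, honor_exclusions = FALSE) {
  bb <- bounding_box(region)
  nv <- pmax(1L, ceiling((bb$hi - bb$lo) / voxel_size_um))
  ax <- lapply(1:3, function(k)
    bb$lo[k] + (seq_len(nv[k]) - 0.5) * voxel_size_um)
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  inside <- contains(region, grid, honor_exclusions = honor_exclusions)
  mask <- array(inside, dim = nv)
  region_voxel(mask, voxel_size_um, origin_um = bb$lo, name = region$name)
}

# ---- ball sub-region extraction ---------------------------------------------

# Boundary clearance of interior points along a fixed direction set,
# vectorised bisection; conservative (a min over 26 directions).
clearance_at <- function(region, pts, r_hi) {
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n <- nrow(pts)
  clear <- rep(r_hi, n)
  inside0 <- region_inside(region, pts)
  clear[!inside0] <- -1
  for (d in seq_len(nrow(dirs))) {
    lo <- numeric(n); hi <- rep(r_hi, n)
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      q <- pts + outer(mid, dirs[d, ])
      ok <- region_inside(region, q)
      lo[ok] <- mid[ok]
      hi[!ok] <- mid[!ok]
    }
    clear <- pmin(clear, lo)
  }
  clear
}

#' Extract a ball-shaped sub-region away from the boundary
#'
#' Restricts a pattern to a ball of given radius placed inside the region, to
#' reduce boundary effects on second-order statistics. With `center = "auto"`
#' the centre is chosen on a 0.1 mm grid as the interior point with maximal
#' boundary clearance (clearance approximated along a 26-direction set).
#'
#' @param pattern A [soma_pattern()].
#' @param region The [region3d] the pattern lives in.
#' @param radius_um Ball radius, micrometres (default 1000).
#' @param center Length-3 centre in micrometres, or `"auto"`.
#' @return List with `pattern` (points inside the ball), `region` (spherical
#'   [region3d]) and `center`.
#' @export
extract_ball_subregion <- function(pattern, region, radius_um = 1000,
                                   center = "auto") {
  bb <- bounding_box(region)
  r_hi <- sqrt(sum((bb$hi - bb$lo)^2))
  if (identical(center, "auto")) {
    step <- 100
    ax <- lapply(1:3, function(k) {
      s <- seq(bb$lo[k] + step / 2, bb$hi[k] - step / 2, by = step)
      if (length(s) == 0) mean(c(bb$lo[k], bb$hi[k])) else s
    })
    # coarse screen, then full clearance on surviving candidates
    grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    grid <- grid[region_inside(region, grid), , drop = FALSE]
    if (nrow(grid) == 0)
      stop_somaspat("no interior grid point found",
                    class = "somaspat_geometry_error")
    if (nrow(grid) > 4000) {
      idx <- seq(1, nrow(grid), length.out = 4000)
      coarse <- grid[unique(round(idx)), , drop = FALSE]
    } else coarse <- grid
    cl <- clearance_at(region, coarse, r_hi)
    center <- coarse[which.max(cl), ]
    best <- max(cl)
  } else {
    center <- as.numeric(center)
    best <- clearance_at(region, matrix(center, 1, 3), r_hi)
  }
  if (best < radius_um * (1 - 5e-3))
    stop_somaspat("no placement with clearance >= radius (best ",
                  round(best), " um)", class = "somaspat_geometry_error")
  ball <- region_sphere(center, radius_um, name = region$name)
  d2 <- rowSums(sweep(pattern$coords, 2, center)^2)
  sub <- pattern[d2 <= radius_um^2]
  sub$region <- ball
  list(pattern = sub, region = ball, center = center)
}
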