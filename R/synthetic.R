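#' Reference per-structure counts and volumes
#'
#' The published per-structure soma counts and structure volumes for the five
#' cholinergic forebrain regions (caudate-putamen CPu, nucleus basalis NB,
#' globus pallidus GP, nucleus accumbens NA, septum S), by hemisphere column
#' as printed. These are the inputs for the density summaries and the targets
#' the synthetic fixtures reproduce. Note that the source's hemisphere column
#' labels conflict with its text totals (see [hemispheric_summary()]); the
#' table is reported as printed and both orientations of the totals are
#' computed downstream.
#'
#' @return data.frame with columns `region`, `hemisphere`, `count`,
#'   `volume_mm3`, `mean_diameter_um`.
#' @export
table1_data <- function() {
  data.frame(
    region = rep(c("GP", "NA", "S", "NB", "CPu"), 2),
    hemisphere = rep(c("L", "R"), each = 5),
    count = c(308, 638, 638, 1130, 4002,
              200, 619, 827, 1078, 4549),
    volume_mm3 = c(2.74, 2.13, 0.89, 3.37, 15.06,
                   2.07, 1.78, 1.17, 2.95, 15.95),
    mean_diameter_um = rep(c(27.37, 24.33, 23.60, 26.54, 25.32), 2),
    stringsAsFactors = FALSE)
}

# Anterior:posterior density ratios used for the gradient fixtures, read off
# the published anterior-vs-posterior F statistics per structure/hemisphere
# (equal-volume halves, so F equals the count ratio).
gradient_ratios <- function() {
  data.frame(region = c("CPu", "CPu", "NB", "NB"),
             hemisphere = c("L", "R", "L", "R"),
             ratio = c(2.10, 1.51, 1.38, 2.43),
             stringsAsFactors = FALSE)
}

# Fixture layout: ellipsoids elongated 1:2:1 along the anterior-posterior
# (Y) axis. Centres (um) are an arbitrary non-anatomical arrangement; only
# volumes, counts and gradients carry scientific meaning.
fixture_centers <- function() {
  base <- list(CPu = c(0, 4500, 3000), NB = c(0, 6500, 5500),
               GP = c(0, 5500, 4500), "NA" = c(0, 3500, 5000),
               S = c(0, 3500, 2500))
  list(base = base, mid_x = 5500, offset_x = 3000)
}

#' Ellipsoidal region fixture for a named structure
#'
#' Axis-aligned ellipsoid elongated 1:2:1 along the anterior-posterior axis
#' whose volume equals the published per-structure volume (exactly, by
#' construction).
#'
#' @param name One of `"CPu"`, `"NB"`, `"GP"`, `"NA"`, `"S"`.
#' @param hemisphere `"L"` or `"R"`.
#' @return A [region3d] (ellipsoid).
#' @examples
#' region_volume(make_region_fixture("GP", "L"))  # 2.74 mm^3
#' @export
make_region_fixture <- function(name, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  t1 <- table1_data()
  row <- t1[t1$region == name & t1$hemisphere == hemisphere, ]
  if (nrow(row) != 1)
    stop_somaspat("unknown region name '", name, "'",
                  class = "somaspat_fixture_error")
  v_um3 <- row$volume_mm3 * UM3_PER_MM3
  a <- (3 * v_um3 / (8 * pi))^(1 / 3)  # semiaxes (a, 2a, a)
  lay <- fixture_centers()
  ctr <- lay$base[[name]]
  ctr[1] <- lay$mid_x + if (hemisphere == "L") lay$offset_x else -lay$offset_x
  region_ellipsoid(ctr, c(a, 2 * a, a),
                   name = paste0(name, "_", hemisphere))
}

#' Completely spatially random (CSR) pattern in a region
#'
#' Uniform (binomial) point process with a fixed number of points,
#' the null model for the Monte Carlo envelopes. Honours any exclusion zones
#' attached to the region.
#'
#' @param region A [region3d].
#' @param n Number of points.
#' @param seed Optional integer seed (byte-identical output for equal seeds).
#' @param honor_exclusions Keep points out of exclusion zones?
#' @return A [soma_pattern()].
#' @export
generate_csr <- function(region, n, seed = NULL, honor_exclusions = TRUE) {
  sample_uniform(region, n, honor_exclusions = honor_exclusions, seed = seed)
}

# Solve the linear-weight slope so the anterior:posterior count ratio at the
# axis-midpoint split equals `ratio`; weights w = max(0, 1 + s*u) with u = +1
# at the anterior extreme. Uses fixed-seed MC quadrature over the region.
solve_gradient_slope <- function(region, axis, ratio, honor_exclusions) {
  k <- match(axis, c("x", "y", "z"))
  bb <- bounding_box(region)
  mid <- (bb$lo[k] + bb$hi[k]) / 2
  half <- (bb$hi[k] - bb$lo[k]) / 2
  pts <- with_seed(424242L, {
    p <- sample_uniform_core(region, 2e4)
    if (honor_exclusions && !is.null(region$exclusions)) {
      drop <- Reduce(`|`, lapply(region$exclusions, in_exclusion, points = p),
                     init = logical(nrow(p)))
      p <- p[!drop, , drop = FALSE]
    }
    p
  })
  u <- (mid - pts[, k]) / half
  ant <- u > 0
  f <- function(s) {
    w <- pmax(0, 1 + s * u)
    sum(w[ant]) / sum(w[!ant]) - ratio
  }
  if (abs(ratio - 1) < 1e-12) return(list(s = 0, mid = mid, half = half, k = k))
  s_hi <- 1
  while (sign(f(s_hi)) == sign(f(-s_hi)) && s_hi < 1e6) s_hi <- s_hi * 2
  s <- stats::uniroot(f, c(-s_hi, s_hi), tol = 1e-10)$root
  list(s = s, mid = mid, half = half, k = k)
}

#' Inhomogeneous pattern with a linear density gradient
#'
#' Conditional (fixed-n) simulation of an inhomogeneous Poisson process whose
#' intensity is linear along one axis, calibrated so that the expected
#' anterior:posterior count ratio at the axis midpoint equals `ratio`
#' (anterior = the low-coordinate side, matching the anatomical frame where
#' Y = 0 is most anterior). Realised by thinning a uniform proposal.
#'
#' @param region A [region3d].
#' @param n Number of points.
#' @param axis `"x"`, `"y"` or `"z"` (default `"y"`, anterior-posterior).
#' @param ratio Anterior:posterior density ratio (> 0; 1 = homogeneous).
#' @param seed Optional integer seed.
#' @param honor_exclusions Keep points out of exclusion zones?
#' @return A [soma_pattern()].
#' @export
generate_gradient <- function(region, n, axis = "y", ratio, seed = NULL,
                              honor_exclusions = TRUE) {
  stopifnot(ratio > 0)
  g <- solve_gradient_slope(region, axis, ratio, honor_exclusions)
  w_max <- 1 + abs(g$s)
  coords <- with_seed(seed, {
    got <- matrix(NA_real_, 0, 3)
    while (nrow(got) < n) {
      m <- max(1000L, ceiling(2 * (n - nrow(got)) * w_max))
      cand <- sample_uniform(region, m, honor_exclusions = honor_exclusions,
                             seed = NULL)$coords
      u <- (g$mid - cand[, g$k]) / g$half
      w <- pmax(0, 1 + g$s * u)
      keep <- runif(m) < w / w_max
      got <- rbind(got, cand[keep, , drop = FALSE])
    }
    got[seq_len(n), , drop = FALSE]
  })
  soma_pattern(coords, region_label = region$name, region = region,
               check = FALSE)
}

#' Thomas-clustered pattern (Poisson cluster process)
#'
#' Uniform parent points; each parent receives a Poisson(`mean_offspring`)
#' number of children displaced isotropically by a Gaussian of standard
#' deviation `sd_um`. Children falling outside the region (or inside an
#' exclusion zone) are discarded, so the realised count is random with mean
#' slightly below `parent_count * mean_offspring`.
#'
#' @param region A [region3d].
#' @param parent_count Number of cluster parents.
#' @param mean_offspring Mean children per parent.
#' @param sd_um Isotropic displacement SD, micrometres.
#' @param seed Optional integer seed.
#' @param honor_exclusions Keep children out of exclusion zones?
#' @return A [soma_pattern()] of the children.
#' @export
generate_thomas <- function(region, parent_count, mean_offspring, sd_um,
                            seed = NULL, honor_exclusions = TRUE) {
  stopifnot(parent_count > 0, mean_offspring > 0, sd_um >= 0)
  coords <- with_seed(seed, {
    parents <- sample_uniform(region, parent_count,
                              honor_exclusions = honor_exclusions,
                              seed = NULL)$coords
    kids <- rpois(parent_count, mean_offspring)
    total <- sum(kids)
    if (total == 0) matrix(numeric(0), 0, 3) else {
      off <- matrix(rnorm(3 * total, sd = sd_um), ncol = 3)
      pts <- parents[rep(seq_len(parent_count), kids), , drop = FALSE] + off
      keep <- contains(region, pts, honor_exclusions = honor_exclusions)
      pts[keep, , drop = FALSE]
    }
  })
  soma_pattern(coords, region_label = region$name, region = region,
               check = FALSE)
}

#' Tube-bundle exclusion zones hitting a target volume fraction
#'
#' Adds anterior-posterior tubes (random cross-sectional positions inside the
#' region) until the excluded volume fraction, measured by deterministic
#' Monte Carlo, is within +/- 1 percentage point (absolute) of
#' `target_fraction`; the radius of the final tube is bisected down when a
#' whole tube would overshoot.
#'
#' @param region A [region3d] (typically a CPu fixture).
#' @param target_fraction Target excluded volume fraction in `[0, 0.9)`.
#' @param tube_radius_um Tube radius, micrometres.
#' @param seed Optional integer seed.
#' @return An `exclusion_tubes` object with attribute `measured_fraction`.
#' @export
generate_bundles <- function(region, target_fraction, tube_radius_um = 100,
                             seed = NULL) {
  stopifnot(target_fraction >= 0, target_fraction < 0.9, tube_radius_um > 0)
  if (target_fraction == 0) {
    ex <- tube_exclusions(numeric(0), numeric(0), tube_radius_um)
    attr(ex, "measured_fraction") <- 0
    return(ex)
  }
  tol <- 0.01
  # coarser MC during construction; the reported fraction is re-measured at
  # full precision at the end
  measure <- function(xs, zs, rs) {
    excluded_fraction(set_exclusions(region, tube_exclusions(xs, zs, rs)),
                      n_mc = 5e4)
  }
  ex <- with_seed(seed, {
    xs <- zs <- rs <- numeric(0)
    frac <- 0
    for (i in 1:2000) {
      p <- sample_uniform_core(region, 1)
      xs2 <- c(xs, p[1]); zs2 <- c(zs, p[3]); rs2 <- c(rs, tube_radius_um)
      f2 <- measure(xs2, zs2, rs2)
      if (f2 >= target_fraction - tol / 4) {
        # final tube: bisect its radius onto the target
        lo <- 0; hi <- tube_radius_um
        for (it in 1:40) {
          midr <- (lo + hi) / 2
          rs2[length(rs2)] <- midr
          fm <- measure(xs2, zs2, rs2)
          if (fm > target_fraction) hi <- midr else lo <- midr
          if (abs(fm - target_fraction) <= tol / 4) break
        }
        f2 <- measure(xs2, zs2, rs2)
      }
      xs <- xs2; zs <- zs2; rs <- rs2; frac <- f2
      if (abs(frac - target_fraction) <= tol / 4) break
    }
    out <- tube_exclusions(xs, zs, rs)
    frac <- excluded_fraction(set_exclusions(region, out))
    if (abs(frac - target_fraction) > tol)
      stop_somaspat("could not reach target exclusion fraction ",
                    target_fraction, class = "somaspat_fixture_error")
    attr(out, "measured_fraction") <- frac
    out
  })
  ex
}

#' Full bilateral synthetic dataset
#'
#' Concatenates fixture patterns for all five structures in both hemispheres
#' with exactly the published per-structure counts; the CPu and NB receive
#' anterior-posterior density gradients at the published anterior:posterior
#' ratios, the other structures are CSR. Somal diameters are drawn from a
#' Gaussian around the published per-structure mean (SD 3 um, truncated at
#' the 15 um detection threshold).
#'
#' @param seed Optional integer seed.
#' @return A [soma_pattern()] with region and hemisphere labels and
#'   diameters; total count 13,989.
#' @export
generate_bilateral_dataset <- function(seed = NULL) {
  t1 <- table1_data()
  gr <- gradient_ratios()
  parts <- vector("list", nrow(t1))
  for (i in seq_len(nrow(t1))) {
    reg <- make_region_fixture(t1$region[i], t1$hemisphere[i])
    sub_seed <- derive_seed(seed, i)
    g <- gr[gr$region == t1$region[i] & gr$hemisphere == t1$hemisphere[i], ]
    p <- if (nrow(g) == 1)
      generate_gradient(reg, t1$count[i], axis = "y", ratio = g$ratio,
                        seed = sub_seed)
    else
      generate_csr(reg, t1$count[i], seed = sub_seed)
    diam <- with_seed(derive_seed(seed, 100L + i), {
      d <- rnorm(t1$count[i], t1$mean_diameter_um[i], 3)
      while (any(d < 15)) d[d < 15] <- rnorm(sum(d < 15),
                                             t1$mean_diameter_um[i], 3)
      d
    })
    parts[[i]] <- soma_pattern(p$coords, region_label = t1$region[i],
                               hemisphere = t1$hemisphere[i],
                               diameter_um = diam, check = FALSE)
  }
  bind_patterns(parts)
}
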