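#' Default radii grid for K-function estimation
#'
#' 100 equally spaced radii from 0 to half the region's maximum chord, the
#' grid under which the paired t comparison of observed and simulated K
#' curves has 99 degrees of freedom.
#'
#' @param region A [region3d].
#' @param n_r Number of radii (default 100).
#' @param r_max Optional maximum radius (um); default half the maximum chord.
#' @return Increasing numeric vector of radii (um).
#' @export
default_radii <- function(region, n_r = 100, r_max = NULL) {
  if (is.null(r_max)) r_max <- max_chord(region) / 2
  seq(0, r_max, length.out = n_r)
}

max_chord <- function(region) {
  if (inherits(region, "region_ellipsoid")) return(2 * max(region$semiaxes))
  bb <- bounding_box(region)
  sqrt(sum((bb$hi - bb$lo)^2))
}

#' Uncorrected 3D Ripley K-function
#'
#' Estimates `K(r) = |V| * sum_i sum_{j != i} 1[D(i,j) <= r] / n^2` with `|V|`
#' the (constant) region volume in mm^3 and exact Euclidean pair distances;
#' ties `D = r` count as within r. No edge correction is applied: the
#' estimator is biased near boundaries, but identically biased for observed
#' and simulated patterns sharing the same region, which is what the Monte
#' Carlo tests rely on.
#'
#' @param pattern A [soma_pattern()] with n >= 1 points.
#' @param region_volume_mm3 Region volume `|V|`; defaults to the volume of the
#'   pattern's attached region.
#' @param radii_um Increasing radii grid (um); defaults to
#'   [default_radii()] of the attached region.
#' @return A `kfun3d` object: data frame with columns `r_um`, `k_obs` (mm^3)
#'   plus attributes `n` and `volume_mm3`.
#' @examples
#' reg <- region_box(c(0, 0, 0), c(1000, 1000, 1000))
#' p <- sample_uniform(reg, 50, seed = 1)
#' k <- k_function(p)
#' head(k)
#' @export
k_function <- function(pattern, region_volume_mm3 = NULL, radii_um = NULL) {
  n <- npoints(pattern)
  if (n < 1) stop_somaspat("empty pattern", class = "somaspat_input_error")
  if (is.null(region_volume_mm3)) {
    if (is.null(pattern$region))
      stop_somaspat("no region attached and no region_volume_mm3 given",
                    class = "somaspat_input_error")
    region_volume_mm3 <- region_volume(pattern$region)
  }
  if (region_volume_mm3 <= 0)
    stop_somaspat("region volume must be positive",
                  class = "somaspat_input_error")
  if (is.null(radii_um)) {
    if (is.null(pattern$region))
      stop_somaspat("no region attached and no radii_um given",
                    class = "somaspat_input_error")
    radii_um <- default_radii(pattern$region)
  }
  stopifnot(all(diff(radii_um) > 0), all(radii_um >= 0))
  cnt <- cpp_pair_count(pattern$coords[, 1], pattern$coords[, 2],
                        pattern$coords[, 3], radii_um)
  k <- region_volume_mm3 * 2 * cnt / n^2
  structure(data.frame(r_um = radii_um, k_obs = k),
            n = n, volume_mm3 = region_volume_mm3,
            class = c("kfun3d", "data.frame"))
}

#' Theoretical CSR K-function
#' @param radii_um Radii (um).
#' @return `(4/3) pi r^3` in mm^3.
#' @export
k_csr_theoretical <- function(radii_um) 4 / 3 * pi * radii_um^3 / UM3_PER_MM3

envelope_rank <- function(n_sims) max(1L, floor(0.025 * (n_sims + 1)))

#' CSR Monte Carlo envelope for the K-function
#'
#' Simulates `n_sims` uniform patterns with the same number of points in the
#' same region (optionally honouring exclusion zones) and computes the same
#' uncorrected K estimator for each, so that observed and simulated
#' estimators share the region, shape, n and bias. The pointwise band uses
#' the m-th smallest and m-th largest simulated value at each radius with
#' `m = floor(0.025 (n_sims + 1))`, the exact-rate Monte Carlo convention
#' (2.5% per tail; e.g. m = 5 for 199 simulations).
#'
#' @param pattern Observed [soma_pattern()].
#' @param region The [region3d] null simulations are drawn from.
#' @param n_sims Number of simulations (default 1000).
#' @param honor_exclusions Exclude simulated points from exclusion zones?
#' @param radii_um Radii grid (um); default [default_radii()] of `region`.
#' @param seed Optional master seed; per-simulation seeds are derived by
#'   counter, so results are reproducible.
#' @return A `kenv3d` object: data frame with `r_um`, `k_obs`, `k_sim_mean`,
#'   `k_lo`, `k_hi` and attributes `sims` (n_sims x n_radii matrix), `n`,
#'   `volume_mm3`, `exclusions_honored`, `seed`.
#' @export
csr_envelope <- function(pattern, region, n_sims = 1000,
                         honor_exclusions = FALSE, radii_um = NULL,
                         seed = NULL) {
  stopifnot(n_sims >= 2)
  if (is.null(radii_um)) radii_um <- default_radii(region)
  v <- region_volume(region)
  n <- npoints(pattern)
  obs <- k_function(pattern, region_volume_mm3 = v, radii_um = radii_um)
  sims <- matrix(NA_real_, n_sims, length(radii_um))
  for (s in seq_len(n_sims)) {
    sim <- sample_uniform(region, n, honor_exclusions = honor_exclusions,
                          seed = derive_seed(seed, s))
    sims[s, ] <- k_function(sim, region_volume_mm3 = v,
                            radii_um = radii_um)$k_obs
  }
  m <- envelope_rank(n_sims)
  lo <- apply(sims, 2, function(v) sort(v)[m])
  hi <- apply(sims, 2, function(v) sort(v, decreasing = TRUE)[m])
  structure(data.frame(r_um = radii_um, k_obs = obs$k_obs,
                       k_sim_mean = colMeans(sims), k_lo = lo, k_hi = hi),
            sims = sims, n = n, volume_mm3 = v,
            exclusions_honored = honor_exclusions, seed = seed,
            class = c("kenv3d", "data.frame"))
}

#' @export
print.kenv3d <- function(x, ...) {
  cat("K-function CSR envelope:", nrow(attr(x, "sims")), "simulations, n =",
      attr(x, "n"), "points, |V| =", signif(attr(x, "volume_mm3"), 4),
      "mm^3\n")
  above <- sum(x$k_obs > x$k_hi)
  below <- sum(x$k_obs < x$k_lo)
  cat("  observed K above band at", above, "radii, below at", below, "of",
      nrow(x), "\n")
  invisible(x)
}

#' @param x A `kenv3d` object.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @rdname csr_envelope
#' @export
plot.kenv3d <- function(x, main = "Ripley K vs CSR envelope", ...) {
  graphics::plot(x$r_um, x$k_obs, type = "n", xlab = "r (um)",
                 ylab = expression(K(r) ~ (mm^3)), main = main, ...)
  graphics::polygon(c(x$r_um, rev(x$r_um)), c(x$k_lo, rev(x$k_hi)),
                    col = "grey85", border = NA)
  graphics::lines(x$r_um, x$k_sim_mean, col = "grey40")
  graphics::lines(x$r_um, x$k_obs, col = "red3", lwd = 2)
  invisible(x)
}

#' Paired t comparison of observed and simulated K curves
#'
#' Classical paired-sample t-test over the per-radius pairs of an observed
#' K curve and the simulation mean; with the default 100-point radii grid
#' the test has 99 degrees of freedom. The radii are autocorrelated, so the
#' p-value is descriptive rather than exact; the Monte Carlo envelope and
#' rank tests carry the calibrated inference.
#'
#' @param k_observed Observed per-radius K values, or a `kenv3d` object (in
#'   which case `k_sim_mean` is taken from it).
#' @param k_sim_mean Simulated-mean per-radius K values.
#' @return List with `t`, `df`, `p` (two-sided) and `degenerate` (TRUE when
#'   the differences have zero variance).
#' @export
paired_t_compare <- function(k_observed, k_sim_mean = NULL) {
  if (inherits(k_observed, "kenv3d")) {
    k_sim_mean <- k_observed$k_sim_mean
    k_observed <- k_observed$k_obs
  }
  m <- length(k_observed)
  if (m != length(k_sim_mean) || m < 2)
    stop_somaspat("need two vectors of equal length >= 2",
                  class = "somaspat_input_error")
  d <- k_observed - k_sim_mean
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = m - 1, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = m - 1, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(k_observed, k_sim_mean, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
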