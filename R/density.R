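#' Point density of a structure
#'
#' @param count Number of somata (>= 0).
#' @param volume_mm3 Structure volume in mm^3 (> 0).
#' @return Density in mm^-3 (exact quotient).
#' @examples
#' density_mm3(308, 2.74)  # 112.41 mm^-3
#' @export
density_mm3 <- function(count, volume_mm3) {
  if (any(volume_mm3 <= 0))
    stop_somaspat("volume must be positive", class = "somaspat_input_error")
  if (any(count < 0))
    stop_somaspat("count must be non-negative", class = "somaspat_input_error")
  count / volume_mm3
}

#' Hemispheric density summary
#'
#' Per-structure densities, per-hemisphere totals, the absolute hemispheric
#' count difference and its percentage of the grand total, per-hemisphere
#' overall densities and their difference, and each structure's proportion of
#' the grand total. Both hemisphere orientations of the totals are reported
#' (`denser_hemisphere` identifies which label carries the higher overall
#' density); the source data's table and text disagree on which label is
#' which, so no orientation is asserted.
#'
#' @param table data.frame with columns `region`, `hemisphere`, `count`,
#'   `volume_mm3` (defaults to [table1_data()]).
#' @return A `density_summary` list; see Details.
#' @details Elements: `per_structure` (with densities), `totals` (per
#'   hemisphere: count, volume, density), `count_difference`,
#'   `count_difference_pct`, `density_difference_mm3`, `denser_hemisphere`,
#'   `proportions` (per structure, summing to 1), `grand_total`.
#' @examples
#' s <- hemispheric_summary()
#' s$count_difference       # 557
#' round(s$count_difference_pct, 2)  # 3.98
#' @export
hemispheric_summary <- function(table = table1_data()) {
  need <- c("region", "hemisphere", "count", "volume_mm3")
  if (!all(need %in% names(table)))
    stop_somaspat("missing columns: ",
                  paste(setdiff(need, names(table)), collapse = ", "),
                  class = "somaspat_input_error")
  cells <- with(table, table(region, hemisphere))
  missing_cells <- which(cells == 0, arr.ind = TRUE)
  if (nrow(missing_cells) > 0)
    stop_somaspat("missing region x hemisphere cells: ",
                  paste(rownames(cells)[missing_cells[, 1]],
                        colnames(cells)[missing_cells[, 2]],
                        sep = "/", collapse = ", "),
                  class = "somaspat_input_error")
  table$density_mm3 <- density_mm3(table$count, table$volume_mm3)
  tot <- aggregate(cbind(count, volume_mm3) ~ hemisphere, table, sum)
  tot$density_mm3 <- density_mm3(tot$count, tot$volume_mm3)
  grand <- sum(table$count)
  prop <- aggregate(count ~ region, table, sum)
  prop$proportion <- prop$count / grand
  list(per_structure = table,
       totals = tot,
       grand_total = grand,
       count_difference = abs(diff(tot$count)),
       count_difference_pct = 100 * abs(diff(tot$count)) / grand,
       density_difference_mm3 = abs(diff(tot$density_mm3)),
       denser_hemisphere = tot$hemisphere[which.max(tot$density_mm3)],
       proportions = prop)
}

#' F-test for equality of point densities in two windows
#'
#' Quadrat-count F statistic for two sub-windows with `n1`, `n2` points and
#' volumes `v1`, `v2`: the test statistic is
#' `F = v2 (2 n1 + 1) / (v1 (2 n2 + 1))` with degrees of freedom
#' `(2 n1 + 1, 2 n2 + 1)`, so that F > 1 indicates window 1 denser, the
#' orientation under which the published per-structure values are
#' reproduced (with equal volumes and n1 = 51, n2 = 43: F = 103/87 = 1.18,
#' df = (103, 87)). The algebraically reciprocal orientation (window 2 in
#' the numerator, as in the formula's usual printed form) is returned as
#' `F_alt`/`df_alt`. The p-value is one-sided from the F distribution.
#'
#' @param n1,n2 Point counts in windows 1 and 2.
#' @param v1,v2 Window volumes (mm^3).
#' @return List with `F`, `df`, `p`, `F_alt`, `df_alt`.
#' @export
homogeneity_f_test <- function(n1, v1, n2, v2) {
  stopifnot(n1 >= 0, n2 >= 0, v1 > 0, v2 > 0)
  d1 <- 2 * n1 + 1
  d2 <- 2 * n2 + 1
  f <- (v2 * d1) / (v1 * d2)
  p <- stats::pf(f, d1, d2, lower.tail = FALSE)
  list(F = f, df = c(d1, d2), p = p,
       F_alt = 1 / f, df_alt = c(d2, d1))
}

#' Split a pattern into anterior and posterior sub-windows
#'
#' Splits the region at a plane perpendicular to the anterior-posterior (Y)
#' axis -- by default the volume-median plane -- and returns counts and
#' volumes of the two sub-windows together with their homogeneity F-test.
#' Points exactly on the plane count as anterior. Sub-window volumes are
#' computed analytically for centre splits of symmetric regions and by
#' fixed-seed Monte Carlo otherwise. The anterior window is the low-Y side
#' (Y = 0 is most anterior in the anatomical frame).
#'
#' @param pattern A [soma_pattern()].
#' @param region The [region3d] the pattern lives in.
#' @param plane Y threshold in micrometres, or `"median"` for the
#'   volume-median plane.
#' @return List with `anterior` and `posterior` (each `n`, `volume_mm3`),
#'   `plane_y_um` and `f_test` ([homogeneity_f_test()] of anterior vs
#'   posterior).
#' @export
split_anterior_posterior <- function(pattern, region, plane = "median") {
  v <- region_volume(region)
  bb <- bounding_box(region)
  if (identical(plane, "median")) {
    if (inherits(region, c("region_ellipsoid", "region_box"))) {
      plane_y <- if (inherits(region, "region_box"))
        (bb$lo[2] + bb$hi[2]) / 2 else region$center[2]
      frac_ant <- 0.5
    } else {
      ys <- with_seed(343434L, sample_uniform_core(region, 2e5))[, 2]
      plane_y <- stats::median(ys)
      frac_ant <- mean(ys <= plane_y)
    }
  } else {
    plane_y <- as.numeric(plane)
    if (plane_y <= bb$lo[2] || plane_y >= bb$hi[2])
      stop_somaspat("split plane outside the region: one side is empty",
                    class = "somaspat_input_error")
    if (inherits(region, "region_box")) {
      frac_ant <- (plane_y - bb$lo[2]) / (bb$hi[2] - bb$lo[2])
    } else {
      ys <- with_seed(343434L, sample_uniform_core(region, 2e5))[, 2]
      frac_ant <- mean(ys <= plane_y)
    }
  }
  if (frac_ant <= 0 || frac_ant >= 1)
    stop_somaspat("degenerate split: one side has no volume",
                  class = "somaspat_input_error")
  ant <- pattern$coords[, 2] <= plane_y
  v_ant <- v * frac_ant
  v_post <- v * (1 - frac_ant)
  list(anterior = list(n = sum(ant), volume_mm3 = v_ant),
       posterior = list(n = sum(!ant), volume_mm3 = v_post),
       plane_y_um = plane_y,
       f_test = homogeneity_f_test(sum(ant), v_ant, sum(!ant), v_post))
}
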