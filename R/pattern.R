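#' 3D point pattern of soma centroids
#'
#' Container for soma centroid coordinates in micrometres with optional
#' per-point region label, hemisphere label and somal diameter, and an
#' optional bounded region of observation (a [region3d] object). The axis
#' convention follows the coordinate frame of the source data: X = 0 at the
#' most lateral point of the right side, Y = 0 at the most anterior point,
#' Z = 0 at the most dorsal point.
#'
#' When a region is attached every point must pass its membership test
#' (honouring exclusion zones), which is checked at construction.
#'
#' @param coords Numeric n x 3 matrix (or data frame) of x/y/z in micrometres.
#' @param region_label Optional character vector of region labels, recycled.
#' @param hemisphere Optional character vector ("L"/"R"), recycled.
#' @param diameter_um Optional numeric vector of somal diameters.
#' @param region Optional [region3d] the pattern lives in.
#' @param check Validate membership of `region` (default `TRUE`).
#' @return An object of class `soma_pattern`.
#' @examples
#' p <- soma_pattern(matrix(runif(30, 0, 1000), ncol = 3))
#' npoints(p)
#' @export
soma_pattern <- function(coords, region_label = NULL, hemisphere = NULL,
                         diameter_um = NULL, region = NULL, check = TRUE) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  recycle <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop(what, " must have length 1 or n")
    v
  }
  region_label <- recycle(region_label, "region_label")
  hemisphere <- recycle(hemisphere, "hemisphere")
  diameter_um <- recycle(diameter_um, "diameter_um")
  if (!is.null(region) && check && n > 0) {
    ok <- contains(region, coords, honor_exclusions = TRUE)
    if (!all(ok))
      stop_somaspat(sum(!ok), " point(s) outside the region (or inside an ",
                    "exclusion zone)", class = "somaspat_membership_error")
  }
  structure(list(coords = coords, region_label = region_label,
                 hemisphere = hemisphere, diameter_um = diameter_um,
                 region = region),
            class = "soma_pattern")
}

#' Number of points in a pattern
#' @param x A `soma_pattern`.
#' @return Integer count.
#' @export
npoints <- function(x) UseMethod("npoints")

#' @export
npoints.soma_pattern <- function(x) nrow(x$coords)

#' @export
print.soma_pattern <- function(x, ...) {
  cat("3D soma point pattern:", npoints(x), "points\n")
  if (npoints(x) > 0) {
    rg <- apply(x$coords, 2, range)
    cat(sprintf("  extent (um): x [%.0f, %.0f]  y [%.0f, %.0f]  z [%.0f, %.0f]\n",
                rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  }
  if (!is.null(x$region_label))
    cat("  regions:", paste(names(table(x$region_label)), collapse = ", "), "\n")
  if (!is.null(x$region))
    cat("  window:", format(x$region), "\n")
  invisible(x)
}

#' @export
as.data.frame.soma_pattern <- function(x, ...) {
  d <- as.data.frame(x$coords)
  if (!is.null(x$region_label)) d$region <- x$region_label
  if (!is.null(x$hemisphere)) d$hemisphere <- x$hemisphere
  if (!is.null(x$diameter_um)) d$diameter_um <- x$diameter_um
  d
}

#' Subset a soma pattern
#' @param x A `soma_pattern`.
#' @param i Index vector.
#' @param ... Ignored.
#' @return A `soma_pattern` with the selected points.
#' @export
`[.soma_pattern` <- function(x, i, ...) {
  soma_pattern(x$coords[i, , drop = FALSE],
               region_label = if (!is.null(x$region_label)) x$region_label[i],
               hemisphere = if (!is.null(x$hemisphere)) x$hemisphere[i],
               diameter_um = if (!is.null(x$diameter_um)) x$diameter_um[i],
               region = x$region, check = FALSE)
}

#' Concatenate soma patterns
#' @param ... `soma_pattern` objects.
#' @return A single `soma_pattern` (no region attached).
#' @export
bind_patterns <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "soma_pattern"))
    ps <- ps[[1]]
  coords <- do.call(rbind, lapply(ps, function(p) p$coords))
  pull <- function(field, default) {
    vals <- lapply(ps, function(p)
      if (is.null(p[[field]])) rep(default, npoints(p)) else p[[field]])
    v <- unlist(vals, use.names = FALSE)
    if (all(is.na(v))) NULL else v
  }
  soma_pattern(coords,
               region_label = pull("region_label", NA_character_),
               hemisphere = pull("hemisphere", NA_character_),
               diameter_um = pull("diameter_um", NA_real_))
}
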