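KNOWN_REGIONS <- c("CPu", "NB", "GP", "NA", "S")

# header synonyms for coordinate tables (supplementary databases vary)
coord_synonyms <- list(
  x_um = c("x_um", "x", "x.um", "x_coordinate"),
  y_um = c("y_um", "y", "y.um", "y_coordinate"),
  z_um = c("z_um", "z", "z.um", "z_coordinate"),
  region = c("region", "structure", "nucleus", "area"),
  hemisphere = c("hemisphere", "hemi", "side"),
  diameter_um = c("diameter_um", "diameter", "size", "somal_diameter",
                  "soma_diameter_um"))

match_columns <- function(nms) {
  lower <- tolower(trimws(nms))
  sapply(names(coord_synonyms), function(canon) {
    hit <- which(lower %in% coord_synonyms[[canon]])
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
}

#' Read a soma coordinate table
#'
#' Reads a delimited coordinate table (CSV, or XLSX when the `readxl`
#' package is available) with one row per cell. Required columns (synonyms
#' are sniffed case-insensitively, e.g. `x`/`x_um`, `structure`/`region`):
#' x/y/z in micrometres. Optional: region, hemisphere, somal diameter. The
#' literal region label `"NA"` (nucleus accumbens) is preserved, not parsed
#' as missing. Row order is preserved.
#'
#' @param path File path (`.csv` or `.xlsx`).
#' @param permissive Accept region labels outside the five known structures?
#' @return A [soma_pattern()]; the header mapping used is attached as
#'   attribute `column_mapping`.
#' @export
read_coordinates <- function(path, permissive = FALSE) {
  if (!file.exists(path))
    stop_somaspat("file not found: ", path, class = "somaspat_io_error")
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_somaspat("reading XLSX requires the 'readxl' package",
                    class = "somaspat_io_error")
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = character(0),
                          check.names = FALSE)
  }
  if (nrow(df) == 0)
    stop_somaspat("empty coordinate file: ", path,
                  class = "somaspat_io_error")
  map <- match_columns(names(df))
  need <- c("x_um", "y_um", "z_um")
  miss <- need[is.na(map[need])]
  if (length(miss) > 0)
    stop_somaspat("missing required column(s): ",
                  paste(miss, collapse = ", "),
                  class = "somaspat_schema_error")
  num <- function(canon) {
    v <- df[[map[[canon]]]]
    x <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(x))
    if (length(bad) > 0)
      stop_somaspat("non-numeric ", canon, " at row(s) ",
                    paste(utils::head(bad, 5), collapse = ", "),
                    class = "somaspat_schema_error")
    x
  }
  coords <- cbind(num("x_um"), num("y_um"), num("z_um"))
  region_label <- if (!is.na(map[["region"]]))
    as.character(df[[map[["region"]]]]) else NULL
  if (!is.null(region_label) && !permissive) {
    unknown <- setdiff(unique(region_label), KNOWN_REGIONS)
    if (length(unknown) > 0)
      stop_somaspat("unknown region label(s): ",
                    paste(unknown, collapse = ", "),
                    " (use permissive = TRUE to accept)",
                    class = "somaspat_schema_error")
  }
  hemi <- if (!is.na(map[["hemisphere"]]))
    as.character(df[[map[["hemisphere"]]]]) else NULL
  diam <- if (!is.na(map[["diameter_um"]])) {
    x <- suppressWarnings(as.numeric(df[[map[["diameter_um"]]]]))
    if (all(is.na(x))) NULL else x
  } else NULL
  p <- soma_pattern(coords, region_label = region_label, hemisphere = hemi,
                    diameter_um = diam)
  attr(p, "column_mapping") <- map
  p
}

#' Write a soma coordinate table
#'
#' CSV with canonical headers (`x_um`, `y_um`, `z_um`, `region`,
#' `hemisphere`, `diameter_um`); round-trips through [read_coordinates()]
#' without loss.
#'
#' @param pattern A [soma_pattern()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(pattern, path) {
  df <- as.data.frame(pattern)
  # full double precision so coordinates round-trip bit-exactly
  for (cn in names(df))
    if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- voxel masks ------------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, voxel_size_um, origin_um, dim) {
  jsonlite::write_json(list(voxel_size_um = voxel_size_um,
                            origin_um = origin_um, dim = dim),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop_somaspat("missing geometry sidecar: ", sp,
                  class = "somaspat_mask_error")
  js <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(js$voxel_size_um) || is.null(js$origin_um) || is.null(js$dim))
    stop_somaspat("sidecar lacks voxel_size_um/origin_um/dim",
                  class = "somaspat_mask_error")
  js
}

#' Write an exclusion mask
#'
#' Two plain formats, chosen by extension: a CSV voxel list (`ix,iy,iz`
#' indices of occupied voxels) or a boolean multi-page TIFF (one page per z
#' slice, rows = y, columns = x). Both carry a JSON sidecar
#' (`<path>.json`) with the voxel size (um), origin (lower corner of voxel
#' `[1,1,1]`) and grid dimensions.
#'
#' @param mask An `exclusion_voxels` object (see [voxel_exclusions()],
#'   [as_voxel_mask()]).
#' @param path Output path (`.csv`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "exclusion_voxels"))
  d <- dim(mask$mask)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    occ <- which(mask$mask, arr.ind = TRUE)
    colnames(occ) <- c("ix", "iy", "iz")
    utils::write.csv(as.data.frame(occ), path, row.names = FALSE,
                     quote = FALSE)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(d[3]), function(k) {
      m <- t(mask$mask[, , k])  # rows = y, cols = x
      storage.mode(m) <- "double"
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    stop_somaspat("unsupported mask format: ", path,
                  class = "somaspat_io_error")
  }
  write_sidecar(path, mask$voxel_size_um, mask$origin_um, d)
  invisible(path)
}

#' Read an exclusion mask
#'
#' Counterpart of [write_mask()]; requires the JSON geometry sidecar.
#'
#' @param path Mask path (`.csv`, `.tif` or `.tiff`).
#' @return An `exclusion_voxels` object.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop_somaspat("file not found: ", path, class = "somaspat_io_error")
  sc <- read_sidecar(path)
  d <- as.integer(sc$dim)
  mask <- array(FALSE, d)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    occ <- utils::read.csv(path)
    if (!all(c("ix", "iy", "iz") %in% names(occ)))
      stop_somaspat("voxel list must have columns ix, iy, iz",
                    class = "somaspat_mask_error")
    if (nrow(occ) > 0) {
      if (max(occ$ix) > d[1] || max(occ$iy) > d[2] || max(occ$iz) > d[3] ||
          min(occ) < 1)
        stop_somaspat("voxel indices outside sidecar dimensions",
                      class = "somaspat_mask_error")
      mask[cbind(occ$ix, occ$iy, occ$iz)] <- TRUE
    }
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != d[3])
      stop_somaspat("TIFF page count does not match sidecar dimensions",
                    class = "somaspat_mask_error")
    for (k in seq_len(d[3])) mask[, , k] <- t(pages[[k]]) > 0.5
  }
  voxel_exclusions(mask, sc$voxel_size_um, sc$origin_um)
}

#' Rasterise tube exclusions into a voxel mask
#'
#' Occupies every voxel of the region's bounding-box grid whose centre lies
#' in a tube and inside the region.
#'
#' @param tubes An `exclusion_tubes` object.
#' @param region The [region3d] supplying the grid extent.
#' @param voxel_size_um Voxel edge length (um).
#' @return An `exclusion_voxels` object.
#' @export
as_voxel_mask <- function(tubes, region, voxel_size_um) {
  stopifnot(inherits(tubes, "exclusion_tubes"))
  bb <- bounding_box(region)
  nv <- pmax(1L, ceiling((bb$hi - bb$lo) / voxel_size_um))
  ax <- lapply(1:3, function(k)
    bb$lo[k] + (seq_len(nv[k]) - 0.5) * voxel_size_um)
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  occ <- in_exclusion(tubes, grid) & region_inside(region, grid)
  voxel_exclusions(array(occ, dim = nv), voxel_size_um, origin_um = bb$lo)
}

#' Volume fraction of a region occupied by an exclusion mask
#'
#' @param exclusion An `exclusion3d` object.
#' @param region The reference [region3d].
#' @return Fraction of the region volume excluded.
#' @export
mask_occupancy <- function(exclusion, region) {
  excluded_fraction(set_exclusions(region, exclusion, validate = FALSE))
}

# ---- mesh regions (PLY / OFF, ASCII) ----------------------------------------

#' Write a region boundary as a PLY or OFF mesh
#'
#' ASCII only; tetrahedral regions from [build_region()] are reduced to
#' their boundary surface first.
#'
#' @param region A `region_mesh` or `region_tets` [region3d].
#' @param path Output path (`.ply` or `.off`).
#' @return `path`, invisibly.
#' @export
write_region <- function(region, path) {
  if (inherits(region, "region_tets")) region <- boundary_mesh(region)
  stopifnot(inherits(region, "region_mesh"))
  v <- region$vertices
  f <- region$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property double x", "property double y",
                 "property double z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(apply(format(v, digits = 17, scientific = FALSE,
                            trim = TRUE), 1, paste, collapse = " "), con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else if (grepl("\\.off$", path, ignore.case = TRUE)) {
    writeLines(c("OFF", paste(nrow(v), nrow(f), 0)), con)
    writeLines(apply(format(v, digits = 17, scientific = FALSE,
                            trim = TRUE), 1, paste, collapse = " "), con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else {
    stop_somaspat("unsupported mesh format: ", path,
                  class = "somaspat_io_error")
  }
  invisible(path)
}

#' Read a triangulated region boundary (ASCII PLY or OFF)
#'
#' @param path Mesh path (`.ply` or `.off`).
#' @param name Optional region label.
#' @return A `region_mesh` [region3d].
#' @export
read_region <- function(path, name = NULL) {
  if (!file.exists(path))
    stop_somaspat("file not found: ", path, class = "somaspat_io_error")
  lines <- readLines(path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    if (lines[1] != "ply" || !any(grepl("ascii", lines)))
      stop_somaspat("only ASCII PLY is supported",
                    class = "somaspat_io_error")
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    body <- which(lines == "end_header") + 1
  } else if (grepl("\\.off$", path, ignore.case = TRUE)) {
    if (trimws(lines[1]) != "OFF")
      stop_somaspat("not an OFF file", class = "somaspat_io_error")
    hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- hdr[1]; nf <- hdr[2]
    body <- 3
  } else {
    stop_somaspat("unsupported mesh format: ", path,
                  class = "somaspat_io_error")
  }
  vtx <- do.call(rbind, lapply(lines[body:(body + nv - 1)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fcs <- do.call(rbind, lapply(lines[(body + nv):(body + nv + nf - 1)],
                               function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3) stop_somaspat("only triangle meshes are supported",
                                 class = "somaspat_io_error")
    x[2:4] + 1L
  }))
  region_mesh(vtx, fcs, name = name)
}

# ---- analysis configuration -------------------------------------------------

#' Analysis pipeline configuration
#'
#' Collects the tunable parameters of [run_pipeline()] with the package
#' defaults; serialises stably to/from YAML.
#'
#' @param coords Path to a coordinate CSV, or `NULL` to generate the
#'   bilateral synthetic dataset.
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param n_sims CSR simulations for envelopes (default 1000).
#' @param n_null Inhomogeneous-Poisson null realisations (default 99).
#' @param k Nearest neighbours profiled (default 10).
#' @param alpha_um Alpha for [build_region()] when regions are built from
#'   the data (default `Inf`, the convex hull).
#' @param voxel_size_um Voronoi clipping resolution (default 20).
#' @param bandwidth Kernel bandwidth (um) or `"silverman"`.
#' @param ball_radius_um Boundary-avoiding ball radius (default 1000).
#' @param use_ball_subregion Restrict the inhomogeneous analysis to a ball?
#' @param honor_exclusions Honour exclusion zones in simulations?
#' @param split Anterior/posterior split plane (`"median"` or a Y value, um).
#' @param stages Character vector of stages to run, a subset of
#'   `c("summary", "homogeneity", "ripley", "neighbors", "clusters",
#'   "voronoi", "inhom")`.
#' @param regions Optional subset of region labels to analyse.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(coords = NULL, out_dir = ".", seed = 17,
                            n_sims = 1000, n_null = 99, k = 10,
                            alpha_um = Inf, voxel_size_um = 20,
                            bandwidth = "silverman", ball_radius_um = 1000,
                            use_ball_subregion = FALSE,
                            honor_exclusions = FALSE, split = "median",
                            stages = c("summary", "homogeneity", "ripley",
                                       "neighbors", "clusters", "voronoi"),
                            regions = NULL) {
  structure(list(coords = coords, out_dir = out_dir, seed = seed,
                 n_sims = n_sims, n_null = n_null, k = k,
                 alpha_um = alpha_um, voxel_size_um = voxel_size_um,
                 bandwidth = bandwidth, ball_radius_um = ball_radius_um,
                 use_ball_subregion = use_ball_subregion,
                 honor_exclusions = honor_exclusions, split = split,
                 stages = stages, regions = regions),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config An `analysis_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$alpha_um <- if (is.infinite(cfg$alpha_um)) "infinite" else cfg$alpha_um
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (identical(cfg$alpha_um, "infinite")) cfg$alpha_um <- Inf
  do.call(analysis_config, cfg)
}
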