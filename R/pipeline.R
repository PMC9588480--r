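write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full spatial-analysis pipeline
#'
#' Orchestrates, per structure and hemisphere: density summaries,
#' anterior/posterior homogeneity F-tests, homogeneous K-function CSR
#' envelopes with paired-t comparison, nearest-neighbour profiles and
#' cluster graphs, Voronoi volumetrics, and (optionally) the inhomogeneous
#' K analysis. All outputs are TSV files plus a JSON manifest recording the
#' configuration, seeds, per-stage status and headline numbers; given the
#' same configuration and seed the outputs are byte-identical. A stage
#' failure aborts the run with the stage name; outputs of completed stages
#' are retained and flagged in the manifest.
#'
#' @param config An [analysis_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pattern <- if (is.null(config$coords))
    generate_bilateral_dataset(seed = config$seed)
  else read_coordinates(config$coords)
  if (is.null(pattern$region_label))
    stop_somaspat("coordinate table has no region labels",
                  class = "somaspat_input_error")
  if (is.null(pattern$hemisphere))
    pattern$hemisphere <- rep("L", npoints(pattern))

  groups <- unique(data.frame(region = pattern$region_label,
                              hemisphere = pattern$hemisphere,
                              stringsAsFactors = FALSE))
  if (!is.null(config$regions))
    groups <- groups[groups$region %in% config$regions, , drop = FALSE]
  groups <- groups[order(groups$region, groups$hemisphere), , drop = FALSE]

  manifest <- list(package = "somaspat",
                   version = as.character(utils::packageVersion("somaspat")),
                   config = unclass(config),
                   seed = config$seed,
                   n_total = npoints(pattern),
                   groups = groups,
                   stages = list(), outputs = character(0), failed = NULL)
  manifest$config$alpha_um <- if (is.infinite(config$alpha_um))
    "infinite" else config$alpha_um

  # region geometry per group: fixture ellipsoids for synthetic data,
  # data-derived hulls/alpha-complexes otherwise
  get_region <- function(reg, hemi, sub) {
    if (is.null(config$coords))
      make_region_fixture(reg, hemi)
    else
      build_region(sub, alpha_um = config$alpha_um,
                   name = paste0(reg, "_", hemi))
  }
  subsets <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- pattern$region_label == groups$region[i] &
      pattern$hemisphere == groups$hemisphere[i]
    pattern[sel]
  })
  regions <- lapply(seq_len(nrow(groups)), function(i)
    get_region(groups$region[i], groups$hemisphere[i], subsets[[i]]))

  run_stage <- function(stage, fun) {
    if (!(stage %in% config$stages)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed <<- stage
      manifest$stages[[stage]] <<- list(status = "error",
                                        message = conditionMessage(res))
      jsonlite::write_json(manifest, file.path(config$out_dir,
                                               "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop_somaspat("pipeline stage '", stage, "' failed: ",
                    conditionMessage(res), class = "somaspat_pipeline_error")
    }
    manifest$stages[[stage]] <<- c(list(status = "ok"), res)
    invisible(NULL)
  }
  emit <- function(df, file) {
    p <- write_tsv(df, file.path(config$out_dir, file))
    manifest$outputs <<- c(manifest$outputs, file)
    p
  }
  tag <- function(i) paste0(groups$region[i], "_", groups$hemisphere[i])

  run_stage("summary", function() {
    tab <- data.frame(region = groups$region, hemisphere = groups$hemisphere,
                      count = vapply(subsets, npoints, 0L),
                      volume_mm3 = vapply(regions, region_volume, 0))
    tab$density_mm3 <- density_mm3(tab$count, tab$volume_mm3)
    emit(tab, "summary.tsv")
    hs <- if (all(table(tab$region) == 2)) hemispheric_summary(tab) else NULL
    c(list(grand_total = sum(tab$count)),
      if (!is.null(hs)) list(count_difference = hs$count_difference,
                             count_difference_pct = hs$count_difference_pct,
                             density_difference_mm3 = hs$density_difference_mm3))
  })

  run_stage("homogeneity", function() {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      sp <- split_anterior_posterior(subsets[[i]], regions[[i]],
                                     plane = config$split)
      data.frame(region = groups$region[i], hemisphere = groups$hemisphere[i],
                 n_anterior = sp$anterior$n, n_posterior = sp$posterior$n,
                 v_anterior_mm3 = sp$anterior$volume_mm3,
                 v_posterior_mm3 = sp$posterior$volume_mm3,
                 F = sp$f_test$F, df1 = sp$f_test$df[1],
                 df2 = sp$f_test$df[2], p = sp$f_test$p)
    })
    emit(do.call(rbind, rows), "homogeneity.tsv")
    list()
  })

  run_stage("ripley", function() {
    tstats <- list()
    for (i in seq_len(nrow(groups))) {
      env <- csr_envelope(subsets[[i]], regions[[i]], n_sims = config$n_sims,
                          honor_exclusions = config$honor_exclusions,
                          seed = derive_seed(config$seed, 1000L + i))
      emit(as.data.frame(env), paste0("k_", tag(i), ".tsv"))
      tt <- paired_t_compare(env)
      tstats[[tag(i)]] <- list(t = tt$t, df = tt$df, p = tt$p)
    }
    list(paired_t = tstats)
  })

  run_stage("neighbors", function() {
    for (i in seq_len(nrow(groups))) {
      env <- nn_compare_to_csr(subsets[[i]], regions[[i]],
                               n_sims = config$n_sims, k = config$k,
                               honor_exclusions = config$honor_exclusions,
                               seed = derive_seed(config$seed, 2000L + i))
      emit(as.data.frame(env), paste0("nn_", tag(i), ".tsv"))
    }
    list()
  })

  run_stage("clusters", function() {
    modal <- list()
    for (i in seq_len(nrow(groups))) {
      g <- nn_graph(subsets[[i]])
      df <- data.frame(component_id = seq_along(g$sizes), size = g$sizes,
                       members = vapply(seq_along(g$sizes), function(cid)
                         paste(which(g$membership == cid), collapse = ","),
                         ""))
      emit(df, paste0("clusters_", tag(i), ".tsv"))
      h <- g$histogram
      modal[[tag(i)]] <- as.integer(names(h)[which.max(h)])
    }
    list(modal_cluster_size = modal)
  })

  run_stage("voronoi", function() {
    for (i in seq_len(nrow(groups))) {
      vv <- voronoi_volumes(subsets[[i]], regions[[i]],
                            voxel_size_um = config$voxel_size_um)
      emit(as.data.frame(vv), paste0("voronoi_", tag(i), ".tsv"))
    }
    list()
  })

  run_stage("inhom", function() {
    ps <- list()
    for (i in seq_len(nrow(groups))) {
      rep_i <- inhom_analysis(subsets[[i]], regions[[i]],
                              use_ball_subregion = config$use_ball_subregion,
                              ball_radius_um = config$ball_radius_um,
                              n_null = config$n_null,
                              bandwidth = config$bandwidth,
                              seed = derive_seed(config$seed, 3000L + i))
      df <- data.frame(r_um = rep_i$observed$r_um,
                       k_inhom_obs = rep_i$observed$k_inhom,
                       k_inhom_null_mean = colMeans(rep_i$nulls))
      emit(df, paste0("kinhom_", tag(i), ".tsv"))
      ps[[tag(i)]] <- rep_i$p
    }
    list(rank_p = ps)
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
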