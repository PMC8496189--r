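#' Pipeline configuration
#'
#' Holds every stage parameter with the published defaults: housekeeping
#' percentile 1, minimum counts 2^16, HVG cutoffs 0.3/0.5, 50 PCs, 17 SNN
#' dimensions, Louvain resolution 1.3, tSNE perplexity 70 with seed 132,
#' extreme-slope k 10, TF thresholds 0.10/0.4/0.3/0.05 with top 3 per
#' cluster. A single global `seed` fans out to per-stage seeds through
#' [stage_seed()].
#'
#' @param mode `"synthetic"` (no input paths needed) or `"real_data"`.
#' @param seed global integer seed.
#' @param paths named list of input paths for real-data mode (`matrix_dir`,
#'   `metadata`, `tf_list`).
#' @param sim a [sim_config()] used in synthetic mode; its seed is replaced
#'   by the fanned-out stage seed.
#' @param qc,hvg,pca,snn,louvain,tsne,trajectory,markers,tf,cytometry named
#'   lists of stage parameters (see defaults in the function signature).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real_data"),
                            seed = 1L,
                            paths = list(),
                            sim = sim_config(),
                            qc = list(actb_percentile = 1,
                                      min_total_counts = 65536),
                            hvg = list(mean_cutoff = 0.3,
                                       dispersion_cutoff = 0.5, n_bins = 20),
                            pca = list(n_components = 50),
                            snn = list(dims = 17, k_neighbors = 20,
                                       prune = 1 / 15),
                            louvain = list(resolution = 1.3),
                            tsne = list(dims = 15, perplexity = 70,
                                        seed = 132),
                            trajectory = list(k = 10,
                                              samples_per_segment = 128,
                                              mode = "projection"),
                            markers = list(logfc_threshold = log(2),
                                           min_pct = 0.1),
                            tf = list(min_diff_pct = 0.10, logfc_min = 0.4,
                                      min_pct = 0.3, fdr_max = 0.05,
                                      top_n = 3),
                            cytometry = list(mode_factor = 1.5,
                                             hoechst_n = 10000,
                                             hoechst_s_fraction = 0.012)) {
  cfg <- list(mode = match.arg(mode), seed = as.integer(seed), paths = paths,
              sim = sim, qc = qc, hvg = hvg, pca = pca, snn = snn,
              louvain = louvain, tsne = tsne, trajectory = trajectory,
              markers = markers, tf = tf, cytometry = cytometry)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the argument structure of [pipeline_config()]; unknown keys
#' are an error, flat overrides (e.g. from CLI flags written
#' `qc.min_total_counts`) take precedence.
#'
#' @param path YAML file (optional).
#' @param overrides named list of `section.key = value` overrides.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- pipeline_config()
  known <- setdiff(names(cfg), "sim")
  for (k in names(raw)) {
    if (k == "sim") next
    if (!k %in% known) stop("unknown config key: ", k)
    if (is.list(cfg[[k]]) && is.list(raw[[k]]))
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    else cfg[[k]] <- raw[[k]]
  }
  if (!is.null(raw$sim)) {
    args <- raw$sim
    cfg$sim <- do.call(sim_config, args)
  }
  for (k in names(overrides)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- overrides[[k]]
    else cfg[[parts[1]]][[parts[2]]] <- overrides[[k]]
  }
  cfg$mode <- match.arg(cfg$mode, c("synthetic", "real_data"))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulation (synthetic mode) or loading (real-data mode), QC,
#' normalization, HVG/PCA/SNN/Louvain/tSNE, centroid-anchored pseudotime with
#' gene-trend ranking, cluster markers, the TF correlogram, and the cytometry
#' utilities, writing every artifact plus a `manifest.json` (parameter echo,
#' derived stage seeds, artifact list) and `run.log` to `outdir`. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, a list with the main in-memory results (`qc`,
#'   `clusters`, `pseudotime`, `trends`, `markers`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  cat("", file = logf)
  note <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                            file = logf, append = TRUE)
  stage <- function(name, expr) {
    note("stage:", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  artifacts <- character(0)
  emit <- function(x, name) {
    p <- file.path(outdir, name)
    write_tsv(x, p)
    artifacts <<- c(artifacts, name)
  }

  truth <- NULL
  if (config$mode == "synthetic") {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    inputs <- stage("simulate", {
      s <- simulate_timecourse(sim_cfg)
      plant_qc_failures(s, sim_cfg)
    })
    truth <- inputs$truth
    stage("write_raw", {
      write_count_matrix(inputs$counts, file.path(outdir, "raw_matrix"))
      emit(inputs$metadata, "metadata.tsv")
      emit(truth$cells, "truth_cells.tsv")
      emit(truth$genes, "truth_genes.tsv")
    })
  } else {
    inputs <- stage("load", {
      list(counts = read_count_matrix(config$paths$matrix_dir),
           metadata = read_cell_metadata(config$paths$metadata))
    })
  }

  thresholds <- qc_thresholds(
    actb_percentile = config$qc$actb_percentile,
    min_total_counts = config$qc$min_total_counts)
  qc <- stage("qc", run_qc(inputs$counts, inputs$metadata, thresholds))
  stage("write_qc", {
    emit(qc$report, "qc_report.tsv")
    write_count_matrix(qc$counts, file.path(outdir, "filtered_matrix"))
  })

  hvg <- stage("hvg", select_hvg(qc$expr, config$hvg$mean_cutoff,
                                 config$hvg$dispersion_cutoff,
                                 config$hvg$n_bins))
  if (length(hvg$gene_ids) < 2)
    stop("pipeline stage 'hvg' failed: no highly variable genes selected")
  pca <- stage("pca", scale_and_pca(qc$expr, hvg, config$pca$n_components))
  snn <- stage("snn", build_snn_graph(pca$scores, config$snn$dims,
                                      config$snn$k_neighbors,
                                      config$snn$prune))
  clusters <- stage("louvain",
                    cluster_louvain(snn, config$louvain$resolution,
                                    stage_seed(config$seed, "louvain")))
  coords <- stage("tsne", embed_tsne(pca$scores, config$tsne$dims,
                                     config$tsne$perplexity,
                                     config$tsne$seed))
  stage("write_embedding", {
    emit(data.frame(cell_id = rownames(pca$scores),
                    round(pca$scores, 6), check.names = FALSE),
         "embeddings.tsv")
    emit(data.frame(cell_id = rownames(coords), coords, check.names = FALSE),
         "tsne.tsv")
    emit(data.frame(cell_id = names(clusters$labels),
                    cluster = clusters$labels), "clusters.tsv")
  })

  # trajectory scope: clusters whose majority membership is the trajectory
  traj_cells <- if (!is.null(truth)) {
    tc <- truth$cells$cell_id[truth$cells$population_label == "trajectory"]
    by_cl <- split(names(clusters$labels), clusters$labels)
    traj_cl <- names(Filter(function(ids) mean(ids %in% tc) > 0.5,
                            stats::setNames(by_cl, names(by_cl))))
    names(clusters$labels)[as.character(clusters$labels) %in% traj_cl]
  } else if (!is.null(config$trajectory$clusters)) {
    names(clusters$labels)[clusters$labels %in% config$trajectory$clusters]
  } else names(clusters$labels)

  traj <- stage("trajectory", {
    # subset re-analysis: the trajectory compartment is re-embedded on its
    # own (HVG -> PCA -> tSNE with the same published parameters) before
    # centroids are placed, the standard workflow for subset analyses
    sub_expr <- qc$expr[, traj_cells, drop = FALSE]
    sub_hvg <- suppressWarnings(select_hvg(sub_expr, config$hvg$mean_cutoff,
                                           config$hvg$dispersion_cutoff,
                                           config$hvg$n_bins))
    sub_pca <- scale_and_pca(sub_expr, sub_hvg, config$pca$n_components)
    sub_coords <- embed_tsne(sub_pca$scores, config$tsne$dims,
                             config$tsne$perplexity, config$tsne$seed)
    cc <- compute_condition_centroids(sub_coords, qc$metadata)
    curve <- fit_principal_curve(cc, config$trajectory$samples_per_segment)
    pt <- project_pseudotime(sub_coords, curve, cc,
                             mode = config$trajectory$mode)
    trends <- fit_gene_trends(qc$expr[, pt$cell_id, drop = FALSE],
                              stats::setNames(pt$pseudotime, pt$cell_id))
    extremes <- select_extreme_slope_genes(trends, config$trajectory$k)
    heat_genes <- c(extremes$up, extremes$down)
    ord_cells <- pt$cell_id[order(pt$pseudotime)]
    heat <- qc$expr[heat_genes, ord_cells, drop = FALSE]
    heat <- heat[order_genes_hierarchically(heat), , drop = FALSE]
    list(centroids = cc, curve = curve, pseudotime = pt, trends = trends,
         extremes = extremes, heatmap = heat)
  })
  stage("write_trajectory", {
    emit(traj$centroids, "centroids.tsv")
    emit(traj$pseudotime, "pseudotime.tsv")
    emit(traj$trends, "gene_trends.tsv")
    emit(data.frame(gene_id = rownames(traj$heatmap),
                    round(traj$heatmap, 6), check.names = FALSE),
         "heatmap_matrix.tsv")
  })

  markers <- stage("markers",
                   find_cluster_markers(qc$expr, clusters$labels,
                                        config$markers$logfc_threshold,
                                        config$markers$min_pct))
  stage("write_markers", emit(markers, "markers.tsv"))

  tf_list <- if (config$mode == "synthetic") {
    stats::na.omit(truth$genes$gene_id[!is.na(truth$genes$archetype)])
  } else if (!is.null(config$paths$tf_list)) {
    readLines(config$paths$tf_list)
  } else character(0)
  if (length(tf_list)) {
    tfm <- stage("tf_correlogram", {
      tf_markers <- find_cluster_markers(qc$expr, clusters$labels,
                                         logfc_threshold = config$tf$logfc_min,
                                         min_pct = 0,
                                         min_diff_pct = config$tf$min_diff_pct,
                                         min_pct_in = config$tf$min_pct)
      suppressWarnings(
        select_tf_correlogram(tf_markers, tf_list, qc$expr,
                              config$tf$min_diff_pct, config$tf$logfc_min,
                              config$tf$min_pct, config$tf$fdr_max,
                              config$tf$top_n))
    })
    stage("write_tf", {
      utils::write.csv(as.data.frame(tfm$correlation),
                       file.path(outdir, "tf_correlogram.csv"))
      artifacts <- c(artifacts, "tf_correlogram.csv")
      emit(tfm$tf_map, "tf_map.tsv")
    })
  }

  if (config$mode == "synthetic") {
    stage("cytometry", {
      isc <- index_sort_config(seed = stage_seed(config$seed, "indexsort"))
      events <- simulate_index_sort(inputs$metadata, isc)
      norm <- normalize_index_sort(events,
                                   channels = names(isc$channels))
      seq_cells <- qc$metadata[, c("cell_id", "plate_id", "well")]
      tb <- facs_traceback(norm, seq_cells, clusters$labels)
      emit(tb[, c("event_id", "CD45", "BSC-A", "label")],
           "facs_traceback.tsv")
      hs <- simulate_hoechst(config$cytometry$hoechst_n,
                             config$cytometry$hoechst_s_fraction,
                             seed = stage_seed(config$seed, "hoechst"))
      pr <- estimate_s_phase_fraction(hs$values,
                                      config$cytometry$mode_factor,
                                      group = "CD45low")
      emit(data.frame(group = pr$group, mode = pr$mode,
                      threshold = pr$threshold,
                      fraction_s_phase = pr$fraction_s_phase),
           "s_phase.tsv")
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sctimecourse")),
    mode = config$mode, seed = config$seed,
    stage_seeds = list(simulate = stage_seed(config$seed, "simulate"),
                       louvain = stage_seed(config$seed, "louvain"),
                       indexsort = stage_seed(config$seed, "indexsort"),
                       hoechst = stage_seed(config$seed, "hoechst"),
                       tsne = config$tsne$seed),
    parameters = config[setdiff(names(config), c("sim", "paths"))],
    config_hash = sum(utf8ToInt(paste(deparse(config[names(config) != "paths"]),
                                      collapse = ""))),
    artifacts = c(artifacts, "raw_matrix/", "filtered_matrix/"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  note("done")
  invisible(list(qc = qc, hvg = hvg, pca = pca, clusters = clusters,
                 coords = coords, trajectory = traj, markers = markers,
                 truth = truth, manifest = manifest))
}
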