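# Shared fixtures: built in code, cached per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, expr, envir = fixture_env)
  get(key, envir = fixture_env)
}

# small, fast world: 6 conditions x 35 cells, 2 archetypes, 500 genes
small_cfg <- function(seed = 7L, ...) {
  defaults <- list(n_conditions = 6L, cells_per_condition = 35L,
                   n_genes = 500L, n_spikeins = 20L,
                   off_trajectory_populations = 2L, cells_per_archetype = 35L,
                   signature_genes_per_archetype = 10L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() memo("small_sim", {
  cfg <- small_cfg()
  plant_qc_failures(simulate_timecourse(cfg), cfg)
})

small_pipeline_cfg <- function(seed = 3L) {
  pipeline_config(
    mode = "synthetic", seed = seed, sim = small_cfg(),
    snn = list(dims = 10, k_neighbors = 15, prune = 1 / 15),
    tsne = list(dims = 10, perplexity = 25, seed = 132),
    cytometry = list(mode_factor = 1.5, hoechst_n = 2000,
                     hoechst_s_fraction = 0.012))
}

small_pipeline_run <- function() memo("small_pipeline_run", {
  out <- file.path(tempdir(), "sctc_small_run")
  res <- suppressWarnings(run_pipeline(small_pipeline_cfg(), out))
  list(res = res, outdir = out)
})

# default-config pipeline replicates shared by the acceptance criteria
acceptance_runs <- function(n_seeds = 5L) memo("acceptance_runs", {
  lapply(seq_len(n_seeds), function(s) {
    out <- file.path(tempdir(), sprintf("sctc_acc_%d", s))
    suppressWarnings(run_pipeline(pipeline_config(seed = s), out))
  })
})

# toy count matrix with dimnames
toy_counts <- function(nr = 5, nc = 3, seed = 1, max = 50) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, max), nr, nc,
              dimnames = list(sprintf("g%02d", seq_len(nr)),
                              sprintf("P01:%s", well_ids(nc))))
  storage.mode(m) <- "integer"
  m
}

well_ids <- function(n) sprintf("%s%02d", LETTERS[(seq_len(n) - 1) %% 16 + 1],
                                (seq_len(n) - 1) %/% 16 + 1)

toy_metadata <- function(cell_ids, well_type = "single_cell",
                         condition = "C01", time_order = 1L) {
  data.frame(cell_id = cell_ids,
             plate_id = sub(":.*", "", cell_ids),
             well = sub(".*:", "", cell_ids),
             condition = condition, condition_time_order = time_order,
             well_type = well_type, sort_gate = "CD45+",
             stringsAsFactors = FALSE)
}

# merge predicted clusters by majority truth label, then score ARI
majority_merged_ari <- function(labels, truth_labels) {
  tl <- truth_labels[names(labels)]
  maj <- tapply(tl, labels, function(x) names(which.max(table(x))))
  adjusted_rand_index(unname(maj[as.character(labels)]), tl)
}
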