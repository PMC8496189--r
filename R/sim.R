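#' Configuration for the synthetic time-course generator
#'
#' Describes a plate-based single-cell RNA-seq time course with a latent
#' one-dimensional trajectory (emulating microglia transforming after spinal
#' cord injury), discrete off-trajectory immune populations, ERCC spike-ins, a
#' high-expression housekeeping gene literally named `"Actb"`, and planted
#' quality-control failures. Defaults emulate Smart-Seq2 depth (median library
#' size around 6e5 counts/cell) and a 12-condition design with 150 cells per
#' condition.
#'
#' @param n_conditions number of time-course conditions (default 12).
#' @param condition_times strictly increasing latent time per condition in
#'   `[0, 1]`; default equally spaced.
#' @param cells_per_condition trajectory cells sorted per condition plate.
#' @param n_genes number of biological genes including the housekeeping gene.
#' @param n_spikeins number of `ERCC-` spike-in rows (default 92).
#' @param n_monotone_up,n_monotone_down,n_transient planted program sizes.
#' @param effect_size |slope| of planted programs, log2 units per unit latent
#'   time (default 2).
#' @param libsize_log_mean,libsize_log_sd lognormal library-size parameters
#'   (defaults `log(6e5)` and 0.5).
#' @param dropout_midpoint,dropout_steepness logistic dropout on expected
#'   log2(CPM+1): keep probability `plogis(steepness * (log2cpm - midpoint))`.
#' @param frac_low_count,frac_low_actb planted QC-failure fractions; defaults
#'   follow the observed plate-accounting rates (888/4734 and 159/4734).
#' @param off_trajectory_populations number of discrete non-trajectory
#'   archetypes (default 3).
#' @param cells_per_archetype cells per off-trajectory archetype.
#' @param signature_genes_per_archetype planted archetype signature genes.
#' @param s_phase_fraction fraction of cells labelled S-phase in the truth
#'   record (default 0.012, the low proliferation regime of injured cord).
#' @param dispersion_log_median,dispersion_log_sd lognormal negative-binomial
#'   dispersion across genes (median 0.3 by default).
#' @param transient_width Gaussian bump width of transient programs in latent
#'   time units (default 0.15).
#' @param controls_per_plate integer vector `c(bulk = , empty = )` control
#'   wells added per plate.
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_conditions = 12L,
                       condition_times = NULL,
                       cells_per_condition = 150L,
                       n_genes = 2000L,
                       n_spikeins = 92L,
                       n_monotone_up = 10L,
                       n_monotone_down = 10L,
                       n_transient = 10L,
                       effect_size = 2,
                       libsize_log_mean = log(6e5),
                       libsize_log_sd = 0.5,
                       dropout_midpoint = 1,
                       dropout_steepness = 1,
                       frac_low_count = 0.19,
                       frac_low_actb = 0.034,
                       off_trajectory_populations = 3L,
                       cells_per_archetype = 150L,
                       signature_genes_per_archetype = 15L,
                       s_phase_fraction = 0.012,
                       dispersion_log_median = log(0.3),
                       dispersion_log_sd = 0.5,
                       transient_width = 0.15,
                       controls_per_plate = c(bulk = 1L, empty = 1L),
                       seed = 1L) {
  if (is.null(condition_times))
    condition_times <- seq(0, 1, length.out = n_conditions)
  cfg <- list(
    n_conditions = as.integer(n_conditions),
    condition_times = as.numeric(condition_times),
    cells_per_condition = as.integer(cells_per_condition),
    n_genes = as.integer(n_genes), n_spikeins = as.integer(n_spikeins),
    n_monotone_up = as.integer(n_monotone_up),
    n_monotone_down = as.integer(n_monotone_down),
    n_transient = as.integer(n_transient),
    effect_size = effect_size,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    dropout_midpoint = dropout_midpoint,
    dropout_steepness = dropout_steepness,
    frac_low_count = frac_low_count, frac_low_actb = frac_low_actb,
    off_trajectory_populations = as.integer(off_trajectory_populations),
    cells_per_archetype = as.integer(cells_per_archetype),
    signature_genes_per_archetype = as.integer(signature_genes_per_archetype),
    s_phase_fraction = s_phase_fraction,
    dispersion_log_median = dispersion_log_median,
    dispersion_log_sd = dispersion_log_sd,
    transient_width = transient_width,
    controls_per_plate = controls_per_plate,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$condition_times) != cfg$n_conditions)
    stop("condition_times must have one entry per condition")
  if (cfg$n_conditions > 1 && any(diff(cfg$condition_times) <= 0))
    stop("condition_times must be strictly increasing")
  fr <- c(cfg$frac_low_count, cfg$frac_low_actb, cfg$s_phase_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_low_count + cfg$frac_low_actb >= 1)
    stop("frac_low_count + frac_low_actb must be < 1")
  if (any(c(cfg$n_conditions, cfg$n_genes, cfg$n_spikeins) < 1))
    stop("counts must be positive")
  if (cfg$cells_per_condition < 0 || cfg$cells_per_archetype < 0)
    stop("cell counts must be nonnegative")
  planted <- cfg$n_monotone_up + cfg$n_monotone_down + cfg$n_transient +
    cfg$off_trajectory_populations * cfg$signature_genes_per_archetype
  if (cfg$n_genes < planted + 1)
    stop("n_genes must exceed the total number of planted program genes")
  invisible(cfg)
}

well_names <- function(i) {
  # 384-well plate order: A01..P01, A02..P02, ...
  sprintf("%s%02d", LETTERS[(i - 1L) %% 16L + 1L], (i - 1L) %/% 16L + 1L)
}

#' Simulate a plate-based single-cell time course with ground truth
#'
#' Draws negative-binomial counts with gene-wise mean `2^(a_g + b_g * tau_i
#' [+ bump_g(tau_i)])` rescaled to each cell's lognormal library size, thins
#' them with logistic dropout, and emits plate/well metadata plus a
#' machine-readable truth record (latent times, planted programs, archetype
#' signatures, planted QC flags and S-phase labels). Spike-ins and the
#' housekeeping gene are constant in latent time; off-trajectory archetypes
#' use time-independent means with boosted signature genes. Control wells
#' (bulk and empty) are appended per plate so the control-exclusion rule can
#' be exercised.
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` (genes x cells integer matrix, cell
#'   ids formatted `PLATE:WELL`), `metadata` (one row per cell), and `truth`
#'   (list with `cells`, `genes`, `condition_times`).
#' @export
simulate_timecourse <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    G <- cfg$n_genes + cfg$n_spikeins
    gene_ids <- c(sprintf("G%04d", seq_len(cfg$n_genes - 1L)), "Actb",
                  if (cfg$n_spikeins > 0) sprintf("ERCC-%05d", seq_len(cfg$n_spikeins)))
    actb_row <- cfg$n_genes
    spike_rows <- if (cfg$n_spikeins > 0) cfg$n_genes + seq_len(cfg$n_spikeins) else integer(0)

    # gene-level parameters
    a_bg <- stats::rnorm(cfg$n_genes - 1L, mean = 2, sd = 2.2)
    a_actb <- 12
    a_spike <- stats::rnorm(cfg$n_spikeins, mean = 5, sd = 1)
    base_log2 <- c(a_bg, a_actb, a_spike)
    phi <- stats::rlnorm(G, cfg$dispersion_log_median, cfg$dispersion_log_sd)

    pool <- sample(seq_len(cfg$n_genes - 1L))
    take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
    idx_up <- take(cfg$n_monotone_up)
    idx_down <- take(cfg$n_monotone_down)
    idx_tr <- take(cfg$n_transient)
    idx_sig <- lapply(seq_len(cfg$off_trajectory_populations),
                      function(k) take(cfg$signature_genes_per_archetype))
    base_log2[idx_up] <- stats::rnorm(length(idx_up), 4, 0.75)
    base_log2[idx_down] <- stats::rnorm(length(idx_down), 4, 0.75)
    base_log2[idx_tr] <- stats::rnorm(length(idx_tr), 3.5, 0.75)

    program <- rep("background", G)
    program[idx_up] <- "monotone_up"
    program[idx_down] <- "monotone_down"
    program[idx_tr] <- "transient"
    program[actb_row] <- "housekeeping"
    program[spike_rows] <- "spikein"
    slope_sign <- rep(0L, G)
    slope_sign[idx_up] <- 1L
    slope_sign[idx_down] <- -1L
    if (cfg$effect_size == 0) slope_sign[] <- 0L
    archetype <- rep(NA_character_, G)
    for (k in seq_along(idx_sig)) archetype[idx_sig[[k]]] <- sprintf("archetype%d", k)
    genes_truth <- data.frame(gene_id = gene_ids, program = program,
                              true_slope_sign = slope_sign, archetype = archetype,
                              stringsAsFactors = FALSE)

    # cell layout: per condition plate, trajectory cells then archetype cells
    n_traj <- cfg$n_conditions * cfg$cells_per_condition
    n_arch <- cfg$off_trajectory_populations * cfg$cells_per_archetype
    cond_of_traj <- rep(seq_len(cfg$n_conditions), each = cfg$cells_per_condition)
    pop_of_arch <- rep(seq_len(cfg$off_trajectory_populations),
                       each = cfg$cells_per_archetype)
    cond_of_arch <- if (n_arch > 0)
      ((seq_len(n_arch) - 1L) %% cfg$n_conditions) + 1L else integer(0)
    cond <- c(cond_of_traj, cond_of_arch)
    pop_label <- c(rep("trajectory", n_traj),
                   if (n_arch > 0) sprintf("archetype%d", pop_of_arch))
    n_cells <- n_traj + n_arch

    if (n_cells == 0) {
      counts <- matrix(0L, nrow = G, ncol = 0,
                       dimnames = list(gene_ids, character(0)))
      md <- data.frame(cell_id = character(0), plate_id = character(0),
                       well = character(0), condition = character(0),
                       condition_time_order = integer(0),
                       well_type = character(0), sort_gate = character(0),
                       stringsAsFactors = FALSE)
      truth <- list(cells = data.frame(cell_id = character(0),
                                       latent_time = numeric(0),
                                       population_label = character(0),
                                       is_low_count = logical(0),
                                       is_low_actb = logical(0),
                                       s_phase = logical(0),
                                       library_size = numeric(0),
                                       stringsAsFactors = FALSE),
                    genes = genes_truth, condition_times = cfg$condition_times)
      return(list(counts = counts, metadata = md, truth = truth))
    }

    # order cells by condition so wells fill plate-wise
    ord <- order(cond, seq_len(n_cells))
    cond <- cond[ord]
    pop_label <- pop_label[ord]
    plate <- sprintf("P%02d", cond)
    well_idx <- stats::ave(seq_len(n_cells), cond, FUN = seq_along)
    well <- well_names(well_idx)
    cell_id <- paste0(plate, ":", well)
    cond_name <- sprintf("C%02d", cond)

    # latent time: condition time plus bounded uniform jitter
    half_gap <- if (cfg$n_conditions > 1) min(diff(cfg$condition_times)) / 2 else 0.5
    tau <- cfg$condition_times[cond] +
      stats::runif(n_cells, -half_gap, half_gap) * 0.9
    tau <- pmin(pmax(tau, 0), 1)

    # log2 relative expression matrix
    A <- matrix(base_log2, nrow = G, ncol = n_cells)
    is_traj <- pop_label == "trajectory"
    tc <- tau[is_traj] - 0.5
    if (any(is_traj) && cfg$effect_size != 0) {
      A[idx_up, is_traj] <- A[idx_up, is_traj] +
        cfg$effect_size * matrix(tc, length(idx_up), sum(is_traj), byrow = TRUE)
      A[idx_down, is_traj] <- A[idx_down, is_traj] -
        cfg$effect_size * matrix(tc, length(idx_down), sum(is_traj), byrow = TRUE)
      bump <- cfg$effect_size *
        exp(-(tc)^2 / (2 * cfg$transient_width^2))
      A[idx_tr, is_traj] <- A[idx_tr, is_traj] +
        matrix(bump, length(idx_tr), sum(is_traj), byrow = TRUE)
    }
    for (k in seq_along(idx_sig)) {
      sel <- pop_label == sprintf("archetype%d", k)
      if (any(sel)) A[idx_sig[[k]], sel] <- A[idx_sig[[k]], sel] + 4
    }

    libsize <- stats::rlnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd)
    W <- 2^A
    P <- sweep(W, 2, colSums(W), "/")
    mu <- sweep(P, 2, libsize, "*")
    counts <- matrix(stats::rnbinom(G * n_cells, mu = mu,
                                    size = rep(1 / phi, times = n_cells)),
                     nrow = G)
    pre_drop_libsize <- colSums(counts)
    log2cpm_mu <- log2(P * 1e6 + 1)
    p_keep <- stats::plogis(cfg$dropout_steepness * (log2cpm_mu - cfg$dropout_midpoint))
    keep <- matrix(stats::rbinom(G * n_cells, 1L, p_keep), nrow = G)
    counts <- counts * keep
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(gene_ids, cell_id)

    md <- data.frame(cell_id = cell_id, plate_id = plate, well = well,
                     condition = cond_name, condition_time_order = cond,
                     well_type = "single_cell", sort_gate = "CD45+",
                     stringsAsFactors = FALSE)
    s_phase <- stats::rbinom(n_cells, 1L, cfg$s_phase_fraction) == 1L
    cells_truth <- data.frame(cell_id = cell_id, latent_time = tau,
                              population_label = pop_label,
                              is_low_count = FALSE, is_low_actb = FALSE,
                              s_phase = s_phase,
                              library_size = as.numeric(pre_drop_libsize),
                              stringsAsFactors = FALSE)

    # control wells: 1 bulk (deep, many-cell pool) + 1 empty per plate
    nb <- as.integer(cfg$controls_per_plate[["bulk"]])
    ne <- as.integer(cfg$controls_per_plate[["empty"]])
    if (nb + ne > 0) {
      ctl_counts <- NULL; ctl_md <- NULL
      for (p in unique(plate)) {
        on_plate <- which(plate == p)
        base_mu <- rowMeans(mu[, on_plate, drop = FALSE])
        nxt <- max(well_idx[on_plate])
        add_col <- function(x, w, type) {
          id <- paste0(p, ":", w)
          ctl_counts <<- cbind(ctl_counts, matrix(x, ncol = 1,
                                                  dimnames = list(NULL, id)))
          ctl_md <<- rbind(ctl_md, data.frame(
            cell_id = id, plate_id = p, well = w,
            condition = cond_name[on_plate[1]],
            condition_time_order = cond[on_plate[1]],
            well_type = type, sort_gate = "CD45+", stringsAsFactors = FALSE))
        }
        for (b in seq_len(nb)) {
          nxt <- nxt + 1L
          add_col(stats::rpois(G, base_mu * 20), well_names(nxt), "bulk_control")
        }
        for (e in seq_len(ne)) {
          nxt <- nxt + 1L
          add_col(stats::rpois(G, 0.005), well_names(nxt), "empty_control")
        }
      }
      storage.mode(ctl_counts) <- "integer"
      rownames(ctl_counts) <- gene_ids
      counts <- cbind(counts, ctl_counts)
      md <- rbind(md, ctl_md)
      ctl_truth <- data.frame(cell_id = ctl_md$cell_id,
                              latent_time = cfg$condition_times[ctl_md$condition_time_order],
                              population_label = "control",
                              is_low_count = FALSE, is_low_actb = FALSE,
                              s_phase = FALSE,
                              library_size = as.numeric(colSums(ctl_counts)),
                              stringsAsFactors = FALSE)
      cells_truth <- rbind(cells_truth, ctl_truth)
    }

    list(counts = counts, metadata = md,
         truth = list(cells = cells_truth, genes = genes_truth,
                      condition_times = cfg$condition_times))
  })
}

#' Plant quality-control failures into a simulated matrix
#'
#' A fraction `frac_low_count` of single-cell wells is downscaled (integer
#' floor-thinning) so their total counts fall strictly below 2^16; a disjoint
#' fraction `frac_low_actb` has the housekeeping gene zeroed so its log2-CPM
#' falls below the dataset-wide 1st percentile. Truth flags are updated so the
#' planted sets can be compared against the QC filters.
#'
#' @param sim result of [simulate_timecourse()].
#' @param config the [sim_config()] that produced `sim` (supplies the
#'   fractions and seed).
#' @return `sim` with modified `counts` and updated `truth$cells` flags.
#' @export
plant_qc_failures <- function(sim, config) {
  validate_sim_config(config)
  if (config$frac_low_count + config$frac_low_actb >= 1)
    stop("frac_low_count + frac_low_actb must be < 1")
  counts <- sim$counts
  truth <- sim$truth
  sc <- sim$metadata$cell_id[sim$metadata$well_type == "single_cell"]
  n_sc <- length(sc)
  n_low <- round(config$frac_low_count * n_sc)
  n_actb <- round(config$frac_low_actb * n_sc)
  if (n_low + n_actb > n_sc) stop("planted fractions exceed available cells")
  if (n_low + n_actb == 0) return(sim)
  with_seed(stage_seed(config$seed, "plant_qc"), {
    picks <- sample(sc, n_low + n_actb)
    low_cells <- picks[seq_len(n_low)]
    actb_cells <- picks[n_low + seq_len(n_actb)]
    for (id in low_cells) {
      target <- stats::runif(1, 20000, 60000)
      tot <- sum(counts[, id])
      if (tot > target) counts[, id] <- as.integer(floor(counts[, id] * target / tot))
    }
    if (n_actb > 0) counts["Actb", actb_cells] <- 0L
    truth$cells$is_low_count <- truth$cells$cell_id %in% low_cells
    truth$cells$is_low_actb <- truth$cells$cell_id %in% actb_cells
  })
  sim$counts <- counts
  sim$truth <- truth
  sim
}

#' Configuration for the index-sort simulator
#'
#' @param channels named numeric vector of per-channel log base intensities.
#' @param cell_sd lognormal spread of per-event intensities.
#' @param plate_shift_sd,plate_scale_sd per-plate affine distortions
#'   (additive shift in raw units, multiplicative lognormal scale) emulating
#'   voltage differences between sorting sessions; set both to 0 for identical
#'   channel distributions across plates.
#' @param n_background analyzed-but-unsorted events (no plate/well).
#' @param seed integer RNG seed.
#' @return a list of class `index_sort_config`.
#' @export
index_sort_config <- function(channels = c(CD45 = log(500), CD11b = log(800),
                                           CD14 = log(300), CD64 = log(250),
                                           `BSC-A` = log(2000),
                                           Hoechst = log(1000)),
                              cell_sd = 0.4,
                              plate_shift_sd = 100,
                              plate_scale_sd = 0.1,
                              n_background = 1000L,
                              seed = 1L) {
  structure(list(channels = channels, cell_sd = cell_sd,
                 plate_shift_sd = plate_shift_sd,
                 plate_scale_sd = plate_scale_sd,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "index_sort_config")
}

#' Simulate per-plate index-sort fluorescence tables
#'
#' One sorted event per single-cell well plus a pool of analyzed-but-unsorted
#' background events. Each plate applies its own affine distortion per channel
#' (scale then shift), emulating voltage differences between sorting sessions.
#'
#' @param metadata cell metadata from [simulate_timecourse()].
#' @param config an [index_sort_config()].
#' @return a data.frame with `event_id`, `plate_id`, `well`, `sequenced`,
#'   `cell_id` and one numeric column per channel.
#' @export
simulate_index_sort <- function(metadata, config = index_sort_config()) {
  stopifnot(inherits(config, "index_sort_config"))
  md <- metadata[metadata$well_type == "single_cell", , drop = FALSE]
  with_seed(config$seed, {
    plates <- unique(md$plate_id)
    shifts <- matrix(stats::rnorm(length(plates) * length(config$channels),
                                  0, config$plate_shift_sd),
                     nrow = length(plates),
                     dimnames = list(plates, names(config$channels)))
    scales <- matrix(stats::rlnorm(length(plates) * length(config$channels),
                                   0, config$plate_scale_sd),
                     nrow = length(plates),
                     dimnames = list(plates, names(config$channels)))
    draw <- function(n) {
      vapply(names(config$channels), function(ch)
        exp(stats::rnorm(n, config$channels[[ch]], config$cell_sd)),
        numeric(n))
    }
    sorted <- as.data.frame(draw(nrow(md)))
    names(sorted) <- names(config$channels)
    for (ch in names(config$channels))
      sorted[[ch]] <- sorted[[ch]] * scales[md$plate_id, ch] +
        shifts[md$plate_id, ch]
    sorted <- cbind(data.frame(event_id = sprintf("EV%06d", seq_len(nrow(md))),
                               plate_id = md$plate_id, well = md$well,
                               sequenced = TRUE, cell_id = md$cell_id,
                               stringsAsFactors = FALSE),
                    sorted)
    if (config$n_background > 0) {
      bg <- as.data.frame(draw(config$n_background))
      names(bg) <- names(config$channels)
      bg <- cbind(data.frame(
        event_id = sprintf("BG%06d", seq_len(config$n_background)),
        plate_id = NA_character_, well = NA_character_,
        sequenced = FALSE, cell_id = NA_character_,
        stringsAsFactors = FALSE), bg)
      sorted <- rbind(sorted, bg)
    }
    rownames(sorted) <- NULL
    sorted
  })
}

#' Simulate a Hoechst DNA-content intensity vector
#'
#' G0/G1 events are lognormal around the primary mode `mode`; S/G2-M events
#' sit at 1.6-2 times the mode (DNA content between 2n and 4n) with the same
#' coefficient of variation. Exactly `round(n * s_fraction)` events are
#' labelled S-phase.
#'
#' @param n number of events.
#' @param s_fraction fraction of S/G2-M events in `[0, 1]`.
#' @param cv lognormal coefficient of variation of the stain.
#' @param seed integer RNG seed.
#' @param mode raw-intensity location of the G0/G1 peak.
#' @return list with numeric `values` and character `labels`
#'   (`"G0G1"`/`"S"`), in shuffled event order.
#' @export
simulate_hoechst <- function(n, s_fraction = 0.1, cv = 0.05, seed = 1L,
                             mode = 1000) {
  stopifnot(s_fraction >= 0, s_fraction <= 1, n >= 0)
  with_seed(seed, {
    n_s <- round(n * s_fraction)
    n_g <- n - n_s
    g1 <- mode * stats::rlnorm(n_g, 0, cv)
    s <- mode * stats::runif(n_s, 1.6, 2) * stats::rlnorm(n_s, 0, cv)
    values <- c(g1, s)
    labels <- c(rep("G0G1", n_g), rep("S", n_s))
    ord <- sample.int(n)
    list(values = values[ord], labels = labels[ord])
  })
}
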