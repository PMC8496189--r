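#' Normalize index-sort fluorescence per plate and channel
#'
#' For every plate/channel the values are mapped to the unit scale with a
#' percentile min-max: `v' = clip((v - q01) / (q99 - q01), 0, 1)` using the
#' 1st and 99th percentiles (robust to the single-event outliers typical of
#' cytometry exports). A constant channel maps to 0 with a warning. Events
#' without a plate id (analyzed but unsorted) form their own normalization
#' group.
#'
#' @param table data.frame with `plate_id` and numeric channel columns.
#' @param channels channel column names; defaults to every numeric column
#'   except `sequenced`.
#' @return the table with channels replaced by their unit-scaled values.
#' @export
normalize_index_sort <- function(table, channels = NULL) {
  if (is.null(channels)) {
    num <- vapply(table, is.numeric, logical(1))
    channels <- setdiff(names(table)[num], c("sequenced"))
  }
  missing_ch <- setdiff(channels, names(table))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  grp <- ifelse(is.na(table$plate_id), "(unsorted)", table$plate_id)
  for (p in unique(grp)) {
    rows <- grp == p
    for (ch in channels) {
      v <- table[[ch]][rows]
      if (anyNA(v)) stop("missing values in plate ", p, " channel ", ch)
      q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
      if (q[2] == q[1]) {
        warning("constant channel ", ch, " on plate ", p, ": mapped to 0")
        table[[ch]][rows] <- 0
      } else {
        table[[ch]][rows] <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
      }
    }
  }
  table
}

#' FACS trace-back: annotate analyzed events with transcriptomic labels
#'
#' Every analyzed event is retained; events whose (plate, well) matches a
#' sequenced cell are joined to that cell's cluster / cell-type label, ready
#' for a CD45-versus-back-scatter scatter export. Sequenced cells with no
#' matching event are listed in the `unmatched` attribute rather than dropped
#' silently; duplicated (plate, well) keys among events are an error.
#'
#' @param events index-sort table with `plate_id` and `well`.
#' @param sequenced_cells data.frame with `cell_id`, `plate_id`, `well`.
#' @param cluster_labels vector of labels named by `cell_id`.
#' @return `events` with `cell_id` and `label` columns appended;
#'   `attr(, "unmatched")` holds ids of sequenced cells without an event.
#' @export
facs_traceback <- function(events, sequenced_cells, cluster_labels) {
  key_ev <- ifelse(is.na(events$plate_id), NA_character_,
                   paste(events$plate_id, events$well, sep = ":"))
  key_sc <- paste(sequenced_cells$plate_id, sequenced_cells$well, sep = ":")
  dup <- key_ev[!is.na(key_ev) & key_ev %in% key_sc]
  dup <- dup[duplicated(dup)]
  if (length(dup))
    stop("ambiguous join: duplicate (plate, well) events: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  hit <- match(key_ev, key_sc)
  events$cell_id <- sequenced_cells$cell_id[hit]
  lab <- rep(NA_character_, nrow(events))
  got <- !is.na(events$cell_id)
  lab[got] <- as.character(cluster_labels[events$cell_id[got]])
  events$label <- lab
  attr(events, "unmatched") <-
    sequenced_cells$cell_id[!key_sc %in% key_ev]
  events
}

#' Estimate the S-phase fraction from a Hoechst intensity vector
#'
#' The primary G0/G1 mode is located by kernel density estimation; events
#' with intensity strictly above `mode_factor` times the mode (DNA content
#' beyond ~3n for the default 1.5) are called S/G2-M. If a secondary density
#' mode comes within 5% of the primary's height the mode is ambiguous: a
#' warning is raised and the higher-density mode is used. The estimate is
#' scale-free: multiplying all intensities by a positive constant leaves the
#' fraction unchanged.
#'
#' @param hoechst_values numeric vector of >= 100 events.
#' @param mode_factor threshold multiple of the primary mode (default 1.5).
#' @param group optional group label carried into the result.
#' @return list of class `proliferation_result` with `group`, `mode`,
#'   `threshold`, `fraction_s_phase`.
#' @export
estimate_s_phase_fraction <- function(hoechst_values, mode_factor = 1.5,
                                      group = NA_character_) {
  if (length(hoechst_values) < 100) stop("need at least 100 events")
  d <- stats::density(hoechst_values, n = 1024)
  is_peak <- c(FALSE, diff(sign(diff(d$y))) < 0, FALSE)
  peaks <- which(is_peak)
  if (length(peaks) == 0) peaks <- which.max(d$y)
  heights <- d$y[peaks]
  best <- peaks[which.max(heights)]
  # competing modes must be genuinely distinct peaks (kernel ripple on one
  # physical peak is not): require > 20% separation in intensity
  distinct <- abs(d$x[peaks] - d$x[best]) > 0.2 * abs(d$x[best])
  if (any(distinct) && max(heights[distinct]) >= 0.95 * max(heights))
    warning("ambiguous primary mode (two modes within 5% density); ",
            "using the larger")
  m <- d$x[best]
  thr <- mode_factor * m
  structure(list(group = group, mode = m, threshold = thr,
                 fraction_s_phase = mean(hoechst_values > thr)),
            class = "proliferation_result")
}
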