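#' Clustering parameters for cross-sample peak matching
#'
#' Two peaks in different samples are considered the same peptide when their
#' mass deviation is within 50 ppm for small peptides (< 4,000 Da) or 75 ppm
#' for larger ones, and their migration times fall within a cluster window
#' whose full width grows linearly with migration time from 2% of the time
#' at 19 min to 5% at 45 min (CE peak widths increase with migration time
#' through analyte diffusion). Clusters detected in fewer than
#' `min_group_detections` samples of every group are treated as sporadic and
#' removed by [filter_sporadic()].
#'
#' @param ppm_small,ppm_large Mass tolerances (ppm) below/above
#'   `small_mass_limit`.
#' @param small_mass_limit Mass (Da) separating the two ppm regimes; the
#'   small regime is strict (`mass < small_mass_limit`).
#' @param width_lo,width_hi Full window width as a fraction of migration
#'   time at `time_lo` and `time_hi`; linearly interpolated and clamped
#'   outside.
#' @param time_lo,time_hi Electropherogram range (min) for the width
#'   interpolation.
#' @param min_group_detections Minimum detections in at least one group for
#'   a cluster to be kept ("detected in more than 6 samples" reads as >= 7).
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(ppm_small = 50, ppm_large = 75,
                              small_mass_limit = 4000,
                              width_lo = 0.02, width_hi = 0.05,
                              time_lo = 19, time_hi = 45,
                              min_group_detections = 7) {
  check_positive(c(ppm_small, ppm_large), "ppm_small/ppm_large")
  if (!(width_lo > 0 && width_lo <= width_hi)) {
    stop_field("width_lo/width_hi", "need 0 < width_lo <= width_hi")
  }
  if (time_lo >= time_hi) stop_field("time_lo/time_hi", "need time_lo < time_hi")
  check_positive(min_group_detections, "min_group_detections")
  structure(list(ppm_small = ppm_small, ppm_large = ppm_large,
                 small_mass_limit = small_mass_limit,
                 width_lo = width_lo, width_hi = width_hi,
                 time_lo = time_lo, time_hi = time_hi,
                 min_group_detections = as.integer(min_group_detections)),
            class = "clustering_params")
}

#' Mass tolerance for a given peptide mass
#'
#' @param mass Peptide mass(es) in Da (> 0).
#' @param params A [clustering_params()].
#' @return Tolerance(s) in ppm: `ppm_small` for masses strictly below
#'   `small_mass_limit`, `ppm_large` otherwise.
#' @export
mass_tolerance <- function(mass, params = clustering_params()) {
  stopifnot(all(mass > 0))
  ifelse(mass < params$small_mass_limit, params$ppm_small, params$ppm_large)
}

#' Cluster window width fraction at a given migration time
#'
#' @param time Migration time(s) in min (> 0).
#' @inheritParams mass_tolerance
#' @return Full window width as a fraction of migration time, linearly
#'   interpolated between (`time_lo`, `width_lo`) and (`time_hi`,
#'   `width_hi`), clamped outside that range.
#' @export
time_window_fraction <- function(time, params = clustering_params()) {
  stopifnot(all(time > 0))
  frac <- params$width_lo + (params$width_hi - params$width_lo) *
    (time - params$time_lo) / (params$time_hi - params$time_lo)
  pmin(params$width_hi, pmax(params$width_lo, frac))
}

#' Cluster peaks across samples into peptide clusters
#'
#' Pools the peaks of all (calibrated, normalized) profiles, sorts them by
#' descending amplitude with deterministic tie keys (mass, time, sample id),
#' and assigns them greedily: each unassigned peak seeds a cluster; a peak
#' joins an existing cluster iff its mass is within [mass_tolerance()] of
#' the cluster consensus, its migration time within half the
#' [time_window_fraction()] window around the consensus time, and its sample
#' is not yet represented in the cluster. Consensus coordinates are frozen
#' at the seed peak during assignment (making the partition independent of
#' sample order) and reported afterwards as amplitude-weighted means of the
#' members. Every input peak lands in exactly one cluster.
#'
#' @param peaks Long peak tibble (`sample_id`, `mass`, `time`, `amplitude`,
#'   optionally `peak_id`).
#' @inheritParams mass_tolerance
#' @return A long cluster table: `cluster_id`, consensus `mass` and `time`,
#'   `sample_id`, `amplitude` (plus `peak_id` when supplied), one row per
#'   member peak, with attribute `samples` giving the full sample set.
#'   Cluster ids are ordered by consensus mass. An empty input yields an
#'   empty table.
#' @export
cluster_profiles <- function(peaks, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  if (nrow(peaks) == 0) {
    out <- tibble::tibble(cluster_id = integer(0), mass = numeric(0),
                          time = numeric(0), sample_id = character(0),
                          amplitude = numeric(0))
    attr(out, "samples") <- character(0)
    return(out)
  }
  samples <- sort(unique(peaks$sample_id))
  ord <- order(-peaks$amplitude, peaks$mass, peaks$time, peaks$sample_id)
  p <- peaks[ord, ]
  assign <- greedy_cluster_cpp(p$mass, p$time,
                               match(p$sample_id, samples), length(samples),
                               params$ppm_small, params$ppm_large,
                               params$small_mass_limit,
                               params$width_lo, params$width_hi,
                               params$time_lo, params$time_hi)
  consensus <- tibble::tibble(raw = assign, mass = p$mass, time = p$time,
                              amplitude = p$amplitude) %>%
    dplyr::group_by(.data$raw) %>%
    dplyr::summarise(mass = weighted.mean(.data$mass, .data$amplitude),
                     time = weighted.mean(.data$time, .data$amplitude),
                     .groups = "drop")
  relabel <- order(order(consensus$mass, consensus$time))
  new_id <- relabel[match(assign, consensus$raw)]
  out <- tibble::tibble(cluster_id = new_id,
                        mass = consensus$mass[match(assign, consensus$raw)],
                        time = consensus$time[match(assign, consensus$raw)],
                        sample_id = p$sample_id,
                        amplitude = p$amplitude)
  if ("peak_id" %in% names(p)) out$peak_id <- p$peak_id
  out <- out[order(out$cluster_id, out$sample_id), ]
  attr(out, "samples") <- samples
  out
}

#' Remove sporadically detected peptide clusters
#'
#' Keeps a cluster only when it is detected in at least
#' `min_group_detections` samples of at least one group.
#'
#' @param table Long cluster table from [cluster_profiles()].
#' @param groups Tibble assigning every sample to a group (`sample_id`,
#'   `group`).
#' @inheritParams mass_tolerance
#' @return The filtered cluster table (attributes preserved).
#' @export
filter_sporadic <- function(table, groups, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  if (nrow(table) == 0) return(table)
  grp <- groups$group[match(table$sample_id, groups$sample_id)]
  if (anyNA(grp)) {
    abort(paste0("unknown group label for sample(s): ",
                 paste(unique(table$sample_id[is.na(grp)]), collapse = ", ")))
  }
  counts <- tibble::tibble(cluster_id = table$cluster_id, group = grp) %>%
    dplyr::count(.data$cluster_id, .data$group) %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(max_n = max(.data$n), .groups = "drop")
  keep <- counts$cluster_id[counts$max_n >= params$min_group_detections]
  out <- table[table$cluster_id %in% keep, ]
  attr(out, "samples") <- attr(table, "samples")
  out
}

#' Per-group detection frequency of each cluster
#'
#' @inheritParams filter_sporadic
#' @return Tibble: `cluster_id`, `group`, `n_detected`, `n_samples`,
#'   `frequency`.
#' @export
detection_frequency <- function(table, groups) {
  grp <- groups$group[match(table$sample_id, groups$sample_id)]
  if (anyNA(grp)) abort("unknown group label in `table`")
  sizes <- dplyr::count(groups, .data$group, name = "n_samples")
  tibble::tibble(cluster_id = table$cluster_id, group = grp) %>%
    dplyr::count(.data$cluster_id, .data$group, name = "n_detected") %>%
    tidyr::complete(.data$cluster_id, group = sizes$group,
                    fill = list(n_detected = 0L)) %>%
    dplyr::left_join(sizes, by = "group") %>%
    dplyr::mutate(frequency = .data$n_detected / .data$n_samples)
}
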