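#' Configure a synthetic CE-MS seminal-plasma cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' emulate the structure of a seminal-plasma peptidome profiling study: a
#' training cohort of 50 samples (22 prostate cancer, 9 benign hyperplasia,
#' 14 chronic prostatitis, 5 healthy controls), roughly 1,800 background
#' peptides spanning 802.4-15,701.8 Da and 19-45 min of migration time,
#' 46 endogenous internal-standard peptides present in >97% of samples with
#' low amplitude variability, and a set of spiked calibrant peptides with
#' known coordinates. Amplitudes are drawn log10-normally; missing values
#' (coded 0 in the matrix layout) arise from an amplitude-dependent dropout
#' model, so low-abundance peptides are missed more often.
#'
#' Per-sample measurement distortions are multiplicative for mass (ppm scale)
#' and affine (offset + gain) for migration time, so the calibration stage has
#' a real error structure to correct; their default magnitudes are half the
#' downstream clustering tolerances.
#'
#' @param group_sizes Named integer vector of samples per group. Names are the
#'   group labels (default `PCa`, `BPH`, `CP`, `HC`).
#' @param n_background_peptides Number of background peptide species.
#' @param mass_range,time_range Numeric length-2 intervals (Da, min) from
#'   which true peptide coordinates are drawn.
#' @param planted_markers Optional tibble of planted differential peptides
#'   with columns `mass`, `time`, `group`, `log10_shift`, `det_freq` and
#'   optionally `base_log10`. One marker is one unique (`mass`, `time`) pair;
#'   each row gives the log10 amplitude shift and detection frequency applied
#'   in one group. Groups not listed behave as background. See
#'   [reference_marker_config()].
#' @param n_internal_standards Number of internal-standard peptides (drawn
#'   from the background slots, high amplitude, low variability).
#' @param internal_standard_presence Detection frequency of the standards.
#' @param n_calibrants Number of spiked calibrant peptides with known true
#'   mass and migration time (present in every sample).
#' @param amplitude_noise_sd Per-peak log10 amplitude noise SD.
#' @param standard_base_sd Spread (log10) of the internal standards'
#'   baseline amplitudes across standards.
#' @param standard_noise_sd Per-peak log10 amplitude noise SD of the
#'   internal standards and calibrants (low: they are selected for signal
#'   stability).
#' @param mass_jitter_ppm SD of the per-sample multiplicative mass error
#'   (ppm).
#' @param mass_noise_ppm SD of the residual per-peak mass noise (ppm).
#' @param time_drift List with `offset_sd` (min), `gain_sd` (dimensionless)
#'   and `noise_sd` (min): the per-sample affine migration-time distortion and
#'   the per-peak time noise.
#' @param missing_rate Baseline detection-failure probability applied on top
#'   of the amplitude-dependent dropout.
#' @param dilution_log10_sd SD of the per-sample global log10 amplitude shift
#'   (dilution/ionization efficiency), removed by normalization.
#' @param base_amplitude_mean,base_amplitude_sd Mean and SD of background
#'   peptide baseline log10 amplitudes.
#' @param detection_midpoint,detection_width Parameters of the logistic
#'   amplitude-dependent detection model (on log10 amplitude).
#' @param seed Default integer seed used by [generate_cohort()].
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(PCa = 22, BPH = 9, CP = 14, HC = 5),
                          n_background_peptides = 1800,
                          mass_range = c(802.4, 15701.8),
                          time_range = c(19, 45),
                          planted_markers = NULL,
                          n_internal_standards = 46,
                          internal_standard_presence = 0.97,
                          n_calibrants = 14,
                          amplitude_noise_sd = 0.15,
                          standard_base_sd = 0.3,
                          standard_noise_sd = 0.08,
                          mass_jitter_ppm = 25,
                          mass_noise_ppm = 5,
                          time_drift = list(offset_sd = 0.3, gain_sd = 0.01,
                                            noise_sd = 0.05),
                          missing_rate = 0.05,
                          dilution_log10_sd = 0.2,
                          base_amplitude_mean = 2.5,
                          base_amplitude_sd = 0.5,
                          detection_midpoint = 2.0,
                          detection_width = 0.4,
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop_field("group_sizes", "must be a named vector of group counts")
  }
  if (any(group_sizes < 0) || any(group_sizes != round(group_sizes))) {
    stop_field("group_sizes", "counts must be non-negative integers")
  }
  if (length(mass_range) != 2 || diff(mass_range) <= 0 || any(mass_range <= 0)) {
    stop_field("mass_range", "must be a nonempty positive interval")
  }
  if (length(time_range) != 2 || diff(time_range) <= 0 || any(time_range <= 0)) {
    stop_field("time_range", "must be a nonempty positive interval")
  }
  check_fraction(internal_standard_presence, "internal_standard_presence")
  check_fraction(missing_rate, "missing_rate")
  check_positive(n_background_peptides, "n_background_peptides")
  if (n_internal_standards < 0) stop_field("n_internal_standards", "must be >= 0")
  if (n_internal_standards > n_background_peptides) {
    stop_field("n_internal_standards",
               "cannot exceed n_background_peptides")
  }
  if (n_calibrants < 0) stop_field("n_calibrants", "must be >= 0")
  if (amplitude_noise_sd < 0) stop_field("amplitude_noise_sd", "must be >= 0")
  if (mass_jitter_ppm < 0) stop_field("mass_jitter_ppm", "must be >= 0")
  if (!is.null(planted_markers)) {
    planted_markers <- tibble::as_tibble(planted_markers)
    needed <- c("mass", "time", "group", "log10_shift", "det_freq")
    missing_cols <- setdiff(needed, names(planted_markers))
    if (length(missing_cols)) {
      stop_field("planted_markers",
                 paste("missing columns:", paste(missing_cols, collapse = ", ")))
    }
    check_fraction(planted_markers$det_freq, "planted_markers$det_freq")
    bad <- setdiff(unique(planted_markers$group), names(group_sizes))
    if (length(bad)) {
      stop_field("planted_markers",
                 paste("unknown group label(s):", paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(group_sizes = group_sizes,
         n_background_peptides = as.integer(n_background_peptides),
         mass_range = mass_range,
         time_range = time_range,
         planted_markers = planted_markers,
         n_internal_standards = as.integer(n_internal_standards),
         internal_standard_presence = internal_standard_presence,
         n_calibrants = as.integer(n_calibrants),
         amplitude_noise_sd = amplitude_noise_sd,
         standard_base_sd = standard_base_sd,
         standard_noise_sd = standard_noise_sd,
         mass_jitter_ppm = mass_jitter_ppm,
         mass_noise_ppm = mass_noise_ppm,
         time_drift = time_drift,
         missing_rate = missing_rate,
         dilution_log10_sd = dilution_log10_sd,
         base_amplitude_mean = base_amplitude_mean,
         base_amplitude_sd = base_amplitude_sd,
         detection_midpoint = detection_midpoint,
         detection_width = detection_width,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Planted-marker configuration from the bundled reference marker table
#'
#' Converts a Table of published seminal biomarker peptides (see
#' [seminal_marker_table()]) into the `planted_markers` tibble expected by
#' [cohort_config()]: each marker is planted at its reported mass and
#' migration time, with group mean amplitudes reproducing the reported signed
#' regulation ratio between the case and the control groups. The group with
#' the larger mean receives the higher detection frequency.
#'
#' @param table Marker tibble with columns `mass`, `time`, `mean_case`,
#'   `mean_control`; defaults to the bundled reference panel.
#' @param case Group label treated as the case group.
#' @param control Character vector of control group labels.
#' @param high_freq,low_freq Detection frequencies for the group with the
#'   larger and the smaller mean amplitude.
#' @return A tibble suitable as `planted_markers`.
#' @export
reference_marker_config <- function(table = seminal_marker_table(),
                                    case = "PCa",
                                    control = c("BPH", "CP", "HC"),
                                    high_freq = 0.9, low_freq = 0.7) {
  table <- tibble::as_tibble(table)
  purrr::pmap_dfr(
    list(table$mass, table$time, table$mean_case, table$mean_control),
    function(mass, time, m_case, m_ctrl) {
      base <- log10(min(m_case, m_ctrl))
      groups <- c(case, control)
      shifts <- c(log10(m_case) - base,
                  rep(log10(m_ctrl) - base, length(control)))
      freqs <- ifelse(c(m_case, rep(m_ctrl, length(control))) >=
                        max(m_case, m_ctrl), high_freq, low_freq)
      tibble::tibble(mass = mass, time = time, group = groups,
                     log10_shift = shifts, det_freq = freqs,
                     base_log10 = base)
    })
}

#' Generate a synthetic cohort of raw CE-MS peak lists
#'
#' Simulates one uncalibrated, unnormalized peak list per requested sample,
#' together with the ground truth needed to test every downstream stage.
#' Background peptides get log-uniform masses and uniform migration times;
#' amplitudes are log10-normal around per-peptide baselines; planted markers
#' realize their configured per-group amplitude shifts and detection
#' frequencies; per-sample measurement distortions (multiplicative mass
#' error, affine time error, global amplitude shift) are applied and recorded
#' in the ground truth. Ground truth is emitted alongside the data but is
#' never consumed by pipeline stages.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. The same
#'   (config, seed) pair always produces an identical cohort.
#' @return A list of class `cems_cohort` with elements
#'   \describe{
#'     \item{peaks}{long tibble of detected peaks: `sample_id`, `peak_id`,
#'       `mass`, `time`, `amplitude`}
#'     \item{samples}{sample metadata: `sample_id`, `group`, `age`,
#'       `psa_ng_ml`, `gleason`, `pt_stage`, `ms_resolution`}
#'     \item{calibrants}{known true coordinates of the spiked calibrants}
#'     \item{standards}{nominal coordinates of the internal standards}
#'     \item{truth}{ground truth: planted marker slots and effects, standard
#'       slot ids, and the per-sample applied distortions}
#'   }
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  gs <- config$group_sizes
  n_samples <- sum(gs)
  if (n_samples < 1) stop_field("group_sizes", "cohort must contain samples")

  n_bg <- config$n_background_peptides
  n_cal <- config$n_calibrants

  # background peptide species: log-uniform mass, uniform migration time
  lm_range <- log10(config$mass_range)
  slot_mass <- 10^runif(n_bg, lm_range[1], lm_range[2])
  slot_time <- runif(n_bg, config$time_range[1], config$time_range[2])
  slot_base <- rnorm(n_bg, config$base_amplitude_mean, config$base_amplitude_sd)
  slot_kind <- rep("background", n_bg)

  # internal standards: endogenous, highly abundant, low variability
  std_ids <- integer(0)
  if (config$n_internal_standards > 0) {
    std_ids <- sort(sample.int(n_bg, config$n_internal_standards))
    slot_base[std_ids] <- rnorm(length(std_ids), 3.8,
                                config$standard_base_sd)
    slot_kind[std_ids] <- "standard"
  }

  # planted markers occupy background slots (never a standard slot)
  marker_tbl <- config$planted_markers
  marker_slot <- integer(0)
  if (!is.null(marker_tbl) && nrow(marker_tbl) > 0) {
    key <- paste(marker_tbl$mass, marker_tbl$time)
    marker_coords <- marker_tbl[!duplicated(key), c("mass", "time")]
    n_mark <- nrow(marker_coords)
    free <- setdiff(seq_len(n_bg), std_ids)
    if (n_mark > length(free)) {
      stop_field("planted_markers", "more markers than available peptide slots")
    }
    marker_slot <- sort(sample(free, n_mark))
    slot_mass[marker_slot] <- marker_coords$mass
    slot_time[marker_slot] <- marker_coords$time
    slot_kind[marker_slot] <- "marker"
    if ("base_log10" %in% names(marker_tbl)) {
      base_by_marker <- marker_tbl$base_log10[!duplicated(key)]
      slot_base[marker_slot] <- base_by_marker
    }
    marker_index <- setNames(marker_slot, unique(key))
  }

  # spiked calibrants: extra slots with known coordinates, evenly spaced
  cal_ids <- integer(0)
  if (n_cal > 0) {
    cal_ids <- n_bg + seq_len(n_cal)
    cal_mass <- 10^seq(lm_range[1] + 0.05, lm_range[2] - 0.05,
                       length.out = n_cal)
    cal_time <- seq(config$time_range[1] + 0.5, config$time_range[2] - 0.5,
                    length.out = n_cal)
    slot_mass <- c(slot_mass, cal_mass)
    slot_time <- c(slot_time, cal_time)
    slot_base <- c(slot_base, rep(3.5, n_cal))
    slot_kind <- c(slot_kind, rep("calibrant", n_cal))
  }
  n_slots <- length(slot_mass)

  # samples and their applied distortions
  group <- rep(names(gs), times = gs)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  distortions <- tibble::tibble(
    sample_id = sample_id,
    mass_scale = 1 + rnorm(n_samples, 0, config$mass_jitter_ppm * 1e-6),
    time_offset = rnorm(n_samples, 0, config$time_drift$offset_sd),
    time_gain = 1 + rnorm(n_samples, 0, config$time_drift$gain_sd),
    amp_log10_shift = rnorm(n_samples, 0, config$dilution_log10_sd))

  samples <- tibble::tibble(
    sample_id = sample_id,
    group = group,
    age = round(rnorm(n_samples,
                      c(PCa = 58, BPH = 60, CP = 45, HC = 48)[group] %|na|% 55,
                      c(PCa = 7, BPH = 6, CP = 13, HC = 11)[group] %|na|% 10)),
    psa_ng_ml = round(pmax(0.1, rnorm(
      n_samples,
      c(PCa = 8, BPH = 4.5, CP = 1.2, HC = 1.0)[group] %|na|% 2,
      c(PCa = 4, BPH = 2, CP = 0.7, HC = 0.6)[group] %|na|% 1)), 2),
    gleason = ifelse(group == "PCa",
                     sample(c("<7", "7", ">7"), n_samples, replace = TRUE,
                            prob = c(0.33, 0.47, 0.20)), NA),
    pt_stage = ifelse(group == "PCa",
                      sample(c("<pT3a", ">=pT3a"), n_samples, replace = TRUE,
                             prob = c(0.85, 0.15)), NA),
    ms_resolution = round(runif(n_samples, 8500, 9500)))

  # long grid sample x slot
  idx_sample <- rep(seq_len(n_samples), each = n_slots)
  idx_slot <- rep(seq_len(n_slots), times = n_samples)
  base_la <- slot_base[idx_slot]

  # per-(slot, group) amplitude shifts and detection frequency overrides
  shift <- numeric(length(idx_slot))
  freq_override <- rep(NA_real_, length(idx_slot))
  if (length(marker_slot)) {
    mt <- marker_tbl
    mt$slot <- marker_index[paste(mt$mass, mt$time)]
    for (j in seq_len(nrow(mt))) {
      hit <- idx_slot == mt$slot[j] & group[idx_sample] == mt$group[j]
      shift[hit] <- mt$log10_shift[j]
      freq_override[hit] <- mt$det_freq[j]
    }
  }

  expected_la <- base_la + shift
  p_bg <- (1 - config$missing_rate) *
    plogis((expected_la - config$detection_midpoint) / config$detection_width)
  kind <- slot_kind[idx_slot]
  p_det <- ifelse(kind == "calibrant", 1,
           ifelse(kind == "standard", config$internal_standard_presence,
                  ifelse(is.na(freq_override), p_bg, freq_override)))
  detected <- rbinom(length(p_det), 1, p_det) == 1

  noise_sd <- ifelse(kind %in% c("standard", "calibrant"),
                     config$standard_noise_sd, config$amplitude_noise_sd)
  la <- expected_la + distortions$amp_log10_shift[idx_sample] +
    rnorm(length(idx_slot), 0, noise_sd)
  obs_mass <- slot_mass[idx_slot] * distortions$mass_scale[idx_sample] *
    (1 + rnorm(length(idx_slot), 0, config$mass_noise_ppm * 1e-6))
  obs_time <- distortions$time_offset[idx_sample] +
    distortions$time_gain[idx_sample] * slot_time[idx_slot] +
    rnorm(length(idx_slot), 0, config$time_drift$noise_sd)

  peaks <- tibble::tibble(
    sample_id = sample_id[idx_sample][detected],
    peak_id = idx_slot[detected],
    mass = obs_mass[detected],
    time = obs_time[detected],
    amplitude = 10^la[detected])

  truth_markers <- NULL
  if (length(marker_slot)) {
    truth_markers <- marker_tbl
    truth_markers$peak_id <- marker_index[paste(marker_tbl$mass,
                                                marker_tbl$time)]
  }

  structure(
    list(peaks = peaks,
         samples = samples,
         calibrants = tibble::tibble(peak_id = cal_ids,
                                     mass = slot_mass[cal_ids],
                                     time = slot_time[cal_ids]),
         standards = tibble::tibble(peak_id = std_ids,
                                    mass = slot_mass[std_ids],
                                    time = slot_time[std_ids]),
         truth = list(markers = truth_markers,
                      standard_ids = std_ids,
                      calibrant_ids = cal_ids,
                      slots = tibble::tibble(peak_id = seq_len(n_slots),
                                             mass = slot_mass,
                                             time = slot_time,
                                             base_log10 = slot_base,
                                             kind = slot_kind),
                      distortions = distortions)),
    class = "cems_cohort")
}

# vectorized NA-coalescing helper for group-keyed lookups
`%|na|%` <- function(x, default) {
  x[is.na(x)] <- default
  x
}

#' @export
print.cems_cohort <- function(x, ...) {
  cat("<cems_cohort>\n")
  cat("  samples: ", nrow(x$samples), " (",
      paste(sprintf("%s=%d", names(table(x$samples$group)),
                    as.integer(table(x$samples$group))), collapse = ", "),
      ")\n", sep = "")
  cat("  detected peaks:", nrow(x$peaks), "\n")
  cat("  calibrants:", nrow(x$calibrants),
      " internal standards:", nrow(x$standards), "\n")
  n_mark <- if (is.null(x$truth$markers)) 0 else
    length(unique(x$truth$markers$peak_id))
  cat("  planted markers:", n_mark, "\n")
  invisible(x)
}

#' Generate a replicate series from one sample's peak list
#'
#' Produces `n` perturbed copies of a single profile, emulating repeated
#' CE-MS measurements of the same specimen (analytical replicates) or a
#' bench-stability time series. With `drift_per_step = 0` the series is
#' exchangeable noise around the source profile; with a nonzero drift a
#' linear log10-amplitude trend of the configured magnitude is imposed on the
#' peaks in `drift_peaks` (all peaks by default), replicate index acting as
#' the time axis.
#'
#' @param peaks Peak tibble of a single sample (columns `sample_id`,
#'   `peak_id`, `mass`, `time`, `amplitude`).
#' @param n Number of replicates (>= 2).
#' @param drift_per_step Log10 amplitude change per replicate step.
#' @param noise_sd Per-peak log10 amplitude noise SD.
#' @param seed Integer seed.
#' @param drift_peaks Optional integer vector of `peak_id`s the drift applies
#'   to; defaults to every peak.
#' @return A tibble of peaks for all replicates, with columns as the input
#'   plus `replicate` (1-based step index); `sample_id` is suffixed `_r<i>`.
#' @export
generate_replicate_series <- function(peaks, n, drift_per_step = 0,
                                      noise_sd = 0, seed = 1L,
                                      drift_peaks = NULL) {
  if (n < 2) abort("invalid replicate count: n must be >= 2")
  ids <- unique(peaks$sample_id)
  if (length(ids) != 1) abort("`peaks` must contain exactly one sample")
  set.seed(seed)
  if (is.null(drift_peaks)) drift_peaks <- unique(peaks$peak_id)
  purrr::map_dfr(seq_len(n), function(i) {
    out <- peaks
    la <- log10(out$amplitude) +
      (i - 1) * drift_per_step * (out$peak_id %in% drift_peaks) +
      rnorm(nrow(out), 0, noise_sd)
    out$amplitude <- 10^la
    out$sample_id <- paste0(ids, "_r", i)
    out$replicate <- i
    out
  })
}
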