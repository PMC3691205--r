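#' Read a tab-separated peak matrix
#'
#' Reads the standard peptide-profile matrix dialect: a header row with
#' `id`, `mass [Da]`, `migration time [min]` followed by one column per
#' sample, and one row per peptide (or peptide cluster). A cell value of `0`
#' denotes an undetected/missing measurement and is dropped from the parsed
#' long table. A format tag in the first header cell (`id [cluster]` or
#' `id [peaks]`) distinguishes clustered cross-sample tables from raw
#' per-sample peak lists; untagged files are read as cluster tables.
#'
#' @param path Path to a tab-separated file.
#' @return A long tibble with columns `cluster_id` (or `peak_id` for raw
#'   format), `mass`, `time`, `sample_id`, `amplitude`, containing only
#'   detected (nonzero) cells. Attributes: `samples` (sample column order),
#'   `format` (`"cluster"` or `"peaks"`), and `parse_report` (row/column
#'   counts and number of zero cells).
#' @export
read_peak_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 4 || nrow(raw) == 0) {
    abort(paste0("parse error in '", path,
                 "': expected header id/mass/time plus >=1 sample column ",
                 "and >=1 data row"), class = "cemarker_parse_error")
  }
  hdr <- names(raw)
  norm <- tolower(gsub("[^a-z]", "", tolower(hdr[1:3])))
  fmt <- if (grepl("peaks", tolower(hdr[1]))) "peaks" else "cluster"
  ok_hdr <- grepl("^id", norm[1]) && grepl("mass", norm[2]) &&
    grepl("time", norm[3])
  if (!ok_hdr) {
    abort(paste0("parse error in '", path, "': malformed header `",
                 paste(hdr[1:3], collapse = "\t"), "`"),
          class = "cemarker_parse_error")
  }
  sample_cols <- hdr[-(1:3)]
  dup <- sample_cols[duplicated(sample_cols)]
  if (length(dup)) {
    abort(paste0("parse error in '", path, "': duplicate sample column(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "cemarker_parse_error")
  }
  num <- suppressWarnings(
    lapply(raw, function(col) as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(raw[[j]]))
    if (length(bad)) {
      abort(sprintf("parse error in '%s': non-numeric cell at row %d, column '%s'",
                    path, bad[1] + 1L, hdr[j]),
            class = "cemarker_parse_error")
    }
    nas <- which(is.na(raw[[j]]))
    if (length(nas)) {
      abort(sprintf("parse error in '%s': empty cell at row %d, column '%s'",
                    path, nas[1] + 1L, hdr[j]),
            class = "cemarker_parse_error")
    }
  }
  wide <- tibble::as_tibble(num, .name_repair = "minimal")
  names(wide) <- c("id", "mass", "time", sample_cols)
  long <- tidyr::pivot_longer(wide, cols = -c("id", "mass", "time"),
                              names_to = "sample_id",
                              values_to = "amplitude")
  n_zero <- sum(long$amplitude == 0)
  long <- long[long$amplitude != 0, , drop = FALSE]
  id_name <- if (fmt == "peaks") "peak_id" else "cluster_id"
  names(long)[names(long) == "id"] <- id_name
  long <- long[, c(id_name, "mass", "time", "sample_id", "amplitude")]
  structure(tibble::as_tibble(long),
            samples = sample_cols,
            format = fmt,
            parse_report = list(n_rows = nrow(wide),
                                n_samples = length(sample_cols),
                                n_zero_cells = n_zero))
}

#' Write a peak matrix in the tab-separated dialect
#'
#' Inverse of [read_peak_matrix()]: writes a long table of detected peaks as
#' the wide matrix layout, filling undetected cells with `0`. Masses are
#' written with 4 decimals, migration times with 2, amplitudes with up to 6
#' significant digits.
#'
#' @param table Long tibble with an id column (`cluster_id`, `peak_id`, or
#'   `id`), `mass`, `time`, `sample_id`, `amplitude`.
#' @param path Output path.
#' @param samples Sample column order; defaults to the table's `samples`
#'   attribute, falling back to sorted unique `sample_id`.
#' @param format Format tag written into the header (`"cluster"` or
#'   `"peaks"`).
#' @return `path`, invisibly.
#' @export
write_peak_matrix <- function(table, path,
                              samples = NULL,
                              format = c("cluster", "peaks")) {
  format <- match.arg(format)
  table <- tibble::as_tibble(table)
  id_col <- intersect(c("cluster_id", "peak_id", "id"), names(table))[1]
  if (is.na(id_col) || nrow(table) == 0) {
    abort("`table` must be nonempty with an id column")
  }
  if (is.null(samples)) samples <- attr(table, "samples")
  if (is.null(samples)) samples <- sort(unique(table$sample_id))

  ids <- table[[id_col]]
  key <- !duplicated(ids)
  row_ids <- ids[key]
  # consensus coordinates: first occurrence per id
  row_mass <- table$mass[key]
  row_time <- table$time[key]
  amp <- matrix(0, nrow = length(row_ids), ncol = length(samples),
                dimnames = list(NULL, samples))
  ri <- match(ids, row_ids)
  ci <- match(table$sample_id, samples)
  if (anyNA(ci)) abort("`samples` does not cover every sample_id in `table`")
  amp[cbind(ri, ci)] <- table$amplitude

  header <- paste(c(sprintf("id [%s]", format), "mass [Da]",
                    "migration time [min]", samples), collapse = "\t")
  body <- vapply(seq_along(row_ids), function(i) {
    paste(c(format(row_ids[i]),
            sprintf("%.4f", row_mass[i]),
            sprintf("%.2f", row_time[i]),
            sprintf("%.6g", amp[i, ])), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Sample metadata travels as a CSV with columns `sample_id`, `group`,
#' `age`, `psa_ng_ml`, `gleason`, `pt_stage`.
#'
#' @param path CSV path.
#' @return `read_sample_metadata()` returns a tibble;
#'   `write_sample_metadata()` returns `path` invisibly.
#' @export
read_sample_metadata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_sample_metadata
#' @param samples Metadata tibble to write.
#' @export
write_sample_metadata <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Quality-control parameters for CE-MS data sets
#'
#' Acceptance thresholds for a single measured profile: at least 1,000
#' detected peptides, a minimum MS resolution of 8,000, a migration-time
#' interval (the window in which separated peptides are detected) of at
#' least 10 minutes, and -- once the profile is calibrated -- a mean
#' migration-time deviation from the reference standards strictly below
#' 0.30 minutes.
#'
#' @param min_peptides,min_resolution,min_time_interval,max_mean_time_deviation
#'   Thresholds; all must be positive.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_peptides = 1000, min_resolution = 8000,
                      min_time_interval = 10,
                      max_mean_time_deviation = 0.30) {
  for (f in c("min_peptides", "min_resolution", "min_time_interval",
              "max_mean_time_deviation")) {
    check_positive(get(f), f)
  }
  structure(list(min_peptides = min_peptides,
                 min_resolution = min_resolution,
                 min_time_interval = min_time_interval,
                 max_mean_time_deviation = max_mean_time_deviation),
            class = "qc_params")
}

#' Compute per-sample QC metrics from a peak table
#'
#' @param peaks Long peak tibble (`sample_id`, `mass`, `time`, `amplitude`).
#' @param samples Optional metadata tibble carrying `ms_resolution` (the
#'   resolution is an instrument property, not derivable from the peak list).
#' @param mean_time_deviation Optional named vector of post-calibration mean
#'   absolute migration-time deviations (min) keyed by sample id, e.g. from
#'   [calibration_summary()].
#' @return A tibble: `sample_id`, `n_peaks`, `ms_resolution`,
#'   `time_interval`, `mean_time_deviation`.
#' @export
compute_qc <- function(peaks, samples = NULL, mean_time_deviation = NULL) {
  qc <- peaks %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(n_peaks = dplyr::n(),
                     time_interval = max(.data$time) - min(.data$time),
                     .groups = "drop")
  qc$ms_resolution <- NA_real_
  if (!is.null(samples) && "ms_resolution" %in% names(samples)) {
    qc$ms_resolution <- samples$ms_resolution[
      match(qc$sample_id, samples$sample_id)]
  }
  qc$mean_time_deviation <- NA_real_
  if (!is.null(mean_time_deviation)) {
    qc$mean_time_deviation <-
      unname(mean_time_deviation[qc$sample_id])
  }
  qc[, c("sample_id", "n_peaks", "ms_resolution", "time_interval",
         "mean_time_deviation")]
}

#' Apply data-set acceptance criteria to QC metrics
#'
#' A profile is accepted iff it has at least `min_peptides` peaks, an MS
#' resolution of at least `min_resolution`, a migration-time interval of at
#' least `min_time_interval` minutes, and (when the metric is available,
#' i.e. after calibration) a mean migration-time deviation strictly below
#' `max_mean_time_deviation` minutes. A missing `mean_time_deviation` skips
#' that criterion; any other missing metric rejects the profile with reason
#' `"metric missing"`.
#'
#' @param qc QC tibble as returned by [compute_qc()] (one row per sample).
#' @param params A [qc_params()] object.
#' @return The input tibble with columns `accepted` (logical) and `reasons`
#'   (comma-separated failure reasons, `""` when accepted).
#' @export
qc_accept <- function(qc, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  eval_row <- function(n_peaks, res, interval, dev) {
    reasons <- character(0)
    for (v in list(c("n_peaks", n_peaks), c("ms_resolution", res),
                   c("time_interval", interval))) {
      if (is.na(as.numeric(v[2]))) {
        reasons <- c(reasons, paste0("metric missing: ", v[1]))
      }
    }
    if (!length(reasons)) {
      if (n_peaks < params$min_peptides) reasons <- c(reasons, "min_peptides")
      if (res < params$min_resolution) reasons <- c(reasons, "min_resolution")
      if (interval < params$min_time_interval) {
        reasons <- c(reasons, "min_time_interval")
      }
      if (!is.na(dev) && dev >= params$max_mean_time_deviation) {
        reasons <- c(reasons, "mean_time_deviation")
      }
    }
    paste(reasons, collapse = ",")
  }
  qc$reasons <- mapply(eval_row, qc$n_peaks, qc$ms_resolution,
                       qc$time_interval, qc$mean_time_deviation)
  qc$accepted <- !nzchar(qc$reasons)
  qc
}
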