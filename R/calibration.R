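#' Assemble a calibration reference set
#'
#' Bundles the reference knowledge used by the calibration stage: peptides of
#' known true mass and migration time (spiked isotope-labelled calibrants
#' and/or housekeeping peptides) and internal-standard peptides used for
#' amplitude normalization. Reference amplitudes for the standards may be
#' left `NA`, in which case [normalize_amplitudes()] fills them with the
#' cohort geometric mean of each standard's observed amplitude.
#'
#' @param calibrants Tibble with columns `mass`, `time` (reference
#'   coordinates), e.g. the `calibrants` element of a [generate_cohort()]
#'   result.
#' @param standards Optional tibble with columns `mass`, `time` and
#'   optionally `ref_amplitude`.
#' @return A list of class `reference_set`.
#' @export
reference_set <- function(calibrants, standards = NULL) {
  calibrants <- tibble::as_tibble(calibrants)
  stopifnot(all(c("mass", "time") %in% names(calibrants)))
  if (nrow(calibrants) < 2) {
    abort("calibration error: need >= 2 reference points")
  }
  if (!is.null(standards)) {
    standards <- tibble::as_tibble(standards)
    stopifnot(all(c("mass", "time") %in% names(standards)))
    if (!"ref_amplitude" %in% names(standards)) {
      standards$ref_amplitude <- NA_real_
    }
  }
  structure(list(calibrants = calibrants, standards = standards),
            class = "reference_set")
}

# Match each reference to the nearest detected peak of one sample within a
# coarse (ppm, min) window. Returns indices into the sample's peaks (NA when
# unmatched), choosing the smallest ppm deviation, then smallest |dt|.
match_refs_one <- function(mass, time, ref_mass, ref_time,
                           ppm_tol, time_tol) {
  vapply(seq_along(ref_mass), function(j) {
    dppm <- abs(mass - ref_mass[j]) / ref_mass[j] * 1e6
    dt <- abs(time - ref_time[j])
    ok <- dppm <= ppm_tol & dt <= time_tol
    if (!any(ok)) return(NA_integer_)
    cand <- which(ok)
    cand[order(dppm[cand], dt[cand])][1]
  }, integer(1))
}

#' Match reference peptides to observed peaks
#'
#' @param peaks Long peak tibble.
#' @param refs Tibble with reference `mass` and `time` columns.
#' @param ppm_tol,time_tol Coarse matching window (ppm, min).
#' @return Tibble with one row per (sample, reference) match: `sample_id`,
#'   `ref_index`, reference and observed coordinates, observed amplitude.
#' @export
match_reference_peaks <- function(peaks, refs, ppm_tol = 200, time_tol = 3) {
  refs <- tibble::as_tibble(refs)
  split_idx <- split(seq_len(nrow(peaks)), peaks$sample_id)
  purrr::imap_dfr(split_idx, function(idx, sid) {
    hit <- match_refs_one(peaks$mass[idx], peaks$time[idx],
                          refs$mass, refs$time, ppm_tol, time_tol)
    keep <- !is.na(hit)
    tibble::tibble(sample_id = sid,
                   ref_index = which(keep),
                   ref_mass = refs$mass[keep],
                   ref_time = refs$time[keep],
                   obs_mass = peaks$mass[idx][hit[keep]],
                   obs_time = peaks$time[idx][hit[keep]],
                   obs_amplitude = peaks$amplitude[idx][hit[keep]])
  })
}

# One-pass robust least squares: fit, drop points with residual > 3 x MAD,
# refit once (keeping the original fit if too few points would remain).
robust_lm <- function(x, y, min_points = 2) {
  fit <- lm(y ~ x)
  r <- stats::residuals(fit)
  s <- mad(r)
  if (s > 0) {
    keep <- abs(r) <= 3 * s
    if (sum(keep) >= min_points && any(!keep)) {
      fit <- lm(y[keep] ~ x[keep])
      return(list(coef = unname(coef(fit)), keep = keep))
    }
  }
  list(coef = unname(coef(fit)), keep = rep(TRUE, length(x)))
}

# Piecewise-local linear map y = f(x), with locality in `loc` (== x for time
# calibration; migration time for amplitude normalization). Overlapping
# windows of width span/n_windows with 50% overlap, fits blended with
# triangular weights; windows with fewer than `min_points` points, and
# locations outside every window, fall back to the global robust fit.
local_linear_map <- function(loc, x, y, loc_range, n_windows = 5,
                             min_points = 2) {
  glob <- robust_lm(x, y)$coef
  span <- diff(loc_range)
  w <- span / n_windows
  centers <- if (span <= 0 || n_windows < 2) numeric(0) else
    seq(loc_range[1] + w / 2, loc_range[2] - w / 2, by = w / 2)
  fits <- lapply(centers, function(cc) {
    in_w <- which(abs(loc - cc) <= w / 2)
    if (length(in_w) < min_points || length(unique(x[in_w])) < 2) return(NULL)
    unname(coef(lm(y[in_w] ~ x[in_w])))
  })
  function(new_loc, new_x) {
    pred_glob <- glob[1] + glob[2] * new_x
    if (!length(centers)) return(pred_glob)
    num <- rep(0, length(new_x))
    den <- rep(0, length(new_x))
    for (j in seq_along(centers)) {
      if (is.null(fits[[j]])) next
      wt <- pmax(0, 1 - abs(new_loc - centers[j]) / (w / 2))
      num <- num + wt * (fits[[j]][1] + fits[[j]][2] * new_x)
      den <- den + wt
    }
    ifelse(den > 0, num / den, pred_glob)
  }
}

#' Calibrate masses and migration times against reference peptides
#'
#' For every sample, reference peptides are matched to observed peaks within
#' a coarse window; masses are then corrected by a single global linear map
#' (least squares after one 3xMAD outlier-rejection pass) and migration
#' times by piecewise-local linear maps fitted in overlapping time windows
#' and blended at their boundaries. Calibration changes only peak
#' coordinates, never peak counts. The post-calibration mean absolute
#' migration-time deviation against the references is recorded per sample.
#'
#' @param peaks Long peak tibble of a cohort.
#' @param refs A [reference_set()] (or a calibrant tibble).
#' @param ppm_tol,time_tol Coarse reference-matching window.
#' @param n_windows Number of local time windows (width = range/n, 50%
#'   overlap).
#' @return The calibrated peak tibble, with a `calibration` attribute
#'   holding the per-sample summary (see [calibration_summary()]).
#' @export
calibrate_profiles <- function(peaks, refs, ppm_tol = 200, time_tol = 3,
                               n_windows = 5) {
  if (!inherits(refs, "reference_set")) refs <- reference_set(refs)
  cal <- refs$calibrants
  out <- peaks
  summaries <- list()
  for (sid in unique(peaks$sample_id)) {
    idx <- which(peaks$sample_id == sid)
    hit <- match_refs_one(peaks$mass[idx], peaks$time[idx],
                          cal$mass, cal$time, ppm_tol, time_tol)
    keep <- !is.na(hit)
    if (sum(keep) < 2) {
      abort(paste0("calibration error: fewer than 2 matched reference ",
                   "points in sample ", sid))
    }
    obs_mass <- peaks$mass[idx][hit[keep]]
    obs_time <- peaks$time[idx][hit[keep]]
    ref_mass <- cal$mass[keep]
    ref_time <- cal$time[keep]

    mfit <- robust_lm(obs_mass, ref_mass)$coef
    out$mass[idx] <- mfit[1] + mfit[2] * peaks$mass[idx]

    tmap <- local_linear_map(obs_time, obs_time, ref_time,
                             range(peaks$time[idx]), n_windows = n_windows)
    out$time[idx] <- tmap(peaks$time[idx], peaks$time[idx])

    cal_ref_time <- tmap(obs_time, obs_time)
    cal_ref_mass <- mfit[1] + mfit[2] * obs_mass
    summaries[[sid]] <- tibble::tibble(
      sample_id = sid,
      n_refs = sum(keep),
      mass_intercept = mfit[1],
      mass_slope = mfit[2],
      mean_mass_ppm_dev = mean(abs(cal_ref_mass - ref_mass) / ref_mass * 1e6),
      mean_time_deviation = mean(abs(cal_ref_time - ref_time)))
  }
  attr(out, "calibration") <- dplyr::bind_rows(summaries)
  out
}

#' Per-sample calibration summary
#'
#' @param peaks A peak tibble returned by [calibrate_profiles()].
#' @return Tibble with one row per sample: number of matched references,
#'   fitted mass map, residual mass (ppm) and migration-time (min)
#'   deviations.
#' @export
calibration_summary <- function(peaks) {
  s <- attr(peaks, "calibration")
  if (is.null(s)) abort("`peaks` carries no calibration summary")
  s
}

#' Normalize signal amplitudes against internal-standard peptides
#'
#' Estimates, per sample, an amplitude correction from the internal
#' standards' log10 ratios of observed to reference amplitude: the
#' correction is fitted by linear regression of the log-ratio on migration
#' time -- locally in overlapping time windows when at least `min_local`
#' standards fall in a window, globally otherwise -- and subtracted from
#' every peak's log10 amplitude. This removes per-sample dilution and
#' ionization-efficiency differences (and any smooth time-dependent drift)
#' while leaving relative abundances untouched: within any time window the
#' map shifts all log amplitudes by the same amount and is therefore
#' strictly order-preserving. Reference amplitudes default to the cohort
#' geometric mean of each standard.
#'
#' @param peaks Long (typically calibrated) peak tibble.
#' @param standards Tibble with `mass`, `time` and optionally
#'   `ref_amplitude`; or a [reference_set()] with standards.
#' @param ppm_tol,time_tol Standard-matching window.
#' @param n_windows Number of local time windows.
#' @param min_local Minimum standards per window for a local fit.
#' @return The normalized peak tibble with a `normalization` attribute
#'   (per-sample number of matched standards and mean log10 correction).
#' @export
normalize_amplitudes <- function(peaks, standards, ppm_tol = 200,
                                 time_tol = 3, n_windows = 5,
                                 min_local = 5) {
  if (inherits(standards, "reference_set")) standards <- standards$standards
  standards <- tibble::as_tibble(standards)
  if (!"ref_amplitude" %in% names(standards)) {
    standards$ref_amplitude <- NA_real_
  }
  matches <- match_reference_peaks(peaks, standards, ppm_tol, time_tol)
  if (anyNA(standards$ref_amplitude)) {
    geo <- matches %>%
      dplyr::group_by(.data$ref_index) %>%
      dplyr::summarise(geo = geometric_mean(.data$obs_amplitude),
                       .groups = "drop")
    fill <- is.na(standards$ref_amplitude)
    standards$ref_amplitude[fill] <-
      geo$geo[match(which(fill), geo$ref_index)]
  }
  out <- peaks
  summaries <- list()
  for (sid in unique(peaks$sample_id)) {
    m <- matches[matches$sample_id == sid, ]
    if (nrow(m) < 3) {
      abort(paste0("normalization error: fewer than 3 internal standards ",
                   "detected in sample ", sid))
    }
    log_ratio <- log10(m$obs_amplitude) -
      log10(standards$ref_amplitude[m$ref_index])
    idx <- which(peaks$sample_id == sid)
    cmap <- local_linear_map(m$obs_time, m$obs_time, log_ratio,
                             range(peaks$time[idx]),
                             n_windows = n_windows, min_points = min_local)
    la <- log10(peaks$amplitude[idx])
    la_new <- la - cmap(peaks$time[idx], peaks$time[idx])
    out$amplitude[idx] <- 10^la_new
    summaries[[sid]] <- tibble::tibble(
      sample_id = sid,
      n_standards = nrow(m),
      mean_log10_correction = mean(la_new - la))
  }
  attr(out, "normalization") <- dplyr::bind_rows(summaries)
  attr(out, "calibration") <- attr(peaks, "calibration")
  out
}

#' Coefficient of variation of internal-standard amplitudes across samples
#'
#' Diagnostic for the normalization stage: matches the standards in every
#' sample and reports, per standard, the across-sample coefficient of
#' variation (SD/mean) of its amplitude.
#'
#' @inheritParams normalize_amplitudes
#' @return Tibble: `ref_index`, `n_samples`, `cv`.
#' @export
standard_amplitude_cv <- function(peaks, standards, ppm_tol = 200,
                                  time_tol = 3) {
  if (inherits(standards, "reference_set")) standards <- standards$standards
  matches <- match_reference_peaks(peaks, standards, ppm_tol, time_tol)
  matches %>%
    dplyr::group_by(.data$ref_index) %>%
    dplyr::summarise(n_samples = dplyr::n(),
                     cv = sd(.data$obs_amplitude) /
                       mean(.data$obs_amplitude),
                     .groups = "drop")
}
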