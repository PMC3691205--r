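#' Frequency filter for candidate biomarkers
#'
#' A cluster enters differential testing only when it is detected in at
#' least `threshold` (default 60%) of the samples of one of the two
#' comparison groups.
#'
#' @param table Long cluster table ([cluster_profiles()]).
#' @param groups Sample metadata tibble (`sample_id`, `group`).
#' @param case,control Group label(s) forming the case and control sides.
#' @param threshold Detection-frequency threshold (inclusive).
#' @return The filtered cluster table.
#' @export
frequency_filter <- function(table, groups, case, control, threshold = 0.60) {
  check_fraction(threshold, "threshold")
  sides <- comparison_sides(table, groups, case, control)
  freq <- dplyr::bind_rows(
    tibble::tibble(cluster_id = sides$case_tbl$cluster_id, side = "case"),
    tibble::tibble(cluster_id = sides$control_tbl$cluster_id,
                   side = "control")) %>%
    dplyr::count(.data$cluster_id, .data$side) %>%
    dplyr::mutate(frequency = .data$n /
                    ifelse(.data$side == "case", sides$n_case,
                           sides$n_control))
  keep <- unique(freq$cluster_id[freq$frequency >= threshold])
  out <- table[table$cluster_id %in% keep, ]
  attr(out, "samples") <- attr(table, "samples")
  out
}

# Split a cluster table into case/control member rows and count samples per
# side; errors on empty sides.
comparison_sides <- function(table, groups, case, control) {
  case_ids <- groups$sample_id[groups$group %in% case]
  control_ids <- groups$sample_id[groups$group %in% control]
  if (length(case_ids) == 0 || length(control_ids) == 0) {
    abort("comparison group with 0 samples")
  }
  list(case_tbl = table[table$sample_id %in% case_ids, ],
       control_tbl = table[table$sample_id %in% control_ids, ],
       case_ids = case_ids, control_ids = control_ids,
       n_case = length(case_ids), n_control = length(control_ids))
}

#' Two-sided Wilcoxon rank-sum p-value (normal approximation)
#'
#' Mid-rank ties, tie-corrected variance and a continuity correction; the
#' two-sided p-value comes from the Gaussian approximation to the rank-sum
#' statistic. Undetected measurements coded 0 simply enter as the smallest
#' tied block, which a rank-based test handles without imputation. Because
#' the statistic depends on the pooled values only through their ranks, any
#' strictly monotone transform (such as log10 on the detected amplitudes)
#' leaves the p-value unchanged.
#'
#' @param case_values,control_values Numeric vectors (>= 2 values each;
#'   zeros allowed).
#' @return The two-sided p-value.
#' @export
rank_sum_test <- function(case_values, control_values) {
  n1 <- length(case_values)
  n2 <- length(control_values)
  if (n1 < 2 || n2 < 2) abort("each side needs >= 2 values")
  pooled <- c(case_values, control_values)
  r <- rank(pooled)
  n <- n1 + n2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(0, z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard false-discovery-rate step-up with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Signed regulation ratio between group means
#'
#' Upregulated clusters (case mean at least the control mean) report
#' `mean_case / mean_control`; downregulated clusters report
#' `-mean_control / mean_case`. The magnitude is therefore always >= 1 and
#' the sign carries the direction. Reported to one decimal by convention.
#'
#' @param mean_case,mean_control Group mean amplitudes (> 0); vectorized.
#' @param digits Decimal places for reporting (`NULL` for the exact value).
#' @return Signed fold change(s); `NA` with a warning when a mean is zero
#'   (infinite regulation).
#' @export
regulation_ratio <- function(mean_case, mean_control, digits = 1) {
  out <- ifelse(mean_case >= mean_control,
                mean_case / mean_control,
                -mean_control / mean_case)
  zero <- mean_case == 0 | mean_control == 0
  if (any(zero, na.rm = TRUE)) {
    warning("infinite regulation: a group mean is zero; returning NA")
    out[zero] <- NA_real_
  }
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Differential marker discovery on a clustered cohort
#'
#' Computes, per cluster, the detection frequencies and group mean
#' amplitudes (over detected values), the signed regulation ratio, the
#' rank-sum p-value with undetected samples entering as zeros, and the
#' Benjamini-Hochberg adjusted p-value across all tested clusters.
#' Candidates are the clusters with adjusted p at or below `fdr_threshold`.
#' The frequency filter is applied first.
#'
#' @inheritParams frequency_filter
#' @param fdr_threshold Benjamini-Hochberg significance threshold.
#' @param freq_threshold Detection-frequency threshold handed to
#'   [frequency_filter()] (`NULL` to skip, e.g. for a pre-filtered table).
#' @return A tibble of class `marker_stats`, sorted by adjusted p then
#'   descending absolute regulation: `cluster_id`, `mass`, `time`,
#'   `freq_case`, `freq_control`, `mean_case`, `mean_control`,
#'   `regulation`, `p_raw`, `p_bh`, `candidate`.
#' @export
discover_markers <- function(table, groups, case, control,
                             fdr_threshold = 0.10, freq_threshold = 0.60) {
  check_fraction(fdr_threshold, "fdr_threshold")
  if (!is.null(freq_threshold)) {
    table <- frequency_filter(table, groups, case, control, freq_threshold)
  }
  sides <- comparison_sides(table, groups, case, control)
  ids <- sort(unique(table$cluster_id))
  if (length(ids) == 0) {
    return(structure(tibble::tibble(), class = c("marker_stats",
                                                 "tbl_df", "tbl", "data.frame")))
  }
  meta <- table[!duplicated(table$cluster_id),
                c("cluster_id", "mass", "time")]
  stats <- purrr::map_dfr(ids, function(cid) {
    cc <- sides$case_tbl[sides$case_tbl$cluster_id == cid, ]
    kk <- sides$control_tbl[sides$control_tbl$cluster_id == cid, ]
    case_vals <- rep(0, sides$n_case)
    case_vals[match(cc$sample_id, sides$case_ids)] <- cc$amplitude
    ctrl_vals <- rep(0, sides$n_control)
    ctrl_vals[match(kk$sample_id, sides$control_ids)] <- kk$amplitude
    m_case <- if (nrow(cc)) mean(cc$amplitude) else 0
    m_ctrl <- if (nrow(kk)) mean(kk$amplitude) else 0
    tibble::tibble(
      cluster_id = cid,
      freq_case = nrow(cc) / sides$n_case,
      freq_control = nrow(kk) / sides$n_control,
      mean_case = m_case,
      mean_control = m_ctrl,
      regulation = if (m_case > 0 && m_ctrl > 0) {
        regulation_ratio(m_case, m_ctrl)
      } else NA_real_,
      p_raw = rank_sum_test(case_vals, ctrl_vals))
  })
  stats$p_bh <- bh_adjust(stats$p_raw)
  stats$candidate <- stats$p_bh <= fdr_threshold
  out <- dplyr::left_join(stats, meta, by = "cluster_id") %>%
    dplyr::relocate("mass", "time", .after = "cluster_id") %>%
    dplyr::arrange(.data$p_bh, dplyr::desc(abs(.data$regulation)))
  class(out) <- c("marker_stats", class(out))
  out
}

#' Intersect candidate lists from several comparisons
#'
#' Multi-comparison specificity screening (e.g. BPH vs PCa, BPH vs CP & HC,
#' BPH vs all) keeps the clusters that are candidates in every supplied
#' comparison.
#'
#' @param ... Two or more `marker_stats` tibbles.
#' @return Integer vector of cluster ids that are candidates in all lists.
#' @export
intersect_markers <- function(...) {
  lists <- list(...)
  if (length(lists) < 2) abort("need at least two marker lists")
  ids <- lapply(lists, function(m) m$cluster_id[m$candidate])
  Reduce(intersect, ids)
}

#' Write a marker report as TSV
#'
#' @param markers A `marker_stats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(markers, path) {
  readr::write_tsv(tibble::as_tibble(markers), path, progress = FALSE)
  invisible(path)
}
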