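# Shared pipeline runners for recovery simulations. Problem sizes are scaled
# to 400 background peptides so a multi-seed simulation stays fast; the
# planted effect sizes are the bundled reference marker table's.

suppressMessages({
  library(dplyr)
})

# Discovery-arm cohort: training-set group sizes, 21 planted markers at the
# reference effect sizes. Returns how many planted markers were recovered
# among the BH candidates, plus the candidate count.
run_discovery_recovery <- function(seed, n_background = 400) {
  cfg <- cohort_config(n_background_peptides = n_background,
                       planted_markers = reference_marker_config())
  coh <- generate_cohort(cfg, seed = seed)
  refs <- reference_set(coh$calibrants, coh$standards)
  norm <- normalize_amplitudes(calibrate_profiles(coh$peaks, refs), refs)
  tab <- filter_sporadic(cluster_profiles(norm), coh$samples)
  mk <- discover_markers(tab, coh$samples, case = "PCa",
                         control = c("BPH", "CP", "HC"))
  planted <- unique(coh$truth$markers[, c("mass", "time")])
  cand <- mk[mk$candidate, ]
  hits <- vapply(seq_len(nrow(planted)), function(i) {
    any(abs(cand$mass - planted$mass[i]) / planted$mass[i] * 1e6 < 60 &
          abs(cand$time - planted$time[i]) < 1)
  }, logical(1))
  list(recovered = sum(hits), n_planted = nrow(planted),
       n_candidates = nrow(cand))
}

# Planted-marker tibbles for the two-panel cohort: a 21-peptide signal
# separating prostate disease (PCa + BPH) from CP/HC, and a 5-peptide
# BPH-specific signal used to exclude PCa.
two_panel_markers <- function() {
  base21 <- reference_marker_config(case = "PCa", control = "BPH")
  m21 <- dplyr::bind_rows(
    base21 %>% dplyr::filter(.data$group == "PCa") %>%
      tidyr::crossing(g2 = c("PCa", "BPH")) %>%
      dplyr::mutate(group = .data$g2) %>% dplyr::select(-"g2"),
    base21 %>% dplyr::filter(.data$group == "BPH") %>%
      tidyr::crossing(g2 = c("CP", "HC")) %>%
      dplyr::mutate(group = .data$g2) %>% dplyr::select(-"g2"))
  m5 <- tibble::tibble(
    mass = c(1301.77, 1452.81, 1733.93, 2051.02, 2902.45),
    time = c(22.5, 27.8, 24.9, 31.2, 26.3)) %>%
    tidyr::crossing(group = c("PCa", "BPH", "CP", "HC")) %>%
    dplyr::mutate(log10_shift = ifelse(.data$group == "BPH", 0.6, 0),
                  det_freq = ifelse(.data$group == "BPH", 0.9, 0.7),
                  base_log10 = 2.6)
  list(m21 = m21, m5 = m5)
}

# Match planted coordinates to cluster ids in a clustered table.
match_planted_clusters <- function(table, coords) {
  cl <- dplyr::distinct(table, .data$cluster_id, .data$mass, .data$time)
  ids <- vapply(seq_len(nrow(coords)), function(i) {
    j <- which(abs(cl$mass - coords$mass[i]) / coords$mass[i] * 1e6 < 60 &
                 abs(cl$time - coords$time[i]) < 1)
    if (length(j)) cl$cluster_id[j[1]] else NA_integer_
  }, integer(1))
  ids[!is.na(ids)]
}

# Full two-panel experiment: generate the 125-sample cohort, calibrate,
# normalize, cluster, train both panels on the training split, apply the
# stepwise rule to the held-out test split, and evaluate PCa detection.
run_stepwise_experiment <- function(seed, n_background = 400) {
  mk <- two_panel_markers()
  cfg <- cohort_config(group_sizes = c(PCa = 70, BPH = 21, CP = 25, HC = 9),
                       n_background_peptides = n_background,
                       planted_markers = dplyr::bind_rows(mk$m21, mk$m5))
  coh <- generate_cohort(cfg, seed = seed)
  refs <- reference_set(coh$calibrants, coh$standards)
  norm <- normalize_amplitudes(calibrate_profiles(coh$peaks, refs), refs)
  tab <- cluster_profiles(norm)

  train_n <- c(PCa = 22, BPH = 9, CP = 14, HC = 5)
  tr_ids <- coh$samples %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$rank <= train_n[.data$group]) %>%
    dplyr::pull(.data$sample_id)
  train_meta <- coh$samples %>% dplyr::filter(.data$sample_id %in% tr_ids)
  test_meta <- coh$samples %>% dplyr::filter(!.data$sample_id %in% tr_ids)

  mem21 <- match_planted_clusters(tab, dplyr::distinct(mk$m21, .data$mass,
                                                       .data$time))
  mem5 <- match_planted_clusters(tab, dplyr::distinct(mk$m5, .data$mass,
                                                      .data$time))
  tr_tab <- tab %>% dplyr::filter(.data$sample_id %in% tr_ids)
  # panels can only use clusters observed in the training split
  mem21 <- intersect(mem21, unique(tr_tab$cluster_id))
  mem5 <- intersect(mem5, unique(tr_tab$cluster_id))
  p21 <- train_panel(tr_tab, train_meta, mem21,
                     positive = c("PCa", "BPH"), panel_id = "21PP")
  p5 <- train_panel(tr_tab, train_meta, mem5, positive = "BPH",
                    panel_id = "5PP")

  te_tab <- tab %>% dplyr::filter(.data$sample_id %in% test_meta$sample_id)
  s21 <- score_samples(p21, te_tab, test_meta$sample_id)
  s5 <- score_samples(p5, te_tab, test_meta$sample_id)
  pred <- stepwise_diagnose(s21$score, s5$score,
                            cutoff_21pp = p21$operating_threshold,
                            cutoff_5pp = p5$operating_threshold)
  truth <- ifelse(test_meta$group == "PCa", "PCa", "notPCa")
  cm <- confusion_metrics(ifelse(pred == "PCa", "PCa", "notPCa"), truth,
                          positive = "PCa")
  list(sensitivity = cm$sensitivity$estimate,
       specificity = cm$specificity$estimate,
       model_21pp = p21, model_5pp = p5,
       train_meta = train_meta, cohort = coh, table = tab)
}
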