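test_that("cohort generation is deterministic and matches requested design", {
  cfg <- cohort_config(n_background_peptides = 150)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$distortions, b$truth$distortions)

  # training-set composition: 22 PCa, 9 BPH, 14 CP, 5 HC
  expect_equal(nrow(a$samples), 50)
  expect_equal(as.integer(table(a$samples$group)[c("PCa", "BPH", "CP", "HC")]),
               c(22, 9, 14, 5))
  expect_equal(sort(unique(a$peaks$sample_id)), sort(a$samples$sample_id))

  c <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$peaks, c$peaks))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(group_sizes = c(5, 5)), "group_sizes")
  expect_error(cohort_config(mass_range = c(1000, 500)), "mass_range")
  expect_error(cohort_config(internal_standard_presence = 1.2),
               "internal_standard_presence")
  expect_error(cohort_config(missing_rate = -0.1), "missing_rate")
  expect_error(
    cohort_config(planted_markers = tibble::tibble(
      mass = 1000, time = 25, group = "PCa", log10_shift = 1,
      det_freq = 1.5)),
    "det_freq")
  expect_error(
    cohort_config(planted_markers = tibble::tibble(
      mass = 1000, time = 25, group = "XX", log10_shift = 1,
      det_freq = 0.9)),
    "unknown group")
})

test_that("peaks respect configured coordinate ranges and conservation", {
  cfg <- cohort_config(n_background_peptides = 300)
  coh <- generate_cohort(cfg, seed = 3)
  # true coordinates stay inside the configured ranges; observed ones can
  # drift only by the configured distortion scale
  expect_true(all(coh$truth$slots$mass >= cfg$mass_range[1] - 1e-9))
  expect_true(all(coh$truth$slots$mass <= cfg$mass_range[2] + 1e-9))
  expect_true(all(coh$peaks$time > cfg$time_range[1] - 1.5))
  expect_true(all(coh$peaks$time < cfg$time_range[2] + 1.5))
  expect_true(all(coh$peaks$amplitude > 0))
  # one detection indicator per (sample, peptide slot)
  expect_false(any(duplicated(coh$peaks[, c("sample_id", "peak_id")])))
  n_slots <- nrow(coh$truth$slots)
  expect_lte(nrow(coh$peaks), n_slots * nrow(coh$samples))
})

test_that("internal standards are near-ubiquitous and calibrants complete", {
  coh <- generate_cohort(cohort_config(n_background_peptides = 300), seed = 5)
  n <- nrow(coh$samples)
  std_freq <- coh$peaks %>%
    dplyr::filter(.data$peak_id %in% coh$standards$peak_id) %>%
    dplyr::count(.data$peak_id) %>%
    dplyr::pull(.data$n) / n
  expect_gt(mean(std_freq), 0.93)
  cal_counts <- coh$peaks %>%
    dplyr::filter(.data$peak_id %in% coh$calibrants$peak_id) %>%
    dplyr::count(.data$peak_id) %>%
    dplyr::pull(.data$n)
  expect_true(all(cal_counts == n))
})

test_that("every planted marker occupies exactly one peptide slot", {
  pm <- reference_marker_config()
  coh <- generate_cohort(
    cohort_config(n_background_peptides = 200, planted_markers = pm),
    seed = 9)
  truth <- coh$truth$markers
  slots_per_marker <- truth %>%
    dplyr::distinct(.data$mass, .data$time, .data$peak_id) %>%
    dplyr::count(.data$mass, .data$time)
  expect_true(all(slots_per_marker$n == 1))
  expect_equal(length(unique(truth$peak_id)),
               nrow(dplyr::distinct(pm, .data$mass, .data$time)))
  # marker slots are never internal-standard slots
  expect_length(intersect(unique(truth$peak_id), coh$truth$standard_ids), 0)
})

test_that("planted fold changes are realized in group mean amplitudes", {
  # Monte-Carlo check: 10 markers at |log10 fold| in [0.4, 0.8], two groups
  # of 25; a marker counts as realized when the detected-value mean ratio is
  # within 25% of nominal. Frozen from a 20-seed oracle run of this exact
  # configuration.
  counts <- vapply(1:20, function(s) {
    set.seed(s + 1000)
    fc <- sample(c(-1, 1), 10, TRUE) * runif(10, 0.4, 0.8)
    pm <- purrr::map_dfr(1:10, function(i) {
      tibble::tibble(mass = 900 + 130 * i, time = 20 + 2 * i,
                     group = c("A", "B"),
                     log10_shift = c(max(fc[i], 0), max(-fc[i], 0)),
                     det_freq = 0.9, base_log10 = 2.5)
    })
    cfg <- cohort_config(group_sizes = c(A = 25, B = 25),
                         n_background_peptides = 100, planted_markers = pm)
    coh <- generate_cohort(cfg, seed = s)
    truth <- coh$truth$markers
    ok <- vapply(unique(truth$peak_id), function(pid) {
      sub <- coh$peaks %>%
        dplyr::filter(.data$peak_id == pid) %>%
        dplyr::left_join(coh$samples, by = "sample_id") %>%
        dplyr::group_by(.data$group) %>%
        dplyr::summarise(m = mean(.data$amplitude), .groups = "drop")
      shift <- truth$log10_shift[truth$peak_id == pid &
                                   truth$log10_shift != 0][1]
      abs(max(sub$m) / min(sub$m) / 10^abs(shift) - 1) < 0.25
    }, logical(1))
    sum(ok)
  }, numeric(1))
  expect_gte(sum(counts >= 8), 15)
  expect_gte(mean(counts), 8)
})

test_that("replicate series reproduce and perturb a profile as configured", {
  coh <- generate_cohort(cohort_config(n_background_peptides = 100), seed = 2)
  one <- coh$peaks[coh$peaks$sample_id == coh$samples$sample_id[1], ]

  expect_error(generate_replicate_series(one, n = 1), "n must be >= 2")
  expect_error(generate_replicate_series(coh$peaks, n = 3), "one sample")

  # zero drift, zero noise: identical copies
  reps <- generate_replicate_series(one, n = 14, drift_per_step = 0,
                                    noise_sd = 0, seed = 1)
  expect_equal(length(unique(reps$sample_id)), 14)
  amp_by_rep <- split(reps$amplitude, reps$replicate)
  for (i in 2:14) expect_equal(amp_by_rep[[i]], amp_by_rep[[1]])

  # configured negative drift on selected peaks recovers a negative slope
  targets <- unique(one$peak_id)[1:10]
  reps <- generate_replicate_series(one, n = 14, drift_per_step = -0.05,
                                    noise_sd = 0.01, seed = 4,
                                    drift_peaks = targets)
  drift_mean <- reps %>%
    dplyr::filter(.data$peak_id %in% targets) %>%
    dplyr::group_by(.data$replicate) %>%
    dplyr::summarise(la = mean(log10(.data$amplitude)), .groups = "drop")
  slope <- coef(lm(la ~ replicate, data = drift_mean))[2]
  expect_lt(slope, 0)
  expect_equal(unname(slope), -0.05, tolerance = 0.2)
})
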