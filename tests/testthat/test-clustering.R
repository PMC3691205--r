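test_that("mass tolerance switches regimes strictly at the small-mass limit", {
  expect_equal(mass_tolerance(1000), 50)
  expect_equal(mass_tolerance(10000), 75)
  expect_equal(mass_tolerance(4000), 75)
  expect_equal(mass_tolerance(3999.999), 50)
  expect_error(mass_tolerance(-5))
})

test_that("time window fraction interpolates linearly and clamps", {
  expect_equal(time_window_fraction(19), 0.02)
  expect_equal(time_window_fraction(45), 0.05)
  expect_equal(time_window_fraction(32), 0.035)
  expect_equal(time_window_fraction(10), 0.02)
  expect_equal(time_window_fraction(60), 0.05)
})

test_that("identical samples cluster pairwise; empty input stays empty", {
  one <- tibble::tibble(sample_id = "A", peak_id = 1:20,
                        mass = seq(900, 4700, by = 200),
                        time = seq(20, 43, length.out = 20),
                        amplitude = 10^runif(20, 2, 4))
  two <- dplyr::mutate(one, sample_id = "B")
  tab <- cluster_profiles(dplyr::bind_rows(one, two))
  sizes <- table(tab$cluster_id)
  expect_true(all(sizes == 2))
  expect_equal(length(sizes), 20)

  empty <- cluster_profiles(one[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("zero-jitter cohorts are recovered with no merge or split errors", {
  cfg <- cohort_config(n_background_peptides = 150,
                       amplitude_noise_sd = 0.1,
                       mass_jitter_ppm = 0, mass_noise_ppm = 0,
                       time_drift = list(offset_sd = 0, gain_sd = 0,
                                         noise_sd = 0))
  coh <- generate_cohort(cfg, seed = 17)
  tab <- cluster_profiles(coh$peaks)
  # each cluster contains exactly the peaks of one peptide slot
  map <- tab %>% dplyr::distinct(.data$cluster_id, .data$peak_id)
  expect_equal(nrow(map), length(unique(tab$cluster_id)))
  expect_equal(nrow(map), length(unique(coh$peaks$peak_id)))
  # and the planted group mean ratio is exact after clustering (planted
  # effect recovery at zero jitter happens at the amplitude level)
  expect_equal(sort(unique(tab$cluster_id)), seq_len(nrow(map)))
})

test_that("every input peak lands in exactly one cluster", {
  coh <- generate_cohort(cohort_config(n_background_peptides = 120), seed = 4)
  cal <- calibrate_profiles(coh$peaks, reference_set(coh$calibrants))
  tab <- cluster_profiles(cal)
  expect_equal(nrow(tab), nrow(cal))
  expect_identical(sort(paste(tab$sample_id, tab$peak_id)),
                   sort(paste(cal$sample_id, cal$peak_id)))
})

test_that("all members satisfy the tolerance tests against their seed", {
  # the frozen consensus during assignment is the seed peak (the cluster's
  # highest-amplitude member), so the tolerance invariant is checkable post
  # hoc against that member's coordinates
  coh <- generate_cohort(cohort_config(n_background_peptides = 150), seed = 23)
  cal <- calibrate_profiles(coh$peaks, reference_set(coh$calibrants))
  tab <- cluster_profiles(cal)
  key <- match(paste(tab$sample_id, tab$peak_id),
               paste(cal$sample_id, cal$peak_id))
  obs <- dplyr::mutate(tab, obs_mass = cal$mass[key], obs_time = cal$time[key])
  bad <- obs %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::mutate(seed_mass = .data$obs_mass[which.max(.data$amplitude)],
                  seed_time = .data$obs_time[which.max(.data$amplitude)]) %>%
    dplyr::ungroup() %>%
    dplyr::filter(
      abs(.data$obs_mass - .data$seed_mass) / .data$seed_mass * 1e6 >
        mass_tolerance(.data$seed_mass) |
        abs(.data$obs_time - .data$seed_time) >
          time_window_fraction(.data$seed_time) * .data$seed_time / 2)
  expect_equal(nrow(bad), 0)
})

test_that("greedy clustering matches the all-pairs brute-force oracle", {
  for (seed in c(101, 202, 303, 404)) {
    inst <- separated_instance(seed)
    expect_lte(nrow(inst), 200)
    tab <- cluster_profiles(inst)
    oracle <- brute_cluster_oracle(inst)
    keys <- paste(inst$sample_id, inst$peak_id)
    keys_tab <- paste(tab$sample_id, tab$peak_id)
    sig_greedy <- partition_signature(keys_tab, tab$cluster_id)
    sig_oracle <- partition_signature(keys, oracle)
    expect_identical(sig_greedy, sig_oracle)
  }
})

test_that("the partition is invariant under sample relabelling", {
  inst <- separated_instance(55)
  tab1 <- cluster_profiles(inst)
  relabel <- setNames(sprintf("Z%02d", rev(seq_along(unique(inst$sample_id)))),
                      unique(inst$sample_id))
  inst2 <- dplyr::mutate(inst, sample_id = unname(relabel[.data$sample_id]))
  inst2 <- inst2[sample(nrow(inst2)), ]
  tab2 <- cluster_profiles(inst2)
  # compare via peak_id + original sample identity
  back <- setNames(names(relabel), relabel)
  sig1 <- partition_signature(paste(tab1$sample_id, tab1$peak_id),
                              tab1$cluster_id)
  sig2 <- partition_signature(paste(unname(back[tab2$sample_id]),
                                    tab2$peak_id), tab2$cluster_id)
  expect_identical(sig1, sig2)
})

test_that("sporadic clusters are removed at the more-than-6 boundary", {
  mk <- function(n_per_group) {
    purrr::imap_dfr(n_per_group, function(n, g) {
      if (n == 0) return(tibble::tibble())
      tibble::tibble(cluster_id = 1L, mass = 1000, time = 25,
                     sample_id = sprintf("%s%02d", g, seq_len(n)),
                     amplitude = 100)
    })
  }
  groups <- tibble::tibble(
    sample_id = c(sprintf("PCa%02d", 1:10), sprintf("BPH%02d", 1:10),
                  sprintf("CP%02d", 1:10), sprintf("HC%02d", 1:10)),
    group = rep(c("PCa", "BPH", "CP", "HC"), each = 10))

  kept <- filter_sporadic(mk(c(PCa = 7, BPH = 0, CP = 0, HC = 0)), groups)
  expect_equal(length(unique(kept$cluster_id)), 1)
  dropped <- filter_sporadic(mk(c(PCa = 6, BPH = 6, CP = 6, HC = 6)), groups)
  expect_equal(nrow(dropped), 0)
  empty <- filter_sporadic(mk(c(PCa = 7))[0, ], groups)
  expect_equal(nrow(empty), 0)
  expect_error(
    filter_sporadic(
      tibble::tibble(cluster_id = 1L, mass = 1, time = 1,
                     sample_id = "nope", amplitude = 1), groups),
    "unknown group")
})

test_that("a full-scale cohort yields a cluster count near the design size", {
  cfg <- cohort_config(group_sizes = c(PCa = 70, BPH = 21, CP = 25, HC = 9),
                       n_background_peptides = 1800)
  coh <- generate_cohort(cfg, seed = 2024)
  refs <- reference_set(coh$calibrants)
  cal <- calibrate_profiles(coh$peaks, refs)
  tab <- filter_sporadic(cluster_profiles(cal), coh$samples)
  n_clusters <- length(unique(tab$cluster_id))
  expect_gt(n_clusters, 1784 * 0.75)
  expect_lt(n_clusters, 1784 * 1.25)
})
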