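toy_table <- function(values, sample_ids, cluster_id = 1L) {
  tibble::tibble(cluster_id = cluster_id, mass = 1000 + cluster_id,
                 time = 25, sample_id = sample_ids, amplitude = values)
}

test_that("the two-point problem yields the closed-form max-margin solution", {
  # log10 amplitudes -1 and +1 around the center: boundary at 0 and unit
  # scores after population-SD standardization
  tab <- toy_table(c(10^1, 10^3), c("a", "b"))
  groups <- tibble::tibble(sample_id = c("a", "b"), group = c("neg", "pos"))
  m <- train_panel(tab, groups, members = 1L, positive = "pos")
  s <- score_samples(m, tab, c("a", "b"))
  expect_equal(s$score, c(-1, 1), tolerance = 1e-2)
  # a point on the hyperplane scores 0
  mid <- score_samples(m, toy_table(10^2, "m"), "m")
  expect_equal(mid$score, 0, tolerance = 1e-6)
})

test_that("a separable toy problem is classified correctly on both sides", {
  set.seed(42)
  n <- 10
  ids <- sprintf("s%02d", 1:(2 * n))
  tab <- dplyr::bind_rows(
    toy_table(10^rnorm(2 * n, rep(c(2, 4), each = n), 0.1), ids, 1L),
    toy_table(10^rnorm(2 * n, rep(c(4, 2), each = n), 0.1), ids, 2L))
  groups <- tibble::tibble(sample_id = ids,
                           group = rep(c("ctrl", "case"), each = n))
  m <- train_panel(tab, groups, members = c(1L, 2L), positive = "case")
  s <- score_samples(m, tab, ids)
  expect_true(all(s$score[groups$group == "case"] > 0))
  expect_true(all(s$score[groups$group == "ctrl"] < 0))
})

test_that("scores are invariant to rescaling of the hyperplane", {
  tab <- toy_table(c(10, 1000, 30, 700), c("a", "b", "c", "d"))
  groups <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                           group = c("n", "p", "n", "p"))
  m <- train_panel(tab, groups, members = 1L, positive = "p")
  s1 <- score_samples(m, tab)
  m2 <- m
  m2$weights <- m$weights * 7.5
  m2$offset <- m$offset * 7.5
  s2 <- score_samples(m2, tab)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("points symmetric about the hyperplane score with opposite sign", {
  set.seed(3)
  ids <- sprintf("s%02d", 1:12)
  tab <- dplyr::bind_rows(
    toy_table(10^rnorm(12, rep(c(2, 3.5), each = 6), 0.2), ids, 1L),
    toy_table(10^rnorm(12, rep(c(3.5, 2), each = 6), 0.2), ids, 2L))
  groups <- tibble::tibble(sample_id = ids,
                           group = rep(c("n", "p"), each = 6))
  m <- train_panel(tab, groups, members = c(1L, 2L), positive = "p")
  # reflect a probe feature vector across the hyperplane in scaled space
  x <- c(0.9, -0.4)
  w <- m$weights
  d <- sum(w * x) - m$offset
  x_ref <- x - 2 * d * w / sum(w^2)
  probe_amp <- function(z) 10^(z * m$scales + m$centers)
  tab_probe <- dplyr::bind_rows(
    toy_table(probe_amp(x)[1], "q1", 1L),
    toy_table(probe_amp(x)[2], "q1", 2L),
    toy_table(probe_amp(x_ref)[1], "q2", 1L),
    toy_table(probe_amp(x_ref)[2], "q2", 2L))
  s <- score_samples(m, tab_probe, c("q1", "q2"))
  expect_equal(s$score[1], -s$score[2], tolerance = 1e-9)
})

test_that("training validates labels and members", {
  tab <- toy_table(c(10, 20, 30), c("a", "b", "c"))
  one_class <- tibble::tibble(sample_id = c("a", "b", "c"),
                              group = c("p", "p", "p"))
  expect_error(train_panel(tab, one_class, 1L, positive = "p"),
               "single class")
  groups <- tibble::tibble(sample_id = c("a", "b", "c"),
                           group = c("p", "p", "n"))
  expect_error(train_panel(tab, groups, members = 99L, positive = "p"),
               "absent from table")
})

test_that("samples with undetected members are scored via pseudo-amplitudes", {
  set.seed(8)
  ids <- sprintf("s%02d", 1:10)
  tab <- toy_table(10^rnorm(10, rep(c(2, 4), each = 5), 0.2), ids)
  groups <- tibble::tibble(sample_id = ids, group = rep(c("n", "p"), each = 5))
  m <- train_panel(tab, groups, members = 1L, positive = "p")
  s <- score_samples(m, tab[0, ], sample_ids = "ghost")
  expect_true(is.finite(s$score))
  expect_lt(s$score, 0)  # imputed at half the minimum: firmly negative side
})

test_that("panel training on a planted discovery cohort reaches high AUC", {
  res <- run_stepwise_experiment(seed = 77)
  tr <- res$model_21pp$training_scores
  auc <- roc_auc(tr$score,
                 ifelse(tr$group %in% c("PCa", "BPH"), "pos", "neg"),
                 positive = "pos", n_boot = 0)
  expect_gte(auc$auc, 0.95)
})

test_that("cut-off arithmetic follows the precision rule", {
  expect_equal(derive_cutoff(0.30, 0.30, "subtract"), 0.00)
  expect_equal(derive_cutoff(1.00, 0.48, "add"), 1.48)
  expect_equal(derive_cutoff(0.7, 0, "add"), 0.7)
  expect_equal(derive_cutoff(0.7, 0, "subtract"), 0.7)
  expect_error(derive_cutoff(0.3, -0.1, "add"), "sd_precision")
})

test_that("the stepwise rule is total and matches the published reading", {
  expect_equal(stepwise_diagnose(0.50, 0.20), "PCa")
  expect_equal(stepwise_diagnose(-0.30, NA), "control")
  expect_equal(stepwise_diagnose(0.50, 2.00), "BPH")
  # boundary: scores at the cut-off are positive
  expect_equal(stepwise_diagnose(0.00, 1.48), "BPH")
  expect_equal(stepwise_diagnose(0.00, 1.47), "PCa")
  expect_error(stepwise_diagnose(0.5, NA), "missing second-panel")
  # totality over a grid
  grid <- expand.grid(s21 = seq(-2, 2, by = 0.5), s5 = seq(-2, 3, by = 0.5))
  labs <- stepwise_diagnose(grid$s21, grid$s5)
  expect_true(all(labs %in% c("PCa", "BPH", "control")))
  expect_length(labs, nrow(grid))
})

test_that("advanced-disease thresholding is inclusive at the cut-off", {
  expect_equal(classify_advanced(0.29), "indolent")
  expect_equal(classify_advanced(0.30), "advanced")
  expect_equal(classify_advanced(-1.0), "indolent")
})

test_that("panel models serialize to JSON and back without changing scores", {
  set.seed(4)
  ids <- sprintf("s%02d", 1:10)
  tab <- dplyr::bind_rows(
    toy_table(10^rnorm(10, rep(c(2, 4), each = 5), 0.3), ids, 1L),
    toy_table(10^rnorm(10, rep(c(3.5, 2.2), each = 5), 0.3), ids, 2L))
  groups <- tibble::tibble(sample_id = ids, group = rep(c("n", "p"), each = 5))
  m <- train_panel(tab, groups, members = c(1L, 2L), positive = "p",
                   panel_id = "toy")
  m <- set_panel_cutoff(m, sd_precision = 0.3, direction = "subtract")
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_model(m, path)
  m2 <- read_panel_model(path)
  expect_equal(score_samples(m2, tab)$score, score_samples(m, tab)$score,
               tolerance = 1e-9)
  expect_equal(m2$cutoff, m$cutoff)

  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_named(td, c("member", "weight", "center", "scale"))
  gl <- glance(m)
  expect_equal(gl$n_members, 2)
  expect_equal(gl$cutoff, m$cutoff)
})

test_that("replicate score noise propagates as predicted through the scorer", {
  # fixed panel, iid log10 noise eps on every member amplitude:
  # score SD = eps * sqrt(sum((w_j / s_j)^2)) / ||w||
  set.seed(10)
  members <- 1:4
  model <- structure(list(
    panel_id = "fixed", members = members,
    weights = setNames(c(1, -0.5, 2, 0.25), members),
    offset = 0.3,
    centers = setNames(rep(3, 4), members),
    scales = setNames(c(0.5, 1, 0.8, 0.3), members),
    pseudo = setNames(rep(1, 4), members),
    positive = "p", operating_threshold = 0, sd_precision = NA_real_,
    cutoff = NA_real_, score_range = c(-3, 3),
    training_scores = tibble::tibble()), class = "panel_model")
  eps <- 0.05
  n_rep <- 400
  tab <- tidyr::crossing(cluster_id = members,
                         sample_id = sprintf("r%03d", 1:n_rep)) %>%
    dplyr::mutate(mass = 1000, time = 25,
                  amplitude = 10^(3 + rnorm(dplyr::n(), 0, eps)))
  s <- score_samples(model, tab, sprintf("r%03d", 1:n_rep))
  w <- model$weights
  pred_sd <- eps * sqrt(sum((w / model$scales)^2)) / sqrt(sum(w^2))
  expect_equal(sd(s$score), pred_sd, tolerance = 0.15)
})
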