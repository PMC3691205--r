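# Feature construction shared by training and scoring: panel members as
# log10 amplitudes, with undetected cells replaced by a per-member
# pseudo-amplitude (half the smallest detected amplitude in training).
build_panel_features <- function(table, members, sample_ids,
                                 pseudo = NULL) {
  amp <- matrix(0, nrow = length(sample_ids), ncol = length(members),
                dimnames = list(sample_ids, as.character(members)))
  sub <- table[table$cluster_id %in% members &
                 table$sample_id %in% sample_ids, ]
  amp[cbind(match(sub$sample_id, sample_ids),
            match(sub$cluster_id, members))] <- sub$amplitude
  if (is.null(pseudo)) {
    pseudo <- apply(amp, 2, function(col) {
      det <- col[col > 0]
      if (length(det)) min(det) / 2 else 1
    })
  }
  la <- log10(sweep(amp, 2, pseudo, function(a, p) ifelse(a == 0, p, a)))
  list(features = la, pseudo = pseudo)
}

#' Train a maximal-margin biomarker panel classifier
#'
#' Fits a linear soft-margin support vector machine on the panel members'
#' log10 amplitudes (undetected values imputed as half the member's smallest
#' detected training amplitude, features centered and scaled by training
#' statistics). Classification scores are the signed Euclidean distance of a
#' sample to the maximal-margin hyperplane, positive toward the designated
#' positive class, so the score is invariant to any rescaling of the weight
#' vector. The default operating threshold is the midpoint between the
#' class median training scores; [set_panel_cutoff()] turns it into a
#' diagnostic cut-off using the analytical precision of the assay.
#'
#' @param table Long cluster table ([cluster_profiles()]).
#' @param groups Sample metadata tibble (`sample_id`, `group`) for the
#'   training samples.
#' @param members Cluster ids forming the panel; every member must be
#'   present in `table`.
#' @param positive Group label(s) forming the positive class.
#' @param panel_id Panel name (e.g. `"21PP"`).
#' @param cost Soft-margin regularization constant.
#' @param score_range Optional fixed score range `c(lo, hi)` used for
#'   coefficient-of-variation reporting; defaults to the training score
#'   range.
#' @return An object of class `panel_model`.
#' @export
train_panel <- function(table, groups, members, positive,
                        panel_id = "panel", cost = 1, score_range = NULL) {
  missing_members <- setdiff(members, unique(table$cluster_id))
  if (length(missing_members)) {
    abort(paste0("panel member(s) absent from table: ",
                 paste(missing_members, collapse = ", ")))
  }
  sample_ids <- groups$sample_id
  y <- factor(ifelse(groups$group %in% positive, "pos", "neg"),
              levels = c("neg", "pos"))
  if (length(unique(y)) < 2) abort("training labels contain a single class")

  feat <- build_panel_features(table, members, sample_ids)
  centers <- apply(feat$features, 2, mean)
  scales <- apply(feat$features, 2, pop_sd)
  scales[scales == 0] <- 1
  x <- scale(feat$features, center = centers, scale = scales)

  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  # libsvm decision values are positive toward the first training label
  if (fit$levels[fit$labels[1]] != "pos") {
    w <- -w
    rho <- -rho
  }
  wnorm <- sqrt(sum(w^2))
  scores <- drop(x %*% w - rho) / wnorm

  med_pos <- median(scores[y == "pos"])
  med_neg <- median(scores[y == "neg"])
  model <- structure(
    list(panel_id = panel_id,
         members = members,
         weights = w,
         offset = rho,
         centers = centers,
         scales = scales,
         pseudo = feat$pseudo,
         positive = positive,
         operating_threshold = (med_pos + med_neg) / 2,
         sd_precision = NA_real_,
         cutoff = NA_real_,
         score_range = score_range %||%
           range(scores),
         training_scores = tibble::tibble(sample_id = sample_ids,
                                          group = groups$group,
                                          score = unname(scores))),
    class = "panel_model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score samples with a trained panel
#'
#' Computes the signed Euclidean distance of each sample to the panel's
#' maximal-margin hyperplane (positive toward the positive class). Samples
#' missing panel members are scored with the training pseudo-amplitude for
#' those members, so a sample where no member was detected still receives a
#' score.
#'
#' @param model A [train_panel()] model.
#' @param table Long cluster table containing the samples to score.
#' @param sample_ids Samples to score; defaults to every sample in `table`.
#' @return A tibble of class `panel_scores`: `sample_id`, `score`; the
#'   panel id and cut-off travel as attributes.
#' @export
score_samples <- function(model, table, sample_ids = NULL) {
  stopifnot(inherits(model, "panel_model"))
  if (is.null(sample_ids)) {
    sample_ids <- attr(table, "samples") %||% sort(unique(table$sample_id))
  }
  feat <- build_panel_features(table, model$members, sample_ids,
                               pseudo = model$pseudo)
  x <- scale(feat$features, center = model$centers, scale = model$scales)
  wnorm <- sqrt(sum(model$weights^2))
  out <- tibble::tibble(
    sample_id = sample_ids,
    score = unname(drop(x %*% model$weights - model$offset) / wnorm))
  structure(out, panel_id = model$panel_id, cutoff = model$cutoff,
            class = c("panel_scores", class(out)))
}

#' @export
predict.panel_model <- function(object, table, sample_ids = NULL, ...) {
  score_samples(object, table, sample_ids)
}

#' Derive a diagnostic cut-off from analytical precision
#'
#' The cut-off shifts the operating threshold by one analytical-precision
#' standard deviation, up or down depending on which error direction must be
#' protected against. Under a Gaussian error model a 1-SD shift leaves less
#' than a 16% chance that a measurement whose true score equals the
#' threshold falls on the wrong side of the cut-off.
#'
#' @param operating_threshold Score threshold chosen on training data
#'   (a.u.).
#' @param sd_precision Analytical-precision standard deviation in a.u.
#'   (non-negative).
#' @param direction `"add"` or `"subtract"`.
#' @return The cut-off (a.u.).
#' @export
derive_cutoff <- function(operating_threshold, sd_precision,
                          direction = c("add", "subtract")) {
  direction <- match.arg(direction)
  if (sd_precision < 0) abort("sd_precision must be >= 0")
  if (direction == "add") operating_threshold + sd_precision
  else operating_threshold - sd_precision
}

#' Attach a precision-derived cut-off to a panel model
#'
#' @param model A [train_panel()] model.
#' @param sd_precision Analytical-precision SD (a.u.).
#' @param direction Passed to [derive_cutoff()].
#' @param operating_threshold Defaults to the model's stored threshold.
#' @return The updated `panel_model`.
#' @export
set_panel_cutoff <- function(model, sd_precision,
                             direction = c("add", "subtract"),
                             operating_threshold = model$operating_threshold) {
  direction <- match.arg(direction)
  model$sd_precision <- sd_precision
  model$operating_threshold <- operating_threshold
  model$cutoff <- derive_cutoff(operating_threshold, sd_precision, direction)
  model
}

#' Stepwise two-panel diagnosis
#'
#' Applies the two-step diagnostic rule: samples below the first panel's
#' cut-off are controls; samples at or above it are re-classified with the
#' second (BPH-exclusion) panel -- below its cut-off they are called PCa, at
#' or above it BPH. Every score pair maps to exactly one label.
#'
#' @param score_21pp,score_5pp Numeric score vectors (a.u.). `score_5pp`
#'   must be available for every sample at or above `cutoff_21pp`.
#' @param cutoff_21pp,cutoff_5pp Diagnostic cut-offs (a.u.).
#' @return Character vector of labels: `"PCa"`, `"BPH"`, or `"control"`.
#' @export
stepwise_diagnose <- function(score_21pp, score_5pp,
                              cutoff_21pp = 0.00, cutoff_5pp = 1.48) {
  pos1 <- score_21pp >= cutoff_21pp
  if (any(pos1 & is.na(score_5pp))) {
    abort("missing second-panel score for a first-panel-positive sample")
  }
  ifelse(!pos1, "control",
         ifelse(score_5pp < cutoff_5pp, "PCa", "BPH"))
}

#' Advanced-disease classification from a panel score
#'
#' @param score_11pp Numeric score vector (a.u.).
#' @param cutoff Cut-off; scores at or above it are called advanced.
#' @return Character vector: `"indolent"` or `"advanced"`.
#' @export
classify_advanced <- function(score_11pp, cutoff = 0.30) {
  ifelse(score_11pp >= cutoff, "advanced", "indolent")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("<panel_model> ", x$panel_id, "\n", sep = "")
  cat("  members:", length(x$members),
      " positive class:", paste(x$positive, collapse = "+"), "\n")
  cat(sprintf("  operating threshold: %.3f  sd(precision): %s  cutoff: %s\n",
              x$operating_threshold,
              ifelse(is.na(x$sd_precision), "unset",
                     sprintf("%.3f", x$sd_precision)),
              ifelse(is.na(x$cutoff), "unset", sprintf("%.3f", x$cutoff))))
  invisible(x)
}

#' @describeIn train_panel Per-member hyperplane weights (standardized
#'   feature space) as a tibble.
#' @param x A `panel_model`.
#' @param ... Unused.
#' @export
tidy.panel_model <- function(x, ...) {
  tibble::tibble(member = x$members,
                 weight = unname(x$weights),
                 center = unname(x$centers),
                 scale = unname(x$scales))
}

#' @describeIn train_panel One-row model summary.
#' @export
glance.panel_model <- function(x, ...) {
  tibble::tibble(panel_id = x$panel_id,
                 n_members = length(x$members),
                 positive = paste(x$positive, collapse = "+"),
                 operating_threshold = x$operating_threshold,
                 sd_precision = x$sd_precision,
                 cutoff = x$cutoff,
                 score_lo = x$score_range[1],
                 score_hi = x$score_range[2])
}

#' Serialize a panel model to a JSON text file
#'
#' @param model A `panel_model`.
#' @param path Output path.
#' @return `path` invisibly; `read_panel_model()` returns the model.
#' @export
write_panel_model <- function(model, path) {
  payload <- unclass(model)
  payload$training_scores <- as.list(model$training_scores)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_panel_model
#' @export
read_panel_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$members <- as.integer(raw$members)
  for (f in c("weights", "centers", "scales", "pseudo", "score_range")) {
    raw[[f]] <- as.numeric(raw[[f]])
  }
  names(raw$weights) <- names(raw$centers) <- names(raw$scales) <-
    names(raw$pseudo) <- as.character(raw$members)
  for (f in c("sd_precision", "cutoff", "operating_threshold")) {
    raw[[f]] <- if (is.null(raw[[f]])) NA_real_ else as.numeric(raw[[f]])
  }
  raw$training_scores <- tibble::as_tibble(raw$training_scores)
  structure(raw[c("panel_id", "members", "weights", "offset", "centers",
                  "scales", "pseudo", "positive", "operating_threshold",
                  "sd_precision", "cutoff", "score_range",
                  "training_scores")],
            class = "panel_model")
}
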