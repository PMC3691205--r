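#' Monoisotopic residue masses of the standard amino acids
#'
#' IUPAC monoisotopic residue masses (Da, 5 decimals) of the 20 standard
#' amino acids; a peptide's neutral monoisotopic mass is the residue sum
#' plus one water (18.010565 Da).
#'
#' @return Named numeric vector keyed by one-letter residue code.
#' @export
amino_acid_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
}

WATER_MONO <- 18.010565

# Known modification mass shifts (Da). `met_ox` also drives the lowercase-m
# sequence convention; `isotope_label` is the 15N + 5x13C proline label of
# the spiked calibrant peptides; `cterm_amide` their C-terminal amidation.
MOD_SHIFTS <- c(met_ox = 15.994915,
                cterm_amide = -0.984016,
                isotope_label = 6.013810)

#' Theoretical monoisotopic mass of a peptide
#'
#' Sums standard residue monoisotopic masses, adds one water, and applies
#' any modification shifts. Lowercase `m` in the sequence denotes oxidized
#' methionine (+15.994915 Da), the convention used in peptide sequencing
#' reports. Named modifications: `met_ox` (+15.994915), `cterm_amide`
#' (-0.984016), `isotope_label` (+6.013810, one 15N and five 13C in a
#' proline residue); a numeric modification vector is applied as given.
#'
#' @param sequence Character vector of peptide sequences over the 20
#'   standard residues (lowercase `m` allowed).
#' @param modifications Character vector of modification names, or a
#'   numeric vector of Da shifts, applied to every sequence.
#' @param digits Decimal places of the reported mass (default 3, matching
#'   reporting convention); `NULL` for the exact sum.
#' @return Numeric vector of monoisotopic masses (Da).
#' @export
monoisotopic_mass <- function(sequence, modifications = NULL, digits = 3) {
  aa <- amino_acid_masses()
  shift <- 0
  if (!is.null(modifications)) {
    if (is.character(modifications)) {
      unknown <- setdiff(modifications, names(MOD_SHIFTS))
      if (length(unknown)) {
        abort(paste0("unknown modification: ",
                     paste(unknown, collapse = ", ")))
      }
      shift <- sum(MOD_SHIFTS[modifications])
    } else {
      shift <- sum(modifications)
    }
  }
  out <- vapply(sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    n_ox <- sum(res == "m")
    res[res == "m"] <- "M"
    if (any(!res %in% names(aa))) {
      abort(paste0("unknown residue: ",
                   paste(unique(res[!res %in% names(aa)]), collapse = ", "),
                   " in sequence ", s))
    }
    sum(aa[res]) + WATER_MONO + n_ox * MOD_SHIFTS[["met_ox"]] + shift
  }, numeric(1), USE.NAMES = FALSE)
  if (!is.null(digits)) out <- round(out, digits) else out
}

#' Relative mass deviation in parts per million
#'
#' @param experimental,theoretical Masses in Da (`theoretical` > 0).
#' @param round Round to the nearest integer ppm (reporting convention).
#' @return `(experimental - theoretical) / theoretical * 1e6`.
#' @export
ppm_deviation <- function(experimental, theoretical, round = TRUE) {
  stopifnot(all(theoretical > 0))
  out <- (experimental - theoretical) / theoretical * 1e6
  if (round) round_half_up(out) else out
}

#' Number of basic residues in a peptide sequence
#'
#' Counts lysine, arginine and histidine; at the CE working pH (~2) the
#' peptide's positive charge -- and hence its migration time -- is governed
#' by these residues plus the N-terminus.
#'
#' @param sequence Character vector of sequences.
#' @return Integer vector of K/R/H counts.
#' @export
basic_residue_count <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    sum(strsplit(s, "")[[1]] %in% c("K", "R", "H"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Predict CE migration time from sequence composition
#'
#' Fits, over a set of calibrant peptides with known sequences and observed
#' migration times, a linear model of migration time on the effective
#' charge (basic residue count + 1 for the N-terminus) and log mass, and
#' predicts the migration time of each candidate sequence from the fitted
#' model.
#'
#' @param sequence Character vector of candidate sequences.
#' @param calibrants Tibble with columns `sequence` and `time` (observed
#'   migration time, min); at least 5 rows.
#' @return Numeric vector of predicted migration times (min).
#' @export
predict_migration_time <- function(sequence, calibrants) {
  calibrants <- tibble::as_tibble(calibrants)
  if (nrow(calibrants) < 5) {
    abort("need at least 5 calibrant peptides with observed times")
  }
  dat <- tibble::tibble(
    time = calibrants$time,
    charge = basic_residue_count(calibrants$sequence) + 1,
    log_mass = log(monoisotopic_mass(calibrants$sequence, digits = NULL)))
  fit <- lm(time ~ charge + log_mass, data = dat)
  new <- tibble::tibble(
    charge = basic_residue_count(sequence) + 1,
    log_mass = log(monoisotopic_mass(sequence, digits = NULL)))
  unname(predict(fit, newdata = new))
}

#' Validation parameters for peptide identifications
#'
#' @param max_ppm Maximum absolute mass deviation (ppm, strict).
#' @param max_time_dev Maximum absolute migration-time deviation (min,
#'   strict).
#' @return A list of class `validation_params`.
#' @export
validation_params <- function(max_ppm = 80, max_time_dev = 2) {
  check_positive(c(max_ppm, max_time_dev), "max_ppm/max_time_dev")
  structure(list(max_ppm = max_ppm, max_time_dev = max_time_dev),
            class = "validation_params")
}

#' Validate peptide sequence identifications
#'
#' A sequence candidate is accepted when its mass deviation is strictly
#' below the ppm bound and its observed migration time lies strictly within
#' the tolerance of the migration time predicted from its sequence.
#'
#' @param candidates Tibble with columns `ppm_deviation`,
#'   `experimental_time`, and `predicted_time`.
#' @param params A [validation_params()].
#' @return The input tibble with logical `accepted` and a `reasons` column
#'   (`""`, `"mass"`, `"time"`, or `"mass,time"`).
#' @export
validate_identification <- function(candidates, params = validation_params()) {
  stopifnot(inherits(params, "validation_params"))
  candidates <- tibble::as_tibble(candidates)
  bad_mass <- abs(candidates$ppm_deviation) >= params$max_ppm
  bad_time <- abs(candidates$experimental_time -
                    candidates$predicted_time) >= params$max_time_dev
  candidates$accepted <- !bad_mass & !bad_time
  candidates$reasons <- paste0(ifelse(bad_mass, "mass", ""),
                               ifelse(bad_mass & bad_time, ",", ""),
                               ifelse(bad_time, "time", ""))
  candidates
}

#' Net mass shift of a spiked calibrant peptide
#'
#' The spiked calibrants carry one 15N and five 13C isotopes in a proline
#' residue (+6.013810 Da) and an amidated C-terminus (-0.984016 Da); the
#' net shift rounds to +5 Da relative to the endogenous peptide.
#'
#' @return The net shift in Da.
#' @export
spike_mass_shift <- function() {
  unname(MOD_SHIFTS[["isotope_label"]] + MOD_SHIFTS[["cterm_amide"]])
}
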