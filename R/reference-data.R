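#' Reference seminal-plasma biomarker panel
#'
#' The published 21-peptide prostate-cancer marker panel from seminal
#' plasma CE-MS profiling: cluster id, consensus mass and migration time,
#' mean normalized amplitude in the cancer (PCa) and benign (BPH/HC)
#' training groups, the signed regulation ratio, and the raw and
#' Benjamini-Hochberg-adjusted Wilcoxon p-values. Two of the peptides are
#' also members of the 11-peptide advanced-disease panel (`in_11pp`).
#'
#' Used as a realistic effect-size catalogue for the synthetic cohort
#' generator (see [reference_marker_config()]) and as worked input for the
#' regulation-ratio arithmetic.
#'
#' @return A tibble with one row per marker peptide.
#' @export
seminal_marker_table <- function() {
  tbl <- tibble::tribble(
    ~cluster_id, ~mass,   ~time, ~mean_case, ~mean_control, ~regulation, ~p_wilcoxon, ~p_bh,
    3495,  1173.56, 25.9,   38,  100,  -2.7, 0.0012, 0.0926,
    3506,  1174.55, 26.1,  544,   77,   7.1, 0.0137, 0.0389,
    3621,  1186.45, 29.6,  281,   41,   6.8, 0.0022, 0.0926,
    3992,  1217.60, 23.4, 3770, 1412,   2.7, 0.0021, 0.0926,
    4437,  1254.56, 23.5,   92,   17,   5.3, 0.0022, 0.0926,
    4679,  1277.56, 29.6, 2600,  930,   2.8, 0.0021, 0.0926,
    4697,  1279.56, 21.6,   25,  252, -10.2, 0.0023, 0.0928,
    5180,  1328.64, 23.1,  299,  115,   2.6, 0.0024, 0.0962,
    6832,  1488.80, 24.2,   46,  280,  -6.0, 0.0023, 0.0928,
    7661,  1576.80, 30.3,  260,  911,  -3.5, 0.0023, 0.0928,
    8698,  1691.76, 20.9,  853, 1648,  -1.9, 0.0022, 0.0926,
    9483,  1779.92, 20.7,  398,  470,  -1.2, 0.0023, 0.0928,
    9645,  1797.95, 24.1,  644,   43,  14.9, 0.0025, 0.0926,
    10502, 1917.92, 20.1,  798, 1385,  -1.7, 0.0023, 0.0928,
    11899, 2139.08, 20.4, 1501, 2749,  -1.8, 0.0024, 0.0977,
    12083, 2167.12, 21.1,  257,  516,  -2.0, 0.0022, 0.0926,
    13995, 2461.29, 20.9,  243,  282,  -1.2, 0.0022, 0.0926,
    14592, 2556.29, 21.9,   34,  158,  -4.6, 0.0023, 0.0928,
    15331, 2670.40, 21.4, 1742, 6996,  -4.0, 0.0022, 0.0926,
    18990, 3266.65, 21.4, 2645,  451,   5.9, 0.0021, 0.0926,
    19773, 3400.52, 28.1,   10,   89,  -8.8, 0.0021, 0.0926)
  tbl$panel <- "21PP"
  tbl$in_11pp <- tbl$cluster_id %in% c(9483, 10502)
  tbl
}

#' Reference biomarker sequence annotations
#'
#' Sequenced seminal biomarker peptides: experimental CE-MS mass and
#' migration time, amino-acid sequence (lowercase `m` = oxidized
#' methionine), parent protein, UniProt accession, fragment boundaries, the
#' reported theoretical monoisotopic mass, and the reported ppm deviation
#' between experimental and theoretical mass.
#'
#' @return A tibble with one row per sequenced peptide.
#' @export
seminal_sequence_table <- function() {
  tibble::tribble(
    ~cluster_id, ~exp_mass, ~time, ~sequence, ~protein, ~uniprot, ~start, ~stop, ~theo_mass, ~ppm, ~direction,
    3506,  1174.55, 26.1, "LLAALMLVAmL",
    "N-acetyllactosaminide beta-1,3-N-acetylglucosaminyltransferase",
    "O43505", 15, 25, 1174.575, -21, "PCa up",
    4679,  1277.56, 29.6, "TELYFEKGEY",
    "Prostatic acid phosphatase", "P15309", 316, 325, 1277.582, -17, "PCa up",
    5650,  1372.71, 22.0, "LPNLLMRLEQm",
    "Stabilin-2", "Q8WWQ8", 1137, 1147, 1372.721, -4, "High risk up",
    7098,  1515.83, 22.9, "LSAPGPHAVLLVTQL",
    "GTPase IMAP family member 6", "Q6P9H5", 118, 132, 1515.817, 9,
    "BPH down",
    11899, 2139.08, 20.4, "TEELVANKQQRETKNSHQ",
    "Semenogelin-1", "P04279", 198, 215, 2139.067, 6, "PCa down",
    12083, 2167.12, 21.1, "TEELVVNKQQRETKNSHQ",
    "Semenogelin-2", "Q02383", 198, 215, 2167.098, 10, "PCa down",
    15331, 2670.40, 21.4, "YVLQTEELVVNKQQRETKNSHQ",
    "Semenogelin-2", "Q02383", 194, 215, 2670.373, 10, "PCa down",
    18990, 3266.65, 21.4, "SQTEEKAQGKSQKQITIPSQEQEHSQKAN",
    "Semenogelin-1", "P04279", 316, 344, 3266.613, 11, "PCa up")
}
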