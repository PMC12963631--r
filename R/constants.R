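# Shared amino-acid tables. All sequence arithmetic in the package is
# defined on the 20 canonical residues; 'X' is admitted only under the
# relaxed residue policy and contributes 0 to charge sums.

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Average residue masses (Da); water added once per chain.
AA_MASS_AVG <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
MASS_WATER <- 18.01524

# pKa tables used by the isoelectric-point bisection. Two published
# scales are pinned; the reported pI is their mean, per-table values are
# also returned. "positive" groups gain a proton below their pKa.
PKA_TABLES <- list(
  bjellqvist = list(
    nterm = 7.50, cterm = 3.55,
    K = 10.00, R = 12.00, H = 5.98,
    D = 4.05, E = 4.45, C = 9.00, Y = 10.00
  ),
  ipc_protein = list(
    nterm = 9.094, cterm = 2.869,
    K = 9.052, R = 11.84, H = 5.637,
    D = 3.872, E = 4.412, C = 7.555, Y = 10.85
  )
)

POSITIVE_AA <- c("K", "R", "H")
NEGATIVE_AA <- c("D", "E", "C", "Y")

#' Package configuration defaults
#'
#' Central knobs shared across modules: the residue policy ('strict'
#' rejects anything outside the 20 canonical letters; 'allow-x' admits
#' 'X' with zero charge and exclusion from GRAVY/aliphatic denominators),
#' the linker-detection alphabet, free-termini handling for pI, and the
#' alignment acceptance threshold used by the numbering engine.
#'
#' @param residue_policy "strict" or "allow-x".
#' @param linker_alphabet residue letters a detected interdomain linker
#'   may be built from.
#' @param min_linker_length linkers must be strictly longer than this.
#' @param free_termini include N/C terminal groups in pI.
#' @param score_threshold minimum alignment score as a fraction of a
#'   template's self-alignment score for a sequence to be accepted as a
#'   variable domain.
#' @return a named list of settings.
#' @export
forge_config <- function(residue_policy = c("strict", "allow-x"),
                         linker_alphabet = c("G", "S", "D", "E"),
                         min_linker_length = 6L,
                         free_termini = TRUE,
                         score_threshold = 0.30) {
  list(
    residue_policy = match.arg(residue_policy),
    linker_alphabet = linker_alphabet,
    min_linker_length = as.integer(min_linker_length),
    free_termini = isTRUE(free_termini),
    score_threshold = score_threshold
  )
}

aa_alphabet <- function(policy = "strict") {
  if (identical(policy, "allow-x")) c(AA_CANONICAL, "X") else AA_CANONICAL
}

check_residues <- function(seq, policy = "strict", what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet(policy))
  if (length(bad)) {
    stop(sprintf("disallowed residue '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(seq)
}

aa_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  tab <- table(factor(chars, levels = c(AA_CANONICAL, "X")))
  stats::setNames(as.integer(tab), names(tab))
}
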