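# Sequence physicochemistry: counting charge, pI, GRAVY, aliphatic mole
# percent and per-region charge summaries. The physiological-pH charge
# is deliberately the integer counting formula (K+R)-(D+E), not a
# Henderson-Hasselbalch evaluation: the solubility predictor downstream
# is calibrated on the counting formula.

#' Net charge at physiological pH (counting formula)
#'
#' Counts (K + R) - (D + E). Additive over concatenation and invariant
#' under residue reordering.
#'
#' @param seq amino-acid string, or a [seq_record].
#' @param policy residue policy, see [forge_config()].
#' @return integer net charge.
#' @examples
#' net_charge("GGGGDGGGGDGGGGDGGGGD")  # -4, the (G4D)4 linker
#' @export
net_charge <- function(seq, policy = "strict") {
  seq <- as_residues(seq)
  check_residues(seq, policy)
  n <- aa_counts(seq)
  as.integer((n[["K"]] + n[["R"]]) - (n[["D"]] + n[["E"]]))
}

#' Net charge at pH 5.5
#'
#' The counting formula with histidines protonated:
#' (K + R + H) - (D + E).
#'
#' @inheritParams net_charge
#' @return integer charge.
#' @export
charge_ph55 <- function(seq, policy = "strict") {
  seq <- as_residues(seq)
  check_residues(seq, policy)
  n <- aa_counts(seq)
  as.integer((n[["K"]] + n[["R"]] + n[["H"]]) - (n[["D"]] + n[["E"]]))
}

# Henderson-Hasselbalch total charge of a sequence at a given pH under
# one pKa table. Vectorised over ph.
hh_charge <- function(counts, ph, table, free_termini = TRUE) {
  pos_frac <- function(pka) 1 / (1 + 10^(ph - pka))
  neg_frac <- function(pka) -1 / (1 + 10^(pka - ph))
  total <- 0
  if (free_termini) {
    total <- total + pos_frac(table$nterm) + neg_frac(table$cterm)
  }
  for (aa in POSITIVE_AA) total <- total + counts[[aa]] * pos_frac(table[[aa]])
  for (aa in NEGATIVE_AA) total <- total + counts[[aa]] * neg_frac(table[[aa]])
  total
}

#' Isoelectric point
#'
#' Bisection on the Henderson-Hasselbalch total charge over pH 0-14 to
#' |charge| < 1e-4, run independently under each configured pKa table;
#' the reported pI is the mean across tables (per-table values are kept
#' as an attribute).
#'
#' @inheritParams net_charge
#' @param pka_tables named list of pKa tables (default: a
#'   Bjellqvist-style and an IPC-style table).
#' @param free_termini include free N/C termini as ionizable groups.
#' @return mean pI, with attribute `per_table`.
#' @export
isoelectric_point <- function(seq, pka_tables = PKA_TABLES,
                              free_termini = TRUE, policy = "strict") {
  seq <- as_residues(seq)
  check_residues(seq, policy)
  counts <- aa_counts(seq)
  n_ionizable <- sum(counts[c(POSITIVE_AA, NEGATIVE_AA)])
  if (n_ionizable == 0 && !free_termini) {
    stop("undefined pI: no ionizable groups and free termini disabled",
         call. = FALSE)
  }
  per <- vapply(pka_tables, function(tab) {
    lo <- 0; hi <- 14
    # charge is monotone decreasing in pH
    repeat {
      mid <- (lo + hi) / 2
      q <- hh_charge(counts, mid, tab, free_termini)
      if (abs(q) < 1e-4 || (hi - lo) < 1e-9) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
  }, numeric(1))
  structure(mean(per), per_table = per)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy per residue. Under the relaxed policy
#' 'X' residues are excluded from the denominator.
#'
#' @inheritParams net_charge
#' @return real GRAVY value.
#' @export
gravy <- function(seq, policy = "strict") {
  seq <- as_residues(seq)
  if (!nzchar(seq)) stop("GRAVY undefined on the empty sequence", call. = FALSE)
  check_residues(seq, policy)
  n <- aa_counts(seq)
  denom <- sum(n[AA_CANONICAL])
  if (denom == 0) stop("GRAVY undefined: no canonical residues", call. = FALSE)
  sum(n[AA_CANONICAL] * KYTE_DOOLITTLE[AA_CANONICAL]) / denom
}

#' Aliphatic mole percent
#'
#' 100 x (#A + #V + #I + #L) / length: the unweighted mole-percent form
#' (not the classical Ikai weighted index, which is available via
#' `weighted = TRUE`).
#'
#' @inheritParams net_charge
#' @param weighted if TRUE, use the classical Ikai weighting
#'   (A + 2.9 V + 3.9 (I + L)) instead of the plain mole percent.
#' @return value in \[0, 100\] (unweighted form).
#' @export
aliphatic_index <- function(seq, weighted = FALSE, policy = "strict") {
  seq <- as_residues(seq)
  if (!nzchar(seq)) stop("aliphatic index undefined on the empty sequence",
                         call. = FALSE)
  check_residues(seq, policy)
  n <- aa_counts(seq)
  denom <- if (identical(policy, "allow-x")) sum(n[AA_CANONICAL]) else sum(n)
  if (weighted) {
    return(100 * (n[["A"]] + 2.9 * n[["V"]] + 3.9 * (n[["I"]] + n[["L"]])) / denom)
  }
  100 * (n[["A"]] + n[["V"]] + n[["I"]] + n[["L"]]) / denom
}

#' Average peptide mass (Da)
#' @inheritParams net_charge
#' @return mass in Daltons using average residue masses.
#' @export
peptide_mass <- function(seq, policy = "strict") {
  seq <- as_residues(seq)
  check_residues(seq, policy)
  n <- aa_counts(seq)
  sum(n[AA_CANONICAL] * AA_MASS_AVG[AA_CANONICAL]) + MASS_WATER
}

#' Full physicochemical profile of a sequence
#'
#' @inheritParams net_charge
#' @return a one-row data.frame: length, net_charge, charge_ph55, pI,
#'   gravy, aliphatic_index, mass.
#' @export
physchem_profile <- function(seq, policy = "strict") {
  res <- as_residues(seq)
  data.frame(
    length = nchar(res),
    net_charge = net_charge(res, policy),
    charge_ph55 = charge_ph55(res, policy),
    pI = as.numeric(isoelectric_point(res, policy = policy)),
    gravy = gravy(res, policy),
    aliphatic_index = aliphatic_index(res, policy = policy),
    mass = peptide_mass(res, policy)
  )
}

#' Per-region charge summary for an Fv pair
#'
#' Integer counting charge per Chothia region (FR1-FR4, CDR1-CDR3) for
#' each chain, plus framework and CDR totals. framework_total +
#' cdr_total equals the domain net charge by construction.
#'
#' @param vl,vh region-labelled [numbered_domain] objects (see
#'   [segment_regions()]).
#' @return an object of class `region_charges`: per-chain named lists of
#'   region charges with `framework_total`, `cdr_total`, `domain_total`.
#' @export
region_charges <- function(vl, vh) {
  one <- function(dom) {
    if (is.null(dom$residues$region)) dom <- segment_regions(dom)
    regs <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
    chg <- vapply(regs, function(r) {
      aa <- dom$residues$aa[dom$residues$region == r]
      if (!length(aa)) return(0L)
      net_charge(paste(aa, collapse = ""))
    }, integer(1))
    fw <- sum(chg[c("FR1", "FR2", "FR3", "FR4")])
    cdr <- sum(chg[c("CDR1", "CDR2", "CDR3")])
    c(as.list(chg), list(framework_total = fw, cdr_total = cdr,
                         domain_total = fw + cdr))
  }
  structure(list(VL = one(vl), VH = one(vh)), class = "region_charges")
}

#' @export
print.region_charges <- function(x, ...) {
  for (ch in names(x)) {
    cat(sprintf("%s: framework %+d, CDR %+d, domain %+d\n", ch,
                x[[ch]]$framework_total, x[[ch]]$cdr_total,
                x[[ch]]$domain_total))
  }
  invisible(x)
}
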