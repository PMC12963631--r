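# Deterministic generators of synthetic test inputs: variable-domain
# pairs with controllable charge composition, mask-respecting design
# ensembles, noisy linear charge -> solubility datasets, and small
# annotated cohorts. Every generator is a pure function of its seed
# (global RNG state is saved and restored).

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

NEUTRAL_SUBS <- c("S", "G", "Y", "N", "T", "A", "Q")

# Positions of a segmented template domain eligible for substitution:
# not cysteine, not the salt bridge, not glycine/proline (scaffold),
# not within three residues of either terminus.
mutable_rows <- function(dom) {
  n <- nrow(dom$residues)
  sb <- SALT_BRIDGE[[if (dom$chain_type == "VH") "VH" else "VL"]]
  ok <- !(dom$residues$aa %in% c("C", "G", "P")) &
    !(dom$residues$num %in% sb & dom$residues$ins == "") &
    seq_len(n) > 3L & seq_len(n) <= n - 3L
  which(ok)
}

set_residue <- function(dom, row, aa) {
  dom$residues$aa[row] <- aa
  chars <- strsplit(dom$sequence, "", fixed = TRUE)[[1]]
  chars[row] <- aa
  dom$sequence <- paste(chars, collapse = "")
  dom
}

# Adjust the summed counting charge of the given rows to `target` by
# +/-1 substitutions (acidic->S / neutral->K to raise; basic->S /
# neutral->D to lower) at seeded-random positions.
adjust_region_charge <- function(dom, rows, target) {
  current <- function() {
    aa <- dom$residues$aa[rows]
    sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  }
  pool <- intersect(rows, mutable_rows(dom))
  pool <- pool[sample.int(length(pool))]   # seeded order
  for (row in pool) {
    delta <- target - current()
    if (delta == 0) break
    aa <- dom$residues$aa[row]
    if (delta > 0) {
      if (aa %in% c("D", "E")) dom <- set_residue(dom, row, "S")
      else if (!aa %in% c("K", "R")) dom <- set_residue(dom, row, "K")
    } else {
      if (aa %in% c("K", "R")) dom <- set_residue(dom, row, "S")
      else if (!aa %in% c("D", "E")) dom <- set_residue(dom, row, "D")
    }
  }
  if (target - current() != 0) {
    stop(sprintf("unreachable target charge %+d for %s region (short by %+d)",
                 target, dom$chain_type, target - current()), call. = FALSE)
  }
  dom
}

region_rows <- function(dom, framework = TRUE) {
  if (is.null(dom$residues$region)) dom <- segment_regions(dom)
  fr <- dom$residues$region %in% c("FR1", "FR2", "FR3", "FR4")
  which(if (framework) fr else !fr)
}

#' Generate a synthetic paired Fv with controlled charge composition
#'
#' Starts from the embedded Chothia-numbered templates and substitutes
#' at eligible framework/CDR positions (never cysteines, the conserved
#' salt bridges, glycines/prolines or the three terminal residues of
#' either end) to hit requested per-region net charges. Defaults
#' emulate the repertoire polarity the analyses assume: VH framework
#' +3 / VH CDR -2, VL framework +1 / VL CDR 0, i.e. a paired-Fv net
#' charge of +2. A few neutral-for-neutral CDR substitutions
#' (`cdr_diversity`) decorrelate CDR loops across seeds without
#' touching charge.
#'
#' @param seed integer seed; identical configs give identical output.
#' @param vh_fr,vh_cdr,vl_fr,vl_cdr target net charge per region group.
#' @param target_charge optional total paired-Fv charge; when given it
#'   overrides the framework targets: CDR targets are applied, then
#'   framework positions of both chains are adjusted so the pair sums
#'   to `target_charge`.
#' @param light "VL-kappa" or "VL-lambda".
#' @param cdr_diversity number of neutral CDR substitutions per domain.
#' @return list(vl, vh): segmented `numbered_domain` objects; use
#'   `$sequence` or [as_fv_records()] for FASTA-ready records.
#' @export
generate_fv <- function(seed = 1L, vh_fr = 3L, vh_cdr = -2L,
                        vl_fr = 1L, vl_cdr = 0L, target_charge = NULL,
                        light = c("VL-kappa", "VL-lambda"),
                        cdr_diversity = 3L) {
  light <- match.arg(light)
  with_seed(seed, {
    vh <- segment_regions(number_domain(TEMPLATES[["VH"]]$sequence))
    vl <- segment_regions(number_domain(TEMPLATES[[light]]$sequence))

    diversify <- function(dom) {
      pool <- intersect(region_rows(dom, framework = FALSE), mutable_rows(dom))
      pool <- pool[dom$residues$aa[pool] %in% NEUTRAL_SUBS]
      take <- sample(pool, min(cdr_diversity, length(pool)))
      for (row in take) {
        dom <- set_residue(dom, row,
                           sample(setdiff(NEUTRAL_SUBS,
                                          dom$residues$aa[row]), 1))
      }
      dom
    }
    vh <- diversify(vh); vl <- diversify(vl)

    vh <- adjust_region_charge(vh, region_rows(vh, FALSE), vh_cdr)
    vl <- adjust_region_charge(vl, region_rows(vl, FALSE), vl_cdr)
    if (is.null(target_charge)) {
      vh <- adjust_region_charge(vh, region_rows(vh, TRUE), vh_fr)
      vl <- adjust_region_charge(vl, region_rows(vl, TRUE), vl_fr)
    } else {
      # split the framework budget between the chains
      fw_total <- as.integer(target_charge) - vh_cdr - vl_cdr
      vh_share <- fw_total %/% 2L + fw_total %% 2L
      vh <- adjust_region_charge(vh, region_rows(vh, TRUE), vh_share)
      vl <- adjust_region_charge(vl, region_rows(vl, TRUE),
                                 fw_total - vh_share)
    }
    list(vl = vl, vh = vh)
  })
}

#' Fv pair as FASTA-ready records
#' @param fv a [generate_fv()] result.
#' @param id base id; chains get `_VL`/`_VH` suffixes.
#' @return list of two [seq_record].
#' @export
as_fv_records <- function(fv, id = "fv") {
  list(seq_record(paste0(id, "_VL"), fv$vl$sequence),
       seq_record(paste0(id, "_VH"), fv$vh$sequence))
}

#' Generate a mask-respecting design ensemble
#'
#' Emulates an inverse-folding output: `n` candidate sequences of the
#' parent's length with substitutions only at non-fixed positions;
#' cysteines and salt-bridge residues are never touched, so every
#' candidate passes [validate_candidate()] by construction.
#'
#' Real inverse-folding models substitute particular positions
#' consistently across their output ensemble, so the generator first
#' draws a set of design positions (a `substitution_rate` fraction of
#' the eligible positions) and one replacement residue per position;
#' each candidate then adopts the replacement at a design position
#' with probability 0.8, keeps the parent residue with 0.1 and takes a
#' random other residue with 0.1. `charge_bias` in \[-1, 1\] sets the
#' probability that a replacement is charge-directed: negative bias
#' draws D/E, positive draws K/R.
#'
#' @param parent an assembled `scfv_construct`.
#' @param mask a [build_fixed_mask()] result for the parent.
#' @param n ensemble size.
#' @param substitution_rate fraction of eligible (non-fixed) positions
#'   redesigned (paper-scale redesigns change roughly 30% of non-fixed
#'   positions).
#' @param charge_bias charge direction of replacements, see above.
#' @param seed integer seed.
#' @return list of [seq_record] candidates (ids design_001, ...).
#' @export
generate_ensemble <- function(parent, mask, n = 100L,
                              substitution_rate = 0.3, charge_bias = 0,
                              seed = 1L) {
  map <- construct_index_map(parent)
  pchars <- strsplit(parent$sequence, "", fixed = TRUE)[[1]]
  sb <- unlist(construct_salt_bridge_indices(map))
  eligible <- setdiff(seq_along(pchars) - 1L,
                      c(mask$indices, which(pchars == "C") - 1L,
                        sb[!is.na(sb)]))
  with_seed(seed, {
    k_design <- round(substitution_rate * length(eligible))
    design_pos <- sort(eligible[sample.int(length(eligible))][seq_len(k_design)])
    replacement <- vapply(design_pos, function(i) {
      if (stats::runif(1) < abs(charge_bias)) {
        if (charge_bias < 0) sample(c("D", "E"), 1) else sample(c("K", "R"), 1)
      } else {
        sample(setdiff(AA_CANONICAL, c("C", pchars[i + 1L])), 1)
      }
    }, "")
    lapply(seq_len(n), function(k) {
      chars <- pchars
      for (j in seq_along(design_pos)) {
        i <- design_pos[j]
        u <- stats::runif(1)
        chars[i + 1L] <- if (u < 0.8) replacement[j]
          else if (u < 0.9) pchars[i + 1L]
          else sample(setdiff(AA_CANONICAL, "C"), 1)
      }
      seq_record(sprintf("design_%03d", k), paste(chars, collapse = ""),
                 description = sprintf("seed=%d rate=%g bias=%g",
                                       seed, substitution_rate, charge_bias))
    })
  })
}

#' Generate a noisy linear charge -> solubility dataset
#'
#' Integer net charges drawn uniformly over `charge_range`; percent
#' solubility is slope x charge + intercept + Gaussian(0, noise_sd),
#' truncated into \[0, 100\] (truncation, not resampling, so extreme
#' charge bins are slightly biased toward the interior).
#'
#' @param n number of points (>= 3); the reference experiment used 45.
#' @param slope,intercept true model (defaults: the package's
#'   predictor coefficients).
#' @param noise_sd Gaussian noise standard deviation (percent).
#' @param charge_range inclusive integer range of net charges; the
#'   reference relationship spans +3 to -20.
#' @param seed integer seed.
#' @return data.frame(net_charge, percent).
#' @export
generate_solubility_dataset <- function(n = 45L, slope = -4.6237,
                                        intercept = 8.2469, noise_sd = 10,
                                        charge_range = c(-20L, 3L),
                                        seed = 1L) {
  stopifnot(n >= 3)
  with_seed(seed, {
    charge <- sample(charge_range[1]:charge_range[2], n, replace = TRUE)
    pct <- slope * charge + intercept + stats::rnorm(n, 0, noise_sd)
    data.frame(net_charge = charge, percent = pmin(100, pmax(0, pct)))
  })
}

#' Generate an annotated synthetic cohort
#'
#' Builds paired-Fv records around [generate_fv()] with randomised
#' metadata flags and, optionally, CDR-identical isoform groups
#' differing only in framework charge (to exercise deduplication).
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param dup_groups number of CDR-isoform groups of size 2 included
#'   within `n`.
#' @param p_remove probability a record carries a disqualifying
#'   metadata flag (split across the filter categories).
#' @return a [cohort_records()] table.
#' @export
generate_cohort <- function(n = 20L, seed = 1L, dup_groups = 0L,
                            p_remove = 0.3) {
  with_seed(seed, {
    locs <- c("bacterial", "viral", "extracellular", "membrane")
    rows <- list()
    i <- 0L
    while (length(rows) < n) {
      i <- i + 1L
      base_seed <- seed * 1000L + i
      vh_cdr <- sample(-3:0, 1); vl_cdr <- sample(-1:1, 1)
      fv <- generate_fv(seed = base_seed,
                        vh_fr = sample(1:4, 1), vh_cdr = vh_cdr,
                        vl_fr = sample(0:2, 1), vl_cdr = vl_cdr)
      flagged <- stats::runif(1) < p_remove
      target_name <- sprintf("antigen_%02d", sample(1:10, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("rec_%03d", length(rows) + 1L),
        vl = fv$vl$sequence, vh = fv$vh$sequence,
        target_is_protein = !(flagged && stats::runif(1) < 0.25),
        target_location = if (flagged && stats::runif(1) < 0.5)
          sample(locs, 1) else "cytoplasmic",
        specificity_arity = if (flagged && stats::runif(1) < 0.3)
          sample(c("bi", "tri"), 1) else "mono",
        target_name = target_name,
        stringsAsFactors = FALSE)
      if (dup_groups > 0L && length(rows) <= 2L * dup_groups &&
          length(rows) %% 2L == 1L && length(rows) < n) {
        # CDR-identical isoform: same seed replays the same CDR draws
        # (diversity positions and CDR charge adjustments), while a
        # more positive framework target changes framework charge only
        iso_fv <- generate_fv(seed = base_seed, vh_fr = 5L,
                              vh_cdr = vh_cdr, vl_fr = 3L, vl_cdr = vl_cdr)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("rec_%03d", length(rows) + 1L),
          vl = iso_fv$vl$sequence, vh = iso_fv$vh$sequence,
          target_is_protein = TRUE, target_location = "cytoplasmic",
          specificity_arity = "mono", target_name = target_name,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows[seq_len(n)])
    class(df) <- c("cohort_records", "data.frame")
    df
  })
}
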