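# Inverse-folding support: fixed-position masks, candidate validation,
# charge-based ranking, and ensemble summaries (conservation,
# consensus, framework charge shift).

# Fixed Chothia ranges per mask mode (inclusive). cdr_only fixes the
# CDR loops alone; extended grows CDR1/FR2/CDR2 and CDR3 by flanking
# residues; production additionally fixes the domain-interface
# beta-strands and the interdomain linker.
MASK_MODES <- list(
  cdr_only = list(
    VL = list(c(24L, 34L), c(50L, 56L), c(89L, 97L)),
    VH = list(c(25L, 32L), c(52L, 56L), c(95L, 102L)),
    fix_linker = FALSE),
  extended = list(
    VL = list(c(24L, 36L), c(47L, 56L), c(86L, 97L)),
    VH = list(c(26L, 59L), c(91L, 105L)),
    fix_linker = FALSE),
  production = list(
    VL = list(c(24L, 56L), c(86L, 100L)),
    VH = list(c(26L, 56L), c(92L, 105L)),
    fix_linker = TRUE)
)

# Per-residue map of a construct's full sequence: 0-based index, part,
# chain class, Chothia label. Requires domains whose residues table
# matches their sequence exactly (true for assembled constructs).
construct_index_map <- function(construct) {
  stopifnot(inherits(construct, "scfv_construct"))
  rows <- list()
  off <- 0L
  add <- function(n, part, chain = NA_character_,
                  num = rep(NA_integer_, n), ins = rep("", n),
                  aa = rep(NA_character_, n)) {
    if (n == 0L) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      index = off + seq_len(n) - 1L, part = part, chain = chain,
      num = num, ins = ins, aa = aa, stringsAsFactors = FALSE)
    off <<- off + n
  }
  for (t in construct$n_tags) add(nchar(t$sequence), paste0("tag:", t$name))
  for (d in list(construct$domain1, NULL, construct$domain2)) {
    if (is.null(d)) { add(nchar(construct$linker$sequence), "linker"); next }
    if (nrow(d$residues) != nchar(d$sequence)) {
      stop("domain residue table does not cover its sequence; renumber first",
           call. = FALSE)
    }
    cls <- if (d$chain_type == "VH") "VH" else "VL"
    add(nchar(d$sequence), "domain", chain = cls,
        num = d$residues$num, ins = d$residues$ins, aa = d$residues$aa)
  }
  for (t in construct$c_tags) add(nchar(t$sequence), paste0("tag:", t$name))
  map <- do.call(rbind, rows)
  stopifnot(nrow(map) == nchar(construct$sequence))
  map
}

#' Build a fixed-position mask for inverse folding
#'
#' Resolves the mode's inclusive Chothia ranges to concrete 0-based
#' indices of the construct's full sequence. Insertion-coded residues
#' within a fixed range are fixed. Chothia numbers referenced by a
#' range but absent from the domain are skipped and recorded as
#' warnings.
#'
#' @param construct an assembled, numbered `scfv_construct`.
#' @param mode "cdr_only", "extended" or "production".
#' @return a `fixed_mask`: mode, ranges, fix_linker, `indices` (sorted
#'   0-based), per-part index sets, warnings.
#' @export
build_fixed_mask <- function(construct,
                             mode = c("production", "cdr_only", "extended")) {
  mode <- match.arg(mode)
  spec <- MASK_MODES[[mode]]
  map <- construct_index_map(construct)
  warnings <- character()
  fixed <- integer()
  for (cls in c("VL", "VH")) {
    dom <- map[!is.na(map$chain) & map$chain == cls, , drop = FALSE]
    for (rg in spec[[cls]]) {
      wanted <- rg[1]:rg[2]
      present <- unique(dom$num[dom$num %in% wanted])
      missing <- setdiff(wanted, present)
      if (length(missing)) {
        warnings <- c(warnings, sprintf(
          "%s Chothia %s absent from domain; skipped", cls,
          paste(missing, collapse = ",")))
      }
      fixed <- c(fixed, dom$index[dom$num %in% wanted])
    }
  }
  if (spec$fix_linker) fixed <- c(fixed, map$index[map$part == "linker"])
  structure(list(
    mode = mode,
    ranges = spec[c("VL", "VH")],
    fix_linker = spec$fix_linker,
    indices = sort(unique(fixed)),
    linker_indices = map$index[map$part == "linker"],
    chain_indices = list(VL = map$index[!is.na(map$chain) & map$chain == "VL"],
                         VH = map$index[!is.na(map$chain) & map$chain == "VH"]),
    warnings = warnings
  ), class = "fixed_mask")
}

#' @export
print.fixed_mask <- function(x, ...) {
  cat(sprintf("<fixed_mask %s: %d fixed positions%s>\n", x$mode,
              length(x$indices),
              if (x$fix_linker) " incl. linker" else ""))
  invisible(x)
}

#' Write a mask handoff file for external design tools
#'
#' JSON listing fixed 0-based indices and their Chothia labels.
#' @param mask a [build_fixed_mask()] result.
#' @param construct the construct the mask was built on.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_mask_json <- function(mask, construct, path) {
  map <- construct_index_map(construct)
  sel <- map[map$index %in% mask$indices, , drop = FALSE]
  label <- ifelse(is.na(sel$chain), sel$part,
                  paste0(sel$chain, " ", sel$num, sel$ins))
  jsonlite::write_json(list(
    mode = mask$mode, coordinate_system = "0-based indices; Chothia labels 1-based",
    fixed = data.frame(index = sel$index, label = label)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# salt-bridge indices (0-based) of a construct, from its index map
construct_salt_bridge_indices <- function(map) {
  out <- list()
  for (cls in c("VL", "VH")) {
    sb <- SALT_BRIDGE[[cls]]
    dom <- map[!is.na(map$chain) & map$chain == cls, , drop = FALSE]
    out[[cls]] <- c(
      basic = dom$index[dom$num == sb[["basic"]] & dom$ins == ""][1],
      acidic = dom$index[dom$num == sb[["acidic"]] & dom$ins == ""][1])
  }
  out
}

#' Validate one inverse-folding candidate against its parent
#'
#' Violations are recorded for (a) any change at a fixed position,
#' named by its Chothia label, (b) loss of any parent cysteine, and
#' (c) a broken framework salt bridge (VL 61/82, VH 66/86).
#'
#' @param parent an assembled, numbered `scfv_construct`.
#' @param candidate candidate sequence ([seq_record] or string) of the
#'   same length as the parent (inverse folding preserves backbone
#'   length; mismatch is a hard error).
#' @param mask a [build_fixed_mask()] result.
#' @param model_rank ordinal position in the generator's output.
#' @param model_score optional per-sequence generator score.
#' @return a `design_candidate`: id, sequence, model_rank, model_score,
#'   predicted_percent, net_charge, valid, violations.
#' @export
validate_candidate <- function(parent, candidate, mask,
                               model_rank = NA_integer_,
                               model_score = NA_real_) {
  seq <- as_residues(candidate)
  id <- if (inherits(candidate, "seq_record")) candidate$id else "candidate"
  if (nchar(seq) != nchar(parent$sequence)) {
    stop(sprintf("candidate length %d != parent length %d",
                 nchar(seq), nchar(parent$sequence)), call. = FALSE)
  }
  map <- construct_index_map(parent)
  pchars <- strsplit(parent$sequence, "", fixed = TRUE)[[1]]
  cchars <- strsplit(seq, "", fixed = TRUE)[[1]]
  violations <- character()

  changed_fixed <- intersect(which(pchars != cchars) - 1L, mask$indices)
  for (i in changed_fixed) {
    row <- map[map$index == i, ]
    lab <- if (!is.na(row$chain)) paste0(row$chain, " ", row$num, row$ins)
           else row$part
    violations <- c(violations, sprintf(
      "substitution %s%s%s at fixed position %s (index %d)",
      pchars[i + 1L], "", cchars[i + 1L], lab, i))
  }
  lost_cys <- which(pchars == "C" & cchars != "C") - 1L
  for (i in lost_cys) {
    violations <- c(violations,
                    sprintf("parent cysteine lost at index %d", i))
  }
  sb <- construct_salt_bridge_indices(map)
  for (cls in names(sb)) {
    b <- sb[[cls]][["basic"]]; a <- sb[[cls]][["acidic"]]
    if (is.na(b) || is.na(a)) next
    if (!(cchars[b + 1L] %in% c("K", "R")) || cchars[a + 1L] != "D") {
      violations <- c(violations, sprintf(
        "%s salt bridge %d-%d broken (%s/%s)", cls,
        SALT_BRIDGE[[cls]][["basic"]], SALT_BRIDGE[[cls]][["acidic"]],
        cchars[b + 1L], cchars[a + 1L]))
    }
  }
  charge <- net_charge(seq)
  structure(list(
    id = id, sequence = seq, model_rank = as.integer(model_rank),
    model_score = model_score, net_charge = charge,
    predicted_percent = predict_percent(charge),
    valid = length(violations) == 0L, violations = violations
  ), class = "design_candidate")
}

#' Rank validated design candidates
#'
#' Invalid candidates are excluded (kept in the `excluded` attribute).
#' Order: predicted percent solubility descending, ties broken by model
#' rank ascending, residual ties lexicographically by sequence — a
#' total, deterministic order.
#'
#' @param candidates list of `design_candidate` objects.
#' @param weights optional c(solubility, rank) weights selecting the
#'   blended-score alternative: candidates are then sorted by
#'   `w1 * percent - w2 * model_rank` descending. Default NULL =
#'   lexicographic rule.
#' @return ordered list of valid candidates with `$rank` assigned;
#'   attribute `excluded` holds the invalid ones.
#' @export
rank_candidates <- function(candidates, weights = NULL) {
  if (!length(candidates)) return(structure(list(), excluded = list()))
  valid <- Filter(function(c) isTRUE(c$valid), candidates)
  invalid <- Filter(function(c) !isTRUE(c$valid), candidates)
  if (length(valid)) {
    pct <- vapply(valid, `[[`, 0, "predicted_percent")
    mr <- vapply(valid, function(c) {
      r <- c$model_rank
      if (is.na(r)) Inf else as.numeric(r)
    }, 0)
    sq <- vapply(valid, `[[`, "", "sequence")
    ord <- if (is.null(weights)) {
      order(-pct, mr, sq)
    } else {
      order(-(weights[1] * pct - weights[2] * ifelse(is.finite(mr), mr, 0)),
            sq)
    }
    valid <- valid[ord]
    for (i in seq_along(valid)) valid[[i]]$rank <- i
  }
  structure(valid, excluded = invalid)
}

#' Summarise a design ensemble against its parent
#'
#' Per-position conservation (fraction of valid candidates matching the
#' parent), the modal consensus sequence (exact ties keep the parent
#' residue), fraction of non-fixed positions substituted in the
#' consensus per chain, and the framework net charge of parent versus
#' consensus.
#'
#' @param parent an assembled, numbered `scfv_construct`.
#' @param candidates list of `design_candidate` (or raw sequences,
#'   validated on the fly); at least one valid candidate required.
#' @param mask the [build_fixed_mask()] used at generation time.
#' @return an `ensemble_summary`: conservation (numeric vector),
#'   consensus, substituted_fraction (per chain), framework_charge
#'   (parent/consensus per chain), n_candidates.
#' @export
ensemble_summary <- function(parent, candidates, mask) {
  candidates <- lapply(candidates, function(c) {
    if (inherits(c, "design_candidate")) c
    else validate_candidate(parent, c, mask)
  })
  valid <- Filter(function(c) isTRUE(c$valid), candidates)
  if (!length(valid)) stop("no valid candidates in ensemble", call. = FALSE)
  seqs <- vapply(valid, `[[`, "", "sequence")
  L <- nchar(parent$sequence)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  pchars <- strsplit(parent$sequence, "", fixed = TRUE)[[1]]
  conservation <- colMeans(mat == matrix(pchars, nrow(mat), L, byrow = TRUE))

  consensus <- vapply(seq_len(L), function(j) {
    tab <- table(mat[, j])
    top <- names(tab)[tab == max(tab)]
    if (pchars[j] %in% top) pchars[j] else sort(top)[1]
  }, "")
  cons_seq <- paste(consensus, collapse = "")

  map <- construct_index_map(parent)
  subst <- vapply(c("VL", "VH"), function(cls) {
    idx <- setdiff(mask$chain_indices[[cls]], mask$indices)
    if (!length(idx)) return(NA_real_)
    mean(consensus[idx + 1L] != pchars[idx + 1L])
  }, 0)

  fw_charge <- lapply(c(VL = "VL", VH = "VH"), function(cls) {
    dom <- map[!is.na(map$chain) & map$chain == cls, , drop = FALSE]
    cdr <- default_region_map()[[cls]]
    in_cdr <- rep(FALSE, nrow(dom))
    for (rg in cdr) in_cdr <- in_cdr | (dom$num >= rg[1] & dom$num <= rg[2])
    fw_idx <- dom$index[!in_cdr]
    c(parent = net_charge(paste(pchars[fw_idx + 1L], collapse = "")),
      consensus = net_charge(paste(consensus[fw_idx + 1L], collapse = "")))
  })

  structure(list(
    n_candidates = length(valid),
    conservation = conservation,
    consensus = cons_seq,
    substituted_fraction = subst,
    framework_charge = fw_charge
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble of %d valid candidates\n", x$n_candidates))
  cat(sprintf("  mean conservation: %.3f\n", mean(x$conservation)))
  cat(sprintf("  non-fixed positions substituted in consensus: VL %.0f%%, VH %.0f%%\n",
              100 * x$substituted_fraction[["VL"]],
              100 * x$substituted_fraction[["VH"]]))
  for (cls in names(x$framework_charge)) {
    cat(sprintf("  %s framework charge: parent %+d -> consensus %+d\n", cls,
                x$framework_charge[[cls]][["parent"]],
                x$framework_charge[[cls]][["consensus"]]))
  }
  invisible(x)
}

#' Read an inverse-folding output ensemble from multi-FASTA
#'
#' One candidate per record; a `score=<x>` key in the header is parsed
#' as the generator's per-sequence score. Model rank is the ordinal
#' position in the file unless scores are present, in which case
#' candidates are ranked by score ascending (generator convention:
#' lower is better).
#'
#' @param path multi-FASTA of candidate sequences.
#' @param policy residue policy.
#' @return list of records with model_rank/model_score attached.
#' @export
read_ensemble_fasta <- function(path, policy = "strict") {
  recs <- read_fasta(path, policy = policy)
  scores <- vapply(recs, function(r) {
    m <- regmatches(r$description,
                    regexec("score=([-0-9.eE+]+)", r$description))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else NA_real_
  }, 0)
  ranks <- if (all(!is.na(scores))) rank(scores, ties.method = "first")
           else seq_along(recs)
  mapply(function(r, rk, sc) { r$model_rank <- rk; r$model_score <- sc; r },
         recs, ranks, scores, SIMPLIFY = FALSE)
}
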