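# Chothia numbering by template transfer.
#
# Three embedded Chothia-numbered templates (human germline frameworks:
# VH3-23 + JH4 for VH, IGKV1-39 + JK for VL-kappa, an IGLV1-40-style
# consensus + JL for VL-lambda) carry per-residue Chothia labels. A
# query is numbered by local affine alignment (BLOSUM62, gap open 10 /
# extend 1) against each template; the best-scoring template's labels
# transfer across matched columns, query insertions relative to the
# template receive insertion codes (a, b, c, ...). Acceptance requires
# the alignment score to exceed a fixed fraction of the template's
# self-alignment score, calibrated so shuffled/non-antibody sequences
# fail.

chothia_labels <- function(num, ins) data.frame(num = as.integer(num),
                                                ins = ins,
                                                stringsAsFactors = FALSE)

TEMPLATES <- local({
  vh_seq <- paste0(
    "EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAISGSGGSTYY",
    "ADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAKGYSSGFDYWGQGTLVTVSS")
  vh_lab <- chothia_labels(
    c(1:52, 52L, 53:82, 82L, 82L, 82L, 83:113),
    c(rep("", 52), "a", rep("", 30), "a", "b", "c", rep("", 31)))

  vk_seq <- paste0(
    "DIQMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIYAASSLQSGVPS",
    "RFSGSGSGTDFTLTISSLQPEDFATYYCQQSYSTPLTFGQGTKVEIK")
  vk_lab <- chothia_labels(1:107, rep("", 107))

  vl_seq <- paste0(
    "QSVLTQPPSVSGAPGQRVTISCTGSSSNIGAGYDVHWYQQLPGTAPKLLIYGNSNRPSGV",
    "PDRFSGSKSGTSASLAITGLQAEDEADYYCQSYDSSLSVFGGGTKLTVL")
  vl_lab <- chothia_labels(
    c(1:9, 11:27, 27L, 27L, 27L, 28:107),
    c(rep("", 26), "a", "b", "c", rep("", 80)))

  stopifnot(nchar(vh_seq) == nrow(vh_lab),
            nchar(vk_seq) == nrow(vk_lab),
            nchar(vl_seq) == nrow(vl_lab))
  list(
    `VH` = list(sequence = vh_seq, labels = vh_lab),
    `VL-kappa` = list(sequence = vk_seq, labels = vk_lab),
    `VL-lambda` = list(sequence = vl_seq, labels = vl_lab)
  )
})

#' Embedded Chothia-numbered templates
#'
#' @param chain_type one of "VH", "VL-kappa", "VL-lambda"; NULL returns
#'   all three.
#' @return a list with `sequence` and `labels` (data.frame num/ins).
#' @export
numbering_template <- function(chain_type = NULL) {
  if (is.null(chain_type)) return(TEMPLATES)
  tpl <- TEMPLATES[[chain_type]]
  if (is.null(tpl)) stop("unknown chain type: ", chain_type, call. = FALSE)
  tpl
}

.template_cache <- new.env(parent = emptyenv())

template_self_score <- function(chain_type) {
  key <- paste0("self_", chain_type)
  if (is.null(.template_cache[[key]])) {
    tpl <- TEMPLATES[[chain_type]]
    .template_cache[[key]] <- align_score(tpl$sequence, tpl$sequence)
  }
  .template_cache[[key]]
}

do_align <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
}

align_score <- function(pattern, subject) Biostrings::score(do_align(pattern, subject))

# Transfer template labels through one alignment. Returns NULL if the
# alignment is empty.
transfer_labels <- function(aln, labels, query) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  tpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  qpos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  q_start <- qpos + 1L
  out_num <- integer(0); out_ins <- character(0); out_aa <- character(0)
  last_num <- NA_integer_; last_ins <- ""
  for (i in seq_along(p)) {
    if (p[i] != "-" && s[i] != "-") {
      tpos <- tpos + 1L; qpos <- qpos + 1L
      out_num <- c(out_num, labels$num[tpos])
      out_ins <- c(out_ins, labels$ins[tpos])
      out_aa <- c(out_aa, s[i])
      last_num <- labels$num[tpos]; last_ins <- labels$ins[tpos]
    } else if (p[i] == "-") {           # insertion in the query
      qpos <- qpos + 1L
      nxt <- next_insertion_code(last_ins)
      out_num <- c(out_num, if (is.na(last_num)) 0L else last_num)
      out_ins <- c(out_ins, nxt)
      out_aa <- c(out_aa, s[i])
      last_ins <- nxt
    } else {                            # deletion relative to template
      tpos <- tpos + 1L
    }
  }
  if (!length(out_num)) return(NULL)
  list(residues = data.frame(num = out_num, ins = out_ins, aa = out_aa,
                             stringsAsFactors = FALSE),
       span = c(q_start - 1L, qpos),    # 0-based half-open
       sequence = substring(query, q_start, qpos))
}

next_insertion_code <- function(last_ins) {
  if (!nzchar(last_ins)) return("a")
  letters[match(last_ins, letters) + 1L]
}

#' Assign Chothia numbers to a variable-domain sequence
#'
#' @param seq amino-acid string (or [seq_record]) of a single variable
#'   domain, typically 80-150 residues.
#' @param config see [forge_config()]; `score_threshold` is the
#'   acceptance cut-off as a fraction of the best template's
#'   self-alignment score.
#' @return a `numbered_domain`: `chain_type`, `residues` (data.frame of
#'   Chothia num, insertion code, amino acid), `score`, `score_norm`,
#'   `source_span` (0-based half-open into the input) and `sequence`
#'   (the spanned residues).
#' @export
number_domain <- function(seq, config = forge_config()) {
  seq <- as_residues(seq)
  best <- best_domain_hit(seq)
  if (is.null(best) || best$score_norm < config$score_threshold) {
    stop(sprintf(
      "not a variable domain: best alignment (%s) scored %.2f of template self-score (threshold %.2f)",
      if (is.null(best)) "none" else best$chain_type,
      if (is.null(best)) 0 else best$score_norm, config$score_threshold),
      call. = FALSE)
  }
  best
}

best_domain_hit <- function(seq) {
  best <- NULL
  for (ct in names(TEMPLATES)) {
    tpl <- TEMPLATES[[ct]]
    aln <- do_align(tpl$sequence, seq)
    norm <- Biostrings::score(aln) / template_self_score(ct)
    if (is.null(best) || norm > best$score_norm) {
      tr <- transfer_labels(aln, tpl$labels, seq)
      if (is.null(tr)) next
      best <- structure(list(
        chain_type = ct,
        residues = tr$residues,
        score = Biostrings::score(aln),
        score_norm = norm,
        source_span = tr$span,
        sequence = tr$sequence
      ), class = "numbered_domain")
    }
  }
  best
}

#' @export
print.numbered_domain <- function(x, ...) {
  cat(sprintf("<numbered_domain %s, %d residues, span [%d,%d), score %.2f (%.2f of self)>\n",
              x$chain_type, nrow(x$residues), x$source_span[1],
              x$source_span[2], x$score, x$score_norm))
  invisible(x)
}

# Find up to `max_domains` non-overlapping variable domains in a
# sequence by repeated scan-and-mask. Returned in sequence order.
scan_domains <- function(seq, config = forge_config(), max_domains = 2L) {
  found <- list()
  masked <- seq
  for (k in seq_len(max_domains)) {
    hit <- best_domain_hit(masked)
    if (is.null(hit) || hit$score_norm < config$score_threshold) break
    # labels must be re-derived on the unmasked sequence? spans identical:
    hit$sequence <- substring(seq, hit$source_span[1] + 1L, hit$source_span[2])
    found[[length(found) + 1L]] <- hit
    masked <- paste0(
      substring(masked, 1L, hit$source_span[1]),
      strrep("X", hit$source_span[2] - hit$source_span[1]),
      substring(masked, hit$source_span[2] + 1L))
  }
  found[order(vapply(found, function(d) d$source_span[1], numeric(1)))]
}

#' Extract variable domains from a full-length chain or scFv
#'
#' Scans the input for variable-domain segments by template alignment,
#' discarding constant domains (the alignment cannot extend past the
#' FR4 end of a template). On an scFv input both domains are returned
#' via repeated scanning.
#'
#' @param seq full chain, Fv or scFv sequence (or [seq_record]).
#' @param config see [forge_config()].
#' @return a list of `numbered_domain` objects in sequence order (length
#'   1 for a single chain, 2 for an scFv/Fv pair).
#' @export
extract_fv <- function(seq, config = forge_config()) {
  seq <- as_residues(seq)
  doms <- scan_domains(seq, config = config, max_domains = 2L)
  if (!length(doms)) {
    stop("not an antibody: no variable domain found", call. = FALSE)
  }
  doms
}

#' Default Chothia CDR boundaries
#'
#' CDR ranges used throughout: VL 24-34, 50-56, 89-97 and VH 25-32,
#' 52-56, 95-102 (inclusive Chothia numbers). Framework regions tile
#' the remainder. The map is data and can be swapped.
#'
#' @return a list per chain class with CDR start/end pairs.
#' @export
default_region_map <- function() {
  list(
    VH = list(CDR1 = c(25L, 32L), CDR2 = c(52L, 56L), CDR3 = c(95L, 102L)),
    VL = list(CDR1 = c(24L, 34L), CDR2 = c(50L, 56L), CDR3 = c(89L, 97L))
  )
}

#' Label every residue of a numbered domain with its region
#'
#' Residues with insertion codes inherit the region of their base
#' Chothia number. Regions tile the domain: FR1 before CDR1, FR2/FR3
#' between CDRs, FR4 after CDR3.
#'
#' @param domain a [numbered_domain].
#' @param scheme region map, see [default_region_map()].
#' @return the domain with a `region` column added to `residues`.
#' @export
segment_regions <- function(domain, scheme = default_region_map()) {
  cls <- if (domain$chain_type == "VH") "VH" else "VL"
  cdr <- scheme[[cls]]
  num <- domain$residues$num
  region <- character(length(num))
  region[num < cdr$CDR1[1]] <- "FR1"
  region[num >= cdr$CDR1[1] & num <= cdr$CDR1[2]] <- "CDR1"
  region[num > cdr$CDR1[2] & num < cdr$CDR2[1]] <- "FR2"
  region[num >= cdr$CDR2[1] & num <= cdr$CDR2[2]] <- "CDR2"
  region[num > cdr$CDR2[2] & num < cdr$CDR3[1]] <- "FR3"
  region[num >= cdr$CDR3[1] & num <= cdr$CDR3[2]] <- "CDR3"
  region[num > cdr$CDR3[2]] <- "FR4"
  domain$residues$region <- region
  domain
}

#' Extract one region's sequence from a segmented domain
#' @param domain a segmented [numbered_domain].
#' @param region one of FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4.
#' @return the region's amino-acid string.
#' @export
region_sequence <- function(domain, region) {
  if (is.null(domain$residues$region)) domain <- segment_regions(domain)
  paste(domain$residues$aa[domain$residues$region == region], collapse = "")
}

#' Apply a position-addressed point mutation
#'
#' @param domain a [numbered_domain].
#' @param mutation either a string like "K20D" (wild type, Chothia
#'   number, replacement), or NULL if `position`/`wt`/`new` are given.
#' @param position Chothia number (integer).
#' @param wt expected wild-type residue at the position.
#' @param new replacement residue.
#' @param ins insertion code ("" for none).
#' @return the domain with the residue replaced; numbering unchanged.
#' @export
apply_mutation <- function(domain, mutation = NULL, position = NULL,
                           wt = NULL, new = NULL, ins = "") {
  if (!is.null(mutation)) {
    m <- regmatches(mutation,
                    regexec("^([A-Z])([0-9]+)([a-z]?)([A-Z])$", mutation))[[1]]
    if (length(m) != 5) stop("cannot parse mutation '", mutation, "'",
                             call. = FALSE)
    wt <- m[2]; position <- as.integer(m[3]); ins <- m[4]; new <- m[5]
  }
  idx <- which(domain$residues$num == position & domain$residues$ins == ins)
  if (!length(idx)) {
    stop(sprintf("no residue at Chothia position %d%s in this %s domain",
                 position, ins, domain$chain_type), call. = FALSE)
  }
  obs <- domain$residues$aa[idx]
  if (!identical(obs, wt)) {
    stop(sprintf("wild-type mismatch at Chothia %d%s: expected %s, found %s",
                 position, ins, wt, obs), call. = FALSE)
  }
  domain$residues$aa[idx] <- new
  chars <- strsplit(domain$sequence, "", fixed = TRUE)[[1]]
  chars[idx] <- new
  domain$sequence <- paste(chars, collapse = "")
  domain
}

# positions of the conserved inter-strand salt bridges, by chain class
SALT_BRIDGE <- list(VL = c(basic = 61L, acidic = 82L),
                    VH = c(basic = 66L, acidic = 86L))

residue_at <- function(domain, position, ins = "") {
  idx <- which(domain$residues$num == position & domain$residues$ins == ins)
  if (!length(idx)) NA_character_ else domain$residues$aa[idx]
}

#' Check the conserved framework salt bridges
#'
#' Flags whether VL Arg/Lys61-Asp82 and VH Arg/Lys66-Asp86 (Chothia
#' numbering) are intact: the basic position must hold K or R and the
#' acidic position D. Positions absent from a domain are reported as
#' absent (NA residues) and the bridge as broken.
#'
#' @param vl,vh [numbered_domain] objects.
#' @return a data.frame with one row per chain: chain, basic_pos,
#'   basic_aa, acidic_pos, acidic_aa, intact.
#' @export
salt_bridge_check <- function(vl, vh) {
  one <- function(domain, cls) {
    sb <- SALT_BRIDGE[[cls]]
    b <- residue_at(domain, sb[["basic"]])
    a <- residue_at(domain, sb[["acidic"]])
    data.frame(chain = cls, basic_pos = sb[["basic"]], basic_aa = b,
               acidic_pos = sb[["acidic"]], acidic_aa = a,
               intact = !is.na(b) && !is.na(a) && b %in% c("K", "R") &&
                 a == "D",
               stringsAsFactors = FALSE)
  }
  rbind(one(vl, "VL"), one(vh, "VH"))
}
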