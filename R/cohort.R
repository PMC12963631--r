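# Repertoire-scale analyses: record filtering, CDR-redundancy
# deduplication, linker surveys, and property histograms.

#' Construct a cohort record table
#'
#' Flat metadata contract: one row per paired-Fv record with columns
#' id, vl, vh (sequences), target_is_protein (logical),
#' target_location (cytoplasmic | extracellular | membrane | viral |
#' bacterial | undefined), specificity_arity (mono | bi | tri),
#' target_name.
#'
#' @param id,vl,vh,target_is_protein,target_location,specificity_arity,target_name
#'   column vectors, recycled to a common length.
#' @return a data.frame of class `cohort_records`.
#' @export
cohort_records <- function(id, vl, vh, target_is_protein = TRUE,
                           target_location = "cytoplasmic",
                           specificity_arity = "mono",
                           target_name = "target") {
  df <- data.frame(id = id, vl = toupper(vl), vh = toupper(vh),
                   target_is_protein = target_is_protein,
                   target_location = target_location,
                   specificity_arity = specificity_arity,
                   target_name = target_name,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate cohort record ids", call. = FALSE)
  class(df) <- c("cohort_records", "data.frame")
  df
}

# Annotate one record's chains; returns NULL on numbering failure.
annotate_record <- function(vl_seq, vh_seq, config = forge_config()) {
  tryCatch({
    vl <- segment_regions(number_domain(vl_seq, config))
    vh <- segment_regions(number_domain(vh_seq, config))
    list(vl = vl, vh = vh)
  }, error = function(e) NULL)
}

#' Default cohort filter rules
#'
#' Ordered as applied: non-protein targets, then bacterial, viral,
#' extracellular and membrane target locations, multispecific
#' antibodies, undefined targets, unusually long CDR loops, and
#' finally annotation failure (three CDRs and four framework regions
#' per domain must be assignable). "Unusually long" defaults to
#' CDR3 > 26 residues, other CDRs > 17.
#'
#' @param cdr3_max,cdr_max CDR length thresholds.
#' @param missing_metadata "exclude" removes records with missing
#'   metadata fields at the relevant rule; "pass" lets them through.
#' @return an ordered named list of rule settings.
#' @export
default_filter_rules <- function(cdr3_max = 26L, cdr_max = 17L,
                                 missing_metadata = c("exclude", "pass")) {
  list(order = c("non_protein", "bacterial", "viral", "extracellular",
                 "membrane", "multispecific", "undefined_target",
                 "long_cdr", "annotation_failure"),
       cdr3_max = cdr3_max, cdr_max = cdr_max,
       missing_metadata = match.arg(missing_metadata))
}

#' Filter a cohort
#'
#' A record is removed at the first failing rule (rules applied in the
#' configured order); the report counts removals per rule. Filtering
#' is idempotent.
#'
#' @param records a [cohort_records()] table.
#' @param rules see [default_filter_rules()].
#' @param config see [forge_config()].
#' @return list(kept, removed (with a `removed_by` column), report
#'   (named integer, one entry per rule)).
#' @export
filter_records <- function(records, rules = default_filter_rules(),
                           config = forge_config()) {
  excl_missing <- rules$missing_metadata == "exclude"
  fails <- function(rule, rec) {
    miss <- function(x) is.na(x) || (is.character(x) && !nzchar(x))
    switch(rule,
      non_protein = if (miss(rec$target_is_protein)) excl_missing
                    else !isTRUE(rec$target_is_protein),
      bacterial = identical(rec$target_location, "bacterial"),
      viral = identical(rec$target_location, "viral"),
      extracellular = identical(rec$target_location, "extracellular"),
      membrane = identical(rec$target_location, "membrane"),
      multispecific = if (miss(rec$specificity_arity)) excl_missing
                      else rec$specificity_arity %in% c("bi", "tri"),
      undefined_target = identical(rec$target_location, "undefined") ||
        (if (miss(rec$target_name)) excl_missing else FALSE),
      long_cdr = {
        ann <- annotate_record(rec$vl, rec$vh, config)
        if (is.null(ann)) FALSE   # handled by annotation_failure next
        else {
          lens <- unlist(lapply(ann, function(d) {
            vapply(c("CDR1", "CDR2", "CDR3"),
                   function(r) nchar(region_sequence(d, r)), 0L)
          }))
          any(lens[c("vl.CDR3", "vh.CDR3")] > rules$cdr3_max) ||
            any(lens[!names(lens) %in% c("vl.CDR3", "vh.CDR3")] > rules$cdr_max)
        }
      },
      annotation_failure = is.null(annotate_record(rec$vl, rec$vh, config)),
      stop("unknown filter rule: ", rule, call. = FALSE)
    )
  }
  removed_by <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    for (rule in rules$order) {
      if (isTRUE(fails(rule, rec))) { removed_by[i] <- rule; break }
    }
  }
  report <- stats::setNames(
    vapply(rules$order, function(r) sum(removed_by == r, na.rm = TRUE), 0L),
    rules$order)
  removed <- records[!is.na(removed_by), , drop = FALSE]
  if (nrow(removed)) removed$removed_by <- removed_by[!is.na(removed_by)]
  list(kept = records[is.na(removed_by), , drop = FALSE],
       removed = removed, report = report)
}

#' Deduplicate a cohort by CDR redundancy
#'
#' Records sharing all six CDR loop sequences (Chothia boundaries) are
#' isoforms; within each group the paired-Fv record with the lowest
#' net charge is kept (ties broken by lexicographically smallest id).
#' Records whose chains cannot be numbered are routed to a rejects
#' list.
#'
#' @param records a [cohort_records()] table.
#' @param config see [forge_config()].
#' @return list(kept, rejects, groups (cdr key per kept record)).
#' @export
dedup_by_cdr <- function(records, config = forge_config()) {
  keys <- character(nrow(records))
  charges <- integer(nrow(records))
  ok <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    ann <- annotate_record(records$vl[i], records$vh[i], config)
    if (is.null(ann)) next
    ok[i] <- TRUE
    keys[i] <- paste(
      vapply(c("CDR1", "CDR2", "CDR3"),
             function(r) region_sequence(ann$vl, r), ""),
      vapply(c("CDR1", "CDR2", "CDR3"),
             function(r) region_sequence(ann$vh, r), ""),
      collapse = "|")
    charges[i] <- net_charge(records$vl[i]) + net_charge(records$vh[i])
  }
  keep <- logical(nrow(records))
  for (k in unique(keys[ok])) {
    grp <- which(ok & keys == k)
    best <- grp[order(charges[grp], records$id[grp])][1]
    keep[best] <- TRUE
  }
  kept <- records[keep, , drop = FALSE]
  if (nrow(kept)) kept$fv_charge <- charges[keep]
  list(kept = kept,
       rejects = records[!ok, , drop = FALSE],
       groups = keys[keep])
}

#' Build a histogram with fixed-width bins
#'
#' Bins are inclusive-left, exclusive-right; edges are strictly
#' increasing and aligned to multiples of `width`.
#'
#' @param values numeric values.
#' @param width bin width (1 for integer charges, 0.1 for pI).
#' @return a `charge_histogram`: edges (length counts+1), counts,
#'   total.
#' @export
make_histogram <- function(values, width = 1) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    return(structure(list(edges = numeric(0), counts = integer(0),
                          total = 0L), class = "charge_histogram"))
  }
  lo <- floor(min(values) / width) * width
  hi <- floor(max(values) / width) * width + width
  edges <- seq(lo, hi, by = width)
  idx <- pmin(findInterval(values, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, counts = as.integer(counts),
                 total = length(values)), class = "charge_histogram")
}

#' @export
print.charge_histogram <- function(x, ...) {
  if (!x$total) { cat("<empty histogram>\n"); return(invisible(x)) }
  for (i in seq_along(x$counts)) {
    cat(sprintf("[%g, %g): %d\n", x$edges[i], x$edges[i + 1], x$counts[i]))
  }
  invisible(x)
}

#' Histogram as a data.frame (for report writers)
#' @param x a `charge_histogram`.
#' @return data.frame(bin_left, bin_right, count).
#' @export
histogram_table <- function(x) {
  data.frame(bin_left = x$edges[-length(x$edges)] %||% numeric(0),
             bin_right = x$edges[-1] %||% numeric(0),
             count = x$counts)
}

#' Survey interdomain linker charges across scFv records
#'
#' Each record is decomposed with [parse_scfv()]; records that do not
#' parse, or whose linker is not longer than six residues, are
#' rejected (and counted). Accepted linker net charges are binned into
#' an integer-width histogram.
#'
#' @param scfv_records list of [seq_record] scFv sequences.
#' @param tag_library tag library for decomposition.
#' @param config see [forge_config()].
#' @return list(histogram, accepted, rejected, reasons).
#' @export
linker_survey <- function(scfv_records, tag_library = scfvforge::tag_library(),
                          config = forge_config()) {
  charges <- integer(); reasons <- character()
  for (rec in scfv_records) {
    parts <- tryCatch(parse_scfv(rec, tag_library, config),
                      error = function(e) conditionMessage(e))
    if (is.character(parts)) { reasons <- c(reasons, parts); next }
    if (is.null(parts$domain2) ||
        nchar(parts$linker) <= config$min_linker_length) {
      reasons <- c(reasons, "linker absent or not longer than six residues")
      next
    }
    charges <- c(charges, net_charge(parts$linker))
  }
  list(histogram = make_histogram(charges, width = 1),
       accepted = length(charges), rejected = length(reasons),
       reasons = reasons)
}

#' Histogram of a physicochemical property across a cohort
#'
#' Deterministic binning: integer-width bins for charges, 0.1-pH bins
#' for pI.
#'
#' @param records a [cohort_records()] table.
#' @param property "net_charge", "pI", "framework_charge" or
#'   "cdr_charge".
#' @param chain "fv" (paired, concatenated), "VL" or "VH"; region
#'   charges require a single chain.
#' @param config see [forge_config()].
#' @return a `charge_histogram` (attribute `values` holds the raw
#'   per-record values).
#' @export
property_histogram <- function(records,
                               property = c("net_charge", "pI",
                                            "framework_charge", "cdr_charge"),
                               chain = c("fv", "VL", "VH"),
                               config = forge_config()) {
  property <- match.arg(property)
  chain <- match.arg(chain)
  if (property %in% c("framework_charge", "cdr_charge") && chain == "fv") {
    stop("region charges require chain = 'VL' or 'VH'", call. = FALSE)
  }
  vals <- vapply(seq_len(nrow(records)), function(i) {
    seq <- switch(chain, fv = paste0(records$vl[i], records$vh[i]),
                  VL = records$vl[i], VH = records$vh[i])
    switch(property,
      net_charge = as.numeric(net_charge(seq, config$residue_policy)),
      pI = as.numeric(isoelectric_point(seq, policy = config$residue_policy)),
      framework_charge = ,
      cdr_charge = {
        dom <- segment_regions(number_domain(seq, config))
        regs <- if (property == "framework_charge")
          c("FR1", "FR2", "FR3", "FR4") else c("CDR1", "CDR2", "CDR3")
        sum(vapply(regs, function(r) {
          s <- region_sequence(dom, r)
          if (nzchar(s)) net_charge(s) else 0L
        }, 0L))
      })
  }, 0)
  width <- if (property == "pI") 0.1 else 1
  h <- make_histogram(vals, width)
  attr(h, "values") <- vals
  h
}
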