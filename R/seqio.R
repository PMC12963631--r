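# Sequence I/O and scFv decomposition.

#' Construct a sequence record
#'
#' The unit all package I/O moves: an id, free-text description and an
#' uppercase amino-acid string.
#'
#' @param id short unique token (non-empty).
#' @param residues amino-acid string (uppercased on construction).
#' @param description free text.
#' @param policy residue policy, see [forge_config()].
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "", policy = "strict") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("record id must be a non-empty string", call. = FALSE)
  }
  residues <- toupper(residues)
  check_residues(residues, policy, what = sprintf("record '%s'", id))
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf(">%s%s\n%s\n", x$id,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              x$residues))
  invisible(x)
}

# Accept a seq_record or a bare string wherever residues are needed.
as_residues <- function(x) {
  if (inherits(x, "seq_record")) return(x$residues)
  if (inherits(x, "numbered_domain")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected a sequence string or seq_record", call. = FALSE)
}

#' Read a FASTA file into a list of records
#'
#' @param path FASTA file.
#' @param policy residue policy ('strict' or 'allow-x').
#' @param gaps "error" (default) rejects '-'/'.' characters, "strip"
#'   removes them.
#' @return list of [seq_record]; empty list for an empty file.
#' @export
read_fasta <- function(path, policy = "strict", gaps = c("error", "strip")) {
  gaps <- match.arg(gaps)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) return(list())
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) return(list())
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (gaps == "strip") seqs <- gsub("[-.]", "", seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate record id in ", path, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  mapply(function(i, s, d) seq_record(i, s, d, policy = policy),
         ids, seqs, descs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to FASTA (80-column wrap)
#'
#' Round trip with [read_fasta()] is the identity on valid records.
#'
#' @param records list of [seq_record].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    header <- paste0(">", r$id,
                     if (nzchar(r$description)) paste0(" ", r$description) else "")
    body <- gsub("(.{80})", "\\1\n", r$residues)
    c(header, strsplit(body, "\n", fixed = TRUE)[[1]])
  }))
  ok <- tryCatch({ writeLines(lines %||% character(), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write FASTA to ", path, call. = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tabular report
#'
#' TSV/CSV with a header row and stable column order, or JSON (array of
#' row objects).
#'
#' @param rows a data.frame.
#' @param path output file.
#' @param format "tsv", "csv" or "json".
#' @return invisibly, `path`.
#' @export
write_table <- function(rows, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  ok <- tryCatch({
    switch(format,
      tsv = utils::write.table(rows, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, fileEncoding = "UTF-8"),
      csv = utils::write.csv(rows, path, row.names = FALSE,
                             fileEncoding = "UTF-8"),
      json = jsonlite::write_json(rows, path, dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA)
    )
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write table to ", path, call. = FALSE)
  invisible(path)
}

#' Decompose an assembled scFv into its parts
#'
#' Identifies terminal fusion tags by exact match against a declared tag
#' library, locates the two variable domains by template alignment, and
#' takes the interdomain linker as the maximal run of residues from the
#' linker alphabet ({G,S,D,E} by default) of length > 6 lying between
#' the two numbering-positive domain segments. The concatenation of all
#' parts in order reproduces the input exactly.
#'
#' @param record a [seq_record] or sequence string.
#' @param tag_library list of tag specs (see [tag_library()]).
#' @param config see [forge_config()].
#' @return an object of class `construct_parts`: `n_tags`, `domain1`,
#'   `linker`, `domain2`, `c_tags` (tags as named character vectors,
#'   domains as [numbered_domain]).
#' @export
parse_scfv <- function(record, tag_library = scfvforge::tag_library(),
                       config = forge_config()) {
  full <- as_residues(record)
  id <- if (inherits(record, "seq_record")) record$id else "scfv"
  check_residues(full, config$residue_policy, what = id)

  tag_seqs <- vapply(tag_library, `[[`, "", "sequence")
  tag_names <- vapply(tag_library, `[[`, "", "name")
  # longest tags first so e.g. 3xFLAG wins over a shorter prefix tag
  ord <- order(-nchar(tag_seqs))
  tag_seqs <- tag_seqs[ord]; tag_names <- tag_names[ord]

  n_tags <- character(); c_tags <- character()
  core <- full
  repeat {
    hit <- which(startsWith(core, tag_seqs))
    if (!length(hit)) break
    i <- hit[1]
    n_tags <- c(n_tags, stats::setNames(tag_seqs[i], tag_names[i]))
    core <- substring(core, nchar(tag_seqs[i]) + 1L)
  }
  repeat {
    hit <- which(endsWith(core, tag_seqs))
    if (!length(hit)) break
    i <- hit[1]
    c_tags <- c(stats::setNames(tag_seqs[i], tag_names[i]), c_tags)
    core <- substring(core, 1L, nchar(core) - nchar(tag_seqs[i]))
  }

  doms <- scan_domains(core, config = config, max_domains = 2L)
  if (length(doms) == 0) {
    stop("not an antibody: no variable domain found in '", id, "'",
         call. = FALSE)
  }
  if (length(doms) == 1L) {
    d <- doms[[1]]
    parts <- structure(list(
      n_tags = n_tags, domain1 = d, linker = "", domain2 = NULL,
      c_tags = c_tags, sequence = full), class = "construct_parts")
    # single-domain (half-Fv) input: concatenation must still hold
    check_parts_concat(parts, core, n_tags, c_tags)
    return(parts)
  }

  d1 <- doms[[1]]; d2 <- doms[[2]]
  gap_start <- d1$source_span[2] + 1L        # 1-based position after domain1
  gap_end <- d2$source_span[1]               # 1-based position before domain2
  gap <- substring(core, gap_start, gap_end)

  runs <- linker_runs(gap, config$linker_alphabet)
  runs <- runs[runs$len > config$min_linker_length, , drop = FALSE]
  if (nrow(runs) == 0) {
    stop(sprintf("no linker (> %d residues of {%s}) found between domains of '%s'",
                 config$min_linker_length,
                 paste(config$linker_alphabet, collapse = ","), id),
         call. = FALSE)
  }
  if (nrow(runs) > 1) {
    spans <- paste(sprintf("[%d-%d]", gap_start - 1L + runs$start,
                           gap_start - 1L + runs$end), collapse = " and ")
    stop("ambiguous linker: two candidate runs at ", spans, " in '", id, "'",
         call. = FALSE)
  }
  lk_start <- gap_start - 1L + runs$start[1]
  lk_end <- gap_start - 1L + runs$end[1]
  linker <- substring(core, lk_start, lk_end)
  # residues of the gap outside the linker run belong to the domains
  seq1 <- substring(core, 1L, lk_start - 1L)
  seq2 <- substring(core, lk_end + 1L, nchar(core))

  parts <- structure(list(
    n_tags = n_tags,
    domain1 = structure(c(d1[setdiff(names(d1), "sequence")],
                          list(sequence = seq1)), class = "numbered_domain"),
    linker = linker,
    domain2 = structure(c(d2[setdiff(names(d2), "sequence")],
                          list(sequence = seq2)), class = "numbered_domain"),
    c_tags = c_tags,
    sequence = full
  ), class = "construct_parts")
  check_parts_concat(parts, core, n_tags, c_tags)
  parts
}

check_parts_concat <- function(parts, core, n_tags, c_tags) {
  rebuilt <- paste0(paste(n_tags, collapse = ""),
                    if (!is.null(parts$domain1)) parts$domain1$sequence else "",
                    parts$linker,
                    if (!is.null(parts$domain2)) parts$domain2$sequence else "",
                    paste(c_tags, collapse = ""))
  if (!identical(rebuilt, parts$sequence)) {
    stop("internal error: construct parts do not concatenate to the input",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Maximal runs of residues drawn from `alphabet` within a string.
linker_runs <- function(s, alphabet) {
  if (!nzchar(s)) return(data.frame(start = integer(), end = integer(),
                                    len = integer()))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  inA <- chars %in% alphabet
  r <- rle(inA)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

#' @export
print.construct_parts <- function(x, ...) {
  cat("scFv parts:\n")
  if (length(x$n_tags)) cat("  N-tags:", paste(names(x$n_tags), collapse = ", "), "\n")
  if (!is.null(x$domain1))
    cat(sprintf("  domain1: %s (%d aa)\n", x$domain1$chain_type,
                nchar(x$domain1$sequence)))
  if (nzchar(x$linker)) cat(sprintf("  linker: %s (%d aa, charge %+d)\n",
                                    x$linker, nchar(x$linker), net_charge(x$linker)))
  if (!is.null(x$domain2))
    cat(sprintf("  domain2: %s (%d aa)\n", x$domain2$chain_type,
                nchar(x$domain2$sequence)))
  if (length(x$c_tags)) cat("  C-tags:", paste(names(x$c_tags), collapse = ", "), "\n")
  invisible(x)
}
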