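# scFv assembly: linker and tag libraries, domain-orientation rule,
# charge budgeting toward a target solubility.

#' The charged interdomain linker library
#'
#' The (G4S)4 workhorse plus its electronegative derivatives: serine
#' replaced by aspartate/glutamate and shorter glycine spacings, tuning
#' linker charge from 0 to -10 while preserving flexibility.
#'
#' @return named list of linker specs (name, sequence, net_charge).
#' @export
linker_library <- function() {
  mk <- function(name, unit, reps) {
    s <- strrep(unit, reps)
    list(name = name, sequence = s, net_charge = net_charge(s))
  }
  specs <- list(
    mk("(G4S)4", "GGGGS", 4),
    mk("(G4D)4", "GGGGD", 4),
    mk("(G4E)4", "GGGGE", 4),
    mk("(G2D)7", "GGD", 7),
    mk("(G2E)7", "GGE", 7),
    mk("(GD)10", "GD", 10),
    mk("(GE)10", "GE", 10)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' The epitope-tag library
#'
#' HA, 3xFLAG and myc with their counting net charges (computed from
#' sequence, never hardcoded): HA -2, 3xFLAG -7, myc -3. 3xFLAG + HA
#' together contribute -9. Default placement: 3xFLAG at the
#' N-terminus, HA at the C-terminus.
#'
#' @return named list of tag specs (name, sequence, terminus,
#'   net_charge).
#' @export
tag_library <- function() {
  mk <- function(name, seq, terminus) {
    list(name = name, sequence = seq, terminus = terminus,
         net_charge = net_charge(seq))
  }
  specs <- list(
    mk("3xFLAG", "DYKDHDGDYKDHDIDYKDDDDK", "N"),
    mk("HA", "YPYDVPDYA", "C"),
    mk("myc", "EQKLISEEDL", "C")
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Choose the scFv domain order
#'
#' VLVH is the reliability default: VHVL constructs whose VH domain
#' carries positive net charge have reduced solubility, because a
#' positively charged VH translated first lacks the chaperoning VL.
#' An explicit VHVL request is honoured, with a solubility-risk
#' warning attached when the VH charge is positive.
#'
#' @param vh_charge integer net charge of the VH domain.
#' @param requested "auto", "VLVH" or "VHVL".
#' @return list(orientation, warnings).
#' @export
choose_orientation <- function(vh_charge,
                               requested = c("auto", "VLVH", "VHVL")) {
  requested <- match.arg(requested)
  warnings <- character()
  orientation <- if (requested == "auto") "VLVH" else requested
  if (orientation == "VHVL" && vh_charge > 0) {
    warnings <- sprintf(
      "VHVL orientation with positively charged VH (%+d): expect reduced solubility relative to VLVH",
      vh_charge)
  }
  list(orientation = orientation, warnings = warnings)
}

#' Assemble an scFv construct from parts
#'
#' Concatenates N-tags, first domain, linker, second domain, C-tags.
#' The construct's net charge is the sum of its parts' charges.
#'
#' @param vl,vh [numbered_domain] objects (or sequence strings, which
#'   are numbered first).
#' @param linker a linker spec from [linker_library()], a name in that
#'   library, or a raw sequence string.
#' @param tags list of tag specs (or names in [tag_library()]); each is
#'   placed at its declared terminus.
#' @param orientation "auto" (= VLVH), "VLVH" or "VHVL".
#' @param config see [forge_config()].
#' @return an `scfv_construct`: orientation, n_tags, domain1, linker,
#'   domain2, c_tags, sequence, net_charge, warnings.
#' @export
assemble_scfv <- function(vl, vh, linker = linker_library()[["(G4D)4"]],
                          tags = list(),
                          orientation = c("auto", "VLVH", "VHVL"),
                          config = forge_config()) {
  orientation <- match.arg(orientation)
  if (!inherits(vl, "numbered_domain")) vl <- number_domain(vl, config)
  if (!inherits(vh, "numbered_domain")) vh <- number_domain(vh, config)
  if (is.character(linker) && length(linker) == 1L) {
    linker <- if (linker %in% names(linker_library())) {
      linker_library()[[linker]]
    } else {
      list(name = "custom", sequence = toupper(linker),
           net_charge = net_charge(linker))
    }
  }
  tags <- lapply(tags, function(t) {
    if (is.character(t)) {
      spec <- tag_library()[[t]]
      if (is.null(spec)) stop("unknown tag: ", t, call. = FALSE)
      spec
    } else t
  })
  tag_names <- vapply(tags, `[[`, "", "name")
  if (anyDuplicated(tag_names)) {
    stop("assembly error: duplicate tag placement (",
         tag_names[duplicated(tag_names)][1], ")", call. = FALSE)
  }
  n_tags <- tags[vapply(tags, `[[`, "", "terminus") == "N"]
  c_tags <- tags[vapply(tags, `[[`, "", "terminus") == "C"]

  pick <- choose_orientation(net_charge(vh$sequence), orientation)
  first <- if (pick$orientation == "VLVH") vl else vh
  second <- if (pick$orientation == "VLVH") vh else vl

  seq <- paste0(
    paste(vapply(n_tags, `[[`, "", "sequence"), collapse = ""),
    first$sequence, linker$sequence, second$sequence,
    paste(vapply(c_tags, `[[`, "", "sequence"), collapse = ""))

  structure(list(
    orientation = pick$orientation,
    n_tags = n_tags, domain1 = first, linker = linker, domain2 = second,
    c_tags = c_tags, sequence = seq,
    net_charge = net_charge(seq),
    warnings = pick$warnings
  ), class = "scfv_construct")
}

#' @export
print.scfv_construct <- function(x, ...) {
  tagfmt <- function(tl) if (length(tl))
    paste(vapply(tl, `[[`, "", "name"), collapse = "+") else "-"
  cat(sprintf("scFv construct (%s): N[%s] %s | %s | %s C[%s]\n",
              x$orientation, tagfmt(x$n_tags), x$domain1$chain_type,
              x$linker$name, x$domain2$chain_type, tagfmt(x$c_tags)))
  cat(sprintf("  %d aa, net charge %+d, predicted solubility %.2f%%\n",
              nchar(x$sequence), x$net_charge,
              predict_percent(x$net_charge)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Pick or compose a linker with a given net charge
#'
#' Returns the library linker when one matches the target exactly
#' (0, -4, -7, -10); otherwise composes a 20-residue G/S/D pattern
#' with exactly |target| aspartates evenly spaced.
#'
#' @param target integer net charge in \[-10, 0\].
#' @return a linker spec (name, sequence, net_charge == target).
#' @export
linker_for_charge <- function(target) {
  if (target < -10 || target > 0) {
    stop("linker charge target must be in [-10, 0], got ", target,
         call. = FALSE)
  }
  lib <- linker_library()
  preferred <- c(`0` = "(G4S)4", `-4` = "(G4D)4", `-7` = "(G2D)7",
                 `-10` = "(GD)10")
  key <- as.character(target)
  if (key %in% names(preferred)) return(lib[[preferred[[key]]]])
  k <- -target
  # k aspartates evenly spaced through a 20-mer of G/S
  chars <- rep("G", 20L)
  pos <- round(seq(1, 20, length.out = k + 2L))[2:(k + 1L)]
  chars[pos] <- "D"
  chars[setdiff(seq(4, 20, by = 5), pos)] <- "S"
  s <- paste(chars, collapse = "")
  list(name = sprintf("composed(%+d)", target), sequence = s,
       net_charge = net_charge(s))
}

#' Charge budget toward a target solubility
#'
#' Inverts the linear predictor: the required construct charge is the
#' largest integer c with predicted percent >= target. Then searches
#' the tag/linker libraries for the lowest-modification combination
#' whose summed charge plus the Fv charge meets the budget; if even the
#' deepest combination (linker -10 + 3xFLAG + HA = -19) falls short,
#' reports infeasibility with the residual gap, indicating framework
#' mutations are additionally needed.
#'
#' @param fv_charge integer net charge of the bare Fv.
#' @param target_percent desired percent solubility.
#' @param model a [solubility_model()].
#' @return a `charge_budget`: required_charge, feasible, recommendation
#'   (linker + tags), achieved_charge, achieved_percent, residual_gap.
#' @export
charge_budget <- function(fv_charge, target_percent,
                          model = solubility_model()) {
  fv_charge <- as.integer(fv_charge)
  required <- as.integer(floor((target_percent - model$intercept) / model$slope))
  # floor() via division by the negative slope gives the largest c with
  # slope*c + intercept >= target; guard against FP edge at equality
  while (model$slope * (required + 1L) + model$intercept >= target_percent) {
    required <- required + 1L
  }
  while (model$slope * required + model$intercept < target_percent) {
    required <- required - 1L
  }
  budget <- required - fv_charge   # combined tag+linker charge must be <= this

  tags_pool <- tag_library()[c("3xFLAG", "HA")]
  tag_sets <- list(list(), tags_pool["HA"], tags_pool["3xFLAG"], tags_pool)
  best <- NULL
  for (ts in tag_sets) {
    tag_charge <- sum(vapply(ts, `[[`, 0L, "net_charge"))
    need_linker <- budget - tag_charge      # linker charge must be <= this
    if (need_linker < -10L) next            # even (GD)10 not enough
    lk <- linker_for_charge(as.integer(min(0L, need_linker)))
    cost <- length(ts) + (lk$net_charge != 0L)
    total <- tag_charge + lk$net_charge
    if (total > budget) next
    if (is.null(best) || cost < best$cost ||
        (cost == best$cost && total > best$total)) {
      best <- list(tags = ts, linker = lk, cost = cost, total = total)
    }
  }
  if (is.null(best)) {
    deepest <- -10L + sum(vapply(tags_pool, `[[`, 0L, "net_charge"))
    return(structure(list(
      required_charge = required, feasible = FALSE, recommendation = NULL,
      achieved_charge = fv_charge + deepest,
      achieved_percent = predict_percent(fv_charge + deepest, model),
      residual_gap = (fv_charge + deepest) - required,
      note = "tags + linker alone cannot meet the budget; framework charge-swap mutations additionally needed"
    ), class = "charge_budget"))
  }
  achieved <- fv_charge + best$total
  structure(list(
    required_charge = required, feasible = TRUE,
    recommendation = list(linker = best$linker, tags = best$tags),
    achieved_charge = achieved,
    achieved_percent = predict_percent(achieved, model),
    residual_gap = 0L, note = ""
  ), class = "charge_budget")
}

#' @export
print.charge_budget <- function(x, ...) {
  cat(sprintf("required construct charge: %+d\n", x$required_charge))
  if (x$feasible) {
    tags <- vapply(x$recommendation$tags, `[[`, "", "name")
    cat(sprintf("recommendation: linker %s%s -> charge %+d (%.2f%% predicted)\n",
                x$recommendation$linker$name,
                if (length(tags)) paste0(" + tags ", paste(tags, collapse = "+")) else "",
                x$achieved_charge, x$achieved_percent))
  } else {
    cat(sprintf("infeasible with tags+linker alone: best %+d (gap %+d); %s\n",
                x$achieved_charge, x$residual_gap, x$note))
  }
  invisible(x)
}
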