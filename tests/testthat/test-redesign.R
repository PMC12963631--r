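test_that("fixed masks resolve the documented Chothia ranges", {
  cons <- std_construct(1)
  map <- scfvforge:::construct_index_map(cons)

  prod <- build_fixed_mask(cons, "production")
  # per-range counting (kappa VL is insertion-free): VL 24-56 -> 33,
  # VL 86-100 -> 15; VH 26-56 -> 31 numbers (+ the 52a insertion,
  # which is fixed by inheritance), VH 92-105 -> 14
  sel <- map[map$index %in% prod$indices, ]
  vl_fixed <- sel[!is.na(sel$chain) & sel$chain == "VL", ]
  vh_fixed <- sel[!is.na(sel$chain) & sel$chain == "VH", ]
  expect_identical(nrow(vl_fixed), 33L + 15L)
  expect_identical(sum(vh_fixed$ins == ""), 31L + 14L)
  expect_true(any(vh_fixed$num == 52 & vh_fixed$ins == "a"))
  # production fixes the linker
  expect_true(all(prod$linker_indices %in% prod$indices))

  cdr <- build_fixed_mask(cons, "cdr_only")
  expect_false(any(cdr$linker_indices %in% cdr$indices))
  expect_lt(length(cdr$indices), length(prod$indices))

  ext <- build_fixed_mask(cons, "extended")
  expect_false(any(ext$linker_indices %in% ext$indices))

  for (m in list(prod, cdr, ext)) {
    expect_true(all(m$indices >= 0 & m$indices < nchar(cons$sequence)))
    expect_false(any(duplicated(m$indices)))
  }
})

test_that("validate_candidate flags fixed-position, cysteine and salt-bridge edits", {
  cons <- std_construct(2)
  mask <- build_fixed_mask(cons, "production")
  self <- validate_candidate(cons, cons$sequence, mask)
  expect_true(self$valid)
  expect_length(self$violations, 0L)

  chars <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]
  map <- scfvforge:::construct_index_map(cons)

  # substitution inside fixed CDR-H3 names the Chothia position
  h3 <- map$index[!is.na(map$chain) & map$chain == "VH" & map$num == 96][1]
  bad <- chars; bad[h3 + 1L] <- if (chars[h3 + 1L] == "A") "G" else "A"
  v <- validate_candidate(cons, paste(bad, collapse = ""), mask)
  expect_false(v$valid)
  expect_match(v$violations, "VH 96", all = FALSE)

  # loss of a cysteine
  cys <- which(chars == "C")[1]
  bad2 <- chars; bad2[cys] <- "S"
  v2 <- validate_candidate(cons, paste(bad2, collapse = ""), mask)
  expect_false(v2$valid)
  expect_match(v2$violations, "cysteine", all = FALSE)

  # VH D86N breaks the salt bridge
  d86 <- map$index[!is.na(map$chain) & map$chain == "VH" &
                     map$num == 86 & map$ins == ""]
  bad3 <- chars; bad3[d86 + 1L] <- "N"
  v3 <- validate_candidate(cons, paste(bad3, collapse = ""), mask)
  expect_false(v3$valid)
  expect_match(v3$violations, "VH salt bridge", all = FALSE)

  expect_error(validate_candidate(cons, substr(cons$sequence, 1, 50), mask),
               "length")
})

test_that("ranking is total, deterministic and solubility-first", {
  cons <- std_construct(3)
  mask <- build_fixed_mask(cons, "production")
  mk <- function(charge_shift, rank) {
    # shift charge by editing eligible non-fixed framework positions
    chars <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]
    eligible <- setdiff(seq_along(chars) - 1L,
                        c(mask$indices, which(chars == "C") - 1L))
    neutral <- eligible[chars[eligible + 1L] %in% c("S", "T", "Q", "N")]
    stopifnot(length(neutral) >= abs(charge_shift))
    take <- neutral[seq_len(abs(charge_shift))]
    chars[take + 1L] <- if (charge_shift < 0) "D" else "K"
    validate_candidate(cons, paste(chars, collapse = ""), mask,
                       model_rank = rank)
  }
  # construct charge is -13; shifts of -3, -1, -2 order accordingly
  cands <- list(mk(-1, 1), mk(-3, 2), mk(-2, 3))
  ranked <- rank_candidates(cands)
  expect_identical(vapply(ranked, `[[`, 0L, "model_rank"), c(2L, 3L, 1L))
  expect_true(all(diff(vapply(ranked, `[[`, 0, "predicted_percent")) <= 0))

  # equal charge: the lower model rank wins
  tie <- list(mk(-2, 7), mk(-2, 2))
  ranked_tie <- rank_candidates(tie)
  expect_identical(ranked_tie[[1]]$model_rank, 2L)

  # invalid candidates are excluded, not penalised
  chars <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]
  cysless <- chars; cysless[which(chars == "C")[1]] <- "A"
  mixed <- c(cands, list(validate_candidate(cons, paste(cysless, collapse = ""),
                                            mask, model_rank = 99)))
  ranked_mixed <- rank_candidates(mixed)
  expect_length(ranked_mixed, 3L)
  expect_length(attr(ranked_mixed, "excluded"), 1L)

  # determinism under shuffling
  set.seed(4)
  for (i in 1:5) {
    shuffled <- sample(cands)
    expect_identical(
      vapply(rank_candidates(shuffled), `[[`, "", "sequence"),
      vapply(ranked, `[[`, "", "sequence"))
  }
  expect_identical(rank_candidates(list()), structure(list(),
                                                      excluded = list()))
})

test_that("ensemble_summary reports conservation, consensus and charge shift", {
  cons <- std_construct(4)
  mask <- build_fixed_mask(cons, "production")

  # pure-parent ensemble
  copies <- replicate(5, cons$sequence)
  es <- ensemble_summary(cons, as.list(copies), mask)
  expect_true(all(es$conservation == 1))
  expect_identical(es$consensus, cons$sequence)
  expect_identical(unname(es$substituted_fraction["VL"]), 0)

  # exact tie at one non-fixed position keeps the parent residue
  map <- scfvforge:::construct_index_map(cons)
  chars <- strsplit(cons$sequence, "", fixed = TRUE)[[1]]
  free_fr3 <- map$index[!is.na(map$chain) & map$chain == "VH" &
                          map$num %in% 70:80 & !(map$index %in% mask$indices) &
                          map$aa == "S"][1]
  mutant <- chars; mutant[free_fr3 + 1L] <- "D"
  half <- c(replicate(5, cons$sequence),
            replicate(5, paste(mutant, collapse = "")))
  es2 <- ensemble_summary(cons, as.list(half), mask)
  expect_equal(es2$conservation[free_fr3 + 1L], 0.5)
  cons_chars <- strsplit(es2$consensus, "", fixed = TRUE)[[1]]
  expect_identical(cons_chars[free_fr3 + 1L], chars[free_fr3 + 1L])

  # K/R -> D/E enriched ensembles shift consensus framework charge down
  cands <- generate_ensemble(cons, mask, n = 40, substitution_rate = 0.3,
                             charge_bias = -0.9, seed = 6)
  es3 <- ensemble_summary(cons, cands, mask)
  expect_lt(es3$framework_charge$VH[["consensus"]],
            es3$framework_charge$VH[["parent"]])
  # fixed positions are perfectly conserved (validated ensemble)
  expect_true(all(es3$conservation[mask$indices + 1L] == 1))
})

test_that("ensemble FASTA round trip preserves scores and ordinals", {
  cons <- std_construct(5)
  mask <- build_fixed_mask(cons, "production")
  cands <- generate_ensemble(cons, mask, n = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".fasta")
  # attach generator scores to two of them
  cands[[1]]$description <- "score=1.25"
  cands[[2]]$description <- "score=0.50"
  cands[[3]]$description <- "score=2.00"
  cands[[4]]$description <- "score=0.75"
  write_fasta(cands, path)
  back <- read_ensemble_fasta(path)
  expect_identical(vapply(back, `[[`, 0, "model_score"),
                   c(1.25, 0.5, 2, 0.75))
  expect_identical(vapply(back, `[[`, 0L, "model_rank"), c(3L, 1L, 4L, 2L))

  # without scores, ordinals are file order
  for (i in seq_along(cands)) cands[[i]]$description <- ""
  write_fasta(cands, path)
  back2 <- read_ensemble_fasta(path)
  expect_identical(vapply(back2, `[[`, 0L, "model_rank"), 1:4)
})

test_that("mask JSON handoff lists indices and Chothia labels", {
  cons <- std_construct(6)
  mask <- build_fixed_mask(cons, "cdr_only")
  path <- withr::local_tempfile(fileext = ".json")
  write_mask_json(mask, cons, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(sort(j$fixed$index), mask$indices)
  expect_true(any(grepl("^VH 9[5-9]$", j$fixed$label)))
})
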