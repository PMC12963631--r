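test_that("templates number themselves with identity labels", {
  for (ct in c("VH", "VL-kappa", "VL-lambda")) {
    tpl <- numbering_template(ct)
    d <- number_domain(tpl$sequence)
    expect_identical(d$chain_type, ct)
    expect_identical(d$residues$num, tpl$labels$num)
    expect_identical(d$residues$ins, tpl$labels$ins)
    expect_identical(d$sequence, tpl$sequence)
    expect_equal(d$score_norm, 1, tolerance = 1e-12)
    expect_identical(d$source_span, c(0L, nchar(tpl$sequence)))
  }
})

# Hand-derived oracle fixture (synthetic stand-in for an external
# numbering tool, which is not available offline): Chothia labels of
# the human germline frameworks VH3-23 (98 residues, with 52a and
# 82a/b/c) and IGKV1-39 (88 residues, strictly sequential 1-88),
# written down directly from the scheme's insertion rules.
test_that("germline numbering agrees with the hand-derived fixture", {
  vh323 <- paste0("EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSA",
                  "ISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK")
  expected_vh <- c(paste0(1:52), "52a", paste0(53:82),
                   "82a", "82b", "82c", paste0(83:94))
  d <- number_domain(vh323)
  expect_identical(d$chain_type, "VH")
  got <- paste0(d$residues$num, d$residues$ins)
  agree <- mean(got == expected_vh[seq_along(got)])
  expect_gte(agree, 0.95)

  igkv139 <- paste0("DIQMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIY",
                    "AASSLQSGVPSRFSGSGSGTDFTLTISSLQPEDFATYYC")
  dk <- number_domain(igkv139)
  expect_identical(dk$chain_type, "VL-kappa")
  expect_identical(paste0(dk$residues$num, dk$residues$ins),
                   paste0(seq_len(nchar(igkv139))))
})

test_that("insertions and deletions relative to the template are handled", {
  tpl <- numbering_template("VH")
  # lengthen CDR-H3 by two residues
  chars <- strsplit(tpl$sequence, "", fixed = TRUE)[[1]]
  cdr3_end <- which(tpl$labels$num == 102)
  longer <- paste(append(chars, c("W", "W"), after = cdr3_end - 2L),
                  collapse = "")
  d <- number_domain(longer)
  expect_identical(nrow(d$residues), nchar(longer))
  ins_rows <- which(nzchar(d$residues$ins) &
                      !paste0(d$residues$num, d$residues$ins) %in%
                        c("52a", "82a", "82b", "82c"))
  expect_length(ins_rows, 2L)
  expect_true(all(d$residues$num[ins_rows] >= 95 &
                    d$residues$num[ins_rows] <= 102))
  seg <- segment_regions(d)
  expect_true(all(seg$residues$region[ins_rows] == "CDR3"))

  # delete two CDR-L1 residues from the kappa template
  ktpl <- numbering_template("VL-kappa")
  kchars <- strsplit(ktpl$sequence, "", fixed = TRUE)[[1]]
  shorter <- paste(kchars[-c(28, 29)], collapse = "")
  dk <- number_domain(shorter)
  expect_identical(nrow(dk$residues), nchar(shorter))
  expect_false(any(duplicated(paste0(dk$residues$num, dk$residues$ins))))
})

test_that("non-antibody sequences are rejected", {
  set.seed(5)
  expect_error(number_domain(random_peptide(110)), "not a variable domain")
  # shuffled template keeps composition but loses the domain
  tpl <- numbering_template("VH")$sequence
  shuffled <- paste(sample(strsplit(tpl, "")[[1]]), collapse = "")
  expect_error(number_domain(shuffled), "not a variable domain")
})

test_that("numbering is idempotent and deterministic", {
  for (seed in c(2, 9, 17)) {
    fv <- std_fv(seed)
    for (dom in fv) {
      again <- number_domain(dom$sequence)
      expect_identical(again$residues$num, dom$residues$num)
      expect_identical(again$residues$ins, dom$residues$ins)
      expect_identical(again$residues$aa, dom$residues$aa)
    }
  }
})

test_that("segment_regions applies the default CDR boundaries", {
  vh <- segment_regions(number_domain(numbering_template("VH")$sequence))
  at <- function(dom, num, ins = "") {
    dom$residues$region[dom$residues$num == num & dom$residues$ins == ins]
  }
  expect_identical(at(vh, 95), "CDR3")
  expect_identical(at(vh, 25), "CDR1")
  expect_identical(at(vh, 24), "FR1")
  expect_identical(at(vh, 52, "a"), "CDR2")   # insertion inherits base
  expect_identical(at(vh, 103), "FR4")

  vl <- segment_regions(number_domain(numbering_template("VL-kappa")$sequence))
  expect_identical(at(vl, 23), "FR1")
  expect_identical(at(vl, 24), "CDR1")
  expect_identical(at(vl, 97), "CDR3")
  expect_identical(at(vl, 98), "FR4")

  # partition: region counts sum to the domain length
  expect_identical(sum(table(vh$residues$region)), nrow(vh$residues))
  expect_setequal(unique(vh$residues$region),
                  c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"))
})

test_that("extract_fv projects onto variable domains", {
  fv <- std_fv(6)
  junk <- strrep("ASTKGPSVFPLAPSS", 7)   # constant-domain-like filler
  doms <- extract_fv(paste0(fv$vh$sequence, junk))
  expect_length(doms, 1L)
  expect_identical(doms[[1]]$sequence, fv$vh$sequence)

  # projection: re-extracting the extracted domain plus junk is stable
  again <- extract_fv(paste0(doms[[1]]$sequence, junk))
  expect_identical(again[[1]]$sequence, doms[[1]]$sequence)

  cons <- assemble_scfv(fv$vl, fv$vh, linker = "(G4S)4")
  both <- extract_fv(cons$sequence)
  expect_length(both, 2L)
  expect_identical(paste0(both[[1]]$sequence, "GGGGSGGGGSGGGGSGGGGS",
                          both[[2]]$sequence), cons$sequence)

  set.seed(31)
  expect_error(extract_fv(random_peptide(150)), "not an antibody")
})

test_that("apply_mutation edits residues by Chothia address", {
  vh <- number_domain(numbering_template("VH")$sequence)
  ks <- vh$residues[vh$residues$aa == "K" & vh$residues$num != 66, ]
  k1 <- ks$num[1]
  before <- net_charge(vh$sequence)
  mut <- apply_mutation(vh, sprintf("K%dD", k1))
  expect_identical(net_charge(mut$sequence), before - 2L)
  expect_identical(mut$residues$num, vh$residues$num)

  # five K->D/E swaps shift net charge by -10
  fv <- std_fv(8)
  doms <- list(fv$vl, fv$vh)
  swapped <- 0L; total_before <- 0L; total_after <- 0L
  for (dom in doms) {
    sb <- scfvforge:::SALT_BRIDGE[[if (dom$chain_type == "VH") "VH" else "VL"]]
    kk <- dom$residues[dom$residues$aa %in% c("K") &
                         !(dom$residues$num %in% sb), ]
    total_before <- total_before + net_charge(dom$sequence)
    for (i in seq_len(nrow(kk))) {
      if (swapped == 5L) break
      dom <- apply_mutation(dom, position = kk$num[i], wt = "K",
                            new = if (swapped %% 2L) "E" else "D",
                            ins = kk$ins[i])
      swapped <- swapped + 1L
    }
    total_after <- total_after + net_charge(dom$sequence)
  }
  expect_identical(swapped, 5L)
  expect_identical(total_after, total_before - 10L)
})

test_that("apply_mutation rejects mismatches and absent positions", {
  vh <- number_domain(numbering_template("VH")$sequence)
  q <- vh$residues$num[vh$residues$aa == "Q"][1]
  expect_error(apply_mutation(vh, sprintf("K%dD", q)), "wild-type mismatch")
  expect_error(apply_mutation(vh, "K300D"), "no residue at")
})

test_that("salt_bridge_check flags the conserved VL61-82 / VH66-86 pairs", {
  vl <- number_domain(numbering_template("VL-kappa")$sequence)
  vh <- number_domain(numbering_template("VH")$sequence)
  rep <- salt_bridge_check(vl, vh)
  expect_true(all(rep$intact))
  expect_identical(rep$basic_aa, c("R", "R"))
  expect_identical(rep$acidic_aa, c("D", "D"))

  vl_broken <- apply_mutation(vl, "R61E")
  rep2 <- salt_bridge_check(vl_broken, vh)
  expect_false(rep2$intact[rep2$chain == "VL"])
  expect_true(rep2$intact[rep2$chain == "VH"])

  vh_broken <- apply_mutation(vh, "D86N")
  rep3 <- salt_bridge_check(vl, vh_broken)
  expect_false(rep3$intact[rep3$chain == "VH"])
})
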