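mini_cohort <- function() {
  fv1 <- std_fv(41); fv2 <- std_fv(42); fv3 <- std_fv(43)
  cohort_records(
    id = c("a", "b", "c"),
    vl = c(fv1$vl$sequence, fv2$vl$sequence, fv3$vl$sequence),
    vh = c(fv1$vh$sequence, fv2$vh$sequence, fv3$vh$sequence))
}

test_that("filter_records removes at the first failing rule", {
  co <- mini_cohort()
  co$target_location[2] <- "membrane"
  co$specificity_arity[3] <- "bi"
  res <- filter_records(co)
  expect_identical(res$kept$id, "a")
  expect_identical(unname(res$report[["membrane"]]), 1L)
  expect_identical(unname(res$report[["multispecific"]]), 1L)
  expect_identical(res$removed$removed_by, c("membrane", "multispecific"))

  # both bacterial and bi-specific: counted once, under the first rule
  co2 <- mini_cohort()
  co2$target_location[1] <- "bacterial"
  co2$specificity_arity[1] <- "bi"
  res2 <- filter_records(co2)
  expect_identical(unname(res2$report[["bacterial"]]), 1L)
  expect_identical(unname(res2$report[["multispecific"]]), 0L)
})

test_that("an all-pass cohort is unchanged and filtering is idempotent", {
  co <- mini_cohort()
  res <- filter_records(co)
  expect_identical(nrow(res$kept), nrow(co))
  expect_true(all(res$report == 0L))
  res2 <- filter_records(res$kept)
  expect_identical(res2$kept$id, res$kept$id)
  expect_true(all(res2$report == 0L))
})

test_that("long-CDR and unannotatable records are filtered", {
  co <- mini_cohort()
  # lengthen CDR-H3 of record 2 beyond the 26-residue default
  vh <- number_domain(co$vh[2])
  chars <- strsplit(vh$sequence, "", fixed = TRUE)[[1]]
  at <- which(vh$residues$num == 100)[1]
  co$vh[2] <- paste(append(chars, rep(c("G", "S"), 10), after = at),
                    collapse = "")
  # record 3 is not an antibody at all
  set.seed(9)
  co$vl[3] <- random_peptide(110)
  res <- filter_records(co)
  expect_identical(res$kept$id, "a")
  expect_identical(unname(res$report[["long_cdr"]]), 1L)
  expect_identical(unname(res$report[["annotation_failure"]]), 1L)
})

test_that("dedup keeps the lowest-charge representative per CDR key", {
  # isoform pairs share CDRs but differ in framework charge
  co <- generate_cohort(n = 10, seed = 3, dup_groups = 3, p_remove = 0)
  dd <- dedup_by_cdr(co)
  expect_lte(nrow(dd$kept), nrow(co))
  expect_identical(nrow(dd$rejects), 0L)
  expect_false(any(duplicated(dd$groups)))

  # brute-force oracle: per key, minimal charge then smallest id
  ann_key <- function(vl, vh) {
    dvl <- segment_regions(number_domain(vl))
    dvh <- segment_regions(number_domain(vh))
    paste(region_sequence(dvl, "CDR1"), region_sequence(dvl, "CDR2"),
          region_sequence(dvl, "CDR3"), region_sequence(dvh, "CDR1"),
          region_sequence(dvh, "CDR2"), region_sequence(dvh, "CDR3"))
  }
  keys <- mapply(ann_key, co$vl, co$vh)
  charges <- mapply(function(a, b) net_charge(a) + net_charge(b),
                    co$vl, co$vh)
  expected <- vapply(split(seq_len(nrow(co)), keys), function(grp) {
    co$id[grp[order(charges[grp], co$id[grp])][1]]
  }, "")
  expect_setequal(dd$kept$id, unname(expected))
  expect_lt(length(unique(keys)), nrow(co))   # the dup groups collapsed

  # all-unique cohort: identity
  co_u <- generate_cohort(n = 5, seed = 8, dup_groups = 0, p_remove = 0)
  dd_u <- dedup_by_cdr(co_u)
  expect_identical(dd_u$kept$id, co_u$id)
})

test_that("dedup breaks exact charge ties by smallest id", {
  fv <- std_fv(51)
  co <- cohort_records(id = c("z", "m", "a"),
                       vl = rep(fv$vl$sequence, 3),
                       vh = rep(fv$vh$sequence, 3))
  dd <- dedup_by_cdr(co)
  expect_identical(dd$kept$id, "a")
})

test_that("linker_survey applies the longer-than-six rule", {
  fv <- neutral_fv(7)
  mk <- function(linker) paste0(fv$vl$sequence, linker, fv$vh$sequence)
  recs <- list(
    seq_record("g4s", mk(strrep("GGGGS", 4))),
    seq_record("g4d", mk(strrep("GGGGD", 4))),
    seq_record("gd10", mk(strrep("GD", 10))),
    seq_record("short", mk("GGGGSG")),     # six residues: rejected
    seq_record("junk", random_peptide(250))
  )
  sv <- linker_survey(recs)
  expect_identical(sv$accepted, 3L)
  expect_identical(sv$rejected, 2L)
  expect_identical(sv$histogram$total, 3L)
  # oracle counting: one linker each at 0, -4, -10
  tab <- histogram_table(sv$histogram)
  expect_identical(tab$count[tab$bin_left == 0], 1L)
  expect_identical(tab$count[tab$bin_left == -4], 1L)
  expect_identical(tab$count[tab$bin_left == -10], 1L)

  # an all-(G4S)4 cohort puts all mass in the zero bin
  all_gs <- lapply(1:3, function(i) seq_record(paste0("r", i),
                                               mk(strrep("GGGGS", 4))))
  sv2 <- linker_survey(all_gs)
  tab2 <- histogram_table(sv2$histogram)
  expect_identical(tab2$count[tab2$bin_left == 0], 3L)
  expect_identical(sv2$histogram$total, 3L)
})

test_that("histograms bin deterministically and conserve counts", {
  h <- make_histogram(c(-4), width = 1)
  tab <- histogram_table(h)
  expect_identical(tab$bin_left, -4)
  expect_identical(tab$bin_right, -3)
  expect_identical(tab$count, 1L)

  h0 <- make_histogram(numeric(0))
  expect_identical(h0$total, 0L)
  expect_length(h0$counts, 0L)

  set.seed(13)
  v <- rnorm(200, sd = 5)
  h2 <- make_histogram(v, width = 1)
  expect_identical(sum(h2$counts), h2$total)
  expect_true(all(diff(h2$edges) > 0))
  # every value lands in the bin containing it
  expect_identical(h2$counts[1] > 0L || h2$counts[length(h2$counts)] > 0L, TRUE)
})

test_that("property histograms reflect the cohort's charge polarity", {
  co <- generate_cohort(n = 8, seed = 5, p_remove = 0)
  hq <- property_histogram(co, "net_charge", "fv")
  expect_identical(hq$total, nrow(co))
  vals <- attr(hq, "values")
  expect_identical(vals, vapply(seq_len(nrow(co)), function(i)
    as.numeric(net_charge(paste0(co$vl[i], co$vh[i]))), 0))

  # VH framework positively shifted relative to VH CDR (generator default)
  fw <- attr(property_histogram(co, "framework_charge", "VH"), "values")
  cdr <- attr(property_histogram(co, "cdr_charge", "VH"), "values")
  expect_gt(mean(fw), mean(cdr))
  expect_gt(mean(fw), 0)
  expect_lt(mean(cdr), 0)

  expect_error(property_histogram(co, "framework_charge", "fv"), "require")
  h_empty <- property_histogram(co[0, ], "net_charge", "fv")
  expect_identical(h_empty$total, 0L)
})
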