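test_that("variant classification reproduces the published family annotations", {
  cases <- list(
    list("c.757C>T", "p.Arg253*", "nonsense"),
    list("c.‐29‐?_*3450+?del", "Complete gene deletion", "whole_gene_deletion"),
    list("c.49+3A>G", "Splice site mutation", "splice_site"),
    list("c.238C>T", "p.Leu80Phe", "missense"),
    list("c.3G>A", "Affects start codon - REP-1 absent", "start_codon"),
    list("c.846delT", "p.Phe282Leufs*9", "frameshift"),
    list("c.117-?_1166+?dup", "Duplication of exons 3-8", "exon_duplication"),
    list("c.-29-(57-63kb)_49+?del", "Deletion of exon 1 - REP-1 absent", "exon_deletion"),
    list("C.1670C>A", "p.Ser557*", "nonsense") # upper-case prefix normalised
  )
  for (cs in cases) {
    v <- parse_variant(cs[[1]], cs[[2]])
    expect_equal(as.character(v$mutation_class), cs[[3]], info = cs[[1]])
  }
  # REP-1 absence implied by whole-gene / start-codon / exon-1 deletions
  v <- parse_variant(
    c("c.-29-?_*3450+?del", "c.3G>A", "c.-29-?_49+?del", "c.757C>T"),
    c("Complete gene deletion", "Affects start codon", "Deletion of exon 1 - REP-1 absent", "p.Arg253*")
  )
  expect_equal(v$rep1_absent_predicted, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("unparseable variants fall back to class 'other' with a warning", {
  expect_warning(v <- parse_variant("not hgvs at all"), "unparseable")
  expect_equal(as.character(v$mutation_class), "other")
  # classification is total on the full published mutation table
  t2 <- chm_table2()
  suppressWarnings(
    classes <- parse_variant(t2$hgvs_c, t2$protein_change)$mutation_class
  )
  expect_false(anyNA(classes))
})

test_that("genotype grouping follows the missense / REP-1-absent / other partition", {
  # two missense variants in one subject -> missense
  co <- make_cohort(
    age = 9, va_od = 0,
    hgvs_c = "c.238C>T", protein_change = "p.Leu80Phe"
  )
  co$hgvs_c_2 <- "c.1327A>G"
  co$protein_change_2 <- "p.Met443Val"
  expect_equal(as.character(assign_genotype_group(co)$genotype_group), "missense")
  # whole-gene deletion -> rep1_absent
  co <- make_cohort(
    age = 20, va_od = 0.1,
    hgvs_c = "c.-29-?_*3450+?del", protein_change = "Complete gene deletion"
  )
  expect_equal(as.character(assign_genotype_group(co)$genotype_group), "rep1_absent")
  # nonsense -> other, by exclusion
  co <- make_cohort(age = 20, va_od = 0.1)
  expect_equal(as.character(assign_genotype_group(co)$genotype_group), "other")
  # partition is exhaustive on the synthetic cohort
  grp <- assign_genotype_group(simulate_cohort(cohort_config(), seed = 11))$genotype_group
  expect_false(anyNA(grp))
})

test_that("family-level spectrum counts deduplicate families and match the published table", {
  t2 <- chm_table2()
  suppressWarnings(counts <- spectrum_counts(t2))
  expect_equal(attr(counts, "n_families_total"), 106)
  expect_equal(
    counts$n_families[counts$mutation_class == "missense"], 4
  )
  # counts never exceed the number of distinct families
  expect_true(all(counts$n_families <= 106))
  # single family with one variant -> exactly one non-zero class
  one <- spectrum_counts(tibble::tibble(
    family_id = "F1", hgvs_c = "c.757C>T", protein_change = "p.Arg253*"
  ))
  expect_equal(sum(one$n_families), 1)
  expect_equal(attr(one, "n_families_total"), 1)
})

test_that("cohort round-trips through delimited text and flags schema problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  t5 <- chm_table5()
  expect_equal(nrow(t5), 8)
  expect_true(is.na(t5$vf_od[t5$subject_id == "S1.2"])) # NC -> absent
  write_cohort(t5, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(t5))

  # synthetic cohort round trip, including NC-encoded missing fields
  co <- simulate_cohort(cohort_config(), seed = 5)
  write_cohort(co, path)
  expect_equal(as.data.frame(read_cohort(path)), as.data.frame(co))

  # empty file with header -> zero-row cohort
  writeLines("subject_id,family_id,hgvs_c,age", path)
  expect_equal(nrow(read_cohort(path)), 0)

  # missing mandatory column is named in the error
  expect_error(as_cohort(tibble::tibble(subject_id = "a", hgvs_c = "c.3G>A", age = 5)),
    "family_id"
  )
  # onset after assessment age is rejected
  expect_error(
    make_cohort(age = 10, va_od = 0, onset_nyctalopia = 20),
    "exceeds age"
  )
})
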