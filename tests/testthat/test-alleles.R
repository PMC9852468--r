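# Allele tabulation and repair-signature annotation.

test_that("allele tabulation groups, ranks and conserves counts", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed)
  edited <- expected_edited_sequence(loc, ed)
  partial5 <- penquant:::.partial_hr_construct(loc, peg, 5L)
  reads <- c(rep(edited, 6), rep(partial5, 3), FX_AMP240)
  calls <- classify_reads(reads, loc, ed, peg)
  al <- tabulate_alleles(calls, loc, ed, peg, by = "read")
  expect_equal(al$count, c(6L, 3L, 1L))
  expect_equal(al$freq, c(0.6, 0.3, 0.1))
  expect_equal(sum(al$count), sum(calls$category != "DISCARD"))
  # reference allele excluded from mutant ranking; allele-1 is the top mutant
  expect_true(is.na(al$rank[al$is_reference]))
  expect_equal(al$rank[al$seq == edited], 1L)
  expect_equal(al$rank[al$seq == partial5], 2L)
})

test_that("window-keyed tabulation absorbs errors outside the window", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed)
  edited <- expected_edited_sequence(loc, ed)
  noisy <- edited
  substr(noisy, 5, 5) <- if (substr(noisy, 5, 5) == "A") "G" else "A"
  calls <- classify_reads(c(edited, noisy), loc, ed, peg)
  expect_equal(nrow(tabulate_alleles(calls, loc, ed, peg, by = "window")), 1L)
  expect_equal(nrow(tabulate_alleles(calls, loc, ed, peg, by = "read")), 2L)
})

test_that("microhomology prediction agrees with brute-force enumeration", {
  set.seed(321)
  for (i in 1:12) {
    d <- rand_design(flank1 = 40L, flank2 = 40L)
    loc <- d$locus; ed <- d$edit; peg <- d$pegrna
    cand <- predict_mh_alleles(loc, peg, ed, min_mh = 3, max_mh = 10,
                               scan_len = 30)
    cut <- loc$cut_site
    oracle <- oracle_mh(
      upstream = substr(loc$amplicon, 1, cut),
      overhang = predicted_3prime_overhang(loc, peg),
      downstream = substr(loc$amplicon, cut + 1,
                          min(nchar(loc$amplicon), cut + 30)),
      ref_after_cut = substr(loc$amplicon, cut + 1, nchar(loc$amplicon)),
      min_mh = 3, max_mh = 10)
    expect_setequal(cand$predicted_allele, oracle$allele)
    m_pkg <- setNames(cand$m, cand$predicted_allele)
    m_or <- setNames(oracle$m, oracle$allele)
    expect_equal(m_pkg[names(m_or)], m_or)
  }
})

test_that("microhomology candidates behave on engineered loci", {
  loc <- fx_locus240()
  # HR anneal at its own genomic position reproduces the precise product
  ed <- edit_spec("insertion", inserted = "TAG")
  peg <- design_hr_pegrna(loc, ed, hr_len = 3)
  cand <- predict_mh_alleles(loc, peg, ed, min_mh = 3)
  hit <- cand[cand$overhang_pos == nchar(peg$pr) & cand$downstream_pos == 0 &
                cand$mh_seq == peg$hr, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$is_precise)
  expect_equal(hit$predicted_allele, expected_edited_sequence(loc, ed))
  # min_mh longer than the overhang itself yields an empty table
  none <- predict_mh_alleles(loc, peg, ed, min_mh = 7, max_mh = 10)
  expect_equal(nrow(none), 0L)
})

test_that("partial-HR joins are annotated with their exact k", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed, hr_len = 20)
  edited <- expected_edited_sequence(loc, ed)
  p7 <- penquant:::.partial_hr_construct(loc, peg, 7L)
  p12 <- penquant:::.partial_hr_construct(loc, peg, 12L)
  calls <- classify_reads(c(rep(edited, 3), rep(p7, 2), p12, FX_AMP240),
                          loc, ed, peg)
  al <- tabulate_alleles(calls, loc, ed, peg, by = "read")
  al <- match_partial_hr_joins(al, loc, peg, ed)
  expect_equal(al$annotations[al$seq == p7], "PARTIAL_HR_JOIN(7)")
  expect_equal(al$annotations[al$seq == p12], "PARTIAL_HR_JOIN(12)")
  expect_equal(al$annotations[al$seq == edited], "PRECISE")
  expect_equal(al$annotations[al$is_reference], "")
})

test_that("the k = 0 blunt join of a cut-site insertion is the precise product", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed, hr_len = 20)
  expect_identical(penquant:::.partial_hr_construct(loc, peg, 0L),
                   expected_edited_sequence(loc, ed))
  # and the full-HR blunt join is a duplication, NOT the precise product
  expect_false(penquant:::.partial_hr_construct(loc, peg, 20L) ==
                 expected_edited_sequence(loc, ed))
})

test_that("full annotation pass covers classical indels and MH alleles", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed, hr_len = 20)
  edited <- expected_edited_sequence(loc, ed)
  cut <- loc$cut_site
  del3 <- paste0(substr(FX_AMP240, 1, cut - 1), substr(FX_AMP240, cut + 3, 240))
  calls <- classify_reads(c(edited, del3, del3), loc, ed, peg)
  al <- tabulate_alleles(calls, loc, ed, peg, by = "read")
  al <- annotate_alleles(al, loc, peg, ed)
  expect_equal(al$annotations[al$seq == edited], "PRECISE")
  ann_del <- al$annotations[al$seq == del3]
  expect_true(ann_del == "CLASSICAL_INDEL" || grepl("MH_JUNCTION", ann_del))
})
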