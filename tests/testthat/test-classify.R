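# Outcome classification: windows, categories, summary identities,
# indel histograms.

test_that("quantification windows extend pad beyond cut and RT end", {
  # cut at 100 with an 18-bp PR and 20-bp HR: edit window [70, 168)
  set.seed(55)
  dna <- c("A", "C", "G", "T")
  repeat {
    amp <- paste0(paste(sample(dna, 83, TRUE), collapse = ""), FX_PROTO,
                  "TGG", paste(sample(dna, 194, TRUE), collapse = ""))
    ok <- sum(gregexpr(FX_PROTO, amp, fixed = TRUE)[[1]] > 0) == 1 &&
      all(gregexpr(FX_PROTO, revcomp(amp), fixed = TRUE)[[1]] < 0)
    if (ok) break
  }
  loc <- locate_protospacer(amp, FX_PROTO)
  expect_equal(loc$cut_site, 100L)
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed, hr_len = 20)
  w <- build_quant_window(loc, peg, ed, pad = 30)
  expect_equal(w$edit_window, c(70L, 168L))
  expect_equal(w$rt_end_edit, 138L)
  expect_equal(w$ref_window, c(70L, 150L))
  w0 <- build_quant_window(loc, peg, ed, pad = 0)
  expect_equal(w0$edit_window, c(100L, 138L))
  # clipping at the amplicon edge warns
  expect_warning(build_quant_window(loc, peg, ed, pad = 250),
                 "clipped")
})

test_that("canonical read types get their defining categories", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed, hr_len = 20)
  w <- build_quant_window(loc, peg, ed)
  edited <- expected_edited_sequence(loc, ed)
  cut <- loc$cut_site

  partial7 <- penquant:::.partial_hr_construct(loc, peg, 7L)
  del2 <- paste0(substr(FX_AMP240, 1, cut), substr(FX_AMP240, cut + 3, 240))
  garbage <- paste(rep(c("A", "C"), 100), collapse = "")

  calls <- classify_reads(c(edited, FX_AMP240, partial7, del2, garbage),
                          loc, ed, peg, w)
  expect_equal(calls$category,
               c("ACCURATE", "UNEDITED", "IMPRECISE_RT", "DIRECT_INDEL",
                 "DISCARD"))
  # the partial-HR join keeps the programmed insert: RT-driven but imprecise,
  # with its indel beyond the programmed region (distal)
  expect_true(calls$contains_pr[3])
  expect_true(calls$distal_indel[3])
  expect_false(calls$contains_pr[4])
  # direct indel call carries the 2-bp deletion at the cut
  ind <- calls$indels[[4]]
  expect_equal(ind$kind[ind$in_window], "del")
  expect_equal(ind$len[ind$in_window], 2L)
})

test_that("reverse-complement input reads are normalized before calling", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed)
  edited <- expected_edited_sequence(loc, ed)
  calls <- classify_reads(c(revcomp(edited), revcomp(FX_AMP240)),
                          loc, ed, peg)
  expect_equal(calls$category, c("ACCURATE", "UNEDITED"))
  expect_equal(calls$seq, c(edited, FX_AMP240))
})

test_that("substitution edits separate edited, unedited and noisy reads", {
  loc <- fx_locus240()
  cut <- loc$cut_site
  ref_block <- substr(FX_AMP240, cut + 1, cut + 2)
  new_block <- c(A = "C", C = "G", G = "T", T = "A")[
    strsplit(ref_block, "")[[1]]]
  ed <- edit_spec("substitution", inserted = paste(new_block, collapse = ""),
                  deleted_len = 2)
  peg <- design_hr_pegrna(loc, ed, hr_len = 20)
  edited <- expected_edited_sequence(loc, ed)
  # unedited read with a stray substitution away from the cut
  noisy <- FX_AMP240
  substr(noisy, 20, 20) <- if (substr(noisy, 20, 20) == "A") "C" else "A"
  calls <- classify_reads(c(edited, FX_AMP240, noisy), loc, ed, peg)
  expect_equal(calls$category, c("ACCURATE", "UNEDITED", "UNEDITED"))
})

test_that("summary percentages and identities follow the definitions", {
  mk <- function(cat, n) data.frame(category = rep(cat, n),
                                    stringsAsFactors = FALSE)
  calls <- rbind(mk("ACCURATE", 500), mk("IMPRECISE_RT", 100),
                 mk("DIRECT_INDEL", 200), mk("UNEDITED", 200))
  s <- summarize_calls(calls)
  expect_equal(s$n_total_mapped, 1000L)
  expect_equal(s$accurate_pct, 50)
  expect_equal(s$all_rt_pct, 60)
  expect_equal(s$unintended_pct, 30)
  expect_equal(s$purity, 500 / 600)
  # count-level identities
  expect_equal(s$n_per_category[["ACCURATE"]] +
                 s$n_per_category[["IMPRECISE_RT"]],
               as.integer(round(s$all_rt_pct / 100 * s$n_total_mapped)))
  # permutation invariance
  s2 <- summarize_calls(calls[sample(nrow(calls)), , drop = FALSE])
  expect_equal(s2$n_per_category, s$n_per_category)

  # no RT-driven reads: purity is missing, not zero
  s3 <- summarize_calls(rbind(mk("UNEDITED", 5), mk("DIRECT_INDEL", 5)))
  expect_true(is.na(s3$purity))
  expect_error(summarize_calls(mk("DISCARD", 3)),
               class = "penquant_empty_sample")
})

test_that("indel histograms count window indels by category", {
  loc <- fx_locus240()
  ed <- edit_spec("insertion", inserted = FX_HIS18)
  peg <- design_hr_pegrna(loc, ed)
  cut <- loc$cut_site
  edited <- expected_edited_sequence(loc, ed)
  del2 <- paste0(substr(FX_AMP240, 1, cut), substr(FX_AMP240, cut + 3, 240))
  calls_acc <- classify_reads(c(edited, edited), loc, ed, peg)
  expect_equal(nrow(indel_size_distribution(calls_acc)), 0L)

  calls <- classify_reads(c(edited, del2, del2), loc, ed, peg)
  h <- indel_size_distribution(calls)
  expect_equal(h$category, "DIRECT_INDEL")
  expect_equal(h$size, -2L)
  expect_equal(h$count, 2L)
  n_window_indels <- sum(vapply(calls$indels,
                                function(d) sum(d$in_window), integer(1)))
  expect_equal(sum(h$count), n_window_indels)
})
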