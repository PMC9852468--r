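# pegRNA design: locus normalization, edit application, HR-pegRNA parts,
# overhang prediction and cloning oligos.

test_that("protospacer location fixes the blunt cut 3 nt 5' of the PAM", {
  loc <- fx_locus()
  expect_equal(loc$proto_start, 40L)
  expect_equal(substr(loc$amplicon, 61, 63), "CGG")
  expect_equal(loc$cut_site, 57L)
  expect_equal(loc$strand, "+")
})

test_that("location is orientation-invariant and errors are classed", {
  loc <- fx_locus()
  loc_rc <- locate_protospacer(revcomp(FX_AMP120), FX_PROTO, name = "toy")
  expect_equal(loc_rc$amplicon, loc$amplicon)
  expect_equal(loc_rc$proto_start, loc$proto_start)
  expect_equal(loc_rc$cut_site, loc$cut_site)
  expect_equal(loc_rc$input_strand, "-")

  expect_error(locate_protospacer(FX_AMP120, strrep("A", 20)),
               class = "penquant_not_found")
  expect_error(locate_protospacer(paste0(FX_AMP120, FX_AMP120), FX_PROTO),
               class = "penquant_ambiguous")
  no_pam <- FX_AMP120
  substr(no_pam, 62, 63) <- "AT"   # break the GG
  expect_error(locate_protospacer(no_pam, FX_PROTO),
               class = "penquant_pam_error")
})

test_that("edit application does the length bookkeeping", {
  loc <- fx_locus()
  expect_equal(nchar(expected_edited_sequence(loc, edit_spec("insertion",
    inserted = "TAG"))), 123L)
  expect_equal(nchar(expected_edited_sequence(loc, edit_spec("deletion",
    deleted_len = 24))), 96L)
  expect_equal(nchar(expected_edited_sequence(loc, edit_spec("replacement",
    inserted = strrep("A", 12), deleted_len = 12))), 120L)
  expect_error(expected_edited_sequence(loc, edit_spec("deletion",
    deleted_len = 80)), class = "penquant_coord_error")
  expect_error(edit_spec("insertion", inserted = ""),
               class = "penquant_type_error")
  expect_error(edit_spec("substitution", inserted = "AC", deleted_len = 3),
               class = "penquant_type_error")
})

test_that("HR-pegRNA parts match a by-hand construction on the toy locus", {
  loc <- fx_locus()
  ed <- edit_spec("insertion", inserted = "TAG")
  peg <- design_hr_pegrna(loc, ed, pbs_len = 13, hr_len = 5)
  # by hand: PBS = revcomp of the 13 nt 5' of the cut (positions 45..57),
  # HR = 5 genomic nt downstream of the cut, RTT = revcomp(HR)+revcomp(PR)
  expect_equal(peg$pbs, revcomp(substr(FX_AMP120, 45, 57)))
  hr_hand <- substr(FX_AMP120, 58, 62)
  expect_equal(peg$hr, hr_hand)
  expect_equal(peg$rtt, paste0(revcomp(hr_hand), revcomp("TAG")))
  expect_equal(peg$extension, paste0(peg$rtt, peg$pbs))
  expect_equal(predicted_3prime_overhang(loc, peg), paste0("TAG", hr_hand))
})

test_that("HR-free and deletion designs degenerate as expected", {
  loc <- fx_locus()
  ins <- edit_spec("insertion", inserted = "TAG")
  peg0 <- design_hr_pegrna(loc, ins, hr_len = 0)
  expect_equal(peg0$rtt, revcomp("TAG"))
  expect_equal(predicted_3prime_overhang(loc, peg0), "TAG")

  del <- edit_spec("deletion", deleted_len = 10)
  pegd <- design_hr_pegrna(loc, del, hr_len = 8)
  expect_equal(pegd$pr, "")
  # HR spans the deletion junction: genomic bases just past the deleted block
  expect_equal(pegd$hr, substr(FX_AMP120, 68, 75))
  expect_equal(pegd$rtt, revcomp(pegd$hr))
  expect_equal(predicted_3prime_overhang(loc, pegd), pegd$hr)

  expect_error(design_hr_pegrna(loc, ins, pbs_len = 5),
               class = "penquant_type_error")
  expect_error(design_hr_pegrna(loc, ins, hr_len = 26),
               class = "penquant_type_error")
  expect_error(design_hr_pegrna(loc, edit_spec("deletion", deleted_len = 40),
                                hr_len = 25),
               class = "penquant_coord_error")
})

test_that("same edit with nested HR sizes shares PR and prefixes of HR", {
  loc <- fx_locus()
  ed <- edit_spec("replacement", inserted = "GGTACC", deleted_len = 4)
  a <- design_hr_pegrna(loc, ed, hr_len = 6)
  b <- design_hr_pegrna(loc, ed, hr_len = 17)
  expect_equal(a$pr, b$pr)
  expect_equal(a$hr, substr(b$hr, 1, 6))
})

test_that("design/repair round trip holds over randomized loci and edits", {
  set.seed(101)
  for (i in 1:40) {
    d <- rand_design()
    expect_identical(precise_repair_product(d$locus, d$pegrna),
                     expected_edited_sequence(d$locus, d$edit))
  }
})

test_that("cloning oligos carry the published overhangs and close the cassette", {
  loc <- fx_locus()
  peg <- design_hr_pegrna(loc, edit_spec("insertion", inserted = FX_HIS18))
  ol <- cloning_oligos(peg)
  spacer <- ol[ol$part == "spacer", ]
  expect_true(startsWith(spacer$top, "ACCG"))
  expect_true(endsWith(spacer$top, "GTTTT"))
  expect_true(startsWith(spacer$bottom, "CTCTAAAAC"))
  ext <- ol[ol$part == "extension", ]
  expect_true(startsWith(ext$top, "GTGC"))
  expect_true(startsWith(ext$bottom, "AAAA"))
  # Golden-Gate closure: concatenated top strands reconstitute the cassette
  expect_equal(paste0(spacer$top, ol$top[ol$part == "scaffold"], ext$top),
               paste0("ACCG", peg$spacer, peg$scaffold, peg$extension))
  # declared sticky ends pair with their ligation partners
  expect_equal(revcomp(substr(ol$bottom[ol$part == "spacer"], 1, 4)),
               substr(ol$top[ol$part == "scaffold"], 1, 4))
  expect_equal(revcomp(substr(ol$bottom[ol$part == "scaffold"], 1, 4)),
               substr(ext$top, 1, 4))
})
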