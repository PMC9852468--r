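# HR-pegRNA design: target loci, edit specifications, pegRNA construction.
#
# Coordinate conventions (used throughout the package):
#   * the amplicon is orientation-normalized so the protospacer lies on the
#     top (+) strand; all coordinates are 0-based, half-open, on that strand;
#   * cut_site is an inter-base coordinate: the blunt Cas9 DSB falls between
#     positions cut_site - 1 and cut_site, i.e. cut_site equals the length of
#     the upstream (PAM-distal) fragment;
#   * the cut lies 3 nt 5' of the PAM on the protospacer strand.

#' Canonical SpCas9 sgRNA scaffold
#'
#' Fixed scaffold used when assembling pegRNA sequences and cloning oligos.
#' Replaceable through the `scaffold` argument of [design_hr_pegrna()].
#' @export
SGRNA_SCAFFOLD <-
  "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"

#' Locate a protospacer on an amplicon and build a normalized target locus
#'
#' Searches both strands of `amplicon` for the 20-nt `protospacer` followed
#' immediately by an NGG PAM. If the unique match lies on the bottom strand
#' the amplicon is reverse-complemented, so the returned locus always has the
#' protospacer on the top strand. The blunt cut site is placed 3 nt 5' of the
#' PAM (between protospacer positions 17 and 18).
#'
#' @param amplicon DNA string (uppercase A/C/G/T) of the reference amplicon.
#' @param protospacer 20-nt DNA string.
#' @param name identifier carried through outputs.
#' @return A `target_locus` object: list with fields `name`, `amplicon`,
#'   `protospacer`, `pam`, `strand` (always `"+"` after normalization;
#'   `input_strand` records the strand of the original match), `proto_start`
#'   (0-based) and `cut_site` (0-based inter-base).
#' @details Errors are classed conditions: `penquant_not_found` (no match),
#'   `penquant_ambiguous` (more than one match over both strands),
#'   `penquant_pam_error` (match without NGG). A warning is emitted when the
#'   cut has less than 30 bp of flank on either side, where quantification
#'   windows would be clipped.
#' @export
#' @examples
#' amp <- paste0(strrep("A", 40), "GACGTTCTCGATGGTGCTAG", "CGG", strrep("T", 40))
#' locate_protospacer(amp, "GACGTTCTCGATGGTGCTAG")$cut_site
locate_protospacer <- function(amplicon, protospacer, name = "locus") {
  .check_dna(amplicon, "amplicon")
  .check_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L)
    .stop("protospacer must be 20 nt", "penquant_type_error")

  hits_fwd <- gregexpr(protospacer, amplicon, fixed = TRUE)[[1]]
  hits_fwd <- hits_fwd[hits_fwd > 0]
  hits_rev <- gregexpr(protospacer, revcomp(amplicon), fixed = TRUE)[[1]]
  hits_rev <- hits_rev[hits_rev > 0]
  n_hits <- length(hits_fwd) + length(hits_rev)
  if (n_hits == 0)
    .stop("protospacer not found on either strand of the amplicon",
          "penquant_not_found")
  if (n_hits > 1)
    .stop(sprintf("protospacer occurs %d times across both strands", n_hits),
          "penquant_ambiguous")

  input_strand <- if (length(hits_fwd)) "+" else "-"
  if (input_strand == "-") amplicon <- revcomp(amplicon)
  proto_start <- if (input_strand == "+") hits_fwd[1] - 1L
                 else hits_rev[1] - 1L

  pam <- .sub0(amplicon, proto_start + 20L, proto_start + 23L)
  if (nchar(pam) != 3L || substr(pam, 2, 3) != "GG")
    .stop(sprintf("no NGG PAM 3' of the protospacer (found '%s')", pam),
          "penquant_pam_error")

  cut_site <- proto_start + 17L
  if (cut_site < 30L || nchar(amplicon) - cut_site < 30L)
    warning("cut site has < 30 bp flank; quantification windows will be clipped",
            call. = FALSE)

  structure(
    list(name = name, amplicon = amplicon, protospacer = protospacer,
         pam = pam, strand = "+", input_strand = input_strand,
         proto_start = as.integer(proto_start),
         cut_site = as.integer(cut_site)),
    class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("target_locus '%s': %d-bp amplicon, protospacer at %d (%s input strand), PAM %s, cut at %d\n",
              x$name, nchar(x$amplicon), x$proto_start, x$input_strand,
              x$pam, x$cut_site))
  invisible(x)
}

#' Specify an intended edit relative to the cut site
#'
#' @param kind one of `"insertion"`, `"deletion"`, `"replacement"`,
#'   `"substitution"`.
#' @param inserted DNA string written into the product (empty for deletions).
#' @param deleted_len number of reference bases removed (0 for insertions).
#' @param position offset of the edit start relative to the cut site on the
#'   top strand; 0 (default) places the edit at the DSB, where the reverse
#'   transcriptase starts writing. Positive offsets (edit downstream of the
#'   cut) are supported; a warning is issued beyond 10 bp. Negative offsets
#'   are rejected: the RT extends the upstream 3' end and cannot rewrite
#'   sequence 5' of the break.
#' @return An `edit_spec` object.
#' @export
#' @examples
#' edit_spec("insertion", inserted = "TAG")
#' edit_spec("deletion", deleted_len = 24)
edit_spec <- function(kind = c("insertion", "deletion", "replacement",
                               "substitution"),
                      inserted = "", deleted_len = 0L, position = 0L) {
  kind <- match.arg(kind)
  deleted_len <- as.integer(deleted_len)
  position <- as.integer(position)
  if (nchar(inserted) > 0) .check_dna(inserted, "inserted")
  ok <- switch(kind,
    insertion    = deleted_len == 0L && nchar(inserted) > 0L,
    deletion     = deleted_len > 0L && nchar(inserted) == 0L,
    replacement  = deleted_len > 0L && nchar(inserted) > 0L,
    substitution = deleted_len > 0L && nchar(inserted) == deleted_len)
  if (!ok)
    .stop(sprintf("inconsistent %s: inserted %d nt, deleted_len %d",
                  kind, nchar(inserted), deleted_len),
          "penquant_type_error")
  if (position < 0L)
    .stop("edit position must be >= 0 (at or downstream of the cut)",
          "penquant_coord_error")
  if (position > 10L)
    warning("edit placed > 10 bp from the cut; RT must traverse the gap",
            call. = FALSE)
  structure(list(kind = kind, inserted = inserted,
                 deleted_len = deleted_len, position = position),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("edit_spec: %s at cut%+d (inserted %d nt, deleted %d nt)\n",
              x$kind, x$position, nchar(x$inserted), x$deleted_len))
  invisible(x)
}

# 0-based interval [start, end) of the reference block replaced by the edit
.edit_ref_span <- function(locus, edit) {
  start <- locus$cut_site + edit$position
  c(start = start, end = start + edit$deleted_len)
}

#' Apply an edit to the reference amplicon
#'
#' Returns the desired-product sequence: the amplicon with `deleted_len`
#' bases removed at the edit position and `inserted` written in their place.
#'
#' @param locus a [locate_protospacer()] result.
#' @param edit an [edit_spec()].
#' @return DNA string of length
#'   `nchar(amplicon) + nchar(inserted) - deleted_len`.
#' @export
expected_edited_sequence <- function(locus, edit) {
  stopifnot(inherits(locus, "target_locus"), inherits(edit, "edit_spec"))
  span <- .edit_ref_span(locus, edit)
  if (span["end"] > nchar(locus$amplicon))
    .stop("edit extends past the end of the amplicon", "penquant_coord_error")
  paste0(.sub0(locus$amplicon, 0L, span["start"]),
         edit$inserted,
         .sub0(locus$amplicon, span["end"], nchar(locus$amplicon)))
}

#' Design an HR-pegRNA for a target locus and edit
#'
#' Constructs the pegRNA 3' extension for nuclease prime editing. The
#' reverse transcription template (RTT) encodes, 5' to 3',
#' `revcomp(HR) + revcomp(PR)`:
#' \itemize{
#'   \item PR (programmed region): the new top-strand sequence the RT writes
#'     at the break. For edits placed downstream of the cut this includes the
#'     intervening reference bases that the RT must re-copy; for pure
#'     deletions PR is empty.
#'   \item HR (homologous region): the `hr_len` reference bases immediately
#'     3' of the edited block, which let the RT-written overhang base-pair
#'     with the (resected) downstream DSB end and align precise repair.
#' }
#' The PBS is the reverse complement of the `pbs_len` bases immediately 5'
#' of the cut on the protospacer strand.
#'
#' @param locus,edit see [expected_edited_sequence()].
#' @param pbs_len primer binding site length, 8-17 nt (default 13).
#' @param hr_len homologous region length, 0-25 nt (default 20, the unified
#'   size used for fragment edits; 0 gives the HR-free configuration).
#' @param scaffold sgRNA scaffold sequence (default [SGRNA_SCAFFOLD]).
#' @return An `hr_pegrna` object with fields `spacer`, `scaffold`, `pbs`,
#'   `rtt`, `extension` (= `rtt + pbs`), `pr`, `hr`, `pr_len`, `hr_len`,
#'   `pbs_len`, plus the genomic anchors `cut_site`, `hr_start` (0-based
#'   start of HR on the reference) and `locus_name`.
#' @export
#' @examples
#' amp <- paste0(strrep("A", 40), "GACGTTCTCGATGGTGCTAG", "CGG", strrep("T", 40))
#' loc <- locate_protospacer(amp, "GACGTTCTCGATGGTGCTAG")
#' peg <- design_hr_pegrna(loc, edit_spec("insertion", inserted = "TAG"),
#'                         pbs_len = 13, hr_len = 5)
#' peg$rtt
design_hr_pegrna <- function(locus, edit, pbs_len = 13L, hr_len = 20L,
                             scaffold = SGRNA_SCAFFOLD) {
  stopifnot(inherits(locus, "target_locus"), inherits(edit, "edit_spec"))
  pbs_len <- as.integer(pbs_len); hr_len <- as.integer(hr_len)
  if (pbs_len < 8L || pbs_len > 17L)
    .stop("pbs_len must be in [8, 17]", "penquant_type_error")
  if (hr_len < 0L || hr_len > 25L)
    .stop("hr_len must be in [0, 25]", "penquant_type_error")

  amp <- locus$amplicon
  cut <- locus$cut_site
  span <- .edit_ref_span(locus, edit)
  if (span["end"] > nchar(amp))
    .stop("edit extends past the end of the amplicon", "penquant_coord_error")
  if (cut - pbs_len < 0L)
    .stop("PBS window extends past the start of the amplicon",
          "penquant_coord_error")
  if (span["end"] + hr_len > nchar(amp))
    .stop("HR window extends past the end of the amplicon",
          "penquant_coord_error")

  # PR: everything newly written between the cut and the start of the HR
  pr <- paste0(.sub0(amp, cut, span["start"]), edit$inserted)
  hr <- .sub0(amp, span["end"], span["end"] + hr_len)
  pbs <- revcomp(.sub0(amp, cut - pbs_len, cut))
  rtt <- paste0(revcomp(hr), revcomp(pr))     # == revcomp(pr + hr)

  structure(
    list(spacer = locus$protospacer, scaffold = scaffold,
         pbs = pbs, rtt = rtt, extension = paste0(rtt, pbs),
         pr = pr, hr = hr,
         pr_len = nchar(pr), hr_len = hr_len, pbs_len = pbs_len,
         cut_site = cut, hr_start = unname(span["end"]),
         locus_name = locus$name),
    class = "hr_pegrna")
}

#' @export
print.hr_pegrna <- function(x, ...) {
  cat(sprintf("hr_pegrna (%s): spacer %s\n  PBS (%d nt): %s\n  RTT (%d nt): %s  [PR %d nt, HR %d nt]\n",
              x$locus_name, x$spacer, x$pbs_len, x$pbs,
              nchar(x$rtt), x$rtt, x$pr_len, x$hr_len))
  invisible(x)
}

#' Predicted 3' overhang written by reverse transcription
#'
#' The single-stranded tail appended to the PAM-distal (upstream) DSB end,
#' in top-strand sense: `PR + HR`. For HR-free pegRNAs this is the PR alone;
#' for pure deletions it is the HR alone.
#'
#' @param locus a `target_locus` (orientation context; unused otherwise).
#' @param pegrna an `hr_pegrna`.
#' @return DNA string.
#' @export
predicted_3prime_overhang <- function(locus, pegrna) {
  stopifnot(inherits(pegrna, "hr_pegrna"))
  paste0(pegrna$pr, pegrna$hr)
}

#' Reconstruct the precise repair product from a pegRNA
#'
#' Splices the RT-written overhang onto the upstream flank and rejoins the
#' genomic sequence downstream of the HR anchor:
#' `amplicon[0, cut) + PR + amplicon[hr_start, end)`. For a correctly
#' designed pegRNA this equals [expected_edited_sequence()] (round-trip
#' identity).
#'
#' @inheritParams predicted_3prime_overhang
#' @return DNA string of the precise product.
#' @export
precise_repair_product <- function(locus, pegrna) {
  stopifnot(inherits(locus, "target_locus"), inherits(pegrna, "hr_pegrna"))
  amp <- locus$amplicon
  paste0(.sub0(amp, 0L, pegrna$cut_site), pegrna$pr,
         .sub0(amp, pegrna$hr_start, nchar(amp)))
}

#' Golden-Gate cloning oligos for a pegRNA expression construct
#'
#' Returns the three oligo duplexes that assemble the pegRNA cassette:
#' spacer duplex (top strand 5' `ACCG` and 3' `GTTTT` overhangs; bottom
#' strand 5' `CTCTAAAAC`), scaffold duplex, and 3'-extension duplex (top
#' strand 5' `GTGC`; bottom strand 5' `AAAA`). The concatenated top strands
#' reconstitute `ACCG + spacer + scaffold + RTT + PBS`.
#'
#' @param pegrna an `hr_pegrna`.
#' @return data.frame with columns `part`, `top`, `bottom`.
#' @export
cloning_oligos <- function(pegrna) {
  stopifnot(inherits(pegrna, "hr_pegrna"))
  sc <- pegrna$scaffold
  L <- nchar(sc)
  spacer_top <- paste0("ACCG", pegrna$spacer, "GTTTT")
  spacer_bot <- paste0("CTCTAAAAC", revcomp(pegrna$spacer))
  # spacer duplex contributes scaffold bases 1-5 (GTTTT); the extension top
  # oligo contributes the final 4 (GTGC); the scaffold duplex spans between
  scaffold_top <- substr(sc, 6L, L - 4L)
  scaffold_bot <- revcomp(substr(sc, 10L, L))
  ext_top <- paste0(substr(sc, L - 3L, L), pegrna$extension)
  ext_bot <- paste0("AAAA", revcomp(pegrna$extension))
  data.frame(
    part = c("spacer", "scaffold", "extension"),
    top = c(spacer_top, scaffold_top, ext_top),
    bottom = c(spacer_bot, scaffold_bot, ext_bot),
    stringsAsFactors = FALSE)
}
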