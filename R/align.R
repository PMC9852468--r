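# Two-template pairwise alignment used by the outcome classifier.
#
# Reads are merged consensus reads spanning (most of) the amplicon, so the
# natural alignment is "fitting": the read aligns end-to-end, template
# overhangs are free. Affine gap scoring; a gap of length L costs
# gap_open + L * gap_ext. Traceback is deterministic: on ties,
# match/mismatch is preferred over a gap, a deletion (gap in the read) over
# an insertion (gap in the template), and placement is leftmost.

#' Alignment scoring parameters
#'
#' @param match,mismatch per-base scores (defaults +2 / -4).
#' @param gap_open,gap_ext affine gap parameters (defaults -6 / -1); a gap of
#'   length L costs `gap_open + L * gap_ext`.
#' @return list of scoring parameters.
#' @export
align_params <- function(match = 2L, mismatch = -4L,
                         gap_open = -6L, gap_ext = -1L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

.align_fit <- function(read, tmpl, params) {
  a <- cpp_align_fit(read, tmpl, params$match, params$mismatch,
                     params$gap_open, params$gap_ext)
  a$identity <- a$nmatch / a$aln_len
  a
}

#' Align a read against the reference and the expected-edit template
#'
#' @param read_seq merged read sequence (DNA string).
#' @param ref reference amplicon sequence.
#' @param edited expected edited amplicon ([expected_edited_sequence()]).
#' @param params scoring from [align_params()].
#' @return list with elements `ref` and `edit`, each an alignment: `score`,
#'   `start`/`end` (0-based half-open template span), gapped strings
#'   `read_aln`/`tmpl_aln`, `nmatch`, `aln_len`, `identity`.
#' @export
align_to_templates <- function(read_seq, ref, edited,
                               params = align_params()) {
  if (nchar(read_seq) == 0)
    .stop("empty read", "penquant_type_error")
  list(ref = .align_fit(read_seq, ref, params),
       edit = .align_fit(read_seq, edited, params))
}

# Per-column decomposition of an alignment.
# Returns list(code, rch, tch, tpos): code in {M,I,D}; tpos is the 0-based
# template position of the column (for insertion columns, the position of
# the next template base, i.e. the junction the insertion is anchored to).
.aln_parse <- function(aln) {
  rch <- strsplit(aln$read_aln, "", fixed = TRUE)[[1]]
  tch <- strsplit(aln$tmpl_aln, "", fixed = TRUE)[[1]]
  code <- ifelse(tch == "-", "I", ifelse(rch == "-", "D", "M"))
  is_t <- tch != "-"
  # template position: start + number of template bases consumed before col
  tpos <- aln$start + cumsum(is_t) - ifelse(is_t, 1L, 0L)
  list(code = code, rch = rch, tch = tch, tpos = as.integer(tpos))
}

# Indel runs from a parsed alignment: data.frame(pos, kind, len).
# pos is the 0-based template coordinate of the first deleted base, or the
# junction position for insertions.
.aln_indels <- function(p) {
  r <- rle(p$code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "M"
  if (!any(keep))
    return(data.frame(pos = integer(0), kind = character(0),
                      len = integer(0), stringsAsFactors = FALSE))
  data.frame(pos = p$tpos[starts[keep]],
             kind = ifelse(r$values[keep] == "I", "ins", "del"),
             len = r$lengths[keep], stringsAsFactors = FALSE)
}

# TRUE for indels lying inside a 0-based half-open window [w1, w2).
# A deletion overlaps the window if its span intersects it; an insertion if
# its junction lies strictly inside (junctions at the window edges belong to
# the flanks).
.indel_in_window <- function(indels, window) {
  if (nrow(indels) == 0) return(logical(0))
  w1 <- window[1]; w2 <- window[2]
  ifelse(indels$kind == "del",
         indels$pos < w2 & (indels$pos + indels$len) > w1,
         indels$pos > w1 & indels$pos < w2)
}

# Read bases aligned to template window [w1, w2), gaps removed; insertions
# anchored strictly inside the window are included.
.aln_project <- function(p, window) {
  w1 <- window[1]; w2 <- window[2]
  keep <- (p$code != "I" & p$tpos >= w1 & p$tpos < w2) |
          (p$code == "I" & p$tpos > w1 & p$tpos < w2)
  paste(p$rch[keep & p$rch != "-"], collapse = "")
}
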