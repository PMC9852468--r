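# Allele tables and repair-signature annotation: partial-HR direct joins
# (programmed region plus a truncated homologous region bluntly ligated to
# the unresected downstream DSB end) and microhomology-mediated (MMEJ)
# junction alleles between the RT-written 3' overhang and the downstream
# flank.

# key under which allele identity is defined: the read subsequence aligned
# to the quantification window ("window", robust to distant sequencing
# errors) or the whole read ("read")
.allele_keys <- function(seqs, by, locus, edit, pegrna, window,
                         params = align_params()) {
  if (by == "read") return(seqs)
  classify_reads(seqs, locus, edit, pegrna, window,
                 params = params, orient = "forward")$window_seq
}

#' Tabulate distinct alleles from outcome calls
#'
#' Groups non-discarded reads by allele identity, by default the exact
#' sequence over the quantification-window projection (so distant
#' sequencing errors do not fragment alleles); `by = "read"` switches to
#' whole-read identity. Records are sorted by count (ties by sequence) and
#' mutant alleles get dense ranks, rank 1 being the most abundant
#' non-reference allele ("allele-1").
#'
#' @param calls data.frame from [classify_reads()].
#' @param locus,edit,pegrna,window sample design objects; `window` defaults
#'   to [build_quant_window()] of the design.
#' @param by `"window"` (default) or `"read"`.
#' @return data.frame with columns `seq` (allele key), `count`, `freq`
#'   (fraction of non-discarded reads), `category` (modal call category),
#'   `is_reference`, `rank` (NA for the reference allele) and `annotations`
#'   (empty; filled by [match_partial_hr_joins()] and
#'   [annotate_mh_alleles()]). Attributes `by` and `n_mapped` carry the
#'   keying mode and denominator.
#' @export
tabulate_alleles <- function(calls, locus, edit, pegrna, window = NULL,
                             by = c("window", "read")) {
  by <- match.arg(by)
  if (is.null(window)) window <- build_quant_window(locus, pegrna, edit)
  keep <- calls$category != "DISCARD"
  keys <- if (by == "window") calls$window_seq[keep] else calls$seq[keep]
  cats <- calls$category[keep]
  n <- length(keys)
  if (n == 0L)
    .stop("no mapped reads to tabulate", "penquant_empty_sample")

  tab <- table(keys)
  seqs <- names(tab)
  counts <- as.integer(tab)
  modal <- vapply(seqs, function(s) {
    t2 <- sort(table(cats[keys == s]), decreasing = TRUE)
    names(t2)[1]
  }, character(1), USE.NAMES = FALSE)

  ref_key <- .allele_keys(locus$amplicon, by, locus, edit, pegrna, window)
  ord <- order(-counts, seqs)
  out <- data.frame(seq = seqs[ord], count = counts[ord],
                    freq = counts[ord] / n, category = modal[ord],
                    is_reference = seqs[ord] == ref_key,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- NA_integer_
  out$rank[!out$is_reference] <- seq_len(sum(!out$is_reference))
  out$annotations <- ""
  attr(out, "by") <- by
  attr(out, "n_mapped") <- n
  out
}

.append_annotation <- function(current, tag) {
  ifelse(current == "", tag, paste(current, tag, sep = ";"))
}

#' Predict microhomology-mediated junction alleles
#'
#' Enumerates all substrings of length `min_mh` to `max_mh` shared between
#' the RT-predicted 3' overhang ([predicted_3prime_overhang()]) and the
#' first `scan_len` bases of the downstream DSB flank, and constructs for
#' each the junction allele obtained by annealing at that microhomology and
#' trimming the flaps:
#' `upstream + overhang[1, o_pos + m] + flank[(d_pos + m + 1), ...]`.
#' Candidates predicting the same allele are de-duplicated, keeping the
#' longest microhomology.
#'
#' @param locus,pegrna,edit sample design objects.
#' @param min_mh,max_mh microhomology length range (defaults 3 and 10, the
#'   conventional MMEJ range).
#' @param scan_len downstream bases scanned (default 30).
#' @return data.frame with columns `mh_seq`, `m` (length), `overhang_pos`
#'   and `downstream_pos` (0-based offsets of the microhomology within the
#'   overhang and within the downstream flank), `predicted_allele`,
#'   `retains_pr` (the junction keeps the full programmed region) and
#'   `is_precise` (the predicted allele equals the precise product, as when
#'   the homologous region itself anneals at its genomic position). Sorted
#'   by decreasing microhomology length.
#' @export
predict_mh_alleles <- function(locus, pegrna, edit, min_mh = 3L,
                               max_mh = 10L, scan_len = 30L) {
  stopifnot(inherits(locus, "target_locus"), inherits(pegrna, "hr_pegrna"))
  min_mh <- as.integer(min_mh); max_mh <- as.integer(max_mh)
  if (min_mh < 2L) .stop("min_mh must be >= 2", "penquant_type_error")
  ref <- locus$amplicon
  cut <- locus$cut_site
  ov <- predicted_3prime_overhang(locus, pegrna)
  down <- .sub0(ref, cut, min(nchar(ref), cut + as.integer(scan_len)))

  empty <- data.frame(mh_seq = character(0), m = integer(0),
                      overhang_pos = integer(0), downstream_pos = integer(0),
                      predicted_allele = character(0),
                      retains_pr = logical(0), is_precise = logical(0),
                      stringsAsFactors = FALSE)
  mmax <- min(max_mh, nchar(ov), nchar(down))
  if (nchar(ov) == 0L || mmax < min_mh) return(empty)

  rows <- list()
  upstream <- .sub0(ref, 0L, cut)
  for (m in seq(min_mh, mmax)) {
    for (o in 0:(nchar(ov) - m)) {
      mh <- .sub0(ov, o, o + m)
      # lookahead so overlapping occurrences are found too
      hits <- gregexpr(paste0("(?=", mh, ")"), down, perl = TRUE)[[1]]
      hits <- hits[hits > 0]
      for (h in hits) {
        d <- h - 1L
        allele <- paste0(upstream, .sub0(ov, 0L, o + m),
                         .sub0(ref, cut + d + m, nchar(ref)))
        rows[[length(rows) + 1L]] <-
          data.frame(mh_seq = mh, m = m, overhang_pos = o,
                     downstream_pos = d, predicted_allele = allele,
                     retains_pr = (o + m) >= pegrna$pr_len,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  # de-duplicate identical predicted alleles, keeping the longest MH
  out <- out[order(-out$m, out$overhang_pos, out$downstream_pos), ,
             drop = FALSE]
  out <- out[!duplicated(out$predicted_allele), , drop = FALSE]
  out$is_precise <- out$predicted_allele == expected_edited_sequence(locus, edit)
  rownames(out) <- NULL
  out
}

# Partial-HR blunt-join construct: upstream + PR + HR[1..k] + unresected
# downstream flank (the unaltered sequence from the cut onward).
.partial_hr_construct <- function(locus, pegrna, k) {
  ref <- locus$amplicon
  cut <- pegrna$cut_site
  paste0(.sub0(ref, 0L, cut), pegrna$pr, .sub0(pegrna$hr, 0L, k),
         .sub0(ref, cut, nchar(ref)))
}

#' Annotate alleles that match partial-HR direct-join products
#'
#' For k = 0..hr_len, constructs the allele expected when the RT-written
#' overhang (programmed region plus the first k bases of the homologous
#' region) is ligated bluntly to the unresected downstream DSB end. Alleles
#' exactly matching a construct are annotated `PARTIAL_HR_JOIN(k)`; an
#' allele matching the precise product (which a blunt join can produce, e.g.
#' the k = 0 join of a pure insertion) is annotated `PRECISE` instead.
#'
#' @param alleles table from [tabulate_alleles()].
#' @param locus,pegrna,edit,window sample design objects (the same used for
#'   tabulation).
#' @return `alleles` with updated `annotations`.
#' @export
match_partial_hr_joins <- function(alleles, locus, pegrna, edit,
                                   window = NULL) {
  by <- attr(alleles, "by")
  if (is.null(by)) by <- "read"
  if (is.null(window)) window <- build_quant_window(locus, pegrna, edit)
  precise <- expected_edited_sequence(locus, edit)
  precise_key <- .allele_keys(precise, by, locus, edit, pegrna, window)

  ks <- 0:pegrna$hr_len
  constructs <- vapply(ks, function(k) .partial_hr_construct(locus, pegrna, k),
                       character(1))
  keys <- .allele_keys(constructs, by, locus, edit, pegrna, window)

  hit_precise <- alleles$seq == precise_key
  alleles$annotations[hit_precise] <-
    .append_annotation(alleles$annotations[hit_precise], "PRECISE")
  for (i in seq_along(ks)) {
    if (keys[i] == precise_key) next
    hit <- alleles$seq == keys[i]
    alleles$annotations[hit] <-
      .append_annotation(alleles$annotations[hit],
                         sprintf("PARTIAL_HR_JOIN(%d)", ks[i]))
  }
  alleles
}

#' Annotate alleles matching predicted microhomology junction products
#'
#' @param alleles table from [tabulate_alleles()].
#' @param candidates data.frame from [predict_mh_alleles()].
#' @inheritParams match_partial_hr_joins
#' @return `alleles` with `MH_JUNCTION(m, pos)` annotations (microhomology
#'   length and its 0-based offset within the overhang).
#' @export
annotate_mh_alleles <- function(alleles, candidates, locus, pegrna, edit,
                                window = NULL) {
  if (nrow(candidates) == 0) return(alleles)
  by <- attr(alleles, "by")
  if (is.null(by)) by <- "read"
  if (is.null(window)) window <- build_quant_window(locus, pegrna, edit)
  keys <- .allele_keys(candidates$predicted_allele, by, locus, edit, pegrna,
                       window)
  for (i in seq_len(nrow(candidates))) {
    if (candidates$is_precise[i]) next
    hit <- alleles$seq == keys[i]
    alleles$annotations[hit] <-
      .append_annotation(alleles$annotations[hit],
                         sprintf("MH_JUNCTION(%d,%d)", candidates$m[i],
                                 candidates$overhang_pos[i]))
  }
  alleles
}

#' Run the full allele annotation pass
#'
#' Convenience wrapper: [match_partial_hr_joins()], [annotate_mh_alleles()]
#' (with default microhomology settings), then a `CLASSICAL_INDEL` tag on
#' otherwise unannotated direct-indel alleles.
#'
#' @inheritParams match_partial_hr_joins
#' @param min_mh,max_mh,scan_len passed to [predict_mh_alleles()].
#' @return annotated allele table.
#' @export
annotate_alleles <- function(alleles, locus, pegrna, edit, window = NULL,
                             min_mh = 3L, max_mh = 10L, scan_len = 30L) {
  alleles <- match_partial_hr_joins(alleles, locus, pegrna, edit, window)
  cand <- predict_mh_alleles(locus, pegrna, edit, min_mh, max_mh, scan_len)
  alleles <- annotate_mh_alleles(alleles, cand, locus, pegrna, edit, window)
  plain <- alleles$annotations == "" & alleles$category == "DIRECT_INDEL"
  alleles$annotations[plain] <- "CLASSICAL_INDEL"
  alleles
}
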