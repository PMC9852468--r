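# Editing-outcome classification and summary metrics.
#
# Taxonomy (mutually exclusive over non-discarded reads):
#   ACCURATE      desired edit present, no extra indels in the window
#   IMPRECISE_RT  programmed sequence present, but with window indels
#   DIRECT_INDEL  no programmed sequence, classical NHEJ indel at the cut
#   UNEDITED      no programmed sequence, no window indels (substitution-only
#                 mismatches count as sequencing error)
#   DISCARD       best alignment identity below the floor

#' Build quantification windows around the cut and the RT 3' end
#'
#' Windows extend `pad` bases beyond the cleavage site on one side and the
#' 3'-end position of the template-dependent RT product on the other,
#' clipped to the sequence bounds (with a warning). On the edited template
#' the RT end is `cut_site + len(PR) + hr_len`; `ref_window` is its
#' projection onto the reference.
#'
#' @param locus,pegrna,edit design objects for the sample.
#' @param pad extension in bases (default 30).
#' @return A `quant_window`: list with `ref_window` and `edit_window`
#'   (0-based half-open intervals), `rt_end_ref`, `rt_end_edit`, `cut_site`,
#'   `pr_len` and `pad`.
#' @export
build_quant_window <- function(locus, pegrna, edit, pad = 30L) {
  stopifnot(inherits(locus, "target_locus"), inherits(pegrna, "hr_pegrna"),
            inherits(edit, "edit_spec"))
  pad <- as.integer(pad)
  if (pad < 0L) .stop("pad must be >= 0", "penquant_type_error")
  cut <- locus$cut_site
  len_ref <- nchar(locus$amplicon)
  len_edit <- len_ref + nchar(edit$inserted) - edit$deleted_len
  rt_end_edit <- cut + pegrna$pr_len + pegrna$hr_len
  rt_end_ref <- cut + edit$position + edit$deleted_len + pegrna$hr_len

  clipped <- FALSE
  clip <- function(lo, hi, n) {
    if (lo < 0L || hi > n) clipped <<- TRUE
    c(max(0L, lo), min(n, hi))
  }
  rw <- clip(cut - pad, rt_end_ref + pad, len_ref)
  ew <- clip(cut - pad, rt_end_edit + pad, len_edit)
  if (clipped)
    warning("quantification window clipped at amplicon edge", call. = FALSE)
  structure(
    list(ref_window = rw,
         edit_window = ew,
         rt_end_ref = rt_end_ref, rt_end_edit = rt_end_edit,
         cut_site = cut, pr_len = pegrna$pr_len, pad = pad),
    class = "quant_window")
}

# Orientation guess from three probe k-mers; falls back to alignment scores.
.orient_read <- function(seq, ref, edited, params) {
  n <- nchar(seq)
  if (n < 25L) return(seq)
  at <- unique(pmax(1L, c(1L, n %/% 2L - 10L, n - 20L)))
  probes <- substring(seq, at, pmin(n, at + 20L))
  hf <- sum(vapply(probes, grepl, logical(1), x = ref, fixed = TRUE))
  if (hf == length(probes)) return(seq)
  rc <- .rc1(seq)
  probes_rc <- substring(rc, at, pmin(n, at + 20L))
  hr <- sum(vapply(probes_rc, grepl, logical(1), x = ref, fixed = TRUE))
  if (hf > hr) return(seq)
  if (hr > hf) return(rc)
  sf <- .align_fit(seq, ref, params)$score
  sr <- .align_fit(rc, ref, params)$score
  if (sr > sf) rc else seq
}

# edit-locus checks on the edited-template alignment. The locus is the
# programmed region plus one flanking base on each side.
# "covered": every locus base aligned, no deletion column, no insertion
# anchored strictly inside (substitution mismatches tolerated - they occur
# at the sequencing error rate). "matched": additionally all exact matches.
.edit_locus_span <- function(parsed, window, tmpl_len) {
  a <- max(0L, window$cut_site - 1L)
  b <- min(tmpl_len, window$cut_site + window$pr_len + 1L)
  list(a = a, b = b, cols = parsed$tpos >= a & parsed$tpos < b)
}

.edit_locus_covered <- function(parsed, window, tmpl_len) {
  lc <- .edit_locus_span(parsed, window, tmpl_len)
  if (lc$b <= lc$a) return(FALSE)
  mpos <- parsed$tpos[parsed$code == "M"]
  ins_inside <- any(parsed$code == "I" & parsed$tpos > lc$a & parsed$tpos < lc$b)
  all(seq(lc$a, lc$b - 1L) %in% mpos) && !ins_inside
}

.edit_locus_matched <- function(parsed, window, tmpl_len) {
  lc <- .edit_locus_span(parsed, window, tmpl_len)
  .edit_locus_covered(parsed, window, tmpl_len) &&
    all(parsed$rch[lc$cols] == parsed$tch[lc$cols])
}

.classify_one <- function(seq, ref, edited, pegrna, edit, window, params,
                          id_floor, orient) {
  if (orient == "auto") seq <- .orient_read(seq, ref, edited, params)
  pr <- pegrna$pr
  aln_r <- NULL; aln_e <- NULL
  get_r <- function() { if (is.null(aln_r)) aln_r <<- .align_fit(seq, ref, params); aln_r }
  get_e <- function() { if (is.null(aln_e)) aln_e <<- .align_fit(seq, edited, params); aln_e }

  # PR evidence: exact substring fast-accept for PR >= 6 nt; otherwise (and
  # for substring misses, e.g. a sequencing error inside the PR) the
  # alignment route: the edited template must score strictly higher than the
  # reference (ties go to the reference) and the edit locus must be aligned
  # without indels -- exactly for substitution edits, mismatch-tolerantly for
  # the rest (substitution noise occurs at the sequencing error rate).
  contains_pr <- nchar(pr) >= 6L && grepl(pr, seq, fixed = TRUE)
  if (contains_pr) {
    get_e()
  } else {
    e <- get_e(); r <- get_r()
    locus_ok <- if (edit$kind == "substitution")
      .edit_locus_matched(.aln_parse(e), window, nchar(edited))
    else .edit_locus_covered(.aln_parse(e), window, nchar(edited))
    contains_pr <- e$score > r$score && locus_ok
  }

  chosen <- if (contains_pr) "edit" else "ref"
  aln <- if (contains_pr) get_e() else get_r()
  parsed <- .aln_parse(aln)
  win <- if (contains_pr) window$edit_window else window$ref_window

  # discard on low identity of the better alignment
  best_id <- aln$identity
  if (best_id < id_floor) {
    other <- if (contains_pr) get_r() else get_e()
    best_id <- max(best_id, other$identity)
    if (best_id < id_floor) {
      return(list(category = "DISCARD", contains_pr = contains_pr,
                  chosen_template = chosen, distal_indel = NA,
                  identity = best_id, window_seq = NA_character_,
                  seq = seq,
                  indels = data.frame(pos = integer(0), kind = character(0),
                                      len = integer(0), in_window = logical(0))))
    }
  }

  indels <- .aln_indels(parsed)
  indels$in_window <- .indel_in_window(indels, win)
  n_win <- sum(indels$in_window)

  if (contains_pr) {
    locus_fn <- if (edit$kind == "substitution") .edit_locus_matched
                else .edit_locus_covered
    accurate <- n_win == 0L && locus_fn(parsed, window, nchar(edited))
    category <- if (accurate) "ACCURATE" else "IMPRECISE_RT"
    # distal: every window indel lies beyond the cut, in the RT-written
    # region or past it, rather than at the guide target itself
    distal <- if (category == "IMPRECISE_RT" && n_win > 0L) {
      all(indels$pos[indels$in_window] > window$cut_site)
    } else NA
  } else {
    category <- if (n_win > 0L) "DIRECT_INDEL" else "UNEDITED"
    distal <- NA
  }

  list(category = category, contains_pr = contains_pr,
       chosen_template = chosen, distal_indel = distal,
       identity = aln$identity,
       window_seq = .aln_project(parsed, win),
       seq = seq, indels = indels)
}

#' Classify merged reads into editing-outcome categories
#'
#' Decision procedure per read: (1) programmed-sequence (PR) evidence — for
#' edits whose PR is at least 6 nt an exact substring hit accepts
#' immediately; otherwise (short PRs, substitutions, or a substring miss,
#' e.g. from a sequencing error inside the PR) the read must align strictly
#' better to the edited template than to the reference *and* carry the edit
#' locus without indels — exactly for substitution edits,
#' mismatch-tolerantly for the rest. (2) Reads with PR evidence and no indels inside
#' the edit-template quantification window (with the edit locus matched
#' exactly) are `ACCURATE`; (3) other PR-containing reads are
#' `IMPRECISE_RT`, with `distal_indel = TRUE` when every window indel lies
#' strictly beyond the cut site (in or past the RT-written region, rather
#' than at the guide target itself). (4) Reads
#' without PR evidence are `DIRECT_INDEL` if the reference alignment has an
#' indel inside the reference window, (5) otherwise `UNEDITED`
#' (substitution-only mismatches count as sequencing error). (6) Reads whose
#' best alignment identity falls below `id_floor` are `DISCARD`ed.
#'
#' @param merged data.frame with columns `id` and `seq`
#'   (from [merge_pairs()]), or a character vector of sequences.
#' @param locus,edit,pegrna design objects for the sample.
#' @param window a [build_quant_window()] result (built with its defaults
#'   when `NULL`).
#' @param params alignment scoring ([align_params()]).
#' @param id_floor minimum identity of the best alignment (default 0.6).
#' @param orient `"auto"` tries both read orientations; `"forward"` trusts
#'   the input orientation.
#' @return data.frame of calls: `read_id`, `category`, `contains_pr`,
#'   `chosen_template`, `distal_indel`, `identity`, `window_seq`, `seq`
#'   (orientation-normalized), and a list-column `indels` (per-read
#'   data.frame `pos`, `kind`, `len`, `in_window`, in chosen-template
#'   coordinates).
#' @export
classify_reads <- function(merged, locus, edit, pegrna, window = NULL,
                           params = align_params(), id_floor = 0.6,
                           orient = c("auto", "forward")) {
  orient <- match.arg(orient)
  stopifnot(inherits(locus, "target_locus"), inherits(edit, "edit_spec"),
            inherits(pegrna, "hr_pegrna"))
  if (is.character(merged))
    merged <- data.frame(id = paste0("read_", seq_along(merged)),
                         seq = merged, stringsAsFactors = FALSE)
  if (is.null(window)) window <- build_quant_window(locus, pegrna, edit)
  ref <- locus$amplicon
  edited <- expected_edited_sequence(locus, edit)

  n <- nrow(merged)
  res <- vector("list", n)
  for (i in seq_len(n))
    res[[i]] <- .classify_one(merged$seq[i], ref, edited, pegrna, edit,
                              window, params, id_floor, orient)
  out <- data.frame(
    read_id = merged$id,
    category = vapply(res, `[[`, character(1), "category"),
    contains_pr = vapply(res, `[[`, logical(1), "contains_pr"),
    chosen_template = vapply(res, `[[`, character(1), "chosen_template"),
    distal_indel = vapply(res, function(x) as.logical(x$distal_indel),
                          logical(1)),
    identity = vapply(res, `[[`, numeric(1), "identity"),
    window_seq = vapply(res, `[[`, character(1), "window_seq"),
    seq = vapply(res, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$indels <- I(lapply(res, `[[`, "indels"))
  out
}

#' Classify a single read
#'
#' Convenience wrapper returning the one-row result of [classify_reads()].
#' @inheritParams classify_reads
#' @param read_seq a single merged-read sequence.
#' @export
classify_read <- function(read_seq, locus, edit, pegrna, window = NULL, ...) {
  classify_reads(read_seq, locus, edit, pegrna, window, ...)
}

#' Summarize outcome calls into per-sample editing metrics
#'
#' Percentages are over non-discarded ("mapped") reads. The count identities
#' hold exactly: accurate + imprecise = all RT-driven; unintended =
#' direct indels + imprecise. Purity is accurate / all RT-driven, reported
#' as `NA` when no RT-driven reads exist.
#'
#' @param calls data.frame from [classify_reads()].
#' @return An `editing_summary` list: `n_total_mapped`, `n_discard`,
#'   `n_per_category` (named counts), `accurate_pct`, `imprecise_pct`,
#'   `all_rt_pct`, `direct_indel_pct`, `unedited_pct`, `unintended_pct`,
#'   `purity`.
#' @export
summarize_calls <- function(calls) {
  cats <- c("ACCURATE", "IMPRECISE_RT", "DIRECT_INDEL", "UNEDITED")
  keep <- calls$category != "DISCARD"
  n <- sum(keep)
  if (n == 0L)
    .stop("all reads were discarded; nothing to summarize",
          "penquant_empty_sample")
  counts <- setNames(vapply(cats, function(k) sum(calls$category[keep] == k),
                            integer(1)), cats)
  pct <- function(k) 100 * counts[[k]] / n
  n_rt <- counts[["ACCURATE"]] + counts[["IMPRECISE_RT"]]
  structure(
    list(n_total_mapped = n, n_discard = sum(!keep), n_per_category = counts,
         accurate_pct = pct("ACCURATE"),
         imprecise_pct = pct("IMPRECISE_RT"),
         all_rt_pct = 100 * n_rt / n,
         direct_indel_pct = pct("DIRECT_INDEL"),
         unedited_pct = pct("UNEDITED"),
         unintended_pct = pct("DIRECT_INDEL") + pct("IMPRECISE_RT"),
         purity = if (n_rt > 0) counts[["ACCURATE"]] / n_rt else NA_real_),
    class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("editing_summary: %d mapped reads (%d discarded)\n",
              x$n_total_mapped, x$n_discard))
  cat(sprintf("  accurate %.2f%% | imprecise RT %.2f%% | all RT-driven %.2f%%\n",
              x$accurate_pct, x$imprecise_pct, x$all_rt_pct))
  cat(sprintf("  direct indel %.2f%% | unintended %.2f%% | unedited %.2f%%\n",
              x$direct_indel_pct, x$unintended_pct, x$unedited_pct))
  cat(sprintf("  purity (accurate / all RT-driven): %s\n",
              if (is.na(x$purity)) "undefined (no RT-driven reads)"
              else sprintf("%.3f", x$purity)))
  invisible(x)
}

#' Signed indel-size histogram, split by outcome category
#'
#' Counts window indels across calls; insertion sizes are positive,
#' deletion sizes negative.
#'
#' @param calls data.frame from [classify_reads()].
#' @return data.frame with columns `category`, `size`, `count`; the counts
#'   sum to the total number of window indels.
#' @export
indel_size_distribution <- function(calls) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    ind <- calls$indels[[i]]
    ind <- ind[ind$in_window, , drop = FALSE]
    if (nrow(ind) == 0) return(NULL)
    data.frame(category = calls$category[i],
               size = ifelse(ind$kind == "ins", ind$len, -ind$len),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (is.null(all))
    return(data.frame(category = character(0), size = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                   by = list(category = all$category, size = all$size),
                   FUN = sum)
  agg[order(agg$category, agg$size), , drop = FALSE]
}
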