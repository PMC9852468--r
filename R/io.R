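# Paired-end amplicon I/O: FASTQ reading/writing, barcode demultiplexing,
# and consensus merging of read pairs.
#
# Read pairs are plain data.frames with columns id, r1_seq, r1_qual,
# r2_seq, r2_qual (Phred+33 qualities), the in-memory form produced by
# simulate_reads() and read_fastq_pairs().

#' Read paired FASTQ files into a read-pair table
#'
#' @param r1_path,r2_path FASTQ files (gzip transparent), mate 1 and mate 2
#'   in matching order.
#' @return data.frame with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # coercions from the quality-scaled container note dropping its qualities
  # metadata column; that is expected here, so the note is muffled
  withCallingHandlers({
    r1 <- Biostrings::readQualityScaledDNAStringSet(r1_path)
    r2 <- Biostrings::readQualityScaledDNAStringSet(r2_path)
    if (length(r1) != length(r2))
      .stop("mate files differ in read count", "penquant_config_error")
    ids <- sub("[/ ].*$", "", names(r1))
    data.frame(id = ids,
               r1_seq = as.character(r1),
               r1_qual = as.character(Biostrings::quality(r1)),
               r2_seq = as.character(r2),
               r2_qual = as.character(Biostrings::quality(r2)),
               stringsAsFactors = FALSE, row.names = NULL)
  }, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Write a read-pair table as paired FASTQ
#'
#' @param pairs read-pair data.frame (see [read_fastq_pairs()]).
#' @param r1_path,r2_path output paths; a `.gz` suffix triggers compression.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  .write_fq <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    # writeXStringSet stores the qualities as a metadata column and then
    # notes dropping it for the sequence output; that note is expected here
    withCallingHandlers(
      Biostrings::writeXStringSet(
        x, path, format = "fastq",
        compress = grepl("\\.gz$", path),
        qualities = Biostrings::BStringSet(quals)),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  .write_fq(pairs$r1_seq, pairs$r1_qual, pairs$id, r1_path)
  .write_fq(pairs$r2_seq, pairs$r2_qual, pairs$id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Demultiplex barcoded read pairs by 5' barcode on mate 1
#'
#' Each pair is assigned to the unique sample whose barcode matches the
#' start of `r1_seq` within `max_mismatch` substitutions; pairs matching no
#' barcode (or, with `max_mismatch > 0`, more than one equally well) fall
#' into the `undetermined` bin.
#'
#' @param pairs read-pair data.frame.
#' @param barcode_table data.frame with columns `sample`, `barcode`; the
#'   barcode set must be prefix-free.
#' @param max_mismatch allowed barcode mismatches (default 0: barcodes are
#'   short, exact matching avoids sample cross-talk).
#' @return list with `samples` (named list of read-pair data.frames),
#'   `undetermined` (data.frame) and `stats` (data.frame of per-bin counts;
#'   counts sum to `nrow(pairs)`).
#' @export
demultiplex <- function(pairs, barcode_table, max_mismatch = 0L) {
  if (!all(c("sample", "barcode") %in% names(barcode_table)))
    .stop("barcode_table needs columns 'sample' and 'barcode'",
          "penquant_config_error")
  bc <- toupper(barcode_table$barcode)
  if (anyDuplicated(barcode_table$sample) || anyDuplicated(bc))
    .stop("duplicate sample names or barcodes", "penquant_config_error")
  for (i in seq_along(bc)) for (j in seq_along(bc)) {
    if (i != j && startsWith(bc[j], bc[i]))
      .stop(sprintf("barcode table is not prefix-free: '%s' is a prefix of '%s'",
                    bc[i], bc[j]), "penquant_config_error")
  }

  assign_one <- function(seq) {
    best <- integer(0); best_mm <- max_mismatch + 1L
    for (i in seq_along(bc)) {
      pre <- substr(seq, 1L, nchar(bc[i]))
      if (nchar(pre) < nchar(bc[i])) next
      mm <- sum(charToRaw(pre) != charToRaw(bc[i]))
      if (mm < best_mm) { best <- i; best_mm <- mm }
      else if (mm == best_mm && mm <= max_mismatch) best <- c(best, i)
    }
    if (length(best) == 1L && best_mm <= max_mismatch) best else NA_integer_
  }
  idx <- vapply(pairs$r1_seq, assign_one, integer(1), USE.NAMES = FALSE)

  samples <- setNames(
    lapply(seq_along(bc), function(i) pairs[!is.na(idx) & idx == i, ,
                                            drop = FALSE]),
    barcode_table$sample)
  undet <- pairs[is.na(idx), , drop = FALSE]
  stats <- data.frame(
    sample = c(barcode_table$sample, "undetermined"),
    n = c(vapply(samples, nrow, integer(1)), nrow(undet)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(samples = samples, undetermined = undet, stats = stats)
}

#' Merge one read pair into a consensus read
#'
#' Finds the best ungapped overlap between mate 1 and the reverse complement
#' of mate 2: overlap lengths are scanned from the longest possible down to
#' `min_overlap` and the longest overlap whose mismatch fraction is at most
#' `max_mismatch_frac` wins. At disagreeing overlap positions the
#' higher-quality base is taken (ties resolved toward mate 1). Pairs with no
#' qualifying overlap return `NULL` (a data outcome, not an error).
#'
#' @param r1_seq,r1_qual,r2_seq,r2_qual mate sequences and Phred+33 quality
#'   strings.
#' @param min_overlap minimum overlap length (default 11, the consensus-merge
#'   rule used for PE150/PE250 amplicon data).
#' @param max_mismatch_frac maximum fraction of mismatching overlap positions
#'   (default 0.1).
#' @return list with `seq`, `qual`, `overlap_len`, `mismatches`, or `NULL`
#'   when merging fails.
#' @export
merge_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                       min_overlap = 11L, max_mismatch_frac = 0.1) {
  if (min_overlap < 1L)
    .stop("min_overlap must be >= 1", "penquant_config_error")
  res <- cpp_merge_pair(r1_seq, r1_qual, revcomp(r2_seq),
                        paste(rev(strsplit(r2_qual, "")[[1]]), collapse = ""),
                        as.integer(min_overlap), max_mismatch_frac)
  if (!res$ok) return(NULL)
  list(seq = res$seq, qual = res$qual, overlap_len = res$overlap,
       mismatches = res$mismatches)
}

#' Merge a table of read pairs
#'
#' Vectorized driver over [merge_pair()]. Pairs that fail to merge are
#' excluded from downstream classification and reported in `stats`.
#'
#' @param pairs read-pair data.frame.
#' @inheritParams merge_pair
#' @return list with `merged` (data.frame `id`, `seq`, `qual`,
#'   `overlap_len`), `failed_ids` (character) and `stats` (list with
#'   `n_input`, `n_merged`, `n_failed`, `merge_rate`).
#' @export
merge_pairs <- function(pairs, min_overlap = 11L, max_mismatch_frac = 0.1) {
  if (min_overlap < 1L)
    .stop("min_overlap must be >= 1", "penquant_config_error")
  n <- nrow(pairs)
  r2rc <- revcomp(pairs$r2_seq)
  q2r <- vapply(pairs$r2_qual,
                function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE)
  seqs <- character(n); quals <- character(n)
  olen <- integer(n); ok <- logical(n)
  for (i in seq_len(n)) {
    res <- cpp_merge_pair(pairs$r1_seq[i], pairs$r1_qual[i], r2rc[i], q2r[i],
                          as.integer(min_overlap), max_mismatch_frac)
    ok[i] <- res$ok
    if (res$ok) { seqs[i] <- res$seq; quals[i] <- res$qual; olen[i] <- res$overlap }
  }
  merged <- data.frame(id = pairs$id[ok], seq = seqs[ok], qual = quals[ok],
                       overlap_len = olen[ok],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(merged = merged,
       failed_ids = pairs$id[!ok],
       stats = list(n_input = n, n_merged = sum(ok), n_failed = sum(!ok),
                    merge_rate = if (n > 0) sum(ok) / n else NA_real_))
}
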