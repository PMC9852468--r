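# Design-sheet interface: TSV in (one row per target/edit), designed pegRNA
# parts, oligo sheets and expected-product FASTA out; plus the end-to-end
# per-sample quantification driver.

#' Read a pegRNA design sheet
#'
#' Tab-separated, one row per design, columns: `name`, `protospacer`,
#' `edit_kind`, `inserted`, `deleted_len`, `position`, `pbs_len`, `hr_len`
#' (missing numeric fields default to position 0, pbs 13, hr 20).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_design_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "protospacer", "edit_kind")
  if (!all(need %in% names(sheet)))
    .stop(paste("design sheet needs columns:", paste(need, collapse = ", ")),
          "penquant_config_error")
  defaults <- c(deleted_len = 0L, position = 0L, pbs_len = 13L, hr_len = 20L)
  for (col in names(defaults)) {
    if (!col %in% names(sheet)) sheet[[col]] <- defaults[[col]]
    sheet[[col]][is.na(sheet[[col]])] <- defaults[[col]]
  }
  if (!"inserted" %in% names(sheet)) sheet$inserted <- ""
  sheet$inserted <- as.character(sheet$inserted)
  sheet$inserted[is.na(sheet$inserted)] <- ""
  sheet
}

#' Build design objects from a design sheet
#'
#' @param sheet data.frame from [read_design_sheet()].
#' @param amplicons named character vector of amplicon sequences, or the
#'   path of a FASTA file whose record names match the sheet's `name`
#'   column.
#' @return named list of designs, each a list with `locus`, `edit`,
#'   `pegrna`, `window`.
#' @export
design_from_sheet <- function(sheet, amplicons) {
  if (is.character(amplicons) && length(amplicons) == 1 &&
      file.exists(amplicons)) {
    fa <- Biostrings::readDNAStringSet(amplicons)
    amplicons <- setNames(as.character(fa),
                          sub("\\s.*$", "", names(fa)))  # id = first token
  }
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    row <- sheet[i, ]
    if (!row$name %in% names(amplicons))
      .stop(sprintf("no amplicon named '%s'", row$name),
            "penquant_config_error")
    locus <- locate_protospacer(toupper(amplicons[[row$name]]),
                                toupper(row$protospacer), name = row$name)
    edit <- edit_spec(row$edit_kind, inserted = toupper(row$inserted),
                      deleted_len = row$deleted_len, position = row$position)
    pegrna <- design_hr_pegrna(locus, edit, pbs_len = row$pbs_len,
                               hr_len = row$hr_len)
    list(locus = locus, edit = edit, pegrna = pegrna,
         window = build_quant_window(locus, pegrna, edit))
  })
  setNames(out, sheet$name)
}

#' Write design outputs: pegRNA parts, oligo sheet, expected products
#'
#' @param designs list from [design_from_sheet()].
#' @param dir output directory (created if needed). Writes `pegrnas.tsv`,
#'   `oligos.tsv` and `expected_products.fa`.
#' @return invisibly, the output paths.
#' @export
write_design_outputs <- function(designs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- do.call(rbind, lapply(names(designs), function(nm) {
    p <- designs[[nm]]$pegrna
    data.frame(name = nm, spacer = p$spacer, pbs = p$pbs, rtt = p$rtt,
               extension = p$extension, pr = p$pr, hr = p$hr,
               pbs_len = p$pbs_len, hr_len = p$hr_len,
               stringsAsFactors = FALSE)
  }))
  oligos <- do.call(rbind, lapply(names(designs), function(nm) {
    o <- cloning_oligos(designs[[nm]]$pegrna)
    cbind(name = nm, o)
  }))
  products <- Biostrings::DNAStringSet(vapply(designs, function(d)
    expected_edited_sequence(d$locus, d$edit), character(1)))
  names(products) <- names(designs)

  paths <- file.path(dir, c("pegrnas.tsv", "oligos.tsv",
                            "expected_products.fa"))
  write.table(parts, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(oligos, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(products, paths[3])
  invisible(paths)
}

#' Quantify one sample end-to-end
#'
#' Merges read pairs, classifies the consensus reads and summarizes:
#' the per-sample pipeline behind the `quantify` command.
#'
#' @param pairs read-pair data.frame ([read_fastq_pairs()] or
#'   [simulate_reads()]`$pairs`).
#' @param design one element of [design_from_sheet()] (list with `locus`,
#'   `edit`, `pegrna`, `window`).
#' @param pad quantification-window extension (default 30).
#' @param min_overlap,max_mismatch_frac merge settings ([merge_pairs()]).
#' @param ... passed to [classify_reads()].
#' @return list with `merge` (merge stats), `calls`, `summary`
#'   ([summarize_calls()]), `alleles` (annotated [tabulate_alleles()] table)
#'   and `indel_hist`.
#' @export
quantify_sample <- function(pairs, design, pad = 30L, min_overlap = 11L,
                            max_mismatch_frac = 0.1, ...) {
  window <- build_quant_window(design$locus, design$pegrna, design$edit,
                               pad = pad)
  mg <- merge_pairs(pairs, min_overlap = min_overlap,
                    max_mismatch_frac = max_mismatch_frac)
  calls <- classify_reads(mg$merged, design$locus, design$edit,
                          design$pegrna, window, ...)
  summary <- summarize_calls(calls)
  alleles <- tabulate_alleles(calls, design$locus, design$edit,
                              design$pegrna, window)
  alleles <- annotate_alleles(alleles, design$locus, design$pegrna,
                              design$edit, window)
  list(merge = mg$stats, calls = calls, summary = summary,
       alleles = alleles, indel_hist = indel_size_distribution(calls))
}
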