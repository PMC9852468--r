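# Ground-truth editing-outcome simulator: allele mixtures and paired-end
# amplicon reads emulating PEn/uPEn targeted deep-sequencing data (PCR
# amplicon with the cut near the center, PE150/PE250 reads overlapping in
# the middle, substitution-type sequencing errors).

#' Ground-truth outcome mixture
#'
#' Proportions of the editing-outcome allele classes a sample is simulated
#' from: the precise product, partial-HR blunt joins, a microhomology
#' junction allele, classical NHEJ indels, and unedited reads.
#'
#' @param p_precise,p_partial_hr,p_mh,p_classical_indel,p_unedited
#'   non-negative fractions summing to 1.
#' @param partial_hr_k_dist named numeric vector: probability per retained
#'   HR length k (names are k values). Default: uniform over
#'   k = 1..hr_len-1 (resolved in [make_allele_set()]; k = 0 and k = hr_len
#'   are excluded because those blunt joins can coincide with the precise
#'   product or the reference).
#' @param classical_indel_dist named numeric vector: probability per signed
#'   indel size (negative = deletion). Default: small deletions dominate
#'   with some +1 insertions, the typical NHEJ spectrum.
#' @return An `outcome_mixture` object.
#' @export
outcome_mixture <- function(p_precise = 0, p_partial_hr = 0, p_mh = 0,
                            p_classical_indel = 0, p_unedited = 0,
                            partial_hr_k_dist = NULL,
                            classical_indel_dist = NULL) {
  p <- c(precise = p_precise, partial_hr = p_partial_hr, mh = p_mh,
         classical_indel = p_classical_indel, unedited = p_unedited)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    .stop("mixture fractions must be >= 0 and sum to 1",
          "penquant_config_error")
  if (is.null(classical_indel_dist))
    classical_indel_dist <- c("-1" = 0.25, "-2" = 0.20, "-3" = 0.15,
                              "-4" = 0.10, "-6" = 0.10, "-10" = 0.05,
                              "1" = 0.15)
  norm <- function(d) {
    if (any(d < 0) || sum(d) <= 0)
      .stop("distributions must be non-negative with positive mass",
            "penquant_config_error")
    d / sum(d)
  }
  classical_indel_dist <- norm(classical_indel_dist)
  if (!is.null(partial_hr_k_dist))
    partial_hr_k_dist <- norm(partial_hr_k_dist)
  structure(list(p = p, partial_hr_k_dist = partial_hr_k_dist,
                 classical_indel_dist = classical_indel_dist),
            class = "outcome_mixture")
}

#' Simulation configuration
#'
#' @param n_reads number of read pairs.
#' @param read_len read length (150 or 250, the PE150/PE250 platforms;
#'   other lengths are accepted).
#' @param error_rate per-base substitution probability, in [0, 0.05).
#' @param seed integer seed; identical seeds give identical output.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_reads, read_len = 150L, error_rate = 0.001,
                       seed = 1L) {
  n_reads <- as.integer(n_reads); read_len <- as.integer(read_len)
  if (is.na(n_reads) || n_reads <= 0L)
    .stop("n_reads must be positive", "penquant_config_error")
  if (read_len < 25L)
    .stop("read_len too short", "penquant_config_error")
  if (error_rate < 0 || error_rate >= 0.05)
    .stop("error_rate must be in [0, 0.05)", "penquant_config_error")
  structure(list(n_reads = n_reads, read_len = read_len,
                 error_rate = error_rate, seed = as.integer(seed),
                 rng = "Mersenne-Twister"),
            class = "sim_config")
}

#' Build the ground-truth allele set for a mixture
#'
#' Materializes the mixture classes into concrete allele sequences:
#' the precise product ([expected_edited_sequence()]); partial-HR blunt
#' joins for each k in the k distribution; the top (longest-microhomology)
#' non-degenerate [predict_mh_alleles()] candidate; classical NHEJ indels
#' at the cut (deletions centered on the cut; insertions duplicate the
#' bases 5' of the cut); and the unedited reference. If no usable
#' microhomology candidate exists its probability mass is reassigned to the
#' classical-indel class (then to unedited). Alleles whose sequences
#' coincide are collapsed with a warning, summing their probabilities.
#'
#' @param locus,pegrna,edit sample design objects.
#' @param mixture an [outcome_mixture()].
#' @return data.frame (class `allele_set`) with columns `label`, `class`,
#'   `seq`, `prob`.
#' @export
make_allele_set <- function(locus, pegrna, edit, mixture) {
  stopifnot(inherits(mixture, "outcome_mixture"))
  ref <- locus$amplicon
  cut <- locus$cut_site
  p <- mixture$p
  rows <- list()
  add <- function(label, class, seq, prob)
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, class = class, seq = seq, prob = prob,
      stringsAsFactors = FALSE)

  precise <- expected_edited_sequence(locus, edit)
  if (p["precise"] > 0) add("precise", "precise", precise, p["precise"])

  if (p["partial_hr"] > 0) {
    kd <- mixture$partial_hr_k_dist
    if (is.null(kd)) {
      if (pegrna$hr_len < 2L) {
        warning("hr_len < 2: partial-HR mass reassigned to classical indels",
                call. = FALSE)
        p["classical_indel"] <- p["classical_indel"] + p["partial_hr"]
        p["partial_hr"] <- 0
      } else {
        ks <- seq_len(pegrna$hr_len - 1L)
        kd <- setNames(rep(1 / length(ks), length(ks)), ks)
      }
    }
    if (p["partial_hr"] > 0) {
      for (k in as.integer(names(kd)))
        add(sprintf("partial_hr_k%d", k), "partial_hr",
            .partial_hr_construct(locus, pegrna, k),
            p["partial_hr"] * kd[[as.character(k)]])
    }
  }

  if (p["mh"] > 0) {
    cand <- predict_mh_alleles(locus, pegrna, edit)
    if (nrow(cand) > 0) {
      cand <- cand[!cand$is_precise & cand$predicted_allele != ref, ,
                   drop = FALSE]
      existing <- vapply(rows, function(r) r$seq, character(1))
      cand <- cand[!(cand$predicted_allele %in% existing), , drop = FALSE]
    }
    if (nrow(cand) == 0) {
      warning("no usable microhomology candidate; mass reassigned",
              call. = FALSE)
      if (p["classical_indel"] > 0)
        p["classical_indel"] <- p["classical_indel"] + p["mh"]
      else p["unedited"] <- p["unedited"] + p["mh"]
    } else {
      add("mh", "mh", cand$predicted_allele[1], p[["mh"]])
    }
  }

  if (p["classical_indel"] > 0) {
    d <- mixture$classical_indel_dist
    for (nm in names(d)) {
      s <- as.integer(nm)
      if (s < 0) {
        size <- -s
        start <- max(0L, cut - size %/% 2L)
        seq <- paste0(.sub0(ref, 0L, start),
                      .sub0(ref, start + size, nchar(ref)))
      } else {
        seq <- paste0(.sub0(ref, 0L, cut), .sub0(ref, cut - s, cut),
                      .sub0(ref, cut, nchar(ref)))
      }
      add(sprintf("classical_%+d", s), "classical_indel", seq,
          p[["classical_indel"]] * d[[nm]])
    }
  }

  if (p["unedited"] > 0) add("unedited", "unedited", ref, p[["unedited"]])

  out <- do.call(rbind, rows)
  if (anyDuplicated(out$seq)) {
    warning("colliding allele sequences collapsed", call. = FALSE)
    first <- match(out$seq, out$seq)
    out$prob <- vapply(seq_len(nrow(out)),
                       function(i) sum(out$prob[first == i]), numeric(1))
    out <- out[!duplicated(out$seq), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("allele_set", "data.frame")
  out
}

#' Simulate paired-end amplicon reads from an allele set
#'
#' For each read pair an allele is drawn from the mixture; mate 1 is its 5'
#' `read_len` bases, mate 2 the reverse complement of its 3' `read_len`
#' bases (the pair overlaps in the middle of the amplicon). Substitution
#' errors are injected at `error_rate` per base; base qualities are constant
#' and consistent with the error rate. Randomness comes from one seeded
#' Mersenne-Twister stream, consumed in documented order (allele indices;
#' mate-1 error mask read-major, then substituted bases; the same for
#' mate 2), so identical seeds give identical output.
#'
#' @param allele_set a [make_allele_set()] result (or data.frame with
#'   columns `label`, `class`, `seq`, `prob`).
#' @param config a [sim_config()].
#' @param out_dir if non-NULL, writes `R1.fastq.gz`, `R2.fastq.gz`,
#'   `truth.tsv` and `provenance.json` there.
#' @return A `pen_simulation` list: `pairs` (read-pair data.frame), `truth`
#'   (`id`, `label`, `class`), `alleles`, `config`, `provenance`.
#' @export
simulate_reads <- function(allele_set, config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  alen <- nchar(allele_set$seq)
  L <- config$read_len
  if (L > min(alen))
    .stop("read_len exceeds the shortest allele", "penquant_config_error")
  n <- config$n_reads

  set.seed(config$seed, kind = "Mersenne-Twister")
  idx <- sample.int(nrow(allele_set), n, replace = TRUE,
                    prob = allele_set$prob)
  r1 <- substr(allele_set$seq[idx], 1L, L)
  r2 <- revcomp(substring(allele_set$seq[idx], alen[idx] - L + 1L, alen[idx]))

  add_errors <- function(reads, e) {
    if (e <= 0) return(reads)
    flat <- strsplit(paste(reads, collapse = ""), "", fixed = TRUE)[[1]]
    hit <- which(runif(length(flat)) < e)
    if (length(hit) > 0) {
      dna <- c("A", "C", "G", "T")
      shift <- sample.int(3L, length(hit), replace = TRUE)
      flat[hit] <- dna[((match(flat[hit], dna) - 1L + shift) %% 4L) + 1L]
    }
    apply(matrix(flat, nrow = L), 2, paste, collapse = "")
  }
  r1 <- add_errors(r1, config$error_rate)
  r2 <- add_errors(r2, config$error_rate)

  q <- if (config$error_rate > 0)
    min(40L, max(2L, as.integer(round(-10 * log10(config$error_rate)))))
  else 40L
  qual <- strrep(rawToChar(as.raw(q + 33L)), L)

  ids <- sprintf("read_%06d", seq_len(n))
  pairs <- data.frame(id = ids, r1_seq = r1, r1_qual = qual,
                      r2_seq = r2, r2_qual = qual,
                      stringsAsFactors = FALSE, row.names = NULL)
  truth <- data.frame(id = ids, label = allele_set$label[idx],
                      class = allele_set$class[idx],
                      stringsAsFactors = FALSE, row.names = NULL)
  provenance <- list(
    generator = "penquant::simulate_reads",
    rng = config$rng, seed = config$seed, n_reads = n, read_len = L,
    error_rate = config$error_rate, quality_phred = q,
    draw_order = c("allele index per read",
                   "mate-1 error mask (read-major), substituted bases",
                   "mate-2 error mask (read-major), substituted bases"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq_pairs(pairs, file.path(out_dir, "R1.fastq.gz"),
                      file.path(out_dir, "R2.fastq.gz"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(pairs = pairs, truth = truth, alleles = allele_set,
                 config = config, provenance = provenance),
            class = "pen_simulation")
}
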