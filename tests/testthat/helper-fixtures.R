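# Shared fixtures and independent oracles.

# 120-bp toy amplicon: protospacer at 0-based index 40, CGG PAM at 60..63,
# blunt cut at 57 (3 nt 5' of the PAM).
FX_PROTO <- "GACGTTCTCGATGGTGCTAG"
FX_AMP120 <- paste0(
  "CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCG",
  "ACGTTCTCGATGGTGCTAGCGGTTGGATCTTGTAATTGACAAACCAGAACTAGATGACC",
  "AGTATCGAAGGCAAAGATGT")

# 240-bp amplicon (cut near the center) for simulation-based tests
FX_AMP240 <- paste0(
  "TACTCCGTCTAATTTCGCATGGTGCCCCGACTTCCATAGCCCTTAAGGTTCCATGAGAT",
  "AACCAAATAGACGGGCGGCGGACAGCCAAGGCTTCAAGAATGACGTTCTCGATGGTGCT",
  "AGCGGCGCGTGTACACTCGACCCCCTTACCGGCCTATCCACTTGCCTGAAGGGCACATC",
  "AGTACATTTTTCATTGCCCAGATCGTTAGAATCATATCCGTTTAACACGTGGTGGGTCCCACC")

FX_HIS18 <- "CATCATCACCACCATCAC"  # 18-bp 6xHis-style insertion payload

fx_locus <- function() locate_protospacer(FX_AMP120, FX_PROTO, name = "toy")
fx_locus240 <- function() locate_protospacer(FX_AMP240, FX_PROTO, name = "toy240")

# random target locus + edit + pegRNA for property tests (caller seeds RNG)
rand_design <- function(flank1 = 60L, flank2 = 60L) {
  dna <- c("A", "C", "G", "T")
  repeat {
    proto <- paste(sample(dna, 20, TRUE), collapse = "")
    amp <- paste0(paste(sample(dna, flank1, TRUE), collapse = ""),
                  proto, sample(dna, 1), "GG",
                  paste(sample(dna, flank2, TRUE), collapse = ""))
    fwd <- gregexpr(proto, amp, fixed = TRUE)[[1]]
    rev <- gregexpr(proto, revcomp(amp), fixed = TRUE)[[1]]
    if (sum(fwd > 0) == 1 && all(rev < 0)) break
  }
  locus <- locate_protospacer(amp, proto)
  kind <- sample(c("insertion", "deletion", "replacement", "substitution"), 1)
  ins_len <- sample(3:20, 1)
  del_len <- sample(2:15, 1)
  ins <- paste(sample(dna, ins_len, TRUE), collapse = "")
  edit <- switch(kind,
    insertion    = edit_spec("insertion", inserted = ins),
    deletion     = edit_spec("deletion", deleted_len = del_len),
    replacement  = edit_spec("replacement", inserted = ins,
                             deleted_len = del_len),
    substitution = edit_spec("substitution",
                             inserted = paste(sample(dna, del_len, TRUE),
                                              collapse = ""),
                             deleted_len = del_len))
  hr_len <- sample(0:20, 1)
  pbs_len <- sample(8:17, 1)
  pegrna <- design_hr_pegrna(locus, edit, pbs_len = pbs_len, hr_len = hr_len)
  list(locus = locus, edit = edit, pegrna = pegrna)
}

# Independent score-only affine fitting-alignment oracle (full Gotoh
# matrices, no traceback): read global, free template end gaps; a gap of
# length L costs gap_open + L * gap_ext.
oracle_align_score <- function(read, tmpl, p = align_params()) {
  r <- strsplit(read, "")[[1]]; t <- strsplit(tmpl, "")[[1]]
  m <- length(r); n <- length(t)
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1); E <- H; F <- H
  H[1, ] <- 0
  for (i in 2:(m + 1)) {
    E[i, 1] <- p$gap_open + (i - 1) * p$gap_ext
    H[i, 1] <- E[i, 1]
  }
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i - 1, j] + p$gap_open + p$gap_ext,
                   E[i - 1, j] + p$gap_ext)
    F[i, j] <- max(H[i, j - 1] + p$gap_open + p$gap_ext,
                   F[i, j - 1] + p$gap_ext)
    s <- if (r[i - 1] == t[j - 1]) p$match else p$mismatch
    H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F[i, j])
  }
  max(H[m + 1, ])
}

# Brute-force microhomology oracle: all substring pairs compared directly.
# Returns one row per distinct predicted allele with the longest MH length.
oracle_mh <- function(upstream, overhang, downstream, ref_after_cut,
                      min_mh, max_mh) {
  res <- list()
  no <- nchar(overhang); nd <- nchar(downstream)
  for (o in seq_len(no)) for (d in seq_len(nd)) for (m in min_mh:max_mh) {
    if (o + m - 1 > no || d + m - 1 > nd) next
    if (substr(overhang, o, o + m - 1) != substr(downstream, d, d + m - 1))
      next
    allele <- paste0(upstream, substr(overhang, 1, o + m - 1),
                     substr(ref_after_cut, d + m, nchar(ref_after_cut)))
    key <- allele
    if (is.null(res[[key]]) || res[[key]] < m) res[[key]] <- m
  }
  if (length(res) == 0)
    return(data.frame(allele = character(0), m = integer(0)))
  data.frame(allele = names(res), m = unlist(res, use.names = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

# construct an error-free read pair from an allele sequence
pair_from_fragment <- function(fragment, read_len, id = "p1", q = "I") {
  n <- nchar(fragment)
  data.frame(id = id,
             r1_seq = substr(fragment, 1, read_len),
             r1_qual = strrep(q, read_len),
             r2_seq = revcomp(substr(fragment, n - read_len + 1, n)),
             r2_qual = strrep(q, read_len),
             stringsAsFactors = FALSE)
}
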