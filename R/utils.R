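# internal helpers: sequence utilities and classed error conditions

.stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(class = c(class, "penquant_error", "error", "condition"),
                 list(message = msg, call = call)))
}

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#' All penquant sequences are plain uppercase A/C/G/T character strings
#' (pegRNA segments are stored in DNA alphabet; the RNA identity is a
#' presentation concern).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- character(length(x))
  nz <- nchar(x) > 0
  out[!nz] <- ""
  if (any(nz))
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  out
}

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    .stop(sprintf("%s must be a single character string", what),
          "penquant_type_error")
  if (grepl("[^ACGT]", x))
    .stop(sprintf("%s contains characters other than A/C/G/T", what),
          "penquant_alphabet_error")
  invisible(x)
}

# 0-based half-open substring: bases [from, to) of a 1-string
.sub0 <- function(x, from, to) {
  if (to <= from) return("")
  substr(x, from + 1L, to)
}

# fast scalar reverse complement for hot loops (A/C/G/T only)
.rc1 <- function(x) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", x))))
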