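#' @importFrom data.table data.table as.data.table setDT := rbindlist
#'   setorder copy setnames fifelse uniqueN setattr dcast setcolorder
#'   .N .SD .GRP .I
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; preserves case-insensitively upper-case
#' output. Empty strings are returned unchanged.
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param len length of each sequence (bp).
#' @return character vector of length `n`.
#' @keywords internal
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Unique random barcodes
#'
#' Draws `n` distinct random `len`-mers, re-drawing any collisions.
#' @keywords internal
random_barcodes <- function(n, len = 20L) {
  bc <- random_dna(n, len)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- random_dna(sum(dup), len)
  }
  bc
}

#' Validate a 20-nt barcode
#' @keywords internal
check_barcode <- function(bc, what = "barcode") {
  if (!is.character(bc) || length(bc) != 1L || is.na(bc)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(bc) != 20L || grepl("[^ACGT]", bc)) {
    stop(what, " must be a 20-nt string over {A,C,G,T}, got '", bc, "'",
         call. = FALSE)
  }
  invisible(bc)
}

#' Hamming distance between equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Apply uniform substitution noise to DNA strings
#' @keywords internal
add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
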