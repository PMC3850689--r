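# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequences
#'
#' Draws uniform random sequences over A/C/G/T. Used by the pool simulator;
#' callers are responsible for seeding the RNG.
#'
#' @param n number of sequences.
#' @param len length of each sequence (scalar).
#' @return character vector of length `n`.
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Reverse complement of character sequences
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic 31-bit seed derived from a base seed and a stream index, so
# per-pool streams are independent of generation order.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 131 + 17) %% 2147483647)
}

is_dna_string <- function(x, allow_empty = TRUE, allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) return(FALSE)
  if (!nzchar(x)) return(allow_empty)
  pat <- if (allow_n) "^[ACGTNacgtn]+$" else "^[ACGTacgt]+$"
  grepl(pat, x)
}

# Count of per-position substitutions between a fixed pattern and the region
# of each read starting at `offset` (0-based). An 'N' in the read never
# matches; a read too short to contain the region counts every missing
# position as a mismatch.
prefix_mismatches <- function(seqs, pattern, offset = 0L) {
  len <- nchar(pattern)
  if (len == 0L) return(integer(length(seqs)))
  region <- substr(seqs, offset + 1L, offset + len)
  mm <- integer(length(seqs))
  pat <- strsplit(pattern, "")[[1L]]
  for (j in seq_len(len)) {
    ch <- substr(region, j, j)
    mm <- mm + as.integer(ch != pat[j] | ch == "N" | ch == "")
  }
  mm
}
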