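#' Filter specification for target-enriched reads
#'
#' Describes the technical prefix every genuine read must start with
#' (library barcode, then enrichment primer, then a short identifier taken
#' from the element terminus that guards against mispriming) and how the
#' sequence index is sliced from what remains. The index is the target-site
#' duplication (TSD) the element created on insertion; for Ds-family
#' transposons it is 8 bp, hence the default `index_length`.
#'
#' Matching is substitution-only (Hamming): indels would shift the trim
#' offset unpredictably, so they are not tolerated. The barcode is matched
#' exactly (it is what demultiplexes libraries); the primer and identifier
#' each get their own mismatch allowance. An `N` in a read never matches.
#'
#' @param primer enrichment primer sequence (required, possibly empty when
#'   reads arrive pre-trimmed).
#' @param barcode library barcode expected at the very start of the read;
#'   empty when pools arrive pre-demultiplexed as one file per pool.
#' @param identifier short element-terminus sequence expected immediately
#'   after the primer; empty to disable.
#' @param max_mismatches_primer,max_mismatches_identifier non-negative
#'   substitution allowances, each strictly smaller than the length of the
#'   corresponding sequence.
#' @param index_length TSD length sliced off as the sequence index
#'   (default 8).
#' @param known_endogenous character vector of index sequences to drop
#'   (previously inferred endogenous elements).
#' @param end_label which element end the library was amplified from:
#'   `"five_prime"` or `"three_prime"`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(primer, barcode = "", identifier = "",
                        max_mismatches_primer = 0L,
                        max_mismatches_identifier = 0L,
                        index_length = 8L,
                        known_endogenous = character(),
                        end_label = c("five_prime", "three_prime")) {
  end_label <- match.arg(end_label)
  for (nm in c("barcode", "primer", "identifier")) {
    v <- get(nm)
    if (!is_dna_string(v, allow_empty = TRUE))
      stop(nm, " must be a DNA string over {A,C,G,T,N}")
  }
  index_length <- as.integer(index_length)
  if (is.na(index_length) || index_length < 1L)
    stop("index_length must be a positive integer")
  max_mismatches_primer <- as.integer(max_mismatches_primer)
  max_mismatches_identifier <- as.integer(max_mismatches_identifier)
  if (max_mismatches_primer < 0L || max_mismatches_identifier < 0L)
    stop("mismatch allowances must be non-negative")
  if (nchar(primer) == 0L && max_mismatches_primer > 0L)
    stop("an empty primer cannot carry a mismatch allowance")
  if (nchar(identifier) == 0L && max_mismatches_identifier > 0L)
    stop("an empty identifier cannot carry a mismatch allowance")
  if (nchar(primer) > 0L && max_mismatches_primer >= nchar(primer))
    stop("max_mismatches_primer must be smaller than the primer length")
  if (nchar(identifier) > 0L && max_mismatches_identifier >= nchar(identifier))
    stop("max_mismatches_identifier must be smaller than the identifier length")
  structure(list(
    barcode = toupper(barcode), primer = toupper(primer),
    identifier = toupper(identifier),
    max_mismatches_primer = max_mismatches_primer,
    max_mismatches_identifier = max_mismatches_identifier,
    index_length = index_length,
    known_endogenous = toupper(as.character(known_endogenous)),
    end_label = end_label), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "filter_spec (%s): barcode '%s' | primer '%s' (<=%d mm) | identifier '%s' (<=%d mm)\n",
    x$end_label, x$barcode, x$primer, x$max_mismatches_primer,
    x$identifier, x$max_mismatches_identifier))
  cat(sprintf("  index length %d, %d known endogenous indices\n",
              x$index_length, length(x$known_endogenous)))
  invisible(x)
}

#' Build the prefix-match predicate for a filter specification
#'
#' Compiles a `filter_spec` into a vectorised predicate over read sequences.
#' A read matches iff it begins with the barcode (exact), followed by the
#' primer within its substitution allowance, followed by the identifier
#' within its allowance. The total technical-prefix length to trim is
#' reported alongside.
#'
#' @param spec a [filter_spec()].
#' @return an object of class `filter_pattern`: list with `trim_length` and
#'   `matches(seqs)`, a function from a character vector of (upper-case)
#'   read sequences to a logical vector.
#' @examples
#' p <- build_filter_pattern(filter_spec(primer = "ACGT"))
#' p$matches("ACGTTTTT")  # TRUE
#' p$trim_length          # 4
#' @export
build_filter_pattern <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  off_primer <- nchar(spec$barcode)
  off_ident <- off_primer + nchar(spec$primer)
  trim_length <- off_ident + nchar(spec$identifier)
  matches <- function(seqs) {
    ok <- rep(TRUE, length(seqs))
    if (nchar(spec$barcode) > 0L)
      ok <- ok & prefix_mismatches(seqs, spec$barcode, 0L) == 0L
    if (nchar(spec$primer) > 0L)
      ok <- ok & prefix_mismatches(seqs, spec$primer, off_primer) <=
        spec$max_mismatches_primer
    if (nchar(spec$identifier) > 0L)
      ok <- ok & prefix_mismatches(seqs, spec$identifier, off_ident) <=
        spec$max_mismatches_identifier
    ok
  }
  structure(list(spec = spec, trim_length = trim_length, matches = matches),
            class = "filter_pattern")
}

detect_read_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fastq", "fq")) return("fastq")
  if (ext %in% c("fasta", "fa", "fna", "fas")) return("fasta")
  con <- file(path, "r"); on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) return("fasta")
  if (startsWith(first, "@")) "fastq" else "fasta"
}

read_seq_chunk <- function(path, format, nrec, skip) {
  tryCatch(
    Biostrings::readDNAStringSet(path, format = format, nrec = nrec,
                                 skip = skip, use.names = TRUE),
    error = function(e) stop("malformed ", toupper(format), " input in '",
                             path, "' at or after record ", skip + 1L, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Convert a FASTQ file to FASTA
#'
#' Streams the file in fixed-size record chunks so arbitrarily large inputs
#' are handled in constant memory. IDs and sequences are preserved
#' one-for-one; quality strings are discarded.
#'
#' @param in_path FASTQ input path.
#' @param out_path FASTA output path (overwritten).
#' @param chunk_size records per chunk.
#' @return number of records written (invisibly visible as an integer).
#' @export
convert_fastq_to_fasta <- function(in_path, out_path, chunk_size = 100000L) {
  con <- file(in_path, "r")
  n_lines <- 0L
  while (length(ln <- readLines(con, n = 65536L, warn = FALSE)) > 0L)
    n_lines <- n_lines + length(ln)
  close(con)
  if (n_lines %% 4L != 0L)
    stop("malformed FASTQ '", in_path, "': line count ", n_lines,
         " is not a multiple of 4 (short record starting near line ",
         (n_lines %/% 4L) * 4L + 1L, ")")
  skip <- 0L
  repeat {
    chunk <- read_seq_chunk(in_path, "fastq", chunk_size, skip)
    if (skip == 0L || length(chunk) > 0L)
      Biostrings::writeXStringSet(chunk, out_path, append = skip > 0L)
    skip <- skip + length(chunk)
    if (length(chunk) < chunk_size) break
  }
  skip
}

empty_filtered_reads <- function() {
  data.table::data.table(index_seq = character(), trimmed_seq = character(),
                         read_id = character(), library_id = character(),
                         end_label = character())
}

#' Filter one pool library down to target-enriched reads
#'
#' Streams a FASTQ/FASTA library, keeps only reads that carry the expected
#' technical prefix (see [build_filter_pattern()]), trims that prefix off,
#' and slices the first `index_length` bases of the remainder as the read's
#' sequence index (the TSD). Reads whose index is a known endogenous element
#' and reads too short to yield a full index are dropped and counted.
#'
#' Filtering is order-preserving and deterministic; per-library runs are
#' independent, so libraries may be processed in any order or in parallel.
#'
#' @param in_path read file (FASTQ or FASTA; format auto-detected).
#' @param spec a [filter_spec()].
#' @param library_id library identifier recorded on every retained read.
#' @param out_path optional path for the tab-separated output
#'   (columns index_seq, trimmed_seq, read_id).
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @param chunk_size records per streamed chunk.
#' @return list with `reads` (data.table: index_seq, trimmed_seq, read_id,
#'   library_id, end_label) and `stats` (named integer vector: total,
#'   matched, dropped_no_match, dropped_endogenous, dropped_short,
#'   retained).
#' @export
filter_library <- function(in_path, spec, library_id, out_path = NULL,
                           format = c("auto", "fastq", "fasta"),
                           chunk_size = 100000L) {
  stopifnot(inherits(spec, "filter_spec"))
  format <- match.arg(format)
  if (format == "auto") format <- detect_read_format(in_path)
  pattern <- build_filter_pattern(spec)
  trim <- pattern$trim_length
  stats <- c(total = 0L, matched = 0L, dropped_no_match = 0L,
             dropped_endogenous = 0L, dropped_short = 0L, retained = 0L)
  out <- list()
  skip <- 0L
  repeat {
    chunk <- read_seq_chunk(in_path, format, chunk_size, skip)
    n <- length(chunk)
    if (n > 0L) {
      seqs <- toupper(as.character(chunk))
      ids <- sub("[ \t].*$", "", names(chunk))
      ok <- pattern$matches(seqs)
      stats["total"] <- stats["total"] + n
      stats["matched"] <- stats["matched"] + sum(ok)
      stats["dropped_no_match"] <- stats["dropped_no_match"] + sum(!ok)
      if (any(ok)) {
        trimmed <- substr(seqs[ok], trim + 1L, nchar(seqs[ok]))
        long_enough <- nchar(trimmed) >= spec$index_length
        stats["dropped_short"] <- stats["dropped_short"] + sum(!long_enough)
        trimmed <- trimmed[long_enough]
        idx <- substr(trimmed, 1L, spec$index_length)
        endo <- idx %in% spec$known_endogenous
        stats["dropped_endogenous"] <- stats["dropped_endogenous"] + sum(endo)
        keep <- !endo
        if (any(keep)) {
          out[[length(out) + 1L]] <- data.table::data.table(
            index_seq = idx[keep], trimmed_seq = trimmed[keep],
            read_id = ids[ok][long_enough][keep])
        }
      }
    }
    skip <- skip + n
    if (n < chunk_size) break
  }
  reads <- if (length(out)) data.table::rbindlist(out) else
    empty_filtered_reads()[, c("index_seq", "trimmed_seq", "read_id")]
  reads[, library_id := library_id]
  reads[, end_label := spec$end_label]
  stats["retained"] <- nrow(reads)
  if (!is.null(out_path))
    data.table::fwrite(reads[, .(index_seq, trimmed_seq, read_id)],
                       out_path, sep = "\t")
  list(reads = reads[], stats = stats)
}
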