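# Element mapping: interpret external alignment results (BLAST tabular or
# SAM) for the assigned flank sequences and annotate each insertion's gene
# context against a GFF3 gene model. No aligner is run here.

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

empty_hits <- function() {
  data.table::data.table(
    query_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), identity_pct = numeric(),
    aln_length = integer(), score = numeric())
}

parse_blast_tabular <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw)) return(list(hits = empty_hits(), query_ids = character()))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1L))
  if (any(nf != 12L))
    stop("unparseable BLAST tabular line ", which(nf != 12L)[1L], " in '",
         path, "': expected 12 tab-separated fields, got ",
         nf[nf != 12L][1L])
  dt <- data.table::as.data.table(do.call(rbind, parts))
  data.table::setnames(dt, BLAST6_COLS)
  num_cols <- setdiff(BLAST6_COLS, c("qseqid", "sseqid"))
  for (cl in num_cols) dt[, (cl) := suppressWarnings(as.numeric(get(cl)))]
  bad <- which(!stats::complete.cases(dt[, num_cols, with = FALSE]))
  if (length(bad))
    stop("unparseable BLAST tabular line ", bad[1L], " in '", path,
         "': non-numeric value in a numeric field")
  hits <- dt[, .(
    query_id = qseqid, chrom = sseqid,
    start = as.integer(pmin(sstart, send)),
    end = as.integer(pmax(sstart, send)),
    strand = ifelse(sstart <= send, "+", "-"),
    identity_pct = pident, aln_length = as.integer(length),
    score = bitscore)]
  list(hits = hits, query_ids = unique(hits$query_id))
}

parse_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(rec$qname)
  if (n == 0L) return(list(hits = empty_hits(), query_ids = character()))
  unmapped <- bitwAnd(rec$flag, 4L) > 0L
  query_ids <- unique(rec$qname)
  if (all(unmapped)) return(list(hits = empty_hits(), query_ids = query_ids))
  keep <- !unmapped
  cig <- rec$cigar[keep]
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  nm <- rec$tag$NM[keep]
  identity <- ifelse(is.na(nm), 100, 100 * (1 - nm / ref_width))
  hits <- data.table::data.table(
    query_id = rec$qname[keep],
    chrom = as.character(rec$rname[keep]),
    start = rec$pos[keep],
    end = rec$pos[keep] + ref_width - 1L,
    strand = ifelse(bitwAnd(rec$flag[keep], 16L) > 0L, "-", "+"),
    identity_pct = identity,
    aln_length = as.integer(ref_width),
    score = as.numeric(rec$mapq[keep]))
  list(hits = hits, query_ids = query_ids)
}

#' Parse external alignment results
#'
#' Reads hits from BLAST 12-column tabular output (`-outfmt 6`) or from a
#' SAM file (e.g. Bowtie2 output). Coordinates are normalised to 1-based
#' inclusive intervals on the forward reference strand; reverse-strand hits
#' carry `strand == "-"`. SAM records flagged unmapped contribute no hits
#' but their query IDs are still reported, so downstream classification can
#' tell "unmapped" from "absent". For SAM, per-hit identity is derived from
#' the NM tag over the reference span (100 when NM is absent) and the score
#' column holds MAPQ; for BLAST it holds the bit score.
#'
#' @param path alignment file.
#' @param format `"blast_tabular"` or `"sam"`.
#' @return list with `hits` (data.table: query_id, chrom, start, end,
#'   strand, identity_pct, aln_length, score) and `query_ids` (all queries
#'   seen, including unmapped ones).
#' @export
parse_alignments <- function(path, format = c("blast_tabular", "sam")) {
  format <- match.arg(format)
  switch(format, blast_tabular = parse_blast_tabular(path), sam = parse_sam(path))
}

#' Classify a query's locus status
#'
#' Hits failing the identity or length floor are discarded; what remains
#' decides the trichotomy: no hit = `unmapped`, one hit = `unique`, several
#' hits whose runner-up scores at least `score_margin` of the best =
#' `multiple` (ambiguous locus, e.g. a repetitive region). A runner-up far
#' below the best does not spoil uniqueness.
#'
#' @param hits data.table of hits for one query (as from
#'   [parse_alignments()]); zero rows or NULL means unmapped.
#' @param query_length query sequence length, used for the default length
#'   floor.
#' @param min_identity minimum percent identity (default 95).
#' @param min_length minimum alignment length (default
#'   `0.8 * query_length`).
#' @param score_margin fraction of the best score at which a second hit
#'   makes the locus ambiguous (default 0.9).
#' @return list with `status` (`"unique"`, `"multiple"` or `"unmapped"`),
#'   `best` (one-row data.table or NULL) and `n_hits` (surviving hits).
#' @export
classify_locus <- function(hits, query_length, min_identity = 95,
                           min_length = NULL, score_margin = 0.9) {
  if (is.null(min_length)) min_length <- 0.8 * query_length
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(status = "unmapped", best = NULL, n_hits = 0L))
  surv <- hits[identity_pct >= min_identity & aln_length >= min_length]
  if (nrow(surv) == 0L)
    return(list(status = "unmapped", best = NULL, n_hits = 0L))
  data.table::setorder(surv, -score, chrom, start)
  if (nrow(surv) >= 2L && surv$score[2L] >= score_margin * surv$score[1L])
    return(list(status = "multiple", best = surv[1L], n_hits = nrow(surv)))
  list(status = "unique", best = surv[1L], n_hits = nrow(surv))
}

#' Load a GFF3 gene annotation
#'
#' Thin wrapper over `rtracklayer::import` returning the GRanges used by
#' [annotate_insertion()]. Exons must carry `Parent` attributes linking them
#' (directly) to their gene's `ID`.
#'
#' @param path GFF3 file.
#' @return a GRanges.
#' @export
read_gene_annotation <- function(path) {
  ann <- rtracklayer::import(path, format = "gff3")
  # honour ##sequence-region pragmas: chromosomes declared there but bearing
  # no features are still covered by the annotation
  regions <- grep("^##sequence-region", readLines(path, n = 200L),
                  value = TRUE)
  if (length(regions)) {
    declared <- vapply(strsplit(regions, "[ \t]+"), `[`, character(1L), 2L)
    GenomeInfoDb::seqlevels(ann) <-
      union(GenomeInfoDb::seqlevels(ann), declared)
  }
  ann
}

#' Annotate one insertion against a gene model
#'
#' The insertion point is taken as the flank-proximal coordinate of the
#' best hit: the trimmed flank read begins with the TSD at the element
#' junction, so the reference base aligned to the start of the query
#' approximates the insertion site to within the TSD length. For a
#' forward-strand hit that is the interval start, for a reverse-strand hit
#' the interval end.
#'
#' Classification: inside a gene span, the point is `exon(k of n)` when it
#' falls in the k-th exon (numbered in transcription order, so exon 1 of a
#' minus-strand gene is its rightmost), otherwise `intron`; within `window`
#' bp of a gene span it is `within_1kb_upstream` / `within_1kb_downstream`
#' relative to the gene's strand; otherwise `intergenic`. A hit on a
#' chromosome absent from the annotation is classified intergenic with a
#' warning (annotation/genome mismatch).
#'
#' @param best one-row hit data.table (from [classify_locus()]).
#' @param annotation a GRanges from [read_gene_annotation()] with `gene` and
#'   `exon` features.
#' @param window flank window in bp (default 1000).
#' @return list: chrom, insertion_point, gene_context, gene_id.
#' @export
annotate_insertion <- function(best, annotation, window = 1000L) {
  stopifnot(nrow(best) == 1L)
  point <- if (best$strand == "+") best$start else best$end
  res <- list(chrom = best$chrom, insertion_point = as.integer(point),
              gene_context = "intergenic", gene_id = NA_character_)
  genes <- annotation[annotation$type == "gene"]
  if (!best$chrom %in% GenomeInfoDb::seqlevels(annotation)) {
    warning("chromosome '", best$chrom,
            "' absent from annotation; classifying intergenic")
    return(res)
  }
  on_chrom <- genes[as.character(GenomicRanges::seqnames(genes)) == best$chrom]
  if (length(on_chrom) == 0L) return(res)
  gs <- GenomicRanges::start(on_chrom); ge <- GenomicRanges::end(on_chrom)
  inside <- which(gs <= point & point <= ge)
  if (length(inside)) {
    g <- on_chrom[inside[order(gs[inside])][1L]]
    gid <- g$ID
    res$gene_id <- gid
    exons <- annotation[annotation$type == "exon"]
    parent <- vapply(as.list(exons$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1L))
    ex <- exons[!is.na(parent) & parent == gid]
    if (length(ex)) {
      o <- order(GenomicRanges::start(ex),
                 decreasing = as.character(GenomicRanges::strand(g)) == "-")
      ex <- ex[o]
      k <- which(GenomicRanges::start(ex) <= point &
                   point <= GenomicRanges::end(ex))
      res$gene_context <- if (length(k))
        sprintf("exon(%d of %d)", k[1L], length(ex)) else "intron"
    } else res$gene_context <- "intron"
    return(res)
  }
  # flanking classification: distance from point to the gene span
  dist_left <- gs - point   # positive when gene lies right of the point
  dist_right <- point - ge  # positive when gene lies left of the point
  near <- which((dist_left > 0L & dist_left <= window) |
                  (dist_right > 0L & dist_right <= window))
  if (length(near)) {
    d <- pmax(dist_left[near], dist_right[near])
    g <- on_chrom[near[order(d, gs[near])][1L]]
    gene_right <- GenomicRanges::start(g) > point
    minus <- as.character(GenomicRanges::strand(g)) == "-"
    # gene to the right of the point: on '+' the point is upstream of the
    # TSS; on '-' it is downstream of the gene. Mirrored on the left.
    res$gene_context <- if (gene_right != minus)
      "within_1kb_upstream" else "within_1kb_downstream"
    res$gene_id <- g$ID
  }
  res
}

#' Pair 5' and 3' end annotations of the same wells
#'
#' Both terminal flanks of a genuine element map to (nearly) the same
#' reference location: their insertion points sit within one TSD of each
#' other. A well's two ends are paired when both map to a unique locus on
#' the same chromosome with insertion points at most `max_gap` apart --
#' strong evidence that both sequences are genuine.
#'
#' @param ann5,ann3 data.tables of annotated insertions for the 5' and 3'
#'   ends (as from [map_insertions()]); must contain well, chrom,
#'   insertion_point, locus_status.
#' @param max_gap maximum insertion-point separation in bp (default 16 =
#'   twice an 8-bp TSD).
#' @return data.table (well, paired) covering wells present in either set.
#' @export
pair_ends <- function(ann5, ann3, max_gap = 16L) {
  a5 <- ann5[, .(well, chrom5 = chrom, ip5 = insertion_point,
                 st5 = locus_status)]
  a3 <- ann3[, .(well, chrom3 = chrom, ip3 = insertion_point,
                 st3 = locus_status)]
  m <- merge(a5, a3, by = "well", all = TRUE)
  m[, paired := !is.na(st5) & !is.na(st3) &
      st5 == "unique" & st3 == "unique" &
      !is.na(chrom5) & !is.na(chrom3) & chrom5 == chrom3 &
      abs(ip5 - ip3) <= max_gap]
  m[, .(well, paired)]
}

#' Map and annotate all assigned sequences of one element end
#'
#' Drives the element-mapping stage: reads the well-tagged FASTA written by
#' [emit_report()], groups external alignment hits per query, classifies
#' each query's locus status and annotates unique hits against the gene
#' model.
#'
#' @param assignments_fasta FASTA of assigned sequences (IDs
#'   `<well>|grade<g>` as written by [emit_report()]).
#' @param aln_path alignment results for those sequences.
#' @param format `"blast_tabular"` or `"sam"`.
#' @param annotation GFF3 path or GRanges.
#' @param end_label which element end these sequences are from.
#' @param window flank window in bp.
#' @param min_identity,score_margin see [classify_locus()].
#' @param min_length_fraction length floor as a fraction of each query's
#'   length (default 0.8).
#' @return data.table: well, grade, end_label, query_id, locus_status,
#'   chrom, insertion_point, gene_id, gene_context, n_hits.
#' @export
map_insertions <- function(assignments_fasta, aln_path,
                           format = c("blast_tabular", "sam"), annotation,
                           end_label = c("five_prime", "three_prime"),
                           window = 1000L, min_identity = 95,
                           score_margin = 0.9, min_length_fraction = 0.8) {
  format <- match.arg(format)
  end_label <- match.arg(end_label)
  if (is.character(annotation)) annotation <- read_gene_annotation(annotation)
  fa <- Biostrings::readDNAStringSet(assignments_fasta)
  aln <- parse_alignments(aln_path, format)
  hits_by_query <- if (nrow(aln$hits)) split(aln$hits, by = "query_id")
    else list()
  out <- lapply(seq_along(fa), function(i) {
    qid <- sub("[ \t].*$", "", names(fa)[i])
    well <- sub("\\|.*$", "", qid)
    grade <- if (grepl("\\|grade[0-9]+", qid))
      as.integer(sub("^.*\\|grade([0-9]+).*$", "\\1", qid)) else NA_integer_
    cls <- classify_locus(hits_by_query[[qid]], query_length = nchar(fa[[i]]),
                          min_identity = min_identity,
                          min_length = min_length_fraction * length(fa[[i]]),
                          score_margin = score_margin)
    if (cls$status == "unique") {
      ann <- annotate_insertion(cls$best, annotation, window)
      data.table::data.table(
        well = well, grade = grade, end_label = end_label, query_id = qid,
        locus_status = cls$status, chrom = ann$chrom,
        insertion_point = ann$insertion_point, gene_id = ann$gene_id,
        gene_context = ann$gene_context, n_hits = cls$n_hits)
    } else {
      data.table::data.table(
        well = well, grade = grade, end_label = end_label, query_id = qid,
        locus_status = cls$status, chrom = NA_character_,
        insertion_point = NA_integer_, gene_id = NA_character_,
        gene_context = NA_character_, n_hits = cls$n_hits)
    }
  })
  data.table::rbindlist(out)
}
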