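# Synthetic pooled-read simulator with exact ground truth.
#
# Emulates a target-enrichment experiment over a 3-D sample cube: a toy
# reference genome, one insertion flank per well, per-pool lognormal
# amplification spread, clonal misprimed off-target loci plus uniform junk
# reads, i.i.d. substitution errors, optional endogenous elements present in
# every pool, optional duplicate (multi-well) insertions and per-pool
# attenuation.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: a 4 x 4 x 6 cube (96 wells, 14 pools), 10,000 reads per pool, a
#' lognormal amplification spread of sigma = 0.5 between elements, 10% noise
#' reads and a 0.5% per-base substitution error rate.
#'
#' @param seed integer RNG seed; every derived stream is keyed on it.
#' @param design a [pool_design()].
#' @param genome_length per-chromosome length of the toy reference (bp).
#' @param n_chroms number of chromosomes.
#' @param reads_per_pool reads emitted per pool library.
#' @param coverage_lognormal_sigma sdlog of the per-element, per-pool
#'   amplification weight (multiplicative PCR bias).
#' @param noise_fraction fraction of each pool's reads that are noise, in
#'   `[0, 1)`; split half-and-half between misprimed reads (correct prefix,
#'   off-target genomic fragment) and junk reads (random sequence, no
#'   primer), so both branches of the prefix filter are exercised.
#' @param substitution_error_rate i.i.d. per-base substitution probability.
#' @param n_noise_loci number of clonal off-target loci behind the misprimed
#'   half of the noise in each pool; misprimed PCR products are clonal
#'   amplicons, so their coverage forms a continuum below the genuine
#'   elements rather than a singleton cloud.
#' @param endogenous_n number of endogenous elements spiked into every pool.
#' @param endogenous_copy_multiplier abundance multiplier of endogenous
#'   elements relative to a typical genuine element.
#' @param duplicate_wells optional data.frame (well, duplicate_of): each
#'   listed well shares the insertion of `duplicate_of` (premeiotic
#'   transposition mimic).
#' @param attenuation optional data.frame (pool, factor): genuine-element
#'   amplification in the named pool is divided by `factor` while the noise
#'   mass keeps its unattenuated scale, shifting the pool's genuine:noise
#'   balance.
#' @param index_length TSD length (default 8).
#' @param primer,identifier technical prefix pieces shared by all pools
#'   (per-pool barcodes come from the design).
#' @param read_length emitted read length (bp).
#' @param min_insertion_spacing minimum spacing between insertion sites, so
#'   toy gene models around different insertions never overlap.
#' @param annotate_genes build a toy GFF3 gene model with a known gene
#'   context per insertion?
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       design = pool_design(4, 4, 6),
                       genome_length = 120000L, n_chroms = 5L,
                       reads_per_pool = 10000L,
                       coverage_lognormal_sigma = 0.5,
                       noise_fraction = 0.1,
                       substitution_error_rate = 0.005,
                       n_noise_loci = 40L,
                       endogenous_n = 0L,
                       endogenous_copy_multiplier = 20,
                       duplicate_wells = NULL,
                       attenuation = NULL,
                       index_length = 8L,
                       primer = "ACGGTCAGTCAAGCTGGTAC",
                       identifier = "TTACGA",
                       read_length = 100L,
                       min_insertion_spacing = 5000L,
                       annotate_genes = TRUE) {
  stopifnot(inherits(design, "pool_design"))
  stopifnot(reads_per_pool > 0, genome_length > 0, n_chroms >= 1,
            coverage_lognormal_sigma >= 0,
            noise_fraction >= 0, noise_fraction < 1,
            substitution_error_rate >= 0, substitution_error_rate < 1,
            n_noise_loci >= 1, endogenous_n >= 0,
            endogenous_copy_multiplier > 0,
            index_length >= 1, read_length > index_length)
  if (!is_dna_string(primer, allow_empty = FALSE, allow_n = FALSE) ||
      !is_dna_string(identifier, allow_empty = TRUE, allow_n = FALSE))
    stop("primer and identifier must be DNA strings over {A,C,G,T}")
  if (!is.null(duplicate_wells)) {
    duplicate_wells <- data.table::as.data.table(duplicate_wells)
    stopifnot(all(c("well", "duplicate_of") %in% names(duplicate_wells)))
  }
  if (!is.null(attenuation)) {
    attenuation <- data.table::as.data.table(attenuation)
    stopifnot(all(c("pool", "factor") %in% names(attenuation)),
              all(attenuation$factor > 0),
              all(attenuation$pool %in% design$pools$label))
  }
  structure(list(
    seed = as.integer(seed), design = design,
    genome_length = as.integer(genome_length),
    n_chroms = as.integer(n_chroms),
    reads_per_pool = as.integer(reads_per_pool),
    coverage_lognormal_sigma = coverage_lognormal_sigma,
    noise_fraction = noise_fraction,
    substitution_error_rate = substitution_error_rate,
    n_noise_loci = as.integer(n_noise_loci),
    endogenous_n = as.integer(endogenous_n),
    endogenous_copy_multiplier = endogenous_copy_multiplier,
    duplicate_wells = duplicate_wells, attenuation = attenuation,
    index_length = as.integer(index_length),
    primer = toupper(primer), identifier = toupper(identifier),
    read_length = as.integer(read_length),
    min_insertion_spacing = as.integer(min_insertion_spacing),
    genome_margin = 2000L,
    annotate_genes = isTRUE(annotate_genes)), class = "sim_config")
}

# i.i.d. substitution errors, vectorised: per read a binomial error count,
# then rounds of single-position substitutions (a position may be drawn
# twice across rounds, which only thins the realised rate marginally).
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  len <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), len, rate)
  if (max(n_err) == 0L) return(seqs)
  for (k in seq_len(max(n_err))) {
    sel <- which(n_err >= k)
    pos <- ceiling(stats::runif(length(sel)) * len[sel])
    cur <- substring(seqs[sel], pos, pos)
    shift <- sample.int(3L, length(sel), replace = TRUE)
    new <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    s <- seqs[sel]
    substring(s, pos, pos) <- new
    seqs[sel] <- s
  }
  seqs
}

# Toy gene model for one insertion point; returns a list of GFF3 feature
# rows (as data.table) plus the expected gene-context label at `pos`.
toy_gene_features <- function(chrom, pos, context, strand, gene_id) {
  g <- function(start, end, type, id, parent = NA_character_)
    data.table::data.table(chrom = chrom, start = start, end = end,
                           type = type, strand = strand, ID = id,
                           Parent = parent)
  feats <- NULL
  expected <- context
  if (context == "exon") {
    feats <- rbind(
      g(pos - 400L, pos + 400L, "gene", gene_id),
      g(pos - 400L, pos - 300L, "exon", paste0(gene_id, ".e1"), gene_id),
      g(pos - 50L, pos + 50L, "exon", paste0(gene_id, ".e2"), gene_id),
      g(pos + 300L, pos + 400L, "exon", paste0(gene_id, ".e3"), gene_id))
    expected <- "exon(2 of 3)"
  } else if (context == "intron") {
    feats <- rbind(
      g(pos - 400L, pos + 400L, "gene", gene_id),
      g(pos - 400L, pos - 200L, "exon", paste0(gene_id, ".e1"), gene_id),
      g(pos + 200L, pos + 400L, "exon", paste0(gene_id, ".e2"), gene_id))
    expected <- "intron"
  } else if (context == "upstream") {
    feats <- if (strand == "+")
      g(pos + 300L, pos + 900L, "gene", gene_id)
    else g(pos - 900L, pos - 300L, "gene", gene_id)
    expected <- "within_1kb_upstream"
  } else if (context == "downstream") {
    feats <- if (strand == "+")
      g(pos - 900L, pos - 300L, "gene", gene_id)
    else g(pos + 300L, pos + 900L, "gene", gene_id)
    expected <- "within_1kb_downstream"
  } else {
    expected <- "intergenic"
  }
  list(features = feats, expected = expected,
       gene_id = if (context == "intergenic") NA_character_ else gene_id)
}

features_to_granges <- function(feats) {
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = feats$strand)
  gr$type <- feats$type
  gr$ID <- feats$ID
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(feats$Parent, function(p) if (is.na(p)) character(0) else p)))
  gr
}

#' Generate the simulation ground truth
#'
#' Builds the toy reference genome, draws one insertion site per well
#' (collision-free, spaced so toy gene models never overlap), extracts the
#' both-end flanks sharing one TSD at the junction, places optional
#' endogenous elements, and (optionally) a toy GFF3 gene model in which
#' every insertion has a known gene context. Deterministic under
#' `cfg$seed`.
#'
#' The 3' trimmed read is `TSD + downstream flank` and aligns forward at the
#' insertion site; the 5' trimmed read is the reverse complement of
#' `upstream flank + TSD`, so it begins with `revcomp(TSD)` and aligns
#' contiguously on the minus strand. Both ends share the same underlying
#' TSD.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_truth`: list with `genome` (DNAStringSet),
#'   `insertions` (data.table: well, plate, row, column, chrom, pos, tsd,
#'   index5, index3, flank5, flank3, duplicate_of, gene_id, gene_context),
#'   `endogenous` (data.table with per-end indices and flanks),
#'   `annotation` (GRanges or NULL) and `cfg`.
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  t <- cfg$index_length
  L <- cfg$read_length
  genome_chr <- random_dna(cfg$n_chroms, cfg$genome_length)
  names(genome_chr) <- paste0("chr", seq_len(cfg$n_chroms))

  margin <- cfg$genome_margin
  if (margin <= L + t)
    stop("read_length too large for the genome margin")
  starts <- seq.int(margin, cfg$genome_length - margin - 1000L,
                    by = cfg$min_insertion_spacing)
  slots <- data.table::CJ(chrom_i = seq_len(cfg$n_chroms), start = starts)

  wells <- design_wells(cfg$design)
  dup <- cfg$duplicate_wells
  dup_wells <- if (is.null(dup)) character(0) else dup$well
  primary <- wells[!well %in% dup_wells]
  need <- nrow(primary) + cfg$endogenous_n
  if (nrow(slots) < need)
    stop("genome too small for the requested design: ", need,
         " insertion sites needed but only ", nrow(slots),
         " spaced slots available; increase genome_length or n_chroms")
  slots <- slots[sample(.N)]

  used3 <- character(0); used5 <- character(0)
  site_rows <- vector("list", need)
  si <- 0L  # slot cursor
  for (k in seq_len(need)) {
    repeat {
      si <- si + 1L
      if (si > nrow(slots))
        stop("could not place ", need, " insertion sites with distinct TSDs")
      chrom_i <- slots$chrom_i[si]
      pos <- slots$start[si] + sample.int(1000L, 1L) - 1L
      seqc <- genome_chr[[chrom_i]]
      tsd <- substr(seqc, pos, pos + t - 1L)
      i5 <- revcomp(tsd)
      if (!(tsd %in% used3) && !(i5 %in% used5)) break
    }
    used3 <- c(used3, tsd); used5 <- c(used5, i5)
    flank3 <- substr(seqc, pos + t, pos + t + L - 1L)
    flank5 <- revcomp(substr(seqc, pos - L, pos - 1L))
    site_rows[[k]] <- data.table::data.table(
      chrom = names(genome_chr)[chrom_i], pos = pos, tsd = tsd,
      index5 = i5, index3 = tsd, flank5 = flank5, flank3 = flank3)
  }
  sites <- data.table::rbindlist(site_rows)

  ins <- cbind(primary, sites[seq_len(nrow(primary))])
  ins[, duplicate_of := NA_character_]
  if (length(dup_wells)) {
    dtab <- data.table::as.data.table(dup)
    src <- ins[match(dtab$duplicate_of, well)]
    if (anyNA(src$chrom))
      stop("duplicate_of wells must be primary wells of the design")
    dup_ins <- cbind(wells[match(dtab$well, well)],
                     src[, .(chrom, pos, tsd, index5, index3, flank5, flank3)])
    dup_ins[, duplicate_of := dtab$duplicate_of]
    ins <- rbind(ins, dup_ins)
  }
  data.table::setorder(ins, plate, row, column)

  endo <- data.table::data.table(
    id = character(), chrom = character(), pos = integer(), tsd = character(),
    index5 = character(), index3 = character(), flank5 = character(),
    flank3 = character())
  if (cfg$endogenous_n > 0L) {
    endo <- sites[nrow(primary) + seq_len(cfg$endogenous_n)]
    endo[, id := sprintf("endo%02d", .I)]
    data.table::setcolorder(endo, "id")
  }

  annotation <- NULL
  ins[, `:=`(gene_id = NA_character_, gene_context = "intergenic")]
  if (cfg$annotate_genes) {
    uniq <- ins[is.na(duplicate_of)]
    classes <- rep_len(c("exon", "intron", "upstream", "downstream",
                         "intergenic"), nrow(uniq))
    strands <- rep_len(c("+", "-"), nrow(uniq))
    feat_list <- vector("list", nrow(uniq))
    for (k in seq_len(nrow(uniq))) {
      tg <- toy_gene_features(uniq$chrom[k], uniq$pos[k], classes[k],
                              strands[k], sprintf("gene%04d", k))
      feat_list[[k]] <- tg$features
      ins[well == uniq$well[k] |
            (!is.na(duplicate_of) & duplicate_of == uniq$well[k]),
          `:=`(gene_id = tg$gene_id, gene_context = tg$expected)]
    }
    feats <- data.table::rbindlist(feat_list[!vapply(feat_list, is.null,
                                                     logical(1L))])
    annotation <- if (nrow(feats)) features_to_granges(feats) else
      GenomicRanges::GRanges()
    # declare every chromosome, so feature-less chromosomes still count as
    # covered by the annotation (they carry genuinely intergenic sites)
    GenomeInfoDb::seqlevels(annotation) <- names(genome_chr)
    GenomeInfoDb::seqlengths(annotation) <-
      stats::setNames(rep(cfg$genome_length, cfg$n_chroms), names(genome_chr))
  }

  genome <- Biostrings::DNAStringSet(genome_chr)
  structure(list(genome = genome, insertions = ins[], endogenous = endo[],
                 annotation = annotation, cfg = cfg),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d insertions over %d wells, %d endogenous, %d chroms\n",
              nrow(x$insertions), x$cfg$design$n_wells, nrow(x$endogenous),
              length(x$genome)))
  invisible(x)
}

#' Write the ground-truth bundle to disk
#'
#' Writes `reference.fasta`, `truth_insertions.tsv`, `truth_endogenous.tsv`
#' and (when gene annotation was generated) `annotation.gff3`.
#'
#' @param truth a [generate_truth()] result.
#' @param dir output directory.
#' @return named list of paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(reference = file.path(dir, "reference.fasta"),
                insertions = file.path(dir, "truth_insertions.tsv"),
                endogenous = file.path(dir, "truth_endogenous.tsv"),
                annotation = file.path(dir, "annotation.gff3"))
  Biostrings::writeXStringSet(truth$genome, paths$reference)
  data.table::fwrite(truth$insertions, paths$insertions, sep = "\t")
  data.table::fwrite(truth$endogenous, paths$endogenous, sep = "\t")
  if (!is.null(truth$annotation)) {
    rtracklayer::export(truth$annotation, paths$annotation, format = "gff3")
    # declare every chromosome via sequence-region pragmas, so feature-less
    # chromosomes still count as covered by the annotation
    lines <- readLines(paths$annotation)
    pragmas <- sprintf("##sequence-region %s 1 %d", names(truth$genome),
                       Biostrings::width(truth$genome))
    writeLines(c(lines[1L], pragmas, lines[-1L]), paths$annotation)
  } else paths$annotation <- NULL
  invisible(paths)
}

end_core_read <- function(tab, end) {
  if (end == "three_prime") paste0(tab$index3, tab$flank3)
  else paste0(tab$index5, tab$flank5)
}

#' Simulate per-pool read libraries
#'
#' For each pool (and element end), emits `reads_per_pool` reads as FASTQ:
#' genuine reads for every insertion whose well lies in the pool, with
#' per-element lognormal abundance (times any pool attenuation), endogenous
#' reads in every pool, clonal misprimed off-target reads and uniform junk
#' reads per `noise_fraction`, all subjected to i.i.d. substitution errors.
#' Every read is `barcode + primer + identifier + index + flank`, truncated
#' to `read_length`; junk reads are unstructured random sequence. Each
#' pool's RNG stream is keyed by `(seed, pool, end)`, so outputs do not
#' depend on generation order. Exact per-source read counts are returned as
#' the truth ledger.
#'
#' @param truth a [generate_truth()] result.
#' @param out_dir directory for the FASTQ files
#'   (`<pool>_<end>.fastq`).
#' @param ends which element ends to emit (default 3' only).
#' @return list with `files` (data.table: pool, end, library_id, path) and
#'   `ledger` (data.table: pool, end, category, source, index_seq, n_reads).
#' @export
simulate_reads <- function(truth, out_dir,
                           ends = "three_prime") {
  stopifnot(inherits(truth, "sim_truth"),
            all(ends %in% c("five_prime", "three_prime")))
  cfg <- truth$cfg
  design <- cfg$design
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t <- cfg$index_length
  margin <- cfg$genome_margin
  ins <- truth$insertions
  endo <- truth$endogenous
  chrom_str <- as.character(truth$genome)
  files <- list(); ledgers <- list()
  for (i in seq_len(design$n_pools)) {
    p <- design$pools[i]
    pool_wells <- switch(p$dimension,
                         plate = ins[plate == p$position],
                         row = ins[row == p$position],
                         column = ins[column == p$position])
    for (e in ends) {
      e_i <- match(e, c("five_prime", "three_prime"))
      set.seed(derive_seed(cfg$seed, 100L + i * 4L + e_i))
      prefix <- paste0(p$barcode, cfg$primer, cfg$identifier)
      frag_len <- cfg$read_length  # prefix+core truncated below
      nw <- nrow(pool_wells)
      w_un <- stats::rlnorm(nw, 0, cfg$coverage_lognormal_sigma)
      att <- 1
      if (!is.null(cfg$attenuation)) {
        hit <- cfg$attenuation[pool == p$label]
        if (nrow(hit)) att <- hit$factor[1L]
      }
      w_g <- w_un / att
      we <- if (nrow(endo))
        cfg$endogenous_copy_multiplier *
          stats::rlnorm(nrow(endo), 0, cfg$coverage_lognormal_sigma)
      else numeric(0)
      base_total <- sum(w_un) + sum(we)
      mis_w <- junk_w <- 0
      mis_loci <- NULL
      if (cfg$noise_fraction > 0) {
        noise_total <- cfg$noise_fraction / (1 - cfg$noise_fraction) *
          base_total
        mis_w <- junk_w <- noise_total / 2
        truth_idx <- if (e == "three_prime")
          unique(c(ins$index3, endo$index3)) else
          unique(c(ins$index5, endo$index5))
        nl <- cfg$n_noise_loci
        loc_chrom <- integer(nl); loc_pos <- integer(nl)
        loc_idx <- character(nl)
        for (j in seq_len(nl)) {
          for (tries in 1:50) {
            ci <- sample.int(cfg$n_chroms, 1L)
            pp <- sample.int(cfg$genome_length - 2L * margin, 1L) + margin
            id8 <- substr(chrom_str[ci], pp, pp + t - 1L)
            if (!id8 %in% truth_idx) break
          }
          loc_chrom[j] <- ci; loc_pos[j] <- pp; loc_idx[j] <- id8
        }
        wl <- stats::rlnorm(nl, 0, cfg$coverage_lognormal_sigma)
        mis_loci <- data.table::data.table(
          chrom_i = loc_chrom, pos = loc_pos, index_seq = loc_idx,
          w = wl / sum(wl) * mis_w)
      }
      counts <- as.vector(stats::rmultinom(
        1L, cfg$reads_per_pool,
        c(w_g, we, if (!is.null(mis_loci)) mis_loci$w,
          if (junk_w > 0) junk_w)))
      ct_g <- counts[seq_len(nw)]
      ct_e <- if (length(we)) counts[nw + seq_along(we)] else integer(0)
      ct_m <- if (!is.null(mis_loci))
        counts[nw + length(we) + seq_len(nrow(mis_loci))] else integer(0)
      ct_j <- if (junk_w > 0) counts[length(counts)] else 0L

      core_g <- end_core_read(pool_wells, e)
      reads_g <- rep(substr(paste0(prefix, core_g), 1L, cfg$read_length), ct_g)
      reads_e <- if (length(we))
        rep(substr(paste0(prefix, end_core_read(endo, e)), 1L,
                   cfg$read_length), ct_e)
      else character(0)
      reads_m <- character(0)
      if (length(ct_m) && sum(ct_m) > 0L) {
        frag <- substr(chrom_str[mis_loci$chrom_i], mis_loci$pos,
                       mis_loci$pos + cfg$read_length - 1L)
        reads_m <- rep(substr(paste0(prefix, frag), 1L, cfg$read_length), ct_m)
      }
      reads_j <- if (ct_j > 0L) random_dna(ct_j, cfg$read_length) else
        character(0)

      reads <- c(reads_g, reads_e, reads_m, reads_j)
      cats <- c(rep("genuine", length(reads_g)),
                rep("endogenous", length(reads_e)),
                rep("misprimed", length(reads_m)),
                rep("junk", length(reads_j)))
      reads <- apply_substitutions(reads, cfg$substitution_error_rate)
      ids <- sprintf("%s_%s_%s_%06d", p$label, e, cats, seq_along(reads))
      path <- file.path(out_dir, paste0(p$label, "_", e, ".fastq"))
      qual <- strrep("I", nchar(reads))
      writeLines(c(rbind(paste0("@", ids), reads, "+", qual)), path)

      led <- rbind(
        data.table::data.table(category = "genuine",
                               source = pool_wells$well,
                               index_seq = if (e == "three_prime")
                                 pool_wells$index3 else pool_wells$index5,
                               n_reads = ct_g),
        if (length(we)) data.table::data.table(
          category = "endogenous", source = endo$id,
          index_seq = if (e == "three_prime") endo$index3 else endo$index5,
          n_reads = ct_e),
        if (length(ct_m)) data.table::data.table(
          category = "misprimed",
          source = sprintf("locus_%s_%d", names(truth$genome)[mis_loci$chrom_i],
                           mis_loci$pos),
          index_seq = mis_loci$index_seq, n_reads = ct_m),
        if (ct_j > 0L) data.table::data.table(
          category = "junk", source = NA_character_,
          index_seq = NA_character_, n_reads = ct_j))
      led[, `:=`(pool = p$label, end = e)]
      data.table::setcolorder(led, c("pool", "end"))
      files[[length(files) + 1L]] <- data.table::data.table(
        pool = p$label, end = e, library_id = p$library_id, path = path)
      ledgers[[length(ledgers) + 1L]] <- led
    }
  }
  list(files = data.table::rbindlist(files),
       ledger = data.table::rbindlist(ledgers))
}

#' Filter specification matching a simulation's read structure
#'
#' @param cfg a [sim_config()].
#' @param end_label element end.
#' @param barcode per-pool barcode (empty by default, matching the default
#'   design).
#' @param max_mismatches_primer,max_mismatches_identifier allowances
#'   (defaults 2 and 1).
#' @param known_endogenous indices to pre-filter.
#' @return a [filter_spec()].
#' @export
sim_filter_spec <- function(cfg, end_label = "three_prime", barcode = "",
                            max_mismatches_primer = 2L,
                            max_mismatches_identifier = 1L,
                            known_endogenous = character()) {
  filter_spec(primer = cfg$primer, barcode = barcode,
              identifier = cfg$identifier,
              max_mismatches_primer = max_mismatches_primer,
              max_mismatches_identifier = max_mismatches_identifier,
              index_length = cfg$index_length,
              known_endogenous = known_endogenous,
              end_label = end_label)
}

#' Emit idealised BLAST-tabular alignments from the ground truth
#'
#' Writes the 12-column alignment lines an aligner would produce for each
#' well's trimmed flank read against the toy reference: the 3' read maps
#' forward starting at the insertion position, the 5' read maps on the
#' minus strand ending at the TSD. Used to exercise the element-mapping
#' stage without running an aligner.
#'
#' @param truth a [generate_truth()] result.
#' @param path output path.
#' @param end element end.
#' @param grade grade tag to embed in the query IDs (default 1).
#' @return `path`, invisibly; query IDs are `<well>|grade<grade>`.
#' @export
truth_alignments <- function(truth, path, end = "three_prime", grade = 1L) {
  cfg <- truth$cfg
  t <- cfg$index_length
  prefix_len <- nchar(cfg$primer) + nchar(cfg$identifier)
  qlen <- cfg$read_length - prefix_len
  ins <- truth$insertions
  lines <- vapply(seq_len(nrow(ins)), function(k) {
    qid <- sprintf("%s|grade%d", ins$well[k], grade)
    if (end == "three_prime") {
      sstart <- ins$pos[k]; send <- ins$pos[k] + qlen - 1L
    } else {
      sstart <- ins$pos[k] + t - 1L; send <- ins$pos[k] + t - qlen
    }
    paste(qid, ins$chrom[k], "100.00", qlen, 0L, 0L, 1L, qlen,
          sstart, send, "1e-30", 2 * qlen, sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Run a full simulation bundle
#'
#' Convenience wrapper: generates the truth, writes the truth bundle and the
#' per-pool FASTQ files, and writes the pool-design config, giving
#' everything the downstream modules need under one directory.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @param ends element ends to simulate reads for.
#' @return list with `truth`, `files`, `ledger` and the paths written.
#' @export
simulate_pools <- function(cfg, out_dir, ends = "three_prime") {
  truth <- generate_truth(cfg)
  paths <- write_truth(truth, file.path(out_dir, "truth"))
  sim <- simulate_reads(truth, file.path(out_dir, "reads"), ends = ends)
  design_path <- file.path(out_dir, "design.yaml")
  write_pool_design(cfg$design, design_path)
  list(truth = truth, files = sim$files, ledger = sim$ledger,
       paths = c(paths, list(design = design_path)))
}
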