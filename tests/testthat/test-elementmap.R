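toy_feats <- function() {
  data.frame(
    chrom = "chr1",
    start = c(1000L, 1000L, 1800L),
    end = c(2000L, 1200L, 2000L),
    type = c("gene", "exon", "exon"),
    strand = "+",
    ID = c("g1", "g1.e1", "g1.e2"),
    Parent = c(NA, "g1", "g1"),
    stringsAsFactors = FALSE)
}

test_that("BLAST tabular hits parse with normalised coordinates", {
  p <- withr::local_tempfile(fileext = ".tsv")
  file.create(p)
  empty <- parse_alignments(p, "blast_tabular")
  expect_equal(nrow(empty$hits), 0L)

  # minus-strand hit: sstart > send swaps to ascending, strand "-"
  writeLines(paste("q1", "chr2", "98.5", "80", "1", "0", "1", "80",
                   "5200", "5121", "1e-30", "150", sep = "\t"), p)
  res <- parse_alignments(p, "blast_tabular")
  expect_equal(res$hits$strand, "-")
  expect_equal(res$hits$start, 5121L)
  expect_equal(res$hits$end, 5200L)
  expect_equal(res$hits$identity_pct, 98.5)
  expect_equal(res$hits$score, 150)

  writeLines("q1\tchr2\tnot-twelve-fields", p)
  expect_error(parse_alignments(p, "blast_tabular"), "line 1")
})

test_that("SAM parsing keeps unmapped queries with zero hits", {
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    paste("q_mapped", "0", "chr1", "501", "60", "10M", "*", "0", "0",
          "ACGTACGTAC", "IIIIIIIIII", "NM:i:1", sep = "\t"),
    paste("q_unmapped", "4", "*", "0", "0", "*", "*", "0", "0",
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t"),
    paste("q_minus", "16", "chr1", "801", "60", "10M", "*", "0", "0",
          "ACGTACGTAC", "IIIIIIIIII", "NM:i:0", sep = "\t")), p)
  res <- parse_alignments(p, "sam")
  expect_setequal(res$query_ids, c("q_mapped", "q_unmapped", "q_minus"))
  expect_equal(nrow(res$hits), 2L)
  h <- res$hits[res$hits$query_id == "q_mapped", ]
  expect_equal(h$start, 501L)
  expect_equal(h$end, 510L)
  expect_equal(h$identity_pct, 90)  # NM=1 over 10 aligned bases
  expect_equal(res$hits[res$hits$query_id == "q_minus", strand], "-")
  # the unmapped query classifies as unmapped, not as absent
  expect_equal(classify_locus(res$hits[res$hits$query_id == "q_unmapped"],
                              10L)$status, "unmapped")
})

test_that("locus classification is an exhaustive, exclusive trichotomy", {
  expect_equal(classify_locus(NULL, 100L)$status, "unmapped")
  expect_equal(classify_locus(blast_hit_row()[0L], 100L)$status, "unmapped")

  one <- blast_hit_row(identity = 100, len = 100)
  cls <- classify_locus(one, 100L)
  expect_equal(cls$status, "unique")
  expect_equal(cls$n_hits, 1L)

  # two equal-score hits on different chromosomes: ambiguous
  two <- rbind(blast_hit_row(chrom = "chr1", score = 200),
               blast_hit_row(chrom = "chr2", score = 200))
  expect_equal(classify_locus(two, 100L)$status, "multiple")

  # runner-up far below the best does not spoil uniqueness
  weak2 <- rbind(blast_hit_row(chrom = "chr1", score = 200),
                 blast_hit_row(chrom = "chr2", score = 100))
  cls2 <- classify_locus(weak2, 100L)
  expect_equal(cls2$status, "unique")
  expect_equal(cls2$best$chrom, "chr1")

  # identity / length floors discard hits entirely
  low_id <- blast_hit_row(identity = 80)
  expect_equal(classify_locus(low_id, 100L)$status, "unmapped")
  short <- blast_hit_row(len = 50)
  expect_equal(classify_locus(short, 100L)$status, "unmapped")
})

test_that("gene-context classification handles the canonical cases", {
  gr <- feats_to_gr(toy_feats())
  hit_at <- function(point) blast_hit_row(start = point, end = point + 73L)
  expect_equal(annotate_insertion(hit_at(1100L), gr)$gene_context,
               "exon(1 of 2)")
  expect_equal(annotate_insertion(hit_at(1500L), gr)$gene_context, "intron")
  up <- annotate_insertion(hit_at(500L), gr)
  expect_equal(up$gene_context, "within_1kb_upstream")
  expect_equal(up$gene_id, "g1")
  expect_equal(annotate_insertion(hit_at(2500L), gr)$gene_context,
               "within_1kb_downstream")
  expect_equal(annotate_insertion(hit_at(5000L), gr)$gene_context,
               "intergenic")
  # insertion point is strand-aware: a minus hit uses its right edge
  minus_hit <- blast_hit_row(start = 1027L, end = 1100L, strand = "-")
  ann <- annotate_insertion(minus_hit, gr)
  expect_equal(ann$insertion_point, 1100L)

  # annotation/genome mismatch warns and falls back to intergenic
  expect_warning(
    mis <- annotate_insertion(blast_hit_row(chrom = "chrX"), gr),
    "absent from annotation")
  expect_equal(mis$gene_context, "intergenic")
})

test_that("exons are numbered in transcription order on the minus strand", {
  feats <- toy_feats()
  feats$strand <- "-"
  gr <- feats_to_gr(feats)
  ann <- annotate_insertion(blast_hit_row(start = 1100L, end = 1150L), gr)
  expect_equal(ann$gene_context, "exon(2 of 2)")  # leftmost exon is last
})

test_that("gene-context classification matches a brute-force interval scan", {
  set.seed(123)
  n_cases <- 300
  for (k in seq_len(n_cases)) {
    strand <- sample(c("+", "-"), 1L)
    gstart <- sample(2000:5000, 1L)
    glen <- sample(300:2000, 1L)
    n_ex <- sample(0:4, 1L)
    feats <- data.frame(chrom = "chr1", start = gstart,
                        end = gstart + glen, type = "gene", strand = strand,
                        ID = "g", Parent = NA_character_,
                        stringsAsFactors = FALSE)
    if (n_ex > 0L) {
      cuts <- sort(sample(seq(gstart, gstart + glen), 2L * n_ex))
      ex <- data.frame(chrom = "chr1",
                       start = cuts[seq(1L, 2L * n_ex, 2L)],
                       end = cuts[seq(2L, 2L * n_ex, 2L)],
                       type = "exon", strand = strand,
                       ID = sprintf("g.e%d", seq_len(n_ex)),
                       Parent = "g", stringsAsFactors = FALSE)
      feats <- rbind(feats, ex)
    }
    point <- sample(1:9000, 1L)
    got <- annotate_insertion(
      blast_hit_row(start = point, end = point + 50L), feats_to_gr(feats))
    want <- annotate_oracle(feats, "chr1", point)
    expect_equal(got$gene_context, want$gene_context,
                 info = sprintf("case %d point %d strand %s", k, point,
                                strand))
    expect_equal(got$gene_id, want$gene_id, info = paste("case", k))
  }
})

test_that("end pairing requires unique loci within one TSD span", {
  ann <- function(well, chrom, ip, status = "unique")
    data.table::data.table(well = well, chrom = chrom,
                           insertion_point = as.integer(ip),
                           locus_status = status)
  a5 <- rbind(ann("1A01", "chr1", 1000L),
              ann("1A02", "chr1", 5000L),
              ann("1A03", "chr2", 700L),
              ann("1A04", "chr1", 900L, status = "multiple"))
  a3 <- rbind(ann("1A01", "chr1", 1008L),
              ann("1A02", "chr2", 5000L),   # different chromosome
              ann("1A03", "chr2", 800L),    # 100 bp apart
              ann("1A04", "chr1", 905L))
  p <- pair_ends(a5, a3, max_gap = 16L)
  expect_equal(p[p$well == "1A01", paired], TRUE)
  expect_equal(p[p$well == "1A02", paired], FALSE)
  expect_equal(p[p$well == "1A03", paired], FALSE)
  expect_equal(p[p$well == "1A04", paired], FALSE)  # not unique on one end
  # paired wells are a subset of both-ends-unique wells
  expect_true(all(p[p$paired == TRUE, well] %in% "1A01"))
})

test_that("truth-derived alignments reproduce gene context and pairing", {
  cfg <- sim_config(seed = 9, design = pool_design(3, 3, 3),
                    genome_length = 60000L)
  truth <- generate_truth(cfg)
  dir <- withr::local_tempdir()
  write_truth(truth, dir)
  fa5 <- file.path(dir, "ends5.fasta"); fa3 <- file.path(dir, "ends3.fasta")
  ins <- truth$insertions
  ids <- sprintf("%s|grade1", ins$well)
  prefix_len <- nchar(cfg$primer) + nchar(cfg$identifier)
  qlen <- cfg$read_length - prefix_len
  w5 <- Biostrings::DNAStringSet(substr(paste0(ins$index5, ins$flank5), 1,
                                        qlen))
  w3 <- Biostrings::DNAStringSet(substr(paste0(ins$index3, ins$flank3), 1,
                                        qlen))
  names(w5) <- names(w3) <- ids
  Biostrings::writeXStringSet(w5, fa5)
  Biostrings::writeXStringSet(w3, fa3)
  aln5 <- truth_alignments(truth, file.path(dir, "aln5.tsv"), "five_prime")
  aln3 <- truth_alignments(truth, file.path(dir, "aln3.tsv"), "three_prime")
  ann <- read_gene_annotation(file.path(dir, "annotation.gff3"))
  m5 <- map_insertions(fa5, aln5, "blast_tabular", ann, "five_prime")
  m3 <- map_insertions(fa3, aln3, "blast_tabular", ann, "three_prime")
  expect_true(all(m5$locus_status == "unique"))
  expect_true(all(m3$locus_status == "unique"))
  # gene context matches the generator's per-well truth for every well
  cmp3 <- merge(m3[, .(well, gene_context)],
                ins[, .(well, truth_ctx = gene_context)], by = "well")
  expect_equal(cmp3$gene_context, cmp3$truth_ctx)
  cmp5 <- merge(m5[, .(well, gene_context)],
                ins[, .(well, truth_ctx = gene_context)], by = "well")
  expect_equal(cmp5$gene_context, cmp5$truth_ctx)
  # both ends pair at the same locus for 100% of wells
  p <- pair_ends(m5, m3, max_gap = 2L * cfg$index_length)
  expect_equal(nrow(p), nrow(ins))
  expect_true(all(p$paired))
})
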