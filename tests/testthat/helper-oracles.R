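# Independent brute-force oracles and small fixture builders. These are
# deliberately written in plain base R, separate from the package's own
# code paths, so they can serve as references for equivalence tests.

# Build a coverage table from a named vector of per-index read counts,
# following the documented contract (norm = count/total; rank by descending
# count then lexicographic index). Used to construct deconvolution inputs
# directly, without reads or a store.
make_cov <- function(counts, reads = NULL) {
  if (length(counts) == 0L)
    return(data.table::data.table(
      index_seq = character(), raw_count = integer(), norm_cov = numeric(),
      rank = integer(), representative_read = character()))
  idx <- names(counts)
  o <- order(-as.integer(counts), idx)
  idx <- idx[o]; cnt <- as.integer(counts)[o]
  data.table::data.table(
    index_seq = idx, raw_count = cnt, norm_cov = cnt / sum(cnt),
    rank = seq_along(idx),
    representative_read = if (is.null(reads)) paste0(idx, "TTTT") else
      reads[idx])
}

# Brute-force coverage computation from a filtered-read table, using only
# base R grouping.
coverage_oracle <- function(reads_df) {
  reads_df <- as.data.frame(reads_df)
  if (nrow(reads_df) == 0L) return(make_cov(integer(0)))
  cnt <- table(reads_df$index_seq)
  rep_read <- vapply(names(cnt), function(ix) {
    tr <- reads_df$trimmed_seq[reads_df$index_seq == ix]
    tt <- table(tr)
    cand <- names(tt)[tt == max(tt)]
    sort(cand)[1L]
  }, character(1L))
  o <- order(-as.integer(cnt), names(cnt))
  data.frame(index_seq = names(cnt)[o],
             raw_count = as.integer(cnt)[o],
             norm_cov = as.integer(cnt)[o] / sum(cnt),
             rank = seq_along(cnt),
             representative_read = unname(rep_read[o]),
             stringsAsFactors = FALSE)
}

# Exhaustive deconvolution enumerator: for every index, recompute its
# candidate pools per dimension straight from the coverage tables and apply
# the Grade-1 / multi-well / Grade-2 rules by direct case analysis.
oracle_deconvolve <- function(design, cov_tables, th_g1 = 1.5, th_g2 = 3,
                              cap = 8L, exclude = character()) {
  pools <- as.data.frame(design$pools)
  exp_size <- c(plate = design$R * design$C, row = design$P * design$C,
                column = design$P * design$R)
  # per pool: ordered candidate indices up to the g2 bound, with their
  # effective rank
  pool_cand <- lapply(seq_len(nrow(pools)), function(i) {
    cov <- as.data.frame(cov_tables[[pools$label[i]]])
    cov <- cov[order(cov$rank), , drop = FALSE]
    cov <- cov[!cov$index_seq %in% exclude, , drop = FALSE]
    cov$eff <- seq_len(nrow(cov))
    cov
  })
  names(pool_cand) <- pools$label
  all_idx <- sort(unique(unlist(lapply(pool_cand, function(x) x$index_seq))))
  g1_assign <- list(); g2_assign <- list(); multi <- list(); suspect <- list()
  g2_amb <- list()
  for (ix in all_idx) {
    hits <- list(plate = list(), row = list(), column = list())
    for (i in seq_len(nrow(pools))) {
      d <- pools$dimension[i]
      cc <- pool_cand[[pools$label[i]]]
      r <- cc$eff[cc$index_seq == ix]
      if (length(r) == 1L) {
        b1 <- floor(th_g1 * exp_size[[d]])
        b2 <- floor(th_g2 * exp_size[[d]])
        if (r <= b2)
          hits[[d]][[length(hits[[d]]) + 1L]] <-
            list(position = pools$position[i], g1 = r <= b1)
      }
    }
    n_g1 <- vapply(hits, function(h)
      sum(vapply(h, function(x) x$g1, logical(1L))), integer(1L))
    n_rel <- vapply(hits, function(h)
      sum(!vapply(h, function(x) x$g1, logical(1L))), integer(1L))
    if (all(n_g1 == 1L)) {
      posn <- vapply(hits, function(h) {
        g <- Filter(function(x) x$g1, h); g[[1L]]$position }, integer(1L))
      g1_assign[[ix]] <- posn
    } else if (all(n_g1 >= 1L)) {
      combos <- prod(n_g1)
      ws <- expand.grid(
        plate = sort(vapply(Filter(function(x) x$g1, hits$plate),
                            `[[`, integer(1L), "position")),
        row = sort(vapply(Filter(function(x) x$g1, hits$row),
                          `[[`, integer(1L), "position")),
        column = sort(vapply(Filter(function(x) x$g1, hits$column),
                             `[[`, integer(1L), "position")))
      if (combos > cap) suspect[[ix]] <- combos
      else multi[[ix]] <- paste(
        well_label(ws$plate, ws$row, ws$column), collapse = ",")
    } else if (sum(n_g1 == 1L) == 2L) {
      weak <- names(n_g1)[n_g1 != 1L]
      if (n_g1[[weak]] == 0L) {
        if (n_rel[[weak]] == 1L) {
          posn <- integer(3L); names(posn) <- c("plate", "row", "column")
          for (d in c("plate", "row", "column")) {
            h <- if (d == weak) Filter(function(x) !x$g1, hits[[d]])
                 else Filter(function(x) x$g1, hits[[d]])
            posn[[d]] <- h[[1L]]$position
          }
          g2_assign[[ix]] <- list(posn = posn, weak = weak)
        } else if (n_rel[[weak]] >= 2L) {
          g2_amb[[ix]] <- weak
        }
      }
    }
  }
  list(g1 = g1_assign, g2 = g2_assign, multi = multi, suspect = suspect,
       g2_ambiguous = g2_amb)
}

# Random deconvolution instance on a small design: a pool of candidate
# indices with random per-pool counts.
random_instance <- function(design, n_indices = 40, max_pools_per_index = 5,
                            seed = 1) {
  set.seed(seed)
  alphabet <- unique(replicate(n_indices, paste0(
    sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")))
  labs <- design$pools$label
  cov <- lapply(labs, function(l) integer(0))
  names(cov) <- labs
  for (ix in alphabet) {
    k <- sample.int(max_pools_per_index, 1L)
    for (l in sample(labs, min(k, length(labs)))) {
      cnt <- sample.int(60L, 1L)
      cov[[l]][ix] <- cnt
    }
  }
  lapply(cov, make_cov)
}

# Brute-force gene-context classification by linear interval scan over a
# plain data.frame of gene/exon features.
annotate_oracle <- function(feats, chrom, point, window = 1000L) {
  genes <- feats[feats$type == "gene" & feats$chrom == chrom, , drop = FALSE]
  if (nrow(genes) == 0L)
    return(list(gene_context = "intergenic", gene_id = NA_character_))
  inside <- genes[genes$start <= point & point <= genes$end, , drop = FALSE]
  if (nrow(inside) > 0L) {
    g <- inside[order(inside$start), , drop = FALSE][1L, ]
    ex <- feats[feats$type == "exon" & !is.na(feats$Parent) &
                  feats$Parent == g$ID, , drop = FALSE]
    if (nrow(ex) == 0L)
      return(list(gene_context = "intron", gene_id = g$ID))
    ex <- ex[order(ex$start, decreasing = (g$strand == "-")), , drop = FALSE]
    hit <- which(ex$start <= point & point <= ex$end)
    ctx <- if (length(hit)) sprintf("exon(%d of %d)", hit[1L], nrow(ex))
           else "intron"
    return(list(gene_context = ctx, gene_id = g$ID))
  }
  d_up <- genes$start - point
  d_down <- point - genes$end
  dist <- pmax(d_up, d_down)
  near <- which(dist > 0 & dist <= window)
  if (!length(near))
    return(list(gene_context = "intergenic", gene_id = NA_character_))
  g <- genes[near[order(dist[near], genes$start[near])][1L], ]
  gene_right <- g$start > point
  ctx <- if (gene_right != (g$strand == "-")) "within_1kb_upstream"
         else "within_1kb_downstream"
  list(gene_context = ctx, gene_id = g$ID)
}

feats_to_gr <- function(feats) {
  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand)
  gr$type <- feats$type
  gr$ID <- feats$ID
  gr$Parent <- IRanges::CharacterList(lapply(feats$Parent, function(p)
    if (is.na(p)) character(0) else p))
  gr
}

blast_hit_row <- function(chrom = "chr1", start = 1L, end = 100L,
                          strand = "+", identity = 100, len = NULL,
                          score = 200, query = "q") {
  data.table::data.table(
    query_id = query, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand, identity_pct = identity,
    aln_length = as.integer(len %||% (end - start + 1L)), score = score)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fastq <- function(ids, seqs, path, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  writeLines(c(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}
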