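# Coverage-table fixtures are constructed directly with make_cov(), so the
# deconvolution rules can be exercised in isolation from reads and store.

cov_set <- function(design, entries = list()) {
  covs <- lapply(design$pools$label, function(l)
    make_cov(entries[[l]] %||% integer(0)))
  names(covs) <- design$pools$label
  covs
}

# counts placing index `ix` at a known effective rank r in one pool:
# r - 1 heavier filler indices above it
rank_filler <- function(ix, r, above_count = 1000L, own_count = 10L,
                        extra = integer(0)) {
  filler <- if (r > 1L)
    stats::setNames(rep(above_count, r - 1L),
                    sprintf("FILL%04d", seq_len(r - 1L))) else integer(0)
  c(filler, stats::setNames(own_count, ix), extra)
}

test_that("candidate bounds follow floor(th x expected) per dimension", {
  d <- pool_design(10, 8, 12)
  expect_equal(candidate_bound(d, "plate", 1.5), 144L)
  expect_equal(candidate_bound(d, "row", 1.5), 180L)
  expect_equal(candidate_bound(d, "column", 1.5), 120L)
  expect_equal(candidate_bound(d, "plate", 3), 288L)
})

test_that("pools with fewer indices than the bound return all of them", {
  d <- pool_design(10, 8, 12)
  counts <- stats::setNames(sample(1:50, 10), sprintf("IDX%02d", 1:10))
  covs <- cov_set(d, list(plate01 = counts))
  sets <- candidate_sets(d, covs)
  expect_setequal(sets$plate01, names(counts))
  expect_equal(sets$plate02, character(0))
})

test_that("a missing pool coverage table is a hard error naming the pool", {
  d <- pool_design(2, 2, 2)
  covs <- cov_set(d)
  covs$rowB <- NULL
  expect_error(deconvolve(d, covs), "rowB")
})

test_that("default thresholds match the shipped configuration", {
  cfg <- deconvolution_config()
  expect_equal(cfg$th_g1, 1.5)
  expect_equal(cfg$th_g2, 3)
  expect_equal(cfg$endogenous_pool_fraction, 0.5)
  expect_error(deconvolution_config(th_g1 = 2, th_g2 = 1.5), "relaxation")
})

test_that("a unique three-pool intersection is a Grade-1 assignment", {
  d <- pool_design(22, 8, 12)
  ix <- "GATTACAT"
  covs <- cov_set(d, list(plate22 = stats::setNames(50, ix),
                          rowE = stats::setNames(40, ix),
                          col04 = stats::setNames(30, ix)))
  res <- deconvolve(d, covs)
  expect_equal(nrow(res$assignments), 1L)
  expect_equal(res$assignments$well, "22E04")
  expect_equal(res$assignments$grade, 1L)
  expect_false(res$assignments$ambiguous_well)
  # everything else is unresolved
  expect_equal(nrow(res$unresolved_wells), d$n_wells - 1L)
})

test_that("multiple pools in one dimension imply a multi-well candidate", {
  d <- pool_design(4, 4, 6)
  ix <- "TTAACCGG"
  covs <- cov_set(d, list(plate01 = stats::setNames(9, ix),
                          plate03 = stats::setNames(8, ix),
                          rowB = stats::setNames(9, ix),
                          col05 = stats::setNames(9, ix)))
  g1 <- assign_grade1(d, covs)
  expect_equal(nrow(g1$assignments), 0L)
  expect_equal(nrow(g1$multi_well), 1L)
  expect_equal(g1$multi_well$n_wells, 2L)  # 2 x 1 x 1 combinations
  expect_equal(g1$multi_well$wells, "1B05,3B05")
  # multi-well candidates do not leave wells "unresolved" silently
  res <- deconvolve(d, covs)
  expect_setequal(
    as.character(res$well_status[well %in% c("1B05", "3B05"), status]),
    "multi_well")
})

test_that("an implied-well explosion is reclassified suspected endogenous", {
  d <- pool_design(3, 3, 3)
  ix <- "AACCGGTT"
  entries <- list()
  for (l in d$pools$label) entries[[l]] <- stats::setNames(9, ix)
  g1 <- assign_grade1(d, cov_set(d, entries))
  expect_equal(nrow(g1$multi_well), 0L)
  expect_equal(g1$suspected_endogenous$index_seq, ix)
  expect_equal(g1$suspected_endogenous$n_wells, 27L)
})

test_that("two indices landing in one well are both kept and flagged", {
  d <- pool_design(2, 2, 2)
  covs <- cov_set(d, list(
    plate01 = c(AAAAAAAA = 9, CCCCCCCC = 8),
    rowA = c(AAAAAAAA = 9, CCCCCCCC = 8),
    col01 = c(AAAAAAAA = 9, CCCCCCCC = 8)))
  res <- deconvolve(d, covs)
  expect_equal(nrow(res$assignments), 2L)
  expect_equal(unique(res$assignments$well), "1A01")
  expect_true(all(res$assignments$ambiguous_well))
})

test_that("Grade-2 recovers a rank beyond TH_G1 but within TH_G2", {
  d <- pool_design(10, 8, 12)
  ix <- "CAGTCAGT"
  # plate rank 150: beyond floor(1.5*96)=144, within floor(3*96)=288
  covs <- cov_set(d, list(
    plate03 = rank_filler(ix, 150L),
    rowD = stats::setNames(20, ix),
    col07 = stats::setNames(20, ix)))
  res <- deconvolve(d, covs)
  a <- res$assignments[index_seq == ix]
  expect_equal(nrow(a), 1L)
  expect_equal(a$grade, 2L)
  expect_equal(a$well, "3D07")
  expect_equal(a$weak_dimension, "plate")
  expect_equal(a$plate_rank, 150L)

  # beyond the TH_G2 bound: no assignment at all
  covs2 <- cov_set(d, list(
    plate03 = rank_filler(ix, 289L),
    rowD = stats::setNames(20, ix),
    col07 = stats::setNames(20, ix)))
  res2 <- deconvolve(d, covs2)
  expect_equal(nrow(res2$assignments[index_seq == ix]), 0L)
})

test_that("a weak dimension ambiguous between two pools is never assigned", {
  d <- pool_design(10, 8, 12)
  ix <- "CAGTCAGT"
  covs <- cov_set(d, list(
    plate03 = rank_filler(ix, 150L),
    plate07 = rank_filler(ix, 160L),
    rowD = stats::setNames(20, ix),
    col07 = stats::setNames(20, ix)))
  res <- deconvolve(d, covs)
  expect_equal(nrow(res$assignments[index_seq == ix]), 0L)
  expect_equal(res$ambiguous_grade2$index_seq, ix)
  expect_equal(res$ambiguous_grade2$weak_dimension, "plate")
  expect_equal(res$ambiguous_grade2$n_relaxed_pools, 2L)
})

test_that("endogenous inference uses a strict >50% pool majority", {
  d <- pool_design(10, 8, 12)  # 30 pools
  ix <- "GGGGCCCC"
  make_entries <- function(n_pools_with) {
    labs <- d$pools$label[seq_len(n_pools_with)]
    entries <- list()
    for (l in labs) entries[[l]] <- stats::setNames(100, ix)
    entries
  }
  endo16 <- infer_endogenous(d, cov_set(d, make_entries(16L)))
  expect_equal(endo16$endogenous$index_seq, ix)
  expect_equal(endo16$endogenous$n_pools_prominent, 16L)
  expect_equal(nrow(endo16$evidence), 16L)
  endo15 <- infer_endogenous(d, cov_set(d, make_entries(15L)))
  expect_equal(nrow(endo15$endogenous), 0L)  # boundary is strict
})

test_that("inferred endogenous indices never occupy candidate rank slots", {
  d <- pool_design(2, 2, 2)  # 6 pools, all bounds floor(1.5*4)=6
  endo_ix <- "EEEEEEEE"
  ix <- "AAAACCCC"
  entries <- list()
  for (l in d$pools$label) entries[[l]] <- stats::setNames(1000, endo_ix)
  entries$plate02 <- c(entries$plate02, stats::setNames(10, ix))
  entries$rowB <- c(entries$rowB, stats::setNames(10, ix))
  entries$col01 <- c(entries$col01, stats::setNames(10, ix))
  res <- deconvolve(d, cov_set(d, entries))
  expect_equal(res$endogenous$index_seq, endo_ix)
  expect_equal(res$assignments$index_seq, ix)
  expect_equal(res$assignments$well, "2B01")
  expect_false(endo_ix %in% res$assignments$index_seq)
})

# normalise a named character vector (possibly NULL/empty) for comparison
sort_named <- function(x) {
  x <- unlist(x)
  if (is.null(x) || length(x) == 0L)
    return(stats::setNames(character(0), character(0)))
  x[order(names(x))]
}

test_that("deconvolution matches the exhaustive enumerator on random cubes", {
  d <- pool_design(3, 3, 3)
  cfg <- deconvolution_config()
  for (seed in 1:25) {
    covs <- random_instance(d, seed = seed)
    want <- oracle_deconvolve(d, covs)
    g1 <- assign_grade1(d, covs, cfg)
    g2 <- assign_grade2(d, covs, cfg,
                        skip_indices = c(g1$assignments$index_seq,
                                         g1$multi_well$index_seq,
                                         g1$suspected_endogenous$index_seq))
    # Grade-1 assignments agree exactly
    got_g1 <- sort_named(g1$assignments[, stats::setNames(well, index_seq)])
    want_g1 <- sort_named(vapply(want$g1, function(p)
      well_label(p[["plate"]], p[["row"]], p[["column"]]), character(1L)))
    expect_equal(got_g1, want_g1, info = paste("seed", seed))
    # multi-well and suspected sets agree
    expect_equal(sort(g1$multi_well$index_seq),
                 sort(as.character(names(want$multi))),
                 info = paste("seed", seed))
    if (nrow(g1$multi_well))
      expect_equal(
        g1$multi_well[order(index_seq), wells],
        unlist(want$multi[sort(names(want$multi))], use.names = FALSE),
        info = paste("seed", seed))
    expect_equal(sort(g1$suspected_endogenous$index_seq),
                 sort(as.character(names(want$suspect))),
                 info = paste("seed", seed))
    # Grade-2 agrees
    got_g2 <- sort_named(g2$assignments[, stats::setNames(well, index_seq)])
    want_g2 <- sort_named(vapply(want$g2, function(x)
      well_label(x$posn[["plate"]], x$posn[["row"]], x$posn[["column"]]),
      character(1L)))
    expect_equal(got_g2, want_g2, info = paste("seed", seed))
    expect_equal(sort(g2$ambiguous$index_seq),
                 sort(as.character(names(want$g2_ambiguous))),
                 info = paste("seed", seed))
  }
})

test_that("raising th_g1 never silently reassigns an element elsewhere", {
  d <- pool_design(3, 3, 3)
  for (seed in 26:35) {
    covs <- random_instance(d, seed = seed)
    a_low <- deconvolve(d, covs, deconvolution_config(th_g1 = 1.5))
    a_high <- deconvolve(d, covs, deconvolution_config(th_g1 = 2.5))
    low <- a_low$assignments[grade == 1L]
    for (k in seq_len(nrow(low))) {
      ix <- low$index_seq[k]
      hi <- a_high$assignments[index_seq == ix]
      if (nrow(hi) == 1L) {
        expect_equal(hi$well, low$well[k], info = paste("seed", seed, ix))
      } else {
        # uniqueness lost: must be flagged, not reassigned
        expect_true(ix %in% c(a_high$multi_well$index_seq,
                              a_high$suspected_endogenous$index_seq,
                              a_high$ambiguous_grade2$index_seq),
                    info = paste("seed", seed, ix))
      }
    }
  }
})

test_that("reports carry assignments to FASTA/TSV/HTML faithfully", {
  d <- pool_design(22, 8, 12)
  ix <- "GATTACAT"
  covs <- cov_set(d, list(plate22 = stats::setNames(50, ix),
                          rowE = stats::setNames(40, ix),
                          col04 = stats::setNames(30, ix)))
  res <- deconvolve(d, covs)
  out <- withr::local_tempdir()
  paths <- emit_report(res, out)
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(length(fa), nrow(res$assignments))
  expect_match(names(fa)[1], "22E04")
  expect_match(names(fa)[1], "grade1")
  expect_true(file.exists(paths$index_html))
  expect_true(file.exists(file.path(out, "report", "plate_22.html")))
  asn <- data.table::fread(paths$assignments,
                           colClasses = list(character = "well"))
  expect_equal(asn$well, "22E04")

  # zero assignments still produce valid empty outputs
  res0 <- deconvolve(pool_design(2, 2, 2), cov_set(pool_design(2, 2, 2)))
  paths0 <- emit_report(res0, withr::local_tempdir())
  expect_equal(length(Biostrings::readDNAStringSet(paths0$fasta)), 0L)
  expect_true(file.exists(paths0$index_html))
})
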