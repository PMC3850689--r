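# Dimension deconvolution: assign each high-coverage index to a well by
# intersecting its candidate ranks across the plate, row and column pools.

#' Deconvolution thresholds and options
#'
#' `th_g1` scales the strict candidate bound: a plate pool is expected to
#' hold `R * C` genuine elements, so its Grade-1 candidate set is the top
#' `floor(th_g1 * R * C)` ranked indices (and analogously `P * C` for rows,
#' `P * R` for columns). The default 1.5 admits half again as many
#' candidates as expected elements, absorbing moderate rank noise. `th_g2`
#' (default 3) is the relaxed bound used for the single "not-so-good"
#' dimension of a Grade-2 assignment; it must be at least `th_g1`.
#'
#' An index ranking within the prominence bound
#' (`floor(endogenous_min_rank_fraction * expected)`) in strictly more than
#' `endogenous_pool_fraction` of all pools is inferred to be an endogenous
#' host element: a genuine single-well insertion can be prominent in only 3
#' pools, whereas host-genome background is amplified everywhere. The
#' prominence fraction defaults to `th_g1` so "prominent" coincides with
#' Grade-1 candidacy.
#'
#' @param th_g1 Grade-1 candidate-bound multiplier (default 1.5).
#' @param th_g2 Grade-2 relaxed-bound multiplier (default 3).
#' @param endogenous_pool_fraction fraction of pools above which a prominent
#'   index is deemed endogenous (strict inequality; default 0.5).
#' @param endogenous_min_rank_fraction multiplier defining "prominent"
#'   (default: `th_g1`).
#' @param multi_well_cap maximum implied wells for a multi-well candidate;
#'   beyond this the index is reclassified suspected-endogenous (default 8).
#' @return an object of class `deconvolution_config`.
#' @export
deconvolution_config <- function(th_g1 = 1.5, th_g2 = 3,
                                 endogenous_pool_fraction = 0.5,
                                 endogenous_min_rank_fraction = th_g1,
                                 multi_well_cap = 8L) {
  stopifnot(th_g1 > 0, th_g2 > 0,
            endogenous_pool_fraction > 0, endogenous_pool_fraction <= 1,
            endogenous_min_rank_fraction > 0, multi_well_cap >= 1L)
  if (th_g2 < th_g1)
    stop("th_g2 must be >= th_g1 (Grade-2 is a relaxation of Grade-1)")
  structure(list(th_g1 = th_g1, th_g2 = th_g2,
                 endogenous_pool_fraction = endogenous_pool_fraction,
                 endogenous_min_rank_fraction = endogenous_min_rank_fraction,
                 multi_well_cap = as.integer(multi_well_cap)),
            class = "deconvolution_config")
}

#' Candidate rank bound for one pool dimension
#'
#' @param design a [pool_design()].
#' @param dimension `"plate"`, `"row"` or `"column"`.
#' @param th bound multiplier (e.g. `th_g1`).
#' @return `floor(th * expected_pool_size(design, dimension))`.
#' @examples
#' d <- pool_design(10, 8, 12)
#' candidate_bound(d, "plate", 1.5)   # floor(1.5 * 96) = 144
#' candidate_bound(d, "row", 1.5)     # floor(1.5 * 120) = 180
#' candidate_bound(d, "column", 1.5)  # floor(1.5 * 80) = 120
#' @export
candidate_bound <- function(design, dimension, th) {
  as.integer(floor(th * expected_pool_size(design, dimension)))
}

# Long table of per-pool candidate hits: for every pool, the indices whose
# effective rank (rank after dropping excluded indices, preserving coverage
# order) lies within floor(th * expected-size). Pools with fewer indices
# than the bound contribute all of them.
pool_hits <- function(design, cov_tables, th, exclude = character()) {
  stopifnot(inherits(design, "pool_design"))
  out <- vector("list", design$n_pools)
  for (i in seq_len(design$n_pools)) {
    p <- design$pools[i]
    cov <- cov_tables[[p$label]]
    if (is.null(cov))
      stop("missing coverage table for pool '", p$label, "'")
    bound <- candidate_bound(design, p$dimension, th)
    if (nrow(cov) > 0L) {
      cov <- cov[order(rank)]
      if (length(exclude)) cov <- cov[!index_seq %in% exclude]
      k <- min(bound, nrow(cov))
      if (k > 0L) {
        hit <- cov[seq_len(k),
                   .(index_seq, raw_count, norm_cov, pool_rank = rank)]
        hit[, eff_rank := seq_len(.N)]
        hit[, `:=`(label = p$label, dimension = p$dimension,
                   position = p$position)]
        out[[i]] <- hit
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out))
    return(data.table::data.table(
      index_seq = character(), raw_count = integer(), norm_cov = numeric(),
      pool_rank = integer(), eff_rank = integer(), label = character(),
      dimension = character(), position = integer()))
  data.table::rbindlist(out)
}

#' Per-pool Grade-1 candidate index sets
#'
#' For each pool, the indices whose effective coverage rank lies within the
#' Grade-1 bound for that pool's dimension (see [candidate_bound()]);
#' excluded (endogenous) indices do not occupy rank slots.
#'
#' @param design a [pool_design()].
#' @param cov_tables named list of coverage tables keyed by pool label
#'   (see [coverage_from_store()]).
#' @param cfg a [deconvolution_config()].
#' @param exclude indices to drop before ranking (e.g. inferred endogenous).
#' @return named list (by pool label) of character vectors of indices.
#' @export
candidate_sets <- function(design, cov_tables, cfg = deconvolution_config(),
                           exclude = character()) {
  hits <- pool_hits(design, cov_tables, cfg$th_g1, exclude)
  sets <- lapply(design$pools$label, function(lb) hits[label == lb, index_seq])
  names(sets) <- design$pools$label
  sets
}

# Pick the representative read for an index from the pool where it is most
# abundant (deterministic: max raw count, then dimension order as listed in
# the design, i.e. plate pools first).
representative_for <- function(hits_for_index) {
  h <- hits_for_index[order(-raw_count, label)]
  h$representative_read[1L]
}

assignment_columns <- function() {
  c("index_seq", "plate", "row", "column", "well", "grade", "weak_dimension",
    "plate_pool", "row_pool", "column_pool",
    "plate_rank", "row_rank", "column_rank",
    "plate_cov", "row_cov", "column_cov",
    "representative_read", "ambiguous_well")
}

empty_assignments <- function() {
  a <- data.table::data.table(
    index_seq = character(), plate = integer(), row = integer(),
    column = integer(), well = character(), grade = integer(),
    weak_dimension = character(), plate_pool = character(),
    row_pool = character(), column_pool = character(),
    plate_rank = integer(), row_rank = integer(), column_rank = integer(),
    plate_cov = numeric(), row_cov = numeric(), column_cov = numeric(),
    representative_read = character(), ambiguous_well = logical())
  a
}

# Wide per-index, per-dimension hit summary from a pool_hits table:
# n pools hit, the (single) position/rank/cov when n == 1.
dim_summary <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.table::data.table(index_seq = character(),
                                  dimension = character(), n = integer(),
                                  position = integer(), eff_rank = integer(),
                                  norm_cov = numeric(), label = character()))
  hits[, .(n = .N,
           position = if (.N == 1L) position[1L] else NA_integer_,
           eff_rank = if (.N == 1L) eff_rank[1L] else NA_integer_,
           norm_cov = if (.N == 1L) norm_cov[1L] else NA_real_,
           label = if (.N == 1L) label[1L] else NA_character_),
       by = .(index_seq, dimension)]
}

add_representatives <- function(assign, cov_tables) {
  if (nrow(assign) == 0L) return(assign)
  reps <- vapply(seq_len(nrow(assign)), function(i) {
    labs <- c(assign$plate_pool[i], assign$row_pool[i], assign$column_pool[i])
    idx <- assign$index_seq[i]
    rows <- data.table::rbindlist(lapply(labs, function(lb) {
      cov <- cov_tables[[lb]]
      r <- cov[index_seq == idx]
      if (nrow(r)) r[, label := lb]
      r
    }), fill = TRUE)
    rows <- rows[order(-raw_count, label)]
    rows$representative_read[1L]
  }, character(1L))
  assign[, representative_read := reps]
  assign
}

#' Grade-1 well assignment
#'
#' An index present in the Grade-1 candidate set of exactly one plate pool,
#' one row pool and one column pool is assigned to the well at that unique
#' intersection. Indices hitting more than one pool in some dimension (but
#' at least one in every dimension) are recorded as multi-well candidates
#' with all implied wells -- legitimately expected for premeiotic
#' transpositions inherited by several progeny -- unless the implied-well
#' count exceeds `cfg$multi_well_cap`, in which case the index is
#' reclassified as suspected endogenous. Two indices assigned to the same
#' well are both kept and flagged ambiguous.
#'
#' @param design a [pool_design()].
#' @param cov_tables named list of per-pool coverage tables.
#' @param cfg a [deconvolution_config()].
#' @param exclude indices excluded from candidacy (endogenous).
#' @return list with `assignments` (see [deconvolve()] for columns),
#'   `multi_well` (index_seq, n_plate, n_row, n_column, n_wells, wells),
#'   `suspected_endogenous` (index_seq, n_wells) and `leftover` (indices
#'   seen in some candidate set but not assignable, available for Grade-2).
#' @export
assign_grade1 <- function(design, cov_tables, cfg = deconvolution_config(),
                          exclude = character()) {
  hits <- pool_hits(design, cov_tables, cfg$th_g1, exclude)
  multi_empty <- data.table::data.table(
    index_seq = character(), n_plate = integer(), n_row = integer(),
    n_column = integer(), n_wells = integer(), wells = character())
  suspect_empty <- data.table::data.table(index_seq = character(),
                                          n_wells = integer())
  if (nrow(hits) == 0L)
    return(list(assignments = empty_assignments(), multi_well = multi_empty,
                suspected_endogenous = suspect_empty, leftover = character()))
  ds <- dim_summary(hits)
  counts <- data.table::dcast(ds, index_seq ~ dimension, value.var = "n",
                              fill = 0L)
  for (d in c("plate", "row", "column"))
    if (is.null(counts[[d]])) counts[, (d) := 0L]
  g1_idx <- counts[plate == 1L & row == 1L & column == 1L, index_seq]
  multi_idx <- counts[plate >= 1L & row >= 1L & column >= 1L &
                        plate * row * column > 1L]

  assignments <- empty_assignments()
  if (length(g1_idx)) {
    w <- data.table::dcast(
      ds[index_seq %in% g1_idx],
      index_seq ~ dimension,
      value.var = c("position", "eff_rank", "norm_cov", "label"))
    assignments <- data.table::data.table(
      index_seq = w$index_seq,
      plate = w$position_plate, row = w$position_row,
      column = w$position_column,
      well = well_label(w$position_plate, w$position_row, w$position_column),
      grade = 1L, weak_dimension = NA_character_,
      plate_pool = w$label_plate, row_pool = w$label_row,
      column_pool = w$label_column,
      plate_rank = w$eff_rank_plate, row_rank = w$eff_rank_row,
      column_rank = w$eff_rank_column,
      plate_cov = w$norm_cov_plate, row_cov = w$norm_cov_row,
      column_cov = w$norm_cov_column,
      representative_read = NA_character_, ambiguous_well = FALSE)
    assignments <- add_representatives(assignments, cov_tables)
    assignments[, ambiguous_well := .N > 1L, by = well]
  }

  multi_well <- multi_empty
  suspected <- suspect_empty
  if (nrow(multi_idx)) {
    rows <- lapply(seq_len(nrow(multi_idx)), function(i) {
      idx <- multi_idx$index_seq[i]
      h <- hits[index_seq == idx]
      combos <- expand.grid(
        plate = sort(h[dimension == "plate", position]),
        row = sort(h[dimension == "row", position]),
        column = sort(h[dimension == "column", position]))
      data.table::data.table(
        index_seq = idx,
        n_plate = multi_idx$plate[i], n_row = multi_idx$row[i],
        n_column = multi_idx$column[i], n_wells = nrow(combos),
        wells = paste(well_label(combos$plate, combos$row, combos$column),
                      collapse = ","))
    })
    mw <- data.table::rbindlist(rows)
    suspected <- mw[n_wells > cfg$multi_well_cap, .(index_seq, n_wells)]
    multi_well <- mw[n_wells <= cfg$multi_well_cap]
  }
  leftover <- setdiff(unique(hits$index_seq),
                      c(assignments$index_seq, multi_well$index_seq,
                        suspected$index_seq))
  list(assignments = assignments, multi_well = multi_well,
       suspected_endogenous = suspected, leftover = leftover)
}

#' Grade-2 well assignment
#'
#' Recovers wells whose element narrowly misses Grade-1: the index must be a
#' unique Grade-1 candidate in exactly two dimensions ("good" dimensions)
#' and, in the remaining dimension, fall beyond the Grade-1 bound but within
#' the relaxed bound `floor(th_g2 * expected)` in exactly one pool. An index
#' whose weak dimension offers two or more relaxed pools is ambiguous and is
#' reported, never assigned.
#'
#' @inheritParams assign_grade1
#' @param skip_indices indices already settled by Grade-1 (assigned,
#'   multi-well or suspected endogenous).
#' @return list with `assignments` (grade = 2, `weak_dimension` set) and
#'   `ambiguous` (index_seq, weak_dimension, n_relaxed_pools).
#' @export
assign_grade2 <- function(design, cov_tables, cfg = deconvolution_config(),
                          exclude = character(), skip_indices = character()) {
  hits2 <- pool_hits(design, cov_tables, cfg$th_g2, exclude)
  amb_empty <- data.table::data.table(index_seq = character(),
                                      weak_dimension = character(),
                                      n_relaxed_pools = integer())
  if (nrow(hits2) == 0L)
    return(list(assignments = empty_assignments(), ambiguous = amb_empty))
  g1_bounds <- vapply(c(plate = "plate", row = "row", column = "column"),
                      function(d) candidate_bound(design, d, cfg$th_g1),
                      integer(1L))
  hits2[, within_g1 := eff_rank <= g1_bounds[dimension]]
  hits2 <- hits2[!index_seq %in% skip_indices]
  if (nrow(hits2) == 0L)
    return(list(assignments = empty_assignments(), ambiguous = amb_empty))

  per_dim <- hits2[, .(n_good = sum(within_g1), n_relaxed = sum(!within_g1)),
                   by = .(index_seq, dimension)]
  wide <- data.table::dcast(per_dim, index_seq ~ dimension,
                            value.var = c("n_good", "n_relaxed"), fill = 0L)
  for (d in c("plate", "row", "column")) {
    for (v in c("n_good_", "n_relaxed_")) {
      col <- paste0(v, d)
      if (is.null(wide[[col]])) wide[, (col) := 0L]
    }
  }
  dims <- c("plate", "row", "column")
  good <- as.matrix(wide[, paste0("n_good_", dims), with = FALSE])
  relaxed <- as.matrix(wide[, paste0("n_relaxed_", dims), with = FALSE])
  weak_ok <- good == 0L & relaxed == 1L
  weak_amb <- good == 0L & relaxed >= 2L
  n_good_one <- rowSums(good == 1L)

  assignments <- empty_assignments()
  ambiguous <- amb_empty
  for (i in seq_len(nrow(wide))) {
    if (n_good_one[i] != 2L) next
    weak_dims <- dims[weak_ok[i, ]]
    amb_dims <- dims[weak_amb[i, ] & good[i, ] == 0L]
    idx <- wide$index_seq[i]
    # the two good dims are fixed; the third either qualifies or is ambiguous
    third <- dims[good[i, ] != 1L]
    if (length(third) != 1L) next
    if (third %in% amb_dims) {
      ambiguous <- rbind(ambiguous, data.table::data.table(
        index_seq = idx, weak_dimension = third,
        n_relaxed_pools = relaxed[i, match(third, dims)]))
      next
    }
    if (!third %in% weak_dims) next
    h <- hits2[index_seq == idx]
    take <- rbind(h[dimension != third & within_g1],
                  h[dimension == third & !within_g1])
    if (nrow(take) != 3L || anyDuplicated(take$dimension)) next
    data.table::setkey(take, dimension)  # column, plate, row
    p <- take["plate"]; r <- take["row"]; cc <- take["column"]
    a <- data.table::data.table(
      index_seq = idx, plate = p$position, row = r$position,
      column = cc$position,
      well = well_label(p$position, r$position, cc$position),
      grade = 2L, weak_dimension = third,
      plate_pool = p$label, row_pool = r$label, column_pool = cc$label,
      plate_rank = p$eff_rank, row_rank = r$eff_rank,
      column_rank = cc$eff_rank,
      plate_cov = p$norm_cov, row_cov = r$norm_cov, column_cov = cc$norm_cov,
      representative_read = NA_character_, ambiguous_well = FALSE)
    assignments <- rbind(assignments, a)
  }
  if (nrow(assignments))
    assignments <- add_representatives(assignments, cov_tables)
  list(assignments = assignments, ambiguous = ambiguous)
}

#' Infer endogenous elements from cross-pool prominence
#'
#' A genuine single-well insertion can be prominent in at most its own three
#' pools; an element of the host genome background is amplified in most or
#' all pools. An index prominent (effective rank within
#' `floor(endogenous_min_rank_fraction * expected)` for the pool's
#' dimension) in strictly more than `endogenous_pool_fraction` of all pools
#' is therefore inferred endogenous. The returned indices can be fed back
#' into [filter_spec()] as `known_endogenous` for future runs.
#'
#' @inheritParams assign_grade1
#' @return list with `endogenous` (index_seq, n_pools_prominent) and
#'   `evidence` (index_seq, label, dimension, pool_rank) for the inferred
#'   indices.
#' @export
infer_endogenous <- function(design, cov_tables,
                             cfg = deconvolution_config()) {
  hits <- pool_hits(design, cov_tables, cfg$endogenous_min_rank_fraction)
  empty <- list(
    endogenous = data.table::data.table(index_seq = character(),
                                        n_pools_prominent = integer()),
    evidence = data.table::data.table(index_seq = character(),
                                      label = character(),
                                      dimension = character(),
                                      pool_rank = integer()))
  if (nrow(hits) == 0L) return(empty)
  prom <- hits[, .(n_pools_prominent = data.table::uniqueN(label)),
               by = index_seq]
  cutoff <- cfg$endogenous_pool_fraction * design$n_pools
  endo <- prom[n_pools_prominent > cutoff]
  if (nrow(endo) == 0L) return(empty)
  data.table::setorder(endo, -n_pools_prominent, index_seq)
  ev <- hits[index_seq %in% endo$index_seq,
             .(index_seq, label, dimension, pool_rank)]
  data.table::setorder(ev, index_seq, label)
  list(endogenous = endo, evidence = ev)
}

#' Deconvolute a full pool set
#'
#' Runs the complete dimension-deconvolution pass for one element type:
#' endogenous inference first (inferred indices are excluded from all
#' candidate ranking), then Grade-1 assignment, then Grade-2 recovery.
#' Wells are partitioned into grade-1 / grade-2 / multi-well / unresolved
#' outcomes.
#'
#' @inheritParams assign_grade1
#' @return object of class `pool_deconvolution`: list with `assignments`
#'   (both grades, ordered by plate, row, column, index), `multi_well`,
#'   `ambiguous_grade2`, `suspected_endogenous`, `endogenous`,
#'   `endogenous_evidence`, `well_status` (every well with status factor),
#'   `unresolved_wells`, plus the `design` and `cfg` used.
#' @export
deconvolve <- function(design, cov_tables, cfg = deconvolution_config()) {
  stopifnot(inherits(design, "pool_design"),
            inherits(cfg, "deconvolution_config"))
  endo <- infer_endogenous(design, cov_tables, cfg)
  exclude <- endo$endogenous$index_seq
  g1 <- assign_grade1(design, cov_tables, cfg, exclude)
  g2 <- assign_grade2(design, cov_tables, cfg, exclude,
                      skip_indices = c(g1$assignments$index_seq,
                                       g1$multi_well$index_seq,
                                       g1$suspected_endogenous$index_seq))
  assignments <- rbind(g1$assignments, g2$assignments)
  if (nrow(assignments)) {
    data.table::setorder(assignments, plate, row, column, index_seq)
    assignments[, ambiguous_well := .N > 1L, by = well]
  }

  wells <- design_wells(design)
  status <- rep("unresolved", nrow(wells))
  mw_wells <- unique(unlist(strsplit(g1$multi_well$wells, ",", fixed = TRUE)))
  status[wells$well %in% mw_wells] <- "multi_well"
  status[wells$well %in% assignments[grade == 2L, well]] <- "grade2"
  status[wells$well %in% assignments[grade == 1L, well]] <- "grade1"
  wells[, status := factor(status,
                           levels = c("grade1", "grade2", "multi_well",
                                      "unresolved"))]
  structure(list(
    assignments = assignments,
    multi_well = g1$multi_well,
    ambiguous_grade2 = g2$ambiguous,
    suspected_endogenous = g1$suspected_endogenous,
    endogenous = endo$endogenous,
    endogenous_evidence = endo$evidence,
    well_status = wells,
    unresolved_wells = wells[status == "unresolved", .(plate, row, column, well)],
    design = design, cfg = cfg), class = "pool_deconvolution")
}

#' @export
print.pool_deconvolution <- function(x, ...) {
  tab <- table(x$well_status$status)
  cat(sprintf("pool_deconvolution over %d wells (%d pools)\n",
              x$design$n_wells, x$design$n_pools))
  cat(sprintf("  grade-1 wells:    %d\n", tab[["grade1"]]))
  cat(sprintf("  grade-2 wells:    %d\n", tab[["grade2"]]))
  cat(sprintf("  multi-well wells: %d (%d candidate indices)\n",
              tab[["multi_well"]], nrow(x$multi_well)))
  cat(sprintf("  unresolved wells: %d\n", tab[["unresolved"]]))
  cat(sprintf("  endogenous indices inferred: %d\n", nrow(x$endogenous)))
  invisible(x)
}
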