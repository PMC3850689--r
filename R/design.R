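#' Pool design for a 3-D sample cube
#'
#' Describes the geometry of a plate x row x column sample cube and the
#' correspondence between pools and sequencing libraries. Each of the
#' `plates + rows + columns` pools is sequenced as one library; a sample in
#' well (p, r, c) contributes reads to exactly the three pools p, r and c,
#' which is what makes deconvolution by pool intersection possible.
#'
#' @param plates,rows,columns dimension sizes (positive integers; rows <= 26
#'   so rows can be lettered A..Z).
#' @param library_ids optional character vector, one per pool in dimension
#'   order (plates, then rows, then columns); defaults to the pool labels.
#' @param barcodes optional per-pool in-read barcodes (same order); defaults
#'   to empty strings (pools arrive pre-demultiplexed, one file per pool).
#' @return an object of class `pool_design`: a list with `P`, `R`, `C`,
#'   `n_wells`, `n_pools` and a `pools` data.table (dimension, position,
#'   label, library_id, barcode).
#' @examples
#' d <- pool_design(10, 8, 12)
#' d$n_wells   # 960
#' d$n_pools   # 30
#' @export
pool_design <- function(plates, rows, columns, library_ids = NULL,
                        barcodes = NULL) {
  stopifnot(length(plates) == 1L, length(rows) == 1L, length(columns) == 1L)
  plates <- as.integer(plates); rows <- as.integer(rows)
  columns <- as.integer(columns)
  if (any(c(plates, rows, columns) < 1L))
    stop("all dimension sizes must be >= 1")
  if (rows > 26L)
    stop("at most 26 rows are supported (rows are lettered A..Z)")
  pools <- data.table::data.table(
    dimension = c(rep("plate", plates), rep("row", rows), rep("column", columns)),
    position  = c(seq_len(plates), seq_len(rows), seq_len(columns))
  )
  pools[, label := c(sprintf("plate%02d", seq_len(plates)),
                     paste0("row", LETTERS[seq_len(rows)]),
                     sprintf("col%02d", seq_len(columns)))]
  n_pools <- nrow(pools)
  if (is.null(library_ids)) library_ids <- pools$label
  if (length(library_ids) != n_pools)
    stop("library_ids must have one entry per pool (", n_pools, ")")
  if (anyDuplicated(library_ids))
    stop("every library_id must map to exactly one pool")
  if (is.null(barcodes)) barcodes <- rep("", n_pools)
  if (length(barcodes) != n_pools)
    stop("barcodes must have one entry per pool (", n_pools, ")")
  ok <- vapply(barcodes, is_dna_string, logical(1L), allow_empty = TRUE)
  if (!all(ok)) stop("barcodes must be DNA strings over {A,C,G,T,N}")
  pools[, library_id := library_ids]
  pools[, barcode := toupper(barcodes)]
  structure(
    list(P = plates, R = rows, C = columns,
         n_wells = plates * rows * columns,
         n_pools = n_pools,
         pools = pools),
    class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("pool_design: %d plates x %d rows x %d columns\n", x$P, x$R, x$C))
  cat(sprintf("  %d wells, %d pool libraries\n", x$n_wells, x$n_pools))
  invisible(x)
}

#' Expected number of genuine elements per pool of a given dimension
#'
#' A plate pool holds `R * C` wells, a row pool `P * C` and a column pool
#' `P * R`; with one insertion per well these are the expected counts of
#' genuine indices per pool, the unit in which candidate-rank bounds are
#' expressed.
#'
#' @param design a [pool_design()].
#' @param dimension one of `"plate"`, `"row"`, `"column"`.
#' @return integer expected element count.
#' @export
expected_pool_size <- function(design, dimension) {
  stopifnot(inherits(design, "pool_design"))
  switch(match.arg(dimension, c("plate", "row", "column")),
         plate  = design$R * design$C,
         row    = design$P * design$C,
         column = design$P * design$R)
}

#' Well label in plate-rowletter-column form
#'
#' Formats coordinates the way wells are labelled on the bench: plate number,
#' row letter, zero-padded column, e.g. plate 22 / row 5 (E) / column 4 is
#' `"22E04"`.
#'
#' @param plate,row,column integer coordinates (1-based).
#' @return character vector of labels.
#' @export
well_label <- function(plate, row, column) {
  sprintf("%d%s%02d", as.integer(plate), LETTERS[as.integer(row)],
          as.integer(column))
}

#' Parse well labels back to coordinates
#' @param label character vector of labels such as `"22E04"`.
#' @return data.table with columns well, plate, row, column.
#' @export
parse_well_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)([A-Z])([0-9]+)$", label))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) stop("unparseable well label: ", label[bad][1L])
  data.table::data.table(
    well = label,
    plate = as.integer(vapply(m, `[`, character(1L), 2L)),
    row = match(vapply(m, `[`, character(1L), 3L), LETTERS),
    column = as.integer(vapply(m, `[`, character(1L), 4L)))
}

#' All wells of a design
#' @param design a [pool_design()].
#' @return data.table (plate, row, column, well) in (plate, row, column) order.
#' @export
design_wells <- function(design) {
  stopifnot(inherits(design, "pool_design"))
  w <- data.table::CJ(plate = seq_len(design$P), row = seq_len(design$R),
                      column = seq_len(design$C))
  w[, well := well_label(plate, row, column)]
  w[]
}

#' Write / read a pool design as a YAML config file
#'
#' The on-disk form carries the dimension sizes plus the per-pool label,
#' library and barcode map, which is everything downstream modules need.
#'
#' @param design a [pool_design()].
#' @param path file path.
#' @return `write_pool_design` returns `path` invisibly; `read_pool_design`
#'   returns a [pool_design()].
#' @export
write_pool_design <- function(design, path) {
  stopifnot(inherits(design, "pool_design"))
  yaml::write_yaml(list(
    plates = design$P, rows = design$R, columns = design$C,
    pools = lapply(seq_len(design$n_pools), function(i) {
      p <- design$pools[i]
      list(label = p$label, dimension = p$dimension, position = p$position,
           library_id = p$library_id, barcode = p$barcode)
    })), path)
  invisible(path)
}

#' @rdname write_pool_design
#' @export
read_pool_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- pool_design(cfg$plates, cfg$rows, cfg$columns,
                   library_ids = vapply(cfg$pools, `[[`, character(1L), "library_id"),
                   barcodes = vapply(cfg$pools, function(p) p$barcode %||% "",
                                     character(1L)))
  got <- vapply(cfg$pools, `[[`, character(1L), "label")
  if (!identical(got, d$pools$label))
    stop("pool labels in ", path, " do not follow dimension order")
  d
}
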