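# Embedded relational store for filtered reads.
#
# One table per (element type x library); with N element types (here the two
# element ends) and L libraries the store holds N * L tables, all with the
# same three fields (index_seq, trimmed_seq, read_id). SQL is generated
# internally so users never write queries themselves.

#' Open (or create) a read store
#'
#' The store is a single-file embedded SQLite database; the path plays the
#' role a DBMS connection string would in a client-server setup.
#'
#' @param path database file path (created if absent); `":memory:"` gives a
#'   transient in-memory store.
#' @return a DBI connection.
#' @export
store_connect <- function(path) {
  DBI::dbConnect(RSQLite::SQLite(), path)
}

#' @rdname store_connect
#' @param con a connection from [store_connect()].
#' @export
store_disconnect <- function(con) {
  DBI::dbDisconnect(con)
  invisible(NULL)
}

#' Table name for an (element type, library) pair
#'
#' @param element_type element-type label, e.g. `"five_prime"`.
#' @param library_id library identifier.
#' @return table name `<element_type>__<library_id>` (non-alphanumeric
#'   characters mapped to `_`).
#' @export
store_table_name <- function(element_type, library_id) {
  clean <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  paste0(clean(element_type), "__", clean(library_id))
}

#' List the (element type, library) tables in a store
#' @param con a store connection.
#' @return data.table with columns table, element_type, library_id.
#' @export
store_tables <- function(con) {
  tabs <- grep("__", DBI::dbListTables(con), value = TRUE, fixed = TRUE)
  data.table::data.table(
    table = tabs,
    element_type = sub("__.*$", "", tabs),
    library_id = sub("^.*?__", "", tabs))
}

#' Load filtered reads into the store
#'
#' Inserts one row per retained read into the table for the given element
#' type and library. Re-loading an already-populated table is refused unless
#' `overwrite = TRUE`, in which case the table is rebuilt from scratch
#' (re-runs are idempotent).
#'
#' @param con a store connection.
#' @param reads a data.table with columns index_seq, trimmed_seq, read_id
#'   (extra columns ignored), or the path of a tab-separated file with those
#'   columns as written by [filter_library()].
#' @param element_type,library_id table key.
#' @param overwrite replace existing rows?
#' @return number of rows inserted.
#' @export
store_load <- function(con, reads, element_type, library_id,
                       overwrite = FALSE) {
  if (is.character(reads) && length(reads) == 1L)
    reads <- data.table::fread(reads, sep = "\t", colClasses = "character")
  need <- c("index_seq", "trimmed_seq", "read_id")
  if (!all(need %in% names(reads)))
    stop("reads must have columns ", paste(need, collapse = ", "))
  tab <- store_table_name(element_type, library_id)
  if (DBI::dbExistsTable(con, tab)) {
    n_existing <- DBI::dbGetQuery(
      con, paste0("SELECT COUNT(*) AS n FROM ", tab))$n
    if (n_existing > 0L && !overwrite)
      stop("table ", tab, " already holds ", n_existing,
           " rows; pass overwrite = TRUE to replace them")
    DBI::dbRemoveTable(con, tab)
  }
  df <- as.data.frame(reads[, need, with = FALSE])
  DBI::dbWriteTable(con, tab, df)
  nrow(df)
}

#' Per-pool coverage table
#'
#' Groups one library's reads by sequence index. Coverage of an index is its
#' read count normalised by the library's total read count (so per-pool
#' totals cancel out library-size differences), and indices are ranked 1..K
#' in descending coverage. Ties are broken by descending raw count, then
#' lexicographic index, so ranking is deterministic and platform-independent.
#' Each index also carries a representative full-length read: the modal
#' trimmed sequence among its reads (lexicographically smallest on ties).
#'
#' @param con a store connection.
#' @param element_type,library_id table key.
#' @return data.table (index_seq, raw_count, norm_cov, rank,
#'   representative_read) ordered by rank; zero rows for an empty library.
#' @export
store_coverage <- function(con, element_type, library_id) {
  tab <- store_table_name(element_type, library_id)
  if (!DBI::dbExistsTable(con, tab))
    stop("no table for element type '", element_type, "', library '",
         library_id, "' (expected ", tab, ")")
  empty <- data.table::data.table(
    index_seq = character(), raw_count = integer(), norm_cov = numeric(),
    rank = integer(), representative_read = character())
  by_read <- data.table::as.data.table(DBI::dbGetQuery(con, paste0(
    "SELECT index_seq, trimmed_seq, COUNT(*) AS n FROM ", tab,
    " GROUP BY index_seq, trimmed_seq")))
  if (nrow(by_read) == 0L) return(empty)
  data.table::setorder(by_read, index_seq, -n, trimmed_seq)
  cov <- by_read[, .(raw_count = sum(n), representative_read = trimmed_seq[1L]),
                 by = index_seq]
  total <- sum(cov$raw_count)
  cov[, norm_cov := raw_count / total]
  data.table::setorder(cov, -raw_count, index_seq)
  cov[, rank := seq_len(.N)]
  cov[, .(index_seq, raw_count, norm_cov, rank, representative_read)]
}

#' Coverage tables for every pool of a design
#'
#' @param con a store connection.
#' @param element_type element-type label.
#' @param design a [pool_design()]; each pool's `library_id` names its table.
#' @return named list of coverage tables keyed by pool label.
#' @export
coverage_from_store <- function(con, element_type, design) {
  stopifnot(inherits(design, "pool_design"))
  covs <- lapply(seq_len(design$n_pools), function(i)
    store_coverage(con, element_type, design$pools$library_id[i]))
  names(covs) <- design$pools$label
  covs
}
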