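#' Run the full deconvolution pipeline over per-pool read files
#'
#' Convenience driver chaining the three upstream stages for one element
#' end: filter every pool library ([filter_library()]), load the retained
#' reads into an embedded store ([store_load()]), build per-pool coverage
#' tables ([store_coverage()]) and deconvolute ([deconvolve()]).
#'
#' @param files data.table/data.frame with columns `pool` (pool label as in
#'   the design) and `path` (read file); e.g. the `files` table of
#'   [simulate_reads()] filtered to one end.
#' @param design a [pool_design()]; per-pool barcodes are taken from it.
#' @param spec a [filter_spec()]; its barcode field is overridden per pool
#'   by the design's barcode map.
#' @param cfg a [deconvolution_config()].
#' @param store_path SQLite file path; default a temporary file.
#' @return list with `decon` (a `pool_deconvolution`), `filter_stats`
#'   (data.table, one row per pool), `cov_tables` and `store_path`.
#' @export
deconvolve_pools <- function(files, design, spec,
                             cfg = deconvolution_config(),
                             store_path = tempfile(fileext = ".sqlite")) {
  stopifnot(inherits(design, "pool_design"), inherits(spec, "filter_spec"))
  files <- data.table::as.data.table(files)
  stopifnot(all(c("pool", "path") %in% names(files)))
  missing <- setdiff(design$pools$label, files$pool)
  if (length(missing))
    stop("no read file for pool(s): ", paste(missing, collapse = ", "))
  con <- store_connect(store_path)
  on.exit(store_disconnect(con))
  stats_rows <- vector("list", design$n_pools)
  for (i in seq_len(design$n_pools)) {
    p <- design$pools[i]
    f <- files[pool == p$label]
    pool_spec <- spec
    pool_spec$barcode <- p$barcode
    res <- filter_library(f$path[1L], pool_spec, p$library_id)
    store_load(con, res$reads, spec$end_label, p$library_id,
               overwrite = TRUE)
    stats_rows[[i]] <- data.table::data.table(
      pool = p$label, library_id = p$library_id, t(res$stats))
  }
  cov <- coverage_from_store(con, spec$end_label, design)
  decon <- deconvolve(design, cov, cfg)
  list(decon = decon, filter_stats = data.table::rbindlist(stats_rows),
       cov_tables = cov, store_path = store_path)
}
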