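# Report emission: machine-readable TSVs, a FASTA of assigned sequences and
# a small set of HTML pages summarising well assignment per plate.

status_colors <- c(grade1 = "#2e8b57", grade2 = "#9acd32",
                   multi_well = "#e8a33d", unresolved = "#c8c8c8")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

plate_grid_html <- function(decon, plate_no) {
  ws <- decon$well_status[plate == plate_no]
  asn <- decon$assignments[plate == plate_no]
  rows <- character(decon$design$R)
  for (r in seq_len(decon$design$R)) {
    cells <- character(decon$design$C)
    for (cc in seq_len(decon$design$C)) {
      w <- ws[row == r & column == cc]
      idx <- asn[row == r & column == cc, index_seq]
      title <- paste0(w$well, " [", as.character(w$status), "]",
                      if (length(idx)) paste0(" ", paste(idx, collapse = "/"))
                      else "")
      cells[cc] <- sprintf(
        '<td style="background:%s" title="%s">%s</td>',
        status_colors[[as.character(w$status)]], html_escape(title),
        html_escape(w$well))
    }
    rows[r] <- paste0("<tr>", paste0(cells, collapse = ""), "</tr>")
  }
  paste0('<table class="plate">', paste0(rows, collapse = "\n"), "</table>")
}

html_page <- function(title, body) {
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'><title>",
    html_escape(title), "</title>\n",
    "<style>table.plate{border-collapse:collapse}",
    "table.plate td{border:1px solid #555;padding:4px 6px;",
    "font:12px monospace;text-align:center}",
    "body{font:14px sans-serif;margin:2em}</style></head><body>\n",
    "<h1>", html_escape(title), "</h1>\n", body, "\n</body></html>\n")
}

#' Write deconvolution reports
#'
#' Emits, under `out_dir`: `assignments.tsv` (all assignments with
#' coordinates, grade, per-dimension ranks and coverages),
#' `assignments.fasta` (ID `<well>|grade<g>`, sequence = the representative
#' full-length read -- the input to element mapping), `endogenous.tsv`,
#' `multi_well.tsv`, `unresolved.tsv`, and `report/index.html` plus one HTML
#' grid page per plate with wells coloured by outcome.
#'
#' @param decon a [deconvolve()] result.
#' @param out_dir output directory (created if needed).
#' @return named list of the paths written, invisibly.
#' @export
emit_report <- function(decon, out_dir) {
  stopifnot(inherits(decon, "pool_deconvolution"))
  dir.create(file.path(out_dir, "report"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(
    assignments = file.path(out_dir, "assignments.tsv"),
    fasta = file.path(out_dir, "assignments.fasta"),
    endogenous = file.path(out_dir, "endogenous.tsv"),
    multi_well = file.path(out_dir, "multi_well.tsv"),
    unresolved = file.path(out_dir, "unresolved.tsv"),
    index_html = file.path(out_dir, "report", "index.html"))

  data.table::fwrite(decon$assignments, paths$assignments, sep = "\t")
  data.table::fwrite(decon$endogenous, paths$endogenous, sep = "\t")
  data.table::fwrite(decon$multi_well, paths$multi_well, sep = "\t")
  data.table::fwrite(decon$unresolved_wells, paths$unresolved, sep = "\t")

  asn <- decon$assignments
  ids <- sprintf("%s|grade%d", asn$well, asn$grade)
  if (anyDuplicated(ids))  # well collisions: disambiguate by index
    ids[duplicated(ids) | duplicated(ids, fromLast = TRUE)] <-
      sprintf("%s|%s", ids[duplicated(ids) | duplicated(ids, fromLast = TRUE)],
              asn$index_seq[duplicated(ids) | duplicated(ids, fromLast = TRUE)])
  fa <- Biostrings::DNAStringSet(asn$representative_read)
  names(fa) <- ids
  Biostrings::writeXStringSet(fa, paths$fasta)

  tab <- table(decon$well_status$status)
  legend <- paste(sprintf(
    '<span style="background:%s;padding:2px 8px;margin-right:1em">%s (%d)</span>',
    status_colors, names(status_colors), as.integer(tab[names(status_colors)])),
    collapse = " ")
  links <- paste(sprintf('<li><a href="plate_%02d.html">plate %d</a></li>',
                         seq_len(decon$design$P), seq_len(decon$design$P)),
                 collapse = "\n")
  writeLines(html_page(
    "Well assignment summary",
    paste0("<p>", legend, "</p>\n",
           sprintf("<p>%d wells, %d assignments, %d endogenous indices.</p>",
                   decon$design$n_wells, nrow(asn), nrow(decon$endogenous)),
           "<ul>", links, "</ul>")), paths$index_html)
  for (p in seq_len(decon$design$P)) {
    writeLines(html_page(sprintf("Plate %d", p), plate_grid_html(decon, p)),
               file.path(out_dir, "report", sprintf("plate_%02d.html", p)))
  }
  invisible(paths)
}
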