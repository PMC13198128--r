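# Recorded train/test split sizes of the real downstream datasets, used to
# validate externally prepared splits cell by cell.

#' Recorded split sizes for the real downstream datasets
#'
#' One row per (task, cell): e.g. DPP-IV inhibition has 532 positive and 532
#' negative training peptides and 133/133 for testing. Shipped as a plain
#' tab-separated table under `inst/extdata/split_specs.tsv`.
#'
#' @return tibble with columns `task`, `cell`, `count`
#' @export
split_spec_table <- function() {
  path <- system.file("extdata", "split_specs.tsv", package = "trimodalign")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "split_specs.tsv")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(task = "c", cell = "c", count = "i"))
}

#' Validate split counts against the recorded specification
#'
#' @param task task identifier present in [split_spec_table()]
#' @param counts named integer vector of cell counts (names matching the
#'   table's `cell` values for that task)
#' @return list with `pass` (logical) and `report` (tibble: cell, expected,
#'   provided, ok); any missing or mismatched cell fails with the cell named
#' @export
validate_split_spec <- function(task, counts) {
  tab <- split_spec_table()
  ref <- tab[tab$task == task, , drop = FALSE]
  if (!nrow(ref)) {
    stop("unknown task '", task, "'; known: ",
         paste(unique(tab$task), collapse = ", "))
  }
  provided <- counts[match(ref$cell, names(counts))]
  report <- tibble::tibble(
    cell = ref$cell,
    expected = ref$count,
    provided = as.integer(provided),
    ok = !is.na(provided) & provided == ref$count
  )
  extra <- setdiff(names(counts), ref$cell)
  if (length(extra)) {
    report <- dplyr::bind_rows(report, tibble::tibble(
      cell = extra, expected = NA_integer_,
      provided = as.integer(counts[extra]), ok = FALSE))
  }
  list(pass = all(report$ok), report = report)
}
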