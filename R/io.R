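#' Read an isotopologue intensity table
#'
#' Reads a delimited (comma or tab) table of measured isotopologue
#' intensities: the metadata columns `compound`, `formula`, `n_bio` and
#' `offset` followed by one numeric column per sample. Each compound
#' occupies a block of rows whose `offset` values (nominal-mass positions
#' relative to `[M+H]+`) must be consecutive integers.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter; `NULL` (default) picks tab for `.tsv`
#'   files and comma otherwise.
#' @return An intensity table tibble, the format produced by
#'   [simulate_mids()].
#' @export
read_mid_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("Table must have a header row and at least one data row.")
  nfield <- lengths(strsplit(lines, delim, fixed = TRUE))
  if (length(unique(nfield)) != 1) {
    abort(sprintf("Ragged table: rows have %s fields.",
                  paste(sort(unique(nfield)), collapse = "/")))
  }
  tbl <- readr::read_delim(I(lines), delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) abort("Malformed table: parsing problems encountered.")
  meta <- c("compound", "formula", "n_bio", "offset")
  missing_cols <- setdiff(meta, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  samples <- setdiff(names(tbl), meta)
  if (length(samples) == 0) abort("Table contains no sample columns.")
  if (anyDuplicated(samples)) abort("Sample names must be unique.")
  if (!all(vapply(tbl[samples], is.numeric, logical(1)))) {
    abort("Sample columns must be numeric.")
  }
  if (!is.numeric(tbl$offset) || any(tbl$offset != round(tbl$offset))) {
    abort("`offset` must hold integers.")
  }
  tbl$offset <- as.integer(tbl$offset)
  tbl$n_bio <- as.integer(tbl$n_bio)
  check <- tbl |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      ok = all(diff(.data$offset) == 1) && dplyr::n_distinct(.data$n_bio) == 1 &&
        dplyr::n_distinct(.data$formula) == 1,
      .groups = "drop"
    )
  if (!all(check$ok)) {
    abort(paste0("Non-consecutive offsets or inconsistent metadata for: ",
                 paste(check$compound[!check$ok], collapse = ", "), "."))
  }
  tbl[c(meta, samples)]
}

#' Write an isotopologue intensity table
#'
#' Inverse of [read_mid_table()]; the delimiter follows the file
#' extension (tab for `.tsv`, comma otherwise) unless given.
#'
#' @param tbl An intensity table tibble.
#' @param path Output path.
#' @param delim Field delimiter, or `NULL` to pick by extension.
#' @return `path`, invisibly.
#' @export
write_mid_table <- function(tbl, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(tbl, path, delim = delim)
  invisible(path)
}

sample_cols <- function(tbl) {
  setdiff(names(tbl), c("compound", "formula", "n_bio", "offset"))
}
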