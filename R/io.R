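#' Read and write cohort and parcel tables as TSV
#'
#' Cohort tables are one row per subject; parcel tables are wide
#' (`subject_id` plus one numeric column per parcel).  Missing entries are
#' written as the literal token `NA`.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_cohort_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' @rdname table_io
#' @export
read_cohort_tsv <- function(path) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE)
  assert_cohort(x)
  x
}

#' @rdname table_io
#' @export
write_parcels_tsv <- function(x, path) {
  assert_parcels(x)
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' @rdname table_io
#' @export
read_parcels_tsv <- function(path) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE)
  assert_parcels(x)
  if (anyNA(parcel_matrix(x))) {
    abort("parcel table contains missing values.")
  }
  x
}
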