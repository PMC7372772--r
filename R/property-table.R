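#' Read and validate an amino-acid physicochemical property table
#'
#' The property table holds one row per standard amino acid and one numeric
#' column per physicochemical descriptor (residue volume, polarizability,
#' solvation free energy, ...). The reference matrix used throughout is
#' 20 x 237, but any table with at least 5 properties is accepted.
#'
#' The file may be tab- or comma-separated, with a header row of property
#' names and the one-letter amino-acid code in the first column.
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble with first column `amino_acid` (sorted as in the file)
#'   followed by the numeric property columns, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_property_table(generate_property_table(n_properties = 8, seed = 1), tf)
#' props <- read_property_table(tf)
#' dim(props)
#' @seealso [generate_property_table()], [fit_embedding()]
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  reader <- if (grepl("\t", first)) readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "amino_acid"
  validate_property_table(tbl)
}

#' Validate an in-memory property table
#'
#' Checks the invariants of the property table: exactly the 20 standard
#' amino acids, each once; every property column numeric with no missing
#' values; at least 5 properties. Errors name the offending row or column.
#'
#' @param tbl A data frame whose first column is the amino-acid code.
#' @return The validated table as a tibble (invisibly unchanged otherwise).
#' @export
validate_property_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  if (ncol(tbl) < 6) {
    abort(sprintf("property table needs at least 5 property columns, got %d", ncol(tbl) - 1L))
  }
  aa <- as.character(tbl[[1]])
  dup <- unique(aa[duplicated(aa)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate amino-acid code(s): %s", paste(dup, collapse = ", ")))
  }
  missing <- setdiff(amino_acid_codes(), aa)
  if (length(missing) > 0) {
    abort(sprintf("property table is missing amino acid(s): %s", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(aa, amino_acid_codes())
  if (length(extra) > 0) {
    abort(sprintf("unknown amino-acid code(s): %s", paste(extra, collapse = ", ")))
  }
  for (j in seq(2L, ncol(tbl))) {
    col <- tbl[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      abort(sprintf("non-numeric value in column '%s', row %s (amino acid %s)",
                    names(tbl)[j], bad %||% NA, aa[bad %||% 1]))
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1]
      abort(sprintf("missing value in column '%s', row %d (amino acid %s)",
                    names(tbl)[j], bad, aa[bad]))
    }
  }
  names(tbl)[1] <- "amino_acid"
  tbl$amino_acid <- aa
  tbl
}

#' @rdname read_property_table
#' @param tbl A validated property table.
#' @param path Output path; written as TSV with 12 significant digits.
#' @export
write_property_table <- function(tbl, path) {
  tbl <- validate_property_table(tbl)
  write_tsv_12(tbl, path)
  invisible(path)
}

# TSV writer that keeps 12 significant digits on doubles so that
# write -> read round-trips within 1e-12 relative error.
write_tsv_12 <- function(tbl, path) {
  out <- dplyr::mutate(as_tibble(tbl), dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.12g", .x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
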