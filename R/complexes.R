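#' Read a table of protein-drug complexes with binding-site sequences
#'
#' Each row describes one protein-drug complex: `complex_id`, `protein_id`,
#' `drug_id` and the binding-site residues. The `site` column is either a
#' plain amino-acid string (the site sequence already assembled) or a
#' numbered residue list `"num:AA;num:AA;..."`. Numbered residues are sorted
#' by residue number ascending before concatenation: binding-site residues
#' are typically discontinuous in sequence, and sequence-number order is the
#' reproducible way to assemble them into one string.
#'
#' @param path Path to a TSV (or CSV) file with columns `complex_id`,
#'   `protein_id`, `drug_id`, `site`.
#' @return A tibble with columns `complex_id`, `protein_id`, `drug_id`,
#'   `site` (the assembled sequence) and `residue_numbers` (a list column of
#'   integer vectors; consecutive integers when the input was a plain string).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("complex_id\tprotein_id\tdrug_id\tsite",
#'              "cx1\tp1\td1\t5:N;7:G;6:M;9:G"), tf)
#' read_complex_table(tf)$site  # "NMGG"
#' @export
read_complex_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  reader <- if (grepl("\t", first)) readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  need <- c("complex_id", "protein_id", "drug_id", "site")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("complex table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  validate_complex_table(tbl[need])
}

#' Validate and normalize an in-memory complex table
#'
#' Applies the same parsing and checks as [read_complex_table()]: unique
#' non-empty `complex_id`s, non-empty sites, valid one-letter codes, and
#' numbered residue lists reordered by residue number.
#'
#' @param tbl Data frame with columns `complex_id`, `protein_id`, `drug_id`,
#'   `site`.
#' @return A normalized tibble (see [read_complex_table()]).
#' @export
validate_complex_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  dup <- unique(tbl$complex_id[duplicated(tbl$complex_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate complex_id(s): %s", paste(dup, collapse = ", ")))
  }
  parsed <- purrr::map2(tbl$site, tbl$complex_id, parse_site)
  tbl$site <- purrr::map_chr(parsed, "sequence")
  tbl$residue_numbers <- purrr::map(parsed, "numbers")
  tbl
}

# Parse one site field: either a residue list "5:N;6:M;..." or a plain
# sequence string. Returns the assembled sequence plus residue numbers.
parse_site <- function(site, complex_id) {
  if (is.na(site) || !nzchar(site)) {
    abort(sprintf("complex '%s': empty binding site", complex_id))
  }
  if (grepl(":", site, fixed = TRUE)) {
    parts <- strsplit(site, ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    m <- regmatches(parts, regexec("^([0-9]+):([A-Za-z])$", parts))
    bad <- parts[vapply(m, length, 1L) != 3L]
    if (length(bad) > 0) {
      abort(sprintf("complex '%s': malformed residue entry '%s' (expected num:AA)",
                    complex_id, bad[1]))
    }
    num <- vapply(m, function(x) as.integer(x[2]), 1L)
    aa <- toupper(vapply(m, function(x) x[3], ""))
    if (anyDuplicated(num)) {
      abort(sprintf("complex '%s': duplicate residue number %d", complex_id,
                    num[duplicated(num)][1]))
    }
    ord <- order(num)
    num <- num[ord]
    aa <- aa[ord]
  } else {
    aa <- strsplit(toupper(site), "")[[1]]
    num <- seq_along(aa)
  }
  check_residues(aa, what = sprintf("amino-acid (complex '%s')", complex_id))
  list(sequence = paste(aa, collapse = ""), numbers = num)
}

#' @rdname read_complex_table
#' @param tbl A complex table (validated or not).
#' @export
write_complex_table <- function(tbl, path) {
  tbl <- validate_complex_table(tbl)
  readr::write_tsv(tbl[c("complex_id", "protein_id", "drug_id", "site")],
                   path, progress = FALSE)
  invisible(path)
}
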