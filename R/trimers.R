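#' Slide a length-3 window over one binding-site sequence
#'
#' A site of length L yields exactly L - 2 overlapping trimers (window step
#' 1, 1-based positions). Each trimer has a central (major) residue and two
#' flanking (subordinate) residues whose left/right order is not
#' distinguished: the canonical key is the window rewritten with its flanks
#' in sorted order, so e.g. windows `NGM` and `MGN` share the key `MGN`.
#' Because a key is itself a window in canonical form, canonicalization is
#' idempotent.
#'
#' @param sequence An amino-acid string of length >= 3.
#' @return A tibble with columns `position`, `raw` (the window as read),
#'   `center`, `flank1`, `flank2` (sorted) and `canonical_key`.
#' @examples
#' trimer_windows("NGMG")  # NGM and GMG
#' @export
trimer_windows <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3) {
    abort(sprintf("site too short for trimer extraction (length %d < 3)", n))
  }
  aa <- strsplit(sequence, "")[[1]]
  check_residues(aa, "amino-acid")
  pos <- seq_len(n - 2L)
  left <- aa[pos]
  center <- aa[pos + 1L]
  right <- aa[pos + 2L]
  f1 <- pmin(left, right)
  f2 <- pmax(left, right)
  tibble(position = pos,
         raw = paste0(left, center, right),
         center = center, flank1 = f1, flank2 = f2,
         canonical_key = paste0(f1, center, f2))
}

#' Canonical key of trimer windows
#'
#' @param raw Character vector of 3-letter windows.
#' @return Character vector of canonical keys (the window with its flanks
#'   sorted). Idempotent: a canonical key maps to itself.
#' @export
canonical_trimer_key <- function(raw) {
  stopifnot(all(nchar(raw) == 3L))
  raw <- toupper(raw)
  l <- substr(raw, 1, 1); c_ <- substr(raw, 2, 2); r <- substr(raw, 3, 3)
  check_residues(c(l, c_, r), "amino-acid")
  paste0(pmin(l, r), c_, pmax(l, r))
}

#' Extract all trimers from a complex table
#'
#' Applies [trimer_windows()] to every binding site, carrying the complex,
#' protein and drug provenance on each trimer occurrence.
#'
#' @param complexes A complex table (see [read_complex_table()]).
#' @param on_short What to do with sites shorter than 3 residues: `"error"`
#'   (default) or `"skip"` (drop them with a warning giving the count).
#' @return A tibble with columns `complex_id`, `protein_id`, `drug_id`,
#'   `position`, `raw`, `center`, `flank1`, `flank2`, `canonical_key`; one
#'   row per window occurrence, site order preserved.
#' @examples
#' cx <- tibble::tibble(complex_id = "cx1", protein_id = "p1",
#'                      drug_id = "d1", site = "NGMG")
#' extract_trimers(cx)
#' @export
extract_trimers <- function(complexes, on_short = c("error", "skip")) {
  on_short <- match.arg(on_short)
  complexes <- validate_complex_table(complexes)
  short <- nchar(complexes$site) < 3
  if (any(short)) {
    if (on_short == "error") {
      abort(sprintf("site too short for trimer extraction (complex '%s', length %d)",
                    complexes$complex_id[short][1], nchar(complexes$site[short][1])))
    }
    warn(sprintf("skipping %d complex(es) with sites shorter than 3 residues", sum(short)))
    complexes <- complexes[!short, , drop = FALSE]
  }
  empty <- dplyr::bind_cols(
    tibble(complex_id = character(), protein_id = character(), drug_id = character()),
    trimer_windows("AAA")[0, ])
  out <- purrr::map(seq_len(nrow(complexes)), function(i) {
    w <- trimer_windows(complexes$site[i])
    dplyr::bind_cols(complexes[i, c("complex_id", "protein_id", "drug_id")], w)
  })
  res <- dplyr::bind_rows(c(list(empty), out))
  attr(res, "n_skipped") <- sum(short)
  res
}

#' Vectorize trimers in the embedded amino-acid space
#'
#' A trimer's vector weights the central residue fully and the two flanking
#' residues at a quarter each:
#' `v(trimer) = X(center) + (X(flank1) + X(flank2)) / 4`,
#' where `X(.)` is the amino acid's embedding. The expression is symmetric
#' in the flanks, so it is a pure function of the canonical key.
#'
#' @param trimers A trimer tibble from [extract_trimers()], or anything with
#'   a `canonical_key` column (plus `center`/`flank1`/`flank2`, recomputed
#'   from the key if absent).
#' @param model A fitted [fit_embedding()] model.
#' @return A tibble of the distinct canonical keys with one column per
#'   embedding component (`V1` ... `V<n>`).
#' @examples
#' props <- generate_property_table(seed = 1)
#' emb <- fit_embedding(props)
#' tr <- trimer_windows("NGMG")
#' vectorize_trimers(tr, emb)
#' @export
vectorize_trimers <- function(trimers, model) {
  stopifnot(inherits(model, "dca_embedding"))
  keys <- sort(unique(trimers$canonical_key))
  center <- substr(keys, 2, 2)
  f1 <- substr(keys, 1, 1)
  f2 <- substr(keys, 3, 3)
  V <- model$scores[center, , drop = FALSE] +
    (model$scores[f1, , drop = FALSE] + model$scores[f2, , drop = FALSE]) / 4
  colnames(V) <- paste0("V", seq_len(ncol(V)))
  dplyr::bind_cols(tibble(canonical_key = keys), as_tibble(V))
}

#' @rdname vectorize_trimers
#' @param window A single 3-letter window (any flank order).
#' @return `vectorize_trimer()` returns one numeric vector.
#' @export
vectorize_trimer <- function(model, window) {
  key <- canonical_trimer_key(window)
  v <- embed_amino_acid(model, substr(key, 2, 2)) +
    (embed_amino_acid(model, substr(key, 1, 1)) +
       embed_amino_acid(model, substr(key, 3, 3))) / 4
  unname(v)
}

#' Trimer multiplicity across proteins
#'
#' For each distinct canonical trimer, counts how many distinct proteins
#' carry it at a binding site, then tabulates the fraction of trimers at
#' each protein count. A value of `{1: 0.6}` means 60% of trimers occur in
#' exactly one protein.
#'
#' @param trimers A trimer tibble with `canonical_key` and `protein_id`.
#' @return A tibble with `n_proteins`, `n_trimers`, `fraction`
#'   (fractions sum to 1 over the distinct trimers).
#' @export
trimer_multiplicity <- function(trimers) {
  per_trimer <- dplyr::summarise(
    dplyr::group_by(trimers, .data$canonical_key),
    n_proteins = dplyr::n_distinct(.data$protein_id), .groups = "drop")
  out <- dplyr::count(per_trimer, .data$n_proteins, name = "n_trimers")
  out$fraction <- out$n_trimers / sum(out$n_trimers)
  out
}

#' Hydrophobicity and charge summary of trimers
#'
#' Classifies each distinct canonical trimer by (a) hydropathy -- the mean
#' of its three residues' scale values, hydrophobic when > 0 -- and (b) net
#' side-chain charge at pH 7 -- the sum of residue charges, classed
#' positive / neutral / negative by sign. Defaults use the Kyte-Doolittle
#' hydropathy scale and [side_chain_charges()]; both are configurable since
#' no single scale is canonical.
#'
#' @param trimers A trimer tibble with a `canonical_key` column.
#' @param hydropathy,charges Named numeric vectors over the 20 amino acids.
#' @return A list with `trimers` (per-trimer tibble: key, `hydropathy`,
#'   `hydro_class`, `net_charge`, `charge_class`), `hydro_counts` and
#'   `charge_counts` (aggregate count tibbles).
#' @export
trimer_physchem_summary <- function(trimers,
                                    hydropathy = kyte_doolittle(),
                                    charges = side_chain_charges()) {
  for (scale in list(hydropathy, charges)) {
    miss <- setdiff(amino_acid_codes(), names(scale))
    if (length(miss) > 0) {
      abort(sprintf("scale is missing residue(s): %s", paste(miss, collapse = ", ")))
    }
  }
  keys <- sort(unique(trimers$canonical_key))
  res <- vapply(keys, function(k) strsplit(k, "")[[1]], character(3))
  hyd <- colMeans(matrix(hydropathy[res], nrow = 3))
  chg <- colSums(matrix(charges[res], nrow = 3))
  per <- tibble(
    canonical_key = keys,
    hydropathy = hyd,
    hydro_class = ifelse(hyd > 0, "hydrophobic", "hydrophilic"),
    net_charge = chg,
    charge_class = dplyr::case_when(chg > 1e-9 ~ "positive",
                                    chg < -1e-9 ~ "negative",
                                    TRUE ~ "neutral"))
  list(trimers = per,
       hydro_counts = dplyr::count(per, .data$hydro_class, name = "n_trimers"),
       charge_counts = dplyr::count(per, .data$charge_class, name = "n_trimers"))
}
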