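#' Standard amino acids and default physicochemical scales
#'
#' `amino_acid_codes()` returns the 20 standard one-letter amino-acid codes.
#' `kyte_doolittle()` returns the Kyte-Doolittle hydropathy scale and
#' `side_chain_charges()` the net side-chain charge at pH 7 (K, R = +1;
#' H = +0.1 reflecting its partial protonation; D, E = -1; all others 0).
#' Both are named numeric vectors over the 20 codes and serve as the default
#' scales for [trimer_physchem_summary()].
#'
#' @return A character vector of length 20, or a named numeric vector of
#'   length 20.
#' @examples
#' amino_acid_codes()
#' kyte_doolittle()[["I"]]
#' @export
amino_acid_codes <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname amino_acid_codes
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
    G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
    M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
}

#' @rdname amino_acid_codes
#' @export
side_chain_charges <- function() {
  ch <- setNames(rep(0, 20), amino_acid_codes())
  ch[c("K", "R")] <- 1
  ch["H"] <- 0.1
  ch[c("D", "E")] <- -1
  ch
}

# Validate a character vector of residues, error naming the offender.
check_residues <- function(codes, what = "residue") {
  bad <- setdiff(unique(codes), amino_acid_codes())
  if (length(bad) > 0) {
    abort(sprintf("invalid %s code(s): %s (must be one of the 20 standard one-letter amino acids)",
                  what, paste(bad, collapse = ", ")))
  }
  invisible(codes)
}
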