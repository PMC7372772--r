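#' Specification for synthetic drug-binding-site data
#'
#' Bundles the parameters of the synthetic generators. Defaults mirror the
#' scale of a curated DNA-binding-protein drug dataset: 97 drugs in 110
#' complexes over 60 proteins, binding sites of 20-40 residues, a 20 x 237
#' property table, and a bipartite density of 0.231 (about 2174 edges in a
#' 97 x 97 network).
#'
#' The planted signal works through latent drug groups: drugs are divided
#' into `n_groups` groups, each group owns `motifs_per_group` trimer motifs
#' (its preferred physicochemical "chemistry"), and a drug's binding sites
#' are assembled mostly from its group's motifs, with a `noise` fraction of
#' positions filled by random residues. Drugs in the same group therefore
#' share clusters, which is exactly the co-occurrence structure the
#' similarity indices exploit.
#'
#' @param n_drugs,n_proteins,n_complexes Dataset sizes.
#' @param site_length Length-2 integer range for site lengths (inclusive).
#' @param n_properties Number of physicochemical property columns.
#' @param n_groups Number of latent drug groups (planted cluster count).
#' @param motifs_per_group Trimer motifs owned by each group.
#' @param motif_similarity In `[0, 1]`: within-group motifs share this
#'   fraction of residues with a group consensus trimer, making a group's
#'   motifs physicochemically related.
#' @param noise Fraction of site content drawn at random instead of from
#'   the drug's motif set (0 = pure signal).
#' @param property_noise Relative noise on top of the rank-5 latent
#'   structure of the property table.
#' @param density Edge density for bare bipartite networks.
#' @return A list of class `dca_synth_spec`.
#' @export
synthetic_spec <- function(n_drugs = 97, n_proteins = 60, n_complexes = 110,
                           site_length = c(20L, 40L), n_properties = 237,
                           n_groups = 8, motifs_per_group = 5,
                           motif_similarity = 0.5, noise = 0.1,
                           property_noise = 0.1, density = 0.231) {
  stopifnot(n_drugs > 0, n_proteins > 0, n_complexes > 0, n_properties >= 5, n_groups > 0, motifs_per_group > 0,
            noise >= 0, noise <= 1, density > 0, density < 1,
            site_length[1] >= 3, site_length[2] >= site_length[1])
  structure(as.list(environment()), class = "dca_synth_spec")
}

#' Generate a synthetic amino-acid property table
#'
#' Draws a 20 x P matrix with planted rank-5 latent structure (5 latent
#' factors per amino acid times random loadings) plus Gaussian noise, so
#' that reduction to 5 principal components is meaningful. With
#' `property_noise = 0` the matrix has exact rank 5.
#'
#' @param spec A [synthetic_spec()]; individual fields can be overridden.
#' @param n_properties,property_noise Optional overrides.
#' @param seed Optional integer seed.
#' @return A property table tibble (see [read_property_table()]).
#' @examples
#' props <- generate_property_table(seed = 1)
#' dim(props)  # 20 x 238 (code column + 237 properties)
#' @export
generate_property_table <- function(spec = synthetic_spec(), n_properties = NULL,
                                    property_noise = NULL, seed = NULL) {
  P <- n_properties %||% spec$n_properties
  nz <- property_noise %||% spec$property_noise
  with_seed_or_current(seed, {
    L <- matrix(rnorm(20 * 5), 20, 5)
    W <- matrix(rnorm(5 * P), 5, P)
    X <- L %*% W
    if (nz > 0) X <- X + matrix(rnorm(20 * P, sd = nz * sd(X)), 20, P)
    colnames(X) <- sprintf("prop_%03d", seq_len(P))
    dplyr::bind_cols(tibble(amino_acid = amino_acid_codes()), as_tibble(X))
  })
}

#' Generate synthetic protein-drug complexes with planted drug-motif affinity
#'
#' Implements the planted-signal model of [synthetic_spec()]: each drug
#' belongs to a latent group with its own motif set; each complex's binding
#' site is assembled by repeatedly appending either a motif from the drug's
#' group (probability `1 - noise`) or three random residues (probability
#' `noise`) until the drawn site length is reached. The returned ground
#' truth (drug -> motif map and drug -> group) is sufficient to compute
#' recovery metrics without looking inside the generator.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed.
#' @return A list with `complexes` (a complex table), `truth` (tibble
#'   `drug_id`, `motif` with canonical motif keys), `groups` (tibble
#'   `drug_id`, `group`) and `spec`.
#' @export
generate_complexes <- function(spec = synthetic_spec(), seed = NULL) {
  stopifnot(inherits(spec, "dca_synth_spec"))
  aa <- amino_acid_codes()
  with_seed_or_current(seed, {
    drugs <- sprintf("D%03d", seq_len(spec$n_drugs))
    proteins <- sprintf("P%03d", seq_len(spec$n_proteins))
    group_of <- rep_len(seq_len(spec$n_groups), spec$n_drugs)[sample.int(spec$n_drugs)]

    motifs <- lapply(seq_len(spec$n_groups), function(g) {
      consensus <- sample(aa, 3, replace = TRUE)
      reps <- vapply(seq_len(spec$motifs_per_group), function(i) {
        keep <- runif(3) < spec$motif_similarity
        m <- ifelse(keep, consensus, sample(aa, 3, replace = TRUE))
        paste(m, collapse = "")
      }, "")
      unique(reps)
    })

    # every drug appears at least once; extra complexes reuse random drugs
    cx_drugs <- c(drugs[seq_len(min(spec$n_drugs, spec$n_complexes))],
                  if (spec$n_complexes > spec$n_drugs)
                    sample(drugs, spec$n_complexes - spec$n_drugs, replace = TRUE))
    cx_prot <- sample(proteins, spec$n_complexes, replace = TRUE)
    lens <- sample(seq(spec$site_length[1], spec$site_length[2]),
                   spec$n_complexes, replace = TRUE)

    sites <- vapply(seq_len(spec$n_complexes), function(i) {
      pool <- motifs[[group_of[match(cx_drugs[i], drugs)]]]
      out <- character(0)
      while (sum(nchar(out)) < lens[i]) {
        out <- c(out, if (runif(1) < spec$noise || length(pool) == 0)
          paste(sample(aa, 3, replace = TRUE), collapse = "") else sample(pool, 1))
      }
      substr(paste(out, collapse = ""), 1, lens[i])
    }, "")

    truth <- dplyr::bind_rows(lapply(seq_along(drugs), function(i) {
      tibble(drug_id = drugs[i],
             motif = canonical_trimer_key(motifs[[group_of[i]]]))
    }))
    list(
      complexes = tibble(complex_id = sprintf("cx%04d", seq_len(spec$n_complexes)),
                         protein_id = cx_prot, drug_id = cx_drugs, site = sites),
      truth = dplyr::distinct(truth),
      groups = tibble(drug_id = drugs, group = group_of),
      spec = spec)
  })
}

#' Generate a bare synthetic bipartite network
#'
#' Each drug-cluster cell is an edge independently with probability
#' `density`. The result carries no evidence and is flagged synthetic; it
#' supports scoring and evaluation but not prediction expansion.
#'
#' @param n_drugs,n_clusters Network dimensions.
#' @param density Edge probability in (0, 1).
#' @param seed Optional integer seed.
#' @return A `dca_network` with `synthetic = TRUE` and `evidence = NULL`.
#' @examples
#' net <- generate_bipartite(97, 97, density = 0.231, seed = 1)
#' glance(net)
#' @export
generate_bipartite <- function(n_drugs = 97, n_clusters = 97, density = 0.231,
                               seed = NULL) {
  stopifnot(density > 0, density < 1)
  with_seed_or_current(seed, {
    drugs <- sprintf("D%03d", seq_len(n_drugs))
    A <- matrix(rbinom(n_drugs * n_clusters, 1L, density), n_drugs, n_clusters,
                dimnames = list(drugs, as.character(seq_len(n_clusters))))
    new_dca_network(drugs, n_clusters, adjacency = A, synthetic = TRUE)
  })
}
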