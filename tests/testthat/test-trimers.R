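test_that("sliding a window over a site yields length-minus-two trimers in order", {
  w <- trimer_windows("NGMG")
  expect_identical(w$raw, c("NGM", "GMG"))
  expect_identical(w$position, 1:2)
  expect_identical(trimer_windows("NGM")$raw, "NGM")
  expect_error(trimer_windows("NG"), "too short")
  expect_equal(nrow(trimer_windows("ACDEFGHIKL")), 8L)
})

test_that("trimer count conservation holds over random complex sets", {
  synth <- generate_complexes(synthetic_spec(n_drugs = 10, n_complexes = 20,
                                             n_proteins = 5), seed = 21)
  tr <- extract_trimers(synth$complexes)
  expect_equal(nrow(tr), sum(nchar(synth$complexes$site) - 2L))
})

test_that("canonicalization ignores flank order and is idempotent", {
  expect_identical(canonical_trimer_key("NGM"), canonical_trimer_key("MGN"))
  k <- canonical_trimer_key(c("NGM", "GMG", "WYA"))
  expect_identical(canonical_trimer_key(k), k)
  expect_identical(trimer_windows("NGM")$canonical_key, "MGN")
})

test_that("short sites error by default and are skipped with a warning on request", {
  cx <- tibble::tibble(complex_id = c("a", "b"), protein_id = "p",
                       drug_id = "d", site = c("NGMG", "NG"))
  expect_error(extract_trimers(cx), "too short")
  expect_warning(tr <- extract_trimers(cx, on_short = "skip"), "skipping 1")
  expect_equal(nrow(tr), 2L)
  expect_equal(attr(tr, "n_skipped"), 1L)
})

test_that("trimer vectors follow the center-plus-quarter-flanks rule", {
  m <- basis_model()  # A = e1, C = e2, D = e3
  # window A-C-D: center C, flanks A and D
  expect_equal(vectorize_trimer(m, "ACD"), c(0.25, 1, 0.25, 0, 0))
  # flank symmetry
  expect_equal(vectorize_trimer(m, "ACD"), vectorize_trimer(m, "DCA"))
  # homogeneous trimer: 1.5 times the residue vector
  expect_equal(vectorize_trimer(m, "AAA"), 1.5 * c(1, 0, 0, 0, 0))

  emb <- fit_embedding(small_props(seed = 22))
  # vectorize_trimers agrees with the scalar form and is keyed canonically
  tr <- trimer_windows("NGMGW")
  v <- vectorize_trimers(tr, emb)
  for (i in seq_len(nrow(tr))) {
    expect_equal(unname(unlist(v[v$canonical_key == tr$canonical_key[i], -1])),
                 vectorize_trimer(emb, tr$raw[i]), tolerance = 1e-12)
  }
})

test_that("vectorization is a pure function of the canonical key", {
  emb <- fit_embedding(small_props(seed = 23))
  t1 <- vectorize_trimers(tibble::tibble(canonical_key = "MGN"), emb)
  t2 <- vectorize_trimers(trimer_windows("NGM"), emb)
  expect_equal(t1, t2, tolerance = 1e-15)
})

test_that("trimer multiplicity fractions are normalized protein counts", {
  # degenerate: every trimer in one protein
  tr1 <- tibble::tibble(canonical_key = c("AAA", "CCC"), protein_id = "p1")
  expect_equal(trimer_multiplicity(tr1),
               tibble::tibble(n_proteins = 1L, n_trimers = 2L, fraction = 1))
  # one trimer in 2 proteins among 4 distinct trimers
  tr2 <- tibble::tibble(
    canonical_key = c("AAA", "CCC", "DDD", "EEE", "AAA"),
    protein_id = c("p1", "p1", "p2", "p2", "p2"))
  m <- trimer_multiplicity(tr2)
  expect_equal(m$fraction[m$n_proteins == 1], 0.75)
  expect_equal(m$fraction[m$n_proteins == 2], 0.25)
  # normalization on random fixtures
  synth <- generate_complexes(seed = 24)
  m3 <- trimer_multiplicity(extract_trimers(synth$complexes))
  expect_equal(sum(m3$fraction), 1)
})

test_that("physicochemical classes follow the hydropathy and charge scales", {
  tr <- tibble::tibble(canonical_key = c("KKK", "DDD", "AGC", "AAH"))
  s <- trimer_physchem_summary(tr)
  per <- s$trimers
  expect_equal(per$charge_class[per$canonical_key == "KKK"], "positive")
  expect_equal(per$net_charge[per$canonical_key == "KKK"], 3)
  expect_equal(per$charge_class[per$canonical_key == "DDD"], "negative")
  # A, G, C hydropathy 1.8, -0.4, 2.5 -> mean 1.3 -> hydrophobic
  expect_equal(per$hydropathy[per$canonical_key == "AGC"], 1.3)
  expect_equal(per$hydro_class[per$canonical_key == "AGC"], "hydrophobic")
  # histidine's partial charge classes AAH as positive
  expect_equal(per$charge_class[per$canonical_key == "AAH"], "positive")
  expect_equal(sum(s$charge_counts$n_trimers), 4L)
  expect_error(trimer_physchem_summary(tr, hydropathy = c(A = 1)), "missing")
})
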