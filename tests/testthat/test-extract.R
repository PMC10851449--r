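test_that("CUI join pairs MedDRA atoms with ICD atoms of the same concept", {
  # one CUI carrying an MDR PT and an ICD9CM atom -> one version-9 pair
  a1 <- make_atoms(
    cui = c("C0000001", "C0000001"),
    sab = c("MDR", "ICD9CM"),
    code = c("10000001", "685.0"),
    str = c("pilonidal cyst", "pilonidal cyst with abscess")
  )
  p1 <- extract_umls_pairs(a1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$icd_version, 9L)
  expect_equal(p1$provenance, "UMLS")
  expect_equal(p1$cui, "C0000001")

  # {MDR PT, MDR LLT, ICD9CM, ICD10CM} in one concept -> 2x2 cross product
  a2 <- make_atoms(
    cui = rep("C0000002", 4),
    sab = c("MDR", "MDR", "ICD9CM", "ICD10CM"),
    code = c("10000002", "20000002", "250.00", "E11.9"),
    str = rep("diabetes mellitus", 4),
    tty = c("PT", "LLT", "PT", "PT")
  )
  p2 <- extract_umls_pairs(a2)
  expect_equal(nrow(p2), 4)
  expect_setequal(p2$meddra_level, c("PT", "LLT"))
  expect_setequal(unique(p2$icd_version), c(9L, 10L))

  # MDR atoms with other term types are ignored
  a3 <- dplyr::mutate(a1, tty = c("OS", "PT"))
  expect_equal(nrow(extract_umls_pairs(a3)), 0)
  expect_equal(nrow(extract_umls_pairs(a1[0, ])), 0)
})

test_that("extraction is idempotent and independent of atom order", {
  fx <- gen_parsed_fixture(sim_config(n_soc = 3, n_pt_per_soc = 5, seed = 31))
  p <- extract_umls_pairs(fx$atoms)
  shuffled <- withr::with_seed(1, dplyr::slice_sample(fx$atoms, prop = 1))
  expect_identical(extract_umls_pairs(shuffled)[, c(1, 2, 4, 5, 7)], p[, c(1, 2, 4, 5, 7)])
  # every UMLS pair's two atoms share the recorded CUI (reverse lookup)
  for (r in seq_len(nrow(p))) {
    cuis_m <- fx$atoms$cui[fx$atoms$sab == "MDR" & fx$atoms$code == p$meddra_code[r]]
    cuis_i <- fx$atoms$cui[fx$atoms$sab %in% c("ICD9CM", "ICD10CM") &
      fx$atoms$code == p$icd_code[r]]
    expect_true(p$cui[r] %in% intersect(cuis_m, cuis_i))
  }
})

test_that("OMOP direct extraction follows the configured relationship ids", {
  concepts <- tibble::tibble(
    concept_id = 1:4,
    concept_name = c("drug abuse", "drug abuse", "opioid abuse", "finding"),
    vocabulary_id = c("MedDRA", "MedDRA", "ICD10CM", "SNOMED"),
    concept_class_id = c("PT", "LLT", "Diagnosis", "Clinical Finding"),
    concept_code = c("10000010", "20000010", "F11.10", "999")
  )
  rel <- tibble::tibble(
    concept_id_1 = c(1L, 4L),
    concept_id_2 = c(3L, 4L),
    relationship_id = c("MedDRA - ICD10CM eq", "MedDRA - ICD10CM eq")
  )
  p <- extract_omop_direct(concepts, rel)
  expect_equal(nrow(p), 1) # the SNOMED-SNOMED row contributes nothing
  expect_equal(p$meddra_level, "PT")
  expect_equal(p$icd_version, 10L)
  expect_equal(p$provenance, "OMOP_DIRECT")
  expect_true(is.na(p$cui))

  # reversed storage direction still qualifies
  rev <- tibble::tibble(
    concept_id_1 = 3L, concept_id_2 = 2L,
    relationship_id = "ICD10CM - MedDRA eq"
  )
  p_rev <- extract_omop_direct(concepts, rev)
  expect_equal(p_rev$meddra_level, "LLT")

  # absent configured relationship -> warning and empty contribution
  expect_warning(
    out <- extract_omop_direct(concepts, rel, relationship_pattern = "NoSuchRel"),
    "contributes nothing"
  )
  expect_equal(nrow(out), 0)
})

test_that("OMOP indirect extraction traverses the SNOMED chain", {
  concepts <- tibble::tibble(
    concept_id = c(1L, 2L, 3L, 4L, 5L),
    concept_name = c("m", "s", "i1", "i2", "i3"),
    vocabulary_id = c("MedDRA", "SNOMED", "ICD9CM", "ICD9CM", "ICD10CM"),
    concept_class_id = c("PT", "Clinical Finding", "Diagnosis", "Diagnosis", "Diagnosis"),
    concept_code = c("10000011", "123456", "001.0", "001.1", "A00.0")
  )
  # single chain M -> S, I -> S (Maps to stored from ICD side)
  rel1 <- tibble::tibble(
    concept_id_1 = c(1L, 3L),
    concept_id_2 = c(2L, 2L),
    relationship_id = c("MedDRA - SNOMED eq", "Maps to")
  )
  p1 <- extract_omop_indirect(concepts, rel1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$icd_code, "001.0")
  expect_equal(p1$provenance, "OMOP_INDIRECT")

  # no ICD attached to the SNOMED intermediate -> nothing
  rel2 <- rel1[1, ]
  expect_warning(p2 <- extract_omop_indirect(concepts, rel2), "contributes nothing")
  expect_equal(nrow(p2), 0)

  # branching: one MedDRA, one SNOMED, three ICD -> three pairs
  rel3 <- tibble::tibble(
    concept_id_1 = c(1L, 3L, 4L, 5L),
    concept_id_2 = c(2L, 2L, 2L, 2L),
    relationship_id = c("MedDRA - SNOMED eq", "Maps to", "Maps to", "Maps to")
  )
  p3 <- extract_omop_indirect(concepts, rel3)
  expect_equal(nrow(p3), 3)
  expect_setequal(p3$icd_code, c("001.0", "001.1", "A00.0"))

  # forward-only traversal: leg-2 "forward" means the ICD concept sits in
  # concept_id_1, which is how OMOP stores "Maps to"
  p4 <- extract_omop_indirect(concepts, rel1, direction = "forward")
  expect_equal(nrow(p4), 1)
})

test_that("merging pair sets unions on identity and concatenates provenance", {
  base <- tibble::tibble(
    meddra_code = "10000001", meddra_level = "PT", meddra_string = "x",
    icd_code = "100.00", icd_version = 9L, icd_string = "x",
    provenance = "UMLS", cui = "C0000001"
  )
  dup <- dplyr::mutate(base, provenance = "OMOP_DIRECT", cui = NA_character_)
  m <- merge_pair_sets(base, dup)
  expect_equal(nrow(m), 1)
  expect_equal(m$provenance, "OMOP_DIRECT+UMLS")
  expect_equal(m$cui, "C0000001")

  disjoint_a <- dplyr::mutate(base[rep(1, 3), ], icd_code = c("1", "2", "3"))
  disjoint_b <- dplyr::mutate(base[rep(1, 4), ], icd_code = c("4", "5", "6", "7"))
  expect_equal(nrow(merge_pair_sets(disjoint_a, disjoint_b)), 7)
  expect_equal(nrow(merge_pair_sets(list(disjoint_a, disjoint_b))), 7)

  # union never exceeds the sum of the parts, over random fixtures
  for (seed in 1:5) {
    fx <- gen_parsed_fixture(sim_config(
      n_soc = 2, n_pt_per_soc = 5, frac_umls_mapped = 0.5,
      frac_omop_direct = 0.5, frac_omop_indirect = 0.5, seed = seed
    ))
    u <- extract_umls_pairs(fx$atoms)
    d <- extract_omop_direct(fx$omop$concepts, fx$omop$relationships)
    i <- extract_omop_indirect(fx$omop$concepts, fx$omop$relationships)
    expect_lte(nrow(merge_pair_sets(u, d, i)), nrow(u) + nrow(d) + nrow(i))
  }
})

test_that("REL/CUI concordance counts match hand tallies", {
  rels <- tibble::tibble(
    cui1 = c("C1", "C2", "C3", "C4", "C5", "C5", "C6"),
    rel = c("RQ", "RQ", "RQ", "RQ", "SY", "SY", "RL"),
    cui2 = c("C1", "C9", "C8", "C7", "C5", "C5", "C6"),
    rela = c("", "classified_as", "classified_as", "mapped_to", "", "", "")
  )
  cc <- rel_cui_concordance(rels, c("RQ", "SY", "XX"))
  rq <- cc[cc$rel == "RQ", ]
  expect_equal(rq$n_total, 4)
  expect_equal(rq$fraction_same_cui, 0.25)
  bd <- rq$rela_breakdown[[1]]
  expect_equal(bd$n[bd$rela == "classified_as"], 2)
  expect_equal(bd$n[bd$rela == "mapped_to"], 1)

  sy <- cc[cc$rel == "SY", ]
  expect_equal(sy$fraction_same_cui, 1.0)

  xx <- cc[cc$rel == "XX", ]
  expect_equal(xx$n_total, 0)
  expect_false(xx$defined)
  expect_true(is.na(xx$fraction_same_cui))
})

test_that("cross-referencing against the MedDRA release filters by official string", {
  llt <- tempfile()
  pt <- tempfile()
  writeLines(c(
    "20000001$pilonidal cyst$10000001$$$$$$$Y$",
    "20000002$buerger disease$10000002$$$$$$$Y$"
  ), llt)
  writeLines(c(
    "10000001$Pilonidal cyst$Skin and subcutaneous tissue disorders$Y$",
    "10000002$Buerger disease$Vascular disorders$Y$"
  ), pt)
  h <- read_meddra_hierarchy(llt, pt)
  pairs <- tibble::tibble(
    meddra_code = c("10000001", "10000002", "10000003"),
    meddra_level = "PT",
    meddra_string = c("PILONIDAL  cyst", "buerger disease", "vanished term"),
    icd_code = c("685.0", "443.1", "000.0"),
    icd_version = 9L,
    icd_string = "s", provenance = "UMLS", cui = c("C1", "C2", "C3")
  )
  kept <- crosscheck_with_meddra(pairs, h)
  expect_equal(nrow(kept), 2) # case/whitespace-only differences retained
  dropped <- attr(kept, "dropped")
  expect_equal(dropped$meddra_code, "10000003")

  # official code attached when the source code differs
  wrong_code <- dplyr::mutate(pairs[1, ], meddra_code = "99999999")
  fixed <- crosscheck_with_meddra(wrong_code, h)
  expect_equal(fixed$meddra_code, "10000001")
  expect_equal(fixed$source_meddra_code, "99999999")
})

test_that("planted obsolete strings are dropped by the crosscheck, exactly", {
  for (k in c(1L, 3L)) {
    fx <- gen_parsed_fixture(sim_config(
      n_soc = 3, n_pt_per_soc = 6,
      frac_umls_mapped = 0.8, n_obsolete = k, seed = 70 + k
    ))
    pairs <- extract_umls_pairs(fx$atoms)
    kept <- suppressMessages(crosscheck_with_meddra(pairs, fx$hierarchy))
    dropped <- attr(kept, "dropped")
    expect_equal(nrow(dropped), sum(fx$gt$umls_pairs$obsolete))
    expect_equal(nrow(kept) + nrow(dropped), nrow(pairs))
  }
})
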