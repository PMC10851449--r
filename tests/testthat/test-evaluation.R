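label_tbl <- function(ids, cats) tibble::tibble(item_id = as.character(ids), category = cats)

test_that("mapped-group sampling uses ceiling arithmetic and a seeded draw", {
  pairs <- tibble::tibble(
    meddra_code = sprintf("%08d", 10000000 + 1:18040),
    meddra_level = "PT", meddra_string = "s",
    icd_code = sprintf("%05d", 1:18040), icd_version = 9L,
    icd_string = "i", provenance = "UMLS", cui = "C1"
  )
  s <- sample_mapped(pairs, fraction = 0.10, seed = 5)
  expect_equal(nrow(s), 1804)
  expect_true(all(c("item_id") %in% names(s)))
  expect_identical(sample_mapped(pairs, 0.10, seed = 5), sample_mapped(pairs, 0.10, seed = 5))
  expect_equal(nrow(sample_mapped(pairs, fraction = 1.0, seed = 1)), 18040)
  expect_error(sample_mapped(pairs[0, ], 0.1, 1), "empty")
  expect_error(sample_mapped(pairs, 0, 1), "fraction")
  expect_error(sample_mapped(pairs, 1.5, 1), "fraction")
})

test_that("unmapped sampling is stratified by primary SOC with shortfall handling", {
  fx <- gen_parsed_fixture(sim_config(
    n_soc = 4, n_pt_per_soc = 40,
    frac_umls_mapped = 0, seed = 19
  ))
  unmapped <- fx$gt$pt_table$pt_code
  # shortfall: every SOC has 40 < 100 available, all are taken
  s <- sample_unmapped(unmapped, fx$hierarchy, per_soc = 100, seed = 2)
  expect_equal(nrow(s), 4 * 40)
  # saturation: per_soc below availability draws exactly per_soc from each
  s2 <- sample_unmapped(unmapped, fx$hierarchy, per_soc = 15, seed = 2)
  expect_equal(nrow(s2), 4 * 15)
  expect_true(all(table(s2$soc_name) == 15))
  expect_identical(
    sample_unmapped(unmapped, fx$hierarchy, 15, seed = 9),
    sample_unmapped(unmapped, fx$hierarchy, 15, seed = 9)
  )
  # total equals sum over SOCs of min(per_soc, available)
  avail <- table(pt_primary_soc(fx$hierarchy)$soc_name[
    pt_primary_soc(fx$hierarchy)$pt_code %in% unmapped
  ])
  expect_equal(nrow(s2), sum(pmin(15, as.numeric(avail))))
})

test_that("Cohen's kappa follows the (po - pe) / (1 - pe) definition", {
  ids <- as.character(1:50)
  # confusion [[20, 5], [10, 15]]: po = 0.70, pe = 0.50, kappa = 0.40
  v1 <- c(rep("A", 25), rep("B", 25))
  v2 <- c(rep("A", 20), rep("B", 5), rep("A", 10), rep("B", 15))
  k <- cohen_kappa(label_tbl(ids, v1), label_tbl(ids, v2))
  expect_equal(k$observed_agreement, 0.70)
  expect_equal(k$expected_agreement, 0.50)
  expect_equal(k$kappa, 0.40)
  expect_equal(glance(k)$kappa, 0.40)

  # identity and symmetry
  expect_equal(cohen_kappa(label_tbl(ids, v1), label_tbl(ids, v1))$kappa, 1)
  expect_equal(
    cohen_kappa(label_tbl(ids, v2), label_tbl(ids, v1))$kappa,
    k$kappa
  )

  # degenerate: both raters constant and equal
  kd <- cohen_kappa(label_tbl(ids, rep("A", 50)), label_tbl(ids, rep("A", 50)))
  expect_true(kd$degenerate)
  expect_true(is.na(kd$kappa))

  # mismatched key sets are rejected with the difference listed
  expect_error(
    cohen_kappa(label_tbl(1:3, rep("A", 3)), label_tbl(2:4, rep("A", 3))),
    "only in first: 1"
  )
})

test_that("kappa equals a confusion-matrix brute force on random label maps", {
  cats <- relation_categories("unmapped")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:200, 1)
    ids <- as.character(seq_len(n))
    v1 <- sample(cats[1:sample(2:7, 1)], n, replace = TRUE)
    v2 <- ifelse(runif(n) < 0.6, v1, sample(cats, n, replace = TRUE))
    if (all(v1 == v2) && length(unique(v1)) == 1) next
    k <- cohen_kappa(label_tbl(ids, v1), label_tbl(ids, v2))
    expect_equal(k$kappa, oracle_kappa(v1, v2), tolerance = 1e-12)
  }
})

test_that("simulated raters recover the configured agreement level", {
  n <- 5000
  items <- paste0("i", seq_len(n))
  for (a in c(0.6, 0.8, 0.95)) {
    cfg <- sim_config(rater_agreement = a, seed = round(1000 * a))
    ann <- generate_annotations(items, cfg)
    po <- mean(rater_labels(ann, "R1")$category == rater_labels(ann, "R2")$category)
    pe_chance <- sum(cfg$category_probs^2)
    expected <- a + (1 - a) * pe_chance
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(po - expected), 3 * se)
  }
})

test_that("the calibration gate passes at and above the threshold", {
  ids <- as.character(1:100)
  make <- function(n_agree) {
    v1 <- rep(c("A", "B"), 50)
    v2 <- v1
    v2[seq_len(100 - n_agree)] <- ifelse(v1[seq_len(100 - n_agree)] == "A", "B", "A")
    list(label_tbl(ids, v1), label_tbl(ids, v2))
  }
  g85 <- calibration_gate(make(85)[[1]], make(85)[[2]])
  expect_true(g85$pass)
  expect_equal(g85$observed_agreement, 0.85)
  g79 <- calibration_gate(make(79)[[1]], make(79)[[2]])
  expect_false(g79$pass)
  g80 <- calibration_gate(make(80)[[1]], make(80)[[2]])
  expect_true(g80$pass) # boundary is inclusive
})

test_that("annotation summaries count every allowed category and reject others", {
  labels <- label_tbl(1:4, c("EXACT_MATCH", "EXACT_MATCH", "PT_BROADER", "PARTIAL_OVERLAP"))
  s <- summarize_annotations(labels, relation_categories("mapped"))
  expect_equal(nrow(s), 4) # zero-count PT_NARROWER row included
  expect_equal(s$n[s$category == "PT_NARROWER"], 0)
  expect_equal(s$pct[s$category == "EXACT_MATCH"], 50.00)
  expect_equal(sum(s$n), 4)

  one <- summarize_annotations(label_tbl(1:7, rep("OTHER", 7)), relation_categories("unmapped"))
  expect_equal(one$pct[one$category == "OTHER"], 100.00)

  expect_error(
    summarize_annotations(label_tbl(1, "TOTALLY_IRRELEVANT"), relation_categories("mapped")),
    "TOTALLY_IRRELEVANT"
  )

  # percentages sum to 100 within rounding slack for random count vectors
  for (seed in 1:20) {
    set.seed(seed)
    counts <- setNames(
      sample(0:500, 7, replace = TRUE),
      relation_categories("unmapped")
    )
    if (sum(counts) == 0) next
    s <- summarize_annotations(counts, relation_categories("unmapped"))
    expect_lt(abs(sum(s$pct) - 100), 0.05)
  }
})

test_that("consolidation resolves disagreements and yields self-agreement 1", {
  ids <- as.character(1:5)
  l1 <- label_tbl(ids, c("EXACT_MATCH", "PT_BROADER", "PT_BROADER", "PARTIAL_OVERLAP", "EXACT_MATCH"))
  l2 <- label_tbl(ids, c("EXACT_MATCH", "PT_BROADER", "PT_NARROWER", "PARTIAL_OVERLAP", "PT_BROADER"))

  expect_identical(
    consolidate_annotations(l1, l1),
    dplyr::arrange(l1, item_id)
  )
  res <- tibble::tibble(item_id = c("3", "5"), category = c("EXACT_MATCH", "PT_BROADER"))
  out <- consolidate_annotations(l1, l2, res)
  expect_equal(nrow(out), 5)
  expect_equal(out$category[out$item_id == "3"], "EXACT_MATCH")
  expect_equal(cohen_kappa(out, out)$observed_agreement, 1)

  expect_error(consolidate_annotations(l1, l2, res[1, ]), "5")
})
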