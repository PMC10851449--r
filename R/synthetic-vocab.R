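#' Configuration for the synthetic vocabulary generator
#'
#' Describes a toy multi-source vocabulary: a MedDRA-like hierarchy
#' (`n_soc` system organ classes, each with `n_pt_per_soc` preferred terms,
#' each PT with an identical self LLT plus `n_llt_per_pt - 1` child LLTs),
#' a counterpart ICD code for every PT (alternating ICD-9-CM / ICD-10-CM),
#' and planted mapping structure: a fraction of PTs share a UMLS CUI with
#' their ICD counterpart (`frac_umls_mapped`), a fraction carry a direct
#' MedDRA-ICD row in the OMOP relationship table (`frac_omop_direct`), and a
#' fraction are linked through a SNOMED intermediate
#' (`frac_omop_indirect`). Each ICD code gets `n_synonyms_per_icd` synonym
#' strings derived from the PT string by token shuffling and, when
#' `lexical_noise > 0`, per-token substitution and modifier insertion, so the
#' BM25 ranker sees graded-difficulty queries. Two simulated raters label the
#' planted mapped pairs: rater 1 draws from `category_probs`, later raters
#' copy rater 1 with probability `rater_agreement` and otherwise redraw.
#'
#' @param n_soc Number of system organ classes (at most 27).
#' @param n_pt_per_soc Preferred terms per SOC.
#' @param n_llt_per_pt LLTs per PT, counting the identical self LLT.
#' @param frac_umls_mapped,frac_omop_direct,frac_omop_indirect Proportions of
#'   PTs planted as mapped through each route, each in \[0, 1\].
#' @param n_synonyms_per_icd Synonym strings per ICD code (>= 1; the first is
#'   the unperturbed PT string).
#' @param lexical_noise Probability that a synonym token is replaced by a
#'   generic modifier (and that a modifier is inserted), in \[0, 1\].
#' @param n_raters Number of simulated annotators (>= 2).
#' @param rater_agreement Probability that a later rater copies rater 1.
#' @param category_probs Named probability vector over relation categories
#'   (names from [relation_categories()]), summing to 1.
#' @param n_obsolete Number of UMLS-mapped PTs whose MedDRA atom string is an
#'   obsolete variant absent from the official hierarchy (exercises
#'   [crosscheck_with_meddra()]).
#' @param seed Integer seed; the whole fixture is a pure function of the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_soc = 3, n_pt_per_soc = 5)
#' cfg$frac_umls_mapped
sim_config <- function(n_soc = 27,
                       n_pt_per_soc = 8,
                       n_llt_per_pt = 3,
                       frac_umls_mapped = 0.27,
                       frac_omop_direct = 0.08,
                       frac_omop_indirect = 0.08,
                       n_synonyms_per_icd = 3,
                       lexical_noise = 0.1,
                       n_raters = 2,
                       rater_agreement = 0.85,
                       category_probs = c(
                         EXACT_MATCH = 0.5144, PT_NARROWER = 0.0377,
                         PT_BROADER = 0.4213, PARTIAL_OVERLAP = 0.0266
                       ),
                       n_obsolete = 0,
                       seed = 1L) {
  cfg <- list(
    n_soc = as.integer(n_soc), n_pt_per_soc = as.integer(n_pt_per_soc),
    n_llt_per_pt = as.integer(n_llt_per_pt),
    frac_umls_mapped = frac_umls_mapped, frac_omop_direct = frac_omop_direct,
    frac_omop_indirect = frac_omop_indirect,
    n_synonyms_per_icd = as.integer(n_synonyms_per_icd),
    lexical_noise = lexical_noise, n_raters = as.integer(n_raters),
    rater_agreement = rater_agreement, category_probs = category_probs,
    n_obsolete = as.integer(n_obsolete), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, name, max = Inf) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x > max) {
      stop(sprintf("`%s` must be a count in [1, %s], got %s", name, max, x), call. = FALSE)
    }
  }
  chk_prop <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("`%s` must be a proportion in [0, 1], got %s", name, x), call. = FALSE)
    }
  }
  chk_count(cfg$n_soc, "n_soc", max = 27)
  chk_count(cfg$n_pt_per_soc, "n_pt_per_soc")
  chk_count(cfg$n_llt_per_pt, "n_llt_per_pt")
  chk_count(cfg$n_synonyms_per_icd, "n_synonyms_per_icd")
  chk_count(cfg$n_raters, "n_raters")
  chk_prop(cfg$frac_umls_mapped, "frac_umls_mapped")
  chk_prop(cfg$frac_omop_direct, "frac_omop_direct")
  chk_prop(cfg$frac_omop_indirect, "frac_omop_indirect")
  chk_prop(cfg$lexical_noise, "lexical_noise")
  chk_prop(cfg$rater_agreement, "rater_agreement")
  if (cfg$n_obsolete < 0) stop("`n_obsolete` must be >= 0", call. = FALSE)
  p <- cfg$category_probs
  if (is.null(names(p)) || !all(names(p) %in% relation_categories("unmapped"))) {
    stop("`category_probs` must be named with relation categories", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf(
      "`category_probs` must be non-negative and sum to 1 (within 1e-9), got sum %.12f",
      sum(p)
    ), call. = FALSE)
  }
  invisible(cfg)
}

# shared modifier pool used for lexical perturbation and LLT child strings
sim_modifiers <- function() {
  c("chronic", "acute", "severe", "recurrent", "unspecified", "benign", "congenital")
}

# token shuffle always possible; substitution/insertion only when noise > 0,
# so at lexical_noise = 0 every synonym keeps exactly its code's own tokens
# (and planted strings stay token-disjoint across codes)
perturb_string <- function(s, noise, modifiers = sim_modifiers()) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  if (length(toks) > 1 && runif(1) < 0.5) toks <- sample(toks)
  if (noise > 0) {
    swap <- runif(length(toks)) < noise
    if (any(swap)) toks[swap] <- sample(modifiers, sum(swap), replace = TRUE)
    if (runif(1) < noise) {
      pos <- sample(0:length(toks), 1)
      toks <- append(toks, sample(modifiers, 1), after = pos)
    }
  }
  paste(toks, collapse = " ")
}

# The in-memory relational model all fixture files are serialized from.
# A single PRNG stream (config$seed) drives structure and strings so the
# emitted files stay mutually consistent; annotations use seed + 1.
# Mapping-route membership is decided by thresholding pre-drawn uniforms, so
# raising a frac_* parameter under the same seed only ever adds pairs.
build_vocab_model <- function(config) {
  set.seed(config$seed)
  socs <- meddra_soc_names()[seq_len(config$n_soc)]
  n_pt <- config$n_soc * config$n_pt_per_soc
  idx <- seq_len(n_pt)

  stems <- c("cardi", "nephr", "hepat", "neur", "dermat", "gastr", "pneum", "arthr", "angi", "myel")
  suffixes <- c("opathy", "itis", "osis", "algia", "oma")
  sites <- c("lesion", "disorder", "syndrome", "injury", "anomaly")
  modifiers <- sim_modifiers()

  # two tokens per PT, both carrying the PT index, so planted strings are
  # token-disjoint across PTs by construction
  tok1 <- paste0(sample(stems, n_pt, TRUE), sample(suffixes, n_pt, TRUE), idx)
  tok2 <- paste0(sample(sites, n_pt, TRUE), idx)
  pt_name <- paste(tok1, tok2)
  pt_code <- sprintf("%08d", 10000000L + idx)
  primary_soc <- rep(socs, each = config$n_pt_per_soc)

  # multiaxiality: ~20% of PTs get a second, non-primary SOC
  sec_draw <- runif(n_pt)
  sec_pick <- sample.int(length(socs), n_pt, replace = TRUE)
  has_secondary <- config$n_soc >= 2 & sec_draw < 0.2
  sec_soc <- socs[ifelse(socs[sec_pick] == primary_soc,
    (sec_pick %% length(socs)) + 1L, sec_pick
  )]

  icd_version <- ifelse(idx %% 2L == 1L, 9L, 10L)
  icd_code <- ifelse(icd_version == 9L,
    sprintf("%03d.%02d", 100L + (idx - 1L) %/% 100L, (idx - 1L) %% 100L),
    sprintf(
      "%s%02d.%d", LETTERS[(idx - 1L) %% 26L + 1L],
      ((idx - 1L) %/% 26L) %% 100L, (idx - 1L) %/% 2600L + 1L
    )
  )
  icd_sab <- ifelse(icd_version == 9L, "ICD9CM", "ICD10CM")

  u_umls <- runif(n_pt)
  u_direct <- runif(n_pt)
  u_indirect <- runif(n_pt)
  u_child_share <- runif(n_pt)
  u_llt_direct <- runif(n_pt)

  umls_mapped <- u_umls < config$frac_umls_mapped
  omop_direct <- u_direct < config$frac_omop_direct
  omop_indirect <- u_indirect < config$frac_omop_indirect
  child_share <- umls_mapped & u_child_share < 0.3 & config$n_llt_per_pt >= 2L
  llt_direct <- omop_direct & u_llt_direct < 0.3

  obsolete <- rep(FALSE, n_pt)
  obsolete[head(which(umls_mapped), config$n_obsolete)] <- TRUE

  cui_pt <- sprintf("C%07d", idx)
  cui_icd <- ifelse(umls_mapped, cui_pt, sprintf("C%07d", 1000000L + idx))

  llt_self_code <- sprintf("%08d", 20000000L + idx)
  n_child <- config$n_llt_per_pt - 1L
  child <- if (n_child > 0) {
    tibble(
      pt_idx = rep(idx, each = n_child),
      j = rep(seq_len(n_child), times = n_pt)
    ) |>
      mutate(
        llt_code = sprintf("%08d", 30000000L + (.data$pt_idx - 1L) * n_child + .data$j),
        llt_name = paste(
          sample(modifiers, n_pt * n_child, replace = TRUE),
          pt_name[.data$pt_idx]
        ),
        shares_cui = .data$j == 1L & child_share[.data$pt_idx],
        cui = ifelse(.data$shares_cui, cui_pt[.data$pt_idx],
          sprintf("C%07d", 2000000L + (.data$pt_idx - 1L) * n_child + .data$j)
        )
      )
  } else {
    tibble(
      pt_idx = integer(), j = integer(), llt_code = character(),
      llt_name = character(), shares_cui = logical(), cui = character()
    )
  }

  # ICD synonym documents: first is the exact PT string, the rest perturbed
  syn <- tidyr::expand_grid(pt_idx = idx, k = seq_len(config$n_synonyms_per_icd))
  syn_str <- character(nrow(syn))
  for (r in seq_len(nrow(syn))) {
    base <- pt_name[syn$pt_idx[r]]
    syn_str[r] <- if (syn$k[r] == 1L) base else perturb_string(base, config$lexical_noise, modifiers)
  }
  syn$str <- syn_str

  pt_atom_str <- ifelse(obsolete, paste(pt_name, "obsoletevariant"), pt_name)

  atoms <- bind_rows(
    tibble(
      cui = cui_pt, lat = "ENG", sab = "MDR", tty = "PT",
      code = pt_code, str = pt_atom_str, suppress = "N"
    ),
    tibble(
      cui = cui_pt, lat = "ENG", sab = "MDR", tty = "LLT",
      code = llt_self_code, str = pt_name, suppress = "N"
    ),
    tibble(
      cui = child$cui, lat = "ENG", sab = "MDR", tty = "LLT",
      code = child$llt_code, str = child$llt_name, suppress = "N"
    ),
    tibble(
      cui = cui_icd[syn$pt_idx], lat = "ENG", sab = icd_sab[syn$pt_idx],
      tty = ifelse(syn$k == 1L, "PT", "SY"),
      code = icd_code[syn$pt_idx], str = syn$str, suppress = "N"
    ),
    tibble(
      cui = sprintf("C%07d", 3000000L + idx[omop_indirect]), lat = "ENG",
      sab = "SNOMEDCT_US", tty = "PT",
      code = sprintf("%d009", 100000L + idx[omop_indirect]),
      str = pt_name[omop_indirect], suppress = "N"
    )
  )

  # MRREL rows exercising the REL/CUI concordance statistics; drawn after the
  # mapping draws so route membership is unaffected by their randomness
  all_cuis <- unique(atoms$cui)
  draw_rel <- function(n, rel, p_same, p_classified = NA) {
    same <- runif(n) < p_same
    cui1 <- sample(all_cuis, n, replace = TRUE)
    cui2 <- ifelse(same, cui1, sample(all_cuis, n, replace = TRUE))
    rela <- rep("", n)
    if (!is.na(p_classified)) {
      rela[!same] <- ifelse(runif(sum(!same)) < p_classified, "classified_as", "mapped_to")
    }
    tibble(cui1 = cui1, rel = rel, cui2 = cui2, rela = rela)
  }
  rels <- bind_rows(
    draw_rel(40L, "RQ", 0.3756, 0.8165),
    draw_rel(40L, "SY", 0.9914),
    tibble(cui1 = all_cuis[1], rel = "RL", cui2 = all_cuis[1], rela = "")
  )

  # OMOP vocabulary tables
  concepts <- bind_rows(
    tibble(
      concept_id = 100000L + idx, concept_name = pt_name,
      vocabulary_id = "MedDRA", concept_class_id = "PT", concept_code = pt_code
    ),
    tibble(
      concept_id = 200000L + idx, concept_name = pt_name,
      vocabulary_id = "MedDRA", concept_class_id = "LLT", concept_code = llt_self_code
    ),
    tibble(
      concept_id = 300000L + idx, concept_name = pt_name,
      vocabulary_id = icd_sab, concept_class_id = "Diagnosis", concept_code = icd_code
    ),
    tibble(
      concept_id = 400000L + idx[omop_indirect], concept_name = pt_name[omop_indirect],
      vocabulary_id = "SNOMED", concept_class_id = "Clinical Finding",
      concept_code = sprintf("%d009", 100000L + idx[omop_indirect])
    )
  )
  direct_rel_id <- sprintf("MedDRA - %s eq", icd_sab)
  snomed_noise <- if (sum(omop_indirect) >= 2) {
    s_ids <- 400000L + idx[omop_indirect]
    tibble(concept_id_1 = s_ids[1], concept_id_2 = s_ids[2], relationship_id = "Is a")
  } else {
    NULL
  }
  concept_rels <- bind_rows(
    tibble(
      concept_id_1 = 100000L + idx[omop_direct],
      concept_id_2 = 300000L + idx[omop_direct],
      relationship_id = direct_rel_id[omop_direct]
    ),
    tibble(
      concept_id_1 = 200000L + idx[llt_direct],
      concept_id_2 = 300000L + idx[llt_direct],
      relationship_id = direct_rel_id[llt_direct]
    ),
    tibble(
      concept_id_1 = 100000L + idx[omop_indirect],
      concept_id_2 = 400000L + idx[omop_indirect],
      relationship_id = "MedDRA - SNOMED eq"
    ),
    tibble(
      concept_id_1 = 300000L + idx[omop_indirect],
      concept_id_2 = 400000L + idx[omop_indirect],
      relationship_id = "Maps to"
    ),
    snomed_noise
  )

  # hierarchy file content
  llt_rows <- bind_rows(
    tibble(llt_code = llt_self_code, llt_name = pt_name, pt_code = pt_code, currency = "Y"),
    tibble(
      llt_code = child$llt_code, llt_name = child$llt_name,
      pt_code = pt_code[child$pt_idx], currency = "Y"
    )
  ) |> arrange(.data$llt_code)
  pt_rows <- bind_rows(
    tibble(pt_code = pt_code, pt_name = pt_name, soc_name = primary_soc, primary = "Y"),
    tibble(
      pt_code = pt_code[has_secondary], pt_name = pt_name[has_secondary],
      soc_name = sec_soc[has_secondary], primary = "N"
    )
  ) |> arrange(.data$pt_code, desc(.data$primary))

  # planted ground truth
  umls_pairs <- bind_rows(
    tibble(
      meddra_code = pt_code[umls_mapped], meddra_level = "PT",
      icd_code = icd_code[umls_mapped], icd_version = icd_version[umls_mapped],
      obsolete = obsolete[umls_mapped]
    ),
    tibble(
      meddra_code = llt_self_code[umls_mapped], meddra_level = "LLT",
      icd_code = icd_code[umls_mapped], icd_version = icd_version[umls_mapped],
      obsolete = FALSE
    ),
    tibble(
      meddra_code = child$llt_code[child$shares_cui], meddra_level = "LLT",
      icd_code = icd_code[child$pt_idx[child$shares_cui]],
      icd_version = icd_version[child$pt_idx[child$shares_cui]],
      obsolete = FALSE
    )
  )
  omop_pairs <- bind_rows(
    tibble(
      meddra_code = pt_code[omop_direct], meddra_level = "PT",
      icd_code = icd_code[omop_direct], icd_version = icd_version[omop_direct],
      route = "direct"
    ),
    tibble(
      meddra_code = llt_self_code[llt_direct], meddra_level = "LLT",
      icd_code = icd_code[llt_direct], icd_version = icd_version[llt_direct],
      route = "direct"
    ),
    tibble(
      meddra_code = pt_code[omop_indirect], meddra_level = "PT",
      icd_code = icd_code[omop_indirect], icd_version = icd_version[omop_indirect],
      route = "indirect"
    )
  )

  pt_table <- tibble(
    pt_code = pt_code, pt_name = pt_name, primary_soc = primary_soc,
    icd_code = icd_code, icd_version = icd_version,
    umls_mapped = umls_mapped, omop_direct = omop_direct,
    omop_indirect = omop_indirect, obsolete = obsolete
  )

  mapped_items <- tibble(
    item_id = paste(pt_code[umls_mapped], icd_code[umls_mapped], sep = "|")
  )
  annotations <- if (nrow(mapped_items) > 0) {
    generate_annotations(mapped_items$item_id, config)
  } else {
    tibble(item_id = character(), rater_id = character(), category = character())
  }

  list(
    atoms = atoms, rels = rels, concepts = concepts, concept_rels = concept_rels,
    llt_rows = llt_rows, pt_rows = pt_rows, annotations = annotations,
    umls_pairs = umls_pairs, omop_pairs = omop_pairs, pt_table = pt_table,
    lexical_matches = tibble(
      pt_code = pt_code, pt_name = pt_name,
      icd_code = icd_code, icd_version = icd_version
    )
  )
}

#' Generate a synthetic vocabulary fixture on disk
#'
#' Writes a self-consistent set of vocabulary files — `MRCONSO.RRF`,
#' `MRREL.RRF`, `CONCEPT.tsv`, `CONCEPT_RELATIONSHIP.tsv`, `llt.asc`,
#' `pt.asc` and `annotations.csv` — whose relational content encodes planted
#' MedDRA-ICD mapping structure, and returns that ground truth so extraction
#' and coverage results can be checked exactly. For every planted UMLS pair a
#' CUI carries both the MedDRA atom and the ICD atom; for every planted
#' indirect OMOP pair the MedDRA-SNOMED / ICD-SNOMED relationship chain is
#' present in `CONCEPT_RELATIONSHIP.tsv`.
#'
#' @param config A [sim_config()].
#' @param output_dir Writable directory; created if absent.
#' @return Invisibly-printed list of class `vocab_ground_truth` with elements
#'   `umls_pairs`, `omop_pairs` (column `route` = direct/indirect),
#'   `lexical_matches` (every PT and its lexically planted ICD counterpart),
#'   `annotations`, `pt_table`, `counts`, `files` and `config`.
#' @export
#' @examples
#' dir <- tempfile()
#' gt <- generate_fixture(sim_config(n_soc = 2, n_pt_per_soc = 4, seed = 7), dir)
#' nrow(gt$umls_pairs)
generate_fixture <- function(config, output_dir) {
  validate_sim_config(config)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  model <- build_vocab_model(config)

  files <- c(
    mrconso = file.path(output_dir, "MRCONSO.RRF"),
    mrrel = file.path(output_dir, "MRREL.RRF"),
    concept = file.path(output_dir, "CONCEPT.tsv"),
    concept_relationship = file.path(output_dir, "CONCEPT_RELATIONSHIP.tsv"),
    llt = file.path(output_dir, "llt.asc"),
    pt = file.path(output_dir, "pt.asc"),
    annotations = file.path(output_dir, "annotations.csv")
  )
  write_mrconso(model$atoms, files[["mrconso"]])
  write_mrrel(model$rels, files[["mrrel"]])
  write_omop_tables(model$concepts, model$concept_rels,
    files[["concept"]], files[["concept_relationship"]]
  )
  write_meddra_hierarchy(model$llt_rows, model$pt_rows, files[["llt"]], files[["pt"]])
  write_annotations(model$annotations, files[["annotations"]])

  structure(
    list(
      umls_pairs = model$umls_pairs,
      omop_pairs = model$omop_pairs,
      lexical_matches = model$lexical_matches,
      annotations = model$annotations,
      pt_table = model$pt_table,
      counts = list(
        n_mrconso = nrow(model$atoms), n_mrrel = nrow(model$rels),
        n_concept = nrow(model$concepts), n_concept_rel = nrow(model$concept_rels),
        n_pt = nrow(model$pt_table), n_llt = nrow(model$llt_rows)
      ),
      files = files,
      config = config
    ),
    class = "vocab_ground_truth"
  )
}

#' @export
print.vocab_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<vocab_ground_truth> %d PTs, %d planted UMLS pairs, %d planted OMOP pairs\n",
    x$counts$n_pt, nrow(x$umls_pairs), nrow(x$omop_pairs)
  ))
  invisible(x)
}

#' Simulate two-rater relation annotations
#'
#' Rater 1 draws a relation category for each item from
#' `config$category_probs`; each later rater copies rater 1's label with
#' probability `config$rater_agreement` and otherwise draws an independent
#' label from the same distribution. Deterministic under `config$seed`
#' (annotations use their own stream, `seed + 1`).
#'
#' @param items Non-empty character vector of item identifiers.
#' @param config A [sim_config()].
#' @return Tibble with columns `item_id`, `rater_id` (`"R1"`, `"R2"`, ...)
#'   and `category`, one row per item and rater.
#' @export
#' @examples
#' ann <- generate_annotations(paste0("it", 1:5), sim_config(rater_agreement = 1))
#' tidyr::pivot_wider(ann, names_from = rater_id, values_from = category)
generate_annotations <- function(items, config) {
  validate_sim_config(config)
  if (length(items) == 0) stop("`items` must be non-empty", call. = FALSE)
  set.seed(config$seed + 1L)
  cats <- names(config$category_probs)
  n <- length(items)
  r1 <- sample(cats, n, replace = TRUE, prob = config$category_probs)
  out <- list(tibble(item_id = items, rater_id = "R1", category = r1))
  for (k in seq_len(config$n_raters - 1L)) {
    copy <- runif(n) < config$rater_agreement
    indep <- sample(cats, n, replace = TRUE, prob = config$category_probs)
    out[[k + 1L]] <- tibble(
      item_id = items, rater_id = paste0("R", k + 1L),
      category = ifelse(copy, r1, indep)
    )
  }
  bind_rows(out)
}
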