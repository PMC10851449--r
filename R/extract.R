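#' Extract MedDRA-ICD mapped pairs from UMLS atoms by CUI join
#'
#' The CUI is the sole mapping criterion: within every concept, each MedDRA
#' atom (source `MDR`, term type PT or LLT) is paired with each ICD-9-CM and
#' ICD-10-CM atom sharing that CUI. MDR atoms with other term types are
#' ignored. The result is deduplicated on
#' (`meddra_code`, `meddra_level`, `icd_code`, `icd_version`) and ordered
#' canonically, so it is independent of atom ordering.
#'
#' @param atoms Atom tibble from [read_mrconso()].
#' @return Mapped-pair tibble: `meddra_code`, `meddra_level`,
#'   `meddra_string`, `icd_code`, `icd_version`, `icd_string`, `provenance`
#'   (`"UMLS"`), `cui`.
#' @export
extract_umls_pairs <- function(atoms) {
  if (nrow(atoms) == 0) {
    return(empty_pairs())
  }
  mdr <- atoms |>
    filter(.data$sab == "MDR", .data$tty %in% c("PT", "LLT")) |>
    select("cui",
      meddra_code = "code", meddra_level = "tty", meddra_string = "str"
    )
  icd <- atoms |>
    filter(.data$sab %in% c("ICD9CM", "ICD10CM")) |>
    mutate(icd_version = ifelse(.data$sab == "ICD9CM", 9L, 10L)) |>
    select("cui", icd_code = "code", "icd_version", icd_string = "str")
  inner_join(mdr, icd, by = "cui", relationship = "many-to-many") |>
    mutate(provenance = "UMLS") |>
    distinct(.data$meddra_code, .data$meddra_level, .data$icd_code,
      .data$icd_version,
      .keep_all = TRUE
    ) |>
    select(
      "meddra_code", "meddra_level", "meddra_string", "icd_code",
      "icd_version", "icd_string", "provenance", "cui"
    ) |>
    arrange_pairs()
}

# classify OMOP concepts into the roles the extractors need
omop_roles <- function(concepts) {
  concepts |>
    mutate(role = case_when(
      .data$vocabulary_id == "MedDRA" ~ "meddra",
      .data$vocabulary_id %in% c("ICD9CM", "ICD10CM") ~ "icd",
      .data$vocabulary_id %in% c("SNOMED", "SNOMEDCT_US") ~ "snomed",
      TRUE ~ "other"
    ))
}

omop_pair_tibble <- function(meddra, icd, provenance) {
  tibble(
    meddra_code = meddra$concept_code,
    meddra_level = meddra$concept_class_id,
    meddra_string = meddra$concept_name,
    icd_code = icd$concept_code,
    icd_version = ifelse(icd$vocabulary_id == "ICD9CM", 9L, 10L),
    icd_string = icd$concept_name,
    provenance = provenance,
    cui = NA_character_
  )
}

#' Extract direct MedDRA-ICD pairs from the OMOP relationship table
#'
#' Relationship rows whose `relationship_id` matches `relationship_pattern`
#' and that join a MedDRA concept to an ICD-9-CM/ICD-10-CM concept (in either
#' direction) become mapped pairs with provenance `OMOP_DIRECT`; the MedDRA
#' level is taken from `concept_class_id`.
#'
#' @param concepts,relationships Tibbles from [read_omop_tables()].
#' @param relationship_pattern Regular expression selecting the direct
#'   mapping relationship ids; the default matches any id naming both MedDRA
#'   and ICD.
#' @return Mapped-pair tibble (see [extract_umls_pairs()] for columns).
#' @export
extract_omop_direct <- function(concepts, relationships,
                                relationship_pattern = "MedDRA.*ICD|ICD.*MedDRA") {
  qualifying <- filter(relationships, grepl(relationship_pattern, .data$relationship_id))
  if (nrow(qualifying) == 0) {
    warning(sprintf(
      "no relationship_id matching '%s' found; direct mapping contributes nothing",
      relationship_pattern
    ), call. = FALSE)
    return(empty_pairs())
  }
  roles <- omop_roles(concepts)
  join_side <- function(rel, meddra_col, icd_col) {
    m <- roles |>
      filter(.data$role == "meddra") |>
      select(meddra_id = "concept_id", "concept_code", "concept_class_id", "concept_name")
    i <- roles |>
      filter(.data$role == "icd") |>
      select(icd_id = "concept_id", "concept_code", "vocabulary_id", "concept_name")
    hits <- rel |>
      inner_join(m, by = setNames("meddra_id", meddra_col)) |>
      inner_join(i, by = setNames("icd_id", icd_col), suffix = c("_m", "_i"))
    omop_pair_tibble(
      tibble(
        concept_code = hits$concept_code_m, concept_class_id = hits$concept_class_id,
        concept_name = hits$concept_name_m
      ),
      tibble(
        concept_code = hits$concept_code_i, vocabulary_id = hits$vocabulary_id,
        concept_name = hits$concept_name_i
      ),
      "OMOP_DIRECT"
    )
  }
  bind_rows(
    join_side(qualifying, "concept_id_1", "concept_id_2"),
    join_side(qualifying, "concept_id_2", "concept_id_1")
  ) |>
    distinct(.data$meddra_code, .data$meddra_level, .data$icd_code,
      .data$icd_version,
      .keep_all = TRUE
    ) |>
    arrange_pairs()
}

#' Extract indirect MedDRA-ICD pairs through SNOMED
#'
#' Traverses the two-leg OMOP chain: a MedDRA concept linked to a SNOMED
#' concept by the equivalence relationship (`eq_pattern`), and an ICD concept
#' linked to the same SNOMED concept by the mapping relationship
#' (`maps_pattern`). In the OMOP model "Maps to" points from the non-standard
#' ICD code to the standard SNOMED concept, so the second leg is traversed
#' against the edge by default; `direction` restricts which orientations are
#' accepted on both legs.
#'
#' @inheritParams extract_omop_direct
#' @param eq_pattern Regular expression for the MedDRA-SNOMED equivalence
#'   relationship id.
#' @param maps_pattern Regular expression for the SNOMED/ICD mapping
#'   relationship id.
#' @param direction `"either"` (default) accepts edges in both orientations;
#'   `"forward"` only rows listing the MedDRA (leg 1) or ICD (leg 2) concept
#'   in `concept_id_1`.
#' @return Mapped-pair tibble with provenance `OMOP_INDIRECT`.
#' @export
extract_omop_indirect <- function(concepts, relationships,
                                  eq_pattern = "MedDRA.*SNOMED|SNOMED.*MedDRA",
                                  maps_pattern = "^Maps to$",
                                  direction = c("either", "forward")) {
  direction <- match.arg(direction)
  roles <- omop_roles(concepts)
  orient <- function(rel, from_ids, to_ids) {
    fwd <- rel |>
      filter(.data$concept_id_1 %in% from_ids, .data$concept_id_2 %in% to_ids) |>
      select(from = "concept_id_1", to = "concept_id_2")
    if (direction == "forward") {
      return(fwd)
    }
    rev <- rel |>
      filter(.data$concept_id_2 %in% from_ids, .data$concept_id_1 %in% to_ids) |>
      select(from = "concept_id_2", to = "concept_id_1")
    distinct(bind_rows(fwd, rev))
  }
  meddra_ids <- roles$concept_id[roles$role == "meddra"]
  snomed_ids <- roles$concept_id[roles$role == "snomed"]
  icd_ids <- roles$concept_id[roles$role == "icd"]

  leg1 <- orient(
    filter(relationships, grepl(eq_pattern, .data$relationship_id)),
    meddra_ids, snomed_ids
  )
  leg2 <- orient(
    filter(relationships, grepl(maps_pattern, .data$relationship_id)),
    icd_ids, snomed_ids
  )
  if (nrow(leg1) == 0 || nrow(leg2) == 0) {
    if (nrow(leg1) == 0) {
      warning("no MedDRA-SNOMED equivalence rows found; indirect mapping contributes nothing",
        call. = FALSE
      )
    } else {
      warning("no SNOMED/ICD mapping rows found; indirect mapping contributes nothing",
        call. = FALSE
      )
    }
    return(empty_pairs())
  }
  chains <- inner_join(leg1, leg2,
    by = "to", suffix = c("_m", "_i"),
    relationship = "many-to-many"
  )
  m <- roles |> select(concept_id = "concept_id", "concept_code", "concept_class_id", "concept_name")
  hits <- chains |>
    inner_join(m, by = c(from_m = "concept_id")) |>
    inner_join(
      roles |> select(concept_id = "concept_id",
        icd_code = "concept_code", "vocabulary_id", icd_name = "concept_name"
      ),
      by = c(from_i = "concept_id")
    )
  omop_pair_tibble(
    tibble(
      concept_code = hits$concept_code, concept_class_id = hits$concept_class_id,
      concept_name = hits$concept_name
    ),
    tibble(
      concept_code = hits$icd_code, vocabulary_id = hits$vocabulary_id,
      concept_name = hits$icd_name
    ),
    "OMOP_INDIRECT"
  ) |>
    distinct(.data$meddra_code, .data$meddra_level, .data$icd_code,
      .data$icd_version,
      .keep_all = TRUE
    ) |>
    arrange_pairs()
}

#' Merge mapped-pair sets from several sources
#'
#' Takes the union of pair sets, deduplicating on
#' (`meddra_code`, `meddra_level`, `icd_code`, `icd_version`). Provenance is
#' preserved as the sorted `+`-joined set of contributing sources; the CUI
#' and term strings come from the first non-missing contributor.
#'
#' @param ... Mapped-pair tibbles, or a single list of them.
#' @return Merged mapped-pair tibble.
#' @export
#' @examples
#' a <- tibble::tibble(
#'   meddra_code = "10000001", meddra_level = "PT", meddra_string = "x",
#'   icd_code = "100.00", icd_version = 9L, icd_string = "x",
#'   provenance = "UMLS", cui = "C0000001"
#' )
#' b <- dplyr::mutate(a, provenance = "OMOP_DIRECT", cui = NA_character_)
#' merge_pair_sets(a, b)$provenance
merge_pair_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  all <- bind_rows(sets)
  if (nrow(all) == 0) {
    return(empty_pairs())
  }
  all |>
    group_by(.data$meddra_code, .data$meddra_level, .data$icd_code, .data$icd_version) |>
    summarise(
      meddra_string = first(.data$meddra_string),
      icd_string = first(.data$icd_string),
      provenance = paste(sort(unique(.data$provenance)), collapse = "+"),
      cui = if (all(is.na(.data$cui))) NA_character_ else first(.data$cui[!is.na(.data$cui)]),
      .groups = "drop"
    ) |>
    select(
      "meddra_code", "meddra_level", "meddra_string", "icd_code",
      "icd_version", "icd_string", "provenance", "cui"
    ) |>
    arrange_pairs()
}

#' CUI concordance of MRREL relationship labels
#'
#' For each relationship label (e.g. `RQ`, `SY`), counts how many rows link
#' two atoms of the same concept (`cui1 == cui2`). Among the discordant rows
#' the RELA attribute values are tallied. These statistics justify using the
#' CUI alone as the mapping criterion: in the 2020AA UMLS release 37.56% of
#' RQ and 99.14% of SY rows are same-CUI, and 81.65% of discordant RQ rows
#' carry a classifies/classified-as RELA.
#'
#' @param relationships Tibble from [read_mrrel()].
#' @param rel_labels Labels to summarize (default `c("RQ", "SY")`).
#' @return Tibble with one row per label: `rel`, `n_total`, `n_same_cui`,
#'   `fraction_same_cui` (`NA` when `n_total == 0`), `defined` flag, and
#'   `rela_breakdown`, a list-column of tibbles (`rela`, `n`) tallied over
#'   the discordant rows.
#' @export
rel_cui_concordance <- function(relationships, rel_labels = c("RQ", "SY")) {
  purrr::map(rel_labels, function(lab) {
    rows <- filter(relationships, .data$rel == lab)
    n_total <- nrow(rows)
    n_same <- sum(rows$cui1 == rows$cui2)
    breakdown <- rows |>
      filter(.data$cui1 != .data$cui2) |>
      count(.data$rela, name = "n") |>
      arrange(desc(.data$n))
    tibble(
      rel = lab, n_total = n_total, n_same_cui = n_same,
      fraction_same_cui = if (n_total > 0) n_same / n_total else NA_real_,
      defined = n_total > 0,
      rela_breakdown = list(breakdown)
    )
  }) |>
    purrr::list_rbind()
}

#' Cross-reference mapped pairs with the official MedDRA release
#'
#' Retains pairs whose MedDRA string matches an official hierarchy term
#' (case-insensitively, after whitespace normalization) at any level. When
#' the matching official term's code differs from the pair's source code, the
#' official code is attached (the original is kept in `source_meddra_code`).
#' Dropped pairs are reported via [message()] and attached as the
#' `"dropped"` attribute with a reason column.
#'
#' @param pairs Mapped-pair tibble.
#' @param hierarchy A [read_meddra_hierarchy()] object.
#' @return The retained pairs, with attribute `"dropped"`.
#' @export
crosscheck_with_meddra <- function(pairs, hierarchy) {
  official <- bind_rows(
    tibble(
      level = "PT", code = hierarchy$pt$pt_code,
      term = normalize_term(hierarchy$pt$pt_name)
    ),
    tibble(
      level = "LLT", code = hierarchy$llt$llt_code,
      term = normalize_term(hierarchy$llt$llt_name)
    )
  ) |>
    distinct(.data$level, .data$term, .keep_all = TRUE)
  checked <- pairs |>
    mutate(.norm = normalize_term(.data$meddra_string)) |>
    left_join(official, by = c(meddra_level = "level", .norm = "term"))
  dropped <- checked |>
    filter(is.na(.data$code)) |>
    select(-".norm", -"code") |>
    mutate(reason = "string absent from MedDRA release")
  kept <- checked |>
    filter(!is.na(.data$code)) |>
    mutate(
      source_meddra_code = .data$meddra_code,
      meddra_code = .data$code
    ) |>
    select(-".norm", -"code")
  if (nrow(dropped) > 0) {
    message(sprintf("crosscheck_with_meddra: dropped %d pair(s) not found in the release", nrow(dropped)))
  }
  structure(arrange_pairs(kept), dropped = dropped)
}
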