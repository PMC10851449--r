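#' Convert LLT-level mapped pairs to the PT level
#'
#' Every PT is self-contained at the LLT level, so LLT-ICD pairs can be
#' lifted to the parent PT: each LLT-level pair is replaced by the pair of
#' its parent PT with the same ICD side, PT-level pairs pass through, and the
#' result is deduplicated. This never increases the number of unique pairs
#' and never changes the ICD side.
#'
#' @param pairs Mapped-pair tibble (mixed PT/LLT levels allowed).
#' @param hierarchy A [read_meddra_hierarchy()] object; every LLT code in
#'   `pairs` must be present, otherwise an error lists the offenders.
#' @return Mapped-pair tibble, all rows at PT level.
#' @export
llt_pairs_to_pt <- function(pairs, hierarchy) {
  if (nrow(pairs) == 0) {
    return(empty_pairs())
  }
  llt_rows <- filter(pairs, .data$meddra_level == "LLT")
  pt_rows <- filter(pairs, .data$meddra_level == "PT")
  unknown <- setdiff(llt_rows$meddra_code, hierarchy$llt$llt_code)
  if (length(unknown) > 0) {
    stop(sprintf(
      "LLT code(s) not in hierarchy: %s",
      paste(head(unknown, 10), collapse = ", ")
    ), call. = FALSE)
  }
  lifted <- llt_rows |>
    inner_join(
      hierarchy$llt |> distinct(.data$llt_code, .data$pt_code),
      by = c(meddra_code = "llt_code")
    ) |>
    inner_join(hierarchy$pt, by = "pt_code") |>
    mutate(
      meddra_code = .data$pt_code, meddra_level = "PT",
      meddra_string = .data$pt_name
    ) |>
    select(-"pt_code", -"pt_name")
  bind_rows(pt_rows, lifted) |>
    distinct(.data$meddra_code, .data$meddra_level, .data$icd_code,
      .data$icd_version,
      .keep_all = TRUE
    ) |>
    arrange_pairs()
}

# map provenance strings (possibly "+"-merged) to the UMLS/OMOP source split
provenance_sources <- function(pairs) {
  pairs |>
    tidyr::separate_longer_delim("provenance", delim = "+") |>
    mutate(source = ifelse(.data$provenance == "UMLS", "UMLS", "OMOP"))
}

#' Summarize MedDRA-ICD mapping coverage
#'
#' Computes the headline coverage statistic — the number and percentage of
#' unique MedDRA PT terms mapped to at least one ICD code, over all PTs in
#' the hierarchy — together with the summary-table machinery: unique-term
#' counts per (MedDRA level, ICD version, source), unique terms per level
#' after taking the union of sources, and per-SOC coverage. LLT-level input
#' pairs contribute to the per-level counts as given and are lifted to PT
#' level (via [llt_pairs_to_pt()]) for the headline numbers.
#'
#' @param pairs Mapped-pair tibble (PT level, or mixed levels).
#' @param hierarchy A [read_meddra_hierarchy()] object; its PT table is the
#'   denominator.
#' @return Object of class `coverage_report`: list with `n_pt_mapped`,
#'   `n_pt_total`, `pct_pt_mapped` (half-up, two decimals), `per_source`
#'   (tibble `meddra_level`, `icd_version`, `source`, `n_terms`),
#'   `union_by_level` (tibble `meddra_level`, `n_terms`) and `per_soc` (see
#'   [per_soc_summary()]).
#' @export
coverage_summary <- function(pairs, hierarchy) {
  per_source <- provenance_sources(pairs) |>
    group_by(.data$meddra_level, .data$icd_version, .data$source) |>
    summarise(n_terms = n_distinct(.data$meddra_code), .groups = "drop")
  union_by_level <- pairs |>
    group_by(.data$meddra_level) |>
    summarise(n_terms = n_distinct(.data$meddra_code), .groups = "drop")
  pt_pairs <- llt_pairs_to_pt(pairs, hierarchy)
  n_total <- nrow(hierarchy$pt)
  n_mapped <- n_distinct(pt_pairs$meddra_code)
  structure(
    list(
      n_pt_mapped = n_mapped,
      n_pt_total = n_total,
      pct_pt_mapped = round_half_up(100 * n_mapped / n_total, 2),
      per_source = per_source,
      union_by_level = union_by_level,
      per_soc = per_soc_summary(pt_pairs, hierarchy)
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> %d / %d PT terms mapped (%.2f%%)\n",
    x$n_pt_mapped, x$n_pt_total, x$pct_pt_mapped
  ))
  invisible(x)
}

#' Per-SOC mapped/unmapped summary
#'
#' Attributes each PT to a single system organ class and reports mapped and
#' unmapped counts and the mapping percentage per SOC. By default the
#' primary SOC is used, so the per-SOC counts partition the PT set; with
#' `all_socs = TRUE` a multiaxial PT is counted under every SOC it belongs
#' to (counts then no longer partition).
#'
#' @param pt_pairs Mapped-pair tibble at PT level.
#' @param hierarchy A [read_meddra_hierarchy()] object.
#' @param all_socs Count each PT under every SOC instead of its primary one.
#' @return Tibble `soc_name`, `n_mapped`, `n_unmapped`, `pct_mapped`
#'   (half-up, two decimals), one row per SOC present in the hierarchy.
#' @export
per_soc_summary <- function(pt_pairs, hierarchy, all_socs = FALSE) {
  attribution <- if (all_socs) {
    select(hierarchy$soc, "pt_code", "soc_name")
  } else {
    pt_primary_soc(hierarchy)
  }
  mapped_codes <- unique(pt_pairs$meddra_code[pt_pairs$meddra_level == "PT"])
  attribution |>
    mutate(mapped = .data$pt_code %in% mapped_codes) |>
    group_by(.data$soc_name) |>
    summarise(
      n_mapped = sum(.data$mapped),
      n_unmapped = sum(!.data$mapped),
      .groups = "drop"
    ) |>
    mutate(pct_mapped = round_half_up(
      100 * .data$n_mapped / (.data$n_mapped + .data$n_unmapped), 2
    )) |>
    arrange(.data$soc_name)
}

#' Coverage across vocabulary snapshots
#'
#' Runs the UMLS extraction and coverage summary on each snapshot of atoms
#' (e.g. yearly Metathesaurus releases) so coverage can be tabulated as a
#' trend. Because the appropriate denominator for a historical snapshot is
#' debatable, two are reported: all PTs in the supplied hierarchy, and the
#' PTs actually present among the snapshot's MDR atoms.
#'
#' @param snapshots Named list of atom tibbles ([read_mrconso()] format);
#'   names label the snapshots.
#' @param hierarchy A [read_meddra_hierarchy()] object.
#' @return Tibble with one row per snapshot, in input order: `snapshot`,
#'   `n_pt_mapped`, `n_pt_total`, `pct_pt_mapped`, `n_pt_in_snapshot`,
#'   `pct_of_snapshot`, and a `report` list-column of `coverage_report`s.
#' @export
snapshot_trend <- function(snapshots, hierarchy) {
  stopifnot(length(snapshots) >= 1)
  labels <- names(snapshots)
  if (is.null(labels)) labels <- as.character(seq_along(snapshots))
  purrr::map2(snapshots, labels, function(atoms, label) {
    pairs <- extract_umls_pairs(atoms)
    rep <- coverage_summary(pairs, hierarchy)
    present <- atoms |>
      filter(.data$sab == "MDR", .data$tty == "PT") |>
      distinct(.data$code) |>
      nrow()
    tibble(
      snapshot = label,
      n_pt_mapped = rep$n_pt_mapped,
      n_pt_total = rep$n_pt_total,
      pct_pt_mapped = rep$pct_pt_mapped,
      n_pt_in_snapshot = present,
      pct_of_snapshot = if (present > 0) {
        round_half_up(100 * rep$n_pt_mapped / present, 2)
      } else {
        NA_real_
      },
      report = list(rep)
    )
  }) |>
    purrr::list_rbind()
}
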