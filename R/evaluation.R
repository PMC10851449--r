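#' Sample mapped pairs for annotation
#'
#' Uniform sample without replacement of `ceiling(fraction * n)` pairs
#' (10% of the mapped group by default, mirroring an annotation workload of
#' 1804 pairs out of 18,040). Deterministic under `seed`.
#'
#' @param pt_pairs Mapped-pair tibble (PT level).
#' @param fraction Sampling fraction in (0, 1\].
#' @param seed Integer seed.
#' @return Tibble of the sampled rows with an added `item_id` column
#'   (`meddra_code|icd_code`).
#' @export
sample_mapped <- function(pt_pairs, fraction = 0.1, seed = 1L) {
  if (nrow(pt_pairs) == 0) stop("cannot sample from an empty pair set", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  n_sel <- ceiling(fraction * nrow(pt_pairs))
  withr::with_seed(seed, slice_sample(pt_pairs, n = n_sel)) |>
    mutate(item_id = paste(.data$meddra_code, .data$icd_code, sep = "|"))
}

#' Sample unmapped PT terms stratified by SOC
#'
#' Draws up to `per_soc` unmapped PTs uniformly without replacement under
#' each system organ class (primary-SOC attribution); a SOC with fewer
#' available terms contributes all of them, so with 100 per SOC and 27 SOCs
#' the total can fall short of 2700 (e.g. 2400 when some SOCs are small).
#'
#' @param unmapped_pts Character vector of unmapped PT codes.
#' @param hierarchy A [read_meddra_hierarchy()] object.
#' @param per_soc Target sample size per SOC (default 100).
#' @param seed Integer seed.
#' @return Tibble `pt_code`, `soc_name` of the selected terms.
#' @export
sample_unmapped <- function(unmapped_pts, hierarchy, per_soc = 100L, seed = 1L) {
  stopifnot(per_soc > 0)
  pool <- pt_primary_soc(hierarchy) |>
    filter(.data$pt_code %in% unmapped_pts)
  withr::with_seed(seed, {
    pool |>
      group_by(.data$soc_name) |>
      group_modify(function(df, key) slice_sample(df, n = min(per_soc, nrow(df)))) |>
      ungroup()
  }) |>
    select("pt_code", "soc_name")
}

# align two label tables on their common item set, erroring on mismatch
align_labels <- function(labels1, labels2) {
  l1 <- select(labels1, "item_id", "category")
  l2 <- select(labels2, "item_id", "category")
  only1 <- setdiff(l1$item_id, l2$item_id)
  only2 <- setdiff(l2$item_id, l1$item_id)
  if (length(only1) > 0 || length(only2) > 0) {
    stop(sprintf(
      "label key sets differ; only in first: %s; only in second: %s",
      paste(head(only1, 5), collapse = ", "), paste(head(only2, 5), collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(l1) == 0) stop("label sets are empty", call. = FALSE)
  inner_join(l1, l2, by = "item_id", suffix = c("1", "2"))
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)`, where `po` is
#' the fraction of items with equal labels and `pe` is the chance agreement
#' computed from each rater's own marginal label distribution (Cohen's
#' kappa, not Scott's pi). When `pe = 1` (both raters constant and equal)
#' kappa is undefined and flagged as degenerate.
#'
#' @param labels1,labels2 Tibbles `item_id`, `category` with identical item
#'   sets (an error lists any difference).
#' @return Object of class `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n_items`, `degenerate`.
#' @export
#' @examples
#' l1 <- tibble::tibble(item_id = as.character(1:4), category = c("A", "A", "B", "B"))
#' l2 <- tibble::tibble(item_id = as.character(1:4), category = c("A", "B", "B", "B"))
#' cohen_kappa(l1, l2)$observed_agreement
cohen_kappa <- function(labels1, labels2) {
  al <- align_labels(labels1, labels2)
  n <- nrow(al)
  cats <- sort(unique(c(al$category1, al$category2)))
  po <- mean(al$category1 == al$category2)
  m1 <- table(factor(al$category1, levels = cats)) / n
  m2 <- table(factor(al$category2, levels = cats)) / n
  pe <- sum(as.numeric(m1) * as.numeric(m2))
  degenerate <- pe >= 1 - 1e-15
  structure(
    list(
      kappa = if (degenerate) NA_real_ else (po - pe) / (1 - pe),
      observed_agreement = po,
      expected_agreement = pe,
      n_items = n,
      degenerate = degenerate
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf(
      "<kappa_result> undefined (expected agreement = 1), po = %.3f, n = %d\n",
      x$observed_agreement, x$n_items
    ))
  } else {
    cat(sprintf(
      "<kappa_result> kappa = %.3f (po = %.3f, pe = %.3f, n = %d)\n",
      x$kappa, x$observed_agreement, x$expected_agreement, x$n_items
    ))
  }
  invisible(x)
}

#' Calibration gate on observed agreement
#'
#' The annotation protocol proceeds only after the two raters reach a
#' threshold raw agreement on a shared calibration set (80% by default);
#' the boundary counts as a pass (`>=`).
#'
#' @inheritParams cohen_kappa
#' @param threshold Required observed agreement in \[0, 1\].
#' @return One-row tibble `pass`, `observed_agreement`, `threshold`,
#'   `n_items`.
#' @export
calibration_gate <- function(labels1, labels2, threshold = 0.8) {
  al <- align_labels(labels1, labels2)
  po <- mean(al$category1 == al$category2)
  tibble(
    pass = po >= threshold,
    observed_agreement = po,
    threshold = threshold,
    n_items = nrow(al)
  )
}

#' Summarize annotation labels by relation category
#'
#' Counts and percentages per relation category (half-up, two decimals),
#' including zero-count categories — the arithmetic behind the mapped-group
#' and unmapped-group summary tables.
#'
#' @param labels Either a tibble with a `category` column (one row per
#'   annotated item) or a named numeric vector of per-category counts.
#' @param allowed Permitted categories, e.g.
#'   `relation_categories("mapped")`; a label outside this set is an error
#'   naming it.
#' @return Tibble `category`, `n`, `pct`, one row per allowed category in
#'   schema order.
#' @export
#' @examples
#' summarize_annotations(
#'   c(EXACT_MATCH = 928, PT_NARROWER = 68, PT_BROADER = 760, PARTIAL_OVERLAP = 48),
#'   allowed = relation_categories("mapped")
#' )
summarize_annotations <- function(labels, allowed = relation_categories("mapped")) {
  counts <- if (is.data.frame(labels)) {
    bad <- setdiff(unique(labels$category), allowed)
    if (length(bad) > 0) {
      stop(sprintf("label(s) outside the allowed schema: %s", paste(bad, collapse = ", ")),
        call. = FALSE
      )
    }
    tab <- table(factor(labels$category, levels = allowed))
    setNames(as.numeric(tab), allowed)
  } else {
    bad <- setdiff(names(labels), allowed)
    if (length(bad) > 0) {
      stop(sprintf("label(s) outside the allowed schema: %s", paste(bad, collapse = ", ")),
        call. = FALSE
      )
    }
    full <- setNames(numeric(length(allowed)), allowed)
    full[names(labels)] <- labels
    full
  }
  total <- sum(counts)
  tibble(
    category = allowed,
    n = as.numeric(counts),
    pct = if (total > 0) round_half_up(100 * as.numeric(counts) / total, 2) else NA_real_
  )
}

#' Consolidate two annotation rounds into final labels
#'
#' After independent annotation the raters resolve every disagreement in a
#' discussion session: agreed items keep their common label and each
#' disagreement item takes the supplied resolution label, yielding 100%
#' agreement with itself.
#'
#' @inheritParams cohen_kappa
#' @param resolutions Tibble `item_id`, `category` covering every
#'   disagreement item (an error lists missing ones).
#' @return Tibble `item_id`, `category`, one row per item.
#' @export
consolidate_annotations <- function(labels1, labels2, resolutions = NULL) {
  al <- align_labels(labels1, labels2)
  disagree <- filter(al, .data$category1 != .data$category2)
  res <- if (is.null(resolutions)) {
    tibble(item_id = character(), category = character())
  } else {
    select(resolutions, "item_id", "category")
  }
  missing <- setdiff(disagree$item_id, res$item_id)
  if (length(missing) > 0) {
    stop(sprintf(
      "no resolution provided for disagreement item(s): %s",
      paste(head(missing, 10), collapse = ", ")
    ), call. = FALSE)
  }
  agreed <- al |>
    filter(.data$category1 == .data$category2) |>
    select("item_id", category = "category1")
  resolved <- res |> filter(.data$item_id %in% disagree$item_id)
  bind_rows(agreed, resolved) |> arrange(.data$item_id)
}
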