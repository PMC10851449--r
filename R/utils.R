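#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (`0.005 -> 0.01`), the
#' convention used when printing the summary tables, rather than base R's
#' round-half-even.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
#' @examples
#' round_half_up(2.665, 2) # 2.67, where round() gives 2.66
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Semantic relation categories
#'
#' The relation schema used to judge a MedDRA-PT/ICD pair: the four Venn-style
#' relations available to the mapped group (exact match, PT narrower, PT
#' broader, partial overlap), extended for the unmapped group with totally
#' irrelevant, no response (nothing returned by the search) and other reasons.
#'
#' @param schema `"mapped"` (four categories) or `"unmapped"` (all seven).
#' @return Character vector of category codes.
#' @export
#' @examples
#' relation_categories("mapped")
relation_categories <- function(schema = c("unmapped", "mapped")) {
  schema <- match.arg(schema)
  mapped <- c("EXACT_MATCH", "PT_NARROWER", "PT_BROADER", "PARTIAL_OVERLAP")
  if (schema == "mapped") {
    return(mapped)
  }
  c(mapped, "TOTALLY_IRRELEVANT", "NO_RESPONSE", "OTHER")
}

#' The 27 MedDRA system organ classes
#'
#' @return Character vector of the 27 SOC names, alphabetical.
#' @export
meddra_soc_names <- function() {
  c(
    "Blood and lymphatic system disorders",
    "Cardiac disorders",
    "Congenital, familial and genetic disorders",
    "Ear and labyrinth disorders",
    "Endocrine disorders",
    "Eye disorders",
    "Gastrointestinal disorders",
    "General disorders and administration site conditions",
    "Hepatobiliary disorders",
    "Immune system disorders",
    "Infections and infestations",
    "Injury, poisoning and procedural complications",
    "Investigations",
    "Metabolism and nutrition disorders",
    "Musculoskeletal and connective tissue disorders",
    "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
    "Nervous system disorders",
    "Pregnancy, puerperium and perinatal conditions",
    "Product issues",
    "Psychiatric disorders",
    "Renal and urinary disorders",
    "Reproductive system and breast disorders",
    "Respiratory, thoracic and mediastinal disorders",
    "Skin and subcutaneous tissue disorders",
    "Social circumstances",
    "Surgical and medical procedures",
    "Vascular disorders"
  )
}

# lower-case + collapse runs of whitespace; the string-matching convention for
# cross-referencing against the official MedDRA release
normalize_term <- function(x) {
  stringr::str_squish(tolower(x))
}

# zero-row mapped-pair tibble with the canonical column types
empty_pairs <- function() {
  tibble::tibble(
    meddra_code = character(),
    meddra_level = character(),
    meddra_string = character(),
    icd_code = character(),
    icd_version = integer(),
    icd_string = character(),
    provenance = character(),
    cui = character()
  )
}

# canonical ordering so pair sets compare independently of construction order
arrange_pairs <- function(pairs) {
  dplyr::arrange(pairs, .data$meddra_level, .data$meddra_code, .data$icd_version, .data$icd_code)
}
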