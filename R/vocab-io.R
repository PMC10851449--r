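# UMLS RRF dialect: UTF-8, pipe-delimited, trailing pipe, no header.
# MRCONSO has 18 columns (CUI, LAT, TS, LUI, STT, SUI, ISPREF, AUI, SAUI,
# SCUI, SDUI, SAB, TTY, CODE, STR, SRL, SUPPRESS, CVF); MRREL has 16
# (CUI1, AUI1, STYPE1, REL, CUI2, AUI2, STYPE2, RELA, RUI, SRUI, SAB, SL,
# RG, DIR, SUPPRESS, CVF).

parse_rrf <- function(path, n_fields) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readr::read_lines(path)
  if (length(lines) == 0) {
    return(matrix(character(), nrow = 0, ncol = n_fields))
  }
  parts <- strsplit(lines, "|", fixed = TRUE)
  len <- lengths(parts)
  bad <- which(len != n_fields)
  if (length(bad) > 0) {
    stop(sprintf(
      "line %d of %s has %d fields, expected %d",
      bad[1], basename(path), len[bad[1]], n_fields
    ), call. = FALSE)
  }
  matrix(unlist(parts), nrow = length(parts), ncol = n_fields, byrow = TRUE)
}

#' Read atoms from an MRCONSO.RRF file
#'
#' Parses the pipe-delimited UMLS concept-names file into one row per atom
#' (a single occurrence of a term string from one source vocabulary).
#' Column positions follow the standard MRCONSO layout: CUI 1st, LAT 2nd,
#' SAB 12th, TTY 13th, CODE 14th, STR 15th, SUPPRESS 17th.
#'
#' @param path Path to an `MRCONSO.RRF`-dialect file (18 fields, trailing
#'   pipe, no header).
#' @param sab Optional character vector of source abbreviations to keep
#'   (e.g. `c("MDR", "ICD9CM")`); `NULL` keeps all.
#' @param english_only Keep only `LAT == "ENG"` rows (default `TRUE`; all
#'   terminologies mapped here are English).
#' @param include_suppressed Keep suppressible atoms (`SUPPRESS` in O/E/Y);
#'   default `TRUE`.
#' @return Tibble with columns `cui`, `lat`, `sab`, `tty`, `code`, `str`,
#'   `suppress`, in file order.
#' @export
read_mrconso <- function(path, sab = NULL, english_only = TRUE, include_suppressed = TRUE) {
  m <- parse_rrf(path, 18L)
  atoms <- tibble(
    cui = m[, 1], lat = m[, 2], sab = m[, 12], tty = m[, 13],
    code = m[, 14], str = m[, 15], suppress = m[, 17]
  )
  if (english_only) atoms <- filter(atoms, .data$lat == "ENG")
  if (!include_suppressed) atoms <- filter(atoms, !.data$suppress %in% c("O", "E", "Y"))
  if (!is.null(sab)) atoms <- filter(atoms, .data$sab %in% .env$sab)
  atoms
}

#' Read relationships from an MRREL.RRF file
#'
#' @param path Path to an `MRREL.RRF`-dialect file (16 fields, trailing pipe).
#' @return Tibble with columns `cui1`, `rel`, `cui2`, `rela`, in file order.
#' @export
read_mrrel <- function(path) {
  m <- parse_rrf(path, 16L)
  tibble(cui1 = m[, 1], rel = m[, 4], cui2 = m[, 5], rela = m[, 8])
}

#' Read OMOP vocabulary tables
#'
#' Reads the CONCEPT and CONCEPT_RELATIONSHIP tables (tab- or comma-delimited
#' with a header row; the delimiter is auto-detected from the header).
#'
#' @param concept_path,relationship_path Paths to the two tables.
#' @param validate If `TRUE`, error when a relationship references a
#'   `concept_id` absent from the CONCEPT table.
#' @return List with tibbles `concepts` (`concept_id`, `concept_name`,
#'   `vocabulary_id`, `concept_class_id`, `concept_code`) and
#'   `relationships` (`concept_id_1`, `concept_id_2`, `relationship_id`).
#' @export
read_omop_tables <- function(concept_path, relationship_path, validate = FALSE) {
  read_one <- function(path, required) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    header <- readr::read_lines(path, n_max = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
    tab <- readr::read_delim(path,
      delim = delim, show_col_types = FALSE,
      progress = FALSE, trim_ws = FALSE
    )
    missing <- setdiff(required, names(tab))
    if (length(missing) > 0) {
      stop(sprintf(
        "%s is missing required column(s): %s",
        basename(path), paste(missing, collapse = ", ")
      ), call. = FALSE)
    }
    tab
  }
  concepts <- read_one(concept_path, c(
    "concept_id", "concept_name", "vocabulary_id", "concept_class_id", "concept_code"
  )) |>
    mutate(concept_id = as.integer(.data$concept_id)) |>
    select("concept_id", "concept_name", "vocabulary_id", "concept_class_id", "concept_code")
  relationships <- read_one(relationship_path, c(
    "concept_id_1", "concept_id_2", "relationship_id"
  )) |>
    mutate(
      concept_id_1 = as.integer(.data$concept_id_1),
      concept_id_2 = as.integer(.data$concept_id_2)
    ) |>
    select("concept_id_1", "concept_id_2", "relationship_id")
  if (validate) {
    ids <- unique(c(relationships$concept_id_1, relationships$concept_id_2))
    orphan <- setdiff(ids, concepts$concept_id)
    if (length(orphan) > 0) {
      stop(sprintf(
        "CONCEPT_RELATIONSHIP references concept_id(s) absent from CONCEPT: %s",
        paste(head(orphan, 10), collapse = ", ")
      ), call. = FALSE)
    }
  }
  list(concepts = concepts, relationships = relationships)
}

#' Read a MedDRA hierarchy from distribution-style ASCII files
#'
#' Two `"$"`-delimited files define the hierarchy: `llt_path` follows the
#' 11-field `llt.asc` layout (LLT code 1st, LLT name 2nd, parent PT code 3rd,
#' currency flag 10th); `pt_path` is a simplified mdhier-style table with one
#' row per PT-SOC assignment: `pt_code$pt_name$soc_name$primary_flag$`
#' (primary flag `"Y"`/`"N"`). Enforced invariants: every LLT has exactly one
#' PT parent, every PT has at least one SOC and exactly one primary SOC, and
#' every PT has an identical self LLT (an LLT whose name equals the PT name).
#'
#' @param llt_path,pt_path Paths to the two files.
#' @return Object of class `meddra_hierarchy`: list of tibbles `llt`
#'   (`llt_code`, `llt_name`, `pt_code`, `currency`), `pt` (`pt_code`,
#'   `pt_name`) and `soc` (`pt_code`, `soc_name`, `primary`).
#' @export
read_meddra_hierarchy <- function(llt_path, pt_path) {
  read_dollar <- function(path, min_fields) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    lines <- readr::read_lines(path)
    parts <- strsplit(lines, "$", fixed = TRUE)
    bad <- which(lengths(parts) < min_fields)
    if (length(bad) > 0) {
      stop(sprintf(
        "line %d of %s has %d fields, expected >= %d",
        bad[1], basename(path), lengths(parts)[bad[1]], min_fields
      ), call. = FALSE)
    }
    parts
  }
  lp <- read_dollar(llt_path, 3L)
  llt <- tibble(
    llt_code = vapply(lp, `[`, "", 1),
    llt_name = vapply(lp, `[`, "", 2),
    pt_code = vapply(lp, `[`, "", 3),
    currency = vapply(lp, function(x) if (length(x) >= 10) x[10] else "", "")
  )
  pp <- read_dollar(pt_path, 4L)
  soc <- tibble(
    pt_code = vapply(pp, `[`, "", 1),
    pt_name = vapply(pp, `[`, "", 2),
    soc_name = vapply(pp, `[`, "", 3),
    primary = vapply(pp, `[`, "", 4) == "Y"
  )
  pt <- distinct(soc, .data$pt_code, .data$pt_name)

  multi_parent <- llt |>
    distinct(.data$llt_code, .data$pt_code) |>
    count(.data$llt_code) |>
    filter(.data$n > 1)
  if (nrow(multi_parent) > 0) {
    stop(sprintf(
      "LLT(s) with multiple PT parents: %s",
      paste(head(multi_parent$llt_code, 10), collapse = ", ")
    ), call. = FALSE)
  }
  orphan <- setdiff(llt$pt_code, pt$pt_code)
  if (length(orphan) > 0) {
    stop(sprintf(
      "PT(s) lacking a SOC assignment: %s",
      paste(head(orphan, 10), collapse = ", ")
    ), call. = FALSE)
  }
  primary_counts <- soc |>
    group_by(.data$pt_code) |>
    summarise(n_primary = sum(.data$primary), .groups = "drop") |>
    filter(.data$n_primary != 1L)
  if (nrow(primary_counts) > 0) {
    stop(sprintf(
      "PT(s) without exactly one primary SOC: %s",
      paste(head(primary_counts$pt_code, 10), collapse = ", ")
    ), call. = FALSE)
  }
  self_llt <- llt |>
    inner_join(pt, by = "pt_code") |>
    filter(normalize_term(.data$llt_name) == normalize_term(.data$pt_name)) |>
    distinct(.data$pt_code)
  no_self <- setdiff(pt$pt_code, self_llt$pt_code)
  if (length(no_self) > 0) {
    stop(sprintf(
      "PT(s) missing their identical self LLT: %s",
      paste(head(no_self, 10), collapse = ", ")
    ), call. = FALSE)
  }

  structure(
    list(llt = llt, pt = pt, soc = select(soc, "pt_code", "soc_name", "primary")),
    class = "meddra_hierarchy"
  )
}

#' @export
print.meddra_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<meddra_hierarchy> %d PTs, %d LLTs, %d SOCs\n",
    nrow(x$pt), nrow(x$llt), length(unique(x$soc$soc_name))
  ))
  invisible(x)
}

#' Primary SOC of every PT
#'
#' @param hierarchy A [read_meddra_hierarchy()] object.
#' @return Tibble `pt_code`, `soc_name` (one row per PT).
#' @export
pt_primary_soc <- function(hierarchy) {
  hierarchy$soc |>
    filter(.data$primary) |>
    select("pt_code", "soc_name")
}

#' Read or write annotation label files
#'
#' Annotation files are plain CSV with columns `item_id`, `rater_id`,
#' `category`.
#'
#' @param path File path.
#' @return `read_annotations()`: tibble with those three columns.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("item_id", "rater_id", "category"), names(tab))
  if (length(missing) > 0) {
    stop(sprintf("annotation file missing column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  mutate(tab, item_id = as.character(.data$item_id)) |>
    select("item_id", "rater_id", "category")
}

#' @rdname read_annotations
#' @param annotations Tibble with `item_id`, `rater_id`, `category`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Labels of a single rater
#'
#' @param annotations Long annotation tibble (`item_id`, `rater_id`,
#'   `category`).
#' @param rater Rater identifier, e.g. `"R1"`.
#' @return Tibble `item_id`, `category`.
#' @export
rater_labels <- function(annotations, rater) {
  annotations |>
    filter(.data$rater_id == rater) |>
    select("item_id", "category")
}

#' Write vocabulary files in the dialects the readers expect
#'
#' `write_mrconso()` / `write_mrrel()` emit pipe-delimited RRF with trailing
#' pipe and no header; unmodelled columns are filled with plausible
#' placeholders. `write_omop_tables()` emits tab-delimited tables with header.
#' `write_meddra_hierarchy()` emits the `"$"`-delimited llt/pt files.
#'
#' @param atoms Tibble as returned by [read_mrconso()].
#' @param path,llt_path,pt_path,concept_path,relationship_path Output paths.
#' @return The path(s), invisibly.
#' @export
write_mrconso <- function(atoms, path) {
  n <- nrow(atoms)
  lines <- if (n == 0) {
    character()
  } else {
    i <- seq_len(n)
    paste(
      atoms$cui, atoms$lat, "P", sprintf("L%07d", i), "PF", sprintf("S%07d", i),
      "Y", sprintf("A%07d", i), "", "", "", atoms$sab, atoms$tty, atoms$code,
      atoms$str, "0", atoms$suppress, "",
      sep = "|"
    )
  }
  readr::write_lines(paste0(lines, "|"), path)
  invisible(path)
}

#' @rdname write_mrconso
#' @param rels Tibble as returned by [read_mrrel()].
#' @export
write_mrrel <- function(rels, path) {
  n <- nrow(rels)
  lines <- if (n == 0) {
    character()
  } else {
    i <- seq_len(n)
    paste(
      rels$cui1, sprintf("A%07d", i), "CUI", rels$rel, rels$cui2,
      sprintf("A%07d", i + n), "CUI", rels$rela, sprintf("R%07d", i), "",
      "MDR", "MDR", "", "N", "N", "",
      sep = "|"
    )
  }
  readr::write_lines(paste0(lines, "|"), path)
  invisible(path)
}

#' @rdname write_mrconso
#' @param concepts,relationships OMOP concept / relationship tibbles.
#' @export
write_omop_tables <- function(concepts, relationships, concept_path, relationship_path) {
  readr::write_tsv(concepts, concept_path, progress = FALSE)
  readr::write_tsv(relationships, relationship_path, progress = FALSE)
  invisible(c(concept_path, relationship_path))
}

#' @rdname write_mrconso
#' @param llt_rows Tibble `llt_code`, `llt_name`, `pt_code`, `currency`.
#' @param pt_rows Tibble `pt_code`, `pt_name`, `soc_name`, `primary`
#'   (`"Y"`/`"N"` or logical).
#' @export
write_meddra_hierarchy <- function(llt_rows, pt_rows, llt_path, pt_path) {
  llt_lines <- sprintf(
    "%s$%s$%s$$$$$$$%s$", llt_rows$llt_code, llt_rows$llt_name,
    llt_rows$pt_code, llt_rows$currency
  )
  primary <- pt_rows$primary
  if (is.logical(primary)) primary <- ifelse(primary, "Y", "N")
  pt_lines <- sprintf(
    "%s$%s$%s$%s$", pt_rows$pt_code, pt_rows$pt_name, pt_rows$soc_name, primary
  )
  readr::write_lines(llt_lines, llt_path)
  readr::write_lines(pt_lines, pt_path)
  invisible(c(llt_path, pt_path))
}
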