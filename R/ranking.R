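#' Build a CUI-grouped ICD synonym dictionary
#'
#' Groups ICD atoms by concept: each entry is a CUI with the set of ICD
#' codes it carries and every synonym string recorded for it. One synonym
#' string (per CUI/code) later becomes one indexed document. By default only
#' ICD-9-CM atoms are included, mirroring a dictionary built from the
#' `ICD9CM` source; add `"ICD10CM"` to cover both code systems.
#'
#' @param atoms Atom tibble from [read_mrconso()].
#' @param sources Source abbreviations to include, a subset of
#'   `c("ICD9CM", "ICD10CM")`.
#' @return Object of class `synonym_dictionary`: list with `entries` (tibble
#'   `cui`, `icd_code`, `icd_version`, `synonym`, one row per synonym
#'   document), `n_cuis` and `n_docs`.
#' @export
build_dictionary <- function(atoms, sources = "ICD9CM") {
  stopifnot(all(sources %in% c("ICD9CM", "ICD10CM")))
  entries <- atoms |>
    filter(.data$sab %in% .env$sources) |>
    mutate(icd_version = ifelse(.data$sab == "ICD9CM", 9L, 10L)) |>
    distinct(.data$cui, icd_code = .data$code, .data$icd_version, synonym = .data$str)
  structure(
    list(
      entries = entries,
      n_cuis = n_distinct(entries$cui),
      n_docs = nrow(entries)
    ),
    class = "synonym_dictionary"
  )
}

#' @export
print.synonym_dictionary <- function(x, ...) {
  cat(sprintf("<synonym_dictionary> %d concepts, %d synonym documents\n", x$n_cuis, x$n_docs))
  invisible(x)
}

#' Tokenize clinical term strings
#'
#' Lower-cases, splits on any run of non-alphanumeric characters and drops
#' empty tokens. No stemming and no stopword removal, so `"Buerger's
#' disease"` yields `buerger`, `s`, `disease`.
#'
#' @param text Character vector.
#' @return List of character token vectors, one per input string.
#' @export
#' @examples
#' tokenize("Pilonidal cyst")[[1]]
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(x) x[nzchar(x)])
}

#' BM25 scoring parameters
#'
#' `k1` controls term-frequency saturation and `b` the strength of document
#' length normalization; the defaults (1.2, 0.75) are the classical
#' Robertson settings, also used by Lucene. `top_k` is the number of
#' candidate codes retrieved per query (25 by default).
#'
#' @param k1 Positive real.
#' @param b Real in \[0, 1\].
#' @param top_k Positive count.
#' @return List of class `bm25_params`.
#' @export
bm25_params <- function(k1 = 1.2, b = 0.75, top_k = 25L) {
  stopifnot(is.numeric(k1), length(k1) == 1, k1 > 0)
  stopifnot(is.numeric(b), length(b) == 1, b >= 0, b <= 1)
  stopifnot(is.numeric(top_k), length(top_k) == 1, top_k >= 1)
  structure(list(k1 = k1, b = b, top_k = as.integer(top_k)), class = "bm25_params")
}

#' Build an inverted index over a synonym dictionary
#'
#' One document per dictionary entry (a synonym string of one ICD code under
#' one CUI). Stores the postings (token, document, term frequency), document
#' lengths, their mean, and per-token document frequencies.
#'
#' @param dictionary A [build_dictionary()] object.
#' @return Object of class `bm25_index`: list with `postings` (tibble
#'   `token`, `doc_id`, `tf`), `doc_lengths` (integer vector indexed by
#'   doc id), `avg_doc_length`, `df` (tibble `token`, `df`), `n_docs` and
#'   `doc_meta` (tibble `doc_id`, `cui`, `icd_code`, `icd_version`,
#'   `synonym`).
#' @export
build_index <- function(dictionary) {
  entries <- dictionary$entries
  if (is.null(entries) || nrow(entries) == 0) {
    stop("cannot index an empty dictionary", call. = FALSE)
  }
  toks <- tokenize(entries$synonym)
  doc_lengths <- lengths(toks)
  postings <- tibble(
    doc_id = rep(seq_along(toks), doc_lengths),
    token = unlist(toks)
  ) |>
    count(.data$doc_id, .data$token, name = "tf")
  structure(
    list(
      postings = postings,
      doc_lengths = doc_lengths,
      avg_doc_length = mean(doc_lengths),
      df = count(postings, .data$token, name = "df"),
      n_docs = nrow(entries),
      doc_meta = mutate(entries, doc_id = dplyr::row_number()) |>
        select("doc_id", "cui", "icd_code", "icd_version", "synonym")
    ),
    class = "bm25_index"
  )
}

#' @export
print.bm25_index <- function(x, ...) {
  cat(sprintf(
    "<bm25_index> %d documents, %d distinct tokens, mean length %.2f\n",
    x$n_docs, nrow(x$df), x$avg_doc_length
  ))
  invisible(x)
}

# score all documents sharing >= 1 token with the (distinct) query tokens;
# idf is the non-negative Lucene form ln(1 + (N - df + 0.5)/(df + 0.5)) and
# query-side term frequency is ignored (binary query model)
score_documents <- function(index, query_tokens, params) {
  qt <- unique(query_tokens)
  if (length(qt) == 0) {
    return(tibble(doc_id = integer(), score = double()))
  }
  n <- index$n_docs
  idf <- index$df |>
    filter(.data$token %in% qt) |>
    mutate(idf = log(1 + (n - .data$df + 0.5) / (.data$df + 0.5)))
  if (nrow(idf) == 0) {
    return(tibble(doc_id = integer(), score = double()))
  }
  index$postings |>
    inner_join(select(idf, "token", "idf"), by = "token") |>
    mutate(
      len = index$doc_lengths[.data$doc_id],
      contrib = .data$idf * .data$tf * (params$k1 + 1) /
        (.data$tf + params$k1 * (1 - params$b + params$b * .data$len / index$avg_doc_length))
    ) |>
    group_by(.data$doc_id) |>
    summarise(score = sum(.data$contrib), .groups = "drop")
}

#' BM25 score of one document for a query
#'
#' Computes `sum over query tokens t of idf(t) * tf * (k1 + 1) /
#' (tf + k1 * (1 - b + b * len/avglen))` with
#' `idf(t) = ln(1 + (N - df + 0.5) / (df + 0.5))`. Tokens absent from the
#' document contribute 0 and repeated query tokens are counted once.
#'
#' @param index A [build_index()] object.
#' @param query_tokens Character vector of query tokens.
#' @param doc_id Document id (row in `index$doc_meta`).
#' @param params A [bm25_params()].
#' @return Non-negative scalar score.
#' @export
bm25_score <- function(index, query_tokens, doc_id, params = bm25_params()) {
  if (length(doc_id) != 1 || !doc_id %in% seq_len(index$n_docs)) {
    stop(sprintf("unknown document id: %s", paste(doc_id, collapse = ",")), call. = FALSE)
  }
  scores <- score_documents(index, query_tokens, params)
  hit <- scores$score[scores$doc_id == doc_id]
  if (length(hit) == 0) 0 else hit
}

#' Rank candidate ICD codes for a query term
#'
#' Scores every indexed synonym document sharing at least one token with the
#' query, aggregates document scores to the code level by the maximum over
#' that code's synonym documents (so synonym count does not inflate scores),
#' sorts by score descending with ties broken by ascending ICD code, and
#' truncates to the top `params$top_k` candidates.
#'
#' @param index A [build_index()] object.
#' @param query A PT term string.
#' @param params A [bm25_params()].
#' @return Tibble `query`, `rank` (1-based, consecutive), `icd_code`,
#'   `icd_version`, `cui`, `score`; zero rows when no document shares a
#'   token with the query.
#' @export
rank_candidates <- function(index, query, params = bm25_params()) {
  qt <- tokenize(query)[[1]]
  scores <- score_documents(index, qt, params)
  if (nrow(scores) == 0) {
    return(tibble(
      query = character(), rank = integer(), icd_code = character(),
      icd_version = integer(), cui = character(), score = double()
    ))
  }
  scores |>
    inner_join(index$doc_meta, by = "doc_id") |>
    group_by(.data$icd_code, .data$icd_version) |>
    arrange(desc(.data$score), .data$doc_id, .by_group = TRUE) |>
    summarise(score = first(.data$score), cui = first(.data$cui), .groups = "drop") |>
    arrange(desc(.data$score), .data$icd_code) |>
    slice_head(n = params$top_k) |>
    mutate(query = query, rank = dplyr::row_number()) |>
    select("query", "rank", "icd_code", "icd_version", "cui", "score")
}

#' @rdname rank_candidates
#' @param queries Character vector of query terms.
#' @export
rank_candidates_all <- function(index, queries, params = bm25_params()) {
  purrr::map(queries, function(q) rank_candidates(index, q, params)) |>
    purrr::list_rbind()
}

#' Retrieval quality of a set of rankings
#'
#' Standard retrieval metrics against known best codes: recall at ranks 1, 5
#' and 25, and the mean reciprocal rank (queries whose true code is not
#' retrieved contribute 0).
#'
#' @param rankings Tibble from [rank_candidates_all()].
#' @param truth Tibble `query`, `icd_code` giving the planted best code per
#'   query; every truth query must appear in `rankings$query` (queries with
#'   empty candidate lists are allowed and score 0).
#' @return One-row tibble: `n_queries`, `recall_at_1`, `recall_at_5`,
#'   `recall_at_25`, `mrr`.
#' @export
rank_quality <- function(rankings, truth) {
  # queries that retrieved nothing simply score 0
  hits <- truth |>
    left_join(rankings, by = c("query", "icd_code")) |>
    group_by(.data$query) |>
    summarise(best_rank = suppressWarnings(min(.data$rank, na.rm = TRUE)), .groups = "drop") |>
    mutate(best_rank = ifelse(is.finite(.data$best_rank), .data$best_rank, NA_integer_))
  tibble(
    n_queries = nrow(hits),
    recall_at_1 = mean(!is.na(hits$best_rank) & hits$best_rank <= 1),
    recall_at_5 = mean(!is.na(hits$best_rank) & hits$best_rank <= 5),
    recall_at_25 = mean(!is.na(hits$best_rank) & hits$best_rank <= 25),
    mrr = mean(ifelse(is.na(hits$best_rank), 0, 1 / hits$best_rank))
  )
}
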