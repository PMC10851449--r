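# Independent oracles, written as plain loops over base data frames so they
# share no code path with the package implementation.

# brute-force CUI join: every (MDR PT/LLT atom) x (ICD atom) pair sharing a CUI
oracle_umls_pairs <- function(atoms) {
  df <- as.data.frame(atoms)
  mdr <- df[df$sab == "MDR" & df$tty %in% c("PT", "LLT"), ]
  icd <- df[df$sab %in% c("ICD9CM", "ICD10CM"), ]
  rows <- list()
  for (i in seq_len(nrow(mdr))) {
    for (j in seq_len(nrow(icd))) {
      if (mdr$cui[i] == icd$cui[j]) {
        rows[[length(rows) + 1L]] <- data.frame(
          meddra_code = mdr$code[i], meddra_level = mdr$tty[i],
          icd_code = icd$code[j],
          icd_version = if (icd$sab[j] == "ICD9CM") 9L else 10L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      meddra_code = character(), meddra_level = character(),
      icd_code = character(), icd_version = integer()
    ))
  }
  unique(do.call(rbind, rows))
}

# direct formula evaluation of the BM25 sum for one document
oracle_bm25 <- function(doc_tokens, query_tokens, doc, k1 = 1.2, b = 0.75) {
  n_docs <- length(doc_tokens)
  avg <- mean(vapply(doc_tokens, length, 0L))
  score <- 0
  for (t in unique(query_tokens)) {
    df <- sum(vapply(doc_tokens, function(d) t %in% d, TRUE))
    if (df == 0) next
    tf <- sum(doc_tokens[[doc]] == t)
    if (tf == 0) next
    idf <- log(1 + (n_docs - df + 0.5) / (df + 0.5))
    len <- length(doc_tokens[[doc]])
    score <- score + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len / avg))
  }
  score
}

# kappa from an explicitly accumulated confusion matrix
oracle_kappa <- function(v1, v2) {
  cats <- sort(union(v1, v2))
  n <- length(v1)
  cm <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_len(n)) cm[v1[i], v2[i]] <- cm[v1[i], v2[i]] + 1
  po <- sum(diag(cm)) / n
  pe <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  (po - pe) / (1 - pe)
}

# canonical set representation of a pair table for exact set comparison
pair_key <- function(df) {
  sort(paste(df$meddra_code, df$meddra_level, df$icd_code, df$icd_version, sep = "~"))
}

# convenience: generate a fixture in a fresh temp dir and parse everything
gen_parsed_fixture <- function(config) {
  dir <- tempfile("fixture")
  gt <- generate_fixture(config, dir)
  atoms <- read_mrconso(gt$files[["mrconso"]])
  omop <- read_omop_tables(gt$files[["concept"]], gt$files[["concept_relationship"]])
  hierarchy <- read_meddra_hierarchy(gt$files[["llt"]], gt$files[["pt"]])
  list(gt = gt, atoms = atoms, omop = omop, hierarchy = hierarchy, dir = dir)
}

# small atom-table constructor for hand-built cases
make_atoms <- function(cui, sab, code, str, tty = "PT", lat = "ENG", suppress = "N") {
  tibble::tibble(
    cui = cui, lat = lat, sab = sab, tty = tty,
    code = code, str = str, suppress = suppress
  )
}
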