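#' Preprocess a transcript into tokens
#'
#' Lowercases, replaces every non-letter character by a space, splits on
#' whitespace and drops empty tokens. No stop-word removal, stemming or
#' frequency floor is applied: plain function words can carry signal in
#' interview language and are kept.
#'
#' @param text Character scalar (or vector, concatenated in order).
#' @return Character vector of lowercase alphabetic tokens.
#' @export
preprocess_transcript <- function(text) {
  txt <- tolower(paste(text, collapse = " "))
  txt <- gsub("[^a-z]+", " ", txt)
  tokens <- strsplit(trimws(txt), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

#' Fit a TF-IDF model and transform a corpus
#'
#' Unigram TF-IDF with the smoothed inverse document frequency
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1` and L2 (Euclidean) row
#' normalization, so each session vector has unit length regardless of
#' response length. The vocabulary is the sorted set of training terms.
#'
#' @param token_lists Named list (by session id) of token vectors from
#'   [preprocess_transcript()]. Sessions with no tokens are dropped with a
#'   warning.
#' @return List with `matrix` (a text [feature_matrix()]) and `model`
#'   (class `tfidf_model`: `vocabulary`, `idf`, `document_frequency`,
#'   `n_documents`) for transforming held-out sessions.
#' @export
fit_tfidf <- function(token_lists) {
  if (length(token_lists) < 2) stop("need at least 2 documents to fit TF-IDF")
  empty <- vapply(token_lists, length, 1L) == 0
  if (all(empty)) stop("all-empty corpus")
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty session(s) from text modality")
    token_lists <- token_lists[!empty]
  }
  vocab <- sort(unique(unlist(token_lists, use.names = FALSE)))
  df_count <- stats::setNames(integer(length(vocab)), vocab)
  for (tok in token_lists) {
    u <- unique(tok)
    df_count[u] <- df_count[u] + 1L
  }
  n_doc <- length(token_lists)
  idf <- log((1 + n_doc) / (1 + df_count)) + 1
  model <- structure(list(vocabulary = vocab, idf = idf,
                          document_frequency = df_count,
                          n_documents = n_doc),
                     class = "tfidf_model")
  list(matrix = transform_tfidf(model, token_lists), model = model)
}

#' Transform sessions with a fitted TF-IDF model
#'
#' Uses only the training-fit vocabulary and idf; out-of-vocabulary tokens
#' contribute nothing (the no-leakage contract for held-out folds).
#'
#' @param model A `tfidf_model` from [fit_tfidf()].
#' @param token_lists Named list of token vectors.
#' @return A text [feature_matrix()] with L2-normalized rows (all-OOV rows
#'   stay zero).
#' @export
transform_tfidf <- function(model, token_lists) {
  vocab <- model$vocabulary
  out <- matrix(0, length(token_lists), length(vocab),
                dimnames = list(names(token_lists), vocab))
  for (i in seq_along(token_lists)) {
    tf <- table(token_lists[[i]])
    keep <- intersect(names(tf), vocab)
    if (length(keep) == 0) next
    row <- as.numeric(tf[keep]) * model$idf[keep]
    nrm <- sqrt(sum(row^2))
    if (nrm > 0) out[i, keep] <- row / nrm
  }
  feature_matrix(out, names(token_lists), vocab, "text")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("tfidf_model:", length(x$vocabulary), "terms over", x$n_documents,
      "documents\n")
  invisible(x)
}

#' Top positively and negatively weighted terms of a linear text model
#'
#' Splits linear-model weights into the `k` largest positive (case-leaning)
#' and `k` most negative (control-leaning) terms, each ordered by decreasing
#' absolute weight with lexicographic tie-breaking. Zero weights belong to
#' neither side.
#'
#' @param weights Named numeric vector of term weights.
#' @param k Number of terms per side (default 10).
#' @return List with `case_terms` and `control_terms` character vectors
#'   (shorter than `k` if a side has fewer nonzero terms).
#' @export
top_weighted_terms <- function(weights, k = 10L) {
  stopifnot(!is.null(names(weights)))
  pick <- function(w) {
    w <- w[order(-abs(w), names(w))]
    utils::head(names(w), k)
  }
  case_terms <- pick(weights[weights > 0])
  control_terms <- pick(weights[weights < 0])
  if (length(case_terms) < k || length(control_terms) < k) {
    message("top_weighted_terms: ", length(case_terms), " case and ",
            length(control_terms), " control term(s) available")
  }
  list(case_terms = case_terms, control_terms = control_terms)
}

#' Tokenized transcripts per session
#'
#' Reads each session's per-task transcript files, concatenates them in
#' canonical task order, and preprocesses into tokens. The session document
#' therefore covers the whole interview, including the read sentence and
#' warm-up response.
#'
#' @param cohort An `mhs_cohort` from [read_cohort()].
#' @param tasks Tasks to include.
#' @return Named list (session id) of token vectors.
#' @export
tokenize_cohort <- function(cohort, tasks = canonical_tasks()) {
  sessions <- cohort$sessions
  out <- vector("list", nrow(sessions))
  names(out) <- sessions$session_id
  for (i in seq_len(nrow(sessions))) {
    texts <- character(0)
    for (task in tasks) {
      p <- sessions[[paste0(task, "_transcript")]][i]
      if (!is.na(p) && nzchar(p) && file.exists(p)) {
        texts <- c(texts, readLines(p, warn = FALSE, encoding = "UTF-8"))
      }
    }
    out[[i]] <- preprocess_transcript(texts)
  }
  out
}

#' Text feature matrix for a cohort
#'
#' Convenience wrapper: tokenize, fit TF-IDF on the whole cohort and return
#' the session-by-term matrix. For cross-validated modeling use
#' [tokenize_cohort()] with fold-nested [fit_tfidf()] instead (the
#' evaluation machinery does this internally).
#'
#' @inheritParams tokenize_cohort
#' @return A text [feature_matrix()].
#' @export
featurize_text <- function(cohort, tasks = canonical_tasks()) {
  fit_tfidf(tokenize_cohort(cohort, tasks))$matrix
}
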