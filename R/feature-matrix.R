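#' Construct a feature matrix
#'
#' Sessions-by-features container shared by all three modalities. Feature
#' names follow the convention `<task>.<measure>` (text features use the
#' bare term). Missing entries (skipped tasks, failed extraction) are NA in
#' `values` and TRUE in `missing_mask`; text matrices never have missing
#' entries.
#'
#' @param values Numeric matrix, sessions x features.
#' @param session_ids Character vector of row identities.
#' @param feature_names Character vector of column identities (unique).
#' @param modality One of `"speech"`, `"facial"`, `"text"`.
#' @param missing_mask Optional logical matrix; defaults to `is.na(values)`.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, session_ids, feature_names, modality,
                           missing_mask = NULL) {
  values <- as.matrix(values)
  modality <- match.arg(modality, c("speech", "facial", "text"))
  if (nrow(values) != length(session_ids)) stop("row/session mismatch")
  if (ncol(values) != length(feature_names)) stop("column/name mismatch")
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values))) stop("mask dim mismatch")
  if (modality == "text" && any(missing_mask)) {
    stop("text feature matrices cannot have missing entries")
  }
  dimnames(values) <- list(session_ids, feature_names)
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values, missing_mask = missing_mask,
                 session_ids = as.character(session_ids),
                 feature_names = as.character(feature_names),
                 modality = modality),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d sessions x %d features, %.1f%% missing\n",
              x$modality, length(x$session_ids), length(x$feature_names),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write a feature matrix as wide CSV
#'
#' One row per session; for each feature a value column and a paired
#' `<feature>__missing` 0/1 mask column. The modality is recorded in a
#' `.modality` column.
#'
#' @param fm A [feature_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(session_id = fm$session_ids, .modality = fm$modality,
                   check.names = FALSE)
  for (j in seq_along(fm$feature_names)) {
    nm <- fm$feature_names[j]
    df[[nm]] <- fm$values[, j]
    df[[paste0(nm, "__missing")]] <- as.integer(fm$missing_mask[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("session_id", ".modality") %in% names(df)))
  mask_cols <- grep("__missing$", names(df), value = TRUE)
  feat_cols <- sub("__missing$", "", mask_cols)
  values <- as.matrix(df[, feat_cols, drop = FALSE])
  mask <- as.matrix(df[, mask_cols, drop = FALSE]) > 0
  feature_matrix(values, df$session_id, feat_cols,
                 modality = df$.modality[1], missing_mask = mask)
}

# subset rows of a feature matrix by session ids (order preserved)
fm_subset <- function(fm, session_ids) {
  idx <- match(session_ids, fm$session_ids)
  if (anyNA(idx)) stop("alignment error: unknown session id(s)")
  feature_matrix(fm$values[idx, , drop = FALSE], session_ids,
                 fm$feature_names, fm$modality,
                 fm$missing_mask[idx, , drop = FALSE])
}
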