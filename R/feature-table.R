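# The tile-by-feature table: interchange object between extraction,
# screening and classification. A plain data.frame with an `id` column,
# named numeric feature columns, and a `label` factor over classes I-VI.
# NA is the missing-value sentinel (e.g. a colour index with a zero
# denominator) and is imputed by training-set medians at model-fit time.

#' Construct a feature table
#'
#' @param features data.frame of numeric feature columns (unique names).
#' @param label Vector of class labels in I..VI (NA allowed).
#' @param id Row identifiers; defaults to row numbers.
#' @return A data.frame of class `ap_features` with columns
#'   `id`, features..., `label`.
#' @export
feature_table <- function(features, label, id = NULL) {
  features <- as.data.frame(features)
  ap_assert(!anyDuplicated(names(features)), "feature names must be unique")
  ap_assert(!any(c("id", "label") %in% names(features)),
            "'id' and 'label' are reserved column names")
  ap_assert(all(vapply(features, is.numeric, TRUE)), "features must be numeric")
  ap_assert(length(label) == nrow(features), "label length must match rows")
  ok <- is.na(label) | label %in% AP_CLASSES
  ap_assert(all(ok), "labels must come from the closed class set I..VI")
  if (is.null(id)) id <- sprintf("row%04d", seq_len(nrow(features)))
  out <- cbind(data.frame(id = as.character(id), stringsAsFactors = FALSE),
               features,
               data.frame(label = factor(label, levels = AP_CLASSES)))
  class(out) <- c("ap_features", "data.frame")
  out
}

#' Names of the feature columns of a feature table
#' @param table An `ap_features` table.
#' @return Character vector (everything except `id` and `label`).
#' @export
feature_names <- function(table) setdiff(names(table), c("id", "label"))

# numeric matrix of the feature columns
feature_matrix <- function(table, features = feature_names(table)) {
  missing <- setdiff(features, names(table))
  if (length(missing))
    ap_stop("unknown feature name(s): ", paste(missing, collapse = ", "),
            "; table has: ", paste(feature_names(table), collapse = ", "),
            class = "ap_config_error")
  as.matrix(table[, features, drop = FALSE])
}

#' Write / read a feature table as CSV
#'
#' Round-trips losslessly (shortest round-trip decimal representation,
#' UTF-8, '.' decimal separator). Header = `id`, feature names, `label`.
#'
#' @param table An `ap_features` table.
#' @param path CSV path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the table.
#' @export
write_feature_table <- function(table, path) {
  ap_assert(inherits(table, "ap_features"), "table must be an ap_features table")
  df <- as.data.frame(table)
  df$label <- as.character(df$label)
  # 17 significant digits: every double round-trips exactly through text
  for (j in which(vapply(df, is.numeric, TRUE)))
    df[[j]] <- ifelse(is.na(df[[j]]), NA_character_, sprintf("%.17g", df[[j]]))
  data.table::fwrite(df, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ap_assert(file.exists(path), "file not found: ", path)
  df <- as.data.frame(data.table::fread(path, na.strings = "NA"))
  if (!"label" %in% names(df))
    ap_stop("feature CSV ", path, " has no 'label' column", class = "ap_format_error")
  id <- if ("id" %in% names(df)) df$id else NULL
  feats <- df[, setdiff(names(df), c("id", "label")), drop = FALSE]
  feature_table(feats, label = as.character(df$label), id = id)
}
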