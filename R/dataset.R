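#' Construct a tabular dataset for fairness analysis
#'
#' The basic container used throughout the package: a feature table, a binary
#' class label (1 = favorable outcome), and one or more named binary protected
#' attributes (0 = unprivileged group). Row identifiers are stable integers so
#' that subset/nesting relationships between resampled training sets can be
#' verified by set inclusion.
#'
#' @param features data.frame or matrix of numeric descriptive features.
#' @param labels vector of class labels in \{0, 1\}; 1 is the favorable label.
#' @param protected data.frame (or named list) of binary protected attribute
#'   columns; 0 codes the unprivileged group.
#' @param row_id optional integer row identifiers; defaults to `1:n`. Must be
#'   unique.
#' @return An object of class `tabular_dataset` with components `features`,
#'   `labels`, `protected`, `row_id`.
#' @examples
#' d <- tabular_dataset(data.frame(x0 = c(-1, 2, 0.5)),
#'                      labels = c(0, 1, 1),
#'                      protected = data.frame(A = c(0, 1, 1)))
#' dataset_n(d)
#' @export
tabular_dataset <- function(features, labels, protected, row_id = NULL) {
  features <- as.data.frame(features)
  protected <- as.data.frame(protected)
  n <- nrow(features)
  if (length(labels) != n || nrow(protected) != n)
    stop_fairpost("features, labels and protected must have the same number of rows",
                  "fairpost_schema_error")
  if (!all(labels %in% c(0, 1)))
    stop_fairpost("labels must be coded 0/1 (1 = favorable)", "fairpost_schema_error")
  if (ncol(protected) < 1L)
    stop_fairpost("at least one protected attribute column is required",
                  "fairpost_schema_error")
  for (nm in names(protected)) {
    if (!all(protected[[nm]] %in% c(0, 1)))
      stop_fairpost(sprintf("protected attribute '%s' must be coded 0/1 (0 = unprivileged)", nm),
                    "fairpost_schema_error")
    protected[[nm]] <- as.integer(protected[[nm]])
  }
  row_id <- if (is.null(row_id)) seq_len(n) else as.integer(row_id)
  if (length(row_id) != n || anyDuplicated(row_id))
    stop_fairpost("row_id must be unique and of length n", "fairpost_schema_error")
  structure(list(features = features, labels = as.integer(labels),
                 protected = protected, row_id = row_id),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d rows, %d features, protected: %s\n",
              dataset_n(x), ncol(x$features),
              paste(names(x$protected), collapse = ", ")))
  cat(sprintf("  favorable class proportion: %.3f\n", favorable_class_proportion(x)))
  for (nm in names(x$protected))
    cat(sprintf("  unprivileged rate (%s): %.3f\n", nm,
                unprivileged_group_rate(x, nm)))
  invisible(x)
}

#' Number of rows in a tabular dataset
#' @param dataset a `tabular_dataset`.
#' @export
dataset_n <- function(dataset) length(dataset$labels)

#' Subset a tabular dataset by row position
#'
#' Row identifiers travel with the rows, so nesting between subsets remains
#' checkable.
#'
#' @param dataset a `tabular_dataset`.
#' @param idx integer row positions.
#' @export
dataset_subset <- function(dataset, idx) {
  tabular_dataset(dataset$features[idx, , drop = FALSE],
                  dataset$labels[idx],
                  dataset$protected[idx, , drop = FALSE],
                  row_id = dataset$row_id[idx])
}

#' @export
as.data.frame.tabular_dataset <- function(x, ...) {
  cbind(x$features, y = x$labels, x$protected)
}

#' Favorable class proportion (FCP)
#' @param dataset a `tabular_dataset`.
#' @return Fraction of rows carrying the favorable label.
#' @export
favorable_class_proportion <- function(dataset) mean(dataset$labels == 1L)

#' Unprivileged group rate (UGR)
#' @param dataset a `tabular_dataset`.
#' @param attr protected attribute name; defaults to the first one.
#' @return Fraction of rows in the unprivileged (0) group.
#' @export
unprivileged_group_rate <- function(dataset, attr = names(dataset$protected)[1]) {
  if (!attr %in% names(dataset$protected))
    stop_fairpost(sprintf("protected attribute '%s' not present", attr),
                  "fairpost_schema_error")
  mean(dataset$protected[[attr]] == 0L)
}
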