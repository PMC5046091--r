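#' ExpressionDataset: a feature-by-sample intensity matrix with group labels
#'
#' The basic container for one microarray dataset: a numeric matrix of
#' non-negative, linear-scale normalized intensities (features in rows,
#' samples in columns) plus a case/control label per sample. The set of row
#' names is the platform's measured feature universe, which downstream
#' consensus and permutation machinery uses as the sampling frame.
#'
#' @param values numeric matrix, features x samples, with row and column
#'   names. Intensities are assumed linear-scale; see `log2_input` in
#'   [read_expression_matrix()].
#' @param groups named character vector mapping every sample (column) name to
#'   `"case"` or `"control"`.
#' @param dataset_id single string identifying the dataset.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `dataset_id`, `values`, `groups` and `universe` (the row names, in
#'   order).
#' @export
expression_dataset <- function(values, groups, dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (feature) and column (sample) names",
         call. = FALSE)
  dup <- duplicated(rownames(values))
  if (any(dup))
    stop("duplicate feature name(s): ",
         paste(unique(rownames(values)[dup]), collapse = ", "),
         "; resolve duplicates via map_feature_ids()", call. = FALSE)
  samples <- colnames(values)
  missing <- setdiff(samples, names(groups))
  if (length(missing))
    stop("sample(s) without a group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  groups <- groups[samples]
  bad <- !groups %in% c("case", "control")
  if (any(bad))
    stop("group labels must be 'case' or 'control'; offending sample(s): ",
         paste(samples[bad], collapse = ", "), call. = FALSE)
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  structure(
    list(dataset_id = dataset_id, values = values, groups = groups,
         universe = rownames(values)),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "ExpressionDataset '%s': %d features x %d samples (%d case / %d control)\n",
    x$dataset_id, nrow(x$values), ncol(x$values),
    sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)
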