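#' Assemble a clustered dataset for analysis
#'
#' Wraps a data frame of numeric analysis variables with a cluster
#' identifier (e.g. the GP practice an individual is registered with).
#' Rows with missing values on any analysis variable are dropped
#' (listwise deletion) and the count recorded.
#'
#' @param data a data frame.
#' @param cluster name of the cluster-identifier column; values are treated
#'   as opaque labels.
#' @param variables analysis variable names; default all columns except the
#'   cluster column that are numeric.
#' @param scales optional named character vector declaring per-variable
#'   scale: `"continuous"`, `"ordinal"` (Likert codes treated as
#'   continuous) or `"categorical"`. Declared-categorical variables are
#'   refused by the fitting functions; recode them as dummies.
#' @return an object of class `clustered_dataset`: a list with the numeric
#'   matrix `$x`, `$cluster` factor, `$scales`, and `$n_dropped`.
#' @export
clustered_dataset <- function(data, cluster, variables = NULL, scales = NULL) {
  stopifnot(is.data.frame(data))
  if (!cluster %in% names(data))
    stop(sprintf("cluster column '%s' not found in data", cluster))
  if (is.null(variables)) {
    variables <- setdiff(names(data), cluster)
    variables <- variables[vapply(data[variables], is.numeric, TRUE)]
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars))
    stop(sprintf("variables not found in data: %s",
                 paste(missing_vars, collapse = ", ")))
  x <- data[variables]
  not_num <- variables[!vapply(x, is.numeric, TRUE)]
  if (length(not_num))
    stop(sprintf("non-numeric analysis variables: %s",
                 paste(not_num, collapse = ", ")))
  x <- as.matrix(x)
  keep <- stats::complete.cases(x) & !is.na(data[[cluster]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("listwise deletion dropped %d of %d rows",
                    n_dropped, nrow(x)))
  x <- x[keep, , drop = FALSE]
  cl <- factor(data[[cluster]][keep])
  if (nrow(x) < length(variables) + 1)
    stop("fewer complete rows than observed variables + 1")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("variable with zero variance: %s",
                 paste(variables[sds == 0], collapse = ", ")))
  scl <- rep("continuous", length(variables))
  names(scl) <- variables
  if (!is.null(scales)) scl[names(scales)] <- scales
  structure(list(x = x, cluster = cl, scales = scl,
                 n = nrow(x), n_clusters = nlevels(cl),
                 n_dropped = n_dropped),
            class = "clustered_dataset")
}

#' @export
print.clustered_dataset <- function(x, ...) {
  cat("clustered_dataset: ", x$n, " rows, ", ncol(x$x), " variables, ",
      x$n_clusters, " clusters (", x$n_dropped, " rows dropped)\n", sep = "")
  invisible(x)
}

#' Sample covariance matrix (divisor n)
#'
#' The maximum-likelihood sample covariance with divisor `n`, the form
#' that makes the fit function vanish for a saturated model. The divisor is
#' recorded in the `"divisor"` attribute.
#'
#' @param data a `clustered_dataset` (or numeric matrix).
#' @return symmetric p x p matrix with attribute `divisor = "n"`.
#' @export
sample_covariance <- function(data) {
  x <- if (inherits(data, "clustered_dataset")) data$x else as.matrix(data)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows")
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    stop(sprintf("variable with zero variance: %s",
                 paste(colnames(x)[v == 0], collapse = ", ")))
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n
  S <- (S + t(S)) / 2
  attr(S, "divisor") <- "n"
  S
}
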