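# End-to-end orchestration: read data and model configuration, fit the
# measurement models with pruning, compile and fit the full structural
# model, standardize, decompose every CMO, compute fit indices, and
# write a structured report.

binding_to_list <- function(b) {
  list(name = b$concept_name, mode = b$mode,
       indicators = as.list(b$indicators), reference = b$reference)
}
binding_from_list <- function(x) {
  concept_binding(x$name, x$mode, unlist(x$indicators),
                  reference = x$reference %||% unlist(x$indicators)[1])
}

#' Write a model configuration file
#'
#' Serializes CMO configurations, residual correlations and the cluster
#' column to YAML or JSON (by file extension). The file round-trips
#' losslessly through [read_model_config()].
#'
#' @param cmos list of `cmo_configuration` objects.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @param residual_correlations list of 2-element indicator pairs.
#' @param cluster_column cluster-identifier column name.
#' @param options free-form named list of options.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(cmos, path, residual_correlations = list(),
                               cluster_column = "practice_id",
                               options = list()) {
  if (inherits(cmos, "cmo_configuration")) cmos <- list(cmos)
  obj <- list(
    cmos = cmos_to_list(cmos),
    residual_correlations = lapply(residual_correlations, as.list),
    cluster_column = cluster_column,
    options = options)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(obj, path)
  else if (ext == "json")
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  else stop("config path must end in .yaml, .yml or .json")
  invisible(path)
}

#' Read a model configuration file
#'
#' @param path a YAML or JSON file written by [write_model_config()] (or
#'   by hand in the same schema).
#' @return list with `cmos` (list of `cmo_configuration`),
#'   `residual_correlations`, `cluster_column`, `options`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json")
           jsonlite::read_json(path, simplifyVector = FALSE)
         else stop("config path must end in .yaml, .yml or .json")
  cmos <- lapply(obj$cmos, function(cm) cmo_configuration(
    binding_from_list(cm$context), binding_from_list(cm$mechanism),
    binding_from_list(cm$outcome),
    include_direct_path = cm$include_direct_path %||% TRUE))
  list(cmos = cmos,
       residual_correlations = lapply(obj$residual_correlations %||% list(),
                                      unlist),
       cluster_column = obj$cluster_column %||% "practice_id",
       options = obj$options %||% list())
}

cmos_to_list <- function(cmos) {
  lapply(cmos, function(cm) list(
    context = binding_to_list(cm$context),
    mechanism = binding_to_list(cm$mechanism),
    outcome = binding_to_list(cm$outcome),
    include_direct_path = cm$include_direct_path))
}

# small non-cryptographic content hash for provenance
config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%09d", h)
}

#' Run the full CMO analysis pipeline
#'
#' Stages, in order: read data and configuration; listwise deletion;
#' one-factor CFA with optional backward pruning for every reflective
#' concept; compile the structural model from the (pruned) CMOs; fit by
#' maximum likelihood with cluster-robust standard errors; standardize;
#' decompose each CMO into direct and indirect effects; compute RMSEA,
#' CFI and TLI against the independence baseline. A non-converged fit
#' yields a report flagged `converged = FALSE`, not an error.
#'
#' @param data_path CSV file, one row per individual, with a header and a
#'   cluster column.
#' @param model_config_path YAML/JSON model configuration
#'   ([read_model_config()] schema).
#' @param cluster cluster column; default from the config.
#' @param alpha pruning significance level (default 0.05).
#' @param prune prune non-significant indicators (default TRUE).
#' @param out_path optional path for the JSON report.
#' @param level confidence level (default 0.95).
#' @param control a [fml_control()].
#' @return an object of class `cmo_report`.
#' @export
run_pipeline <- function(data_path, model_config_path, cluster = NULL,
                         alpha = 0.05, prune = TRUE, out_path = NULL,
                         level = 0.95, control = fml_control()) {
  if (!file.exists(data_path))
    stop(sprintf("data file not found: %s", data_path))
  cfg <- read_model_config(model_config_path)
  cluster <- cluster %||% cfg$cluster_column
  raw <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  if (!cluster %in% names(raw))
    stop(sprintf("cluster column '%s' not found in data", cluster))
  cmos <- cfg$cmos
  if (!length(cmos)) stop("empty CMO list")

  vars <- unique(unlist(lapply(cmos, function(cm)
    c(cm$context$indicators, cm$mechanism$indicators,
      cm$outcome$indicators))))
  missing_vars <- setdiff(vars, names(raw))
  if (length(missing_vars))
    stop(sprintf("model variables missing from data: %s",
                 paste(missing_vars, collapse = ", ")))
  data <- clustered_dataset(raw, cluster, variables = vars)

  # measurement stage: CFA (+ pruning) per reflective concept
  cfa_summaries <- list()
  prune_binding <- function(b) {
    if (b$mode != "reflective" || length(b$indicators) < 3) return(b)
    mfit <- fit_cfa(b, data, control = control)
    cfa_summaries[[b$concept_name]] <<- mfit
    if (!prune) return(b)
    pruned <- prune_indicators(mfit, alpha = alpha)
    pruned
  }
  seen <- character()
  for (i in seq_along(cmos)) {
    for (role in c("context", "mechanism", "outcome")) {
      b <- cmos[[i]][[role]]
      if (b$concept_name %in% seen) {
        # reuse the already-pruned binding for shared concepts
        for (j in seq_len(i - 1)) for (r2 in c("context", "mechanism",
                                               "outcome"))
          if (cmos[[j]][[r2]]$concept_name == b$concept_name)
            cmos[[i]][[role]] <- cmos[[j]][[r2]]
        next
      }
      seen <- c(seen, b$concept_name)
      cmos[[i]][[role]] <- prune_binding(b)
    }
  }

  model <- build_sem_from_cmos(cmos,
                               residual_correlations =
                                 cfg$residual_correlations)
  fit <- suppressWarnings(fit_ml(model, data, control = control))

  report <- structure(list(
    converged = fit$converged,
    model = model, fit = fit,
    cfa = cfa_summaries,
    std = NULL, effects = NULL, indices = NULL,
    provenance = list(
      data_path = data_path, model_config_path = model_config_path,
      config_hash = config_hash(list(cmos_to_list(cfg$cmos),
                       lapply(cfg$residual_correlations, as.list))),
      package_version = as.character(utils::packageVersion("realistsem")),
      n_rows_in = nrow(raw), n_analyzed = data$n,
      n_dropped = data$n_dropped, n_clusters = data$n_clusters,
      cluster_column = cluster, alpha = alpha, prune = prune)),
    class = "cmo_report")

  if (fit$converged) {
    report$std <- standardize(fit, level = level)
    report$effects <- decompose_all(fit, std = report$std, level = level)
    report$indices <- fit_indices(fit)
  }
  if (!is.null(out_path)) write_report_json(report, out_path)
  report
}

write_report_json <- function(report, path) {
  plain_df <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.data.frame(x)
    class(x) <- "data.frame"
    attributes(x)[setdiff(names(attributes(x)),
                          c("names", "row.names", "class"))] <- NULL
    x
  }
  idx <- report$indices
  obj <- list(
    converged = report$converged,
    provenance = report$provenance,
    n_free_parameters = report$model$q,
    degrees_of_freedom = degrees_of_freedom(report$model),
    cfa = lapply(report$cfa, function(m)
      list(concept = m$binding$concept_name, se_type = m$se_type,
           loadings = m$loadings)),
    standardized = plain_df(report$std),
    effects = plain_df(report$effects),
    fit_indices = if (!is.null(idx))
      list(T = idx$T, df = idx$df, T_baseline = idx$T_baseline,
           df_baseline = idx$df_baseline, rmsea = idx$rmsea,
           cfi = idx$cfi, tli = idx$tli,
           verdicts = as.list(idx$verdicts)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.cmo_report <- function(x, digits = 3, ...) {
  cat("CMO pipeline report (converged = ", x$converged, ")\n", sep = "")
  pv <- x$provenance
  cat(sprintf("n analyzed = %d (of %d; %d dropped), clusters = %d\n",
              pv$n_analyzed, pv$n_rows_in, pv$n_dropped, pv$n_clusters))
  if (!x$converged) return(invisible(x))
  print(x$indices, digits = digits)
  cat("\nEffect decomposition:\n")
  print(x$effects, digits = digits)
  invisible(x)
}

#' Simulate a dataset to file
#'
#' Writes a CSV drawn from a synthetic configuration plus a sidecar JSON
#' (`<out>.truth.json`) recording the generating configuration; the
#' sidecar round-trips through [synthetic_config_from_list()].
#'
#' @param config a `synthetic_config`, e.g. [paper_fixture()].
#' @param seed integer seed.
#' @param out_path CSV output path.
#' @return `out_path`, invisibly.
#' @export
simulate_dataset <- function(config, seed, out_path) {
  df <- generate_linked_dataset(config, seed = seed)
  ok <- tryCatch({ utils::write.csv(df, out_path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", out_path))
  truth <- list(seed = seed, config = synthetic_config_to_list(config))
  jsonlite::write_json(truth, paste0(out_path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_path)
}

#' @rdname synthetic_config_from_list
#' @export
synthetic_config_to_list <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- unclass(config)
  out$equations <- lapply(out$equations, function(eq) {
    eq$coef <- as.list(eq$coef)
    eq
  })
  out
}

#' Serialize a synthetic configuration
#'
#' `synthetic_config_to_list()` turns a `synthetic_config` into plain
#' lists (JSON-safe); `synthetic_config_from_list()` reconstructs it.
#'
#' @param x a plain list as produced by `synthetic_config_to_list` (or
#'   parsed from the sidecar JSON).
#' @param config a `synthetic_config`.
#' @return a `synthetic_config` (or a plain list).
#' @export
synthetic_config_from_list <- function(x) {
  eqs <- lapply(x$equations, function(eq) {
    eq$coef <- unlist(eq$coef)
    eq
  })
  concepts <- lapply(x$concepts, function(cc) {
    for (f in c("probs")) if (!is.null(cc[[f]])) cc[[f]] <- unlist(cc[[f]])
    for (f in c("levels", "dummies"))
      if (!is.null(cc[[f]])) cc[[f]] <- unlist(cc[[f]])
    cc
  })
  measurement <- lapply(x$measurement, function(ms) lapply(ms, function(ind) {
    for (f in c("thresholds"))
      if (!is.null(ind[[f]])) ind[[f]] <- unlist(ind[[f]])
    ind
  }))
  synthetic_config(n_individuals = x$n_individuals,
                   n_practices = x$n_practices,
                   concepts = concepts, equations = eqs,
                   measurement = measurement,
                   icc_default = x$icc_default %||% 0.3,
                   missing_rate = x$missing_rate %||% 0,
                   demographics = isTRUE(x$demographics))
}
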