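#' Bind a realist concept to observed data
#'
#' A concept (context, mechanism or outcome) is bound to data in one of
#' four measurement modes:
#' \describe{
#'   \item{observed}{a single observed variable stands for the concept.}
#'   \item{reflective}{the concept is a latent variable causing two or more
#'     observed indicators (confirmatory factor model); the first indicator
#'     is the reference whose loading is fixed to 1.}
#'   \item{formative}{the observed indicators compose the concept; compiled
#'     as a composite with free weights (first fixed to 1) and zero
#'     disturbance.}
#'   \item{categorical}{a categorical concept represented by its dummy
#'     columns (baseline omitted); every dummy receives its own structural
#'     paths.}
#' }
#'
#' @param name concept name.
#' @param mode one of `"observed"`, `"reflective"`, `"formative"`,
#'   `"categorical"`.
#' @param indicators character vector of observed variable names.
#' @param reference reference indicator (reflective mode); defaults to the
#'   first indicator.
#' @return an object of class `concept_binding`.
#' @export
concept_binding <- function(name, mode = c("observed", "reflective",
                                           "formative", "categorical"),
                            indicators, reference = indicators[[1]]) {
  mode <- match.arg(mode)
  indicators <- as.character(indicators)
  if (anyDuplicated(indicators))
    stop("indicator names must be unique within a binding")
  if (mode == "observed" && length(indicators) != 1L)
    stop("observed mode requires exactly 1 indicator")
  if (mode == "reflective") {
    if (length(indicators) < 2L)
      stop("reflective mode requires at least 2 indicators")
    if (!reference %in% indicators)
      stop("reference indicator not among indicators")
    indicators <- c(reference, setdiff(indicators, reference))
  }
  if (mode == "formative" && length(indicators) < 2L)
    stop("formative mode requires at least 2 indicators")
  if (mode == "categorical" && length(indicators) < 1L)
    stop("categorical mode requires at least 1 dummy indicator")
  structure(list(concept_name = name, mode = mode,
                 indicators = indicators, reference = indicators[[1]]),
            class = "concept_binding")
}

#' Declare a context-mechanism-outcome configuration
#'
#' The unit of analysis of a realist evaluation: a context that triggers a
#' mechanism which generates an outcome. The mechanism is modelled as a
#' mediator; `include_direct_path` additionally frees the context-to-outcome
#' path so direct and indirect effects can be separated.
#'
#' @param context,mechanism,outcome `concept_binding` objects.
#' @param include_direct_path free a direct context-to-outcome path
#'   (default `TRUE`).
#' @return an object of class `cmo_configuration`.
#' @export
cmo_configuration <- function(context, mechanism, outcome,
                              include_direct_path = TRUE) {
  for (b in list(context, mechanism, outcome))
    stopifnot(inherits(b, "concept_binding"))
  nms <- c(context$concept_name, mechanism$concept_name, outcome$concept_name)
  if (anyDuplicated(nms))
    stop("context, mechanism and outcome must be distinct concepts")
  structure(list(context = context, mechanism = mechanism, outcome = outcome,
                 include_direct_path = isTRUE(include_direct_path)),
            class = "cmo_configuration")
}

# Latent names a binding contributes as structural nodes: one per concept,
# except categorical bindings which expand to one node per dummy.
binding_nodes <- function(b) {
  if (b$mode == "categorical") b$indicators else b$concept_name
}

#' Compile CMO configurations into one structural equation model
#'
#' Builds a single recursive model containing every declared CMO: a free
#' context-to-mechanism and mechanism-to-outcome path per CMO, plus a
#' direct context-to-outcome path where requested. Concepts shared between
#' CMOs appear once. Reflective latents are identified by fixing the
#' reference loading to 1 with a free latent variance; formative concepts
#' become composites (indicator weights into the latent, first weight fixed
#' to 1, zero disturbance); observed and categorical concepts are promoted
#' to degenerate latents. Exogenous concepts get free variances and
#' pairwise covariances.
#'
#' @param cmos list of `cmo_configuration` objects sharing one outcome.
#' @param residual_correlations optional list of 2-element character
#'   vectors naming indicator pairs whose residual covariance is freed in
#'   `Theta` (e.g. theoretically justified correlations flagged by
#'   modification indices).
#' @return a `sem_model`; its `$meta` records the CMO structure used later
#'   by [decompose_all()].
#' @export
build_sem_from_cmos <- function(cmos, residual_correlations = NULL) {
  if (inherits(cmos, "cmo_configuration")) cmos <- list(cmos)
  if (!length(cmos)) stop("at least one CMO configuration is required")
  for (cm in cmos) stopifnot(inherits(cm, "cmo_configuration"))

  out_names <- unique(vapply(cmos, function(cm) cm$outcome$concept_name, ""))
  if (length(out_names) != 1L)
    stop("all CMO configurations must share a single outcome")

  # collect unique concepts, checking a name is always bound the same way
  concepts <- list()
  add_concept <- function(b) {
    prev <- concepts[[b$concept_name]]
    if (is.null(prev)) {
      concepts[[b$concept_name]] <<- b
    } else if (!identical(prev[c("mode", "indicators")],
                          b[c("mode", "indicators")])) {
      stop(sprintf("concept '%s' bound inconsistently across CMOs",
                   b$concept_name))
    }
    invisible(NULL)
  }
  for (cm in cmos) {
    add_concept(cm$context); add_concept(cm$mechanism); add_concept(cm$outcome)
  }

  # a variable may serve only one concept
  all_ind <- unlist(lapply(concepts, `[[`, "indicators"))
  if (anyDuplicated(all_ind)) {
    dup <- unique(all_ind[duplicated(all_ind)])
    stop(sprintf("variable bound to two concepts: %s",
                 paste(dup, collapse = ", ")))
  }

  observed <- as.character(all_ind)
  p <- length(observed)

  # latent nodes: concept nodes (categorical -> per dummy), plus degenerate
  # latents for formative indicators (they feed the composite through B)
  latents <- character()
  for (b in concepts) {
    if (b$mode == "formative") latents <- c(latents, b$indicators)
    latents <- c(latents, binding_nodes(b))
  }
  m <- length(latents)

  Lambda <- matrix(0, p, m, dimnames = list(observed, latents))
  B <- matrix(0, m, m, dimnames = list(latents, latents))
  Psi <- matrix(0, m, m, dimnames = list(latents, latents))
  Theta <- matrix(0, p, p, dimnames = list(observed, observed))

  mech_names <- unique(vapply(cmos, function(cm) cm$mechanism$concept_name, ""))
  endo <- c(mech_names, out_names)

  for (b in concepts) {
    cn <- b$concept_name
    switch(b$mode,
      observed = , categorical = {
        for (v in b$indicators) Lambda[v, v] <- 1   # degenerate latent
      },
      reflective = {
        Lambda[b$reference, cn] <- 1
        for (v in setdiff(b$indicators, b$reference)) Lambda[v, cn] <- NA
        for (v in b$indicators) Theta[v, v] <- NA
      },
      formative = {
        for (v in b$indicators) Lambda[v, v] <- 1   # degenerate indicators
        B[cn, b$indicators[1]] <- 1                  # first weight fixed
        for (v in b$indicators[-1]) B[cn, v] <- NA   # free weights
        # composite disturbance fixed to 0 (Psi stays 0)
      })
  }

  # structural paths
  for (cm in cmos) {
    mech <- cm$mechanism$concept_name
    for (cnode in binding_nodes(cm$context)) {
      B[mech, cnode] <- NA
      if (cm$include_direct_path) B[out_names, cnode] <- NA
    }
    B[out_names, mech] <- NA
  }

  # exogenous nodes: everything that never receives a structural path or
  # composite weight; free their variances and pairwise covariances
  receives <- rownames(B)[apply(B, 1, function(r) any(is.na(r) | r != 0))]
  exo <- setdiff(latents, receives)
  for (a in exo) Psi[a, a] <- NA
  if (length(exo) > 1) {
    for (i in seq_along(exo)[-1]) for (j in seq_len(i - 1)) {
      Psi[exo[i], exo[j]] <- NA; Psi[exo[j], exo[i]] <- NA
    }
  }
  # endogenous disturbances (mechanisms + outcome); composites stay fixed 0
  for (e in endo) {
    if (concepts[[e]]$mode != "formative") Psi[e, e] <- NA
  }
  # categorical endogenous would be odd but keep the contract simple

  # requested residual correlations
  for (pr in residual_correlations %||% list()) {
    if (length(pr) != 2L)
      stop("each residual correlation must name exactly 2 indicators")
    if (!all(pr %in% observed))
      stop(sprintf("residual correlation references undeclared indicator: %s",
                   paste(setdiff(pr, observed), collapse = ", ")))
    Theta[pr[1], pr[2]] <- NA; Theta[pr[2], pr[1]] <- NA
  }

  cmo_meta <- lapply(cmos, function(cm) list(
    label = paste0(cm$context$concept_name, " -> ",
                   cm$mechanism$concept_name, " -> ",
                   cm$outcome$concept_name),
    context = cm$context$concept_name,
    context_nodes = binding_nodes(cm$context),
    mechanism = cm$mechanism$concept_name,
    outcome = out_names,
    direct = cm$include_direct_path))

  B_start <- matrix(0, m, m, dimnames = dimnames(B))
  for (b in concepts) if (b$mode == "formative")
    B_start[b$concept_name, b$indicators[-1]] <- 1

  sem_model(observed, latents, Lambda, B, Psi, Theta,
            start = list(B = B_start),
            meta = list(cmos = cmo_meta, concepts = concepts,
                        outcome = out_names, mechanisms = mech_names,
                        exogenous = exo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
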