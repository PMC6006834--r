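# Synthetic linked two-level survey data.
#
# Emulates the structure of an individual-level ageing-cohort survey
# joined to practice-level patient-experience percentages: individuals
# nested in GP practices, practice-level variables constant within
# cluster, reflective Likert indicators, a formative transport composite,
# and a continuous travel-time variable.
#
# Concept scores are generated from a recursive standardized structural
# model. Every individual-level stochastic term is split into a practice
# component and an individual component (intraclass share `icc`), and the
# generator keeps an exact linear representation of each concept over the
# underlying independent shocks. Practice-level endogenous concepts
# (e.g. the appointment-availability percentages) are driven by the
# practice components of their predictors, rescaled so the marginal
# covariance between predictor and outcome equals the declared
# standardized coefficient; this keeps the single-level structural model
# exactly recoverable from the pooled data while practice-level variables
# stay constant within cluster.

#' Declare a synthetic-data generating configuration
#'
#' @param n_individuals number of individuals.
#' @param n_practices number of practice clusters (must not exceed
#'   `n_individuals`; every practice receives at least one individual).
#' @param concepts list of concept declarations: each a list with `name`,
#'   `level` ("individual" or "practice"), `type` ("normal" or
#'   "categorical"), optional `icc` (cluster variance share for
#'   individual-level normal concepts), and for categorical concepts
#'   `levels` (labels, first = baseline), `probs`, and `dummies` (exported
#'   dummy column names for the non-baseline levels).
#' @param equations list of structural equations: each a list with `lhs`
#'   (an endogenous concept) and `coef`, a named vector of standardized
#'   path coefficients on concept nodes (dummy node names for categorical
#'   predictors); optional `icc` for the disturbance of individual-level
#'   concepts.
#' @param measurement list keyed by concept name; each entry a list of
#'   indicator declarations `list(var=, loading=, kind=, ...)` where
#'   `kind` is one of `"likert"` (needs `thresholds`), `"percent"` (needs
#'   `mean`, `sd`), `"lognormal"` (needs `mu`, `sigma`), `"raw"`.
#' @param icc_default default intraclass share for individual-level terms.
#' @param missing_rate MCAR missingness rate applied per cell of the
#'   analysis columns (default 0).
#' @param demographics generate cosmetic demographic columns (sex, age
#'   band, occupation) excluded from the model (default TRUE).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals, n_practices, concepts,
                             equations, measurement,
                             icc_default = 0.3, missing_rate = 0,
                             demographics = TRUE) {
  n_individuals <- as.integer(n_individuals)
  n_practices <- as.integer(n_practices)
  stopifnot(n_individuals >= 1, n_practices >= 1,
            n_practices <= n_individuals,
            missing_rate >= 0, missing_rate < 1)
  names(concepts) <- vapply(concepts, `[[`, "", "name")
  structure(list(n_individuals = n_individuals, n_practices = n_practices,
                 concepts = concepts, equations = equations,
                 measurement = measurement, icc_default = icc_default,
                 missing_rate = missing_rate, demographics = demographics),
            class = "synthetic_config")
}

#' Discretize continuous values to ordinal Likert codes
#'
#' Codes `1..k` with `k-1` strictly increasing thresholds; code `i` is
#' assigned to values in the right-closed interval `(t[i-1], t[i]]`, so a
#' value exactly at a threshold falls in the lower-adjacent category.
#' With no thresholds every value receives code 1.
#'
#' @param values numeric vector.
#' @param thresholds strictly increasing numeric vector.
#' @return integer codes `1..(length(thresholds)+1)`.
#' @export
discretize_to_likert <- function(values, thresholds) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0) return(rep(1L, length(values)))
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  codes <- rep(1L, length(values))
  for (t in thresholds) codes <- codes + (values > t)
  codes
}

# run one RNG-consuming block under a local seed, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

#' Generate a linked two-level dataset
#'
#' Draws one dataset from a [synthetic_config()]: practice-level
#' variables are constant within cluster, individual-level latents follow
#' the declared structural model plus practice random effects, reflective
#' indicators are loading times latent plus noise (then discretized or
#' rescaled), and the formative transport block is drawn so the composite
#' carries the configured paths. Bit-identical given the same seed.
#'
#' @param config a `synthetic_config`.
#' @param seed integer seed.
#' @return a data frame with a `practice_id` column; the generating truth
#'   (concept covariance handled exactly) is attached as attribute
#'   `"truth"`.
#' @export
generate_linked_dataset <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, generate_impl(config))
}

# ---- internal ------------------------------------------------------------

# node table: categorical concepts expand to one node per dummy
node_table <- function(config) {
  rows <- list()
  for (cc in config$concepts) {
    if (identical(cc$type, "categorical")) {
      for (d in cc$dummies)
        rows[[length(rows) + 1L]] <- data.frame(
          node = d, concept = cc$name, level = cc$level,
          type = "dummy", stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        node = cc$name, concept = cc$name, level = cc$level,
        type = "normal", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

generate_impl <- function(config) {
  n <- config$n_individuals
  G <- config$n_practices
  nodes <- node_table(config)
  nn <- nrow(nodes)
  endo <- vapply(config$equations, `[[`, "", "lhs")

  # dummy covariance blocks per categorical concept
  dummy_info <- list()
  for (cc in config$concepts) {
    if (!identical(cc$type, "categorical")) next
    pr <- cc$probs / sum(cc$probs)
    pd <- pr[-1]                         # non-baseline probabilities
    Sd <- diag(pd * (1 - pd), length(pd)) - outer(pd, pd) +
      diag(0, length(pd))
    diag(Sd) <- pd * (1 - pd)
    dimnames(Sd) <- list(cc$dummies, cc$dummies)
    dummy_info[[cc$name]] <- list(probs = pr, levels = cc$levels,
                                  dummies = cc$dummies, cov = Sd,
                                  p_dummy = stats::setNames(pd, cc$dummies))
  }
  all_dummies <- unlist(lapply(dummy_info, `[[`, "dummies"))
  Sdd <- matrix(0, length(all_dummies), length(all_dummies),
                dimnames = list(all_dummies, all_dummies))
  for (di in dummy_info)
    Sdd[di$dummies, di$dummies] <- di$cov

  # linear representation over shocks: A_P (practice), A_I (individual),
  # D (centered dummy variables)
  shocks <- data.frame(name = character(), level = character(),
                       stringsAsFactors = FALSE)
  A_P <- matrix(0, nn, 0); A_I <- matrix(0, nn, 0)
  rownames(A_P) <- rownames(A_I) <- nodes$node
  D <- matrix(0, nn, length(all_dummies),
              dimnames = list(nodes$node, all_dummies))
  add_shock <- function(name, level) {
    shocks <<- rbind(shocks, data.frame(name = name, level = level,
                                        stringsAsFactors = FALSE))
    A_P <<- cbind(A_P, 0); A_I <<- cbind(A_I, 0)
    ncol(A_P)
  }
  node_var <- function(v)  sum(A_P[v, ]^2) + sum(A_I[v, ]^2) +
    drop(D[v, , drop = FALSE] %*% Sdd %*% t(D[v, , drop = FALSE]))
  node_pvar <- function(v) sum(A_P[v, ]^2)

  unrealized <- character()

  # exogenous nodes first
  for (k in seq_len(nn)) {
    v <- nodes$node[k]
    if (nodes$concept[k] %in% endo || v %in% endo) next
    if (nodes$type[k] == "dummy") { D[v, v] <- 1; next }
    cc <- config$concepts[[nodes$concept[k]]]
    if (nodes$level[k] == "practice") {
      s <- add_shock(paste0("u_", v), "practice"); A_P[v, s] <- 1
    } else {
      icc <- cc$icc %||% config$icc_default
      s1 <- add_shock(paste0("u_", v), "practice"); A_P[v, s1] <- sqrt(icc)
      s2 <- add_shock(paste0("e_", v), "individual"); A_I[v, s2] <- sqrt(1 - icc)
    }
  }

  # endogenous nodes in declared (topological) order
  for (eq in config$equations) {
    v <- eq$lhs
    lev <- nodes$level[match(v, nodes$node)]
    if (is.na(lev)) stop(sprintf("equation for undeclared concept '%s'", v))
    comb_P <- rep(0, ncol(A_P)); comb_I <- rep(0, ncol(A_I))
    comb_D <- rep(0, length(all_dummies)); names(comb_D) <- all_dummies
    for (pn in names(eq$coef)) {
      cf <- eq$coef[[pn]]
      if (cf == 0) next
      if (!pn %in% nodes$node)
        stop(sprintf("equation for '%s' references unknown node '%s'", v, pn))
      plev <- nodes$level[match(pn, nodes$node)]
      if (nodes$type[match(pn, nodes$node)] == "dummy") {
        sd_d <- sqrt(Sdd[pn, pn])
        if (lev == "practice") {          # dummies carry no practice part
          unrealized <- c(unrealized, paste0(v, "~", pn))
          next
        }
        comb_D[pn] <- comb_D[pn] + cf / sd_d
      } else if (lev == "individual" || plev == "practice") {
        comb_P <- comb_P + cf * A_P[pn, ]
        comb_I <- comb_I + cf * A_I[pn, ]
        comb_D <- comb_D + cf * D[pn, ]
      } else {
        # individual predictor in a practice-level equation: use its
        # practice component, scaled so cov(predictor, lhs) = coefficient
        vP <- node_pvar(pn)
        if (vP < 1e-12) {
          unrealized <- c(unrealized, paste0(v, "~", pn))
          next
        }
        comb_P <- comb_P + (cf / vP) * A_P[pn, ]
      }
    }
    A_P[v, ] <- comb_P; A_I[v, ] <- comb_I; D[v, ] <- comb_D
    expl <- node_var(v)
    psi <- 1 - expl
    if (psi <= 1e-8)
      stop(sprintf(paste0("non-positive-definite implied covariance: ",
                          "equation for '%s' explains variance %.3f >= 1 ",
                          "(coefficients: %s)"),
                   v, expl, paste(sprintf("%s=%.3f", names(eq$coef),
                                          unlist(eq$coef)), collapse = ", ")))
    if (lev == "practice") {
      s <- add_shock(paste0("z_", v), "practice"); A_P[v, s] <- sqrt(psi)
    } else {
      icc <- eq$icc %||% config$icc_default
      s1 <- add_shock(paste0("zu_", v), "practice")
      A_P[v, s1] <- sqrt(icc * psi)
      s2 <- add_shock(paste0("ze_", v), "individual")
      A_I[v, s2] <- sqrt((1 - icc) * psi)
    }
  }

  # ---- numeric draw ----
  sizes <- rep(1L, G)
  if (n > G)
    sizes <- sizes + stats::rmultinom(1, n - G, rep(1, G))[, 1]
  practice_id <- rep(sprintf("p%04d", seq_len(G)), times = sizes)
  cl_index <- rep(seq_len(G), times = sizes)

  ns <- nrow(shocks)
  shock_rows <- matrix(0, n, ns)
  for (s in seq_len(ns)) {
    if (shocks$level[s] == "practice")
      shock_rows[, s] <- stats::rnorm(G)[cl_index]
    else shock_rows[, s] <- stats::rnorm(n)
  }

  # categorical draws
  dummy_raw <- matrix(0L, n, length(all_dummies),
                      dimnames = list(NULL, all_dummies))
  dummy_centered <- matrix(0, n, length(all_dummies),
                           dimnames = list(NULL, all_dummies))
  cat_labels <- list()
  for (cname in names(dummy_info)) {
    di <- dummy_info[[cname]]
    draw <- sample(seq_along(di$probs), n, replace = TRUE, prob = di$probs)
    cat_labels[[cname]] <- di$levels[draw]
    for (j in seq_along(di$dummies)) {
      d <- di$dummies[j]
      dummy_raw[, d] <- as.integer(draw == j + 1L)
      dummy_centered[, d] <- dummy_raw[, d] - di$p_dummy[d]
    }
  }

  scores <- shock_rows %*% t(A_P + A_I)
  if (length(all_dummies))
    scores <- scores + dummy_centered %*% t(D)
  colnames(scores) <- nodes$node

  # ---- measurement / export ----
  out <- list(practice_id = practice_id)
  for (cname in names(config$measurement)) {
    cc <- config$concepts[[cname]]
    lev <- cc$level %||% "individual"
    sc <- scores[, cname]
    for (ind in config$measurement[[cname]]) {
      lam <- ind$loading %||% 1
      if (abs(lam) > 1) stop("indicator loadings must be in [-1, 1]")
      noise_sd <- sqrt(max(1 - lam^2, 0))
      if (noise_sd > 0) {
        noise <- if (lev == "practice") stats::rnorm(G)[cl_index]
                 else stats::rnorm(n)
      } else noise <- 0
      z <- lam * sc + noise_sd * noise
      val <- switch(ind$kind %||% "raw",
        likert = discretize_to_likert(z, ind$thresholds),
        percent = pmin(pmax(ind$mean + ind$sd * z, 0), 100),
        lognormal = exp(ind$mu + ind$sigma * z),
        raw = z,
        stop(sprintf("unknown indicator kind '%s'", ind$kind)))
      out[[ind$var]] <- val
    }
  }
  for (d in all_dummies) out[[d]] <- dummy_raw[, d]
  for (cname in names(cat_labels))
    out[[paste0(cname, "_level")]] <- cat_labels[[cname]]

  if (isTRUE(config$demographics)) {
    out$sex <- sample(c("female", "male"), n, replace = TRUE,
                      prob = c(0.612, 0.388))
    age_bands <- c("50-54", "55-59", "60-64", "65-69", "70-74", "75-79", "80+")
    age_probs <- c(4.0, 7.8, 20.9, 14.3, 23.6, 17.0, 12.0)
    out$age_band <- sample(age_bands, n, replace = TRUE, prob = age_probs)
    occ <- c("routine", "semi-routine", "lower supervisory and technical",
             "small employers and own account")
    out$occupation <- sample(occ, n, replace = TRUE,
                             prob = c(26.8, 48.6, 22.8, 1.1))
  }

  df <- as.data.frame(out, stringsAsFactors = FALSE)

  if (config$missing_rate > 0) {
    model_cols <- setdiff(names(df), c("practice_id", "sex", "age_band",
                                       "occupation",
                                       paste0(names(cat_labels), "_level")))
    for (cn in model_cols) {
      hit <- stats::runif(n) < config$missing_rate
      df[[cn]][hit] <- NA
    }
  }

  attr(df, "truth") <- list(config = config, unrealized = unique(unrealized),
                            nodes = nodes)
  df
}
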