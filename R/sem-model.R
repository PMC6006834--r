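#' Construct a structural equation model from pattern matrices
#'
#' Represents a covariance-structure model in the standard all-y LISREL
#' parameterization: observed variables load on latent variables through
#' `Lambda`, latent variables are connected by directed paths in `B`
#' (row = dependent, column = predictor), `Psi` holds latent (co)variances
#' and disturbances, and `Theta` holds indicator residual (co)variances.
#' Observed variables that stand for themselves are promoted to degenerate
#' latents (loading 1, residual 0) by the higher-level builders.
#'
#' Pattern matrices use `NA` for a free parameter and a number for a fixed
#' value. Start values for free cells may be supplied through `start`
#' matrices of the same shape; unset starts default to 0 (paths and
#' covariances) or 1 (loadings) or 0.5 (variances).
#'
#' @param observed character vector of observed variable names (length p).
#' @param latents character vector of latent variable names (length m).
#' @param Lambda p x m pattern matrix of loadings.
#' @param B m x m pattern matrix of directed paths; must describe a
#'   recursive (acyclic) system.
#' @param Psi m x m symmetric pattern matrix of latent (co)variances.
#' @param Theta p x p symmetric pattern matrix of residual (co)variances.
#' @param start optional named list of start-value matrices
#'   (`Lambda`, `B`, `Psi`, `Theta`).
#' @param meta optional list of bookkeeping carried along (CMO structure).
#' @return An object of class `sem_model` with a parameter table
#'   (`$par_table`) indexing every free parameter.
#' @export
sem_model <- function(observed, latents, Lambda, B, Psi, Theta,
                      start = list(), meta = list()) {
  p <- length(observed)
  m <- length(latents)
  stopifnot(is.matrix(Lambda), nrow(Lambda) == p, ncol(Lambda) == m)
  stopifnot(is.matrix(B), nrow(B) == m, ncol(B) == m)
  stopifnot(is.matrix(Psi), nrow(Psi) == m, ncol(Psi) == m)
  stopifnot(is.matrix(Theta), nrow(Theta) == p, ncol(Theta) == p)
  if (anyDuplicated(observed)) stop("duplicate observed variable names")
  if (anyDuplicated(latents)) stop("duplicate latent variable names")

  check_sym_pattern <- function(M, name) {
    free <- is.na(M)
    if (!isTRUE(all(free == t(free))))
      stop(sprintf("%s free/fixed pattern is not symmetric", name))
    vals <- M; vals[free] <- 0
    if (!isTRUE(all.equal(vals, t(vals))))
      stop(sprintf("%s fixed values are not symmetric", name))
  }
  check_sym_pattern(Psi, "Psi")
  check_sym_pattern(Theta, "Theta")

  if (any(is.na(diag(B))) || any(diag(B) != 0))
    stop("B must have a zero, fixed diagonal")
  # recursive (acyclic) check on the support of B, free or fixed non-zero
  adj <- is.na(B) | B != 0
  if (has_cycle(adj)) stop("non-recursive model unsupported")

  dimnames(Lambda) <- list(observed, latents)
  dimnames(B) <- dimnames(Psi) <- list(latents, latents)
  dimnames(Theta) <- list(observed, observed)

  default_start <- function(M, kind) {
    s <- matrix(switch(kind, load = 1, path = 0, var = 0.5),
                nrow(M), ncol(M), dimnames = dimnames(M))
    if (kind == "var") s[row(M) != col(M)] <- 0
    s
  }
  st <- list(
    Lambda = if (!is.null(start$Lambda)) start$Lambda else default_start(Lambda, "load"),
    B      = if (!is.null(start$B))      start$B      else default_start(B, "path"),
    Psi    = if (!is.null(start$Psi))    start$Psi    else default_start(Psi, "var"),
    Theta  = if (!is.null(start$Theta))  start$Theta  else default_start(Theta, "var"))

  # enumerate free parameters; symmetric matrices use lower triangle
  rows <- list()
  add <- function(mat_name, M, S, sym, lab_fun) {
    idx <- which(is.na(M), arr.ind = TRUE)
    if (sym) idx <- idx[idx[, 1] >= idx[, 2], , drop = FALSE]
    if (nrow(idx) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      matrix = mat_name, row = idx[, 1], col = idx[, 2],
      label = lab_fun(idx), start = S[idx],
      stringsAsFactors = FALSE)
  }
  add("Lambda", Lambda, st$Lambda, FALSE,
      function(i) paste0(latents[i[, 2]], "=~", observed[i[, 1]]))
  add("B", B, st$B, FALSE,
      function(i) paste0(latents[i[, 1]], "~", latents[i[, 2]]))
  add("Psi", Psi, st$Psi, TRUE,
      function(i) paste0(latents[i[, 1]], "~~", latents[i[, 2]]))
  add("Theta", Theta, st$Theta, TRUE,
      function(i) paste0(observed[i[, 1]], "~~", observed[i[, 2]]))
  par_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(matrix = character(), row = integer(), col = integer(),
               label = character(), start = numeric())
  par_table$id <- seq_len(nrow(par_table))

  structure(list(observed = observed, latents = latents,
                 Lambda = Lambda, B = B, Psi = Psi, Theta = Theta,
                 par_table = par_table, q = nrow(par_table),
                 p = p, m = m, meta = meta),
            class = "sem_model")
}

has_cycle <- function(adj) {
  diag(adj) <- FALSE
  n <- nrow(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, n)
  repeat {
    leaf <- which(active & indeg == 0)
    if (!length(leaf)) break
    for (v in leaf) {
      active[v] <- FALSE
      indeg <- indeg - adj[v, ] * 1
    }
  }
  any(active)
}

#' @export
print.sem_model <- function(x, ...) {
  cat("sem_model: ", x$p, " observed, ", x$m, " latent, ",
      x$q, " free parameters, df = ", degrees_of_freedom(x), "\n", sep = "")
  if (!is.null(x$meta$cmos))
    cat("CMO configurations: ", length(x$meta$cmos), "\n", sep = "")
  invisible(x)
}

#' Expand a free-parameter vector into the four model matrices
#'
#' @param model a `sem_model`.
#' @param theta numeric vector of length `model$q`.
#' @return list with numeric matrices `Lambda`, `B`, `Psi`, `Theta`.
#' @keywords internal
sem_matrices <- function(model, theta) {
  stopifnot(length(theta) == model$q)
  L <- model$Lambda; B <- model$B; P <- model$Psi; Th <- model$Theta
  L[is.na(L)] <- 0; B[is.na(B)] <- 0; P[is.na(P)] <- 0; Th[is.na(Th)] <- 0
  pt <- model$par_table
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k]; j <- pt$col[k]; v <- theta[k]
    switch(pt$matrix[k],
      Lambda = { L[i, j] <- v },
      B      = { B[i, j] <- v },
      Psi    = { P[i, j] <- v; P[j, i] <- v },
      Theta  = { Th[i, j] <- v; Th[j, i] <- v })
  }
  list(Lambda = L, B = B, Psi = P, Theta = Th)
}

#' Model-implied covariance matrix
#'
#' Computes `Sigma(theta) = Lambda (I-B)^-1 Psi (I-B)^-T Lambda' + Theta`.
#'
#' @param theta free-parameter vector.
#' @param model a `sem_model`.
#' @return symmetric p x p matrix.
#' @export
model_implied_covariance <- function(theta, model) {
  mats <- sem_matrices(model, theta)
  IB <- diag(model$m) - mats$B
  G <- tryCatch(solve(IB), error = function(e)
    stop("structural matrix not invertible"))
  V <- G %*% mats$Psi %*% t(G)
  S <- mats$Lambda %*% V %*% t(mats$Lambda) + mats$Theta
  S <- (S + t(S)) / 2
  dimnames(S) <- list(model$observed, model$observed)
  S
}

#' Degrees of freedom of a model
#'
#' The counting rule `p(p+1)/2 - q`, the number of non-redundant sample
#' moments minus the number of free parameters.
#'
#' @param model a `sem_model`.
#' @return non-negative integer.
#' @export
degrees_of_freedom <- function(model) {
  pstar <- model$p * (model$p + 1) / 2
  if (model$q > pstar) stop("model not identified by counting rule")
  as.integer(pstar - model$q)
}
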