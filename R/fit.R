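# Maximum-likelihood covariance structure estimation.
#
# The discrepancy function is the standard ML fit function
#   F(theta) = ln|Sigma(theta)| + tr(S Sigma^-1) - ln|S| - p
# minimized over the free parameters. Gradients are analytic; the Hessian
# is obtained by central differences of the analytic gradient. Standard
# errors come from the observed information (naive) and from a cluster
# sandwich with cluster-summed casewise scores (robust).

#' Control options for [fit_ml()]
#'
#' @param max_iter maximum quasi-Newton iterations (default 500).
#' @param grad_tol convergence when the largest absolute element of the
#'   fit-function gradient falls below this (default 1e-6).
#' @param newton_iter maximum Newton polishing steps after the quasi-Newton
#'   stage (default 50).
#' @param improvement_tol secondary convergence criterion, in chi-square
#'   units: the fit is also declared converged when the achievable
#'   improvement of a full (eigenvalue-clamped) Newton step, `n/2 g'step`,
#'   falls below this (default 0.05, far below chi-square reporting
#'   precision), which happens along near-flat
#'   likelihood directions (e.g. weakly identified composite weights)
#'   where the gradient criterion is unattainable in double precision.
#' @param cluster_correction small-sample factor for the cluster
#'   sandwich: `"cr1"` (default) scales by `G/(G-1) (n-1)/(n-q)` as in
#'   Stata's clustered regression - without it the sandwich is measurably
#'   anti-conservative when the parameter count is non-trivial relative
#'   to the number of clusters; `"gg1"` applies `G/(G-1)` only; `"none"`
#'   disables the correction.
#' @return a list of class `fml_control`.
#' @export
fml_control <- function(max_iter = 500, grad_tol = 1e-6, newton_iter = 50,
                        improvement_tol = 0.05,
                        cluster_correction = c("cr1", "gg1", "none")) {
  cluster_correction <- match.arg(cluster_correction)
  structure(list(max_iter = max_iter, grad_tol = grad_tol,
                 newton_iter = newton_iter,
                 improvement_tol = improvement_tol,
                 cluster_correction = cluster_correction),
            class = "fml_control")
}

# log determinant via Cholesky; NULL if not positive definite
chol_logdet <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  list(logdet = 2 * sum(log(diag(ch))), chol = ch)
}

# tr(dSigma/dtheta_k %*% A) for every free parameter, A symmetric p x p
trace_forms <- function(model, mats, G, V, A) {
  pt <- model$par_table
  out <- numeric(model$q)
  LV <- mats$Lambda %*% V                 # p x m
  ALV <- A %*% LV                         # p x m
  N <- crossprod(mats$Lambda, A) %*% mats$Lambda  # m x m
  GNV <- crossprod(G, N) %*% V            # m x m
  GNG <- crossprod(G, N %*% G)            # m x m
  for (mt in unique(pt$matrix)) {
    k <- which(pt$matrix == mt)
    ij <- cbind(pt$row[k], pt$col[k])
    out[k] <- switch(mt,
      Lambda = 2 * ALV[ij],
      B      = 2 * GNV[ij],
      Psi    = GNG[ij] * ifelse(ij[, 1] == ij[, 2], 1, 2),
      Theta  = A[ij] * ifelse(ij[, 1] == ij[, 2], 1, 2))
  }
  out
}

# Sigma and helper matrices at theta; NULL when (I-B) singular
sigma_parts <- function(model, theta) {
  mats <- sem_matrices(model, theta)
  IB <- diag(model$m) - mats$B
  G <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(G)) return(NULL)
  V <- G %*% mats$Psi %*% t(G)
  Sigma <- mats$Lambda %*% V %*% t(mats$Lambda) + mats$Theta
  Sigma <- (Sigma + t(Sigma)) / 2
  list(mats = mats, G = G, V = V, Sigma = Sigma)
}

fml_value <- function(theta, model, S, logdetS) {
  sp <- sigma_parts(model, theta)
  if (is.null(sp)) return(1e10)
  ld <- chol_logdet(sp$Sigma)
  if (is.null(ld)) return(1e10 + sum(theta^2))  # keep finite, sloped
  Sigma_inv <- chol2inv(ld$chol)
  ld$logdet + sum(Sigma_inv * S) - logdetS - model$p
}

fml_gradient <- function(theta, model, S, logdetS) {
  sp <- sigma_parts(model, theta)
  if (is.null(sp)) return(rep(0, model$q))
  ld <- chol_logdet(sp$Sigma)
  if (is.null(ld)) return(rep(0, model$q))
  Sigma_inv <- chol2inv(ld$chol)
  A <- Sigma_inv - Sigma_inv %*% S %*% Sigma_inv
  A <- (A + t(A)) / 2
  trace_forms(model, sp$mats, sp$G, sp$V, A)
}

# central-difference Hessian of F from the analytic gradient
fml_hessian <- function(theta, model, S, logdetS, h = 1e-5) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (k in seq_len(q)) {
    hk <- h * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + hk
    tm <- theta; tm[k] <- tm[k] - hk
    H[, k] <- (fml_gradient(tp, model, S, logdetS) -
               fml_gradient(tm, model, S, logdetS)) / (2 * hk)
  }
  (H + t(H)) / 2
}

# data-informed start values following the documented rule: loadings 1,
# structural paths 0 (formative weights 1), residual and latent variances
# half the observed variance of the corresponding indicator, exogenous
# covariances of singleton concepts at their sample values.
start_values <- function(model, S) {
  pt <- model$par_table
  theta <- pt$start
  obs_var <- diag(S)
  degenerate <- intersect(model$latents, model$observed)
  ref_ind <- vapply(model$latents, function(l) {
    col <- model$Lambda[, l]
    fixed1 <- which(!is.na(col) & col == 1)
    if (length(fixed1)) model$observed[fixed1[1]] else NA_character_
  }, "")
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k]; j <- pt$col[k]
    if (pt$matrix[k] == "Theta" && i == j)
      theta[k] <- obs_var[i] / 2
    if (pt$matrix[k] == "Psi" && i == j) {
      l <- model$latents[i]
      if (l %in% degenerate) theta[k] <- obs_var[l]
      else if (!is.na(ref_ind[l]) && ref_ind[l] %in% model$observed)
        theta[k] <- obs_var[ref_ind[l]] / 2
    }
    if (pt$matrix[k] == "Psi" && i != j) {
      li <- model$latents[i]; lj <- model$latents[j]
      if (li %in% degenerate && lj %in% degenerate)
        theta[k] <- S[li, lj]
    }
  }
  theta
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML fit function for the covariance structure implied by
#' `model` over the sample covariance of `data` (divisor n). Ordinal
#' variables are expected as numeric codes (treated as continuous);
#' declared-categorical variables are refused. After convergence the
#' observed-information (naive) and cluster-robust sandwich covariance
#' matrices of the estimates are computed.
#'
#' Non-convergence is reported through the `converged` flag, not an error.
#' Negative estimated variances (Heywood cases) trigger a warning and are
#' retained.
#'
#' @param model a `sem_model`.
#' @param data a `clustered_dataset` whose variables cover
#'   `model$observed`.
#' @param control a [fml_control()] list.
#' @param se which standard errors to compute: `"both"` (default),
#'   `"naive"`, or `"none"`.
#' @return an object of class `sem_fit`.
#' @export
fit_ml <- function(model, data, control = fml_control(), se = "both") {
  stopifnot(inherits(model, "sem_model"), inherits(data, "clustered_dataset"))
  miss <- setdiff(model$observed, colnames(data$x))
  if (length(miss))
    stop(sprintf("model variables missing from data: %s",
                 paste(miss, collapse = ", ")))
  cat_vars <- names(data$scales)[data$scales == "categorical"]
  cat_used <- intersect(cat_vars, model$observed)
  if (length(cat_used))
    stop(sprintf(paste0("declared-categorical variables cannot enter the ",
                        "continuous-ML model: %s; recode as dummies or use ",
                        "the ordinal-as-continuous convention"),
                 paste(cat_used, collapse = ", ")))
  if (degrees_of_freedom(model) < 0) stop("negative degrees of freedom")

  x <- data$x[, model$observed, drop = FALSE]
  n <- nrow(x)
  S <- sample_covariance(x)
  ldS <- chol_logdet(S)
  if (is.null(ldS)) stop("sample covariance matrix not positive definite")
  logdetS <- ldS$logdet

  theta <- start_values(model, S)
  opt <- stats::optim(theta, fml_value, gr = fml_gradient,
                      model = model, S = S, logdetS = logdetS,
                      method = "BFGS",
                      control = list(maxit = control$max_iter,
                                     reltol = 1e-14,
                                     parscale = pmax(1, abs(theta))))
  theta <- opt$par
  g <- fml_gradient(theta, model, S, logdetS)
  # modified-Newton polish to drive the gradient to tolerance: clamp the
  # Hessian eigenvalues so the step is a descent direction even when the
  # quasi-Newton stage stops short of the optimum
  expected_improvement <- Inf
  for (it in seq_len(control$newton_iter)) {
    if (max(abs(g)) < control$grad_tol) break
    H <- fml_hessian(theta, model, S, logdetS)
    ev <- eigen(H, symmetric = TRUE)
    lam_min <- 1e-8 * max(abs(ev$values), 1e-8)
    step <- ev$vectors %*% ((crossprod(ev$vectors, g)) /
                              pmax(abs(ev$values), lam_min))
    step <- drop(step)
    expected_improvement <- n * sum(g * step) / 2
    # take the step (it is cheap), then stop if its predicted gain was
    # already immaterial: along near-flat likelihood directions the
    # gradient criterion is unattainable and the crawl must terminate
    if (max(abs(g)) < 1e-4) {
      # close to the optimum the fit-function differences fall below
      # floating-point noise; backtrack on the gradient norm instead
      g0 <- max(abs(g)); lam <- 1; accepted <- FALSE
      repeat {
        cand <- theta - lam * step
        g1 <- fml_gradient(cand, model, S, logdetS)
        if (max(abs(g1)) < g0) { accepted <- TRUE; break }
        lam <- lam / 2
        if (lam < 1e-6) break
      }
      if (accepted) { theta <- cand; g <- g1 }
      if (!accepted || expected_improvement < control$improvement_tol)
        break
      next
    }
    f0 <- fml_value(theta, model, S, logdetS)
    lam <- 1
    repeat {
      cand <- theta - lam * step
      f1 <- fml_value(cand, model, S, logdetS)
      if (f1 <= f0 + 1e-12 || lam < 1e-10) break
      lam <- lam / 2
    }
    if (f1 > f0) break
    theta <- cand
    g <- fml_gradient(theta, model, S, logdetS)
    if (expected_improvement < control$improvement_tol) break
  }
  grad_norm <- max(abs(g))
  criterion <- if (grad_norm < control$grad_tol) "gradient"
    else if (expected_improvement < control$improvement_tol) "improvement"
    else NA_character_
  converged <- !is.na(criterion)
  if (!converged)
    warning(sprintf("fit_ml did not converge (max |gradient| = %.2e)",
                    grad_norm))
  F_min <- fml_value(theta, model, S, logdetS)

  mats <- sem_matrices(model, theta)
  heywood <- any(diag(mats$Psi) < 0) || any(diag(mats$Theta) < 0)
  if (heywood)
    warning("Heywood case: negative estimated variance retained")

  names(theta) <- model$par_table$label
  fit <- structure(list(model = model, theta_hat = theta, F_min = F_min,
                        sample_cov = S, n = n, converged = converged,
                        criterion = criterion,
                        gradient_norm = grad_norm, heywood = heywood,
                        cluster = data$cluster,
                        Sigma_hat = model_implied_covariance(theta, model),
                        logdetS = logdetS,
                        control = control,
                        vcov_naive = NULL, vcov_robust = NULL,
                        naive_se = NULL, robust_se = NULL),
                   class = "sem_fit")
  if (se %in% c("both", "naive") && converged) {
    H <- fml_hessian(theta, model, S, logdetS)
    fit$hessian <- H
    fit$vcov_naive <- naive_vcov(fit, on_singular = "clamp")
    fit$naive_se <- sqrt(pmax(diag(fit$vcov_naive), 0))
    if (se == "both" && nlevels(droplevels(data$cluster)) >= 2) {
      fit$vcov_robust <- cluster_robust_vcov(fit, data = data)
      fit$robust_se <- sqrt(pmax(diag(fit$vcov_robust), 0))
    }
  }
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("sem_fit: q = ", x$model$q, ", n = ", x$n,
      ", F_min = ", format(x$F_min, digits = 6),
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Naive (observed-information) covariance of the estimates
#'
#' The inverse of the Hessian of the total log-likelihood, i.e.
#' `(2/n) H_F^{-1}` where `H_F` is the Hessian of the ML fit function at
#' the optimum.
#'
#' @param fit a converged `sem_fit`.
#' @param on_singular `"error"` (default) stops with the offending
#'   parameter named when the information matrix is numerically singular;
#'   `"clamp"` floors the near-zero eigenvalues instead, which yields very
#'   large (honest) variances along weakly identified directions, and
#'   warns.
#' @return symmetric q x q matrix.
#' @export
naive_vcov <- function(fit, on_singular = c("error", "clamp")) {
  stopifnot(inherits(fit, "sem_fit"))
  on_singular <- match.arg(on_singular)
  if (!fit$converged) stop("naive_vcov requires a converged fit")
  H <- fit$hessian
  if (is.null(H))
    H <- fml_hessian(unname(fit$theta_hat), fit$model, fit$sample_cov,
                     fit$logdetS)
  ev <- eigen(H, symmetric = TRUE)
  floor_ev <- 1e-10 * max(abs(ev$values))
  if (any(ev$values < floor_ev)) {
    bad <- which.min(ev$values)
    culprit <- fit$model$par_table$label[which.max(abs(ev$vectors[, bad]))]
    if (on_singular == "error")
      stop(sprintf("parameter not locally identified: %s", culprit))
    warning(sprintf(paste0("near-singular information matrix; standard ",
                           "errors along weakly identified directions ",
                           "(e.g. %s) are unreliable"), culprit))
  }
  vals <- pmax(ev$values, floor_ev)
  Vc <- (2 / fit$n) * ev$vectors %*% (t(ev$vectors) / vals)
  Vc <- (Vc + t(Vc)) / 2
  dimnames(Vc) <- list(fit$model$par_table$label, fit$model$par_table$label)
  Vc
}

# casewise score matrix (n x q) of the log-likelihood at theta_hat
casewise_scores <- function(fit, x) {
  model <- fit$model
  sp <- sigma_parts(model, unname(fit$theta_hat))
  ld <- chol_logdet(sp$Sigma)
  Sigma_inv <- chol2inv(ld$chol)
  P1 <- Sigma_inv
  LV <- sp$mats$Lambda %*% sp$V
  LG <- sp$mats$Lambda %*% sp$G
  P2 <- Sigma_inv %*% LV
  P3 <- Sigma_inv %*% LG
  Z <- sweep(x, 2, colMeans(x))
  ZP1 <- Z %*% P1
  ZP2 <- Z %*% P2
  ZP3 <- Z %*% P3
  t0 <- trace_forms(model, sp$mats, sp$G, sp$V, Sigma_inv)
  pt <- model$par_table
  n <- nrow(Z)
  scores <- matrix(0, n, model$q)
  for (k in seq_len(model$q)) {
    i <- pt$row[k]; j <- pt$col[k]
    qk <- switch(pt$matrix[k],
      Lambda = 2 * ZP1[, i] * ZP2[, j],
      B      = 2 * ZP3[, i] * ZP2[, j],
      Psi    = if (i == j) ZP3[, i]^2 else 2 * ZP3[, i] * ZP3[, j],
      Theta  = if (i == j) ZP1[, i]^2 else 2 * ZP1[, i] * ZP1[, j])
    scores[, k] <- 0.5 * qk - 0.5 * t0[k]
  }
  scores
}

#' Cluster-robust (sandwich) covariance of the estimates
#'
#' `A^-1 B A^-1` where `A` is the observed information of the total
#' log-likelihood and `B` the outer product of cluster-summed casewise
#' score vectors. With every cluster of size 1 (and no correction) this
#' reduces to the HC0-type heteroskedasticity-robust sandwich.
#'
#' @param fit a converged `sem_fit`.
#' @param data the `clustered_dataset` the model was fitted to.
#' @param cluster_correction `"cr1"`, `"gg1"` or `"none"` (see
#'   [fml_control()]); defaults to the fit's control setting.
#' @return symmetric q x q matrix.
#' @export
cluster_robust_vcov <- function(fit, data,
                                cluster_correction =
                                  fit$control$cluster_correction) {
  stopifnot(inherits(fit, "sem_fit"), inherits(data, "clustered_dataset"))
  if (!fit$converged) stop("cluster_robust_vcov requires a converged fit")
  cl <- droplevels(data$cluster)
  G <- nlevels(cl)
  if (G < 2) stop("clustered variance undefined: a single cluster")
  x <- data$x[, fit$model$observed, drop = FALSE]
  scores <- casewise_scores(fit, x)
  Sg <- rowsum(scores, cl, reorder = FALSE)
  meat <- crossprod(Sg)
  H <- fit$hessian
  if (is.null(H))
    H <- fml_hessian(unname(fit$theta_hat), fit$model, fit$sample_cov,
                     fit$logdetS)
  A <- (fit$n / 2) * H
  ev <- eigen(A, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-10 * max(abs(ev$values)))
  Ainv <- ev$vectors %*% (t(ev$vectors) / vals)
  Vc <- Ainv %*% meat %*% Ainv
  n <- fit$n; q <- fit$model$q
  corr <- switch(cluster_correction,
                 cr1 = G / (G - 1) * (n - 1) / max(n - q, 1),
                 gg1 = G / (G - 1),
                 none = 1)
  Vc <- Vc * corr
  Vc <- (Vc + t(Vc)) / 2
  dimnames(Vc) <- list(fit$model$par_table$label, fit$model$par_table$label)
  Vc
}
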