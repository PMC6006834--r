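# Measurement models: one-factor confirmatory fits, pruning of
# non-contributing indicators, and score-test modification indices.

one_factor_model <- function(binding) {
  ind <- binding$indicators
  p <- length(ind)
  Lambda <- matrix(NA_real_, p, 1)
  Lambda[1, 1] <- 1
  Theta <- diag(NA_real_, p)
  sem_model(ind, binding$concept_name, Lambda,
            B = matrix(0, 1, 1), Psi = matrix(NA_real_, 1, 1),
            Theta = Theta, meta = list(binding = binding))
}

#' Fit a one-factor measurement model
#'
#' Fits the reflective binding as a single-factor confirmatory model
#' (reference loading fixed to 1, free factor variance) and reports each
#' indicator's loading with its standard error, z statistic and two-sided
#' p value. Cluster-robust standard errors are used when the data carry
#' two or more clusters, mirroring a clustered analysis; otherwise naive
#' ones.
#'
#' @param binding a reflective `concept_binding` with at least 3
#'   indicators (a 2-indicator factor is only identified inside a larger
#'   model).
#' @param data a `clustered_dataset`.
#' @param control a [fml_control()].
#' @return an object of class `cfa_fit` with the underlying `sem_fit`, a
#'   per-indicator `loadings` table and a `retained` flag per indicator.
#' @export
fit_cfa <- function(binding, data, control = fml_control()) {
  stopifnot(inherits(binding, "concept_binding"))
  if (binding$mode != "reflective")
    stop("fit_cfa requires a reflective binding")
  if (length(binding$indicators) < 3L)
    stop("a standalone one-factor model needs at least 3 indicators")
  model <- one_factor_model(binding)
  fit <- suppressWarnings(fit_ml(model, data, control = control))
  se_type <- if (!is.null(fit$robust_se)) "robust" else "naive"
  ses <- if (se_type == "robust") fit$robust_se else fit$naive_se
  ind <- binding$indicators
  load <- est_se <- rep(NA_real_, length(ind))
  names(load) <- names(est_se) <- ind
  load[1] <- 1                       # reference, fixed
  pt <- fit$model$par_table
  for (k in which(pt$matrix == "Lambda")) {
    v <- fit$model$observed[pt$row[k]]
    load[v] <- fit$theta_hat[k]
    if (!is.null(ses)) est_se[v] <- ses[k]
  }
  z <- load / est_se
  tab <- data.frame(indicator = ind, loading = load, se = est_se, z = z,
                    pvalue = 2 * stats::pnorm(-abs(z)),
                    reference = ind == binding$reference,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(binding = binding, fit = fit, loadings = tab,
                 retained = stats::setNames(rep(TRUE, length(ind)), ind),
                 se_type = se_type, data = data, control = control),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, digits = 3, ...) {
  cat("cfa_fit for concept '", x$binding$concept_name, "' (",
      x$se_type, " SEs), converged = ", x$fit$converged, "\n", sep = "")
  tab <- x$loadings
  tab[c("loading", "se", "z", "pvalue")] <-
    lapply(tab[c("loading", "se", "z", "pvalue")], round, digits)
  print(tab, ...)
  invisible(x)
}

#' Remove indicators that do not contribute to a latent variable
#'
#' Backward pruning: while any non-reference indicator has p >= alpha
#' (the convention is p < alpha to retain, so a p exactly at alpha is
#' removed), the one with the largest p is dropped and the factor model
#' refitted. Stops when all retained indicators are significant or when
#' removal would leave fewer than 2 indicators, in which case a warning is
#' issued and the minimal binding returned.
#'
#' @param mfit a `cfa_fit` from [fit_cfa()].
#' @param alpha significance level in (0, 1), default 0.05.
#' @return the pruned `concept_binding`.
#' @export
prune_indicators <- function(mfit, alpha = 0.05) {
  stopifnot(inherits(mfit, "cfa_fit"), alpha > 0, alpha < 1)
  binding <- mfit$binding
  current <- mfit
  repeat {
    tab <- current$loadings
    cand <- tab[!tab$reference & !is.na(tab$pvalue) & tab$pvalue >= alpha, ]
    if (nrow(cand) == 0L) return(current$binding)
    worst <- cand$indicator[which.max(cand$pvalue)]
    kept <- setdiff(current$binding$indicators, worst)
    if (length(kept) < 2L) {
      warning("pruning would leave fewer than 2 indicators; ",
              "returning minimal binding")
      return(current$binding)
    }
    binding <- concept_binding(binding$concept_name, "reflective",
                               kept, reference = binding$reference)
    if (length(kept) == 2L) {
      warning("pruned to 2 indicators; identified only inside a larger model")
      return(binding)
    }
    current <- fit_cfa(binding, mfit$data, control = mfit$control)
  }
}

#' Modification indices for fixed residual covariances
#'
#' For each candidate fixed entry of `Theta` the univariate score-test
#' statistic (1 df) for freeing it, together with the expected parameter
#' change. The statistic approximates the chi-square drop that refitting
#' with the parameter freed would achieve. Candidates that are already
#' free are skipped with a warning. Only residual covariances are
#' considered, the one modification type a measurement model typically
#' admits on theoretical grounds.
#'
#' @param fit a converged `sem_fit`.
#' @param candidates list of 2-element character vectors naming indicator
#'   pairs.
#' @return data frame with columns `parameter`, `mi`, `epc`, sorted by
#'   `mi` descending.
#' @export
modification_indices <- function(fit, candidates) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("modification_indices requires a converged fit")
  model <- fit$model
  rows <- list()
  for (pr in candidates) {
    if (length(pr) != 2L || !all(pr %in% model$observed))
      stop("each candidate must name 2 declared indicators")
    i <- match(pr[1], model$observed); j <- match(pr[2], model$observed)
    if (is.na(model$Theta[i, j])) {
      warning(sprintf("candidate %s~~%s already free; skipped",
                      pr[1], pr[2]))
      next
    }
    aug <- model
    aug$Theta[i, j] <- aug$Theta[j, i] <- NA_real_
    aug <- sem_model(model$observed, model$latents, aug$Lambda, aug$B,
                     aug$Psi, aug$Theta, meta = model$meta)
    theta_aug <- aug$par_table$start
    idx <- match(model$par_table$label, aug$par_table$label)
    theta_aug[idx] <- unname(fit$theta_hat)
    lab_c <- paste0(model$observed[max(i, j)], "~~",
                    model$observed[min(i, j)])
    kc <- match(lab_c, aug$par_table$label)
    if (is.na(kc))  # label order depends on row/col
      kc <- setdiff(seq_len(aug$q), idx)
    theta_aug[kc] <- model$Theta[i, j]

    gF <- fml_gradient(theta_aug, aug, fit$sample_cov, fit$logdetS)
    HF <- fml_hessian(theta_aug, aug, fit$sample_cov, fit$logdetS)
    info <- (fit$n / 2) * HF
    s <- -(fit$n / 2) * gF
    Iinv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(Iinv)) next
    mi <- s[kc]^2 * Iinv[kc, kc]
    epc <- (Iinv %*% s)[kc]
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0(pr[1], "~~", pr[2]), mi = mi, epc = epc,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(), mi = numeric(), epc = numeric())
  out[order(-out$mi), , drop = FALSE]
}
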