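# Model fit assessment: chi-square against the independence baseline,
# RMSEA, CFI and TLI with the conventional good-fit thresholds
# (RMSEA < 0.06, CFI > 0.95, TLI > 0.95).

#' Independence (baseline) model fit
#'
#' The baseline frees every variance and fixes all covariances to zero;
#' its ML solution is the diagonal of the sample covariance, so the
#' minimized fit function is `-ln|R|` with `R` the sample correlation
#' matrix. The chi-square convention is `T = (n-1) F`.
#'
#' @param data a `clustered_dataset`, numeric matrix, or a sample
#'   covariance matrix (then `n` must be given).
#' @param n sample size when `data` is already a covariance matrix.
#' @return list with `T_baseline`, `df_baseline`, `F_baseline`, `n`.
#' @export
baseline_fit <- function(data, n = NULL) {
  if (inherits(data, "clustered_dataset")) {
    S <- sample_covariance(data)
    n <- data$n
  } else if (is.matrix(data) && !is.null(n)) {
    S <- data                      # already a covariance matrix
  } else {
    S <- sample_covariance(data)
    n <- nrow(data)
  }
  p <- ncol(S)
  R <- stats::cov2cor(S)
  ld <- chol_logdet(R)
  if (is.null(ld)) stop("sample covariance matrix not positive definite")
  F_b <- -ld$logdet
  list(T_baseline = (n - 1) * F_b, df_baseline = p * (p - 1) / 2,
       F_baseline = F_b, n = n)
}

#' RMSEA, CFI and TLI from chi-square statistics
#'
#' \itemize{
#'   \item `RMSEA = sqrt(max(T - df, 0) / (df (n-1)))`, the per-degree-of-
#'     freedom misfit, using the `(n-1)` denominator consistent with
#'     `T = (n-1) F`.
#'   \item `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`.
#'   \item `TLI = ((T_b/df_b) - (T/df)) / ((T_b/df_b) - 1)`, reported
#'     uncapped by default (may exceed 1 for well-fitting models).
#' }
#' Verdicts use the strict thresholds RMSEA < 0.06 and CFI, TLI > 0.95.
#'
#' @param T chi-square statistic of the fitted model.
#' @param df its degrees of freedom (>= 1; with df = 0 the indices are
#'   undefined and returned as `NA` with an explanation).
#' @param T_baseline,df_baseline independence-model statistic and df.
#' @param n sample size (> 1).
#' @param cap_tli cap TLI at 1 (default FALSE).
#' @return object of class `sem_fit_indices`.
#' @export
compute_indices <- function(T, df, T_baseline, df_baseline, n,
                            cap_tli = FALSE) {
  stopifnot(n > 1)
  if (df < 1) {
    out <- list(T = T, df = df, T_baseline = T_baseline,
                df_baseline = df_baseline, n = n,
                rmsea = NA_real_, cfi = NA_real_, tli = NA_real_,
                note = "df = 0: a just-identified model has no testable misfit",
                verdicts = c(rmsea = NA, cfi = NA, tli = NA))
    class(out) <- "sem_fit_indices"
    return(out)
  }
  excess <- max(T - df, 0)
  rmsea <- sqrt(excess / (df * (n - 1)))
  denom <- max(T_baseline - df_baseline, T - df, 0)
  cfi <- if (denom > 0) 1 - excess / denom else 1
  tli <- ((T_baseline / df_baseline) - (T / df)) /
    ((T_baseline / df_baseline) - 1)
  if (cap_tli) tli <- min(tli, 1)
  out <- list(T = T, df = df, T_baseline = T_baseline,
              df_baseline = df_baseline, n = n,
              rmsea = rmsea, cfi = cfi, tli = tli, note = NULL,
              verdicts = c(rmsea = rmsea < 0.06, cfi = cfi > 0.95,
                           tli = tli > 0.95))
  class(out) <- "sem_fit_indices"
  out
}

#' Fit indices for a fitted model
#'
#' Convenience wrapper: `T = (n-1) F_min`, degrees of freedom from the
#' model, and the independence baseline from the fit's own sample
#' covariance. The chi-square statistic itself is the plain (unscaled) ML
#' statistic even when robust standard errors are in use; no scaled-test
#' correction is applied.
#'
#' @param fit a converged `sem_fit`.
#' @param cap_tli cap TLI at 1.
#' @return object of class `sem_fit_indices`.
#' @export
fit_indices <- function(fit, cap_tli = FALSE) {
  stopifnot(inherits(fit, "sem_fit"))
  base <- baseline_fit(fit$sample_cov, n = fit$n)
  compute_indices(T = (fit$n - 1) * fit$F_min,
                  df = degrees_of_freedom(fit$model),
                  T_baseline = base$T_baseline,
                  df_baseline = base$df_baseline,
                  n = fit$n, cap_tli = cap_tli)
}

#' @export
print.sem_fit_indices <- function(x, digits = 3, ...) {
  cat("chi-square T = ", format(x$T, digits = 6), " on df = ", x$df,
      " (baseline T = ", format(x$T_baseline, digits = 6),
      ", df = ", x$df_baseline, ")\n", sep = "")
  if (!is.null(x$note)) cat(x$note, "\n")
  else
    cat(sprintf("RMSEA = %.*f (<0.06: %s)  CFI = %.*f (>0.95: %s)  TLI = %.*f (>0.95: %s)\n",
                digits, x$rmsea, ifelse(x$verdicts["rmsea"], "good", "not good"),
                digits, x$cfi, ifelse(x$verdicts["cfi"], "good", "not good"),
                digits, x$tli, ifelse(x$verdicts["tli"], "good", "not good")))
  invisible(x)
}
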