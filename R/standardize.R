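# Standardization of estimates by model-implied latent and observed
# variances, with delta-method standard errors.

# rows of the standardized table: all loadings and structural paths that
# are free or fixed non-zero
std_cells <- function(model) {
  pt <- model$par_table
  cells <- pt[pt$matrix %in% c("Lambda", "B"),
              c("matrix", "row", "col", "label", "id")]
  fixed <- list()
  Lf <- which(!is.na(model$Lambda) & model$Lambda != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(Lf)))
    fixed[[length(fixed) + 1L]] <- data.frame(
      matrix = "Lambda", row = Lf[k, 1], col = Lf[k, 2],
      label = paste0(model$latents[Lf[k, 2]], "=~",
                     model$observed[Lf[k, 1]]), id = NA_integer_)
  Bf <- which(!is.na(model$B) & model$B != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(Bf)))
    fixed[[length(fixed) + 1L]] <- data.frame(
      matrix = "B", row = Bf[k, 1], col = Bf[k, 2],
      label = paste0(model$latents[Bf[k, 1]], "~",
                     model$latents[Bf[k, 2]]), id = NA_integer_)
  if (length(fixed)) cells <- rbind(cells, do.call(rbind, fixed))
  cells
}

std_vector <- function(theta, model, cells) {
  sp <- sigma_parts(model, theta)
  sd_lat <- sqrt(pmax(diag(sp$V), 0))
  sd_obs <- sqrt(pmax(diag(sp$Sigma), 0))
  if (any(sd_lat == 0) || any(sd_obs == 0))
    stop("zero model-implied variance; cannot standardize")
  vals <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    i <- cells$row[k]; j <- cells$col[k]
    vals[k] <- if (cells$matrix[k] == "Lambda")
      sp$mats$Lambda[i, j] * sd_lat[j] / sd_obs[i]
    else
      sp$mats$B[i, j] * sd_lat[j] / sd_lat[i]
  }
  vals
}

#' Standardized coefficients with delta-method standard errors
#'
#' Standardizes every loading and structural path by the model-implied
#' standard deviations of its predictor and dependent variable (latent
#' variances for latent-level paths, observed variances for indicators),
#' so a coefficient reads as the change in the dependent variable, in
#' standard deviation units, per standard deviation of the predictor.
#' Standard errors are propagated from the parameter covariance matrix by
#' the delta method (numeric Jacobian of the standardization map).
#'
#' @param fit a converged `sem_fit`.
#' @param se `"robust"` (cluster sandwich, default when available) or
#'   `"naive"`.
#' @param level confidence level for the normal-theory intervals.
#' @return a data frame of class `sem_std` with columns `label`, `est`
#'   (unstandardized), `std`, `se`, `z`, `pvalue`, `ci_lower`, `ci_upper`;
#'   the full covariance matrix of the standardized estimates is attached
#'   as attribute `"vcov_std"`.
#' @export
standardize <- function(fit, se = c("robust", "naive"), level = 0.95) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("standardize requires a converged fit")
  se <- match.arg(se)
  V <- if (se == "robust" && !is.null(fit$vcov_robust)) fit$vcov_robust
       else fit$vcov_naive
  if (is.null(V)) stop("fit carries no parameter covariance matrix")
  model <- fit$model
  cells <- std_cells(model)
  theta <- unname(fit$theta_hat)
  std <- std_vector(theta, model, cells)

  # numeric Jacobian of the standardization map
  J <- matrix(0, nrow(cells), model$q)
  for (k in seq_len(model$q)) {
    h <- 1e-6 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    J[, k] <- (std_vector(tp, model, cells) -
               std_vector(tm, model, cells)) / (2 * h)
  }
  vcov_std <- J %*% V %*% t(J)
  vcov_std <- (vcov_std + t(vcov_std)) / 2
  dimnames(vcov_std) <- list(cells$label, cells$label)

  ses <- sqrt(pmax(diag(vcov_std), 0))
  est <- ifelse(is.na(cells$id), NA_real_, theta[cells$id])
  fixed_cell <- is.na(cells$id)
  # fixed parameters carry no sampling variance of their own, but their
  # standardized value does (through the variances); keep the delta SE
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  z <- ifelse(ses > 0, std / ses, NA_real_)
  out <- data.frame(label = cells$label, matrix = cells$matrix,
                    row = cells$row, col = cells$col,
                    free = !fixed_cell,
                    est = ifelse(fixed_cell,
                                 vapply(seq_len(nrow(cells)), function(k) {
                                   if (cells$matrix[k] == "Lambda")
                                     model$Lambda[cells$row[k], cells$col[k]]
                                   else model$B[cells$row[k], cells$col[k]]
                                 }, 0), est),
                    std = std, se = ses, z = z,
                    pvalue = 2 * stats::pnorm(-abs(z)),
                    ci_lower = std - zcrit * ses,
                    ci_upper = std + zcrit * ses,
                    stringsAsFactors = FALSE)
  attr(out, "vcov_std") <- vcov_std
  attr(out, "se_type") <- se
  attr(out, "level") <- level
  class(out) <- c("sem_std", "data.frame")
  out
}
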