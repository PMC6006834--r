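# Decomposition of CMO configurations into standardized direct and
# indirect effects with delta-method intervals and proportion mediated.

#' Indirect effect of a context on the outcome via its mechanism
#'
#' The product of the context-to-mechanism and mechanism-to-outcome
#' coefficients, with a delta-method standard error
#' `sqrt(b^2 var(a) + a^2 var(b) + 2ab cov(a,b))` and a normal-theory
#' confidence interval.
#'
#' @param a context-to-mechanism coefficient.
#' @param b mechanism-to-outcome coefficient.
#' @param vcov_ab 2x2 covariance matrix of `(a, b)`; if the covariance
#'   term is missing (`NA`) it is set to 0 with a warning.
#' @param level confidence level (default 0.95).
#' @return list with `estimate`, `se`, `ci_lower`, `ci_upper`.
#' @export
indirect_effect <- function(a, b, vcov_ab, level = 0.95) {
  stopifnot(is.matrix(vcov_ab), all(dim(vcov_ab) == c(2, 2)))
  if (is.na(vcov_ab[1, 2])) {
    warning("missing cov(a, b); computed with cov = 0")
    vcov_ab[1, 2] <- vcov_ab[2, 1] <- 0
  }
  est <- a * b
  se <- sqrt(max(b^2 * vcov_ab[1, 1] + a^2 * vcov_ab[2, 2] +
                   2 * a * b * vcov_ab[1, 2], 0))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se,
       ci_lower = est - zc * se, ci_upper = est + zc * se)
}

#' Proportion of the total effect carried by the mechanism
#'
#' The magnitude convention `|indirect| / (|direct| + |indirect|)`:
#' denominators use absolute values so the proportion stays in `[0, 1]`
#' even when direct and indirect effects have opposite signs.
#'
#' @param direct direct-effect estimate.
#' @param indirect indirect-effect estimate.
#' @return fraction in `[0, 1]`; `NA` when both effects are zero.
#' @export
proportion_mediated <- function(direct, indirect) {
  if (direct == 0 && indirect == 0) return(NA_real_)
  abs(indirect) / (abs(direct) + abs(indirect))
}

#' Decompose every CMO configuration of a fitted model
#'
#' For each CMO compiled into the model (one row per context node, so a
#' categorical context yields one row per dummy) the standardized
#' context-to-mechanism coefficient `a`, mechanism-to-outcome coefficient
#' `b`, direct effect, indirect effect `a*b`, total effect, delta-method
#' standard errors, confidence intervals, proportion mediated and
#' significance flags (interval excluding zero).
#'
#' @param fit a converged `sem_fit` from a model built by
#'   [build_sem_from_cmos()].
#' @param std optionally a precomputed [standardize()] table.
#' @param level confidence level.
#' @param se passed to [standardize()] when `std` is not supplied.
#' @return a data frame of class `cmo_effects`, one row per
#'   (CMO, context node).
#' @export
decompose_all <- function(fit, std = NULL, level = 0.95,
                          se = c("robust", "naive")) {
  stopifnot(inherits(fit, "sem_fit"))
  cmos <- fit$model$meta$cmos
  if (is.null(cmos))
    stop("model carries no CMO structure; build it with build_sem_from_cmos")
  se <- match.arg(se)
  if (is.null(std)) std <- standardize(fit, se = se, level = level)
  Vs <- attr(std, "vcov_std")
  zc <- stats::qnorm(1 - (1 - level) / 2)

  row_of <- function(lhs, rhs) {
    lab <- paste0(lhs, "~", rhs)
    k <- match(lab, std$label)
    if (is.na(k)) stop(sprintf("CMO path missing from model: %s", lab))
    k
  }
  concepts <- fit$model$meta$concepts
  rows <- list()
  for (cm in cmos) {
    kb <- row_of(cm$outcome, cm$mechanism)
    # Significance flags for effects of a formative composite use a
    # selection-adjusted critical value, chi-square with df = number of
    # composite indicators: the fitted weights pick the indicator
    # direction most associated with the outcomes, so the usual 1-df
    # reference is anti-conservative when the composite's paths are null.
    # Reported confidence intervals stay normal-theory (unadjusted).
    ctx_binding <- concepts[[cm$context]]
    zflag <- if (!is.null(ctx_binding) && ctx_binding$mode == "formative")
      sqrt(stats::qchisq(level, df = length(ctx_binding$indicators)))
    else zc
    for (cnode in cm$context_nodes) {
      ka <- row_of(cm$mechanism, cnode)
      a <- std$std[ka]; b <- std$std[kb]
      vab <- Vs[c(ka, kb), c(ka, kb)]
      ind <- indirect_effect(a, b, vab, level = level)
      if (cm$direct) {
        kd <- row_of(cm$outcome, cnode)
        direct <- std$std[kd]; d_se <- std$se[kd]
      } else {
        direct <- 0; d_se <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cmo = cm$label, context = cm$context, context_node = cnode,
        mechanism = cm$mechanism, outcome = cm$outcome,
        a = a, b = b,
        direct = direct, direct_se = d_se,
        direct_ci_lower = direct - zc * d_se,
        direct_ci_upper = direct + zc * d_se,
        indirect = ind$estimate, indirect_se = ind$se,
        indirect_ci_lower = ind$ci_lower, indirect_ci_upper = ind$ci_upper,
        total = direct + ind$estimate,
        proportion_mediated = proportion_mediated(direct, ind$estimate),
        direct_significant = !is.na(d_se) && d_se > 0 &&
          abs(direct) / d_se > zflag,
        indirect_significant = ind$se > 0 &&
          abs(ind$estimate) / ind$se > zflag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("cmo_effects", "data.frame")
  out
}

#' @export
print.cmo_effects <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  print(df[c("cmo", "context_node", "direct", "direct_ci_lower",
             "direct_ci_upper", "indirect", "indirect_ci_lower",
             "indirect_ci_upper", "proportion_mediated")], ...)
  invisible(x)
}
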