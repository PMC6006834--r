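test_that("sample covariance uses divisor n and flags degenerate input", {
  x <- c(1, 2, 4, 7)
  df <- data.frame(a = x, b = x, c = -x, cl = 1:4)
  d <- clustered_dataset(df, "cl")
  S <- sample_covariance(d)
  v <- mean((x - mean(x))^2)              # divisor n by hand
  expect_equal(S["a", "a"], v)
  expect_equal(S["a", "b"], v)            # identical columns
  expect_equal(S["a", "c"], -v)           # negated column
  expect_identical(attr(S, "divisor"), "n")
  # hand-computed 3-variable fixture by brute-force summation
  y <- c(0, 3, 3, 6); z <- c(2, 2, 5, 5)
  S2 <- sample_covariance(cbind(x = x, y = y, z = z))
  expect_equal(S2["x", "y"], sum((x - mean(x)) * (y - mean(y))) / 4)
  expect_equal(S2["y", "z"], sum((y - mean(y)) * (z - mean(z))) / 4)
  expect_error(sample_covariance(cbind(x = x, k = rep(1, 4))), "k")
})

test_that("model-implied covariance reduces and composes correctly", {
  # Lambda = I, B = 0, Theta = 0 => Sigma = Psi
  m <- sem_model(c("a", "b"), c("a", "b"), diag(1, 2), matrix(0, 2, 2),
                 matrix(NA_real_, 2, 2), matrix(0, 2, 2))
  Psi <- c(1.3, 0.4, 0.9)                 # a~~a, b~~a, b~~b (lower tri)
  Sig <- model_implied_covariance(Psi, m)
  expect_equal(unname(Sig), matrix(c(1.3, 0.4, 0.4, 0.9), 2, 2))
  # single path y = 0.5 x, var(x) = 1, disturbance 0.75
  mr <- regression_model()
  th <- c(0.5, 1, 0.75)                   # y~x, x~~x, y~~y order by table
  th <- th[match(c("y~x", "x~~x", "y~~y"), mr$par_table$label)]
  Sig2 <- model_implied_covariance(th, mr)
  expect_equal(unname(Sig2), matrix(c(1, .5, .5, 1), 2, 2))
  # symmetry for random admissible parameter vectors
  set.seed(42)
  m9 <- access_model()
  for (i in 1:5) {
    theta <- m9$par_table$start + runif(m9$q, -0.3, 0.3)
    Sig9 <- model_implied_covariance(theta, m9)
    expect_lt(max(abs(Sig9 - t(Sig9))), 1e-12)
  }
})

test_that("a singular structural matrix is reported", {
  B <- matrix(0, 2, 2); B[1, 2] <- 1; B[2, 1] <- 1  # fixed non-zero cycle
  expect_error(sem_model(c("a", "b"), c("a", "b"), diag(1, 2), B,
                         diag(NA_real_, 2), matrix(0, 2, 2)),
               "non-recursive")
})

test_that("the factor triad solves to its closed form", {
  d <- data_with_cov(triad_cov(), n = 400, seed = 1,
                     clusters = rep(1:40, each = 10))
  fit <- fit_ml(triad_model(), d)
  expect_true(fit$converged)
  # closed-form triad solution: lambda1 = sqrt(s12 s13 / s23)
  expect_equal(unname(fit$theta_hat["f=~x1"]), sqrt(.6 * .5 / .48),
               tolerance = 1e-6)
  expect_equal(fit$F_min, 0, tolerance = 1e-8)  # just-identified
})

test_that("a saturated model attains F = 0", {
  d <- regression_data(150, seed = 3)
  fit <- fit_ml(regression_model(), d)
  expect_equal(fit$F_min, 0, tolerance = 1e-9)
})

test_that("parameters are recovered from data simulated at known truth", {
  d <- chain_data(5000, a = 0.5, b = 0.4, direct = 0.3, seed = 7)
  model <- build_sem_from_cmos(list(observed_cmo()))
  fit <- fit_ml(model, d)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta_hat[["m~c"]] - 0.5), 0.05)
  expect_lt(abs(fit$theta_hat[["o~m"]] - 0.4), 0.05)
  expect_lt(abs(fit$theta_hat[["o~c"]] - 0.3), 0.05)
})

test_that("latent-free ML reproduces OLS with the textbook ML variance", {
  d <- regression_data(200, seed = 2)
  x <- d$x[, "x"]; y <- d$x[, "y"]
  fit <- fit_ml(regression_model(), d)
  beta_ols <- stats::cov(x, y) / stats::var(x)
  expect_equal(unname(fit$theta_hat["y~x"]), beta_ols, tolerance = 1e-6)
  n <- length(x)
  res <- (y - mean(y)) - fit$theta_hat["y~x"] * (x - mean(x))
  se_ml <- sqrt((sum(res^2) / n) / (n * mean((x - mean(x))^2)))
  k <- match("y~x", fit$model$par_table$label)
  expect_equal(unname(fit$naive_se[k]), unname(se_ml), tolerance = 1e-6)
  # vcov has rows only for free parameters
  expect_identical(dim(fit$vcov_naive), c(3L, 3L))
})

test_that("duplicating the data shrinks naive SEs by sqrt(2)", {
  d <- regression_data(150, seed = 5)
  df2 <- data.frame(rbind(d$x, d$x))
  df2$cl <- seq_len(nrow(df2))
  d2 <- clustered_dataset(df2, "cl")
  f1 <- fit_ml(regression_model(), d)
  f2 <- fit_ml(regression_model(), d2)
  expect_equal(unname(f1$naive_se / f2$naive_se), rep(sqrt(2), 3),
               tolerance = 1e-4)
})

test_that("size-1 clusters make the sandwich equal the HC0 form", {
  d <- regression_data(120, seed = 4)      # every cluster has one row
  fit <- fit_ml(regression_model(), d)
  Vr <- cluster_robust_vcov(fit, d, cluster_correction = "none")
  # independent oracle: casewise scores by numeric differentiation of the
  # per-observation Gaussian log-likelihood
  theta <- unname(fit$theta_hat)
  Z <- sweep(d$x[, c("x", "y")], 2, colMeans(d$x[, c("x", "y")]))
  ll_case <- function(th) {
    Sig <- model_implied_covariance(th, fit$model)
    Si <- solve(Sig)
    -0.5 * (log(det(Sig)) + rowSums((Z %*% Si) * Z))
  }
  q <- length(theta)
  Sc <- matrix(0, nrow(Z), q)
  for (k in seq_len(q)) {
    h <- 1e-6 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    Sc[, k] <- (ll_case(tp) - ll_case(tm)) / (2 * h)
  }
  A <- (fit$n / 2) * fit$hessian
  V_oracle <- solve(A) %*% crossprod(Sc) %*% solve(A)
  expect_equal(unname(Vr), unname(V_oracle), tolerance = 1e-5)
})

test_that("robust and naive SEs agree without clustering effects", {
  d <- chain_data(5000, seed = 11)         # independent rows
  fit <- fit_ml(build_sem_from_cmos(list(observed_cmo())), d)
  ratio <- fit$robust_se / fit$naive_se
  expect_true(all(ratio > 0.9 & ratio < 1.1))
})

test_that("cluster correlation inflates robust SEs for a cluster-constant predictor", {
  set.seed(13)
  G <- 60; m <- 25; n <- G * m
  cl <- rep(seq_len(G), each = m)
  x <- rnorm(G)[cl]                        # practice-level predictor
  u <- rnorm(G)[cl]                        # shared cluster disturbance
  y <- 0.3 * x + u + rnorm(n, sd = 0.5)
  d <- clustered_dataset(data.frame(x = x, y = y, cl = cl), "cl")
  fit <- fit_ml(regression_model(), d)
  k <- match("y~x", fit$model$par_table$label)
  expect_gt(fit$robust_se[k] / fit$naive_se[k], 1.5)
})

test_that("a single cluster is refused for the sandwich", {
  df <- data.frame(x = rnorm(30), y = rnorm(30), cl = 1)
  d <- clustered_dataset(df, "cl")
  fit <- fit_ml(regression_model(), d, se = "naive")
  expect_error(cluster_robust_vcov(fit, d), "single cluster")
})

test_that("the fit function is invariant to observed-variable order", {
  d <- factor_data(c(0.8, 0.7, 0.6, 0.5), n = 600, seed = 17)
  b1 <- concept_binding("f", "reflective", paste0("y", 1:4))
  b2 <- concept_binding("f", "reflective", paste0("y", c(1, 4, 3, 2)))
  f1 <- fit_ml(realistsem:::one_factor_model(b1), d)
  f2 <- fit_ml(realistsem:::one_factor_model(b2), d)
  expect_equal(f1$F_min, f2$F_min, tolerance = 1e-8)
})

test_that("non-convergence is flagged, not thrown", {
  d <- chain_data(300, seed = 31)
  ctl <- fml_control(max_iter = 1, newton_iter = 0)
  expect_warning(fit <- fit_ml(build_sem_from_cmos(list(observed_cmo())),
                               d, control = ctl),
                 "did not converge")
  expect_false(fit$converged)
})

test_that("declared-categorical variables are refused by the engine", {
  d <- chain_data(200, seed = 41)
  d$scales["c"] <- "categorical"
  expect_error(fit_ml(build_sem_from_cmos(list(observed_cmo())), d),
               "categorical")
})

test_that("standardization scales by model-implied sds and round-trips", {
  d <- chain_data(2000, a = 0.5, b = 0.4, direct = 0.3, seed = 8)
  # rescale one variable: standardized estimates must be unaffected
  df2 <- data.frame(d$x); df2$c <- df2$c * 7; df2$cl <- d$cluster
  d2 <- clustered_dataset(df2, "cl")
  model <- build_sem_from_cmos(list(observed_cmo()))
  f1 <- fit_ml(model, d); f2 <- fit_ml(model, d2)
  s1 <- standardize(f1); s2 <- standardize(f2)
  expect_equal(s1$std, s2$std, tolerance = 1e-6)
  # de-standardization recovers the raw estimate
  sp <- realistsem:::sigma_parts(model, unname(f2$theta_hat))
  sds <- sqrt(diag(sp$V))
  k <- match("m~c", s2$label)
  raw_back <- s2$std[k] * sds[s2$row[k]] / sds[s2$col[k]]
  expect_equal(unname(raw_back), unname(f2$theta_hat["m~c"]),
               tolerance = 1e-10)
})

test_that("with unit-variance variables the standardized and raw estimates coincide", {
  S <- matrix(c(1, .5, .35,
                .5, 1, .44,
                .35, .44, 1), 3, 3,
              dimnames = list(c("c", "m", "o"), c("c", "m", "o")))
  d <- data_with_cov(S, n = 300, seed = 6)
  fit <- fit_ml(build_sem_from_cmos(list(observed_cmo())), d)
  s <- standardize(fit)
  for (lab in c("m~c", "o~m", "o~c"))
    expect_equal(s$std[match(lab, s$label)],
                 unname(fit$theta_hat[lab]), tolerance = 1e-6)
})

test_that("standardized loadings equal implied indicator-factor correlations", {
  d <- factor_data(c(0.8, 0.7, 0.6, 0.5), n = 20000, seed = 9)
  b <- concept_binding("f", "reflective", paste0("y", 1:4))
  fit <- fit_ml(realistsem:::one_factor_model(b), d)
  s <- standardize(fit)
  lam <- s$std[s$matrix == "Lambda"]
  obs <- fit$model$observed[s$row[s$matrix == "Lambda"]]
  Sig <- fit$Sigma_hat
  sp <- realistsem:::sigma_parts(fit$model, unname(fit$theta_hat))
  implied_corr <- (sp$mats$Lambda %*% sp$V)[, 1] /
    (sqrt(diag(Sig)) * sqrt(sp$V[1, 1]))
  expect_equal(unname(lam), unname(implied_corr[obs]), tolerance = 1e-8)
  # and they approximate the generating loadings
  expect_equal(sort(unname(lam), decreasing = TRUE), c(.8, .7, .6, .5),
               tolerance = 0.06)
})
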