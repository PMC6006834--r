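test_that("a one-factor fit recovers generating loadings", {
  d <- factor_data(c(1, 0.8, 0.6) / sqrt(2), n = 2000, seed = 1)
  # loadings scaled so the reference has loading 1 on its own scale:
  # free loadings relative to y1 are 0.8 and 0.6
  b <- concept_binding("f", "reflective", paste0("y", 1:3))
  mfit <- fit_cfa(b, d)
  expect_true(mfit$fit$converged)
  expect_equal(unname(mfit$loadings$loading[1]), 1)
  expect_true(mfit$loadings$reference[1])
  expect_equal(unname(mfit$loadings$loading[2]), 0.8, tolerance = 0.1)
  expect_equal(unname(mfit$loadings$loading[3]), 0.6, tolerance = 0.1)
  expect_true(all(mfit$loadings$pvalue[-1] >= 0 &
                    mfit$loadings$pvalue[-1] <= 1))
})

test_that("uncorrelated indicators yield non-significant free loadings", {
  set.seed(2)
  hits <- 0
  for (r in 1:5) {
    df <- data.frame(y1 = rnorm(800), y2 = rnorm(800), y3 = rnorm(800),
                     cl = rep(1:80, each = 10))
    d <- clustered_dataset(df, "cl")
    b <- concept_binding("f", "reflective", c("y1", "y2", "y3"))
    mfit <- suppressWarnings(fit_cfa(b, d))
    if (mfit$fit$converged)
      hits <- hits + sum(mfit$loadings$pvalue[-1] < 0.05, na.rm = TRUE)
  }
  expect_lte(hits, 2)  # ~5% of 10 tests under the null
})

test_that("a five-indicator binding reports five loadings, first fixed", {
  d <- factor_data(c(0.8, 0.82, 0.85, 0.6, 0.78), n = 1500, seed = 3,
                   names_prefix = "s")
  b <- concept_binding("selfesteem", "reflective", paste0("s", 1:5))
  mfit <- fit_cfa(b, d)
  expect_identical(nrow(mfit$loadings), 5L)
  expect_equal(mfit$loadings$loading[1], 1)
  expect_true(all(is.na(mfit$loadings$se[1])))
  expect_true(all(!is.na(mfit$loadings$se[-1])))
})

test_that("single-indicator and two-indicator bindings are refused standalone", {
  d <- factor_data(c(0.8, 0.7), n = 200, seed = 4)
  b2 <- concept_binding("f", "reflective", c("y1", "y2"))
  expect_error(fit_cfa(b2, d), "at least 3")
  expect_error(concept_binding("f", "observed", "y1") |> fit_cfa(d),
               "reflective")
})

test_that("pruning drops only non-contributing indicators, deterministically", {
  # y4 has a true zero loading
  gen <- function(seed) {
    set.seed(seed)
    n <- 1000
    f <- rnorm(n)
    df <- data.frame(y1 = 0.8 * f + 0.6 * rnorm(n),
                     y2 = 0.7 * f + 0.71 * rnorm(n),
                     y3 = 0.6 * f + 0.8 * rnorm(n),
                     y4 = rnorm(n),
                     cl = rep(1:100, each = 10))
    clustered_dataset(df, "cl")
  }
  b <- concept_binding("f", "reflective", paste0("y", 1:4))
  removed <- 0
  for (r in 1:20) {
    d <- gen(100 + r)
    mfit <- suppressWarnings(fit_cfa(b, d))
    pruned <- suppressWarnings(prune_indicators(mfit, alpha = 0.05))
    if (!"y4" %in% pruned$indicators &&
        all(c("y1", "y2", "y3") %in% pruned$indicators))
      removed <- removed + 1
  }
  expect_gte(removed, 18)  # >= 90% of replications
  # determinism: same data and alpha give the same pruned binding
  d <- gen(7)
  p1 <- suppressWarnings(prune_indicators(suppressWarnings(fit_cfa(b, d))))
  p2 <- suppressWarnings(prune_indicators(suppressWarnings(fit_cfa(b, d))))
  expect_identical(p1$indicators, p2$indicators)
})

test_that("all-significant bindings are returned unchanged, and the p >= alpha rule is right-closed", {
  d <- factor_data(c(0.8, 0.7, 0.6, 0.5), n = 1500, seed = 5)
  b <- concept_binding("f", "reflective", paste0("y", 1:4))
  mfit <- fit_cfa(b, d)
  expect_identical(prune_indicators(mfit, alpha = 0.05)$indicators,
                   b$indicators)
  # an indicator whose p equals alpha exactly is removed (retention
  # requires p < alpha): prune with alpha set to an observed p-value
  p3 <- mfit$loadings$pvalue[4]
  pruned <- suppressWarnings(prune_indicators(mfit, alpha = p3))
  expect_false(mfit$loadings$indicator[4] %in% pruned$indicators)
})

test_that("modification indices find an omitted residual correlation", {
  gen <- function(seed, rho = 0.3) {
    set.seed(seed)
    n <- 1500
    f <- rnorm(n)
    e12 <- corr_noise(n, rho)
    df <- data.frame(y1 = 0.7 * f + e12[, 1] * 0.71,
                     y2 = 0.7 * f + e12[, 2] * 0.71,
                     y3 = 0.7 * f + 0.71 * rnorm(n),
                     y4 = 0.7 * f + 0.71 * rnorm(n),
                     cl = seq_len(n))
    clustered_dataset(df, "cl")
  }
  b <- concept_binding("f", "reflective", paste0("y", 1:4))
  model <- realistsem:::one_factor_model(b)
  d <- gen(11)
  fit <- suppressWarnings(fit_ml(model, d))
  cand <- list(c("y1", "y2"), c("y1", "y3"), c("y2", "y4"), c("y3", "y4"))
  mi <- modification_indices(fit, cand)
  expect_identical(mi$parameter[1], "y1~~y2")
  expect_gt(mi$mi[1], 10)
  expect_gt(mi$epc[1], 0)

  # MI approximates the chi-square drop from actually freeing the entry;
  # the score test tracks the likelihood ratio in the moderate-misfit
  # regime, so compare on a milder draw
  d2 <- gen(103, rho = 0.15)
  fitm <- suppressWarnings(fit_ml(model, d2, se = "none"))
  mi2 <- modification_indices(fitm, list(c("y1", "y2")))
  freed <- model
  freed$Theta[1, 2] <- freed$Theta[2, 1] <- NA_real_
  freed <- sem_model(model$observed, model$latents, freed$Lambda, freed$B,
                     freed$Psi, freed$Theta)
  fit2 <- suppressWarnings(fit_ml(freed, d2, se = "none"))
  lr_drop <- fitm$n * (fitm$F_min - fit2$F_min)
  expect_gt(mi2$mi[1], 5)
  expect_lt(abs(mi2$mi[1] - lr_drop) / lr_drop, 0.2)

  # already-free candidates are skipped with a warning
  expect_warning(modification_indices(fit2, list(c("y1", "y2"))),
                 "already free")
})


test_that("a correctly specified model produces small modification indices", {
  b <- concept_binding("f", "reflective", paste0("y", 1:4))
  model <- realistsem:::one_factor_model(b)
  below <- 0; total <- 0
  for (r in 1:10) {
    d <- factor_data(c(0.8, 0.7, 0.6, 0.5), n = 5000, seed = 200 + r)
    fit <- suppressWarnings(fit_ml(d = d, model = model, se = "none"))
    if (!fit$converged) next
    mi <- modification_indices(fit, list(c("y1", "y2"), c("y3", "y4")))
    total <- total + nrow(mi)
    below <- below + sum(mi$mi < 3.84)
  }
  expect_gte(below / total, 0.9)
})
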