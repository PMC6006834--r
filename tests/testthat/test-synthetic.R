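test_that("Likert discretization follows right-closed intervals", {
  expect_identical(discretize_to_likert(c(-2, 0, 2), numeric(0)),
                   rep(1L, 3))
  expect_error(discretize_to_likert(1:3, c(0.5, 0.5)), "increasing")
  th <- c(-1, 0, 1)
  expect_identical(discretize_to_likert(c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5),
                                        th),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L))  # boundary -> lower
  # quantile thresholds give near-uniform categories
  set.seed(81)
  z <- rnorm(100000)
  codes <- discretize_to_likert(z, stats::qnorm(c(.2, .4, .6, .8)))
  expect_true(all(abs(tabulate(codes, 5) / 1e5 - 0.2) < 0.01))
})

test_that("the generator is bit-reproducible given a seed", {
  cfg <- paper_fixture(n = 300)
  d1 <- generate_linked_dataset(cfg, seed = 5)
  d2 <- generate_linked_dataset(cfg, seed = 5)
  expect_identical(d1, d2)
  d3 <- generate_linked_dataset(cfg, seed = 6)
  expect_false(identical(d1$obtain_appointment, d3$obtain_appointment))
})

test_that("the default fixture reproduces the study dimensions", {
  cfg <- paper_fixture()
  expect_identical(cfg$n_individuals, 276L)
  expect_identical(cfg$n_practices, 178L)
  df <- generate_linked_dataset(cfg, seed = 1)
  expect_identical(nrow(df), 276L)
  expect_identical(length(unique(df$practice_id)), 178L)
})

test_that("practice-level variables are constant within cluster", {
  df <- generate_linked_dataset(paper_fixture(n = 2000), seed = 2)
  for (v in c("ease_getting_through", "convenience", "obtain_appointment",
              "clear_information", "hce_gp_time")) {
    spread <- tapply(df[[v]], df$practice_id, function(x) diff(range(x)))
    expect_equal(max(spread), 0)
  }
  # individual-level variables do vary within at least some clusters
  spread_i <- tapply(df$se_ideal, df$practice_id,
                     function(x) diff(range(x)))
  expect_gt(max(spread_i), 0)
})

test_that("fixture travel times match the printed quartiles", {
  df <- generate_linked_dataset(paper_fixture(n = 10000), seed = 3)
  expect_gt(stats::median(df$tr_travel_time), 4.3)
  expect_lt(stats::median(df$tr_travel_time), 5.3)
  tt <- travel_lognormal_params()
  expect_equal(exp(tt$mu), 4.80)
  expect_equal(exp(tt$mu + stats::qnorm(.75) * tt$sigma) /
                 exp(tt$mu - stats::qnorm(.75) * tt$sigma),
               7.88 / 2.76, tolerance = 1e-10)
})

test_that("demographic marginals match the declared shares", {
  df <- generate_linked_dataset(paper_fixture(n = 10000), seed = 4)
  expect_equal(mean(df$sex == "female"), 0.612, tolerance = 0.05)
  expect_true(all(c("age_band", "occupation") %in% names(df)))
  # education category shares (renormalized over stated categories)
  p_noqual <- 35.9 / (17.7 + 35.9 + 8.7 + 22.8 + 8.0)
  expect_equal(mean(df$edu_no_qual), p_noqual, tolerance = 0.02)
})

test_that("with all paths zero and no cluster effects correlations vanish", {
  cfg <- paper_fixture(n = 10000, effects = "null", icc = 0)
  df <- generate_linked_dataset(cfg, seed = 5)
  vars <- access_model()$observed
  R <- stats::cor(as.matrix(df[vars]))
  # exclude within-concept blocks (indicators of one latent correlate by
  # construction) and the mutually exclusive education dummies
  blocks <- list(paste0("se_", c("ideal", "excellent", "satisfied",
                                 "noregrets", "important")),
                 c("assert_determined", "assert_outgoing", "assert_proud"),
                 c("hce_not_overheard", "hce_gp_time", "hce_gp_explain",
                   "hce_gp_involve"),
                 c("tr_lifts", "tr_travel_time", "tr_public"),
                 c("edu_no_qual", "edu_cse", "edu_o_level", "edu_a_level"))
  same_block <- matrix(FALSE, length(vars), length(vars),
                       dimnames = list(vars, vars))
  for (bl in blocks) same_block[bl, bl] <- TRUE
  off <- abs(R[!same_block & upper.tri(R)])
  expect_lt(max(off), 0.05)
})

test_that("stronger cluster effects raise the intraclass correlation", {
  icc_est <- function(icc) {
    df <- generate_linked_dataset(paper_fixture(n = 6000, icc = icc,
                                                effects = "null"),
                                  seed = 6)
    v <- df$se_ideal
    cl <- factor(df$practice_id)
    ms <- summary(stats::aov(v ~ cl))[[1]][["Mean Sq"]]
    n0 <- mean(table(cl))
    (ms[1] - ms[2]) / (ms[1] + (n0 - 1) * ms[2])
  }
  est <- vapply(c(0.05, 0.3, 0.6), icc_est, 0)
  expect_true(all(diff(est) > 0))
})

test_that("an over-explained equation is rejected as non-positive-definite", {
  concepts <- list(list(name = "c", level = "individual", type = "normal"),
                   list(name = "m", level = "individual", type = "normal"))
  eqs <- list(list(lhs = "m", coef = c(c = 1.2)))
  meas <- list(c = list(list(var = "c", kind = "raw")),
               m = list(list(var = "m", kind = "raw")))
  cfg <- synthetic_config(100, 10, concepts, eqs, meas)
  expect_error(generate_linked_dataset(cfg, seed = 1),
               "non-positive-definite")
})

test_that("the fixture's generating arithmetic implies the published proportions", {
  cf <- realistsem:::fixture_coefficients()
  a_ease <- cf$a$convenience[["ease_getting_through"]]
  b_conv <- cf$b[["convenience"]]
  expect_equal(a_ease * b_conv, 0.140, tolerance = 1e-12)
  expect_equal(cf$direct[["ease_getting_through"]], 0.514)
  expect_equal(proportion_mediated(cf$direct[["ease_getting_through"]],
                                   a_ease * b_conv),
               0.140 / (0.140 + 0.514), tolerance = 1e-12)
  # health care experience pair
  ind_hce <- cf$a$convenience[["health_care_experience"]] * b_conv
  expect_equal(round(proportion_mediated(cf$direct[["health_care_experience"]],
                                         ind_hce), 2), 0.53)
})

test_that("MCAR missingness is applied and logged downstream", {
  cfg <- paper_fixture(n = 1500, missing_rate = 0.02)
  df <- generate_linked_dataset(cfg, seed = 7)
  expect_gt(sum(is.na(df$se_ideal)), 0)
  expect_equal(sum(is.na(df$sex)), 0)        # demographics untouched
  vars <- access_model()$observed
  expect_message(d <- clustered_dataset(df, "practice_id",
                                        variables = vars),
                 "listwise deletion")
  expect_identical(d$n + d$n_dropped, nrow(df))
})
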