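# The access-to-primary-care study model: nine CMO configurations for the
# "obtain an appointment" outcome, and a synthetic fixture calibrated to
# its reported standardized coefficients so parameter recovery can be
# checked end to end without the restricted microdata.

#' Concept bindings of the access-to-primary-care model
#'
#' Three reflective latents (assertiveness, self-esteem, health care
#' experience), one formative composite (transport), a categorical
#' education context expanded to dummies with the higher-education
#' baseline, and observed singletons for the remaining concepts.
#'
#' @return named list of `concept_binding` objects.
#' @export
access_bindings <- function() {
  list(
    assertiveness = concept_binding("assertiveness", "reflective",
      c("assert_determined", "assert_outgoing", "assert_proud")),
    self_esteem = concept_binding("self_esteem", "reflective",
      c("se_ideal", "se_excellent", "se_satisfied", "se_noregrets",
        "se_important")),
    health_care_experience = concept_binding("health_care_experience",
      "reflective",
      c("hce_not_overheard", "hce_gp_time", "hce_gp_explain",
        "hce_gp_involve")),
    transport = concept_binding("transport", "formative",
      c("tr_lifts", "tr_travel_time", "tr_public")),
    education = concept_binding("education", "categorical",
      c("edu_no_qual", "edu_cse", "edu_o_level", "edu_a_level")),
    health_literacy = concept_binding("health_literacy", "observed",
      "health_literacy"),
    technology = concept_binding("technology", "observed", "technology"),
    convenience = concept_binding("convenience", "observed", "convenience"),
    ease_getting_through = concept_binding("ease_getting_through",
      "observed", "ease_getting_through"),
    clear_information = concept_binding("clear_information", "observed",
      "clear_information"),
    obtain_appointment = concept_binding("obtain_appointment", "observed",
      "obtain_appointment"))
}

#' The nine CMO configurations of the access-to-primary-care model
#'
#' Contexts: clear information (paired with all three mechanisms),
#' education, self-esteem, technology, health care experience, ease of
#' getting through to the surgery, and transport. Mechanisms: health
#' literacy, assertiveness, convenience. Single outcome: obtaining an
#' appointment.
#'
#' @return list of 9 `cmo_configuration` objects.
#' @export
access_cmos <- function() {
  b <- access_bindings()
  list(
    cmo_configuration(b$clear_information, b$health_literacy,
                      b$obtain_appointment),
    cmo_configuration(b$education, b$health_literacy, b$obtain_appointment),
    cmo_configuration(b$self_esteem, b$assertiveness, b$obtain_appointment),
    cmo_configuration(b$clear_information, b$assertiveness,
                      b$obtain_appointment),
    cmo_configuration(b$technology, b$convenience, b$obtain_appointment),
    cmo_configuration(b$health_care_experience, b$convenience,
                      b$obtain_appointment),
    cmo_configuration(b$ease_getting_through, b$convenience,
                      b$obtain_appointment),
    cmo_configuration(b$transport, b$convenience, b$obtain_appointment),
    cmo_configuration(b$clear_information, b$convenience,
                      b$obtain_appointment))
}

#' Compile the full access-to-primary-care structural model
#'
#' @param residual_correlations optional indicator pairs to correlate in
#'   `Theta` (e.g. within the self-esteem factor when flagged by
#'   modification indices and theoretically justified).
#' @return a `sem_model` with all nine CMOs.
#' @export
access_model <- function(residual_correlations = NULL) {
  build_sem_from_cmos(access_cmos(),
                      residual_correlations = residual_correlations)
}

# Generating standardized coefficients of the fixture. The per-CMO
# direct effects and indirect products equal the study's reported point
# estimates; the mechanism-to-outcome coefficients b are fixture
# calibration choices (one per mechanism), and each context-to-mechanism
# coefficient is then indirect / b.
fixture_coefficients <- function() {
  b <- c(health_literacy = 0.05, assertiveness = 0.10, convenience = 0.40)
  a <- list(
    health_literacy = c(clear_information = 0 / b[["health_literacy"]],
                        edu_no_qual = 0.011 / b[["health_literacy"]],
                        edu_cse = 0.004 / b[["health_literacy"]],
                        edu_o_level = 0.005 / b[["health_literacy"]],
                        edu_a_level = 0.007 / b[["health_literacy"]]),
    assertiveness = c(self_esteem = 0.035 / b[["assertiveness"]],
                      clear_information = -0.002 / b[["assertiveness"]]),
    convenience = c(technology = 0.029 / b[["convenience"]],
                    health_care_experience = 0.088 / b[["convenience"]],
                    ease_getting_through = 0.140 / b[["convenience"]],
                    transport = 0.018 / b[["convenience"]],
                    clear_information = 0.037 / b[["convenience"]]))
  direct <- c(clear_information = 0.084,
              edu_no_qual = 0.009, edu_cse = 0.006,
              edu_o_level = -0.026, edu_a_level = -0.028,
              self_esteem = -0.095, technology = 0.080,
              health_care_experience = -0.078,
              ease_getting_through = 0.514, transport = 0.011)
  list(a = a, b = b, direct = direct)
}

#' Travel-time log-normal parameters from printed quartiles
#'
#' Solves `mu = log(median)` and
#' `sigma = log(q75/q25) / (2 qnorm(0.75))`.
#'
#' @param median,q25,q75 travel-time quartiles in minutes.
#' @return list with `mu`, `sigma`.
#' @export
travel_lognormal_params <- function(median = 4.80, q25 = 2.76, q75 = 7.88) {
  list(mu = log(median), sigma = log(q75 / q25) / (2 * stats::qnorm(0.75)))
}

#' Synthetic fixture calibrated to the access-to-primary-care study
#'
#' Returns a generating configuration whose standardized direct effect
#' from ease of getting through to obtaining an appointment is 0.514 and
#' whose indirect product through convenience is 0.140 (implied
#' proportion mediated 0.21), with the remaining CMO effects at the
#' study's reported point estimates. The default size reproduces the
#' study: 276 individuals in 178 practices; for other `n` the practice
#' count scales to preserve the mean cluster size 276/178, so that
#' practice-level sampling error shrinks with `n`.
#'
#' @param n number of individuals (default 276).
#' @param n_practices number of practices; default scales with `n`.
#' @param effects `"paper"` (reported coefficients) or `"null"` (all
#'   structural paths zero, for calibration studies).
#' @param icc intraclass (practice) variance share of individual-level
#'   variables and disturbances; 0 removes cluster effects.
#' @param missing_rate MCAR missingness per cell (default 0).
#' @return a `synthetic_config`.
#' @export
paper_fixture <- function(n = 276, n_practices = max(1L, round(n * 178 / 276)),
                          effects = c("paper", "null"), icc = 0.3,
                          missing_rate = 0) {
  effects <- match.arg(effects)
  cf <- fixture_coefficients()
  if (effects == "null") {
    cf$a <- lapply(cf$a, function(x) x * 0)
    cf$b <- cf$b * 0
    cf$direct <- cf$direct * 0
  }
  tt <- travel_lognormal_params()

  concepts <- list(
    list(name = "clear_information", level = "practice", type = "normal"),
    list(name = "education", level = "individual", type = "categorical",
         levels = c("higher_or_degree", "no_qual", "cse", "o_level",
                    "a_level"),
         probs = c(17.7, 35.9, 8.7, 22.8, 8.0),
         dummies = c("edu_no_qual", "edu_cse", "edu_o_level",
                     "edu_a_level")),
    list(name = "self_esteem", level = "individual", type = "normal",
         icc = icc),
    list(name = "technology", level = "individual", type = "normal",
         icc = icc),
    list(name = "health_care_experience", level = "practice",
         type = "normal"),
    list(name = "ease_getting_through", level = "practice", type = "normal"),
    list(name = "transport", level = "individual", type = "normal",
         icc = icc),
    list(name = "health_literacy", level = "individual", type = "normal"),
    list(name = "assertiveness", level = "individual", type = "normal"),
    list(name = "convenience", level = "practice", type = "normal"),
    list(name = "obtain_appointment", level = "practice", type = "normal"))

  equations <- list(
    list(lhs = "health_literacy", coef = cf$a$health_literacy, icc = icc),
    list(lhs = "assertiveness", coef = cf$a$assertiveness, icc = icc),
    list(lhs = "convenience", coef = cf$a$convenience),
    list(lhs = "obtain_appointment",
         coef = c(convenience = unname(cf$b[["convenience"]]),
                  health_literacy = unname(cf$b[["health_literacy"]]),
                  assertiveness = unname(cf$b[["assertiveness"]]),
                  cf$direct)))

  lik5 <- c(-1.8, -1.0, -0.2, 0.8)
  lik7 <- c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5)
  measurement <- list(
    assertiveness = list(
      list(var = "assert_determined", loading = 0.75, kind = "likert",
           thresholds = lik5),
      list(var = "assert_outgoing", loading = 0.55, kind = "likert",
           thresholds = c(-1.2, 0, 1.0)),
      list(var = "assert_proud", loading = 0.70, kind = "likert",
           thresholds = lik5)),
    self_esteem = list(
      list(var = "se_ideal", loading = 0.80, kind = "likert",
           thresholds = lik7),
      list(var = "se_excellent", loading = 0.82, kind = "likert",
           thresholds = lik7),
      list(var = "se_satisfied", loading = 0.85, kind = "likert",
           thresholds = lik7),
      list(var = "se_noregrets", loading = 0.60, kind = "likert",
           thresholds = lik7),
      list(var = "se_important", loading = 0.78, kind = "likert",
           thresholds = lik7)),
    health_care_experience = list(
      list(var = "hce_not_overheard", loading = 0.85, kind = "percent",
           mean = 88, sd = 6),
      list(var = "hce_gp_time", loading = 0.88, kind = "percent",
           mean = 87, sd = 7),
      list(var = "hce_gp_explain", loading = 0.90, kind = "percent",
           mean = 86, sd = 7),
      list(var = "hce_gp_involve", loading = 0.86, kind = "percent",
           mean = 82, sd = 8)),
    transport = list(
      list(var = "tr_lifts", loading = 0.55, kind = "likert",
           thresholds = c(-2.652, -1.507, -1.054, -0.815, -0.529)),
      list(var = "tr_travel_time", loading = -0.60, kind = "lognormal",
           mu = tt$mu, sigma = tt$sigma),
      list(var = "tr_public", loading = 0.65, kind = "likert",
           thresholds = c(-1.751, -1.108, -0.831, -0.553, 0.230))),
    health_literacy = list(
      list(var = "health_literacy", loading = 1, kind = "likert",
           thresholds = c(-2.620, -1.745, -1.236, -0.563))),
    technology = list(
      list(var = "technology", loading = 1, kind = "likert",
           thresholds = c(-0.486, -0.056, 0.053, 0.093, 0.154))),
    clear_information = list(
      list(var = "clear_information", loading = 1, kind = "percent",
           mean = 62, sd = 12)),
    convenience = list(
      list(var = "convenience", loading = 1, kind = "percent",
           mean = 82, sd = 8)),
    ease_getting_through = list(
      list(var = "ease_getting_through", loading = 1, kind = "percent",
           mean = 78, sd = 11)),
    obtain_appointment = list(
      list(var = "obtain_appointment", loading = 1, kind = "percent",
           mean = 85, sd = 8)))

  synthetic_config(n_individuals = n, n_practices = n_practices,
                   concepts = concepts, equations = equations,
                   measurement = measurement, icc_default = icc,
                   missing_rate = missing_rate)
}
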