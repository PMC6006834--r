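# Shared fixtures: tiny models and generators used across the suite.

# dataset with an exact given covariance matrix (n rows, centered)
data_with_cov <- function(S, n, seed = 1, clusters = NULL) {
  set.seed(seed)
  p <- ncol(S)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, scale = FALSE)
  X <- X %*% solve(chol(crossprod(X) / n)) %*% chol(S)
  colnames(X) <- colnames(S)
  df <- as.data.frame(X)
  df$cl <- if (is.null(clusters)) seq_len(n) else clusters
  clustered_dataset(df, "cl")
}

triad_cov <- function() {
  S <- matrix(c(1, .6, .5,
                .6, 1, .48,
                .5, .48, 1), 3, 3)
  dimnames(S) <- list(c("x1", "x2", "x3"), c("x1", "x2", "x3"))
  S
}

# one-factor model with all loadings free and factor variance fixed to 1
triad_model <- function() {
  sem_model(c("x1", "x2", "x3"), "f",
            Lambda = matrix(NA_real_, 3, 1),
            B = matrix(0, 1, 1),
            Psi = matrix(1, 1, 1),
            Theta = diag(NA_real_, 3))
}

# simple regression y ~ x as a latent-free SEM
regression_model <- function() {
  Lambda <- diag(1, 2)
  B <- matrix(0, 2, 2); B[2, 1] <- NA
  Psi <- matrix(0, 2, 2); Psi[1, 1] <- NA; Psi[2, 2] <- NA
  sem_model(c("x", "y"), c("x", "y"), Lambda, B, Psi,
            Theta = matrix(0, 2, 2))
}

regression_data <- function(n = 200, beta = 0.7, seed = 1,
                            clusters = NULL) {
  set.seed(seed)
  x <- rnorm(n)
  y <- beta * x + rnorm(n, sd = 0.8)
  df <- data.frame(x = x, y = y,
                   cl = if (is.null(clusters)) seq_len(n) else clusters)
  clustered_dataset(df, "cl")
}

# reflective factor data from given loadings (standardized indicators)
factor_data <- function(loadings, n, seed = 1, n_clusters = 50,
                        names_prefix = "y") {
  set.seed(seed)
  f <- rnorm(n)
  X <- sapply(loadings, function(l) l * f + sqrt(max(1 - l^2, 0.05)) * rnorm(n))
  colnames(X) <- paste0(names_prefix, seq_along(loadings))
  df <- as.data.frame(X)
  df$cl <- sample(n_clusters, n, replace = TRUE)
  clustered_dataset(df, "cl")
}

# three observed singleton concepts forming one CMO
observed_cmo <- function(cname = "c", mname = "m", oname = "o") {
  cmo_configuration(concept_binding(cname, "observed", cname),
                    concept_binding(mname, "observed", mname),
                    concept_binding(oname, "observed", oname))
}

# data from a linear chain c -> m -> o with a direct path
chain_data <- function(n, a = 0.5, b = 0.4, direct = 0.3, seed = 1,
                       clusters = NULL) {
  set.seed(seed)
  c_ <- rnorm(n)
  m <- a * c_ + rnorm(n, sd = sqrt(1 - a^2))
  o <- b * m + direct * c_ +
    rnorm(n, sd = sqrt(max(1 - b^2 - direct^2 - 2 * a * b * direct, 0.05)))
  df <- data.frame(c = c_, m = m, o = o,
                   cl = if (is.null(clusters)) seq_len(n) else clusters)
  clustered_dataset(df, "cl")
}

count_free <- function(model, mat) sum(model$par_table$matrix == mat)

free_structural_paths <- function(model) {
  pt <- model$par_table
  b <- pt[pt$matrix == "B", ]
  # composite weights are B entries too; exclude rows whose label targets
  # a formative concept listed in meta
  formative <- names(Filter(function(x) x$mode == "formative",
                            model$meta$concepts %||% list()))
  keep <- !(model$latents[b$row] %in% formative)
  b[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pair of standard-normal noises with correlation rho
corr_noise <- function(n, rho) {
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2)
}
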