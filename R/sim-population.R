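#' Simulate the study population
#'
#' Draws per-individual metadata (sex, birth year, latent community) and the
#' individual reaction-norm deviations \eqn{(u_{0i}, u_{1i})} jointly from
#' the configured 2x2 covariance. The deviations are simulation truth used
#' by [simulate_encounters()]; estimation code must not read them.
#'
#' Birth years: a fraction of individuals (first seen as adults) have
#' unknown birth year, mirroring photo-ID catalogues where age is known only
#' for animals first sighted as calves. Known birth years are spread between
#' `birth_year_span` years before the study and its penultimate years.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `id`, `sex` (`"F"`, `"M"`, `"U"`),
#'   `birth_year` (NA when unknown), `community`, `u0`, `u1`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  if (n < 1) stop("empty population", call. = FALSE)

  with_stream_seed(config$seed, 2L, {
    sex <- ifelse(runif(n) < config$unknown_sex_frac, "U",
                  ifelse(runif(n) < config$sex_ratio, "F", "M"))
    unknown_birth <- runif(n) < config$unknown_birth_frac
    birth_year <- sample(
      seq(config$start_year - config$birth_year_span,
          config$start_year + max(0L, config$n_years - 4L)),
      n, replace = TRUE)
    birth_year[unknown_birth] <- NA_integer_

    u <- rmvn_psd(n, config$rn_covariance)
    data.frame(
      id = sprintf("ID%04d", seq_len(n)),
      sex = sex,
      birth_year = birth_year,
      community = sample.int(config$n_communities, n, replace = TRUE),
      u0 = u[, 1],
      u1 = u[, 2],
      stringsAsFactors = FALSE
    )
  })
}

# multivariate normal draw tolerant of singular (PSD) covariance
rmvn_psd <- function(n, sigma) {
  d <- nrow(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  root <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  matrix(rnorm(n * d), n, d) %*% root
}
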