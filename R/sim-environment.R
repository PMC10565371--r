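#' Simulate a monthly environmental covariate series
#'
#' Two generators are available. `"ar1_index"` produces a stationary
#' Gaussian first-order autoregressive monthly series (climate-index style:
#' mean zero, configurable marginal standard deviation and lag-1
#' autocorrelation `phi`), with the yearly series defined as the mean of the
#' monthly values within each calendar year. `"seasonal_count"` produces
#' non-negative, right-skewed monthly counts from a negative binomial whose
#' log mean carries a Gaussian-bump seasonal peak (resource-count style,
#' e.g. monthly rod catches of migratory fish), with the yearly series
#' defined as the sum of monthly counts within each calendar year.
#'
#' @param config a [sim_config()].
#' @return an `env_series`: a data frame with columns `year`, `month`,
#'   `value` covering all 12 months of each simulated year, with the yearly
#'   aggregate available via [yearly_series()].
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ep <- config$env_params
  years <- config$start_year + seq_len(config$n_years) - 1L
  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  n <- nrow(grid)

  value <- with_stream_seed(config$seed, 1L, {
    if (config$env_model == "ar1_index") {
      phi <- ep$ar1_phi
      innov_sd <- ep$ar1_sd * sqrt(1 - phi^2)
      x <- numeric(n)
      x[1] <- rnorm(1, 0, ep$ar1_sd)
      for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + rnorm(1, 0, innov_sd)
      x
    } else {
      bump <- exp(-((grid$month - ep$seasonal_peak)^2) /
                    (2 * ep$seasonal_width^2))
      lambda <- ep$count_mean * exp(ep$seasonal_amplitude * (bump - mean(bump)))
      rnbinom(n, mu = lambda, size = ep$count_dispersion)
    }
  })

  out <- data.frame(year = grid$year, month = grid$month, value = value)
  structure(out,
            class = c("env_series", "data.frame"),
            env_model = config$env_model,
            yearly_aggregate = if (config$env_model == "seasonal_count") "sum" else "mean")
}

#' Aggregate a monthly environmental series to yearly values
#'
#' Index-style series are averaged within calendar years; count-style series
#' are summed.
#'
#' @param env an `env_series` (or any data frame with `year`, `month`,
#'   `value`).
#' @param aggregate `"mean"` or `"sum"`; defaults to the convention recorded
#'   on the series.
#' @return data frame with columns `year`, `value`.
#' @export
yearly_series <- function(env, aggregate = NULL) {
  aggregate <- aggregate %||% attr(env, "yearly_aggregate") %||% "mean"
  fun <- if (aggregate == "sum") sum else mean
  out <- aggregate(list(value = env$value), by = list(year = env$year), FUN = fun)
  out[order(out$year), , drop = FALSE]
}

#' Standardize a covariate to mean zero and unit variance
#'
#' Mean-centres and scales the values entering a model fit. The default
#' follows the population-sd convention (divide by
#' \eqn{\sqrt{\sum (x-\bar x)^2 / n}}); `method = "sample"` uses the usual
#' \eqn{n-1} denominator. The centring constants are stored as attributes so
#' fitted effects can be mapped back to the raw scale with
#' [destandardize()].
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param method `"population"` or `"sample"` sd convention.
#' @return standardized numeric vector with attributes `center` and `scale`.
#' @export
#' @examples
#' z <- standardize_covariate(c(1, 2, 3))
#' destandardize(z)
standardize_covariate <- function(values, method = c("population", "sample")) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2) {
    stop("cannot standardize a constant covariate", call. = FALSE)
  }
  m <- mean(v)
  s <- if (method == "population") {
    sqrt(mean((v - m)^2))
  } else {
    sd(v)
  }
  structure((values - m) / s, center = m, scale = s, method = method)
}

#' @rdname standardize_covariate
#' @param z a vector produced by [standardize_covariate()].
#' @export
destandardize <- function(z) {
  as.numeric(z) * attr(z, "scale") + attr(z, "center")
}
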