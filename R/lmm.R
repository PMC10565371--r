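#' Transform a response variable to the modelling scale
#'
#' Strength and closeness distributions from association networks are
#' right-skewed and positive, so they are log-transformed; clustering
#' coefficients are bounded in (0, 1) and logit-transformed. Rows violating
#' the transform's domain (zeros under log, 0/1 under logit, NAs) are
#' dropped, with the count recorded in the `n_dropped` attribute.
#'
#' @param values numeric vector.
#' @param transform `"log"`, `"logit"` or `"identity"`.
#' @return transformed vector with attributes `keep` (logical row filter
#'   applied) and `n_dropped`.
#' @export
transform_response <- function(values, transform = c("log", "logit", "identity")) {
  transform <- match.arg(transform)
  ok <- switch(transform,
               log = !is.na(values) & values > 0,
               logit = !is.na(values) & values > 0 & values < 1,
               identity = !is.na(values))
  out <- switch(transform,
                log = log(values[ok]),
                logit = qlogis(values[ok]),
                identity = values[ok])
  structure(out, keep = ok, n_dropped = sum(!ok))
}

#' Marginal covariance matrix of the random-regression model
#'
#' Builds, explicitly, the n x n covariance of the observations implied by
#' a variance-component vector `theta`:
#' \deqn{V = Z G Z' + V_{year} K_{ar1} + V_{month} K_{month} + V_{resid} I}
#' where Z has rows (1, x) blocked by individual, G is the 2x2 intercept /
#' slope covariance, `K_ar1[s, t] = rho^|year_s - year_t|` is shared by all
#' observations, and `K_month` indicates shared year-months. Used for
#' direct-density checks and small problems; the fitting code never forms
#' this matrix.
#'
#' @param data data frame with columns `id`, `x`, and (if the components
#'   are used) `year` and `month`.
#' @param theta named list/vector with `V_int`, `V_slope`, `Cov`, `V_year`,
#'   `rho_year`, `V_month`, `V_resid` (absent components default to 0).
#' @return symmetric n x n matrix.
#' @export
marginal_covariance <- function(data, theta) {
  th <- theta_defaults(theta)
  n <- nrow(data)
  same_id <- outer(data$id, data$id, "==")
  xx <- outer(data$x, data$x)
  xs <- outer(data$x, data$x, "+")
  V <- same_id * (th$V_int + th$Cov * xs + th$V_slope * xx)
  if (th$V_year > 0) {
    gap <- abs(outer(data$year, data$year, "-"))
    V <- V + th$V_year * th$rho_year^gap
  }
  if (th$V_month > 0) {
    ymlab <- paste(data$year, data$month)
    V <- V + th$V_month * outer(ymlab, ymlab, "==")
  }
  V + diag(th$V_resid, n)
}

theta_defaults <- function(theta) {
  th <- list(V_int = 0, V_slope = 0, Cov = 0, V_year = 0, rho_year = 0,
             V_month = 0, V_resid = 0)
  th[names(theta)] <- theta
  th
}

# ---- internal: data marshalling for the C++ likelihood kernel ----------

# Sorts rows by individual and encodes year/month levels; X columns follow
# the fixed-effect structure sex + x + sex:x (or just x when sex is absent
# or single-level).
rrn_prepare <- function(data, include_year_ar1, include_month) {
  need <- c("y", "x", "id")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("model data must have columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(match(data$id, unique(data$id)))
  d <- data[ord, , drop = FALSE]

  use_sex <- "sex" %in% names(d) && length(unique(d$sex)) > 1
  use_x <- length(unique(d$x)) > 1   # constant covariate: drop from design
  X <- if (use_sex && use_x) {
    sexM <- as.numeric(d$sex == "M")
    cbind("(Intercept)" = 1, sexM = sexM, x = d$x, "sexM:x" = sexM * d$x)
  } else if (use_sex) {
    cbind("(Intercept)" = 1, sexM = as.numeric(d$sex == "M"))
  } else if (use_x) {
    cbind("(Intercept)" = 1, x = d$x)
  } else {
    cbind("(Intercept)" = rep(1, nrow(d)))
  }

  if (include_year_ar1) {
    if (!"year" %in% names(d)) stop("year column required for the AR1 term",
                                    call. = FALSE)
    ylev <- sort(unique(d$year))
    year_idx <- as.integer(match(d$year, ylev) - 1L)
    year_vals <- as.numeric(ylev)
  } else {
    year_idx <- rep(-1L, nrow(d))
    year_vals <- numeric(0)
  }
  if (include_month) {
    if (!all(c("year", "month") %in% names(d))) {
      stop("year and month columns required for the month term", call. = FALSE)
    }
    ymlab <- paste(d$year, d$month)
    month_idx <- as.integer(match(ymlab, unique(ymlab)) - 1L)
  } else {
    month_idx <- rep(-1L, nrow(d))
  }
  list(data = d, X = X,
       id = as.integer(match(d$id, unique(d$id)) - 1L),
       year_idx = year_idx, year_vals = year_vals, month_idx = month_idx)
}

# unconstrained parameter vector <-> natural-scale theta
rrn_par_names <- function(random, include_year_ar1, include_month) {
  pn <- "log_V_int"
  if (random %in% c("full", "zero_corr")) pn <- c(pn, "log_V_slope")
  if (random == "full") pn <- c(pn, "atanh_corr")
  if (include_year_ar1) pn <- c(pn, "log_V_year", "atanh_rho_year")
  if (include_month) pn <- c(pn, "log_V_month")
  c(pn, "log_V_resid")
}

rrn_expand_theta <- function(par, pn) {
  g <- function(nm, def = 0) if (nm %in% pn) unname(par[match(nm, pn)]) else def
  V_int <- exp(g("log_V_int", -Inf))
  V_slope <- exp(g("log_V_slope", -Inf))
  corr <- tanh(g("atanh_corr"))
  c(V_int = V_int, V_slope = V_slope,
    Cov = corr * sqrt(V_int * V_slope),
    V_year = exp(g("log_V_year", -Inf)),
    rho_year = tanh(g("atanh_rho_year")),
    V_month = exp(g("log_V_month", -Inf)),
    V_resid = exp(unname(par[length(par)])))
}

#' Fit the random-regression mixed model by maximum likelihood
#'
#' Fits, on the transformed response scale, the Gaussian linear mixed model
#' `y ~ sex + x + sex:x` with correlated individual random intercepts and
#' slopes on the (standardized) environmental covariate `x`, optional AR1
#' year effects shared across individuals, optional year-month effects, and
#' iid residuals. The fixed effects are profiled out by generalized least
#' squares and the variance components are maximized on an unconstrained
#' scale (log variances, atanh correlations) by quasi-Newton multi-start
#' optimization; estimates are ML (not REML) so nested likelihood-ratio
#' tests are coherent.
#'
#' @param data data frame with columns `y` (transformed response), `x`
#'   (standardized covariate), `id` (individual), optionally `sex`
#'   (`"F"`/`"M"`), and `year`/`month` as required by the variance
#'   structure.
#' @param random random-effect structure: `"full"` (intercept + slope +
#'   correlation), `"zero_corr"` (correlation fixed at zero) or
#'   `"intercept_only"`.
#' @param include_year_ar1 include AR1-correlated year effects.
#' @param include_month include iid year-month effects (monthly models).
#' @param n_starts number of optimizer starts (first from moment-based
#'   values, the rest jittered deterministically from `seed`).
#' @param seed seed for start jitter.
#' @param control passed to [stats::optim()] (method `"L-BFGS-B"`); a
#'   Nelder-Mead retry runs automatically if no start converges.
#' @return an `rrn_fit`: coefficients with standard errors, variance
#'   components (`V_int`, `V_slope`, `Cov`, `corr`, `V_year`, `rho_year`,
#'   `V_month`, `V_resid`), `logLik`, convergence flag and optimizer trace.
#' @export
fit_rrn <- function(data,
                    random = c("full", "zero_corr", "intercept_only"),
                    include_year_ar1 = FALSE,
                    include_month = FALSE,
                    n_starts = 3,
                    seed = 1L,
                    control = list()) {
  random <- match.arg(random)
  prep <- rrn_prepare(data, include_year_ar1, include_month)
  y <- prep$data$y
  n <- length(y)
  if (n < 3) stop("too few observations to fit", call. = FALSE)

  # slope components need repeated-measures individuals spanning >= 2
  # distinct covariate values; else fix slopes at zero
  if (random != "intercept_only") {
    nx <- tapply(prep$data$x, prep$data$id, function(v) length(unique(v)))
    if (!any(nx >= 2)) {
      warning("no individual has 2+ distinct covariate values; fixing random slopes at 0")
      random <- "intercept_only"
    }
  }

  pn <- rrn_par_names(random, include_year_ar1, include_month)
  vy <- var(y)
  start0 <- setNames(rep(0, length(pn)), pn)
  start0[pn == "log_V_int"] <- log(0.4 * vy + 1e-8)
  start0[pn == "log_V_slope"] <- log(0.1 * vy + 1e-8)
  start0[pn == "log_V_year"] <- log(0.1 * vy + 1e-8)
  start0[pn == "log_V_month"] <- log(0.1 * vy + 1e-8)
  start0[length(pn)] <- log(0.5 * vy + 1e-8)

  obj <- function(par) {
    th <- rrn_expand_theta(par, pn)
    res <- rrn_objective_cpp(y, prep$X, prep$id, prep$data$x,
                             prep$year_idx, prep$month_idx, prep$year_vals,
                             th, TRUE, numeric(0))
    if (!isTRUE(res$ok)) return(1e10)
    res$nll
  }

  starts <- list(start0)
  if (n_starts > 1) {
    jit <- with_stream_seed(seed, 17L, {
      lapply(seq_len(n_starts - 1), function(k) {
        start0 + rnorm(length(pn), 0, 0.7)
      })
    })
    starts <- c(starts, jit)
  }

  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e4), control)
  lower <- rep(-30, length(pn)); upper <- rep(30, length(pn))
  lower[grepl("atanh", pn)] <- -6; upper[grepl("atanh", pn)] <- 6

  fits <- lapply(starts, function(st) {
    f <- tryCatch(optim(st, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper, control = ctrl),
                  error = function(e) NULL)
    f
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value) &&
                   f$value < 1e9, fits)
  if (length(fits) == 0) {
    # fallback optimizer, mirroring the practice of switching algorithms
    # when the default fails to converge
    fits <- list(tryCatch(optim(start0, obj, method = "Nelder-Mead",
                                control = list(maxit = 2000)),
                          error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
  }
  if (length(fits) == 0) {
    return(structure(list(converged = FALSE, logLik = NA_real_,
                          random = random, n_obs = n), class = "rrn_fit"))
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  if (best$convergence != 0) {
    # switch algorithm and polish, as is standard practice when the default
    # optimizer stalls on these variance surfaces
    polish <- tryCatch(optim(best$par, obj, method = "Nelder-Mead",
                             control = list(maxit = 2000)),
                       error = function(e) NULL)
    if (!is.null(polish) && is.finite(polish$value) &&
        polish$value <= best$value + 1e-6) {
      best <- polish
    }
  }
  converged <- best$convergence == 0 && best$value < 1e9

  th <- rrn_expand_theta(best$par, pn)
  res <- rrn_objective_cpp(y, prep$X, prep$id, prep$data$x,
                           prep$year_idx, prep$month_idx, prep$year_vals,
                           th, TRUE, numeric(0))
  if (!isTRUE(res$ok)) {
    return(structure(list(converged = FALSE, logLik = NA_real_,
                          random = random, n_obs = n), class = "rrn_fit"))
  }
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(prep$X)
  vcov_beta <- tryCatch(solve(res$XtViX), error = function(e) {
    matrix(NA_real_, length(beta), length(beta))
  })
  se <- sqrt(pmax(diag(vcov_beta), 0))
  corr <- if (th["V_int"] > 0 && th["V_slope"] > 0) {
    th[["Cov"]] / sqrt(th[["V_int"]] * th[["V_slope"]])
  } else 0

  structure(list(
    coefficients = data.frame(term = names(beta), estimate = beta,
                              se = se, row.names = NULL),
    vcov = vcov_beta,
    theta = as.list(th),
    corr = unname(corr),
    logLik = -best$value,
    n_obs = n,
    n_individuals = length(unique(prep$data$id)),
    random = random,
    include_year_ar1 = include_year_ar1,
    include_month = include_month,
    converged = converged,
    optimizer = list(n_starts = length(starts),
                     objective_values = vals,
                     convergence_codes = vapply(fits, `[[`, numeric(1),
                                                "convergence"))
  ), class = "rrn_fit")
}

#' @export
print.rrn_fit <- function(x, ...) {
  cat(sprintf("<rrn_fit> random = %s%s%s | n = %d obs, %d individuals | logLik = %.3f%s\n",
              x$random,
              if (x$include_year_ar1) " + year AR1" else "",
              if (x$include_month) " + month" else "",
              x$n_obs, x$n_individuals %||% NA, x$logLik,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$coefficients)) {
    cf <- x$coefficients
    cat("fixed effects:\n")
    for (i in seq_len(nrow(cf))) {
      cat(sprintf("  %-12s %8.4f +/- %.4f\n", cf$term[i], cf$estimate[i],
                  cf$se[i]))
    }
    th <- x$theta
    cat(sprintf("variance components: V_int=%.4g V_slope=%.4g corr=%.3f V_year=%.4g rho=%.3f V_month=%.4g V_resid=%.4g\n",
                th$V_int, th$V_slope, x$corr, th$V_year, th$rho_year,
                th$V_month, th$V_resid))
  }
  invisible(x)
}

#' Log-likelihood of an `rrn_fit`
#' @param object an `rrn_fit`.
#' @param ... unused.
#' @export
logLik.rrn_fit <- function(object, ...) object$logLik

#' Evaluate the marginal log-likelihood at given parameters
#'
#' Exposes the fitting kernel's likelihood at a fixed variance-component
#' vector, either with the fixed effects profiled out (`beta = NULL`) or at
#' a supplied coefficient vector. Useful for likelihood surface checks.
#'
#' @param data as in [fit_rrn()].
#' @param theta named variance components (see [marginal_covariance()]).
#' @param beta fixed-effect vector matching the design columns, or NULL to
#'   profile.
#' @param include_year_ar1,include_month variance structure flags.
#' @return log-likelihood (scalar), or -Inf if `theta` is infeasible.
#' @export
rrn_loglik <- function(data, theta, beta = NULL,
                       include_year_ar1 = FALSE, include_month = FALSE) {
  prep <- rrn_prepare(data, include_year_ar1, include_month)
  th <- theta_defaults(theta)
  thv <- c(th$V_int, th$V_slope, th$Cov, th$V_year, th$rho_year,
           th$V_month, th$V_resid)
  res <- rrn_objective_cpp(prep$data$y, prep$X, prep$id, prep$data$x,
                           prep$year_idx, prep$month_idx, prep$year_vals,
                           thv, is.null(beta),
                           if (is.null(beta)) numeric(0) else as.numeric(beta))
  if (!isTRUE(res$ok)) return(-Inf)
  -res$nll
}

#' Per-term Wald chi-square tests of the fixed effects
#'
#' For each fixed-effect term, \eqn{\chi^2 = (\hat\beta / SE)^2} on one
#' degree of freedom, with main effects tested in the presence of the
#' interaction (type-III convention under the model's centred covariate).
#'
#' @param fit a converged `rrn_fit`.
#' @return data frame with `term`, `estimate`, `se`, `chisq`, `df`, `p`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "rrn_fit"))
  cf <- fit$coefficients
  chisq <- (cf$estimate / cf$se)^2
  data.frame(term = cf$term, estimate = cf$estimate, se = cf$se,
             chisq = chisq, df = 1,
             p = pchisq(chisq, df = 1, lower.tail = FALSE),
             row.names = NULL)
}
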