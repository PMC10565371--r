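#' Likelihood-ratio test for the intercept-slope correlation
#'
#' First stage of the testing hierarchy for individual variation in
#' plasticity: the full model (random intercepts + slopes + correlation) is
#' compared against the same model with the correlation suppressed to zero.
#' The correlation is an interior parameter, so the statistic
#' \eqn{2\Delta\ell} is referred to a chi-square with one degree of freedom.
#' If either fit fails to converge the caller should fall back to the 2-df
#' comparison of the full model against the no-slopes model (see
#' [test_random_slopes()]).
#'
#' @param fit_full converged full `rrn_fit`.
#' @param fit_zero_corr converged zero-correlation `rrn_fit`.
#' @param alpha clarity threshold (default 0.05).
#' @return an `rrn_lrt` list: `comparison`, `statistic`, `df`, `null`,
#'   `p`, `clear`, `marginal`.
#' @export
test_intercept_slope_correlation <- function(fit_full, fit_zero_corr,
                                             alpha = 0.05) {
  stat <- max(0, 2 * (fit_full$logLik - fit_zero_corr$logLik))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  new_lrt("full_vs_zero_corr", stat, "chisq_1", p, alpha)
}

#' Boundary likelihood-ratio test for the random slopes
#'
#' Second stage, run when the correlation test is unclear: the
#' zero-correlation model is compared against the model without random
#' slopes. The slope variance sits on the boundary of its parameter space
#' under the null, so the statistic is referred to an equal mixture of a
#' point mass at zero and a chi-square with one degree of freedom
#' ("a mix of zero and one degree of freedom"):
#' \eqn{p = 0.5\,P(\chi^2_1 \ge 2\Delta\ell)}, giving p = 0.5 at a zero
#' statistic.
#'
#' @param fit_zero_corr converged zero-correlation `rrn_fit`.
#' @param fit_intercept_only converged intercept-only `rrn_fit`.
#' @param alpha clarity threshold.
#' @return an `rrn_lrt` (comparison `"zero_corr_vs_no_slopes"`).
#' @export
test_random_slopes <- function(fit_zero_corr, fit_intercept_only,
                               alpha = 0.05) {
  stat <- max(0, 2 * (fit_zero_corr$logLik - fit_intercept_only$logLik))
  p <- 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  new_lrt("zero_corr_vs_no_slopes", stat, "mixture_chisq_0_1", p, alpha)
}

#' Fallback 2-df test of intercept-slope terms jointly
#'
#' Used only when the zero-correlation model cannot be fitted: the full
#' model is compared directly against the intercept-only model on two
#' degrees of freedom.
#'
#' @param fit_full,fit_intercept_only converged `rrn_fit`s.
#' @param alpha clarity threshold.
#' @return an `rrn_lrt` (comparison `"full_vs_no_slopes_2df"`).
#' @export
test_slopes_2df <- function(fit_full, fit_intercept_only, alpha = 0.05) {
  stat <- max(0, 2 * (fit_full$logLik - fit_intercept_only$logLik))
  p <- pchisq(stat, df = 2, lower.tail = FALSE)
  new_lrt("full_vs_no_slopes_2df", stat, "chisq_2", p, alpha)
}

new_lrt <- function(comparison, stat, null, p, alpha) {
  structure(list(comparison = comparison, statistic = stat, df = null,
                 null = null, p = p,
                 clear = is.finite(p) && p < alpha,
                 marginal = is.finite(p) && p >= alpha && p < 0.07),
            class = "rrn_lrt")
}

#' @export
print.rrn_lrt <- function(x, ...) {
  cat(sprintf("<rrn_lrt> %s: stat = %.4f (%s), p = %.4g%s\n",
              x$comparison, x$statistic, x$null, x$p,
              if (x$clear) "  [clear]" else if (x$marginal) "  [marginal]" else ""))
  invisible(x)
}

#' Run the two-stage plasticity testing procedure
#'
#' Implements the testing hierarchy in order: (1) test the intercept-slope
#' correlation (full vs zero-correlation, 1 df); (2) only if that is
#' unclear, test the random slopes (zero-correlation vs intercept-only,
#' 0:1 mixture). If the zero-correlation model fails to converge, fall back
#' to the 2-df full vs intercept-only comparison. An audit trail records
#' which tests ran and in what order.
#'
#' @param fit_full,fit_zero_corr,fit_intercept_only `rrn_fit`s (the
#'   zero-correlation and intercept-only fits may be `NULL`/non-converged).
#' @param alpha clarity threshold.
#' @return list with `correlation_test`, `slope_test` (either may be NULL),
#'   `correlation_clear`, `slopes_clear`, `procedure` (character audit log).
#' @export
plasticity_tests <- function(fit_full, fit_zero_corr, fit_intercept_only,
                             alpha = 0.05) {
  ok <- function(f) !is.null(f) && isTRUE(f$converged)
  procedure <- character(0)

  if (!ok(fit_full)) {
    return(list(correlation_test = NULL, slope_test = NULL,
                correlation_clear = NA, slopes_clear = NA,
                procedure = "full model did not converge; no tests run"))
  }

  if (!ok(fit_zero_corr)) {
    # zero-correlation fit unavailable: joint 2-df fallback
    procedure <- c(procedure,
                   "zero-correlation model did not converge; fell back to 2-df full vs intercept-only test")
    st <- if (ok(fit_intercept_only)) {
      test_slopes_2df(fit_full, fit_intercept_only, alpha)
    } else NULL
    return(list(correlation_test = NULL, slope_test = st,
                correlation_clear = NA,
                slopes_clear = if (is.null(st)) NA else st$clear,
                procedure = procedure))
  }

  ct <- test_intercept_slope_correlation(fit_full, fit_zero_corr, alpha)
  procedure <- c(procedure, sprintf(
    "1: correlation LRT (full vs zero-corr), stat %.3f, p %.4g -> %s",
    ct$statistic, ct$p, if (ct$clear) "clear, stop" else "unclear, proceed"))
  if (ct$clear) {
    # a clear correlation implies random slopes exist; slope test skipped
    return(list(correlation_test = ct, slope_test = NULL,
                correlation_clear = TRUE, slopes_clear = TRUE,
                procedure = procedure))
  }

  st <- if (ok(fit_intercept_only)) {
    test_random_slopes(fit_zero_corr, fit_intercept_only, alpha)
  } else NULL
  if (!is.null(st)) {
    procedure <- c(procedure, sprintf(
      "2: random-slope boundary LRT (zero-corr vs intercept-only), stat %.3f, p %.4g -> %s",
      st$statistic, st$p, if (st$clear) "slopes clear" else "slopes unclear"))
  } else {
    procedure <- c(procedure, "2: intercept-only model did not converge; slope test unavailable")
  }
  list(correlation_test = ct, slope_test = st,
       correlation_clear = FALSE,
       slopes_clear = if (is.null(st)) NA else st$clear,
       procedure = procedure)
}

#' Marginal and conditional repeatability
#'
#' Following the variance-partitioning approach for random-regression
#' models, the among-individual variance at covariate value x is
#' \deqn{V_{ind}(x) = V_{int} + 2x\,Cov + x^2 V_{slope}}
#' and the marginal among-individual variance averages this over the
#' covariate distribution:
#' \deqn{V_{ind} = V_{int} + 2\,Cov\,E[x] + V_{slope}(Var[x] + E[x]^2)}
#' which reduces to \eqn{V_{int} + V_{slope}} for a standardized covariate.
#' Repeatability divides by the total non-fixed-effect variance:
#' \deqn{R = V_{ind} / (V_{ind} + V_{year} + V_{month} + V_{resid}).}
#'
#' @param fit an `rrn_fit`, or a named variance-component list.
#' @param x_values covariate values at which conditional repeatability is
#'   evaluated (default -2..2 standard deviations).
#' @param x_mean,x_var moments of the covariate distribution (0, 1 for a
#'   standardized covariate).
#' @param denominator `"all"` includes year and month components in the
#'   denominator; `"residual_only"` drops them (sensitivity switch).
#' @return an `rrn_repeatability` list: `R_marginal`, data frame
#'   `conditional` (`x`, `V_ind`, `R`), and the components used.
#' @export
marginal_repeatability <- function(fit, x_values = -2:2,
                                   x_mean = 0, x_var = 1,
                                   denominator = c("all", "residual_only")) {
  denominator <- match.arg(denominator)
  th <- theta_defaults(if (inherits(fit, "rrn_fit")) fit$theta else fit)
  comps <- c(V_int = th$V_int, V_slope = th$V_slope, Cov = th$Cov,
             V_year = th$V_year, V_month = th$V_month, V_resid = th$V_resid)
  if (any(comps[c("V_int", "V_slope", "V_year", "V_month", "V_resid")] < 0)) {
    stop("negative variance component", call. = FALSE)
  }
  other <- th$V_resid + if (denominator == "all") th$V_year + th$V_month else 0

  v_ind_marg <- th$V_int + 2 * th$Cov * x_mean +
    th$V_slope * (x_var + x_mean^2)
  v_ind_marg <- max(v_ind_marg, 0)
  R_marg <- v_ind_marg / (v_ind_marg + other)

  v_ind_x <- pmax(th$V_int + 2 * x_values * th$Cov + x_values^2 * th$V_slope, 0)
  cond <- data.frame(x = x_values, V_ind = v_ind_x,
                     R = v_ind_x / (v_ind_x + other))
  structure(list(R_marginal = R_marg, conditional = cond,
                 components = comps, denominator = denominator),
            class = "rrn_repeatability")
}

#' @export
print.rrn_repeatability <- function(x, ...) {
  cat(sprintf("<rrn_repeatability> marginal R = %.4f\n", x$R_marginal))
  cat("conditional R(x):\n")
  for (i in seq_len(nrow(x$conditional))) {
    cat(sprintf("  x = %+g : R = %.4f\n", x$conditional$x[i],
                x$conditional$R[i]))
  }
  invisible(x)
}
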