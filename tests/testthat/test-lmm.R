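test_that("covariate standardization matches hand arithmetic", {
  z <- standardize_covariate(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
})

test_that("response transforms and their domain rules", {
  expect_equal(as.numeric(transform_response(1, "log")), 0)
  expect_equal(as.numeric(transform_response(0.5, "logit")), 0)
  expect_equal(as.numeric(transform_response(0.75, "logit")), log(3))
  y <- c(0.2, 0, 1, 0.8, NA)
  t1 <- transform_response(y, "logit")
  expect_equal(attr(t1, "n_dropped"), 3L)
  expect_equal(attr(t1, "keep"), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  t2 <- transform_response(c(-1, 2, 0), "log")
  expect_equal(attr(t2, "n_dropped"), 2L)
  expect_equal(as.numeric(transform_response(y, "identity")), y[!is.na(y)])
})

test_that("marginal covariance: closed forms and elementwise oracle", {
  d <- data.frame(id = c(1, 1, 1, 2, 2), x = c(-1, 0, 1, 0.5, -0.5),
                  year = c(2000, 2001, 2002, 2000, 2002),
                  month = c(5, 6, 7, 5, 7))
  # compound symmetry when only V_int and V_resid are present
  V <- marginal_covariance(d, list(V_int = 2, V_resid = 3))
  expect_equal(diag(V), rep(5, 5))
  expect_equal(V[1, 2], 2); expect_equal(V[1, 4], 0)
  # rho = 0: year effects only shared within the same year
  V2 <- marginal_covariance(d, list(V_year = 1.5, rho_year = 0, V_resid = 1))
  expect_equal(V2[1, 4], 1.5)  # same year, different id
  expect_equal(V2[1, 2], 0)    # adjacent years decoupled
  # random thetas against the double-loop oracle
  set.seed(3)
  for (s in 1:10) {
    th <- list(V_int = runif(1, 0.1, 2), V_slope = runif(1, 0, 1),
               V_year = runif(1, 0, 1), rho_year = runif(1, -0.8, 0.8),
               V_month = runif(1, 0, 1), V_resid = runif(1, 0.2, 2))
    th$Cov <- runif(1, -1, 1) * sqrt(th$V_int * th$V_slope)
    dd <- data.frame(id = sample(1:4, 12, TRUE), x = rnorm(12),
                     year = sample(2000:2003, 12, TRUE),
                     month = sample(5:9, 12, TRUE))
    expect_equal(marginal_covariance(dd, th), cov_oracle(dd, th),
                 tolerance = 1e-12)
  }
})

test_that("kernel log-likelihood equals a direct MVN density", {
  set.seed(4)
  for (s in 1:8) {
    n <- sample(15:30, 1)
    d <- data.frame(id = sort(sample(1:6, n, TRUE)), x = rnorm(n),
                    year = sample(2000:2005, n, TRUE),
                    month = sample(5:9, n, TRUE))
    d$y <- rnorm(n)
    th <- list(V_int = runif(1, 0.1, 1.5), V_slope = runif(1, 0.01, 0.8),
               V_year = runif(1, 0.05, 1), rho_year = runif(1, -0.7, 0.7),
               V_month = runif(1, 0.05, 1), V_resid = runif(1, 0.3, 2))
    th$Cov <- runif(1, -0.9, 0.9) * sqrt(th$V_int * th$V_slope)
    beta <- rnorm(2)
    ll <- rrn_loglik(d, th, beta = beta, include_year_ar1 = TRUE,
                     include_month = TRUE)
    V <- cov_oracle(d, th)
    ll_or <- mvn_loglik_oracle(d$y, beta[1] + beta[2] * d$x, V)
    expect_equal(ll, ll_or, tolerance = 1e-8)
  }
})

test_that("fitted likelihood dominates the truth and nests monotonically", {
  th <- list(V_int = 0.5, V_slope = 0.2, Cov = -0.2, V_resid = 1)
  d <- sim_rrn_data(60, 6, th, seed = 41)
  f_full <- fit_rrn(d, "full", n_starts = 2)
  f_zc <- fit_rrn(d, "zero_corr", n_starts = 2)
  f_int <- fit_rrn(d, "intercept_only", n_starts = 2)
  expect_true(f_full$converged)
  expect_gte(f_full$logLik, rrn_loglik(d, th))          # ML dominance
  expect_gte(f_full$logLik, f_zc$logLik - 1e-6)         # nesting
  expect_gte(f_zc$logLik, f_int$logLik - 1e-6)
})

test_that("estimates are invariant to row order and covariate scaling", {
  th <- list(V_int = 0.6, V_slope = 0.25, Cov = -0.15, V_resid = 0.8)
  d <- sim_rrn_data(40, 5, th, seed = 42)
  f1 <- fit_rrn(d, "full", n_starts = 1)
  d_shuf <- d[sample(nrow(d)), ]
  f2 <- fit_rrn(d_shuf, "full", n_starts = 1)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-5)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-4)
  # scaling x by c rescales beta_x by 1/c and V_slope by 1/c^2
  c0 <- 2.5
  d_sc <- d; d_sc$x <- d$x * c0
  f3 <- fit_rrn(d_sc, "full", n_starts = 1)
  bx1 <- f1$coefficients$estimate[f1$coefficients$term == "x"]
  bx3 <- f3$coefficients$estimate[f3$coefficients$term == "x"]
  expect_equal(bx3, bx1 / c0, tolerance = 1e-3)
  expect_equal(f3$theta$V_slope, f1$theta$V_slope / c0^2, tolerance = 5e-3)
  expect_equal(f3$logLik, f1$logLik, tolerance = 1e-4)
})

test_that("balanced intercept-only fit matches one-way ANOVA closed forms", {
  set.seed(43)
  m <- 60; k <- 8
  d <- data.frame(id = rep(1:m, each = k), x = rnorm(m * k))
  d$y <- 2 + rnorm(m, 0, sqrt(0.7))[d$id] + rnorm(m * k, 0, 1)
  f <- fit_rrn(d, "intercept_only", n_starts = 1)
  ybar_i <- tapply(d$y, d$id, mean)
  ssw <- sum((d$y - ybar_i[d$id])^2)
  s2e <- ssw / (m * (k - 1))
  s2a <- (k * sum((ybar_i - mean(d$y))^2) / m - s2e) / k
  expect_equal(f$theta$V_resid, s2e, tolerance = 0.01)
  expect_equal(f$theta$V_int, s2a, tolerance = 0.01)
})

test_that("degenerate covariate designs fall back to intercept-only", {
  d <- data.frame(id = rep(1:10, each = 3), x = 1, y = rnorm(30))
  d$x <- rep(1, 30)
  expect_warning(f <- fit_rrn(d, "full", n_starts = 1), "distinct covariate")
  expect_equal(f$random, "intercept_only")
})

test_that("Wald chi-square tests follow the chi2(1) reference", {
  fit <- structure(list(coefficients = data.frame(
    term = c("a", "b"), estimate = c(1.96, 0), se = c(1, 1))),
    class = "rrn_fit")
  wt <- wald_tests(fit)
  expect_equal(wt$chisq, c(3.8416, 0), tolerance = 1e-6)
  expect_equal(wt$p[1], 0.05, tolerance = 2e-3)
  expect_equal(wt$p[2], 1)
  expect_true(all(wt$df == 1))
})

test_that("sex enters the design as main effect plus interaction", {
  th <- list(V_int = 0.3, V_resid = 1)
  d <- sim_rrn_data(40, 4, th, seed = 44)
  d$sex <- rep(c("F", "M"), length.out = nrow(d))
  f <- fit_rrn(d, "zero_corr", n_starts = 1)
  expect_setequal(f$coefficients$term,
                  c("(Intercept)", "sexM", "x", "sexM:x"))
})
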