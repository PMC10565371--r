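# Study-shaped longitudinal draw straight from the reaction-norm model:
# a yearly standardized covariate shared by all individuals, each individual
# observed in a random subset of years (p_obs ~ 0.22 gives ~6.8 measures
# per individual over 30 years, the scale of a long-term photo-ID study).
sim_longitudinal <- function(m, n_years, theta, beta = c(1, 0.3),
                             p_obs = 0.22, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- function(nm) if (!is.null(theta[[nm]])) theta[[nm]] else 0
  xy <- as.numeric(scale(stats::arima.sim(list(ar = 0.4), n_years)))
  G <- matrix(c(g("V_int"), g("Cov"), g("Cov"), g("V_slope")), 2)
  e <- eigen(G, symmetric = TRUE)
  u <- matrix(rnorm(m * 2), m) %*%
    (e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    yrs <- which(runif(n_years) < p_obs)
    if (!length(yrs)) next
    rows[[i]] <- data.frame(id = i, year = yrs, x = xy[yrs])
  }
  d <- do.call(rbind, rows)
  d$y <- beta[1] + beta[2] * d$x + u[d$id, 1] + u[d$id, 2] * d$x +
    rnorm(nrow(d), 0, sqrt(g("V_resid")))
  d
}
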