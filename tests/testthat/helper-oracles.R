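# Independent oracles used by the test suite. Everything here is written
# from first principles (double loops, exhaustive enumeration, direct
# matrix-algebra densities) and deliberately shares no code with the
# package implementation paths it checks.

# --- simple ratio index by explicit pair counting -----------------------
sri_oracle <- function(encounters) {
  ids <- sort(unique(encounters$individual_id))
  encs <- split(encounters$individual_id, encounters$encounter_id)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      together <- 0L; either <- 0L
      for (e in encs) {
        a <- ids[i] %in% e; b <- ids[j] %in% e
        if (a && b) together <- together + 1L
        if (a || b) either <- either + 1L
      }
      W[i, j] <- if (either > 0) together / either else 0
    }
  }
  W
}

# --- Barrat weighted clustering by triple enumeration -------------------
barrat_oracle <- function(W) {
  n <- nrow(W)
  a <- (W > 0) * 1
  s <- rowSums(W)
  k <- rowSums(a)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    tot <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == h || j == i || h == i) next
        tot <- tot + ((W[i, j] + W[i, h]) / 2) * a[i, j] * a[i, h] * a[j, h]
      }
    }
    out[i] <- tot / (s[i] * (k[i] - 1))
  }
  out
}

# --- size-corrected closeness via Floyd-Warshall ------------------------
closeness_oracle <- function(W) {
  n <- nrow(W)
  if (n == 1) return(0)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0) 0 else (r / sum(d)) * (r / (n - 1))
  }, numeric(1))
}

# --- elementwise marginal covariance (naive double loop) ----------------
cov_oracle <- function(data, theta) {
  g <- function(nm) if (!is.null(theta[[nm]])) theta[[nm]] else 0
  n <- nrow(data)
  V <- matrix(0, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      v <- 0
      if (data$id[s] == data$id[t]) {
        v <- v + g("V_int") + g("Cov") * (data$x[s] + data$x[t]) +
          g("V_slope") * data$x[s] * data$x[t]
      }
      if (g("V_year") > 0) {
        v <- v + g("V_year") * g("rho_year")^abs(data$year[s] - data$year[t])
      }
      if (g("V_month") > 0 && data$year[s] == data$year[t] &&
          data$month[s] == data$month[t]) {
        v <- v + g("V_month")
      }
      if (s == t) v <- v + g("V_resid")
      V[s, t] <- v
    }
  }
  V
}

# multivariate normal log density from the covariance matrix directly
mvn_loglik_oracle <- function(y, mean, V) {
  n <- length(y)
  L <- chol(V)
  r <- y - mean
  z <- backsolve(L, r, transpose = TRUE)
  -0.5 * (2 * sum(log(diag(L))) + sum(z^2) + n * log(2 * pi))
}

# --- tiny builders ------------------------------------------------------

# wrap a symmetric weight matrix as a social_network (sightings cosmetic)
net_from_weights <- function(W, ids = NULL) {
  n <- nrow(W)
  ids <- ids %||% sprintf("n%02d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(list(window = "w", ids = ids, weights = W,
                 pair_counts = ceiling(W * 10), sightings = setNames(rep(5, n), ids),
                 n_encounters = 10L),
            class = "social_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_weighted_graph <- function(n, p_edge = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  w <- ifelse(runif(m) < p_edge, round(runif(m, 0.05, 1), 3), 0)
  W[upper.tri(W)] <- w
  W + t(W)
}

random_encounter_table <- function(n_ind = 10, n_enc = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("A%02d", seq_len(n_ind))
  rows <- lapply(seq_len(n_enc), function(e) {
    size <- sample.int(min(n_ind, 6), 1)
    data.frame(encounter_id = sprintf("e%03d", e),
               survey_id = sprintf("s%03d", e),
               year = 2000L, month = 6L, day = 1L,
               individual_id = sample(ids, size),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- direct draw from the reaction-norm LMM (for fitting checks) --------
sim_rrn_data <- function(m, k, theta, beta = c(1, 0.3), x = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- function(nm) if (!is.null(theta[[nm]])) theta[[nm]] else 0
  G <- matrix(c(g("V_int"), g("Cov"), g("Cov"), g("V_slope")), 2)
  e <- eigen(G, symmetric = TRUE)
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  u <- matrix(rnorm(m * 2), m) %*% root
  d <- data.frame(id = rep(seq_len(m), each = k),
                  x = if (is.null(x)) rnorm(m * k) else rep(x, m))
  d$y <- beta[1] + beta[2] * d$x + u[d$id, 1] + u[d$id, 2] * d$x +
    rnorm(m * k, 0, sqrt(g("V_resid")))
  d
}
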