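test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(detection_prob = 0), "detection_prob")
  expect_error(sim_config(surveys_per_year = c(5, 3)), "surveys_per_year")
  expect_error(sim_config(rn_covariance = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
  expect_error(sim_config(rn_covariance = matrix(c(1, 0, 0.5, 1), 2)),
               "symmetric")
})

test_that("AR1 index series has the configured lag-1 autocorrelation", {
  # 834 years x 12 months > 10,000 steps
  for (phi in c(0, 0.6)) {
    cfg <- sim_config(n_years = 834, env_model = "ar1_index",
                      env_params = list(ar1_phi = phi), seed = 101)
    env <- simulate_environment(cfg)
    r1 <- cor(env$value[-1], env$value[-nrow(env)])
    expect_lt(abs(r1 - phi), 0.03)
    expect_lt(abs(sd(env$value) - 1), 0.05)
  }
})

test_that("seasonal count series: degenerate seasonality recovers the mean, and the default is peaked and right-skewed", {
  cfg <- sim_config(n_years = 400, env_model = "seasonal_count",
                    env_params = list(seasonal_amplitude = 0,
                                      count_mean = 150), seed = 102)
  env <- simulate_environment(cfg)
  expect_true(all(env$value >= 0))
  se <- sqrt(var(env$value) / nrow(env))
  expect_lt(abs(mean(env$value) - 150), 4 * se)

  cfg2 <- sim_config(n_years = 200, env_model = "seasonal_count", seed = 103)
  env2 <- simulate_environment(cfg2)
  bym <- tapply(env2$value, env2$month, mean)
  expect_equal(as.integer(names(which.max(bym))),
               cfg2$env_params$seasonal_peak)
  expect_gt(mean(env2$value) , median(env2$value))  # right skew
})

test_that("yearly aggregation follows the series convention", {
  cfg <- sim_config(n_years = 3, env_model = "seasonal_count", seed = 9)
  env <- simulate_environment(cfg)
  ys <- yearly_series(env)
  expect_equal(ys$value, as.numeric(tapply(env$value, env$year, sum)))
  cfg2 <- sim_config(n_years = 3, env_model = "ar1_index", seed = 9)
  env2 <- simulate_environment(cfg2)
  expect_equal(yearly_series(env2)$value,
               as.numeric(tapply(env2$value, env2$year, mean)))
})

test_that("population draws match the configured moments", {
  cfg0 <- sim_config(n_individuals = 50,
                     rn_covariance = matrix(0, 2, 2), seed = 4)
  pop0 <- simulate_population(cfg0)
  expect_true(all(pop0$u0 == 0) && all(pop0$u1 == 0))

  cfg <- sim_config(n_individuals = 5000,
                    rn_covariance = matrix(c(1, -0.3, -0.3, 0.25), 2),
                    unknown_sex_frac = 0, seed = 5)
  pop <- simulate_population(cfg)
  expect_false(any(pop$sex == "U"))
  S <- cov(cbind(pop$u0, pop$u1))
  # sample-moment check: MC error of var/cov at n = 5000 is ~ 0.02-0.03
  expect_lt(abs(S[1, 1] - 1), 0.08)
  expect_lt(abs(S[2, 2] - 0.25), 0.03)
  expect_lt(abs(S[1, 2] + 0.3), 0.05)
  expect_false(any(duplicated(pop$id)))
  first_year <- cfg$start_year
  expect_true(all(is.na(pop$birth_year) |
                    pop$birth_year <= first_year + cfg$n_years))
})

test_that("encounter records respect their invariants", {
  cfg <- sim_config(n_individuals = 30, n_years = 2, seed = 6)
  env <- simulate_environment(cfg)
  pop <- simulate_population(cfg)
  enc <- simulate_encounters(cfg, env, pop)
  expect_true(all(enc$month %in% cfg$months_active))
  per <- split(enc$individual_id, enc$encounter_id)
  expect_true(all(vapply(per, function(v) !any(duplicated(v)), logical(1))))
  expect_true(all(lengths(per) >= 1))
  expect_error(simulate_encounters(cfg, env, pop[0, ]), "empty")
  expect_error(simulate_encounters(cfg, env[env$year != cfg$start_year, ], pop),
               "cover")
})

test_that("within-group photo-identification rate matches detection_prob", {
  cfg <- sim_config(n_individuals = 60, n_years = 40,
                    surveys_per_year = c(30, 35), detection_prob = 0.84,
                    seed = 7)
  env <- simulate_environment(cfg)
  pop <- simulate_population(cfg)
  enc <- simulate_encounters(cfg, env, pop)
  tr <- attr(enc, "truth")
  expect_gt(nrow(tr), 2000)  # plenty of group draws
  frac <- sum(tr$size_detected) / sum(tr$size_true)
  expect_lt(abs(frac - 0.84), 0.01)
})

test_that("expected detected group size increases with the covariate", {
  # hand-built environment of -1 / +1 months; beta_x = 0.5, no slope variance
  cfg <- sim_config(n_individuals = 40, n_years = 12,
                    surveys_per_year = c(30, 30), months_active = 5:8,
                    fixed_effects = c(intercept = 0.5, environment = 0.5),
                    rn_covariance = matrix(c(0.1, 0, 0, 0), 2),
                    seed = 8)
  env <- simulate_environment(cfg)
  env$value <- ifelse(env$month %% 2 == 0, 1, -1)
  pop <- simulate_population(cfg)
  enc <- simulate_encounters(cfg, env, pop)
  tr <- attr(enc, "truth")
  hi <- tr$size_true[tr$month %% 2 == 0]
  lo <- tr$size_true[tr$month %% 2 == 1]
  expect_gt(mean(hi), mean(lo))
})

test_that("a -Inf latent propensity forces singleton encounters", {
  cfg <- sim_config(n_individuals = 15, n_years = 1, n_communities = 1,
                    detection_prob = 1,
                    fixed_effects = c(intercept = -Inf),
                    rn_covariance = matrix(0, 2, 2), seed = 9)
  env <- simulate_environment(cfg)
  pop <- simulate_population(cfg)
  enc <- simulate_encounters(cfg, env, pop)
  expect_true(all(table(enc$encounter_id) == 1))
})

test_that("identical seeds give byte-identical encounter tables", {
  cfg <- sim_config(n_individuals = 25, n_years = 2, seed = 123)
  run <- function() {
    env <- simulate_environment(cfg)
    pop <- simulate_population(cfg)
    simulate_encounters(cfg, env, pop)
  }
  a <- run(); b <- run()
  expect_identical(as.data.frame(a), as.data.frame(b))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_encounters(a, f1); write_encounters(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("standardization round-trips and hits mean 0, sd 1", {
  set.seed(11)
  v <- rgamma(50, 2, 0.1)
  z <- standardize_covariate(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((as.numeric(z) - mean(z))^2)), 1, tolerance = 1e-12)
  expect_equal(destandardize(z), v, tolerance = 1e-10)
  zs <- standardize_covariate(v, method = "sample")
  expect_equal(sd(zs), 1, tolerance = 1e-12)
  # idempotence to tolerance
  z2 <- standardize_covariate(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-10)
  expect_error(standardize_covariate(rep(3, 5)), "constant")
})

test_that("uniform community affinity leaves associations community-blind", {
  cfg <- sim_config(n_individuals = 40, n_years = 6,
                    surveys_per_year = c(25, 30), affinity_ratio = 1,
                    unknown_sex_frac = 0, seed = 12)
  env <- simulate_environment(cfg)
  pop <- simulate_population(cfg)
  enc <- simulate_encounters(cfg, env, pop)
  net <- build_network(as.data.frame(enc), window = "all")
  comm <- setNames(pop$community, pop$id)[net$ids]
  same <- outer(comm, comm, "==") & upper.tri(net$weights)
  diff <- (!outer(comm, comm, "==")) & upper.tri(net$weights)
  w_same <- mean(net$weights[same])
  w_diff <- mean(net$weights[diff])
  # MC check: within- and between-community mean SRI agree
  pool <- net$weights[upper.tri(net$weights)]
  se <- sd(pool) * sqrt(1 / sum(same) + 1 / sum(diff))
  expect_lt(abs(w_same - w_diff), 4 * se)
})
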