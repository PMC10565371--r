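#' Run the full trait x covariate x timescale model grid
#'
#' Drives the whole analysis on an encounter table: calf filtering, yearly
#' and monthly network construction (with the sparse-month filter), node
#' metrics, then one random-regression model per combination of social
#' trait (strength, clustering, closeness), environmental covariate and
#' timescale — 12 models for the default 3 x 2 x 2 grid. Each model fits the
#' full, zero-correlation and intercept-only random structures, runs the
#' two-stage plasticity testing procedure, and computes marginal
#' repeatability. A model never carries random slopes for more than one
#' covariate (each model has exactly one environmental variable).
#'
#' Responses are transformed before fitting: log for strength and
#' closeness (right-skewed, positive), logit for the clustering coefficient
#' (bounded in (0, 1)); rows outside the transform domain are dropped and
#' counted. The covariate is mean-centred and scaled to unit variance over
#' the rows entering each fit.
#'
#' @param encounters long-format encounter table.
#' @param metadata individual metadata (`id`, `sex`, `birth_year`).
#' @param environments named list of `env_series`, e.g.
#'   `list(climate_index = ..., resource_count = ...)`.
#' @param traits,timescales subsets of the default grid.
#' @param min_age,min_encounters_per_month,min_sightings filtering
#'   thresholds (defaults 3 years, 10 encounters, 5 sightings).
#' @param alpha clarity threshold for the tests.
#' @param n_starts optimizer starts per fit.
#' @param seed seed for optimizer start jitter.
#' @param verbose log filtering and per-model progress via `message()`.
#' @return an `rrn_study`: list with data frames `fixed_effects`,
#'   `variance_components`, `lrt_decisions`, `repeatability`, a `models`
#'   list of per-cell details (fits, tests, audit trail), and `log`.
#' @export
run_study <- function(encounters, metadata, environments,
                      traits = c("strength", "clustering", "closeness"),
                      timescales = c("year", "month"),
                      min_age = 3, min_encounters_per_month = 10,
                      min_sightings = 5, alpha = 0.05,
                      n_starts = 3, seed = 1L, verbose = FALSE) {
  stopifnot(is.list(environments), length(names(environments)) > 0)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }

  n0 <- nrow(encounters)
  encounters <- filter_calves(encounters, metadata, min_age = min_age)
  say("age filter (< %d years): removed %d of %d rows, leaving %d",
      min_age, attr(encounters, "n_removed"), n0, nrow(encounters))

  nets <- list()
  for (ts in timescales) {
    wins <- window_encounters(encounters, scale = ts)
    if (ts == "month") {
      wins <- drop_sparse_windows(wins, min_encounters = min_encounters_per_month)
      wl <- attr(wins, "window_log")
      say("month filter (< %d encounters): removed %d of %d months, leaving %d",
          min_encounters_per_month, sum(!wl$retained), nrow(wl),
          sum(wl$retained))
    }
    nets[[ts]] <- lapply(names(wins), function(w) build_network(wins[[w]], window = w))
  }

  transforms <- c(strength = "log", clustering = "logit", closeness = "log")
  trait_cols <- c(strength = "strength", clustering = "clustering",
                  closeness = "closeness")

  fixed_effects <- list(); var_comps <- list(); lrt_rows <- list()
  rep_rows <- list(); models <- list()

  for (ts in timescales) {
    if (length(nets[[ts]]) == 0) {
      say("timescale %s: no windows retained; %d model(s) skipped", ts,
          length(traits) * length(environments))
      for (cv in names(environments)) for (tr in traits) {
        key <- paste(tr, cv, ts, sep = ".")
        models[[key]] <- list(status = "no windows retained")
      }
      next
    }
    for (cv in names(environments)) {
      tab <- metrics_table(nets[[ts]], metadata, environments[[cv]],
                           timescale = ts, min_sightings = min_sightings)
      say("timescale %s, covariate %s: %d scores; sighting mask removed %d, unknown sex removed %d, analysing %d",
          ts, cv, nrow(tab), sum(!tab$included_sightings),
          sum(tab$included_sightings & !tab$known_sex), sum(tab$included))
      for (tr in traits) {
        key <- paste(tr, cv, ts, sep = ".")
        cell <- list(trait = tr, covariate = cv, timescale = ts)
        d <- tab[tab$included, , drop = FALSE]
        yt <- transform_response(d[[trait_cols[tr]]], transforms[tr])
        d <- d[attr(yt, "keep"), , drop = FALSE]
        if (attr(yt, "n_dropped") > 0) {
          say("model %s: dropped %d rows outside the %s domain", key,
              attr(yt, "n_dropped"), transforms[tr])
        }
        if (nrow(d) < 10 || length(unique(d$covariate_raw)) < 2) {
          cell$status <- "insufficient data"
          models[[key]] <- cell
          say("model %s: insufficient data (%d rows)", key, nrow(d))
          next
        }
        md <- data.frame(y = as.numeric(yt),
                         x = as.numeric(standardize_covariate(d$covariate_raw)),
                         id = d$individual, sex = d$sex,
                         year = d$year, month = d$month)
        fits <- lapply(c(full = "full", zero_corr = "zero_corr",
                         intercept_only = "intercept_only"), function(rs) {
          fit_rrn(md, random = rs, include_year_ar1 = TRUE,
                  include_month = (ts == "month"), n_starts = n_starts,
                  seed = derive_seed(seed, nchar(key)))
        })
        tests <- plasticity_tests(fits$full, fits$zero_corr,
                                  fits$intercept_only, alpha = alpha)
        fit <- fits$full
        cell$fits <- fits; cell$tests <- tests; cell$status <- "ok"
        if (!isTRUE(fit$converged)) cell$status <- "full model not converged"
        models[[key]] <- cell

        if (!is.null(fit$coefficients)) {
          wt <- wald_tests(fit)
          wt$trait <- tr; wt$covariate <- cv; wt$timescale <- ts
          fixed_effects[[key]] <- wt
          th <- fit$theta
          var_comps[[key]] <- data.frame(
            trait = tr, covariate = cv, timescale = ts,
            V_int = th$V_int, V_slope = th$V_slope, Cov = th$Cov,
            corr = fit$corr, V_year = th$V_year, rho_year = th$rho_year,
            V_month = th$V_month, V_resid = th$V_resid,
            logLik = fit$logLik, n_obs = fit$n_obs,
            n_individuals = fit$n_individuals,
            converged = fit$converged)
          rp <- marginal_repeatability(fit)
          rep_rows[[key]] <- data.frame(
            trait = tr, covariate = cv, timescale = ts,
            R_marginal = rp$R_marginal,
            R_minus2 = rp$conditional$R[rp$conditional$x == -2],
            R_0 = rp$conditional$R[rp$conditional$x == 0],
            R_plus2 = rp$conditional$R[rp$conditional$x == 2])
        }
        ct <- tests$correlation_test; st <- tests$slope_test
        lrt_rows[[key]] <- data.frame(
          trait = tr, covariate = cv, timescale = ts,
          isc = fit$corr,
          isc_stat = if (is.null(ct)) NA_real_ else ct$statistic,
          isc_p = if (is.null(ct)) NA_real_ else ct$p,
          isc_clear = tests$correlation_clear,
          slope_comparison = if (is.null(st)) NA_character_ else st$comparison,
          slope_stat = if (is.null(st)) NA_real_ else st$statistic,
          slope_p = if (is.null(st)) NA_real_ else st$p,
          slopes_clear = tests$slopes_clear,
          procedure = paste(tests$procedure, collapse = " | "))
        say("model %s: %s", key, utils::tail(tests$procedure, 1))
      }
    }
  }

  rbind_all <- function(lst) {
    if (length(lst) == 0) return(NULL)
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  structure(list(
    fixed_effects = rbind_all(fixed_effects),
    variance_components = rbind_all(var_comps),
    lrt_decisions = rbind_all(lrt_rows),
    repeatability = rbind_all(rep_rows),
    models = models,
    log = log_lines,
    settings = list(min_age = min_age,
                    min_encounters_per_month = min_encounters_per_month,
                    min_sightings = min_sightings, alpha = alpha,
                    seed = seed)
  ), class = "rrn_study")
}

#' @export
print.rrn_study <- function(x, ...) {
  n_ok <- sum(vapply(x$models, function(m) identical(m$status, "ok"), logical(1)))
  cat(sprintf("<rrn_study> %d model cells (%d fitted cleanly)\n",
              length(x$models), n_ok))
  if (!is.null(x$lrt_decisions)) {
    print(x$lrt_decisions[, c("trait", "covariate", "timescale", "isc",
                              "isc_p", "isc_clear", "slope_p", "slopes_clear")])
  }
  invisible(x)
}

#' Write a study results bundle to CSV files
#'
#' Writes `fixed_effects.csv`, `variance_components.csv`,
#' `lrt_decisions.csv`, `repeatability.csv`, a `filter_log.txt` and a JSON
#' manifest into `dir`.
#'
#' @param study an `rrn_study`.
#' @param dir output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
write_study_results <- function(study, dir) {
  stopifnot(inherits(study, "rrn_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("fixed_effects", "variance_components", "lrt_decisions",
               "repeatability")) {
    df <- study[[nm]]
    if (!is.null(df)) {
      write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  writeLines(study$log, file.path(dir, "filter_log.txt"))
  jsonlite::write_json(list(package = "plastnet", settings = study$settings,
                            n_models = length(study$models)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Render a plain-text report of a study
#'
#' One section per model cell with the fixed-effect table (estimate, SE,
#' chi-square, p), the variance components, the plasticity test decisions
#' and repeatabilities; convergence warnings are surfaced inline.
#'
#' @param study an `rrn_study`.
#' @param path output text file, or NULL to return the lines.
#' @return (invisibly) the report lines.
#' @export
report_study <- function(study, path = NULL) {
  stopifnot(inherits(study, "rrn_study"))
  L <- c("Social network reaction-norm study report",
         strrep("=", 42), "", "Filtering log:", paste(" ", study$log), "")
  for (key in names(study$models)) {
    m <- study$models[[key]]
    L <- c(L, sprintf("Model %s", key), strrep("-", 40))
    if (!identical(m$status, "ok")) {
      L <- c(L, sprintf("  status: %s", m$status %||% "unknown"), "")
      if (is.null(m$fits)) next
    }
    fit <- m$fits$full
    if (!isTRUE(fit$converged)) {
      L <- c(L, "  WARNING: full model did not converge")
    }
    wt <- wald_tests(fit)
    for (i in seq_len(nrow(wt))) {
      L <- c(L, sprintf("  %-12s beta = %8.4f +/- %.4f   chi2(1) = %7.3f  p = %.4g",
                        wt$term[i], wt$estimate[i], wt$se[i], wt$chisq[i],
                        wt$p[i]))
    }
    th <- fit$theta
    L <- c(L, sprintf("  variance components: V_int=%.4g V_slope=%.4g corr=%.3f V_year=%.4g rho=%.3f V_month=%.4g V_resid=%.4g",
                      th$V_int, th$V_slope, fit$corr, th$V_year,
                      th$rho_year, th$V_month, th$V_resid))
    L <- c(L, paste("  procedure:", paste(m$tests$procedure, collapse = "; ")))
    rp <- marginal_repeatability(fit)
    L <- c(L, sprintf("  marginal repeatability = %.4f (R at x=-2: %.4f, x=+2: %.4f)",
                      rp$R_marginal, rp$conditional$R[1],
                      rp$conditional$R[nrow(rp$conditional)]), "")
  }
  if (!is.null(path)) writeLines(L, path)
  invisible(L)
}
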