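#' Simulate photo-identification encounters
#'
#' Emulates a boat-survey observation process. For each year a number of
#' surveys is drawn uniformly from `surveys_per_year` and placed uniformly
#' over `months_active`. On each survey every born individual is available
#' independently with `presence_prob`; available individuals are then
#' partitioned into groups by sequential preference-weighted assignment:
#' taken in random order, individual *i* joins an existing group *g* with
#' weight \eqn{\exp(\eta_{it}) \times |g| \times a_{ig}} (where
#' \eqn{a_{ig}} is `affinity_ratio` when *i* shares the group founder's
#' community, else 1) or founds a new group with weight `new_group_weight`.
#' The linear predictor
#' \eqn{\eta_{it} = \beta_0 + \beta_x x_t + \beta_s s_i + \beta_{sx} s_i x_t
#' + u_{0i} + u_{1i} x_t} uses the standardized monthly environmental value
#' \eqn{x_t}, so expected group size is non-decreasing in \eqn{\eta}.
#' Finally each group member is photo-identified independently with
#' `detection_prob`; groups with no detected member leave no record.
#'
#' @param config a [sim_config()].
#' @param env an `env_series` from [simulate_environment()] covering all
#'   simulated years.
#' @param pop population data frame from [simulate_population()].
#' @return long-format data frame (class `encounter_table`): one row per
#'   detected individual per encounter, columns `encounter_id`, `survey_id`,
#'   `year`, `month`, `day`, `individual_id`. A `truth` attribute records,
#'   per simulated group, the true and detected sizes (for calibration
#'   checks only).
#' @export
simulate_encounters <- function(config, env, pop) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(pop) == 0) stop("empty population", call. = FALSE)
  years <- config$start_year + seq_len(config$n_years) - 1L
  if (!all(years %in% env$year)) {
    stop("environmental series does not cover all simulated years",
         call. = FALSE)
  }

  # standardize the monthly series once so eta lives on a stable scale
  z <- (env$value - mean(env$value)) /
    max(sqrt(mean((env$value - mean(env$value))^2)), .Machine$double.eps)
  zkey <- setNames(z, paste(env$year, env$month, sep = "-"))

  fe <- config$fixed_effects
  sex_num <- ifelse(pop$sex == "M", 1, 0)   # F and unknown at baseline

  with_stream_seed(config$seed, 3L, {
    rows <- vector("list", 2048L)
    truth <- vector("list", 2048L)
    nrow_used <- 0L
    ntruth <- 0L
    enc_counter <- 0L
    srv_counter <- 0L

    for (yr in years) {
      n_srv <- sample(seq(config$surveys_per_year[1],
                          config$surveys_per_year[2]), 1L)
      srv_month <- sort(sample(config$months_active, n_srv, replace = TRUE))
      srv_day <- sample(1:28, n_srv, replace = TRUE)
      for (s in seq_len(n_srv)) {
        srv_counter <- srv_counter + 1L
        mo <- srv_month[s]
        x_t <- zkey[[paste(yr, mo, sep = "-")]]
        born <- is.na(pop$birth_year) | pop$birth_year <= yr
        avail <- which(born & runif(nrow(pop)) < config$presence_prob)
        if (length(avail) == 0) next

        eta <- fe["intercept"] + fe["environment"] * x_t +
          fe["sex"] * sex_num[avail] +
          fe["sex_environment"] * sex_num[avail] * x_t +
          pop$u0[avail] + pop$u1[avail] * x_t
        w_self <- exp(eta)

        order_i <- sample(seq_along(avail))
        groups <- list()
        founder_comm <- integer(0)
        for (k in order_i) {
          w_join <- if (length(groups)) {
            vapply(seq_along(groups), function(g) {
              aff <- if (pop$community[avail[k]] == founder_comm[g]) {
                config$affinity_ratio
              } else 1
              w_self[k] * length(groups[[g]]) * aff
            }, numeric(1))
          } else numeric(0)
          w <- c(w_join, config$new_group_weight)
          w[!is.finite(w)] <- .Machine$double.xmax / (length(w) + 1)
          pick <- sample.int(length(w), 1L, prob = w)
          if (pick > length(groups)) {
            groups[[length(groups) + 1L]] <- avail[k]
            founder_comm <- c(founder_comm, pop$community[avail[k]])
          } else {
            groups[[pick]] <- c(groups[[pick]], avail[k])
          }
        }

        for (g in seq_along(groups)) {
          members <- groups[[g]]
          seen <- members[runif(length(members)) < config$detection_prob]
          ntruth <- ntruth + 1L
          if (ntruth > length(truth)) truth <- c(truth, vector("list", length(truth)))
          truth[[ntruth]] <- c(yr, mo, length(members), length(seen))
          if (length(seen) == 0) next
          enc_counter <- enc_counter + 1L
          nrow_used <- nrow_used + 1L
          if (nrow_used > length(rows)) rows <- c(rows, vector("list", length(rows)))
          rows[[nrow_used]] <- data.frame(
            encounter_id = sprintf("E%06d", enc_counter),
            survey_id = sprintf("S%05d", srv_counter),
            year = yr, month = mo, day = srv_day[s],
            individual_id = pop$id[seen],
            stringsAsFactors = FALSE)
        }
      }
    }

    out <- do.call(rbind, rows[seq_len(nrow_used)])
    if (is.null(out)) {
      out <- data.frame(encounter_id = character(), survey_id = character(),
                        year = integer(), month = integer(), day = integer(),
                        individual_id = character(), stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, truth[seq_len(ntruth)])
    tr <- as.data.frame(tr)
    names(tr) <- c("year", "month", "size_true", "size_detected")
    structure(out, class = c("encounter_table", "data.frame"), truth = tr)
  })
}
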