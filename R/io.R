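#' Read and write pipeline data files
#'
#' Plain-CSV interchange for the three core inputs: long-format encounter
#' tables (one row per individual per encounter), individual metadata, and
#' monthly environmental series. `write_simulation()` writes all three plus
#' a JSON manifest recording the generating configuration and seed.
#'
#' @param x object to write.
#' @param path file path.
#' @name plastnet_io
NULL

#' @rdname plastnet_io
#' @export
write_encounters <- function(x, path) {
  write.csv(as.data.frame(x)[, c("encounter_id", "survey_id", "year",
                                 "month", "day", "individual_id")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname plastnet_io
#' @export
read_encounters <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("encounter_id", "survey_id", "year", "month", "day",
            "individual_id")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("malformed encounter CSV, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(x[, need], class = c("encounter_table", "data.frame"))
}

#' @rdname plastnet_io
#' @export
write_metadata <- function(x, path) {
  write.csv(as.data.frame(x)[, c("id", "sex", "birth_year")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname plastnet_io
#' @export
read_metadata <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "sex"), names(x))
  if (length(miss)) {
    stop("malformed metadata CSV, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$birth_year)) x$birth_year <- NA_integer_
  x
}

#' @rdname plastnet_io
#' @export
write_environment <- function(x, path) {
  df <- as.data.frame(x)[, c("year", "month", "value")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname plastnet_io
#' @param yearly_aggregate `"mean"` or `"sum"`, how to roll the monthly
#'   series up to years when reading back.
#' @export
read_environment <- function(path, yearly_aggregate = "mean") {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("year", "month", "value"), names(x))
  if (length(miss)) {
    stop("malformed environment CSV, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(x, class = c("env_series", "data.frame"),
            yearly_aggregate = yearly_aggregate)
}

#' Write a simulated dataset and its manifest
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if absent).
#' @return (invisibly) named vector of the file paths written.
#' @export
write_simulation <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- simulate_environment(config)
  pop <- simulate_population(config)
  enc <- simulate_encounters(config, env, pop)
  paths <- c(encounters = file.path(dir, "encounters.csv"),
             metadata = file.path(dir, "metadata.csv"),
             environment = file.path(dir, "environment.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_encounters(enc, paths["encounters"])
  write_metadata(pop, paths["metadata"])
  write_environment(env, paths["environment"])
  manifest <- list(
    package = "plastnet",
    created = "simulated dataset",
    seed = config$seed,
    config = unclass(config),
    rows = list(encounters = nrow(enc), individuals = nrow(pop),
                environment = nrow(env))
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
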