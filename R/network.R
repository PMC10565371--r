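#' Remove encounters of dependent calves
#'
#' Drops rows for individuals younger than `min_age` in the encounter year,
#' since the associations of dependent calves mostly reflect the mother's
#' preferences. Individuals of unknown birth year (first catalogued as
#' adults) are retained.
#'
#' @param encounters long-format encounter table.
#' @param metadata data frame with `id` and `birth_year`.
#' @param min_age minimum age in years to retain (default 3).
#' @return filtered encounter table; attribute `n_removed` records the row
#'   count removed.
#' @export
filter_calves <- function(encounters, metadata, min_age = 3) {
  birth <- setNames(metadata$birth_year, metadata$id)
  b <- birth[encounters$individual_id]
  keep <- is.na(b) | (encounters$year - b) >= min_age
  out <- encounters[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(encounters),
            n_removed = sum(!keep),
            truth = attr(encounters, "truth"))
}

#' Partition encounters into time windows
#'
#' @param encounters long-format encounter table.
#' @param scale `"year"` (calendar years) or `"month"` (calendar
#'   year-months; months never span years).
#' @return named list of encounter tables, one per window, labelled
#'   `"1990"` or `"1990-06"`.
#' @export
window_encounters <- function(encounters, scale = c("year", "month")) {
  scale <- match.arg(scale)
  lab <- if (scale == "year") {
    sprintf("%d", encounters$year)
  } else {
    sprintf("%d-%02d", encounters$year, encounters$month)
  }
  out <- split(as.data.frame(encounters), lab)
  out[order(names(out))]
}

#' Drop windows with too few encounters
#'
#' Networks built from very few grouping records are unreliable, so monthly
#' windows with fewer than `min_encounters` encounters are removed before
#' any network is built.
#'
#' @param windows named list from [window_encounters()].
#' @param min_encounters minimum number of distinct encounters (default 10).
#' @param verbose print a retention log line.
#' @return the retained windows; attribute `window_log` holds a data frame
#'   of per-window encounter counts and retention flags.
#' @export
drop_sparse_windows <- function(windows, min_encounters = 10,
                                verbose = FALSE) {
  counts <- vapply(windows, function(w) length(unique(w$encounter_id)),
                   integer(1))
  keep <- counts >= min_encounters
  if (verbose) {
    message(sprintf("drop_sparse_windows: removed %d of %d windows (< %d encounters), leaving %d",
                    sum(!keep), length(windows), min_encounters, sum(keep)))
  }
  structure(windows[keep],
            window_log = data.frame(window = names(windows),
                                    n_encounters = as.integer(counts),
                                    retained = keep, row.names = NULL))
}

#' Build a weighted social network from one window of encounters
#'
#' Applies the gambit of the group: all individuals identified in the same
#' encounter are taken to be associating. The encounter table is converted
#' to a group-by-individual matrix and edge weights are the simple ratio
#' index
#' \deqn{SRI_{ij} = x_{ij} / (n_i + n_j - x_{ij})}
#' where \eqn{x_{ij}} counts encounters containing both individuals and
#' \eqn{n_i} counts encounters containing \eqn{i}; the index runs from 0
#' (never seen together) to 1 (always seen together). Every individual
#' sighted in the window becomes a node, regardless of any later masking
#' of its own trait scores.
#'
#' @param encounters encounter table for a single window (>= 1 encounter).
#' @param window optional window label.
#' @return a `social_network`: list with `window`, `ids`, `weights`
#'   (symmetric, zero diagonal), `pair_counts`, `sightings`, `n_encounters`.
#' @export
#' @examples
#' enc <- data.frame(encounter_id = c("e1", "e1", "e2", "e2", "e3"),
#'                   individual_id = c("A", "B", "A", "C", "B"))
#' net <- build_network(enc)
#' net$weights
build_network <- function(encounters, window = NULL) {
  if (is.null(encounters) || nrow(encounters) == 0) {
    stop("cannot build a network from an empty window", call. = FALSE)
  }
  gbi <- group_by_individual(encounters)
  x <- crossprod(gbi)              # joint sighting counts
  n <- diag(x)                     # per-individual sighting counts
  denom <- outer(n, n, "+") - x
  w <- x / denom
  diag(w) <- 0
  structure(list(window = window %||% NA_character_,
                 ids = colnames(gbi),
                 weights = w,
                 pair_counts = x,
                 sightings = n,
                 n_encounters = nrow(gbi)),
            class = "social_network")
}

#' Group-by-individual matrix for one window
#'
#' @param encounters encounter table for a single window.
#' @return binary matrix, encounters (rows) by individuals (columns,
#'   sorted ids).
#' @export
group_by_individual <- function(encounters) {
  tab <- table(encounters$encounter_id, encounters$individual_id)
  gbi <- matrix(as.integer(tab > 0), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  gbi[, order(colnames(gbi)), drop = FALSE]
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network> window %s: %d individuals, %d encounters, %d non-zero edges\n",
              x$window, length(x$ids), x$n_encounters,
              sum(x$weights > 0) / 2))
  invisible(x)
}

#' Plot a social network
#'
#' Basic force-directed display: vertices are individuals, edge width is
#' proportional to the simple ratio index.
#'
#' @param x a `social_network`.
#' @param ... passed on to [igraph::plot.igraph()].
#' @export
plot.social_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(g, edge.width = 1 + 4 * igraph::E(g)$weight,
                      vertex.size = 6, vertex.label = NA,
                      main = paste("window", x$window), ...)
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write a network edge list as CSV
#'
#' One row per non-zero edge: `i, j, x_ij, n_i, n_j, sri`.
#'
#' @param net a `social_network`.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  df <- data.frame(i = net$ids[idx[, 1]],
                   j = net$ids[idx[, 2]],
                   x_ij = net$pair_counts[idx],
                   n_i = net$sightings[idx[, 1]],
                   n_j = net$sightings[idx[, 2]],
                   sri = net$weights[idx])
  write.csv(df[order(df$i, df$j), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
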