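#' Node strength
#'
#' Sum of all of an individual's association weights. With simple-ratio
#' edges from grouped sightings this is a proxy for gregariousness (typical
#' group size experienced).
#'
#' @param net a `social_network`.
#' @param node optional id (or vector of ids); default all nodes.
#' @return named numeric vector of strengths (0 for isolated nodes).
#' @export
strength <- function(net, node = NULL) {
  s <- rowSums(net$weights)
  if (is.null(node)) return(s)
  if (!all(node %in% net$ids)) {
    stop("unknown node id(s): ",
         paste(setdiff(node, net$ids), collapse = ", "), call. = FALSE)
  }
  s[node]
}

#' Weighted clustering coefficient
#'
#' How strongly an individual's associates associate with each other. The
#' default is the Barrat et al. weighted form
#' \deqn{C_i = \frac{1}{s_i (k_i - 1)} \sum_{j,h}
#'   \frac{w_{ij} + w_{ih}}{2} a_{ij} a_{ih} a_{jh}}
#' (s = strength, k = degree, a = adjacency indicator), which lies in
#' [0, 1]. It is undefined (NA) for nodes with fewer than two network
#' neighbours. The Onnela et al. geometric-mean variant is available as a
#' sensitivity switch.
#'
#' @param net a `social_network`.
#' @param node optional id(s); default all nodes.
#' @param method `"barrat"` (default) or `"onnela"`.
#' @return named numeric vector; NA where undefined.
#' @export
clustering_coefficient <- function(net, node = NULL,
                                   method = c("barrat", "onnela")) {
  method <- match.arg(method)
  w <- net$weights
  a <- (w > 0) * 1
  k <- rowSums(a)
  cc <- if (method == "barrat") {
    g <- as_igraph(net)
    out <- igraph::transitivity(g, type = "barrat", isolates = "NaN")
    names(out) <- net$ids
    out
  } else {
    wh <- w / max(w)
    num <- diag(wh^(1 / 3) %*% wh^(1 / 3) %*% wh^(1 / 3))
    out <- num / (k * (k - 1))
    names(out) <- net$ids
    out
  }
  cc[k < 2] <- NA_real_
  cc[is.nan(cc)] <- NA_real_
  if (is.null(node)) return(cc)
  if (!all(node %in% net$ids)) {
    stop("unknown node id(s): ",
         paste(setdiff(node, net$ids), collapse = ", "), call. = FALSE)
  }
  cc[node]
}

#' Size-corrected weighted closeness
#'
#' Connectedness to the wider network: the inverse of the mean shortest-path
#' length from a node to every other node, corrected for network size so
#' values are comparable among windows with different numbers of
#' individuals. Edge lengths are reciprocal weights (stronger association =
#' shorter path). With R the set of nodes reachable from *i* (excluding
#' *i*), r = |R| and n the node count:
#' \deqn{closeness_i = \frac{r}{\sum_{j \in R} d(i,j)} \times \frac{r}{n-1}}
#' (Wasserman-Faust style reachable-fraction correction). On a connected
#' graph this reduces to \eqn{(n-1)/\sum_j d(i,j)}, the inverse mean path
#' length. Isolated nodes, and the single node of a 1-node network, score 0.
#'
#' @param net a `social_network`.
#' @param node optional id(s); default all nodes.
#' @return named numeric vector in [0, 1] when weights are in [0, 1].
#' @export
closeness <- function(net, node = NULL) {
  n <- length(net$ids)
  out <- setNames(numeric(n), net$ids)
  if (n > 1) {
    g <- as_igraph(net)
    dmat <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    for (i in seq_len(n)) {
      d <- dmat[i, -i]
      d <- d[is.finite(d)]
      r <- length(d)
      if (r > 0) out[i] <- (r / sum(d)) * (r / (n - 1))
    }
  }
  if (is.null(node)) return(out)
  if (!all(node %in% net$ids)) {
    stop("unknown node id(s): ",
         paste(setdiff(node, net$ids), collapse = ", "), call. = FALSE)
  }
  out[node]
}

#' Flag individuals with too few sightings in a window
#'
#' Individuals seen fewer than `min_sightings` times in a window have highly
#' uncertain network positions, so their own trait scores are excluded from
#' analysis. The networks are NOT rebuilt: rare individuals still shape the
#' social environment and hence the metrics of everyone else.
#'
#' @param rows a metric table from [metrics_table()].
#' @param min_sightings minimum sightings to analyse a score (default 5).
#' @return the table with `included_sightings` (and the combined `included`)
#'   flags updated; attribute `n_masked` records how many rows were masked.
#' @export
mask_rare_individuals <- function(rows, min_sightings = 5) {
  rows$included_sightings <- rows$n_sightings >= min_sightings
  rows$included <- rows$included_sightings & rows$known_sex
  structure(rows, n_masked = sum(!rows$included_sightings))
}

#' Assemble the node-by-window analysis table
#'
#' One row per individual per window with the three social traits, sighting
#' counts, sex, and the window's environmental covariate. Individuals of
#' unknown sex keep their network contribution (their edges shape others'
#' metrics) but are flagged for exclusion from model fitting.
#'
#' @param networks list of `social_network`s (one per retained window).
#' @param metadata data frame with `id`, `sex` (birth_year optional).
#' @param env an `env_series`; matched monthly or yearly according to
#'   `timescale`.
#' @param timescale `"year"` or `"month"` (how window labels are parsed and
#'   matched against `env`).
#' @param min_sightings passed to [mask_rare_individuals()].
#' @return data frame with columns `individual`, `window`, `year`, `month`,
#'   `strength`, `clustering`, `closeness`, `n_sightings`, `known_sex`,
#'   `included_sightings`, `included`, `sex`, `covariate_raw`.
#' @export
metrics_table <- function(networks, metadata, env,
                          timescale = c("year", "month"),
                          min_sightings = 5) {
  timescale <- match.arg(timescale)
  envkey <- if (timescale == "year") {
    ys <- yearly_series(env)
    setNames(ys$value, sprintf("%d", ys$year))
  } else {
    setNames(env$value, sprintf("%d-%02d", env$year, env$month))
  }
  sexkey <- setNames(metadata$sex, metadata$id)

  rows <- lapply(networks, function(net) {
    win <- net$window
    if (!win %in% names(envkey)) {
      stop(sprintf("window %s has no environmental covariate value", win),
           call. = FALSE)
    }
    yr <- as.integer(substr(win, 1, 4))
    mo <- if (timescale == "month") as.integer(substr(win, 6, 7)) else NA_integer_
    sex <- unname(sexkey[net$ids])
    sex[is.na(sex)] <- "U"
    data.frame(individual = net$ids,
               window = win,
               year = yr,
               month = mo,
               strength = unname(strength(net)),
               clustering = unname(clustering_coefficient(net)),
               closeness = unname(closeness(net)),
               n_sightings = unname(net$sightings),
               known_sex = sex %in% c("F", "M"),
               sex = sex,
               covariate_raw = unname(envkey[win]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mask_rare_individuals(out, min_sightings = min_sightings)
}
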