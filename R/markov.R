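#' Emission-type classification and Markov transition estimation
#'
#' City-year emission values are pooled over the whole panel and cut into K
#' ordered types (default K = 4: low, medium-low, medium-high, high) at the
#' empirical quantiles j/K. Annual transitions between types are then pooled
#' over cities and estimated by maximum likelihood,
#' \eqn{\hat p_{ij} = n_{ij}/n_i}; the spatial variant stratifies the
#' transitions by the type of each city's neighbourhood (its spatial lag) in
#' the origin year.
#'
#' @name emission-markov
NULL

#' @keywords internal
bin_by_thresholds <- function(values, thresholds) {
  # lower-closed bins: a value equal to a threshold falls in the upper bin;
  # the top bin is closed above
  findInterval(values, thresholds) + 1L
}

#' Classify city-year emission values into K pooled quantile types
#'
#' Thresholds are the pooled empirical quantiles at probabilities j/K,
#' j = 1..K-1, over all city-years; bins are lower-closed, upper-open, with
#' the top bin closed. The classification depends only on ranks, so any
#' monotone transformation of the values leaves the types unchanged.
#'
#' @param df Data frame with columns \code{city}, \code{year} and a value
#'   column.
#' @param K Number of types (default 4).
#' @param value Name of the value column (default \code{"etotal"}).
#' @return Data frame \code{city}, \code{year}, \code{type} with attributes
#'   \code{"thresholds"} (the K-1 cut points) and \code{"K"}.
#' @export
classify_levels <- function(df, K = 4, value = "etotal") {
  if (!all(c("city", "year", value) %in% names(df)))
    stop_format(sprintf("need columns city, year, %s", value))
  if (K < 2) stop_validation("K must be at least 2")
  v <- df[[value]]
  if (length(unique(v)) < K)
    stop_validation("fewer distinct values than types K")
  thresholds <- stats::quantile(v, probs = seq_len(K - 1) / K, names = FALSE)
  if (any(duplicated(thresholds)))
    stop_validation("quantile thresholds are not distinct; reduce K")
  out <- data.frame(city = df$city, year = df$year,
                    type = bin_by_thresholds(v, thresholds),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  attr(out, "K") <- as.integer(K)
  out
}

#' Maximum-likelihood Markov transition matrix of a typed panel
#'
#' Transitions (t, t + lag) are pooled over all cities; row i is normalised
#' by its count total. Rows never visited have zero counts, are rendered as
#' all-zero probability rows, and are flagged.
#'
#' @param typed Data frame \code{city}, \code{year}, \code{type} (as from
#'   \code{\link{classify_levels}}).
#' @param lag Transition lag in years (default 1).
#' @param K Number of types; defaults to \code{attr(typed, "K")} or the
#'   maximum observed type.
#' @return Object of class \code{ghg_markov}: list with \code{K},
#'   \code{counts} (K x K integer), \code{probs} (K x K), \code{row_totals},
#'   \code{zero_rows} (logical).
#' @export
transition_matrix <- function(typed, lag = 1, K = NULL) {
  if (!all(c("city", "year", "type") %in% names(typed)))
    stop_format("need columns city, year, type")
  if (is.null(K)) K <- attr(typed, "K")
  if (is.null(K)) K <- max(typed$type)
  K <- as.integer(K)
  origin <- typed
  dest <- typed
  dest$year <- dest$year - lag
  m <- merge(origin, dest, by = c("city", "year"),
             suffixes = c("_from", "_to"))
  if (nrow(m) == 0) stop_validation("no transitions at this lag")
  counts <- matrix(0L, K, K,
                   dimnames = list(from = seq_len(K), to = seq_len(K)))
  tab <- table(factor(m$type_from, levels = seq_len(K)),
               factor(m$type_to, levels = seq_len(K)))
  counts[] <- as.integer(tab)
  row_totals <- rowSums(counts)
  probs <- counts / ifelse(row_totals == 0, 1, row_totals)
  structure(list(K = K, counts = counts, probs = probs,
                 row_totals = row_totals, zero_rows = row_totals == 0),
            class = "ghg_markov")
}

#' @export
print.ghg_markov <- function(x, ...) {
  cat(sprintf("<ghg_markov> K = %d, %d transitions\n", x$K, sum(x$counts)))
  print(round(x$probs, 4))
  if (any(x$zero_rows))
    cat("empty rows:", paste(which(x$zero_rows), collapse = ", "), "\n")
  invisible(x)
}

#' Spatial lag class of each city-year
#'
#' The spatial lag of a city is the unweighted mean of its neighbours'
#' emission values (binary contiguity weights, row-standardised); the lag is
#' binned with the same pooled thresholds used for the city types, so lag
#' classes live on the same I..K scale.
#'
#' @param df Data frame \code{city}, \code{year}, value column.
#' @param adjacency Named list city -> neighbours covering every city.
#' @param thresholds The K-1 cut points (e.g.
#'   \code{attr(classify_levels(df), "thresholds")}).
#' @param value Name of the value column (default \code{"etotal"}).
#' @return Data frame \code{city}, \code{year}, \code{lag_value},
#'   \code{lag_class}.
#' @export
spatial_lag_class <- function(df, adjacency, thresholds, value = "etotal") {
  cities <- unique(df$city)
  uncovered <- setdiff(cities, names(adjacency))
  if (length(uncovered))
    stop_validation(paste("cities missing from adjacency:",
                          paste(uncovered, collapse = ", ")))
  iso <- cities[vapply(adjacency[cities], length, integer(1)) == 0]
  if (length(iso))
    stop_validation(paste("isolated cities:", paste(iso, collapse = ", ")))
  key <- paste(df$city, df$year)
  val <- stats::setNames(df[[value]], key)
  lag_value <- vapply(seq_len(nrow(df)), function(i) {
    nb_keys <- paste(adjacency[[df$city[i]]], df$year[i])
    mean(val[nb_keys])
  }, numeric(1))
  data.frame(city = df$city, year = df$year,
             lag_value = lag_value,
             lag_class = bin_by_thresholds(lag_value, thresholds),
             stringsAsFactors = FALSE)
}

#' Spatially conditioned Markov transition matrices
#'
#' Each annual transition (t, t+1) is assigned to the stratum g equal to the
#' city's spatial lag class in the origin year t; within each stratum the
#' transition matrix is estimated by maximum likelihood exactly as in
#' \code{\link{transition_matrix}}. Summing stratum counts reproduces the
#' conventional counts exactly.
#'
#' @param typed Typed panel (\code{city}, \code{year}, \code{type}).
#' @param lag_classes Data frame \code{city}, \code{year}, \code{lag_class}
#'   (as from \code{\link{spatial_lag_class}}).
#' @param K Number of types; defaults to \code{attr(typed, "K")}.
#' @return Named list of \code{ghg_markov} objects, one per stratum
#'   \code{"1"}..\code{"K"}.
#' @export
spatial_transition_matrices <- function(typed, lag_classes, K = NULL) {
  if (is.null(K)) K <- attr(typed, "K")
  if (is.null(K)) K <- max(typed$type)
  K <- as.integer(K)
  merged <- merge(typed, lag_classes[c("city", "year", "lag_class")],
                  by = c("city", "year"))
  out <- lapply(seq_len(K), function(g) {
    sub <- merged
    # keep all rows as transition destinations but restrict origins to
    # stratum g: drop the type at origin years outside the stratum by
    # filtering transitions after the merge
    origin <- sub[sub$lag_class == g, c("city", "year", "type")]
    dest <- merged[c("city", "year", "type")]
    dest$year <- dest$year - 1L
    m <- merge(origin, dest, by = c("city", "year"),
               suffixes = c("_from", "_to"))
    counts <- matrix(0L, K, K,
                     dimnames = list(from = seq_len(K), to = seq_len(K)))
    if (nrow(m)) {
      tab <- table(factor(m$type_from, levels = seq_len(K)),
                   factor(m$type_to, levels = seq_len(K)))
      counts[] <- as.integer(tab)
    }
    row_totals <- rowSums(counts)
    probs <- counts / ifelse(row_totals == 0, 1, row_totals)
    structure(list(K = K, counts = counts, probs = probs,
                   row_totals = row_totals, zero_rows = row_totals == 0),
              class = "ghg_markov")
  })
  names(out) <- as.character(seq_len(K))
  out
}

#' Minimum and maximum self-locking probability
#'
#' The diagonal of a transition matrix gives the probability that a city
#' keeps its emission type over one period ("self-locking"). Returns the
#' range over rows that were actually visited.
#'
#' @param m A \code{ghg_markov} object or a plain probability matrix (in
#'   which case all rows with a positive sum count as visited).
#' @return Named numeric vector \code{c(min = ..., max = ...)}.
#' @export
diagonal_summary <- function(m) {
  if (inherits(m, "ghg_markov")) {
    probs <- m$probs
    occupied <- !m$zero_rows
  } else {
    probs <- as.matrix(m)
    occupied <- rowSums(probs) > 0
  }
  if (!any(occupied)) stop_domain("all rows empty")
  d <- diag(probs)[occupied]
  c(min = min(d), max = max(d))
}
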