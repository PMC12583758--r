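#' Theil index of inequality
#'
#' The Theil T index over \eqn{n} units with values \eqn{E_i} and mean
#' \eqn{\mu}:
#' \deqn{T = \frac{1}{n}\sum_i \frac{E_i}{\mu}\ln\frac{E_i}{\mu}}
#' Zero for perfect equality, increasing with concentration, invariant to a
#' common positive rescaling of the values; its upper bound is \eqn{\ln n}.
#'
#' @param values Positive numeric vector (one entry per city).
#' @return The Theil index (dimensionless).
#' @examples
#' theil(c(1, 3))   # 0.1308121
#' @export
theil <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)) || any(values <= 0))
    stop_domain("Theil index requires strictly positive values")
  r <- values / mean(values)
  mean(r * log(r))
}

#' Within/between-region decomposition of the Theil index
#'
#' The Theil T index is additively decomposable by groups with value-share
#' weights \eqn{s_g = n_g \mu_g / (n \mu)}:
#' \deqn{T = \sum_g s_g T_g + \sum_g s_g \ln(\mu_g/\mu)}
#' The first term is the within-region component (share-weighted group Theil
#' indices), the second the between-region component (inequality of group
#' means). Contribution percentages are component / total x 100; when the
#' total is exactly 0 they are returned as \code{NA}.
#'
#' @param values Named positive numeric vector, names are cities.
#' @param scheme Named character vector mapping every city to a region.
#' @return List of class \code{theil_decomposition}: \code{total},
#'   \code{within}, \code{between}, \code{group} (named vector of group Theil
#'   indices), \code{group_share} (the weights \eqn{s_g}),
#'   \code{within_pct}, \code{between_pct}.
#' @export
theil_decompose <- function(values, scheme) {
  if (is.null(names(values)))
    stop_validation("values must be named by city")
  missing_cities <- setdiff(names(values), names(scheme))
  if (length(missing_cities))
    stop_validation(paste("cities not in region scheme:",
                          paste(missing_cities, collapse = ", ")))
  total <- theil(values)
  groups <- split(as.numeric(values), scheme[names(values)])
  if (any(vapply(groups, length, integer(1)) == 0))
    stop_validation("empty region group")
  n <- length(values)
  mu <- mean(values)
  group_T <- vapply(groups, theil, numeric(1))
  group_share <- vapply(groups, function(v) length(v) * mean(v), numeric(1)) / (n * mu)
  within <- sum(group_share * group_T)
  between <- sum(group_share * log(vapply(groups, mean, numeric(1)) / mu))
  pct <- function(x) if (total > 0) 100 * x / total else NA_real_
  structure(
    list(total = total, within = within, between = between,
         group = group_T, group_share = group_share,
         within_pct = pct(within), between_pct = pct(between)),
    class = "theil_decomposition"
  )
}

#' Per-year Theil decomposition of a panel variable
#'
#' Applies \code{\link{theil_decompose}} year by year to city totals of a
#' variable — total emissions from a stage table, or output value from the
#' panel's gdp table.
#'
#' @param df Data frame with columns \code{city}, \code{year} and the value
#'   column.
#' @param scheme Region scheme (named character vector).
#' @param value Name of the value column (default \code{"etotal"}).
#' @return Data frame with one row per year: \code{year}, \code{total},
#'   \code{within}, \code{between}, \code{within_pct}, \code{between_pct},
#'   plus one \code{T_<region>} column per region.
#' @export
theil_series <- function(df, scheme, value = "etotal") {
  if (!all(c("city", "year", value) %in% names(df)))
    stop_format(sprintf("need columns city, year, %s", value))
  years <- sort(unique(df$year))
  rows <- lapply(years, function(y) {
    sub <- df[df$year == y, ]
    v <- stats::setNames(sub[[value]], sub$city)
    d <- theil_decompose(v, scheme)
    grp <- stats::setNames(as.list(d$group), paste0("T_", names(d$group)))
    cbind(data.frame(year = y, total = d$total, within = d$within,
                     between = d$between, within_pct = d$within_pct,
                     between_pct = d$between_pct),
          as.data.frame(grp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
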