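#' Configuration for the synthetic panel generator
#'
#' The generator emulates the structure of a provincial livestock panel: 18
#' prefecture-level cities in 5 regions observed over 21 years, with city
#' inventories declining slowly over time, one dominant livestock region
#' (roughly twice the provincial scale, mirroring the southern region of the
#' study system), multiplicative lognormal noise, and livestock output value
#' growing geometrically with occasional recession years.
#'
#' Defaults (in head per city for the inventory medians) are chosen to be
#' realistic for a large agricultural province: hundreds of thousands of
#' cattle and sheep, millions of pigs, tens of millions of poultry per city.
#' The default annual trend of -1.2 percent per year reproduces the slow
#' province-wide decline the analysis is designed to detect.
#'
#' @param n_cities Number of cities (default 18).
#' @param n_regions Number of regions (default 5).
#' @param years Inclusive year range (default 2001:2021).
#' @param species Species set.
#' @param base_inventory Named lognormal median head count per species.
#' @param trend Annual geometric trend per species (fraction/year; scalar is
#'   recycled). Inventories follow \code{(1 + trend)^(year - start)}.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 = deterministic).
#' @param city_sdlog Log-sd of the fixed city-level scatter around the
#'   species medians (0 makes all cities of a region identical).
#' @param region_multipliers Named region -> relative scale. \code{NULL}
#'   uses the default five-region profile with a dominant Southern region;
#'   for other region counts a flat profile is used.
#' @param gdp_growth_mean,gdp_growth_sd Annual output-value growth (fraction).
#' @param recession_years Years whose growth is forced negative.
#' @param seed Integer seed; fixed seed implies identical output.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(n_cities = 18, n_regions = 5, years = 2001:2021,
                         species = c("cattle", "pig", "sheep", "poultry"),
                         base_inventory = c(cattle = 2e5, pig = 2e6,
                                            sheep = 6e5, poultry = 3e7),
                         trend = -0.012,
                         noise_cv = 0.1,
                         city_sdlog = 0.5,
                         region_multipliers = NULL,
                         gdp_growth_mean = 0.09, gdp_growth_sd = 0.04,
                         recession_years = c(2006, 2009, 2014, 2015),
                         seed = 1L) {
  if (n_regions > n_cities)
    stop_config("n_regions must not exceed n_cities")
  if (any(trend <= -1 | trend >= 1))
    stop_config("trend must lie in (-1, 1)")
  if (noise_cv < 0) stop_config("noise_cv must be non-negative")
  trend <- rep_len(trend, length(species))
  names(trend) <- species
  structure(
    list(n_cities = n_cities, n_regions = n_regions, years = as.integer(years),
         species = species, base_inventory = base_inventory[species],
         trend = trend, noise_cv = noise_cv, city_sdlog = city_sdlog,
         region_multipliers = region_multipliers,
         gdp_growth_mean = gdp_growth_mean, gdp_growth_sd = gdp_growth_sd,
         recession_years = as.integer(recession_years),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# product -> (source species, tonnes of product per head per year)
.product_yields <- data.frame(
  product = c("pork", "beef", "milk", "mutton", "poultry_meat", "eggs"),
  species = c("pig", "cattle", "cattle", "sheep", "poultry", "poultry"),
  yield   = c(0.08, 0.05, 0.40, 0.015, 0.0015, 0.01),
  stringsAsFactors = FALSE
)

# per-head annual energy expenditure, CNY
.energy_costs <- data.frame(
  species = c("cattle", "pig", "sheep", "poultry"),
  elec    = c(60, 25, 8, 0.8),
  coal    = c(40, 15, 5, 0.5),
  stringsAsFactors = FALSE
)

#' Generate a synthetic city-by-year panel
#'
#' City base levels are lognormal around the species medians, scaled by the
#' city's region multiplier; inventories evolve as
#' \code{base x multiplier x (1 + trend)^(year - start) x noise} with
#' mean-one lognormal noise. Product outputs are proportional to the source
#' species inventory with fixed per-head yields, so every accounting stage
#' inherits the configured trend exactly when noise is zero. Energy costs
#' per head are species constants; output value grows geometrically from a
#' city base with negative growth forced in recession years.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with elements \code{panel} (a \code{ghg_panel}),
#'   \code{scheme} (named city -> region vector) and \code{adjacency}
#'   (named neighbour list, ring layout).
#' @export
generate_panel <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  years <- config$years
  y0 <- min(years)

  if (config$n_cities == 18 && config$n_regions == 5) {
    scheme <- default_region_scheme()
    cities <- names(scheme)
  } else {
    cities <- sprintf("City%02d", seq_len(config$n_cities))
    regions <- sprintf("R%d", seq_len(config$n_regions))
    scheme <- stats::setNames(
      regions[ceiling(seq_along(cities) / (config$n_cities / config$n_regions))],
      cities)
  }
  mult <- config$region_multipliers
  if (is.null(mult)) {
    mult <- if (config$n_regions == 5 && "Southern" %in% scheme)
      c(Southern = 2.0, Eastern = 1.3, North = 1.0, Central = 0.8, West = 0.6)
    else stats::setNames(rep(1, config$n_regions), unique(scheme))
  }
  missing_regions <- setdiff(unique(scheme), names(mult))
  if (length(missing_regions))
    stop_config(paste("region_multipliers missing:",
                      paste(missing_regions, collapse = ", ")))

  n_sp <- length(config$species)
  # fixed city x species base levels, lognormal around the species median
  base <- outer(rep(1, length(cities)), config$base_inventory) *
    matrix(exp(stats::rnorm(length(cities) * n_sp, 0, config$city_sdlog)),
           length(cities), n_sp) *
    mult[scheme[cities]]
  dimnames(base) <- list(cities, config$species)

  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) {
    if (cv == 0) rep(1, n) else stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }

  grid <- expand.grid(city = cities, year = years,
                      species = config$species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  growth <- (1 + config$trend[grid$species])^(grid$year - y0)
  grid$head <- base[cbind(grid$city, grid$species)] * growth * noise(nrow(grid))
  inventory <- grid[order(grid$city, grid$year, grid$species), ]
  rownames(inventory) <- NULL

  # outputs proportional to the source-species inventory
  inv_lookup <- stats::setNames(
    inventory$head, paste(inventory$city, inventory$year, inventory$species))
  og <- expand.grid(city = cities, year = years,
                    product = .product_yields$product,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sp <- stats::setNames(.product_yields$species, .product_yields$product)
  yld <- stats::setNames(.product_yields$yield, .product_yields$product)
  og$tonnes <- inv_lookup[paste(og$city, og$year, sp[og$product])] *
    yld[og$product]
  output <- og[order(og$city, og$year, og$product), ]
  rownames(output) <- NULL

  energycost <- expand.grid(city = cities, year = years,
                            species = config$species,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ec_e <- stats::setNames(.energy_costs$elec, .energy_costs$species)
  ec_c <- stats::setNames(.energy_costs$coal, .energy_costs$species)
  energycost$elec_cost <- unname(ec_e[energycost$species])
  energycost$coal_cost <- unname(ec_c[energycost$species])

  # output value: city base proportional to initial herd scale, then
  # geometric growth with recessions
  base_value <- rowSums(base) * 1500 *
    exp(stats::rnorm(length(cities), 0, if (config$city_sdlog > 0) 0.2 else 0))
  growth_rates <- matrix(
    stats::rnorm(length(cities) * (length(years) - 1),
                 config$gdp_growth_mean, config$gdp_growth_sd),
    length(cities), length(years) - 1)
  recession <- years[-1] %in% config$recession_years
  growth_rates[, recession] <- -abs(growth_rates[, recession]) - 0.02
  value <- matrix(NA_real_, length(cities), length(years),
                  dimnames = list(cities, years))
  value[, 1] <- base_value
  for (j in seq_len(length(years) - 1))
    value[, j + 1] <- value[, j] * (1 + growth_rates[, j])
  gdp <- data.frame(
    city = rep(cities, times = length(years)),
    year = rep(years, each = length(cities)),
    output_value = as.vector(value), stringsAsFactors = FALSE)

  feed <- data.frame(product = .product_yields$product,
                     feed_factor = c(3.5, 7.0, 0.9, 4.5, 2.1, 2.4),
                     stringsAsFactors = FALSE)
  shares <- data.frame(grain = c("corn", "wheat", "soybean"),
                       share = c(0.60, 0.15, 0.20),
                       stringsAsFactors = FALSE)

  panel <- new_panel(inventory, output, feed, shares, energycost, gdp)
  list(panel = panel, scheme = scheme,
       adjacency = generate_adjacency(cities, "ring"))
}

#' Generate independent Markov chains as a typed panel
#'
#' Each unit is an independent realisation of the chain with transition
#' matrix \code{P_true} started from a uniform initial state — a recovery
#' oracle for the transition-matrix estimator.
#'
#' @param P_true K x K row-stochastic matrix (rows sum to 1 within 1e-12).
#' @param n_units Number of independent units.
#' @param n_years Sequence length per unit.
#' @param seed Integer seed.
#' @return Typed panel data frame \code{city} (unit id), \code{year}
#'   (1..n_years), \code{type}, with attribute \code{"K"}.
#' @export
generate_typed_sequences <- function(P_true, n_units, n_years, seed = 1L) {
  P_true <- as.matrix(P_true)
  K <- nrow(P_true)
  if (ncol(P_true) != K || any(P_true < 0) ||
      any(abs(rowSums(P_true) - 1) > 1e-12))
    stop_validation("P_true must be a square row-stochastic matrix")
  set.seed(seed)
  states <- matrix(NA_integer_, n_units, n_years)
  states[, 1] <- sample.int(K, n_units, replace = TRUE)
  cum <- t(apply(P_true, 1, cumsum))
  for (t in seq_len(n_years - 1)) {
    u <- stats::runif(n_units)
    thresholds <- cum[states[, t], , drop = FALSE]
    states[, t + 1] <- 1L + rowSums(u > thresholds[, -K, drop = FALSE])
  }
  out <- data.frame(
    city = rep(sprintf("U%04d", seq_len(n_units)), times = n_years),
    year = rep(seq_len(n_years), each = n_units),
    type = as.vector(states), stringsAsFactors = FALSE)
  attr(out, "K") <- K
  out
}

#' Generate a symmetric contiguity structure for a set of cities
#'
#' @param cities Ordered character vector (at least 3).
#' @param layout \code{"ring"} (every city has exactly two neighbours) or
#'   \code{"lattice"} (rectangular grid with rook contiguity; the grid is
#'   \code{r x c} with \code{r} the largest divisor of the city count not
#'   exceeding its square root).
#' @return Named list city -> neighbours.
#' @export
generate_adjacency <- function(cities, layout = c("ring", "lattice")) {
  layout <- match.arg(layout)
  n <- length(cities)
  if (n < 3) stop_config("need at least 3 cities")
  if (layout == "ring") {
    adj <- lapply(seq_len(n), function(i)
      sort(cities[c((i - 2) %% n + 1, i %% n + 1)]))
  } else {
    r <- max(which(seq_len(floor(sqrt(n))) %in% which(n %% seq_len(n) == 0)))
    if (r == 1) stop_config("lattice layout needs a composite city count")
    cc <- n / r
    idx <- matrix(seq_len(n), r, cc)
    adj <- lapply(seq_len(n), function(i) {
      pos <- which(idx == i, arr.ind = TRUE)
      nb <- c(if (pos[1] > 1) idx[pos[1] - 1, pos[2]],
              if (pos[1] < r) idx[pos[1] + 1, pos[2]],
              if (pos[2] > 1) idx[pos[1], pos[2] - 1],
              if (pos[2] < cc) idx[pos[1], pos[2] + 1])
      sort(cities[nb])
    })
  }
  stats::setNames(adj, cities)
}
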