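#' City-by-year livestock panel
#'
#' A \code{ghg_panel} bundles the six long tables the accounting engine needs:
#' \describe{
#'   \item{inventory}{city, year, species, head — average annual head count.}
#'   \item{output}{city, year, product, tonnes — annual product output.}
#'   \item{feed}{product, feed_factor — tonnes of concentrate feed consumed
#'     per tonne of product.}
#'   \item{shares}{grain, share — fraction of each grain in the concentrate
#'     formulation (shares lie in [0,1] and sum to at most 1).}
#'   \item{energycost}{city, year, species, elec_cost, coal_cost — CNY spent
#'     on electricity / coal per head per year.}
#'   \item{gdp}{city, year, output_value — livestock gross output value (CNY),
#'     the economic series used by the decoupling and inequality analyses.}
#' }
#'
#' @param inventory,output,feed,shares,energycost,gdp Data frames as above.
#' @param allow_missing If \code{TRUE}, value cells may be \code{NA} (to be
#'   filled by \code{\link{impute_missing}}) and absent (city, year) rows are
#'   completed with \code{NA}.
#' @return A validated object of class \code{ghg_panel} with attributes
#'   \code{cities} and \code{years}.
#' @seealso \code{\link{read_panel}}, \code{\link{impute_missing}},
#'   \code{\link{generate_panel}}
#' @export
new_panel <- function(inventory, output, feed, shares, energycost, gdp,
                      allow_missing = FALSE) {
  panel <- list(inventory = inventory, output = output, feed = feed,
                shares = shares, energycost = energycost, gdp = gdp)
  validate_panel(panel, allow_missing = allow_missing)
}

#' @keywords internal
validate_panel <- function(panel, allow_missing = FALSE) {
  req <- list(
    inventory  = c("city", "year", "species", "head"),
    output     = c("city", "year", "product", "tonnes"),
    feed       = c("product", "feed_factor"),
    shares     = c("grain", "share"),
    energycost = c("city", "year", "species", "elec_cost", "coal_cost"),
    gdp        = c("city", "year", "output_value")
  )
  for (nm in names(req)) {
    if (is.null(panel[[nm]]) || !all(req[[nm]] %in% names(panel[[nm]])))
      stop_format(sprintf("panel table '%s' must have columns: %s",
                          nm, paste(req[[nm]], collapse = ", ")))
    panel[[nm]] <- as.data.frame(panel[[nm]])[req[[nm]]]
  }

  dup_check <- function(tab, keys, nm) {
    if (anyDuplicated(tab[keys]))
      stop_format(sprintf("duplicate rows in '%s' for key (%s)",
                          nm, paste(keys, collapse = ", ")))
  }
  dup_check(panel$inventory, c("city", "year", "species"), "inventory")
  dup_check(panel$output, c("city", "year", "product"), "output")
  dup_check(panel$energycost, c("city", "year", "species"), "energycost")
  dup_check(panel$gdp, c("city", "year"), "gdp")
  dup_check(panel$feed, "product", "feed")
  dup_check(panel$shares, "grain", "shares")

  cities <- sort(unique(c(panel$inventory$city, panel$gdp$city)))
  years <- sort(unique(c(panel$inventory$year, panel$gdp$year)))
  if (length(years) > 1 && !identical(as.integer(years),
                                      seq(min(years), max(years)))) {
    stop_validation("panel years are not contiguous")
  }
  years <- as.integer(years)

  # every city must carry the full year range in the gdp (master) table
  full <- expand.grid(city = cities, year = years, stringsAsFactors = FALSE)
  have <- paste(panel$gdp$city, panel$gdp$year)
  missing_rows <- !paste(full$city, full$year) %in% have
  if (any(missing_rows)) {
    if (!allow_missing)
      stop_validation("gdp table does not cover every (city, year)")
    add <- full[missing_rows, ]
    add$output_value <- NA_real_
    panel$gdp <- rbind(panel$gdp, add)
  }

  nonneg <- function(x, what) {
    if (any(!is.na(x) & x < 0))
      stop_validation(sprintf("negative values in %s", what))
    if (!allow_missing && anyNA(x))
      stop_validation(sprintf("missing values in %s (use allow_missing / impute_missing)", what))
  }
  nonneg(panel$inventory$head, "inventory head counts")
  nonneg(panel$output$tonnes, "product outputs")
  nonneg(panel$energycost$elec_cost, "electricity costs")
  nonneg(panel$energycost$coal_cost, "coal costs")
  nonneg(panel$feed$feed_factor, "feed factors")
  if (any(!is.na(panel$gdp$output_value) & panel$gdp$output_value <= 0))
    stop_validation("output_value must be strictly positive")
  if (!allow_missing && anyNA(panel$gdp$output_value))
    stop_validation("missing values in output_value")
  s <- panel$shares$share
  if (any(is.na(s)) || any(s < 0 | s > 1) || sum(s) > 1 + 1e-9)
    stop_validation("grain shares must lie in [0,1] and sum to at most 1")

  structure(panel, cities = cities, years = years, class = "ghg_panel")
}

#' @export
print.ghg_panel <- function(x, ...) {
  cat(sprintf("<ghg_panel> %d cities x %d years (%d-%d)\n",
              length(attr(x, "cities")), length(attr(x, "years")),
              min(attr(x, "years")), max(attr(x, "years"))))
  cat("  species:", paste(sort(unique(x$inventory$species)), collapse = ", "), "\n")
  cat("  products:", paste(sort(unique(x$output$product)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a panel from a directory of CSV files
#'
#' Expects the standard file set \code{inventory.csv}, \code{output.csv},
#' \code{feed.csv}, \code{shares.csv}, \code{energycost.csv}, \code{gdp.csv}
#' (UTF-8, header row, "." decimal). Column headers follow the documented
#' schemas, e.g. \code{feed.csv} carries \code{feed_factor_t_per_t} and
#' \code{gdp.csv} carries \code{output_value_cny}.
#'
#' @param dir Directory containing the CSV file set.
#' @param allow_missing Permit \code{NA} cells (see \code{\link{new_panel}}).
#' @return A \code{ghg_panel}.
#' @export
read_panel <- function(dir, allow_missing = FALSE) {
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop_format(sprintf("missing panel file '%s'", path))
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  inventory <- rd("inventory.csv")
  output <- rd("output.csv")
  feed <- rd("feed.csv")
  names(feed)[names(feed) == "feed_factor_t_per_t"] <- "feed_factor"
  shares <- rd("shares.csv")
  energycost <- rd("energycost.csv")
  names(energycost)[names(energycost) == "elec_cny_per_head"] <- "elec_cost"
  names(energycost)[names(energycost) == "coal_cny_per_head"] <- "coal_cost"
  gdp <- rd("gdp.csv")
  names(gdp)[names(gdp) == "output_value_cny"] <- "output_value"
  new_panel(inventory, output, feed, shares, energycost, gdp,
            allow_missing = allow_missing)
}

#' Write a panel (and optional spatial metadata) as the standard CSV file set
#'
#' @param panel A \code{ghg_panel}.
#' @param dir Output directory (created if absent).
#' @param scheme Optional region scheme (named character vector city -> region)
#'   written as \code{regions.csv}.
#' @param adjacency Optional adjacency list (named list city -> neighbours)
#'   written as \code{adjacency.csv} (one row per unordered edge).
#' @return \code{dir}, invisibly.
#' @export
write_panel <- function(panel, dir, scheme = NULL, adjacency = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  wr(panel$inventory, "inventory.csv")
  wr(panel$output, "output.csv")
  feed <- panel$feed
  names(feed)[names(feed) == "feed_factor"] <- "feed_factor_t_per_t"
  wr(feed, "feed.csv")
  wr(panel$shares, "shares.csv")
  ec <- panel$energycost
  names(ec)[names(ec) == "elec_cost"] <- "elec_cny_per_head"
  names(ec)[names(ec) == "coal_cost"] <- "coal_cny_per_head"
  wr(ec, "energycost.csv")
  gdp <- panel$gdp
  names(gdp)[names(gdp) == "output_value"] <- "output_value_cny"
  wr(gdp, "gdp.csv")
  if (!is.null(scheme))
    wr(data.frame(city = names(scheme), region = unname(scheme)), "regions.csv")
  if (!is.null(adjacency)) {
    edges <- adjacency_edges(adjacency)
    wr(edges, "adjacency.csv")
  }
  invisible(dir)
}

#' Fill missing panel cells by distance-weighted interpolation within a city
#'
#' Each missing cell in a (city, series) time series is filled with the
#' inverse-distance-in-years weighted average of the two nearest observed
#' values (equivalently, linear interpolation in the year axis); gaps at the
#' boundary of the observation window are filled with the nearest observed
#' value. Imputation acts independently on every (city, species/product)
#' series of the inventory, output, energy-cost and output-value tables.
#'
#' @param panel A \code{ghg_panel} built with \code{allow_missing = TRUE}.
#' @return A complete \code{ghg_panel}; the attribute \code{"imputed"} is a
#'   data frame logging every filled cell (table, city, key, year).
#' @export
impute_missing <- function(panel) {
  years <- attr(panel, "years")
  log_rows <- list()

  fill_series <- function(y, v, what) {
    obs <- which(!is.na(v))
    if (length(obs) == 0)
      stop_validation(sprintf("all values missing for %s", what))
    if (length(obs) == length(v)) return(v)
    if (length(obs) == 1) {
      v[] <- v[obs]
      return(v)
    }
    stats::approx(y[obs], v[obs], xout = y, method = "linear", rule = 2)$y
  }

  fill_table <- function(tab, value_col, key_cols, table_name) {
    split_keys <- interaction(tab[c("city", key_cols)], drop = TRUE)
    for (grp in split(seq_len(nrow(tab)), split_keys)) {
      idx <- grp[order(tab$year[grp])]
      v <- tab[[value_col]][idx]
      if (!anyNA(v)) next
      what <- paste0(table_name, " ", tab$city[idx[1]],
                     if (length(key_cols)) paste0("/", tab[[key_cols]][idx[1]]) else "",
                     "/", value_col)
      filled <- fill_series(tab$year[idx], v, what)
      miss <- which(is.na(v))
      log_rows[[length(log_rows) + 1]] <<- data.frame(
        table = table_name, city = tab$city[idx[1]],
        key = if (length(key_cols)) as.character(tab[[key_cols]][idx[1]]) else value_col,
        year = tab$year[idx][miss], stringsAsFactors = FALSE)
      tab[[value_col]][idx] <- filled
    }
    tab
  }

  panel$inventory <- fill_table(panel$inventory, "head", "species", "inventory")
  panel$output <- fill_table(panel$output, "tonnes", "product", "output")
  panel$energycost <- fill_table(panel$energycost, "elec_cost", "species", "energycost")
  panel$energycost <- fill_table(panel$energycost, "coal_cost", "species", "energycost")
  panel$gdp <- fill_table(panel$gdp, "output_value", character(0), "gdp")

  out <- validate_panel(unclass(panel))
  attr(out, "imputed") <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(table = character(), city = character(),
               key = character(), year = integer())
  out
}

#' Default five-region scheme for the 18 prefecture-level cities
#'
#' The standard physiographic grouping of the 18 cities into Eastern,
#' Central, Southern, West and North regions.
#'
#' @return Named character vector mapping city to region label.
#' @export
default_region_scheme <- function() {
  c(Kaifeng = "Eastern", Shangqiu = "Eastern", Zhoukou = "Eastern",
    Zhengzhou = "Central", Pingdingshan = "Central", Xuchang = "Central",
    Luohe = "Central",
    Nanyang = "Southern", Xinyang = "Southern", Zhumadian = "Southern",
    Luoyang = "West", Jiaozuo = "West", Sanmenxia = "West", Jiyuan = "West",
    Anyang = "North", Hebi = "North", Xinxiang = "North", Puyang = "North")
}

#' Read a region scheme from regions.csv
#' @param path CSV with columns \code{city}, \code{region}.
#' @return Named character vector city -> region.
#' @export
read_region_scheme <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("city", "region") %in% names(df)))
    stop_format("regions file must have columns city, region")
  if (anyDuplicated(df$city)) stop_format("duplicate city in regions file")
  stats::setNames(df$region, df$city)
}

#' Read a binary spatial adjacency list from adjacency.csv
#'
#' @param path CSV with columns \code{city_a}, \code{city_b}, one row per
#'   (possibly directed) edge; the result is symmetrised.
#' @param cities Optional vector of cities that must all be present.
#' @return Named list city -> character vector of neighbours.
#' @export
read_adjacency <- function(path, cities = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("city_a", "city_b") %in% names(df)))
    stop_format("adjacency file must have columns city_a, city_b")
  edges_to_adjacency(df$city_a, df$city_b, cities = cities)
}

#' @keywords internal
edges_to_adjacency <- function(a, b, cities = NULL) {
  if (any(a == b)) stop_validation("adjacency contains a self-loop")
  all_cities <- sort(unique(c(a, b, cities)))
  adj <- lapply(all_cities, function(ct)
    sort(unique(c(b[a == ct], a[b == ct]))))
  names(adj) <- all_cities
  if (!is.null(cities)) {
    iso <- cities[!vapply(adj[cities], length, integer(1)) > 0]
    if (length(iso))
      stop_validation(paste("isolated cities in adjacency:",
                            paste(iso, collapse = ", ")))
  }
  adj
}

#' @keywords internal
adjacency_edges <- function(adjacency) {
  pairs <- do.call(rbind, lapply(names(adjacency), function(ct) {
    nb <- adjacency[[ct]]
    if (!length(nb)) return(NULL)
    data.frame(city_a = ct, city_b = nb, stringsAsFactors = FALSE)
  }))
  keep <- pairs$city_a < pairs$city_b
  pairs[keep, , drop = FALSE]
}

#' Split a panel into per-(city, year) records
#'
#' Each record is a list with named numeric vectors \code{inventories},
#' \code{outputs}, \code{elec_cost}, \code{coal_cost} (keyed by species or
#' product), the panel-level \code{feed_factor} and \code{grain_shares}
#' vectors, and the scalar \code{output_value}. This is the unit the stage
#' accounting functions operate on.
#'
#' @param panel A \code{ghg_panel}.
#' @return Named list of records, keyed \code{"city.year"}.
#' @export
panel_records <- function(panel) {
  feed_factor <- stats::setNames(panel$feed$feed_factor, panel$feed$product)
  grain_shares <- stats::setNames(panel$shares$share, panel$shares$grain)
  inv <- split(panel$inventory, paste(panel$inventory$city, panel$inventory$year, sep = "."))
  out <- split(panel$output, paste(panel$output$city, panel$output$year, sep = "."))
  ec <- split(panel$energycost, paste(panel$energycost$city, panel$energycost$year, sep = "."))
  gdp_key <- paste(panel$gdp$city, panel$gdp$year, sep = ".")
  recs <- lapply(seq_len(nrow(panel$gdp)), function(i) {
    key <- gdp_key[i]
    inv_i <- inv[[key]]
    out_i <- out[[key]]
    ec_i <- ec[[key]]
    list(
      city = panel$gdp$city[i],
      year = panel$gdp$year[i],
      inventories = if (is.null(inv_i)) stats::setNames(numeric(0), character(0)) else
        stats::setNames(inv_i$head, inv_i$species),
      outputs = if (is.null(out_i)) stats::setNames(numeric(0), character(0)) else
        stats::setNames(out_i$tonnes, out_i$product),
      elec_cost = if (is.null(ec_i)) stats::setNames(numeric(0), character(0)) else
        stats::setNames(ec_i$elec_cost, ec_i$species),
      coal_cost = if (is.null(ec_i)) stats::setNames(numeric(0), character(0)) else
        stats::setNames(ec_i$coal_cost, ec_i$species),
      feed_factor = feed_factor,
      grain_shares = grain_shares,
      output_value = panel$gdp$output_value[i]
    )
  })
  names(recs) <- gdp_key
  recs
}
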