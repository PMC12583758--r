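#' Run the full emission analysis chain over a panel
#'
#' Accounting under one or two GWP sets, provincial series and annualized
#' rates, stage correlations, per-year Theil decompositions of emissions and
#' of output value, the year-over-year Tapio decoupling table, and the
#' conventional and spatially conditioned Markov transition matrices.
#'
#' @param panel A \code{ghg_panel}.
#' @param scheme Region scheme (named city -> region vector).
#' @param adjacency Named neighbour list covering every city.
#' @param gwp Character vector of GWP set names to account under; the first
#'   is the headline set used by the Theil / decoupling / Markov stages.
#' @param K Number of emission types for the Markov analysis.
#' @param rate_periods List of \code{c(start, end)} year pairs for the
#'   annualized-rate report; defaults to the full span.
#' @param factors_config Optional YAML path overriding the default factors.
#' @param out_dir If given, the tables are written there as CSV files
#'   (\code{emissions.csv}, \code{theil.csv}, \code{decoupling.csv},
#'   \code{markov_conventional.csv}, \code{markov_spatial.csv},
#'   \code{type_thresholds.csv}) plus a JSON \code{summary.json}.
#' @param seed Seed recorded in the summary for provenance (the analysis
#'   itself is deterministic given the panel).
#' @return List with elements \code{stage_tables}, \code{provincial},
#'   \code{rates}, \code{correlations}, \code{theil_emissions},
#'   \code{theil_economy}, \code{decoupling}, \code{markov},
#'   \code{markov_spatial}, \code{thresholds}.
#' @export
run_report <- function(panel, scheme, adjacency,
                       gwp = c("GWP100", "GWP20"), K = 4,
                       rate_periods = NULL, factors_config = NULL,
                       out_dir = NULL, seed = NA_integer_) {
  factor_sets <- lapply(gwp, function(g) {
    if (is.null(factors_config)) default_factors(g) else {
      f <- load_factors(factors_config)
      f$gwp <- default_factors(g)$gwp
      f
    }
  })
  names(factor_sets) <- gwp

  stage_tables <- lapply(factor_sets, function(f) account_panel(panel, f))
  provincial <- lapply(gwp, function(g)
    provincial_series(stage_tables[[g]], factor_sets[[g]]$gwp))
  names(provincial) <- gwp

  years <- attr(panel, "years")
  if (is.null(rate_periods))
    rate_periods <- list(c(min(years), max(years)))
  rates <- do.call(rbind, lapply(gwp, function(g) {
    prov <- provincial[[g]]
    do.call(rbind, lapply(rate_periods, function(p) {
      series <- stats::setNames(prov$etotal, prov$year)
      data.frame(gwp = g, start = p[1], end = p[2],
                 rate = annualized_rate(series, p[1], p[2]),
                 stringsAsFactors = FALSE)
    }))
  }))

  head_gwp <- gwp[1]
  head_table <- stage_tables[[head_gwp]]
  correlations <- stage_correlations(provincial[[head_gwp]])

  theil_emissions <- theil_series(head_table, scheme, value = "etotal")
  theil_economy <- theil_series(panel$gdp, scheme, value = "output_value")

  prov <- provincial[[head_gwp]]
  gdp_year <- stats::aggregate(output_value ~ year, panel$gdp, sum)
  decoupling <- decoupling_series(
    stats::setNames(prov$etotal, prov$year),
    stats::setNames(gdp_year$output_value, gdp_year$year))

  typed <- classify_levels(head_table, K = K, value = "etotal")
  conv <- transition_matrix(typed)
  lags <- spatial_lag_class(head_table, adjacency,
                            attr(typed, "thresholds"), value = "etotal")
  spat <- spatial_transition_matrices(typed, lags)

  result <- list(
    stage_tables = stage_tables, provincial = provincial, rates = rates,
    correlations = correlations, theil_emissions = theil_emissions,
    theil_economy = theil_economy, decoupling = decoupling,
    markov = conv, markov_spatial = spat,
    thresholds = attr(typed, "thresholds"), seed = seed
  )
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' @keywords internal
markov_long <- function(m, lag_class = NULL) {
  K <- m$K
  df <- expand.grid(from_type = seq_len(K), to_type = seq_len(K),
                    KEEP.OUT.ATTRS = FALSE)
  df$count <- m$counts[cbind(df$from_type, df$to_type)]
  df$prob <- m$probs[cbind(df$from_type, df$to_type)]
  if (!is.null(lag_class)) df <- cbind(lag_class = lag_class, df)
  df
}

#' Write the tables of a report to CSV plus a JSON summary
#'
#' Emission totals are reported in 10^4 t CO2-eq in \code{emissions.csv}
#' (internal computation stays in t); probabilities and Theil indices keep
#' full precision in the CSVs and are rounded to 4 decimals in the JSON.
#'
#' @param result A list as returned by \code{\link{run_report}}.
#' @param out_dir Output directory.
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) utils::write.csv(df, file.path(out_dir, file),
                                            row.names = FALSE)
  emis <- result$stage_tables[[1]]
  emis$etotal_co2eq_1e4t <- emis$etotal / 1e4
  emis$etotal <- NULL
  wr(emis, "emissions.csv")
  wr(result$theil_emissions, "theil.csv")
  wr(result$decoupling, "decoupling.csv")
  wr(markov_long(result$markov), "markov_conventional.csv")
  wr(do.call(rbind, lapply(names(result$markov_spatial), function(g)
    markov_long(result$markov_spatial[[g]], g))), "markov_spatial.csv")
  wr(data.frame(threshold = seq_along(result$thresholds),
                value = result$thresholds), "type_thresholds.csv")
  summary <- list(
    seed = result$seed,
    provincial = lapply(result$provincial, function(p)
      list(year = p$year, etotal_1e4t = round(p$etotal / 1e4, 4))),
    rates_pct = transform(result$rates, rate = round(100 * rate, 2)),
    theil_total = round(stats::setNames(result$theil_emissions$total,
                                        result$theil_emissions$year), 4),
    decoupling_states = stats::setNames(result$decoupling$code,
                                        result$decoupling$period),
    markov_diag = round(diagonal_summary(result$markov), 4)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
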