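#' Life-cycle stage emissions
#'
#' The accounting engine decomposes livestock greenhouse-gas emissions into
#' six life-cycle stages per city and year:
#' \describe{
#'   \item{efc}{CO2-eq from feed-grain cultivation (t).}
#'   \item{eft}{CO2-eq from feed-grain transport and processing (t).}
#'   \item{efg_ch4}{CH4 from enteric (gastrointestinal) fermentation (kg).}
#'   \item{efm_ch4}{CH4 from manure management (kg).}
#'   \item{efs_n2o}{N2O from manure management (kg).}
#'   \item{efe}{CO2 from feeding energy use, electricity and coal (t).}
#'   \item{efp}{CO2 from slaughtering/processing of products (t).}
#' }
#' The total puts the gases on a common scale with GWP weights:
#' \deqn{E_{total} = EFC + EFT + (EFG + EFM)\,GWP_{CH_4}/1000
#'       + EFS\,GWP_{N_2O}/1000 + EFE + EFP}
#' with the \code{/1000} converting kg of gas to tonnes before weighting.
#' Two unit bridges are applied throughout: expenditure / price gives kWh,
#' divided by 1000 to MWh before the electricity factor (t CO2/MWh); product
#' masses in tonnes are converted to kg before the MJ/kg processing
#' intensities.
#'
#' @name stage-emissions
NULL

# grains whose cultivation factor is absent and have already been warned about
.efc_warned <- new.env(parent = emptyenv())

#' Feed-grain cultivation CO2-eq (t)
#'
#' Sum over products of output (t) x feed factor (t feed / t product) x
#' sum over grains of formulation share x cultivation factor (t CO2-eq / t).
#' Grains without a cultivation factor (e.g. soybean in the default set) are
#' skipped with a one-time warning unless an override supplies one.
#'
#' @param record A panel record (see \code{\link{panel_records}}).
#' @param factors A \code{ghg_factors} set.
#' @return Emissions in t CO2-eq.
#' @export
efc <- function(record, factors) {
  feed_grain_stage(record, factors, grain_factor(factors, "cultivation_co2"),
                   warn_absent = TRUE)
}

#' Feed-grain transport and processing CO2-eq (t)
#' @inheritParams efc
#' @return Emissions in t CO2-eq.
#' @export
eft <- function(record, factors) {
  feed_grain_stage(record, factors, grain_factor(factors, "transport_co2"),
                   warn_absent = FALSE)
}

#' @keywords internal
feed_grain_stage <- function(record, factors, ef, warn_absent) {
  q <- record$outputs
  if (!length(q)) return(0)
  unknown <- setdiff(names(q), names(record$feed_factor))
  if (length(unknown))
    stop_validation(paste("products without a feed factor:",
                          paste(unknown, collapse = ", ")))
  t_feed <- record$feed_factor[names(q)]
  shares <- record$grain_shares
  unknown_grain <- setdiff(names(shares), names(ef))
  if (length(unknown_grain))
    stop_validation(paste("grains without factors:",
                          paste(unknown_grain, collapse = ", ")))
  ef_g <- ef[names(shares)]
  absent <- is.na(ef_g)
  if (any(absent)) {
    if (warn_absent) {
      for (g in names(shares)[absent]) {
        if (is.null(.efc_warned[[g]])) {
          warning(sprintf(
            "grain '%s' has no cultivation factor; excluded from the cultivation stage", g),
            call. = FALSE)
          .efc_warned[[g]] <- TRUE
        }
      }
    }
    shares <- shares[!absent]
    ef_g <- ef_g[!absent]
  }
  per_tonne_feed <- sum(shares * ef_g)
  sum(q * t_feed) * per_tonne_feed
}

#' Enteric fermentation CH4 (kg)
#'
#' Sum over species of average annual head count x per-head enteric CH4
#' factor. Poultry carry an exact-zero factor.
#'
#' @inheritParams efc
#' @return Emissions in kg CH4.
#' @export
efg <- function(record, factors) {
  per_head_stage(record$inventories, species_factor(factors, "enteric_ch4"))
}

#' Manure-management CH4 (kg)
#' @inheritParams efc
#' @return Emissions in kg CH4.
#' @export
efm <- function(record, factors) {
  per_head_stage(record$inventories, species_factor(factors, "manure_ch4"))
}

#' Manure-management N2O (kg)
#' @inheritParams efc
#' @return Emissions in kg N2O.
#' @export
efs <- function(record, factors) {
  per_head_stage(record$inventories, species_factor(factors, "manure_n2o"))
}

#' @keywords internal
per_head_stage <- function(inventories, ef) {
  if (!length(inventories)) return(0)
  unknown <- setdiff(names(inventories), names(ef))
  if (length(unknown))
    stop_validation(paste("species without emission factors:",
                          paste(unknown, collapse = ", ")))
  sum(inventories * ef[names(inventories)])
}

#' Feeding-energy CO2 (t)
#'
#' Per-head electricity expenditure divided by the electricity price gives
#' kWh per head; /1000 converts to MWh before the t CO2/MWh factor. Coal
#' expenditure divided by the coal price gives tonnes of coal before the
#' t CO2/t factor. Both terms are summed over species weighted by head count.
#'
#' @inheritParams efc
#' @return Emissions in t CO2.
#' @export
efe <- function(record, factors) {
  inv <- record$inventories
  if (!length(inv)) return(0)
  en <- factors$energy
  elec <- record$elec_cost[names(inv)]
  coal <- record$coal_cost[names(inv)]
  if (anyNA(elec) || anyNA(coal))
    stop_validation("energy costs missing for some species in the inventory")
  sum(inv * (elec / en$price_e) / 1000 * en$ef_e) +
    sum(inv * (coal / en$price_c) * en$ef_c)
}

#' Product-processing CO2 (t)
#'
#' Product output in kg x (MJ/kg intensity / MJ-per-kWh heating value) gives
#' kWh; /1000 converts to MWh before the electricity emission factor.
#'
#' @inheritParams efc
#' @return Emissions in t CO2.
#' @export
efp <- function(record, factors) {
  q <- record$outputs
  if (!length(q)) return(0)
  mj <- processing_factor(factors)
  unknown <- setdiff(names(q), names(mj))
  if (length(unknown))
    stop_validation(paste("products without processing intensities:",
                          paste(unknown, collapse = ", ")))
  en <- factors$energy
  sum(q * 1000 * (mj[names(q)] / en$e_n) / 1000 * en$ef_e)
}

#' Total CO2-equivalent emissions (t)
#'
#' Combines the stage quantities under a GWP set; CH4 and N2O masses (kg) are
#' converted to tonnes before weighting.
#'
#' @param stages A list or one-row data frame with fields \code{efc},
#'   \code{eft}, \code{efg_ch4}, \code{efm_ch4}, \code{efs_n2o}, \code{efe},
#'   \code{efp}.
#' @param gwp A GWP set (list with \code{gwp_ch4}, \code{gwp_n2o}), e.g.
#'   \code{default_factors("GWP100")$gwp}.
#' @return Total emissions in t CO2-eq.
#' @export
etotal <- function(stages, gwp) {
  stages$efc + stages$eft +
    (stages$efg_ch4 + stages$efm_ch4) * gwp$gwp_ch4 / 1000 +
    stages$efs_n2o * gwp$gwp_n2o / 1000 +
    stages$efe + stages$efp
}

#' Run the full stage accounting over a panel
#'
#' @param panel A \code{ghg_panel}.
#' @param factors A \code{ghg_factors} set.
#' @return Data frame with one row per (city, year): the seven stage columns
#'   (\code{efc}, \code{eft} in t CO2-eq; \code{efg_ch4}, \code{efm_ch4},
#'   \code{efs_n2o} in kg gas; \code{efe}, \code{efp} in t CO2) and
#'   \code{etotal} in t CO2-eq under the factor set's GWP.
#' @export
account_panel <- function(panel, factors) {
  recs <- panel_records(panel)
  rows <- lapply(recs, function(r) {
    st <- list(efc = efc(r, factors), eft = eft(r, factors),
               efg_ch4 = efg(r, factors), efm_ch4 = efm(r, factors),
               efs_n2o = efs(r, factors), efe = efe(r, factors),
               efp = efp(r, factors))
    data.frame(city = r$city, year = r$year,
               efc = st$efc, eft = st$eft, efg_ch4 = st$efg_ch4,
               efm_ch4 = st$efm_ch4, efs_n2o = st$efs_n2o,
               efe = st$efe, efp = st$efp,
               etotal = etotal(st, factors$gwp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$city, out$year), ]
  rownames(out) <- NULL
  out
}

#' Provincial (all-city) annual series from a stage table
#'
#' Column sums by year; the CH4/N2O stages are also returned as CO2-eq
#' contributions under the given GWP set, and manure CH4 + N2O are combined
#' into a single manure-management column \code{ems}.
#'
#' @param stage_table Output of \code{\link{account_panel}}.
#' @param gwp GWP set used for the gas-to-CO2-eq columns.
#' @return Data frame with one row per year: \code{efc}, \code{eft},
#'   \code{efe}, \code{efg} (enteric CO2-eq), \code{ems} (manure CO2-eq),
#'   \code{efp}, \code{etotal}, all in t CO2-eq.
#' @export
provincial_series <- function(stage_table, gwp) {
  agg <- stats::aggregate(
    stage_table[c("efc", "eft", "efg_ch4", "efm_ch4", "efs_n2o", "efe", "efp",
                  "etotal")],
    by = list(year = stage_table$year), FUN = sum)
  data.frame(
    year = agg$year,
    efc = agg$efc, eft = agg$eft, efe = agg$efe,
    efg = agg$efg_ch4 * gwp$gwp_ch4 / 1000,
    ems = agg$efm_ch4 * gwp$gwp_ch4 / 1000 + agg$efs_n2o * gwp$gwp_n2o / 1000,
    efp = agg$efp,
    etotal = agg$etotal
  )
}

#' Geometric (compound) annual rate of change of a series
#'
#' \eqn{(x_{y_1}/x_{y_0})^{1/(y_1-y_0)} - 1}: the constant annual rate that
#' carries the series from its start to its end value. Invariant to constant
#' rescaling of the series.
#'
#' @param series Named numeric vector, names are years.
#' @param y0,y1 Start and end year.
#' @return Fraction per year (e.g. -0.0118 for an average 1.18 percent annual
#'   decline).
#' @export
annualized_rate <- function(series, y0, y1) {
  y0 <- as.character(y0); y1 <- as.character(y1)
  if (!y0 %in% names(series) || !y1 %in% names(series))
    stop_domain("endpoint years not present in the series")
  v0 <- series[[y0]]; v1 <- series[[y1]]
  if (as.numeric(y1) <= as.numeric(y0))
    stop_domain("end year must exceed start year")
  if (!is.finite(v0) || !is.finite(v1) || v0 <= 0 || v1 <= 0)
    stop_domain("annualized rate requires positive endpoint values")
  (v1 / v0)^(1 / (as.numeric(y1) - as.numeric(y0))) - 1
}

#' Pearson correlation of each stage with total emissions
#'
#' Correlates the provincial annual total against each stage series over a
#' year window, with two-sided p-values from the t distribution on n-2
#' degrees of freedom. A zero-variance series yields \code{NA} r and p with
#' \code{undefined = TRUE} rather than an error.
#'
#' @param prov Output of \code{\link{provincial_series}}.
#' @param years Years to include (default all).
#' @param stages Stage columns to correlate (default the six stage series).
#' @return Data frame: stage, r, p, undefined.
#' @export
stage_correlations <- function(prov, years = prov$year,
                               stages = c("efc", "eft", "efe", "efg", "ems", "efp")) {
  sub <- prov[prov$year %in% years, ]
  if (nrow(sub) < 3) stop_domain("need at least 3 years for correlation")
  rows <- lapply(stages, function(s) {
    x <- sub[[s]]; y <- sub$etotal
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(stage = s, r = NA_real_, p = NA_real_, undefined = TRUE))
    ct <- stats::cor.test(x, y)
    data.frame(stage = s, r = unname(ct$estimate), p = ct$p.value,
               undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
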