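#' Tapio decoupling elasticity
#'
#' The elasticity of emissions with respect to economic output between two
#' years:
#' \deqn{E = \frac{\Delta C / C_0}{\Delta G / G_0}}
#' where \eqn{C} is emissions and \eqn{G} is gross output value. The sign
#' pattern of the two relative changes together with magnitude bands of
#' \eqn{E} defines the eight Tapio states (see \code{\link{classify_decoupling}}).
#'
#' @param c0,c1 Emissions in the base and current year (\code{c0 > 0}).
#' @param g0,g1 Output value in the base and current year (\code{g0 > 0}).
#' @return List with \code{dc_rel}, \code{dg_rel} and \code{elasticity}
#'   (\code{NA} when \code{dg_rel == 0}).
#' @export
tapio_elasticity <- function(c0, c1, g0, g1) {
  if (!is.finite(c0) || !is.finite(g0) || c0 <= 0 || g0 <= 0)
    stop_domain("base-year emissions and output value must be positive")
  dc <- (c1 - c0) / c0
  dg <- (g1 - g0) / g0
  list(dc_rel = dc, dg_rel = dg,
       elasticity = if (dg == 0) NA_real_ else dc / dg)
}

# full state names and the conventional letter codes
.tapio_codes <- c(
  weak_decoupling = "D", weak_negative_decoupling = "DI",
  strong_decoupling = "G", strong_negative_decoupling = "GI",
  expansive_negative_decoupling = "Q", recessive_decoupling = "N",
  expansive_coupling = "QI", recessive_coupling = "NI",
  undefined = NA_character_
)

#' Classify a (relative change, elasticity) triple into a Tapio state
#'
#' With growing output (\code{dg_rel > 0}): negative elasticity is strong
#' decoupling; \eqn{0 \le E < 0.8} weak decoupling; \eqn{0.8 \le E \le 1.2}
#' expansive coupling; \eqn{E > 1.2} expansive negative decoupling. With
#' shrinking output (\code{dg_rel < 0}): negative elasticity is strong
#' negative decoupling; \eqn{0 \le E < 0.8} weak negative decoupling;
#' \eqn{0.8 \le E \le 1.2} recessive coupling; \eqn{E > 1.2} recessive
#' decoupling. The band boundaries 0.8 and 1.2 belong to the coupling band.
#' \code{dg_rel == 0} yields the \code{"undefined"} state, never an error.
#'
#' The elasticity argument is trusted over the ratio of the (possibly
#' rounded) relative changes, so published triples can be classified exactly
#' as printed.
#'
#' @param dc_rel Relative change in emissions.
#' @param dg_rel Relative change in output value.
#' @param elasticity The elasticity \code{dc_rel / dg_rel}; defaults to the
#'   recomputed ratio.
#' @return The state name (character); the letter code is available via
#'   \code{\link{tapio_code}}.
#' @examples
#' classify_decoupling(-0.306, 0.215, -1.421)  # strong_decoupling
#' @export
classify_decoupling <- function(dc_rel, dg_rel,
                                elasticity = if (dg_rel == 0) NA_real_ else dc_rel / dg_rel) {
  if (!is.finite(dg_rel) || !is.finite(dc_rel))
    stop_domain("relative changes must be finite")
  if (dg_rel == 0 || !is.finite(elasticity)) return("undefined")
  band <- if (elasticity < 0) "negative"
          else if (elasticity < 0.8) "low"
          else if (elasticity <= 1.2) "coupling"
          else "high"
  if (dg_rel > 0) {
    switch(band,
      negative = "strong_decoupling",
      low      = "weak_decoupling",
      coupling = "expansive_coupling",
      high     = "expansive_negative_decoupling")
  } else {
    switch(band,
      negative = "strong_negative_decoupling",
      low      = "weak_negative_decoupling",
      coupling = "recessive_coupling",
      high     = "recessive_decoupling")
  }
}

#' Letter code for a Tapio state
#' @param state State name as returned by \code{\link{classify_decoupling}}.
#' @return Letter code (D, DI, G, GI, Q, N, QI, NI; \code{NA} for undefined).
#' @export
tapio_code <- function(state) {
  unname(.tapio_codes[state])
}

#' Year-over-year decoupling records for an emission and an output series
#'
#' @param emissions Named numeric vector of emissions, names are years.
#' @param output_value Named numeric vector of output value over the same
#'   contiguous years.
#' @return Data frame with one row per consecutive year pair: \code{period},
#'   \code{dc_rel}, \code{dg_rel}, \code{elasticity}, \code{state},
#'   \code{code}.
#' @export
decoupling_series <- function(emissions, output_value) {
  ye <- sort(as.integer(names(emissions)))
  yg <- sort(as.integer(names(output_value)))
  if (!identical(ye, yg))
    stop_validation("emission and output series must cover the same years")
  if (length(ye) > 1 && !identical(ye, seq(min(ye), max(ye))))
    stop_validation("years must be contiguous")
  rows <- lapply(ye[-length(ye)], function(y0) {
    y1 <- y0 + 1L
    el <- tapio_elasticity(emissions[[as.character(y0)]],
                           emissions[[as.character(y1)]],
                           output_value[[as.character(y0)]],
                           output_value[[as.character(y1)]])
    state <- classify_decoupling(el$dc_rel, el$dg_rel, el$elasticity)
    data.frame(period = sprintf("%d-%d", y0, y1),
               dc_rel = el$dc_rel, dg_rel = el$dg_rel,
               elasticity = el$elasticity, state = state,
               code = tapio_code(state), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
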