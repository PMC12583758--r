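#' Emission-factor registry
#'
#' All coefficients used by the life-cycle accounting engine live in a single
#' factor set: per-head gas emission factors for enteric (gastrointestinal)
#' fermentation and manure management, per-tonne CO2-eq factors for feed-grain
#' cultivation and transport/processing, energy emission factors and unit
#' prices, per-kg processing energy intensities, and a global-warming-potential
#' (GWP) set used to put CH4 and N2O on the CO2 scale.
#'
#' Factors are stored in their source units (kg gas per head per year for the
#' livestock factors, t CO2-eq per t grain, t CO2 per MWh, MJ per kg product);
#' all unit conversion happens inside the accounting functions, never here.
#'
#' Poultry have no enteric CH4 factor in the underlying inventory tables
#' (monogastric birds: negligible enteric fermentation); this is encoded as an
#' exact 0. Soybean has a transport/processing factor but no cultivation
#' factor; its cultivation factor is stored as \code{NA} and soybean is
#' excluded from the cultivation stage with a warning unless an override
#' supplies a value.
#'
#' @param gwp_name Name of the GWP set: \code{"GWP100"} (CH4 27, N2O 273,
#'   the 100-year horizon used in long-term climate policy) or \code{"GWP20"}
#'   (CH4 81.2, N2O 273, the 20-year horizon that weights short-lived gases
#'   more heavily).
#' @return An object of class \code{ghg_factors}: a list with elements
#'   \code{species} (data frame: species, enteric_ch4, manure_ch4, manure_n2o),
#'   \code{grains} (data frame: grain, cultivation_co2, transport_co2; the
#'   cultivation factor may be \code{NA} meaning "absent"),
#'   \code{energy} (list: ef_e, price_e, ef_c, price_c, e_n),
#'   \code{processing} (data frame: product, mj_per_kg), and
#'   \code{gwp} (list: name, gwp_ch4, gwp_n2o).
#' @examples
#' f <- default_factors("GWP100")
#' f$species[f$species$species == "cattle", "enteric_ch4"]  # 52.90
#' default_factors("GWP20")$gwp$gwp_ch4                     # 81.2
#' @export
default_factors <- function(gwp_name = "GWP100") {
  gwp <- switch(gwp_name,
    GWP100 = list(name = "GWP100", gwp_ch4 = 27, gwp_n2o = 273),
    GWP20  = list(name = "GWP20",  gwp_ch4 = 81.2, gwp_n2o = 273),
    stop_config(sprintf("unknown GWP set '%s' (expected GWP100 or GWP20)", gwp_name))
  )

  species <- data.frame(
    species     = c("cattle", "pig", "sheep", "mule", "donkey", "horse",
                    "rabbit", "poultry"),
    enteric_ch4 = c(52.90, 1.00, 5.00, 10.00, 10.00, 18.00, 0.254, 0),
    manure_ch4  = c(3.31, 3.50, 0.16, 0.90, 0.90, 1.64, 0.08, 0.02),
    manure_n2o  = c(0.85, 0.53, 0.33, 1.39, 1.39, 1.39, 0.02, 0.02),
    stringsAsFactors = FALSE
  )

  grains <- data.frame(
    grain           = c("corn", "wheat", "soybean"),
    cultivation_co2 = c(1.50, 1.22, NA),    # t CO2-eq / t grain; soybean absent
    transport_co2   = c(0.0102, 0.0319, 0.1013),
    stringsAsFactors = FALSE
  )

  energy <- list(
    ef_e    = 0.9734,   # t CO2 / MWh electricity
    price_e = 0.4275,   # CNY / kWh
    ef_c    = 1.98,     # t CO2 / t coal
    price_c = 800,      # CNY / t coal
    e_n     = 3.60      # MJ / kWh
  )

  processing <- data.frame(
    product   = c("pork", "beef", "mutton", "poultry_meat", "milk", "eggs"),
    mj_per_kg = c(3.76, 4.37, 10.4, 2.59, 1.12, 8.16),
    stringsAsFactors = FALSE
  )

  structure(
    list(species = species, grains = grains, energy = energy,
         processing = processing, gwp = gwp),
    class = "ghg_factors"
  )
}

#' Load an emission-factor set from a YAML config file
#'
#' Reads a config with optional top-level \code{base} (a default set name,
#' \code{"GWP100"} or \code{"GWP20"}) and optional override sections
#' \code{species}, \code{grains}, \code{energy}, \code{processing} and
#' \code{gwp}. Overrides are applied field-by-field on top of the base set;
#' the result is validated against the factor invariants (non-negative
#' livestock/grain/processing factors, strictly positive energy factors and
#' prices, GWPs > 1).
#'
#' Species/grain/product override sections are nested maps, e.g.
#' \preformatted{
#' base: GWP100
#' species:
#'   cattle: {enteric_ch4: 60.0}
#' energy:
#'   price_c: 750
#' }
#'
#' @param path Path to the YAML file.
#' @return A validated \code{ghg_factors} object.
#' @export
load_factors <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("factor config '%s' not found", path))
  cfg <- yaml::yaml.load_file(path)
  if (is.null(cfg)) cfg <- list()
  base <- if (!is.null(cfg$base)) cfg$base else "GWP100"
  f <- default_factors(base)

  override_table <- function(tab, key_col, section, allowed_fields) {
    for (key in names(section)) {
      row <- which(tab[[key_col]] == key)
      if (length(row) == 0) {
        # a new species/grain/product is appended rather than rejected
        new <- as.list(rep(NA_real_, ncol(tab)))
        names(new) <- names(tab)
        new[[key_col]] <- key
        tab <- rbind(tab, as.data.frame(new, stringsAsFactors = FALSE))
        row <- nrow(tab)
      }
      for (field in names(section[[key]])) {
        if (!field %in% allowed_fields)
          stop_validation(sprintf("unknown factor field '%s' for '%s'", field, key))
        tab[row, field] <- as.numeric(section[[key]][[field]])
      }
    }
    tab
  }

  if (!is.null(cfg$species))
    f$species <- override_table(f$species, "species", cfg$species,
                                c("enteric_ch4", "manure_ch4", "manure_n2o"))
  if (!is.null(cfg$grains))
    f$grains <- override_table(f$grains, "grain", cfg$grains,
                               c("cultivation_co2", "transport_co2"))
  if (!is.null(cfg$processing))
    f$processing <- override_table(f$processing, "product", cfg$processing,
                                   "mj_per_kg")
  for (field in names(cfg$energy)) {
    if (!field %in% names(f$energy))
      stop_validation(sprintf("unknown energy field '%s'", field))
    f$energy[[field]] <- as.numeric(cfg$energy[[field]])
  }
  for (field in names(cfg$gwp)) {
    if (!field %in% c("name", "gwp_ch4", "gwp_n2o"))
      stop_validation(sprintf("unknown gwp field '%s'", field))
    f$gwp[[field]] <- if (field == "name") cfg$gwp[[field]] else as.numeric(cfg$gwp[[field]])
  }

  validate_factors(f)
}

#' @keywords internal
validate_factors <- function(f) {
  sp <- f$species
  for (col in c("enteric_ch4", "manure_ch4", "manure_n2o")) {
    bad <- !is.na(sp[[col]]) & sp[[col]] < 0
    if (any(is.na(sp[[col]])))
      stop_validation(sprintf("species factor '%s' missing for: %s", col,
                              paste(sp$species[is.na(sp[[col]])], collapse = ", ")))
    if (any(bad))
      stop_validation(sprintf("negative species factor '%s' for: %s", col,
                              paste(sp$species[bad], collapse = ", ")))
  }
  gr <- f$grains
  if (any(!is.na(gr$cultivation_co2) & gr$cultivation_co2 < 0) ||
      any(is.na(gr$transport_co2)) || any(gr$transport_co2 < 0))
    stop_validation("grain factors must be non-negative (transport factor required)")
  en <- f$energy
  if (any(vapply(en, function(x) !is.numeric(x) || is.na(x) || x <= 0, logical(1))))
    stop_validation("energy factors and prices must be strictly positive")
  if (any(is.na(f$processing$mj_per_kg)) || any(f$processing$mj_per_kg < 0))
    stop_validation("processing energy intensities must be non-negative")
  if (!is.numeric(f$gwp$gwp_ch4) || !is.numeric(f$gwp$gwp_n2o) ||
      f$gwp$gwp_ch4 <= 1 || f$gwp$gwp_n2o <= 1)
    stop_validation("GWP values must exceed 1")
  f
}

# Named lookup helpers: factor tables as named vectors keyed by identifier.
species_factor <- function(f, col) {
  stats::setNames(f$species[[col]], f$species$species)
}
grain_factor <- function(f, col) {
  stats::setNames(f$grains[[col]], f$grains$grain)
}
processing_factor <- function(f) {
  stats::setNames(f$processing$mj_per_kg, f$processing$product)
}
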