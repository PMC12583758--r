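# Shared fixtures and independent oracles.

# One-city, one-year hand fixture: 100 cattle + 1000 pigs, 2 t pork + 1 t
# milk, costs chosen so the electricity term is 50 kWh/head for pigs and the
# coal term 0.1 t/head (pigs only).
hand_record <- function() {
  list(
    city = "A", year = 2001,
    inventories = c(cattle = 100, pig = 1000),
    outputs = c(pork = 2, milk = 1),
    elec_cost = c(cattle = 0, pig = 21.375),
    coal_cost = c(cattle = 0, pig = 80),
    feed_factor = c(pork = 3.5, milk = 0.9),
    grain_shares = c(corn = 0.6, wheat = 0.2),
    output_value = 1e6
  )
}

# Fully hand-written arithmetic for the fixture above (independent of the
# package's stage functions). Every coefficient is written out literally.
hand_oracle <- function(gwp_ch4, gwp_n2o) {
  efc <- (2 * 3.5 + 1 * 0.9) * (0.6 * 1.50 + 0.2 * 1.22)
  eft <- (2 * 3.5 + 1 * 0.9) * (0.6 * 0.0102 + 0.2 * 0.0319)
  efg <- 100 * 52.90 + 1000 * 1.00
  efm <- 100 * 3.31 + 1000 * 3.50
  efs <- 100 * 0.85 + 1000 * 0.53
  efe <- 1000 * (21.375 / 0.4275) / 1000 * 0.9734 + 1000 * (80 / 800) * 1.98
  efp <- 2 * 1000 * (3.76 / 3.60) / 1000 * 0.9734 +
         1 * 1000 * (1.12 / 3.60) / 1000 * 0.9734
  list(efc = efc, eft = eft, efg_ch4 = efg, efm_ch4 = efm, efs_n2o = efs,
       efe = efe, efp = efp,
       etotal = efc + eft + (efg + efm) * gwp_ch4 / 1000 +
         efs * gwp_n2o / 1000 + efe + efp)
}

# Two-city, two-year minimal panel as raw data frames.
tiny_tables <- function() {
  cities <- c("A", "B"); years <- 2001:2002
  inv <- expand.grid(city = cities, year = years, species = "pig",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inv$head <- c(100, 110, 200, 210)  # expand.grid: (A,2001) (B,2001) (A,2002) (B,2002)
  out <- expand.grid(city = cities, year = years, product = "pork",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$tonnes <- c(8, 9, 16, 17)
  ec <- inv[c("city", "year", "species")]
  ec$elec_cost <- 20; ec$coal_cost <- 10
  gdp <- expand.grid(city = cities, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gdp$output_value <- c(1e5, 1.1e5, 2e5, 2.2e5)
  list(inventory = inv, output = out,
       feed = data.frame(product = "pork", feed_factor = 3.5),
       shares = data.frame(grain = c("corn", "wheat"), share = c(0.6, 0.2)),
       energycost = ec, gdp = gdp)
}

tiny_panel <- function() do.call(new_panel, tiny_tables())

# Brute-force two-pass Theil oracle: explicit loop, no vectorisation.
theil_bruteforce <- function(values) {
  n <- length(values)
  mu <- 0
  for (v in values) mu <- mu + v / n
  total <- 0
  for (v in values) total <- total + (v / mu) * log(v / mu) / n
  total
}

# Brute-force between-group Theil from first principles.
between_bruteforce <- function(values, scheme) {
  mu <- mean(values)
  n <- length(values)
  out <- 0
  for (g in unique(scheme[names(values)])) {
    v <- values[scheme[names(values)] == g]
    s <- length(v) * mean(v) / (n * mu)
    out <- out + s * log(mean(v) / mu)
  }
  out
}

# The published conventional transition matrix (four emission types).
published_markov <- function() {
  matrix(c(0.8947, 0.1053, 0.0000, 0.0000,
           0.2877, 0.6712, 0.0411, 0.0000,
           0.0375, 0.2000, 0.6750, 0.0875,
           0.0000, 0.0128, 0.1923, 0.7949),
         nrow = 4, byrow = TRUE)
}

# The 20 published year-over-year decoupling triples with their state codes.
published_decoupling <- function() {
  data.frame(
    period = c("2001-2002", "2002-2003", "2003-2004", "2004-2005", "2005-2006",
               "2006-2007", "2007-2008", "2008-2009", "2009-2010", "2010-2011",
               "2011-2012", "2012-2013", "2013-2014", "2014-2015", "2015-2016",
               "2016-2017", "2017-2018", "2018-2019", "2019-2020", "2020-2021"),
    dc = c(0.016, 0.082, 0.089, 0.060, 0.067, -0.306, 0.059, 0.017, -0.009,
           -0.007, 0.010, 0.018, 0.022, 0.004, -0.027, -0.233, -0.010, -0.033,
           -0.065, 0.122),
    dg = c(0.125, 0.089, 0.327, 0.124, -0.151, 0.215, 0.358, -0.064, 0.049,
           0.202, 0.015, 0.087, -0.003, -0.032, 0.053, 0.005, -0.067, 0.047,
           0.233, 0.030),
    e = c(0.124, 0.920, 0.271, 0.488, -0.440, -1.421, 0.165, -0.270, -0.186,
          -0.037, 0.679, 0.207, -8.452, -0.115, -0.502, -43.058, 0.154,
          -0.687, -0.278, 4.038),
    code = c("D", "QI", "D", "D", "GI", "G", "D", "GI", "G", "G", "D", "D",
             "GI", "GI", "G", "G", "DI", "G", "G", "Q"),
    stringsAsFactors = FALSE
  )
}
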