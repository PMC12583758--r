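test_that("a small panel validates and splits into one record per city-year", {
  p <- tiny_panel()
  expect_s3_class(p, "ghg_panel")
  recs <- panel_records(p)
  expect_length(recs, 4)
  expect_setequal(names(recs), c("A.2001", "A.2002", "B.2001", "B.2002"))
  expect_equal(recs[["A.2002"]]$inventories, c(pig = 200))
  expect_equal(recs[["B.2001"]]$output_value, 1.1e5)
})

test_that("malformed panels are rejected with classed errors", {
  tabs <- tiny_tables()

  dup <- tabs
  dup$inventory <- rbind(dup$inventory, dup$inventory[1, ])
  expect_error(do.call(new_panel, dup), class = "herdghg_format_error")

  neg <- tabs
  neg$inventory$head[1] <- -5
  expect_error(do.call(new_panel, neg), class = "herdghg_validation_error")

  gap <- tabs
  gap$inventory$year[gap$inventory$year == 2002] <- 2003
  gap$gdp$year[gap$gdp$year == 2002] <- 2003
  gap$energycost$year[gap$energycost$year == 2002] <- 2003
  gap$output$year[gap$output$year == 2002] <- 2003
  expect_error(do.call(new_panel, gap), class = "herdghg_validation_error")

  badshare <- tabs
  badshare$shares$share <- c(0.7, 0.6)
  expect_error(do.call(new_panel, badshare), class = "herdghg_validation_error")
})

test_that("write_panel / read_panel round-trips a panel field-identically", {
  dir <- withr::local_tempdir()
  p <- tiny_panel()
  scheme <- c(A = "R1", B = "R2")
  adj <- list(A = "B", B = "A")
  write_panel(p, dir, scheme = scheme, adjacency = adj)
  p2 <- read_panel(dir)
  expect_equal(p2, p)
  expect_identical(read_region_scheme(file.path(dir, "regions.csv")), scheme)
  expect_identical(read_adjacency(file.path(dir, "adjacency.csv")), adj)
  # a second round trip is byte-stable
  dir2 <- withr::local_tempdir()
  write_panel(p2, dir2)
  expect_identical(readLines(file.path(dir, "inventory.csv")),
                   readLines(file.path(dir2, "inventory.csv")))
})

test_that("imputation interpolates by inverse year distance and flags cells", {
  mk <- function(heads, years) {
    tabs <- tiny_tables()
    n <- length(years)
    tabs$inventory <- data.frame(city = "A", year = years, species = "pig",
                                 head = heads)
    tabs$output <- data.frame(city = "A", year = years, product = "pork",
                              tonnes = 1)
    tabs$energycost <- data.frame(city = "A", year = years, species = "pig",
                                  elec_cost = 1, coal_cost = 1)
    tabs$gdp <- data.frame(city = "A", year = years, output_value = 1)
    do.call(new_panel, c(tabs, allow_missing = TRUE))
  }

  # equal distances: plain average
  p <- impute_missing(mk(c(10, NA, 20), 2001:2003))
  expect_equal(p$inventory$head, c(10, 15, 20))
  expect_equal(attr(p, "imputed")$year, 2002)

  # distances 1 and 2: weights 2/3 and 1/3
  p <- impute_missing(mk(c(10, NA, NA, 40), 2001:2004))
  expect_equal(p$inventory$head, c(10, 20, 30, 40))

  # boundary gap: nearest observed value
  p <- impute_missing(mk(c(NA, 7, 9), 2001:2003))
  expect_equal(p$inventory$head, c(7, 7, 9))

  # no gaps: identity, empty log
  full <- impute_missing(mk(c(1, 2, 3), 2001:2003))
  expect_equal(full$inventory$head, c(1, 2, 3))
  expect_equal(nrow(attr(full, "imputed")), 0)

  # idempotence
  once <- impute_missing(mk(c(10, NA, 20), 2001:2003))
  twice <- impute_missing(once)
  expect_equal(twice$inventory$head, once$inventory$head)

  # an all-missing series cannot be filled
  expect_error(impute_missing(mk(c(NA, NA, NA), 2001:2003)),
               class = "herdghg_validation_error")
})

test_that("the default region scheme maps 18 cities to 5 regions", {
  s <- default_region_scheme()
  expect_length(s, 18)
  expect_length(unique(s), 5)
  expect_identical(unname(s["Zhoukou"]), "Eastern")
  expect_identical(unname(s["Jiyuan"]), "West")
  expect_identical(unname(s["Zhumadian"]), "Southern")
  expect_identical(unname(s["Luohe"]), "Central")
  expect_identical(unname(s["Puyang"]), "North")
})

test_that("adjacency lists are symmetrised and self-loops rejected", {
  adj <- herdghg:::edges_to_adjacency(c("A", "B"), c("B", "C"))
  expect_identical(adj$B, c("A", "C"))
  expect_identical(adj$C, "B")
  expect_error(herdghg:::edges_to_adjacency("A", "A"),
               class = "herdghg_validation_error")
  expect_error(herdghg:::edges_to_adjacency("A", "B", cities = c("A", "B", "D")),
               class = "herdghg_validation_error")
})
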