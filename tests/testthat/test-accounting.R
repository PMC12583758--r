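f100 <- default_factors("GWP100")
f20 <- default_factors("GWP20")

test_that("feed-grain stages match hand arithmetic", {
  rec <- hand_record()
  rec$outputs <- c(pork = 2)
  # 2 t pork x 3.5 t feed/t x (0.6 x 1.50 + 0.2 x 1.22)
  expect_equal(efc(rec, f100), 8.008)
  rec$grain_shares <- c(corn = 0.6, soybean = 0.2)
  expect_equal(eft(rec, f100), 7 * (0.6 * 0.0102 + 0.2 * 0.1013))

  none <- hand_record()
  none$outputs <- c(pork = 0, milk = 0)
  expect_equal(efc(none, f100), 0)
  expect_equal(eft(none, f100), 0)

  zero_shares <- hand_record()
  zero_shares$grain_shares <- c(corn = 0, wheat = 0)
  expect_equal(eft(zero_shares, f100), 0)
})

test_that("a grain without a cultivation factor is skipped with a warning", {
  rm(list = ls(envir = herdghg:::.efc_warned), envir = herdghg:::.efc_warned)
  rec <- hand_record()
  rec$outputs <- c(pork = 2)
  rec$grain_shares <- c(corn = 0.6, soybean = 0.2)
  expect_warning(v <- efc(rec, f100), "soybean")
  expect_equal(v, 7 * 0.6 * 1.50)  # soybean term dropped
  # warned once per session, value unchanged on repeat
  expect_silent(expect_equal(efc(rec, f100), v))
})

test_that("per-head gas stages match the published factors", {
  rec <- hand_record()
  rec$inventories <- c(cattle = 100)
  expect_equal(efg(rec, f100), 5290)
  rec$inventories <- c(poultry = 1000)
  expect_equal(efg(rec, f100), 0)
  rec$inventories <- c(pig = 1000)
  expect_equal(efm(rec, f100), 3500)
  expect_equal(efs(rec, f100), 530)
  rec$inventories <- numeric(0)
  expect_equal(efg(rec, f100), 0)
  rec$inventories <- c(dragon = 1)
  expect_error(efg(rec, f100), class = "herdghg_validation_error")
})

test_that("energy and processing stages apply the unit bridges", {
  rec <- hand_record()
  rec$inventories <- c(pig = 10)
  # 21.375 CNY / 0.4275 CNY/kWh = 50 kWh = 0.05 MWh; 80 CNY / 800 = 0.1 t coal
  expect_equal(efe(rec, f100), 10 * 0.05 * 0.9734 + 10 * 0.1 * 1.98)

  rec$elec_cost <- c(cattle = 0, pig = 0)
  rec$coal_cost <- c(cattle = 0, pig = 0)
  expect_equal(efe(rec, f100), 0)

  rec10 <- hand_record(); rec10$inventories <- c(pig = 10)
  rec20 <- hand_record(); rec20$inventories <- c(pig = 20)
  expect_equal(efe(rec20, f100), 2 * efe(rec10, f100))

  pork1 <- hand_record(); pork1$outputs <- c(pork = 1)
  expect_equal(efp(pork1, f100), 1000 * (3.76 / 3.60) / 1000 * 0.9734)
  milk1 <- hand_record(); milk1$outputs <- c(milk = 1)
  expect_equal(efp(milk1, f100), 1000 * (1.12 / 3.60) / 1000 * 0.9734)
  none <- hand_record(); none$outputs <- c(pork = 0)
  expect_equal(efp(none, f100), 0)
})

test_that("etotal converts gas masses to tonnes before GWP weighting", {
  zero <- list(efc = 0, eft = 0, efg_ch4 = 0, efm_ch4 = 0, efs_n2o = 0,
               efe = 0, efp = 0)
  expect_equal(etotal(zero, f100$gwp), 0)
  only_efg <- modifyList(zero, list(efg_ch4 = 1000))
  expect_equal(etotal(only_efg, f100$gwp), 27)
  expect_equal(etotal(only_efg, f20$gwp), 81.2)
  only_efs <- modifyList(zero, list(efs_n2o = 1000))
  expect_equal(etotal(only_efs, f100$gwp), 273)
})

test_that("account_panel composes the stage functions additively", {
  p <- tiny_panel()
  tab <- account_panel(p, f100)
  expect_equal(nrow(tab), 4)
  recs <- panel_records(p)
  r <- recs[["B.2002"]]
  row <- tab[tab$city == "B" & tab$year == 2002, ]
  expect_equal(row$efc, efc(r, f100))
  expect_equal(row$efg_ch4, efg(r, f100))
  expect_equal(row$etotal,
               etotal(list(efc = row$efc, eft = row$eft, efg_ch4 = row$efg_ch4,
                           efm_ch4 = row$efm_ch4, efs_n2o = row$efs_n2o,
                           efe = row$efe, efp = row$efp), f100$gwp))

  # permuting record order leaves the result unchanged
  tabs <- tiny_tables()
  perm <- tabs
  perm$inventory <- perm$inventory[rev(seq_len(nrow(perm$inventory))), ]
  perm$gdp <- perm$gdp[c(3, 1, 4, 2), ]
  expect_equal(account_panel(do.call(new_panel, perm), f100), tab)

  # duplicating a city doubles the provincial total
  dup <- tabs
  for (nm in c("inventory", "output", "energycost", "gdp")) {
    extra <- dup[[nm]]
    extra$city <- paste0(extra$city, "x")
    dup[[nm]] <- rbind(dup[[nm]], extra)
  }
  tab2 <- account_panel(do.call(new_panel, dup), f100)
  expect_equal(sum(tab2$etotal), 2 * sum(tab$etotal))
})

test_that("every stage is homogeneous of degree 1 in quantities", {
  rec <- hand_record()
  scaled <- rec
  for (nm in c("inventories", "outputs")) scaled[[nm]] <- 3 * scaled[[nm]]
  for (fn in list(efc, eft, efg, efm, efs, efe, efp)) {
    expect_equal(fn(scaled, f100), 3 * fn(rec, f100))
  }
})

test_that("the annualized rate is geometric and reproduces published values", {
  s <- c("2001" = 4829.90, "2007" = 4533.08, "2015" = 5069.75,
         "2021" = 3805.48)
  expect_equal(round(100 * annualized_rate(s, 2001, 2021), 2), -1.18)
  expect_equal(round(100 * annualized_rate(s, 2001, 2007), 2), -1.05)
  expect_equal(round(100 * annualized_rate(s, 2015, 2021), 2), -4.67)

  const <- c("2001" = 5, "2010" = 5)
  expect_equal(annualized_rate(const, 2001, 2010), 0)
  expect_equal(annualized_rate(10 * s, 2001, 2021),
               annualized_rate(s, 2001, 2021))
  expect_error(annualized_rate(c("2001" = 0, "2002" = 1), 2001, 2002),
               class = "herdghg_domain_error")
  expect_error(annualized_rate(s, 2007, 2001), class = "herdghg_domain_error")
})

test_that("stage correlations match hand Pearson values and flag degeneracy", {
  prov <- data.frame(year = 2001:2003, efc = c(6, 4, 5), eft = c(2, 4, 6),
                     efe = c(1, 1, 1), efg = c(1, 2, 3), ems = c(1, 2, 3),
                     efp = c(1, 2, 3), etotal = c(1, 2, 3))
  ct <- stage_correlations(prov)
  expect_equal(ct$r[ct$stage == "efc"], -0.5)
  expect_equal(ct$r[ct$stage == "eft"], 1)
  expect_equal(ct$r[ct$stage == "efg"], 1)
  expect_true(ct$undefined[ct$stage == "efe"])
  expect_true(is.na(ct$r[ct$stage == "efe"]))
  expect_error(stage_correlations(prov[1:2, ]), class = "herdghg_domain_error")
})
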