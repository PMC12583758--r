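#!/usr/bin/env Rscript
# Theil-index decomposition of city-level emissions and of livestock output
# value into within- and between-region components, year by year.

suppressPackageStartupMessages(library(herdghg))

panel <- read_panel("results/panel")
scheme <- read_region_scheme("results/panel/regions.csv")
tab <- suppressWarnings(account_panel(panel, default_factors("GWP100")))

te <- theil_series(tab, scheme, value = "etotal")
tg <- theil_series(panel$gdp, scheme, value = "output_value")
te$variable <- "emissions"
tg$variable <- "economy"
out <- rbind(te, tg)
utils::write.csv(out[c("year", "variable", setdiff(names(te), c("year", "variable")))],
                 "results/theil.csv", row.names = FALSE)

cat(sprintf(
  "Emission Theil index %0.4f (2001) -> %0.4f (2021); between-region share %0.0f-%0.0f%%\n",
  te$total[1], te$total[nrow(te)], min(te$between_pct), max(te$between_pct)))
cat(sprintf("Economy Theil index %0.4f (2001) -> %0.4f (2021)\n",
            tg$total[1], tg$total[nrow(tg)]))
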