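#!/usr/bin/env Rscript
# Tapio decoupling of provincial emissions from livestock output value:
# year-over-year elasticities and the eight-state classification.

suppressPackageStartupMessages(library(herdghg))

panel <- read_panel("results/panel")
tab <- suppressWarnings(account_panel(panel, default_factors("GWP100")))
prov <- provincial_series(tab, default_factors("GWP100")$gwp)
gdp <- stats::aggregate(output_value ~ year, panel$gdp, sum)

dec <- decoupling_series(stats::setNames(prov$etotal, prov$year),
                         stats::setNames(gdp$output_value, gdp$year))
utils::write.csv(dec, "results/decoupling.csv", row.names = FALSE)

cat("Decoupling state counts over", nrow(dec), "year pairs:\n")
print(table(dec$code))
cat("Sequence:", paste(dec$code, collapse = " "), "\n")
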