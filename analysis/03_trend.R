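#!/usr/bin/env Rscript
# Stage 3 — where is the carbon sink strengthening?
#
# Fits the closed-form least-squares trend to every pixel's annual NEP
# series, tests it with the regression F-test and maps the five
# significance classes.

library(nepsink)

scenario <- nep_scenario()
climate <- generate_climate(scenario)
veg <- generate_vegetation(scenario, climate)
nep <- compute_nep(compute_npp(climate, veg$ndvi, veg$vegtype),
                   compute_rh(climate$T, climate$R))

tm <- trend_map(nep$nep_annual)
mean_series <- apply(nep$nep_annual, 3, mean, na.rm = TRUE)
regional <- fit_trend(mean_series)

cat(sprintf("regional mean NEP trend: %.3f g C m-2 a-1 per year (p = %.3g)\n",
            regional[["slope"]], regional[["p"]]))
cat(sprintf("pixel trends: mean slope %.3f, %.1f%% significantly increasing, %.1f%% decreasing\n",
            mean(tm$slope, na.rm = TRUE),
            100 * sum(tm$class_proportions[c("extremely_significant_increase",
                                             "significant_increase")]),
            100 * sum(tm$class_proportions[c("extremely_significant_decrease",
                                             "significant_decrease")])))

out <- data.frame(class = names(tm$class_proportions),
                  area_fraction = as.numeric(tm$class_proportions))
write.csv(out, "results/03_trend_classes.csv", row.names = FALSE)
cat("trend class proportions -> results/03_trend_classes.csv\n")
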