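#!/usr/bin/env Rscript
# Stage 4 -- the contribution ledger lambda * E and its aggregations:
# species, sector (both levels), country, month, and the seasonal
# winter/summer contribution ratios.
# run from the repository root: Rscript analysis/04_attribution.R
source("analysis/00_common.R")

world <- generate_world(study_config())
base <- run_base(world, ctm_params(world), world_health(world))
sens <- run_adjoint(base)
ledger <- compute_contributions(sens, world$emissions[["2015"]], world$mask)
out <- file.path(RESULTS, "attribution")
dir.create(out, showWarnings = FALSE)

say("total anthropogenic contribution: %.0f deaths (%.1f%% of J = %.0f)",
    ledger$total, 100 * ledger$total / base$cost$J, base$cost$J)
for (by in c("species", "main_sector", "detailed_sector", "country", "month",
             "sector_species", "country_sector")) {
  write_table_csv(aggregate_ledger(ledger, by), file.path(out, paste0(by, ".csv")))
}
top_sp <- aggregate_ledger(ledger, "species")
say("top species: %s",
    paste(sprintf("%s %.1f%%", top_sp$species[1:3], top_sp$share_pct[1:3]),
          collapse = ", "))
top_sec <- aggregate_ledger(ledger, "main_sector")
say("top main sectors: %s",
    paste(sprintf("%s %.1f%%", top_sec$main_sector[1:3], top_sec$share_pct[1:3]),
          collapse = ", "))

write_table_csv(as.data.frame(monthly_shares(ledger, "main_sector")),
                file.path(out, "monthly_shares_main_sector.csv"))
write_gridded(field(world$grids$fine, pmadjoint:::ledger_cell_totals(ledger),
                    "deaths"),
              file.path(out, "contributions_annual_fine.grid.txt"))
say("seasonal DJF/JJA contribution ratios: OC %.2f, BC %.2f, SO2 %.2f, SOAP %.2f",
    seasonal_ratio(ledger, species = "OC"), seasonal_ratio(ledger, species = "BC"),
    seasonal_ratio(ledger, species = "SO2"), seasonal_ratio(ledger, species = "SOAP"))
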