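#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study world: country partition,
# clustered population, the 2015/2005 sectoral emission inventories with
# seasonal cycles, mortality and risk curves with bounds, meteorology,
# boundary inflow, and the noisy satellite PM2.5 field.
# run from the repository root: Rscript analysis/01_generate_world.R
source("analysis/00_common.R")

world <- generate_world(study_config())
out <- file.path(RESULTS, "world")
dir.create(out, showWarnings = FALSE)

say("domain: %d x %d coarse cells, %d x %d fine cells, %d countries (%d receptor)",
    world$grids$coarse$nlat, world$grids$coarse$nlon,
    world$grids$fine$nlat, world$grids$fine$nlon,
    length(world$mask$names), sum(world$mask$receptor))
say("population: %.2f million; satellite mean %.1f ug/m3 (cv %.2f)",
    sum(world$population$values) / 1e6, mean(world$satellite$values),
    world$config$satellite_noise_cv)

write_gridded(world$population, file.path(out, "population_fine.grid.txt"))
write_gridded(world$satellite, file.path(out, "satellite_fine.grid.txt"))
write_gridded(field(world$grids$fine, as.numeric(world$mask$ids), "country id"),
              file.path(out, "country_mask_fine.grid.txt"))
write_table_csv(world$mortality, file.path(out, "mortality_table.csv"))

for (yr in c("2015", "2005")) {
  tot <- inventory_totals(world$emissions[[yr]], "species_main_sector")
  write_table_csv(tot, file.path(out, paste0("emission_totals_", yr, ".csv")))
  say("%s inventory: %.3g kg/yr over %d species x %d sectors", yr,
      sum(tot$total_kg), length(world$emissions[[yr]]$species),
      length(world$emissions[[yr]]$sector_map))
}
say("world artifacts written to %s", out)
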