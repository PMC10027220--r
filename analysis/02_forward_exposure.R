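#!/usr/bin/env Rscript
# Stage 2 -- forward simulation and exposure fusion: monthly steady-state
# transport/chemistry of the 2015 inventory, satellite rescaling of the
# modeled PM2.5 and downscaling to the fine exposure grid, then the
# GBD-style mortality cost function.
# run from the repository root: Rscript analysis/02_forward_exposure.R
source("analysis/00_common.R")

world <- generate_world(study_config())
params <- ctm_params(world)
health <- world_health(world)
base <- run_base(world, params, health)
out <- file.path(RESULTS, "exposure")
dir.create(out, showWarnings = FALSE)

pm_model <- base$pm$annual
say("modeled annual PM2.5 (coarse): mean %.2f, max %.2f ug/m3",
    mean(pm_model), max(pm_model))
say("fused exposure (fine): mean %.2f ug/m3, population-weighted %.2f ug/m3",
    mean(base$exposure$fine_annual),
    population_weighted_mean(base$exposure, world$population,
                             receptor_cells(world$mask)))
say("rescale ratios: median %.2f, %d cells at the clamp",
    stats::median(base$rescale$ratios),
    sum(base$rescale$ratios %in% base$rescale$clamp))
say("total PM2.5-attributable deaths J = %.0f", base$cost$J)

write_gridded(field(world$grids$coarse, pm_model, "ug m-3"),
              file.path(out, "pm25_annual_coarse_model.grid.txt"))
write_gridded(field(world$grids$fine, base$exposure$fine_annual, "ug m-3"),
              file.path(out, "exposure_annual_fine.grid.txt"))
write_gridded(field(world$grids$fine, base$cost$per_cell, "deaths"),
              file.path(out, "deaths_fine.grid.txt"))
write_table_csv(base$cost$per_cause, file.path(out, "deaths_by_cause.csv"))
say("per-cause shares: %s",
    paste(sprintf("%s %.1f%%", base$cost$per_cause$cause,
                  base$cost$per_cause$share_pct), collapse = ", "))
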