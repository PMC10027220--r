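#!/usr/bin/env Rscript
# Stage 7 -- the end-to-end pipeline with the report layer: headline shares,
# health-uncertainty bounds, and the full artifact bundle with its manifest.
# run from the repository root: Rscript analysis/07_report.R
source("analysis/00_common.R")

out <- file.path(RESULTS, "report")
res <- run_pipeline(study_config(), out_dir = out)

say("J = %.0f deaths (bounds %.0f - %.0f, i.e. %d%% / %d%% of mid)",
    res$base$cost$J, res$bounds$J_low, res$bounds$J_high,
    res$bounds$low_pct_of_mid, res$bounds$high_pct_of_mid)
print(res$headline)
say("population-weighted exposure: %.2f ug/m3", res$popwt_exposure)
say("counterfactual net change: %.0f deaths", res$delta$delta_total)
say("%d artifacts + manifest written to %s", length(res$files), out)
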