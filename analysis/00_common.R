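# Shared setup for the numbered analysis scripts: the study configuration
# (the default synthetic world, seed 1) and the output locations. Every
# script is standalone: it regenerates what it needs from the seed, so the
# scripts can be run in any order.
suppressMessages(library(pmadjoint))

STUDY_SEED <- 1L
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

study_config <- function() world_config(seed = STUDY_SEED)

say <- function(...) cat(sprintf(...), "\n")
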