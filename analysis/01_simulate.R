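#!/usr/bin/env Rscript
# Stage 1 -- simulate the study inputs.
#
# Generates the synthetic study landscape (100 x 100 cells spanning
# latitudes 0-70 N): four bioclimatic predictors, a human-influence layer,
# a water-habitat mask, and 500 presence records sampled from the known
# bell-shaped suitability truth (optimum at a coldest-month minimum of
# 0 C, dry-quarter precipitation of 195 mm, plus a positive
# human-influence response). Writes the input bundle that the later
# stages consume.

suppressPackageStartupMessages(library(nichecast))

master_seed <- 20260927L
out <- "results/simdata"

land <- generate_landscape(100, 100, seed = derive_seed(master_seed, "landscape"))
truth <- truth_model()
suit <- true_suitability(truth, land$predictors)
occ <- sample_presences(suit, land$mask,
  n_target = 500,
  seed = derive_seed(master_seed, "presences")
)
write_landscape(land, occ, truth, out)

cat(sprintf(
  paste0(
    "landscape: %d x %d cells, %.0f%% water habitat\n",
    "T_min range: %.1f .. %.1f C | Prec_dry range: %.0f .. %.0f mm\n",
    "true suitability: max %.3f, mean %.3f over habitat cells\n",
    "presences: %d records written to %s\n"
  ),
  land$predictors$T_min$n_rows, land$predictors$T_min$n_cols,
  100 * mean(land$mask$values),
  min(land$predictors$T_min$values), max(land$predictors$T_min$values),
  min(land$predictors$Prec_dry$values), max(land$predictors$Prec_dry$values),
  max(suit$values), mean(suit$values[land$mask$values == 1]),
  nrow(occ), out
))
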