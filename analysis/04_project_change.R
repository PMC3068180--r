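#!/usr/bin/env Rscript
# Stage 4 -- project suitability under climate change and quantify range
# change.
#
# Projects the fitted model onto the current landscape and onto two
# emission-pathway presets ("strong": +2.0 C, precipitation x 0.85;
# "mild": +1.2 C, x 0.95), each realised as a two-member consensus
# (equal-weight mean of two circulation-model-like variants, +/- 0.25 C
# around the pathway's warming). Binary range maps use the stage-3
# 10th-percentile training presence threshold for both periods; range
# gain/loss/retained, the turnover statistic T = 100 (L+G)/(CR+G),
# regional summaries and latitudinal profiles follow, under the
# full-dispersal assumption.

suppressPackageStartupMessages(library(nichecast))

predictors <- local({
  files <- list.files("results/simdata", pattern = "\\.asc$", full.names = TRUE)
  files <- files[basename(files) != "mask.asc"]
  setNames(lapply(files, read_ascii_grid), sub("\\.asc$", "", basename(files)))
})
kept <- utils::read.csv("results/screening.csv")
preds <- predictors[kept$layer[kept$status == "kept"]]
full <- read_maxent_model("results/model_full.yaml")
thr <- as.numeric(readLines("results/threshold.txt"))

suit_cur <- predict_logistic(full, predict_raw(full, preds))
write_ascii_grid(suit_cur, "results/suitability_current.asc")
cur_bin <- binarize(suit_cur, thr)
cat(sprintf(
  "current range: %d of %d cells suitable at threshold %.4f\n",
  sum(cur_bin$values == 1), length(cur_bin$values), thr
))

regions <- local({ # two pseudo-continents, west and east half
  v <- matrix(1, cur_bin$n_rows, cur_bin$n_cols)
  v[, seq_len(cur_bin$n_cols %/% 2)] <- 2
  raster_grid(v, cur_bin$x_ll, cur_bin$y_ll, cur_bin$cell_size)
})

summary_rows <- list()
for (name in c("strong", "mild")) {
  base <- scenario_preset(name)
  variants <- list(
    scenario_delta(base$delta_t - 0.25, base$rho, name = paste0(name, "_gcmA")),
    scenario_delta(base$delta_t + 0.25, base$rho, name = paste0(name, "_gcmB"))
  )
  cons <- consensus(lapply(variants, function(d) {
    predict_logistic(full, predict_raw(full, apply_scenario(preds, d)))
  }))
  write_ascii_grid(cons, sprintf("results/suitability_%s.asc", name))
  chg <- classify_change(cur_bin, binarize(cons, thr), dispersal = "full")
  write_ascii_grid(chg$map, sprintf("results/change_%s.asc", name))
  s <- chg$summary
  prof <- latitudinal_profile(chg$map, band_width = 1)
  utils::write.csv(prof$bands, sprintf("results/lat_profile_%s.csv", name),
    row.names = FALSE
  )
  reg <- regional_summary(chg$map, regions, labels = c("1" = "east", "2" = "west"))
  utils::write.csv(reg, sprintf("results/regional_%s.csv", name), row.names = FALSE)
  cat(sprintf(
    paste0(
      "scenario %-6s: retained %d, gained %d, lost %d (CR %d) -> turnover %.1f%%\n",
      "                gain centroid %.1f N vs loss centroid %.1f N (poleward shift %s)\n"
    ),
    name, s$R, s$G, s$L, s$CR, s$T,
    prof$centroids[["gain"]], prof$centroids[["loss"]],
    if (prof$centroids[["gain"]] > prof$centroids[["loss"]]) "yes" else "no"
  ))
  summary_rows[[name]] <- data.frame(
    scenario = name, CR = s$CR, retained = s$R, gain = s$G, loss = s$L,
    turnover = s$T,
    gain_centroid_lat = prof$centroids[["gain"]],
    loss_centroid_lat = prof$centroids[["loss"]]
  )
}
utils::write.csv(do.call(rbind, summary_rows), "results/range_change_summary.csv",
  row.names = FALSE
)
cat("range-change tables written under results/\n")
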