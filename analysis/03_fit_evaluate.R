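#!/usr/bin/env Rscript
# Stage 3 -- fit the maximum-entropy niche model and validate it.
#
# Deduplicates the presence records to grid cells, samples a
# habitat-restricted (target-group style) background, fits the full
# linear+quadratic+hinge model, evaluates ten independent 75/25
# cross-validation replicates, runs the 99-replicate null-model
# significance test, and reports jackknife variable importance. Writes
# the evaluation tables consumed by stage 4.

suppressPackageStartupMessages(library(nichecast))

master_seed <- 20260927L
dir.create("results", showWarnings = FALSE)

predictors <- local({
  files <- list.files("results/simdata", pattern = "\\.asc$", full.names = TRUE)
  files <- files[basename(files) != "mask.asc"]
  setNames(lapply(files, read_ascii_grid), sub("\\.asc$", "", basename(files)))
})
mask <- read_ascii_grid("results/simdata/mask.asc")
occ <- read_occurrences("results/simdata/occurrences.csv")
kept <- utils::read.csv("results/screening.csv")
vars <- kept$layer[kept$status == "kept"]
preds <- predictors[vars]
cat(sprintf("modelling with: %s\n", paste(vars, collapse = ", ")))

presences <- dedup_to_grid(occ, preds[[1]])
cat(sprintf(
  "%d records -> %d unique grid cells after deduplication\n",
  presences$n_raw, presences$n_unique
))
background <- sample_background(mask, preds,
  n = 2000,
  seed = derive_seed(master_seed, "background")
)
Xp <- extract_values(preds, presences$cells)
Xb <- extract_values(preds, background$cells)

# full model and the 10th-percentile training presence threshold
full <- fit_maxent(Xp, Xb)
thr <- threshold_10pct(predict_logistic(full, score_raw(full, Xp)))
write_maxent_model(full, "results/model_full.yaml")
cat(sprintf(
  "full model: training gain %.4f, entropy %.4f nats, threshold %.4f\n",
  full$training_gain, full$H, thr
))

# ten independent 75/25 cross-validation replicates
parts <- split_train_test(presences,
  train_fraction = 0.75, n_replicates = 10,
  seed = derive_seed(master_seed, "partitions")
)
ev <- evaluate_replicates(parts, function(train, test) {
  mdl <- fit_maxent(Xp[train, , drop = FALSE], Xb)
  sb <- score_raw(mdl, Xb)
  list(
    train_auc = auc(score_raw(mdl, Xp[train, , drop = FALSE]), sb),
    test_auc = auc(score_raw(mdl, Xp[test, , drop = FALSE]), sb)
  )
})
utils::write.csv(ev$replicates, "results/cv_auc.csv", row.names = FALSE)
cat(sprintf(
  "AUC over 10 replicates: training %.4f +/- %.4f, test %.4f +/- %.4f\n",
  ev$train_mean, ev$train_sd, ev$test_mean, ev$test_sd
))

# null-model significance test: 99 random pseudo-presence sets of the
# actual presence size, drawn from the water-habitat background pool
actual_auc <- auc(score_raw(full, Xp), score_raw(full, Xb))
nt <- null_model_test(
  actual_auc,
  n_presences = presences$n_unique,
  pool = background$cells,
  fit_and_score = function(cells) {
    Xn <- extract_values(preds, cells)
    mdl <- fit_maxent(Xn, Xb, max_iter = 200)
    auc(score_raw(mdl, Xn), score_raw(mdl, Xb))
  },
  n_null = 99, mode = "target-group",
  seed = derive_seed(master_seed, "null")
)
utils::write.csv(data.frame(null_auc = nt$null_aucs), "results/null_aucs.csv",
  row.names = FALSE
)
cat(sprintf(
  paste0(
    "null models: median %.4f, 95%% CI %.4f-%.4f; actual %.4f -> %s\n",
    "rank p = %.3f (min attainable 0.01); normal-tail p = %.2g\n"
  ),
  nt$median, nt$ci_lower, nt$ci_upper, actual_auc,
  if (nt$significant) "significant (above the CI upper limit)" else "NOT significant",
  nt$p_rank, nt$p_normal
))

# jackknife variable importance
vi <- variable_importance(Xp, Xb)
utils::write.csv(vi$table, "results/variable_importance.csv", row.names = FALSE)
cat("variable importance (percent contribution | gain in isolation):\n")
for (k in seq_len(nrow(vi$table))) {
  cat(sprintf(
    "  %-16s %5.1f%% | %.4f\n",
    vi$table$variable[k], vi$table$percent_contribution[k], vi$table$gain_only[k]
  ))
}
writeLines(format(thr, digits = 17), "results/threshold.txt")
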