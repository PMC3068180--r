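# Model evaluation: presence-background ROC/AUC, cross-validation replicate
# aggregation, the 10th-percentile training presence threshold, and the
# null-model randomisation test of model significance.

#' Presence-background AUC
#'
#' The Mann--Whitney form: the proportion of presence/background score
#' pairs in which the presence scores higher, counting ties as half.
#' Ranges from 0.5 (no better than random) to 1.0 (perfect
#' discrimination), and is invariant under any strictly increasing
#' transform of the scores.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.4), c(0.5, 0.1, 0.2)) # 5/6
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores)
  nb <- length(background_scores)
  if (np == 0L || nb == 0L) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  if (anyNA(presence_scores) || anyNA(background_scores)) {
    stop("scores contain missing values", call. = FALSE)
  }
  r <- rank(c(presence_scores, background_scores)) # average ranks on ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' 10th-percentile training presence threshold
#'
#' Returns the `floor(0.1 n) + 1`-th smallest training suitability, so at
#' most 10% of training presences fall strictly below it. Downstream
#' classification calls a cell suitable when its suitability is `>=` this
#' threshold.
#'
#' @param training_suitabilities Numeric vector, length at least 2.
#' @return The threshold value.
#' @export
#' @examples
#' threshold_10pct(seq(0.1, 1, by = 0.1)) # 0.2
threshold_10pct <- function(training_suitabilities) {
  n <- length(training_suitabilities)
  if (n < 2L) stop("need at least 2 training suitabilities", call. = FALSE)
  if (anyNA(training_suitabilities)) stop("suitabilities contain missing values", call. = FALSE)
  sort(training_suitabilities)[floor(0.1 * n) + 1L]
}

#' Aggregate AUCs over cross-validation replicates
#'
#' Runs a user closure once per partition and summarises the training and
#' test AUCs as mean and (n-1) standard deviation across replicates.
#'
#' @param partitions List of partitions from [split_train_test()].
#' @param fit_and_score Closure `function(train, test)` returning a list
#'   or named vector with `train_auc` and `test_auc` (and optionally other
#'   fields, carried through).
#' @return A list with `replicates` (data frame, one row each),
#'   `train_mean`, `train_sd`, `test_mean`, `test_sd`.
#' @export
evaluate_replicates <- function(partitions, fit_and_score) {
  rows <- lapply(seq_along(partitions), function(i) {
    p <- partitions[[i]]
    res <- fit_and_score(p$train, p$test)
    data.frame(replicate = i, train_auc = res$train_auc, test_auc = res$test_auc)
  })
  df <- do.call(rbind, rows)
  list(
    replicates = df,
    train_mean = mean(df$train_auc), train_sd = stats::sd(df$train_auc),
    test_mean = mean(df$test_auc), test_sd = stats::sd(df$test_auc)
  )
}

#' Null-model significance test
#'
#' Draws `n_null` random pseudo-presence sets of the actual presence size,
#' without replacement, from an eligible cell pool (all valid cells for
#' `"random-locality"` mode, habitat-mask cells for `"target-group"`
#' mode), refits the same modelling pipeline on each, and compares the
#' actual AUC with the null AUC distribution. The model is called
#' significant when the actual AUC exceeds the 95% CI upper limit (the
#' nearest-rank 97.5th percentile) of the nulls. Two p-values are
#' reported: the permutation-rank p `(1 + #{null >= actual})/(n_null + 1)`
#' and a normal-approximation tail p from the null mean and SD.
#'
#' @param actual_auc AUC of the model fitted to the real presences.
#' @param n_presences Number of pseudo-presences per null draw.
#' @param pool Integer matrix of eligible cells (columns `row`, `col`).
#' @param fit_and_score Closure `function(cells)` fitting the pipeline on
#'   a pseudo-presence cell matrix and returning its AUC.
#' @param n_null Number of null replicates (99 by convention).
#' @param mode Label recording how the pool was built
#'   (`"random-locality"` or `"target-group"`).
#' @param seed Integer seed.
#' @return A list with `null_aucs`, `median`, `ci_lower`, `ci_upper`
#'   (nearest-rank 2.5th/97.5th percentiles), `p_rank`, `p_normal`,
#'   `significant`, `mode`.
#' @export
null_model_test <- function(actual_auc, n_presences, pool, fit_and_score,
                            n_null = 99L,
                            mode = c("target-group", "random-locality"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(pool) < n_presences) {
    stop(sprintf(
      "null-model pool has %d cells but %d pseudo-presences are required",
      nrow(pool), n_presences
    ), call. = FALSE)
  }
  null_aucs <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      cells <- pool[sample.int(nrow(pool), n_presences, replace = FALSE), , drop = FALSE]
      as.numeric(fit_and_score(cells))
    }, numeric(1))
  })
  ci_upper <- pct_nearest(null_aucs, 97.5)
  list(
    null_aucs = null_aucs,
    median = stats::median(null_aucs),
    ci_lower = pct_nearest(null_aucs, 2.5),
    ci_upper = ci_upper,
    p_rank = (1 + sum(null_aucs >= actual_auc)) / (n_null + 1),
    p_normal = stats::pnorm(actual_auc,
      mean = mean(null_aucs),
      sd = stats::sd(null_aucs), lower.tail = FALSE
    ),
    significant = actual_auc > ci_upper,
    mode = mode
  )
}
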