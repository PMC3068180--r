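# Maximum-entropy presence-background niche model.
#
# The model is the Gibbs distribution over background cells
#     q_lambda(x) = exp(sum_j lambda_j f_j(x)) / Z(lambda),
# with Z summing over the background, fitted by minimising the convex
# L1-regularised negative presence log-likelihood
#     J(lambda) = -(1/|P|) sum_{x in P} log q_lambda(x) + sum_j beta_j |lambda_j|.
# Features f_j are the linear, quadratic and (forward/reverse) hinge
# transforms of each predictor, scaled into [0,1] from the training data.
# The optimiser is cyclic coordinate descent with soft-thresholding and an
# exact backtracking check, which reaches the convex optimum and yields a
# natural per-feature attribution of the objective decrease (used for
# percent-contribution bookkeeping).

#' Build the feature set
#'
#' Scaling bounds come from the union of presence and background values.
#' Hinge knots sit at `n_hinge_knots` equally spaced quantiles of the
#' background values (probabilities `1/(k+1), ..., k/(k+1)`), per direction
#' and variable. A constant predictor contributes only a (degenerate,
#' all-zero) linear feature, with a warning.
#'
#' @param pres,bg Numeric matrices of predictor values (same column names)
#'   at presence and background cells.
#' @param classes Subset of `c("linear", "quadratic", "hinge")`.
#' @param n_hinge_knots Hinge knots per direction per variable.
#' @return An object of class `"maxent_features"`: a data frame of feature
#'   definitions (`var`, `class`, `knot`, `lo`, `hi`).
#' @export
build_features <- function(pres, bg,
                           classes = c("linear", "quadratic", "hinge"),
                           n_hinge_knots = 20L) {
  stopifnot(
    is.matrix(pres), is.matrix(bg),
    identical(colnames(pres), colnames(bg)),
    ncol(bg) >= 1L
  )
  classes <- match.arg(classes, several.ok = TRUE)
  defs <- list()
  for (v in colnames(bg)) {
    x_all <- c(pres[, v], bg[, v])
    lo <- min(x_all)
    hi <- max(x_all)
    if (lo == hi) {
      warning(sprintf("predictor '%s' is constant; linear feature only", v),
        call. = FALSE
      )
      defs[[length(defs) + 1L]] <- data.frame(
        var = v, class = "linear", knot = NA_real_, lo = lo, hi = hi
      )
      next
    }
    if ("linear" %in% classes) {
      defs[[length(defs) + 1L]] <- data.frame(
        var = v, class = "linear", knot = NA_real_, lo = lo, hi = hi
      )
    }
    if ("quadratic" %in% classes) {
      defs[[length(defs) + 1L]] <- data.frame(
        var = v, class = "quadratic", knot = NA_real_, lo = lo, hi = hi
      )
    }
    if ("hinge" %in% classes && n_hinge_knots > 0L) {
      probs <- seq_len(n_hinge_knots) / (n_hinge_knots + 1)
      knots <- unique(as.numeric(stats::quantile(bg[, v], probs, names = FALSE)))
      fwd <- knots[knots < hi]
      rev_ <- knots[knots > lo]
      if (length(fwd)) {
        defs[[length(defs) + 1L]] <- data.frame(
          var = v, class = "hinge_fwd", knot = fwd, lo = lo, hi = hi
        )
      }
      if (length(rev_)) {
        defs[[length(defs) + 1L]] <- data.frame(
          var = v, class = "hinge_rev", knot = rev_, lo = lo, hi = hi
        )
      }
    }
  }
  out <- do.call(rbind, defs)
  rownames(out) <- NULL
  structure(out, class = c("maxent_features", "data.frame"))
}

#' Evaluate features at predictor values
#'
#' Inputs are clamped to the training bounds (so projections beyond the
#' training range behave like the nearest trained value), then mapped into
#' \[0, 1\]: linear `(x-lo)/(hi-lo)`, quadratic its square, forward hinge
#' `max(0, (x-t)/(hi-t))`, reverse hinge `max(0, (t-x)/(t-lo))`.
#'
#' @param features A [build_features()] object.
#' @param X Numeric matrix of predictor values (columns named as in
#'   training).
#' @param clamp Clamp inputs to the training bounds (disable only for
#'   diagnostics).
#' @return Numeric matrix, one column per feature, values in \[0, 1\].
#' @export
feature_values <- function(features, X, clamp = TRUE) {
  n <- nrow(X)
  out <- matrix(0, n, nrow(features))
  for (j in seq_len(nrow(features))) {
    f <- features[j, ]
    x <- X[, f$var]
    if (clamp) x <- pmin(pmax(x, f$lo), f$hi)
    rng <- f$hi - f$lo
    out[, j] <- switch(f$class,
      linear = if (rng > 0) (x - f$lo) / rng else 0,
      quadratic = if (rng > 0) ((x - f$lo) / rng)^2 else 0,
      hinge_fwd = pmax(0, (x - f$knot) / (f$hi - f$knot)),
      hinge_rev = pmax(0, (f$knot - x) / (f$knot - f$lo))
    )
  }
  colnames(out) <- feature_labels(features)
  out
}

feature_labels <- function(features) {
  ifelse(is.na(features$knot),
    paste(features$var, features$class, sep = "."),
    sprintf("%s.%s@%.6g", features$var, features$class, features$knot)
  )
}

# default per-class regularisation constants
reg_class_constant <- c(
  linear = 1.0, quadratic = 1.0, hinge_fwd = 0.5, hinge_rev = 0.5
)

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit the maximum-entropy model
#'
#' Minimises the convex objective `J(lambda)` above by cyclic coordinate
#' descent with soft-thresholding; every accepted step is verified against
#' the exact objective (halving the step if needed), so the objective is
#' monotonically non-increasing. Default regularisation weights are
#' `beta_multiplier * class_constant * s_j / sqrt(n_presences)` with `s_j`
#' the feature's standard deviation over presences (floored at 0.01) and
#' class constants 1.0 (linear, quadratic) / 0.5 (hinge); each automatic
#' weight is additionally floored just above the gap between the presence
#' feature mean and the background's attainable expectations, which is the
#' condition for the penalised objective to have a finite minimiser.
#'
#' @param pres,bg Numeric matrices of predictor values at presence and
#'   background cells (same columns), or `NULL` if `Fp`/`Fb` are given.
#' @param classes,n_hinge_knots Passed to [build_features()].
#' @param features Optional pre-built [build_features()] object.
#' @param beta_multiplier Scales the automatic regularisation weights.
#' @param beta Optional explicit regularisation weight(s), recycled across
#'   features; overrides the automatic rule (required if fewer than two
#'   presences).
#' @param tau Logistic prevalence parameter (probability at a "typical"
#'   presence site), default 0.5.
#' @param tol Stop when a full coordinate sweep decreases the objective by
#'   less than this.
#' @param max_iter Maximum number of sweeps.
#' @param add_samples_to_background Append the presence cells to the
#'   background defining the Gibbs distribution (the presence-background
#'   convention used by reference implementations). With the presences in
#'   the support, the penalised objective is bounded for any `beta >= 0`
#'   even when presences are separable from the background in feature
#'   space; disable only for controlled comparisons on a fixed background.
#' @return An object of class `"MaxEntModel"`: features, `lambda`, `logZ`,
#'   entropy `H`, `tau`, `beta`, the fitted objective `J`, per-feature and
#'   per-variable gain attribution, convergence info, and the background
#'   feature means needed for prediction.
#' @export
fit_maxent <- function(pres, bg,
                       classes = c("linear", "quadratic", "hinge"),
                       n_hinge_knots = 20L, features = NULL,
                       beta_multiplier = 1.0, beta = NULL, tau = 0.5,
                       tol = 1e-6, max_iter = 500L,
                       add_samples_to_background = TRUE) {
  if (is.null(features)) {
    features <- build_features(pres, bg, classes = classes, n_hinge_knots = n_hinge_knots)
  }
  Fp <- feature_values(features, pres)
  Fb <- feature_values(features, bg)
  if (add_samples_to_background) Fb <- rbind(Fb, Fp)
  np <- nrow(Fp)
  nb <- nrow(Fb)
  m <- ncol(Fb)
  if (np < 1L) stop("at least one presence cell is required", call. = FALSE)
  if (anyNA(Fp) || anyNA(Fb)) stop("feature values contain missing entries", call. = FALSE)

  fbar_p <- colMeans(Fp)
  if (is.null(beta)) {
    if (np < 2L) {
      stop("automatic regularisation needs >= 2 presences; supply `beta` explicitly",
        call. = FALSE
      )
    }
    s <- pmax(apply(Fp, 2L, stats::sd), 0.01)
    beta_vec <- beta_multiplier * reg_class_constant[features$class] * s / sqrt(np)
    # the objective has a finite minimiser only if beta_j exceeds the gap
    # between the presence mean and the background's attainable feature
    # expectations (can be positive when presences lie beyond the
    # background range of a hinge feature); floor just above that gap
    gap <- pmax(
      0,
      fbar_p - apply(Fb, 2L, max),
      apply(Fb, 2L, min) - fbar_p
    )
    beta_vec <- pmax(beta_vec, gap + 1e-3)
  } else {
    beta_vec <- rep_len(beta, m)
  }
  beta_vec <- as.numeric(beta_vec)
  lambda <- numeric(m)
  eta <- numeric(nb) # Fb %*% lambda
  logZ <- log(nb)
  mean_eta_p <- 0
  J <- -mean_eta_p + logZ # + 0 penalty
  gain_feat <- numeric(m)

  obj <- function(mean_eta_p, logZ, lambda) {
    -mean_eta_p + logZ + sum(beta_vec * abs(lambda))
  }

  converged <- FALSE
  iters <- 0L
  for (sweep in seq_len(max_iter)) {
    iters <- sweep
    J_start <- J
    for (j in seq_len(m)) {
      fj <- Fb[, j]
      w <- exp(eta - logZ)
      Eb <- sum(w * fj)
      Vb <- sum(w * fj^2) - Eb^2
      g <- Eb - fbar_p[j]
      h <- max(Vb, 1e-10)
      z <- lambda[j] - g / h
      lam_new <- sign(z) * max(abs(z) - beta_vec[j] / h, 0)
      d <- lam_new - lambda[j]
      if (d == 0) next
      # exact backtracking on the true objective
      accepted <- FALSE
      for (half in 0:25) {
        eta_try <- eta + d * fj
        logZ_try <- log_sum_exp(eta_try)
        mep_try <- mean_eta_p + d * fbar_p[j]
        lam_try <- lambda
        lam_try[j] <- lambda[j] + d
        J_try <- obj(mep_try, logZ_try, lam_try)
        if (J_try <= J + 1e-12) {
          gain_feat[j] <- gain_feat[j] + (J - J_try)
          eta <- eta_try
          logZ <- logZ_try
          mean_eta_p <- mep_try
          lambda <- lam_try
          J <- J_try
          accepted <- TRUE
          break
        }
        d <- d / 2
      }
    }
    if (J_start - J < tol) {
      converged <- TRUE
      break
    }
  }

  w <- exp(eta - logZ)
  if (!converged) {
    grad <- as.numeric(crossprod(Fb, w)) - fbar_p
    sub <- pmax(abs(grad) - beta_vec, 0) * (abs(lambda) < 1e-12) +
      abs(grad + beta_vec * sign(lambda)) * (abs(lambda) >= 1e-12)
    warning(sprintf(
      "coordinate descent stopped at max_iter = %d; max subgradient %.3g",
      max_iter, max(sub)
    ), call. = FALSE)
  }
  H <- -sum(w * (eta - logZ))

  gain_var <- tapply(gain_feat, features$var, sum)
  total <- sum(gain_feat)
  pct <- if (total > 0) 100 * gain_var / total else gain_var * 0

  structure(
    list(
      features = features, lambda = lambda, beta = beta_vec,
      logZ = logZ, H = H, tau = tau,
      n_presences = np, n_background = nb,
      objective = J,
      training_gain = log(nb) + (mean_eta_p - logZ),
      gain_by_feature = stats::setNames(gain_feat, feature_labels(features)),
      percent_contribution = pct,
      converged = converged, iterations = iters
    ),
    class = "MaxEntModel"
  )
}

#' @export
print.MaxEntModel <- function(x, ...) {
  cat(sprintf(
    "<MaxEntModel> %d features over %d variable(s); %d presences vs %d background\n",
    length(x$lambda), length(unique(x$features$var)), x$n_presences, x$n_background
  ))
  cat(sprintf(
    "  objective %.6f, training gain %.4f, entropy %.4f nats, %s in %d sweeps\n",
    x$objective, x$training_gain, x$H,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Raw suitability scores for a matrix of predictor values
#'
#' Evaluates `q_lambda` (normalised by the training `Z`) at arbitrary
#' predictor values — the matrix-level counterpart of [predict_raw()],
#' used for evaluating response curves and scoring presence/background
#' sets.
#'
#' @param model A fitted [fit_maxent()] model.
#' @param X Numeric matrix with the training variables as columns.
#' @param clamp Clamp features to training bounds.
#' @return Numeric vector of raw scores.
#' @export
score_raw <- function(model, X, clamp = TRUE) {
  Fx <- feature_values(model$features, X, clamp = clamp)
  as.numeric(exp(Fx %*% model$lambda - model$logZ))
}

#' Project raw (Gibbs) suitability over a predictor stack
#'
#' Computes `q_lambda` per cell using the training normaliser; with
#' `clamp = TRUE` (default) feature inputs beyond the training range are
#' clamped, the conservative convention for projecting into novel
#' (e.g. future) climates. Raw values sum to 1 over the training
#' background, not over the map.
#'
#' @param model A fitted [fit_maxent()] model.
#' @param predictors Named list of aligned `Raster`s covering the training
#'   variables.
#' @param clamp Clamp features to training bounds.
#' @return A `Raster` of raw suitability.
#' @export
predict_raw <- function(model, predictors, clamp = TRUE) {
  vars <- unique(model$features$var)
  miss <- setdiff(vars, names(predictors))
  if (length(miss)) {
    stop(sprintf("missing predictor layer(s): %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  ref <- stop_unless_aligned(predictors[vars], "prediction predictors")
  valid <- Reduce(`&`, lapply(predictors[vars], function(l) !is.na(l$values)))
  idx <- which(valid)
  X <- vapply(predictors[vars], function(l) l$values[idx], numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, 1L, dimnames = list(NULL, vars))
  colnames(X) <- vars
  out <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  out[idx] <- score_raw(model, X, clamp = clamp)
  raster_grid(out, ref$x_ll, ref$y_ll, ref$cell_size, ref$nodata)
}

#' Logistic suitability from raw output
#'
#' `p = c q / (1 + c q)` with `c = tau/(1-tau) * exp(H)`; for the uniform
#' fitted model this gives `tau` everywhere, and `p` is strictly increasing
#' in `q` with values in (0, 1).
#'
#' @param model A fitted [fit_maxent()] model.
#' @param raw A `Raster` from [predict_raw()] or a numeric vector of raw
#'   values.
#' @return Same shape as `raw`, logistic suitability in (0, 1).
#' @export
predict_logistic <- function(model, raw) {
  cc <- model$tau / (1 - model$tau) * exp(model$H)
  tr <- function(q) cc * q / (1 + cc * q)
  if (is_raster(raw)) {
    raster_grid(tr(raw$values), raw$x_ll, raw$y_ll, raw$cell_size, raw$nodata)
  } else {
    tr(raw)
  }
}

#' Jackknife variable importance
#'
#' For each variable: the training gain of the full model, of the model
#' with the variable excluded, and of the model using the variable in
#' isolation; test AUCs for the same three fits when test presences are
#' supplied; and the percent contribution (the variable's share of the
#' accumulated objective decrease during full-model training, normalised
#' to 100).
#'
#' @param pres,bg Training presence/background predictor matrices.
#' @param test_pres Optional test-presence predictor matrix for AUCs.
#' @param ... Passed to [fit_maxent()] (classes, knots, regularisation).
#' @return A list with `table` (one row per variable) and `full` (the full
#'   model).
#' @export
variable_importance <- function(pres, bg, test_pres = NULL, ...) {
  vars <- colnames(bg)
  full <- fit_maxent(pres, bg, ...)
  test_auc <- function(model, cols) {
    if (is.null(test_pres)) {
      return(NA_real_)
    }
    auc(
      score_raw(model, test_pres[, cols, drop = FALSE]),
      score_raw(model, bg[, cols, drop = FALSE])
    )
  }
  rows <- lapply(vars, function(v) {
    rest <- setdiff(vars, v)
    m_only <- fit_maxent(pres[, v, drop = FALSE], bg[, v, drop = FALSE], ...)
    if (length(rest)) {
      m_wo <- fit_maxent(pres[, rest, drop = FALSE], bg[, rest, drop = FALSE], ...)
      gain_wo <- m_wo$training_gain
      auc_wo <- test_auc(m_wo, rest)
    } else {
      gain_wo <- NA_real_
      auc_wo <- NA_real_
    }
    data.frame(
      variable = v,
      percent_contribution = as.numeric(full$percent_contribution[v]),
      gain_full = full$training_gain,
      gain_without = gain_wo,
      gain_only = m_only$training_gain,
      auc_full = test_auc(full, vars),
      auc_without = auc_wo,
      auc_only = test_auc(m_only, v)
    )
  })
  list(table = do.call(rbind, rows), full = full)
}

#' Serialise / restore a fitted model as plain text
#'
#' The YAML document carries the feature table, coefficients, normaliser,
#' entropy, tau and regularisation weights; [read_maxent_model()] restores
#' a model that scores bit-identically.
#'
#' @param model A fitted [fit_maxent()] model.
#' @param path Output path.
#' @return `path` (write) or a `MaxEntModel` (read).
#' @export
write_maxent_model <- function(model, path) {
  yaml::write_yaml(
    list(
      features = lapply(seq_len(nrow(model$features)), function(j) {
        as.list(model$features[j, c("var", "class", "knot", "lo", "hi")])
      }),
      lambda = model$lambda, beta = model$beta,
      logZ = model$logZ, H = model$H, tau = model$tau,
      n_presences = model$n_presences, n_background = model$n_background,
      objective = model$objective, training_gain = model$training_gain
    ),
    path, precision = 17L
  )
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  doc <- yaml::read_yaml(path)
  feats <- do.call(rbind, lapply(doc$features, function(f) {
    data.frame(
      var = f$var, class = f$class,
      knot = if (is.null(f$knot)) NA_real_ else as.numeric(f$knot),
      lo = as.numeric(f$lo), hi = as.numeric(f$hi)
    )
  }))
  structure(
    list(
      features = structure(feats, class = c("maxent_features", "data.frame")),
      lambda = as.numeric(doc$lambda), beta = as.numeric(doc$beta),
      logZ = doc$logZ, H = doc$H, tau = doc$tau,
      n_presences = doc$n_presences, n_background = doc$n_background,
      objective = doc$objective, training_gain = doc$training_gain,
      gain_by_feature = NULL, percent_contribution = NULL,
      converged = NA, iterations = NA_integer_
    ),
    class = "MaxEntModel"
  )
}
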