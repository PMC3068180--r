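# maximum-entropy core: feature construction, convex fit against oracles,
# prediction, logistic transform, jackknife importance

test_that("features are scaled into [0,1] with the documented edge values", {
  feats <- structure(
    data.frame(
      var = c("x", "x", "x", "x"),
      class = c("linear", "quadratic", "hinge_fwd", "hinge_rev"),
      knot = c(NA, NA, 2, 8), lo = 0, hi = 10
    ),
    class = c("maxent_features", "data.frame")
  )
  X <- matrix(c(0, 2, 5, 8, 10, 12), ncol = 1, dimnames = list(NULL, "x"))
  Fv <- feature_values(feats, X)
  expect_equal(Fv[1, ], c(x.linear = 0, x.quadratic = 0, `x.hinge_fwd@2` = 0, `x.hinge_rev@8` = 1))
  expect_equal(unname(Fv[5, 1:2]), c(1, 1)) # x = max
  expect_equal(unname(Fv[6, ]), unname(Fv[5, ])) # clamped beyond max
  # forward hinge with knot at the minimum reproduces the linear feature
  f0 <- feats[3, ]
  f0$knot <- 0
  expect_equal(
    feature_values(structure(f0, class = class(feats)), X)[, 1],
    Fv[, "x.linear"]
  )
  # hand check of interior hinge values
  expect_equal(unname(Fv[3, "x.hinge_fwd@2"]), (5 - 2) / (10 - 2))
  expect_equal(unname(Fv[3, "x.hinge_rev@8"]), (8 - 5) / (8 - 0))
})

test_that("all generated features lie in [0,1] and constants are degraded", {
  with_seed(55, {
    bg <- cbind(a = stats::rnorm(80), b = stats::rexp(80))
    pr <- cbind(a = stats::rnorm(15), b = stats::rexp(15))
  })
  fs <- build_features(pr, bg, n_hinge_knots = 10)
  Fv <- feature_values(fs, rbind(pr, bg))
  expect_true(all(Fv >= 0 & Fv <= 1))
  expect_true(all(c("linear", "quadratic", "hinge_fwd", "hinge_rev") %in% fs$class))

  con_bg <- cbind(a = rep(2, 30))
  con_pr <- cbind(a = rep(2, 5))
  expect_warning(fs2 <- build_features(con_pr, con_bg), "constant")
  expect_equal(nrow(fs2), 1)
})

test_that("matched presence and background means give the uniform model", {
  bg <- matrix(seq(0, 1, length = 11), ncol = 1, dimnames = list(NULL, "x"))
  pr <- matrix(rep(0.5, 4), ncol = 1, dimnames = list(NULL, "x"))
  m <- fit_maxent(pr, bg, classes = "linear", beta = 0.01)
  expect_equal(m$lambda, 0, tolerance = 1e-8)
  expect_equal(m$training_gain, 0, tolerance = 1e-8)
})

test_that("one-feature fit matches a dense grid search of the objective", {
  # 3 background cells with linear feature (0, 0.5, 1); presence at f = 1
  bg <- matrix(c(0, 0.5, 1), ncol = 1, dimnames = list(NULL, "x"))
  pr <- matrix(1, 1, 1, dimnames = list(NULL, "x"))
  m <- fit_maxent(pr, bg,
    classes = "linear", beta = 0.1,
    add_samples_to_background = FALSE
  )
  grid <- seq(-2, 15, by = 1e-4)
  J <- vapply(
    grid,
    function(l) -l + log(sum(exp(l * c(0, 0.5, 1)))) + 0.1 * abs(l),
    numeric(1)
  )
  expect_lt(abs(m$lambda - grid[which.min(J)]), 1e-4)
  expect_lt(abs(m$objective - min(J)), 1e-8)
})

test_that("fits reach the convex optimum found by a generic search", {
  # instances with <= 3 features and <= 50 background cells
  cases <- list(
    list(seed = 1, nb = 30, np = 6, classes = c("linear", "quadratic")),
    list(seed = 2, nb = 50, np = 10, classes = "linear"),
    list(seed = 3, nb = 40, np = 8, classes = c("linear", "quadratic"))
  )
  for (cs in cases) {
    with_seed(cs$seed, {
      bg <- cbind(x = stats::runif(cs$nb))
      pr <- cbind(x = stats::rbeta(cs$np, 4, 2))
    })
    m <- fit_maxent(pr, bg,
      classes = cs$classes, tol = 1e-10, max_iter = 2000,
      add_samples_to_background = FALSE
    )
    Fb <- feature_values(m$features, bg)
    Fp <- feature_values(m$features, pr)
    Jfun <- function(l) {
      -mean(Fp %*% l) + log(sum(exp(Fb %*% l))) + sum(m$beta * abs(l))
    }
    if (ncol(Fb) == 1L) {
      best <- min(vapply(
        seq(-30, 30, by = 1e-3),
        function(l) Jfun(l), numeric(1)
      ))
    } else {
      starts <- list(rep(0, ncol(Fb)), m$lambda, m$lambda + 0.5)
      best <- min(vapply(
        starts,
        function(s) {
          stats::optim(s, Jfun,
            method = "Nelder-Mead",
            control = list(reltol = 1e-14, maxit = 20000)
          )$value
        },
        numeric(1)
      ))
    }
    expect_lt(abs(m$objective - best), 1e-4)
  }
})

test_that("the fitted objective is below random perturbations (convexity spot check)", {
  toy <- fit_toy_model(n_hinge_knots = 4, tol = 1e-9)
  m <- toy$model
  # the fit appends the presences to the background support
  Fb <- feature_values(m$features, rbind(toy$bg, toy$pres))
  Fp <- feature_values(m$features, toy$pres)
  Jfun <- function(l) -mean(Fp %*% l) + log(sum(exp(Fb %*% l))) + sum(m$beta * abs(l))
  with_seed(70, {
    for (i in 1:100) {
      pert <- m$lambda + stats::rnorm(length(m$lambda), sd = 0.2)
      expect_gte(Jfun(pert), m$objective - 1e-9)
    }
  })
})

test_that("normalisation, entropy bound and non-negative gain hold", {
  toy <- fit_toy_model()
  m <- toy$model
  q <- score_raw(m, rbind(toy$bg, toy$pres)) # the training support
  expect_lt(abs(sum(q) - 1), 1e-10)
  expect_lte(m$H, log(m$n_background) + 1e-12)
  expect_gte(m$training_gain, 0)
})

test_that("raw prediction reuses the training normaliser and clamps", {
  toy <- fit_toy_model()
  m <- toy$model
  q_train <- score_raw(m, toy$bg)
  # raster carrying the background values in its first cells
  nb <- nrow(toy$bg)
  va <- matrix(NA_real_, 8, 8)
  vb <- matrix(NA_real_, 8, 8)
  va[seq_len(nb)] <- toy$bg[, "a"]
  vb[seq_len(nb)] <- toy$bg[, "b"]
  preds <- list(
    a = raster_grid(va, 0, 0, 1),
    b = raster_grid(vb, 0, 0, 1)
  )
  out <- predict_raw(m, preds)
  expect_equal(out$values[seq_len(nb)], q_train, tolerance = 1e-12)
  # clamped cell beyond the maximum behaves like the maximum-value cell
  imax <- which.max(toy$bg[, "a"])
  beyond <- matrix(c(toy$bg[imax, "a"] + 10, toy$bg[imax, "b"]),
    ncol = 2,
    dimnames = list(NULL, c("a", "b"))
  )
  atmax <- matrix(toy$bg[imax, ], ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(score_raw(m, beyond), score_raw(m, atmax))
})

test_that("logistic output is calibrated, monotone and inside (0,1)", {
  # uniform fitted model: q = 1/n over the 9 + 4 support cells,
  # H = log n -> p = tau = 0.5 everywhere
  bg <- matrix(seq(0, 1, length = 9), ncol = 1, dimnames = list(NULL, "x"))
  pr <- matrix(rep(0.5, 4), ncol = 1, dimnames = list(NULL, "x"))
  m <- fit_maxent(pr, bg, classes = "linear", beta = 0.05)
  expect_equal(m$lambda, 0, tolerance = 1e-8)
  expect_equal(predict_logistic(m, rep(1 / 13, 5)), rep(0.5, 5), tolerance = 1e-6)

  toy <- fit_toy_model()
  q <- sort(score_raw(toy$model, toy$bg))
  p <- predict_logistic(toy$model, q)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("jackknife importance behaves on single and duplicated variables", {
  toy <- fit_toy_model(n_hinge_knots = 4)
  # single variable: isolated gain equals full gain
  vi1 <- variable_importance(
    toy$pres[, "a", drop = FALSE], toy$bg[, "a", drop = FALSE],
    n_hinge_knots = 4
  )
  expect_equal(vi1$table$gain_only, vi1$table$gain_full)
  expect_true(is.na(vi1$table$gain_without))

  # duplicated variable: excluding one copy costs (almost) no gain
  pr2 <- cbind(toy$pres, a2 = toy$pres[, "a"])
  bg2 <- cbind(toy$bg, a2 = toy$bg[, "a"])
  vi2 <- variable_importance(pr2, bg2, n_hinge_knots = 4)
  row_a <- vi2$table[vi2$table$variable == "a", ]
  expect_lt(abs(row_a$gain_full - row_a$gain_without), 0.02)

  # percent contributions sum to 100
  expect_equal(sum(vi2$full$percent_contribution), 100, tolerance = 1e-6)
})

test_that("models serialise to text and reload with identical scores", {
  toy <- fit_toy_model(n_hinge_knots = 3)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_maxent_model(toy$model, p)
  m2 <- read_maxent_model(p)
  X <- with_seed(81, cbind(a = stats::runif(20), b = stats::runif(20)))
  expect_identical(score_raw(toy$model, X), score_raw(m2, X))
  expect_identical(predict_logistic(toy$model, 0.01), predict_logistic(m2, 0.01))
})

test_that("degenerate fits are rejected with instructive errors", {
  bg <- matrix(1:5 / 5, ncol = 1, dimnames = list(NULL, "x"))
  pr1 <- matrix(0.9, 1, 1, dimnames = list(NULL, "x"))
  expect_error(fit_maxent(pr1, bg, classes = "linear"), "beta")
  expect_silent(fit_maxent(pr1, bg, classes = "linear", beta = 0.1))
  expect_warning(
    fit_maxent(matrix(c(0.8, 1), 2, 1, dimnames = list(NULL, "x")), bg,
      classes = "linear", max_iter = 1L, tol = 0
    ),
    "max_iter"
  )
})
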