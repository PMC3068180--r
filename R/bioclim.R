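# Bioclimatic predictor derivation and collinearity screening.
#
# The four predictors used for modelling are the classic bioclim summaries:
#   T_max     max temperature of the warmest month (deg C)
#   T_min     min temperature of the coldest month (deg C)
#   Prec_dry  precipitation of the driest quarter (mm)
#   Prec_wet  precipitation of the wettest quarter (mm)
# Quarters are any 3 consecutive calendar months, with December-January
# wrap-around (the standard BIO16/BIO17 convention).

#' Bundle monthly climate layers
#'
#' @param tmin,tmax,prec Lists of 12 [raster_grid()] layers each, calendar
#'   order (deg C, deg C, mm). All 36 layers must share one grid geometry.
#' @return An object of class `"MonthlyClimate"`.
#' @export
monthly_climate <- function(tmin, tmax, prec) {
  for (nm in c("tmin", "tmax", "prec")) {
    stack <- get(nm)
    if (length(stack) != 12L || !all(vapply(stack, is_raster, logical(1)))) {
      stop(sprintf("`%s` must be a list of 12 Raster layers", nm), call. = FALSE)
    }
  }
  stop_unless_aligned(c(tmin, tmax, prec), "monthly climate layers")
  structure(list(tmin = tmin, tmax = tmax, prec = prec),
    class = "MonthlyClimate"
  )
}

#' Read a monthly climate stack from a directory
#'
#' Layers follow the filename pattern `{var}_{month}.asc` with zero-padded
#' months, e.g. `tmin_01.asc` ... `prec_12.asc`.
#'
#' @param dir Directory of ASCII grids.
#' @return A [monthly_climate()] object.
#' @export
read_monthly_climate <- function(dir) {
  rd <- function(var) {
    lapply(sprintf("%s/%s_%02d.asc", dir, var, 1:12), read_ascii_grid)
  }
  monthly_climate(rd("tmin"), rd("tmax"), rd("prec"))
}

#' Derive the four bioclimatic predictors
#'
#' Per cell: `T_max` is the across-month maximum of `tmax`; `T_min` the
#' minimum of `tmin`; `Prec_dry`/`Prec_wet` the minimum/maximum over the 12
#' wrapped 3-month windows of summed precipitation. A nodata value in any
#' contributing month propagates to the output cell.
#'
#' @param monthly A [monthly_climate()] object.
#' @return Named list of four `Raster` layers: `T_max`, `T_min`,
#'   `Prec_dry`, `Prec_wet`.
#' @export
#' @examples
#' # constant 30 mm per month gives a 90 mm quarter in every window
derive_bioclim <- function(monthly) {
  stopifnot(inherits(monthly, "MonthlyClimate"))
  ref <- monthly$tmin[[1L]]
  as_stack <- function(layers) {
    array(
      unlist(lapply(layers, function(l) l$values)),
      dim = c(ref$n_rows, ref$n_cols, 12L)
    )
  }
  tmin <- as_stack(monthly$tmin)
  tmax <- as_stack(monthly$tmax)
  prec <- as_stack(monthly$prec)

  red <- function(a, f) apply(a, c(1, 2), function(v) if (anyNA(v)) NA_real_ else f(v))
  t_max <- red(tmax, max)
  t_min <- red(tmin, min)

  # 12 wrapped quarterly sums, then min/max across windows
  qsum <- array(NA_real_, dim = c(ref$n_rows, ref$n_cols, 12L))
  for (m in 1:12) {
    idx <- ((m - 1L):(m + 1L) - 1L) %% 12L + 1L
    qsum[, , m] <- prec[, , idx[1L]] + prec[, , idx[2L]] + prec[, , idx[3L]]
  }
  p_dry <- red(qsum, min)
  p_wet <- red(qsum, max)

  mk <- function(m) raster_grid(m, ref$x_ll, ref$y_ll, ref$cell_size, ref$nodata)
  list(
    T_max = mk(t_max), T_min = mk(t_min),
    Prec_dry = mk(p_dry), Prec_wet = mk(p_wet)
  )
}

#' Screen predictors for collinearity
#'
#' Samples `n_points` cells that are valid in *all* layers (complete-case),
#' computes pairwise Pearson correlations on the sampled values, and for
#' every pair with `|r| >= threshold` drops the lower-priority member.
#' Priority is the order of `keep_priority` (earlier = kept in preference);
#' layers not listed rank after listed ones, in input order.
#'
#' @param layers Named list of aligned [raster_grid()] layers.
#' @param n_points Number of random cells sampled for the correlations.
#' @param threshold Absolute correlation at or above which a pair is
#'   flagged.
#' @param keep_priority Character vector of layer names, highest retention
#'   priority first.
#' @param seed Integer seed for the cell sample.
#' @return A list with `kept`, `dropped` (character vectors), `correlation`
#'   (symmetric matrix with unit diagonal) and `n_sampled`.
#' @export
screen_predictors <- function(layers, n_points = 1000L, threshold = 0.8,
                              keep_priority = names(layers), seed = 1L) {
  stopifnot(length(layers) >= 2L, !is.null(names(layers)))
  stop_unless_aligned(layers, "predictor layers")
  nm <- names(layers)
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  eligible <- which(valid)
  if (length(eligible) < 2L) stop("too few jointly valid cells to screen", call. = FALSE)
  n_take <- min(n_points, length(eligible))
  idx <- with_seed(seed, sample(eligible, n_take, replace = FALSE))
  X <- vapply(layers, function(l) l$values[idx], numeric(n_take))

  sds <- apply(X, 2L, stats::sd)
  degenerate <- nm[sds == 0 | is.na(sds)]
  if (length(degenerate)) {
    warning(sprintf(
      "layer(s) with zero variance at the sample excluded from flagging: %s",
      paste(degenerate, collapse = ", ")
    ), call. = FALSE)
  }
  cmat <- suppressWarnings(stats::cor(X, method = "pearson"))
  diag(cmat) <- 1

  prio <- match(nm, keep_priority)
  prio[is.na(prio)] <- length(keep_priority) + seq_along(nm)[is.na(prio)]
  names(prio) <- nm

  kept <- nm
  dropped <- character()
  usable <- setdiff(nm, degenerate)
  repeat {
    flagged <- NULL
    worst <- -Inf
    for (a in usable) {
      for (b in usable) {
        if (prio[a] < prio[b] && b %in% kept && a %in% kept &&
          !is.na(cmat[a, b]) && abs(cmat[a, b]) >= threshold) {
          # candidate to drop: the lower-priority member b
          if (prio[b] > worst) {
            worst <- prio[b]
            flagged <- b
          }
        }
      }
    }
    if (is.null(flagged)) break
    kept <- setdiff(kept, flagged)
    dropped <- c(dropped, flagged)
  }
  list(
    kept = kept, dropped = dropped,
    correlation = cmat, n_sampled = n_take
  )
}

#' Write a screening report as CSV
#'
#' @param screen Result of [screen_predictors()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(screen, path) {
  cm <- screen$correlation
  df <- data.frame(
    layer = rownames(cm),
    status = ifelse(rownames(cm) %in% screen$kept, "kept", "dropped"),
    as.data.frame(cm, check.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
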