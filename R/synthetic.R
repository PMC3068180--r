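# Synthetic study inputs: spatially autocorrelated climate surfaces, a
# habitat mask, a human-influence layer, presences sampled from a known
# bell-shaped suitability truth, and future-scenario perturbations.
#
# The generator emulates a northern-hemisphere domain: a strong latitudinal
# temperature gradient (cold poleward) so that warming moves the optimal
# band toward higher latitudes, plus a longitudinal moisture gradient so
# that temperature and dry-quarter precipitation are nearly independent.

# separable Gaussian-kernel smoothing of a matrix (reflective edges);
# scale = 0 returns the input (pure white noise)
smooth_field <- function(m, scale) {
  if (scale <= 0) {
    return(m)
  }
  half <- max(1L, as.integer(ceiling(3 * scale)))
  half <- min(half, min(dim(m)) - 1L) # kernel cannot exceed the grid
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  pad_smooth <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[(n - half + 1L):n]))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m <- apply(m, 2L, pad_smooth)
  t(apply(m, 1L, pad_smooth))
}

#' Generate a synthetic predictor landscape
#'
#' Builds the full predictor stack the downstream pipeline expects:
#' temperature layers with a strong latitudinal gradient plus smoothed
#' noise, non-negative precipitation layers with a longitudinal gradient,
#' a human-influence layer scaled to \[0, 100\], and a 0/1 habitat
#' ("water") mask with a configurable water fraction.
#'
#' @param n_rows,n_cols Grid size (each at least 10).
#' @param x_ll,y_ll,cell_size Grid registration, decimal degrees. Defaults
#'   span latitudes 0--70 N on a 0.7-degree lattice, so the coldest-month
#'   minimum covers a hemisphere-like range (about -34 to +22 deg C).
#' @param autocorr_scale Gaussian smoothing kernel width for the noise
#'   component, in cells; 0 gives white noise.
#' @param water_fraction Fraction of cells flagged as habitat.
#' @param noise_sd Standard deviation of the (smoothed) temperature noise,
#'   deg C.
#' @param seed Integer seed; the landscape is bit-reproducible from it.
#' @return A list with `predictors` (named list of `Raster`s: `T_min`,
#'   `T_max`, `Prec_dry`, `Prec_wet`, `human_influence`) and `mask` (0/1
#'   `Raster`).
#' @export
#' @examples
#' land <- generate_landscape(20, 20, seed = 1)
#' names(land$predictors)
generate_landscape <- function(n_rows = 100L, n_cols = 100L,
                               x_ll = -35, y_ll = 0, cell_size = 0.7,
                               autocorr_scale = 3, water_fraction = 0.35,
                               noise_sd = 1.5, seed = 1L) {
  stopifnot(n_rows >= 10L, n_cols >= 10L, water_fraction > 0, water_fraction <= 1)
  with_seed(seed, {
    mk <- function(m) raster_grid(m, x_ll, y_ll, cell_size)
    ref <- mk(matrix(0, n_rows, n_cols))
    lat <- lat_matrix(ref)
    lon <- matrix(cell_centers(ref)$lon, n_rows, n_cols, byrow = TRUE)

    rnoise <- function(sd) {
      raw <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
      sm <- smooth_field(raw, autocorr_scale)
      s <- stats::sd(as.vector(sm))
      if (s > 0) sm <- sm / s
      sm * sd
    }

    # coldest-month minimum: warm tropical plateau (~ +22 C) with a steep
    # mid-latitude decline to ~ -33 C at 70 N -- the sigmoidal profile of
    # hemispheric winter-minimum fields, which keeps intermediate
    # temperatures (the niche optimum) geographically rare
    t_min <- 22 - 56 * stats::plogis((lat - 45) / 8) + rnoise(noise_sd)
    t_max <- t_min + 10 + pmax(rnoise(1), 0) # warmest-month max, always above
    lon_rel <- (lon - min(lon)) / (max(lon) - min(lon))
    # dry-quarter precipitation is right-skewed over real land surfaces
    # (arid cells common, very wet dry-quarters rare): cubic ramp west to
    # east, roughly 0-1200 mm with most mass below 300 mm
    p_dry <- pmax(1200 * lon_rel^3 + rnoise(25) + 5, 0)
    p_wet <- p_dry + 150 + pmax(rnoise(40), 0)
    hf <- rnoise(1)
    hf <- 100 * (hf - min(hf)) / (max(hf) - min(hf))
    wfield <- rnoise(1)
    mask01 <- (wfield <= stats::quantile(wfield, water_fraction)) * 1

    list(
      predictors = list(
        T_min = mk(t_min), T_max = mk(t_max),
        Prec_dry = mk(p_dry), Prec_wet = mk(p_wet),
        human_influence = mk(hf)
      ),
      mask = mk(mask01)
    )
  })
}

#' Define a known suitability truth
#'
#' Response curves per predictor: `bell` curves are Gaussian in the
#' predictor (`exp(-(x - opt)^2 / (2 sd^2))`, in \[0, 1\] with a closed-form
#' optimum), `monotone` curves are logistic in the scaled predictor. The
#' combined suitability is the product of the curves times a prevalence
#' scaling.
#'
#' @param curves Named list, one element per predictor, each a list with
#'   `type = "bell"` (`opt`, `sd`) or `type = "monotone"` (`slope`,
#'   `center`).
#' @param prevalence Scaling of the product, in (0, 1].
#' @return An object of class `"TruthModel"`.
#' @export
#' @examples
#' truth_model(list(T_min = list(type = "bell", opt = 0, sd = 6)))
truth_model <- function(curves = list(
                          T_min = list(type = "bell", opt = 0, sd = 6),
                          Prec_dry = list(type = "bell", opt = 195, sd = 110),
                          human_influence = list(
                            type = "monotone", slope = 0.05, center = 40
                          )
                        ),
                        prevalence = 1) {
  stopifnot(prevalence > 0, prevalence <= 1, length(curves) >= 1L)
  for (cv in curves) {
    stopifnot(cv$type %in% c("bell", "monotone"))
  }
  structure(list(curves = curves, prevalence = prevalence),
    class = "TruthModel"
  )
}

response_curve <- function(curve, x) {
  if (curve$type == "bell") {
    exp(-(x - curve$opt)^2 / (2 * curve$sd^2))
  } else {
    stats::plogis(curve$slope * (x - curve$center))
  }
}

#' Evaluate the true suitability surface
#'
#' @param truth A [truth_model()].
#' @param predictors Named list of aligned `Raster`s covering every curve.
#' @return A `Raster` with values in \[0, 1\].
#' @export
true_suitability <- function(truth, predictors) {
  stopifnot(inherits(truth, "TruthModel"))
  need <- names(truth$curves)
  miss <- setdiff(need, names(predictors))
  if (length(miss)) {
    stop(sprintf("no predictor layer for curve(s): %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  ref <- predictors[[need[1L]]]
  out <- matrix(truth$prevalence, ref$n_rows, ref$n_cols)
  for (nm in need) {
    out <- out * response_curve(truth$curves[[nm]], predictors[[nm]]$values)
  }
  raster_grid(out, ref$x_ll, ref$y_ll, ref$cell_size, ref$nodata)
}

#' Sample presence records from a suitability surface
#'
#' Draws `n_target` cells (with replacement) with probability proportional
#' to suitability times an optional bias layer, restricted to habitat
#' cells, then places one point uniformly inside each drawn cell.
#'
#' @param suitability A `Raster` in \[0, 1\].
#' @param mask 0/1 habitat `Raster`.
#' @param n_target Number of records to produce.
#' @param bias Optional non-negative `Raster` (e.g. human influence) that
#'   multiplies the sampling weight, emulating survey bias.
#' @param seed Integer seed.
#' @return Data frame with `species`, `longitude`, `latitude`, `source`.
#' @export
sample_presences <- function(suitability, mask, n_target, bias = NULL,
                             seed = 1L) {
  stop_unless_aligned(
    c(list(suitability, mask), if (!is.null(bias)) list(bias)),
    "suitability, mask and bias"
  )
  w <- suitability$values
  if (any(w < -1e-12 | w > 1 + 1e-12, na.rm = TRUE)) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  w[is.na(w)] <- 0
  w[is.na(mask$values) | mask$values != 1] <- 0
  if (!is.null(bias)) w <- w * pmax(bias$values, 0)
  if (sum(w) <= 0) {
    stop("all-zero suitability on the habitat mask: nothing to sample", call. = FALSE)
  }
  s <- suitability$cell_size
  with_seed(seed, {
    idx <- sample.int(length(w), n_target, replace = TRUE, prob = as.vector(w))
    row <- ((idx - 1L) %% suitability$n_rows) + 1L
    col <- ((idx - 1L) %/% suitability$n_rows) + 1L
    lon <- suitability$x_ll + (col - 1L + stats::runif(n_target)) * s
    lat <- suitability$y_ll + (suitability$n_rows - row + stats::runif(n_target)) * s
    data.frame(
      species = "synthetic_species",
      longitude = lon, latitude = lat,
      source = "synthetic"
    )
  })
}

#' Future-climate scenario deltas
#'
#' A scenario perturbs the current layers: temperatures shift by `delta_t`
#' (optionally plus a north--south gradient), precipitation is multiplied
#' by `rho`; the habitat mask and human influence are held constant. Two
#' presets emulate a stronger and a milder emission pathway.
#'
#' @param delta_t Temperature offset, deg C.
#' @param rho Precipitation multiplier (> 0).
#' @param gradient Optional deg C per degree latitude added poleward of
#'   the domain mid-latitude (0 disables).
#' @param name Scenario label.
#' @return An object of class `"ScenarioDelta"`.
#' @export
#' @examples
#' scenario_delta(2, 0.85)
#' scenario_preset("strong")
scenario_delta <- function(delta_t, rho, gradient = 0, name = "scenario") {
  stopifnot(rho > 0)
  structure(
    list(delta_t = delta_t, rho = rho, gradient = gradient, name = name),
    class = "ScenarioDelta"
  )
}

#' @rdname scenario_delta
#' @param preset `"strong"` (delta_t = 2.0, rho = 0.85) or `"mild"`
#'   (delta_t = 1.2, rho = 0.95).
#' @export
scenario_preset <- function(preset = c("strong", "mild")) {
  preset <- match.arg(preset)
  switch(preset,
    strong = scenario_delta(2.0, 0.85, name = "strong"),
    mild = scenario_delta(1.2, 0.95, name = "mild")
  )
}

#' Apply a scenario to current predictor layers
#'
#' Layer names starting with `T` are treated as temperatures and shifted;
#' names starting with `Prec` as precipitation and scaled; everything else
#' (human influence, masks) passes through unchanged.
#'
#' @param current Named list of `Raster`s.
#' @param delta A [scenario_delta()].
#' @return Named list of `Raster`s with the same names and geometry.
#' @export
apply_scenario <- function(current, delta) {
  stopifnot(inherits(delta, "ScenarioDelta"))
  out <- current
  for (nm in names(current)) {
    r <- current[[nm]]
    if (grepl("^T", nm)) {
      shift <- delta$delta_t
      if (delta$gradient != 0) {
        lat <- lat_matrix(r)
        shift <- shift + delta$gradient * (lat - mean(cell_centers(r)$lat))
      }
      out[[nm]] <- raster_grid(r$values + shift, r$x_ll, r$y_ll, r$cell_size, r$nodata)
    } else if (grepl("^Prec", nm)) {
      out[[nm]] <- raster_grid(r$values * delta$rho, r$x_ll, r$y_ll, r$cell_size, r$nodata)
    }
  }
  out
}

#' Generate a synthetic monthly climate stack
#'
#' Monthly minimum/maximum temperatures follow the landscape's latitudinal
#' gradient plus a sinusoidal seasonal cycle; monthly precipitation keeps
#' the longitudinal gradient with a seasonal peak. Used to exercise the
#' bioclim derivation end to end.
#'
#' @inheritParams generate_landscape
#' @param seasonal_amp Seasonal half-amplitude of temperature, deg C.
#' @return A [monthly_climate()] object.
#' @export
generate_monthly_climate <- function(n_rows = 40L, n_cols = 40L,
                                     x_ll = -10, y_ll = 10, cell_size = 0.5,
                                     autocorr_scale = 2, seasonal_amp = 8,
                                     seed = 1L) {
  with_seed(seed, {
    mk <- function(m) raster_grid(m, x_ll, y_ll, cell_size)
    ref <- mk(matrix(0, n_rows, n_cols))
    lat <- lat_matrix(ref)
    lon <- matrix(cell_centers(ref)$lon, n_rows, n_cols, byrow = TRUE)
    lon_rel <- (lon - min(lon)) / (max(lon) - min(lon))
    annual_mean <- 26 - 0.55 * lat
    noise <- function(sd) {
      m <- smooth_field(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), autocorr_scale)
      s <- stats::sd(as.vector(m))
      if (s > 0) m <- m / s
      m * sd
    }
    tmin <- vector("list", 12L)
    tmax <- vector("list", 12L)
    prec <- vector("list", 12L)
    for (m in 1:12) {
      season <- -cos(2 * pi * (m - 1) / 12) # coldest in January
      tmid <- annual_mean + seasonal_amp * season + noise(0.8)
      tmin[[m]] <- mk(tmid - 4 - abs(noise(0.5)))
      tmax[[m]] <- mk(tmid + 4 + abs(noise(0.5)))
      prec[[m]] <- mk(pmax(120 * lon_rel * (1 + 0.6 * season) + noise(8) + 5, 0))
    }
    monthly_climate(tmin, tmax, prec)
  })
}

#' Write a synthetic input bundle to a directory
#'
#' Dumps the predictor grids, mask and occurrences of a generated study in
#' the package's on-disk formats (ASCII grids + occurrence CSV + a YAML
#' truth description), so a pipeline run can start from files.
#'
#' @param land Result of [generate_landscape()].
#' @param presences Data frame from [sample_presences()].
#' @param truth The [truth_model()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(land, presences, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(land$predictors)) {
    write_ascii_grid(land$predictors[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  write_ascii_grid(land$mask, file.path(dir, "mask.asc"))
  utils::write.csv(presences, file.path(dir, "occurrences.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(curves = truth$curves, prevalence = truth$prevalence),
    file.path(dir, "truth.yaml")
  )
  invisible(dir)
}
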