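# shared fixture builders; everything is generated in code at test time

# raster from a matrix given by rows (reads like the printed grid, north first)
grid_of <- function(rows, x_ll = 0, y_ll = 0, cell_size = 1, nodata = -9999) {
  raster_grid(
    matrix(unlist(rows), nrow = length(rows), byrow = TRUE),
    x_ll, y_ll, cell_size, nodata
  )
}

rand_grid <- function(n_rows, n_cols, seed, x_ll = 0, y_ll = 0, cell_size = 1,
                      na_frac = 0) {
  with_seed(seed, {
    v <- matrix(stats::runif(n_rows * n_cols), n_rows, n_cols)
    if (na_frac > 0) v[stats::runif(length(v)) < na_frac] <- NA
    raster_grid(v, x_ll, y_ll, cell_size)
  })
}

# monthly stacks from per-month constants (or matrices) on a shared grid
monthly_from <- function(tmin, tmax, prec, n_rows = 2, n_cols = 2) {
  lift <- function(x) {
    lapply(x, function(m) {
      if (length(m) == 1L) m <- matrix(m, n_rows, n_cols)
      raster_grid(m, 0, 0, 1)
    })
  }
  monthly_climate(lift(tmin), lift(tmax), lift(prec))
}

# small fitted-model fixture shared by maxent tests
fit_toy_model <- function(seed = 7, n_bg = 60, n_pres = 12, ...) {
  with_seed(seed, {
    bg <- cbind(a = stats::runif(n_bg), b = stats::runif(n_bg))
    pr <- cbind(a = stats::runif(n_pres, 0.5, 1), b = stats::runif(n_pres))
    list(pres = pr, bg = bg, model = fit_maxent(pr, bg, ...))
  })
}
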