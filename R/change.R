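# Range-change analysis: consensus projection, binary range maps,
# gain/loss/retained classification, the species-turnover statistic
# T = 100 (L + G) / (CR + G), latitudinal band profiles and regional
# summaries.

# change-map category codes (documented in the sidecar written by the pipeline)
CHANGE_CODES <- c(unsuitable = 0, retained = 1, gain = 2, loss = 3)

#' Equal-weight consensus of suitability maps
#'
#' Cell-wise weighted mean across maps (weights default to equal and are
#' normalised to sum to 1); a nodata cell in any input propagates.
#'
#' @param maps List of aligned suitability `Raster`s.
#' @param weights Optional numeric weights, one per map.
#' @return A `Raster`.
#' @export
consensus <- function(maps, weights = NULL) {
  stopifnot(length(maps) >= 1L)
  ref <- stop_unless_aligned(maps, "consensus maps")
  if (is.null(weights)) weights <- rep(1, length(maps))
  stopifnot(length(weights) == length(maps), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  acc <- maps[[1L]]$values * weights[1L]
  for (i in seq_along(maps)[-1L]) acc <- acc + maps[[i]]$values * weights[i]
  raster_grid(acc, ref$x_ll, ref$y_ll, ref$cell_size, ref$nodata)
}

#' Binary range map from a suitability threshold
#'
#' 1 where suitability `>=` threshold, 0 below, nodata propagated — the
#' "suitable at the 10th-percentile training presence threshold"
#' convention.
#'
#' @param suitability A `Raster`.
#' @param threshold Numeric cutoff.
#' @return A 0/1 `Raster`.
#' @export
binarize <- function(suitability, threshold) {
  v <- (suitability$values >= threshold) * 1
  raster_grid(
    v, suitability$x_ll, suitability$y_ll,
    suitability$cell_size, suitability$nodata
  )
}

#' Classify range change between two binary maps
#'
#' Per-cell truth table: current 1 / future 1 is retained, 1/0 loss, 0/1
#' gain, 0/0 unsuitable; codes 0--3 as in the package's change maps.
#' Excluded cells (e.g. a native range, where only invaded-range dynamics
#' are of interest) are set to nodata and removed from all counts. With
#' `dispersal = "none"` cells outside the current range cannot be gained.
#'
#' @param current,future Aligned 0/1 `Raster`s.
#' @param exclude Optional 0/1 `Raster`; cells with 1 are excluded.
#' @param dispersal `"full"` (default) or `"none"`.
#' @return A list with `map` (categorical `Raster`) and `summary` (class
#'   `"RangeChangeSummary"`: counts `CR`, `G`, `L`, `R`, turnover `T`).
#' @export
classify_change <- function(current, future, exclude = NULL,
                            dispersal = c("full", "none")) {
  dispersal <- match.arg(dispersal)
  layers <- c(list(current, future), if (!is.null(exclude)) list(exclude))
  ref <- stop_unless_aligned(layers, "change maps")
  cur <- current$values
  fut <- future$values
  if (dispersal == "none") fut <- fut * (cur == 1)
  cat_ <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  ok <- !is.na(cur) & !is.na(fut)
  if (!is.null(exclude)) ok <- ok & !(!is.na(exclude$values) & exclude$values == 1)
  cat_[ok & cur == 0 & fut == 0] <- CHANGE_CODES[["unsuitable"]]
  cat_[ok & cur == 1 & fut == 1] <- CHANGE_CODES[["retained"]]
  cat_[ok & cur == 0 & fut == 1] <- CHANGE_CODES[["gain"]]
  cat_[ok & cur == 1 & fut == 0] <- CHANGE_CODES[["loss"]]
  map <- raster_grid(cat_, ref$x_ll, ref$y_ll, ref$cell_size, ref$nodata)
  list(map = map, summary = change_summary_from_map(map))
}

change_summary_from_map <- function(map, region = "all") {
  v <- map$values
  R <- sum(v == CHANGE_CODES[["retained"]], na.rm = TRUE)
  G <- sum(v == CHANGE_CODES[["gain"]], na.rm = TRUE)
  L <- sum(v == CHANGE_CODES[["loss"]], na.rm = TRUE)
  summ <- structure(
    list(CR = R + L, G = G, L = L, R = R, T = NA_real_, region = region),
    class = "RangeChangeSummary"
  )
  summ$T <- turnover(summ)
  summ
}

#' Species turnover statistic
#'
#' `T = 100 (L + G) / (CR + G)` with `CR = R + L` the current range size:
#' 0 means the range is unchanged between time slices, 100 that the future
#' range shares no cell with the current one. Undefined (NA, with a
#' message) when `CR + G = 0`.
#'
#' @param summary A `RangeChangeSummary` from [classify_change()], or a
#'   list/vector with elements `CR`, `G`, `L`.
#' @return Turnover percentage in \[0, 100\], or `NA` when undefined.
#' @export
#' @examples
#' turnover(list(CR = 50, G = 0, L = 0)) # 0
#' turnover(list(CR = 30, G = 12, L = 30)) # 100
turnover <- function(summary) {
  CR <- summary[["CR"]]
  G <- summary[["G"]]
  L <- summary[["L"]]
  if (CR + G <= 0) {
    message("turnover undefined: no current or gained cells (CR + G = 0)")
    return(NA_real_)
  }
  100 * (L + G) / (CR + G)
}

#' @export
print.RangeChangeSummary <- function(x, ...) {
  cat(sprintf(
    "<RangeChangeSummary> %s: CR %d (retained %d, lost %d), gained %d, turnover %s\n",
    x$region, x$CR, x$R, x$L, x$G,
    if (is.na(x$T)) "n/a" else sprintf("%.1f%%", x$T)
  ))
  invisible(x)
}

#' Latitudinal profile of range change
#'
#' Counts cells of each change category per latitudinal band (half-open
#' bands `[b, b + width)` aligned to multiples of `band_width`, membership
#' by cell-centre latitude) and reports the mean centre latitude
#' (centroid) of the gain and loss cells.
#'
#' @param change_map Categorical `Raster` from [classify_change()].
#' @param band_width Band width in degrees.
#' @return A list with `bands` (data frame: `band`, `retained`, `gain`,
#'   `loss`, `unsuitable`) and `centroids` (named vector with `gain` and
#'   `loss` latitudes, `NA` when a category is empty).
#' @export
latitudinal_profile <- function(change_map, band_width = 1.0) {
  lat <- lat_matrix(change_map)
  v <- change_map$values
  ok <- !is.na(v)
  if (!any(ok)) {
    return(list(
      bands = data.frame(
        band = numeric(0), unsuitable = integer(0), retained = integer(0),
        gain = integer(0), loss = integer(0)
      ),
      centroids = c(gain = NA_real_, loss = NA_real_)
    ))
  }
  band <- floor(lat[ok] / band_width) * band_width
  cats <- v[ok]
  tab <- table(
    band = band,
    category = factor(cats,
      levels = CHANGE_CODES,
      labels = names(CHANGE_CODES)
    )
  )
  bands <- data.frame(
    band = as.numeric(rownames(tab)),
    unsuitable = as.integer(tab[, "unsuitable"]),
    retained = as.integer(tab[, "retained"]),
    gain = as.integer(tab[, "gain"]),
    loss = as.integer(tab[, "loss"])
  )
  bands <- bands[order(bands$band), , drop = FALSE]
  rownames(bands) <- NULL
  cen <- function(code) {
    sel <- ok & v == code
    if (!any(sel)) NA_real_ else mean(lat[sel])
  }
  list(
    bands = bands,
    centroids = c(
      gain = cen(CHANGE_CODES[["gain"]]),
      loss = cen(CHANGE_CODES[["loss"]])
    )
  )
}

#' Per-region range-change summaries
#'
#' Splits a change map by a labelled region mask and reports, per region,
#' the raw counts with turnover plus the percentage convention in which
#' retained/gain/loss are expressed as shares of the union `R + G + L`
#' (each region's three percentages sum to 100).
#'
#' @param change_map Categorical `Raster` from [classify_change()].
#' @param regions Aligned `Raster` of integer region labels (NA = outside
#'   all regions).
#' @param labels Optional named character vector mapping label values to
#'   region names.
#' @return A data frame, one row per region: counts, `turnover`,
#'   `retained_pct`, `gain_pct`, `loss_pct`.
#' @export
regional_summary <- function(change_map, regions, labels = NULL) {
  stop_unless_aligned(list(change_map, regions), "change map and regions")
  v <- change_map$values
  reg <- regions$values
  ids <- sort(unique(reg[!is.na(reg) & !is.na(v)]))
  rows <- lapply(ids, function(id) {
    sel <- !is.na(reg) & reg == id & !is.na(v)
    R <- sum(v[sel] == CHANGE_CODES[["retained"]])
    G <- sum(v[sel] == CHANGE_CODES[["gain"]])
    L <- sum(v[sel] == CHANGE_CODES[["loss"]])
    u <- R + G + L
    name <- if (!is.null(labels) && as.character(id) %in% names(labels)) {
      labels[[as.character(id)]]
    } else {
      as.character(id)
    }
    data.frame(
      region = name, CR = R + L, R = R, G = G, L = L,
      turnover = if (R + L + G > 0) 100 * (L + G) / (R + L + G) else NA_real_,
      retained_pct = if (u > 0) 100 * R / u else NA_real_,
      gain_pct = if (u > 0) 100 * G / u else NA_real_,
      loss_pct = if (u > 0) 100 * L / u else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Quick-look raster plot
#'
#' A minimal image plot of a layer on its geographic axes (base
#' graphics); intended for inspection, not cartography.
#'
#' @param raster A `Raster`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `raster`.
#' @export
plot_raster <- function(raster, main = "", ...) {
  cc <- cell_centers(raster)
  z <- t(raster$values[raster$n_rows:1, , drop = FALSE])
  graphics::image(
    x = cc$lon, y = rev(cc$lat), z = z,
    xlab = "longitude", ylab = "latitude", main = main, useRaster = TRUE, ...
  )
  invisible(raster)
}
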