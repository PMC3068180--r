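# Occurrence handling: one presence per grid cell, cross-validation
# partitions, and background (pseudo-absence) sampling from a habitat mask.

#' Deduplicate occurrences to grid cells
#'
#' Assigns each record to the grid cell containing it and keeps one
#' presence per occupied cell, mirroring the "remove duplicate presence
#' records" convention of presence-background modelling. Records outside
#' the template extent are dropped and counted.
#'
#' @param points Data frame with `longitude` and `latitude` columns.
#' @param template A [raster_grid()] supplying the reference geometry.
#' @return An object of class `"PresenceGrid"`: list with `cells` (integer
#'   matrix, columns `row`/`col`, one row per occupied cell), `n_raw`,
#'   `n_unique`, `n_outside` and the template geometry.
#' @export
#' @examples
#' r <- raster_grid(matrix(0, 20, 20), 0, 0, 1)
#' pts <- data.frame(longitude = c(1.1, 1.2, 5.5), latitude = c(2.1, 2.3, 9.9))
#' dedup_to_grid(pts, r)$n_unique
dedup_to_grid <- function(points, template) {
  if (is.null(points) || nrow(points) == 0L) {
    stop("empty occurrence set", call. = FALSE)
  }
  validate_occurrences(points)
  s <- template$cell_size
  inside <- points$longitude >= template$x_ll &
    points$longitude < template$x_ll + template$n_cols * s &
    points$latitude >= template$y_ll &
    points$latitude < template$y_ll + template$n_rows * s
  n_outside <- sum(!inside)
  pts <- points[inside, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no occurrences fall inside the template extent", call. = FALSE)
  rc <- cell_index(template, pts$longitude, pts$latitude)
  key <- (rc[, "row"] - 1L) * template$n_cols + rc[, "col"]
  keep <- !duplicated(key)
  cells <- rc[keep, , drop = FALSE]
  structure(
    list(
      cells = cells,
      n_raw = nrow(points), n_unique = nrow(cells), n_outside = n_outside,
      geometry = template[c("n_rows", "n_cols", "x_ll", "y_ll", "cell_size")]
    ),
    class = "PresenceGrid"
  )
}

#' @export
print.PresenceGrid <- function(x, ...) {
  cat(sprintf(
    "<PresenceGrid> %d raw records -> %d occupied cells (%d outside extent)\n",
    x$n_raw, x$n_unique, x$n_outside
  ))
  invisible(x)
}

#' Random train/test partitions of presence cells
#'
#' Produces `n_replicates` independent random splits with
#' `round(train_fraction * n)` training cells each (the 75/25 convention by
#' default), fully reproducible from `seed`. A `"kfold"` method is offered
#' as an alternative cross-validation structure.
#'
#' @param presences A [dedup_to_grid()] result, or an integer matrix of
#'   cells with columns `row`/`col`.
#' @param train_fraction Fraction of cells assigned to training, in (0, 1).
#' @param n_replicates Number of random splits (or folds for `"kfold"`).
#' @param seed Integer seed.
#' @param method `"random"` for independent splits, `"kfold"` for a single
#'   shuffled partition into `n_replicates` folds (each fold a test set).
#' @return A list of length `n_replicates`; each element has integer index
#'   vectors `train` and `test` (row indices into the presence cell
#'   matrix).
#' @export
split_train_test <- function(presences, train_fraction = 0.75,
                             n_replicates = 10L, seed = 1L,
                             method = c("random", "kfold")) {
  method <- match.arg(method)
  cells <- if (inherits(presences, "PresenceGrid")) presences$cells else presences
  n <- nrow(cells)
  if (n < 4L) stop("need at least 4 presence cells to split", call. = FALSE)
  if (method == "random" &&
    (train_fraction <= 0 || train_fraction >= 1)) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  with_seed(seed, {
    if (method == "random") {
      n_train <- round(train_fraction * n)
      lapply(seq_len(n_replicates), function(i) {
        tr <- sort(sample.int(n, n_train))
        list(train = tr, test = setdiff(seq_len(n), tr))
      })
    } else {
      fold <- sample(rep_len(seq_len(n_replicates), n))
      lapply(seq_len(n_replicates), function(k) {
        list(train = which(fold != k), test = which(fold == k))
      })
    }
  })
}

#' Sample background (pseudo-absence) cells
#'
#' Draws a uniform sample without replacement from the cells that are
#' habitat (`mask == 1`), valid (non-missing) in every predictor, and not
#' excluded. This is the "target-group" style background restricted to the
#' habitats the species could occupy.
#'
#' @param mask A 0/1 [raster_grid()] habitat mask.
#' @param predictors Named list of aligned predictor `Raster`s.
#' @param n Sample size (without replacement).
#' @param exclude Optional integer matrix of cells (`row`/`col`) to remove
#'   from the eligible pool, e.g. presence cells.
#' @param seed Integer seed.
#' @return An object of class `"BackgroundSample"`: list with `cells`
#'   (integer matrix `row`/`col`), `n` and `source_mask`.
#' @export
sample_background <- function(mask, predictors, n = 10000L, exclude = NULL,
                              seed = 1L, source_mask = "habitat") {
  stopifnot(is_raster(mask))
  stop_unless_aligned(c(list(mask), predictors), "mask and predictors")
  ok <- !is.na(mask$values) & mask$values == 1
  for (p in predictors) ok <- ok & !is.na(p$values)
  eligible <- which(ok)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    excl_lin <- (exclude[, "col"] - 1L) * mask$n_rows + exclude[, "row"]
    eligible <- setdiff(eligible, excl_lin)
  }
  if (length(eligible) < n) {
    stop(sprintf(
      "cannot sample %d background cells: only %d eligible (short by %d)",
      n, length(eligible), n - length(eligible)
    ), call. = FALSE)
  }
  idx <- with_seed(seed, sample(eligible, n, replace = FALSE))
  cells <- cbind(
    row = ((idx - 1L) %% mask$n_rows) + 1L,
    col = ((idx - 1L) %/% mask$n_rows) + 1L
  )
  structure(list(cells = cells, n = n, source_mask = source_mask),
    class = "BackgroundSample"
  )
}

#' Extract predictor values at cells
#'
#' @param predictors Named list of aligned [raster_grid()] layers.
#' @param cells Integer matrix with columns `row`, `col`.
#' @return Numeric matrix, one column per predictor.
#' @export
extract_values <- function(predictors, cells) {
  stopifnot(!is.null(names(predictors)))
  lin <- cbind(cells[, "row"], cells[, "col"])
  X <- vapply(
    predictors, function(p) p$values[lin],
    numeric(nrow(cells))
  )
  if (nrow(cells) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(predictors)))
  X
}

#' Dump partitions and background for audit
#'
#' Writes a CSV of `row,col,role,replicate` covering every partition and
#' the background sample.
#'
#' @param presences A `PresenceGrid`.
#' @param partitions Result of [split_train_test()].
#' @param background A `BackgroundSample` (optional).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(presences, partitions, background = NULL, path) {
  rows <- list()
  for (i in seq_along(partitions)) {
    p <- partitions[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      row = presences$cells[p$train, "row"], col = presences$cells[p$train, "col"],
      role = "train", replicate = i
    )
    rows[[length(rows) + 1L]] <- data.frame(
      row = presences$cells[p$test, "row"], col = presences$cells[p$test, "col"],
      role = "test", replicate = i
    )
  }
  if (!is.null(background)) {
    rows[[length(rows) + 1L]] <- data.frame(
      row = background$cells[, "row"], col = background$cells[, "col"],
      role = "background", replicate = NA_integer_
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
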