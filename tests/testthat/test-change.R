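# consensus projection, binary maps, gain/loss/retained classification,
# turnover, latitudinal profiles, regional summaries

test_that("consensus is an exact weighted mean with nodata propagation", {
  a <- grid_of(list(c(0, 0), c(0, 0)))
  b <- grid_of(list(c(1, 1), c(1, 1)))
  expect_equal(consensus(list(a, a))$values, a$values) # identical inputs
  expect_equal(consensus(list(a, b))$values, matrix(0.5, 2, 2))
  maps <- lapply(1:4, function(i) rand_grid(6, 6, seed = 100 + i))
  cons <- consensus(maps)
  direct <- (maps[[1]]$values + maps[[2]]$values + maps[[3]]$values + maps[[4]]$values) / 4
  expect_equal(cons$values, direct, tolerance = 1e-12)
  # weights normalise; nodata propagates
  wtd <- consensus(list(a, b), weights = c(3, 1))
  expect_equal(wtd$values[1, 1], 0.25)
  a_na <- a
  a_na$values[1, 1] <- NA
  expect_true(is.na(consensus(list(a_na, b))$values[1, 1]))
  expect_error(consensus(list(a, rand_grid(3, 3, seed = 1))), "geometry")
})

test_that("binarisation is >= threshold with nodata carried through", {
  r <- rand_grid(10, 10, seed = 15, na_frac = 0.1)
  expect_true(all(binarize(r, 0)$values[!is.na(r$values)] == 1))
  expect_true(all(binarize(r, max(r$values, na.rm = TRUE) + 0.01)$values == 0,
    na.rm = TRUE
  ))
  thr <- 0.5
  bin <- binarize(r, thr)
  oracle <- ifelse(r$values >= thr, 1, 0)
  expect_equal(bin$values, oracle)
  expect_equal(is.na(bin$values), is.na(r$values))
})

test_that("change classification follows the truth table and conserves cells", {
  cur <- grid_of(list(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(
    classify_change(cur, cur)$summary[c("CR", "G", "L", "R")],
    list(CR = 3L, G = 0L, L = 0L, R = 3L)
  )
  # disjoint ranges: everything current is lost
  fut <- grid_of(list(c(0, 0, 1), c(0, 1, 0), c(0, 0, 1)))
  s <- classify_change(cur, fut)$summary
  expect_equal(s$R, 0L)
  expect_equal(s$L, s$CR)
  expect_equal(s$T, 100)

  with_seed(16, {
    c30 <- raster_grid(matrix(stats::rbinom(900, 1, 0.4), 30, 30), 0, 0, 1)
    f30 <- raster_grid(matrix(stats::rbinom(900, 1, 0.4), 30, 30), 0, 0, 1)
  })
  res <- classify_change(c30, f30)
  tally <- c(
    R = sum(c30$values == 1 & f30$values == 1),
    G = sum(c30$values == 0 & f30$values == 1),
    L = sum(c30$values == 1 & f30$values == 0)
  )
  expect_equal(res$summary$R, unname(tally["R"]))
  expect_equal(res$summary$G, unname(tally["G"]))
  expect_equal(res$summary$L, unname(tally["L"]))
  v <- res$map$values
  expect_equal(sum(v == 0) + sum(v == 1) + sum(v == 2) + sum(v == 3), 900)
})

test_that("exclusion masks and the no-dispersal flag reshape the counts", {
  cur <- grid_of(list(c(1, 1), c(0, 0)))
  fut <- grid_of(list(c(1, 0), c(1, 1)))
  excl <- grid_of(list(c(1, 0), c(0, 0))) # drop the north-west cell
  s <- classify_change(cur, fut, exclude = excl)$summary
  expect_equal(list(s$R, s$L, s$G), list(0L, 1L, 2L))
  expect_true(is.na(classify_change(cur, fut, exclude = excl)$map$values[1, 1]))
  nd <- classify_change(cur, fut, dispersal = "none")$summary
  expect_equal(nd$G, 0L) # gains outside the current range are disallowed
})

test_that("turnover reproduces its boundary identities and printed-table checks", {
  expect_equal(turnover(list(CR = 50, G = 0, L = 0)), 0)
  expect_equal(turnover(list(CR = 30, G = 12, L = 30)), 100)
  # fractional-area summaries: retained 49.0 / gain 38.3 / loss 12.7 -> 51.0
  expect_equal(turnover(list(CR = 49.0 + 12.7, G = 38.3, L = 12.7)), 51.0)
  expect_message(out <- turnover(list(CR = 0, G = 0, L = 0)), "undefined")
  expect_true(is.na(out))
})

test_that("turnover is monotone in losses and gains", {
  base <- function(L, G, CR) turnover(list(CR = CR, G = G, L = L))
  expect_true(all(diff(sapply(0:10, base, G = 5, CR = 20)) > 0))
  t_g <- sapply(0:10, function(g) base(L = 5, G = g, CR = 20))
  expect_true(all(diff(t_g) > 0))
})

test_that("latitudinal profiles tally bands by cell-centre latitude", {
  # all gain cells in one row -> a single nonzero gain band at that latitude
  cur <- raster_grid(matrix(0, 4, 4), 0, 40, 1)
  futv <- matrix(0, 4, 4)
  futv[2, ] <- 1
  fut <- raster_grid(futv, 0, 40, 1)
  prof <- latitudinal_profile(classify_change(cur, fut)$map)
  nz <- prof$bands[prof$bands$gain > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$band, 42) # row 2 centre latitude 42.5 -> band [42, 43)
  expect_equal(nz$gain, 4)
  expect_equal(prof$centroids[["gain"]], 42.5)
  expect_true(is.na(prof$centroids[["loss"]]))

  with_seed(18, {
    c2 <- raster_grid(matrix(stats::rbinom(400, 1, 0.3), 20, 20), 0, 10, 0.5)
    f2 <- raster_grid(matrix(stats::rbinom(400, 1, 0.3), 20, 20), 0, 10, 0.5)
  })
  map <- classify_change(c2, f2)$map
  prof2 <- latitudinal_profile(map, band_width = 1)
  lat <- lat_matrix(map)
  for (k in seq_len(nrow(prof2$bands))) {
    b <- prof2$bands$band[k]
    sel <- lat >= b & lat < b + 1
    expect_equal(prof2$bands$gain[k], sum(map$values[sel] == 2))
    expect_equal(prof2$bands$loss[k], sum(map$values[sel] == 3))
  }
})

test_that("regional summaries split counts and their percentages sum to 100", {
  with_seed(19, {
    cur <- raster_grid(matrix(stats::rbinom(144, 1, 0.5), 12, 12), 0, 0, 1)
    fut <- raster_grid(matrix(stats::rbinom(144, 1, 0.5), 12, 12), 0, 0, 1)
  })
  map <- classify_change(cur, fut)$map
  one <- raster_grid(matrix(1, 12, 12), 0, 0, 1)
  rs1 <- regional_summary(map, one)
  s <- classify_change(cur, fut)$summary
  expect_equal(list(rs1$R, rs1$G, rs1$L), list(s$R, s$G, s$L))
  expect_equal(rs1$retained_pct + rs1$gain_pct + rs1$loss_pct, 100)

  # change confined to region 1 leaves region 2 all zero
  half <- matrix(1, 12, 12)
  half[, 7:12] <- 2
  cur2 <- cur
  fut2 <- fut
  cur2$values[, 7:12] <- 0
  fut2$values[, 7:12] <- 0
  rs2 <- regional_summary(
    classify_change(cur2, fut2)$map,
    raster_grid(half, 0, 0, 1),
    labels = c("1" = "west", "2" = "east")
  )
  east <- rs2[rs2$region == "east", ]
  expect_equal(east$CR + east$G + east$L, 0)
  west <- rs2[rs2$region == "west", ]
  expect_equal(west$retained_pct + west$gain_pct + west$loss_pct, 100)
})
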