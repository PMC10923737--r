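test_that("composite calendar reproduces the MODIS 8-day convention", {
  cal10 <- build_calendar("2012-01-01", "2022-01-01")
  expect_equal(nrow(cal10), 460)

  cal13 <- build_calendar("2013-01-01", "2014-01-01")
  expect_equal(nrow(cal13), 46)
  expect_equal(cal13$start[46], as.Date("2013-12-27"))
  expect_equal(cal13$end[46], as.Date("2014-01-01"))      # 5-day tail
  expect_equal(as.integer(cal13$end[46] - cal13$start[46]), 5L)

  cal12 <- build_calendar("2012-01-01", "2013-01-01")     # leap year
  expect_equal(as.integer(cal12$end[46] - cal12$start[46]), 6L)
  expect_true(all(as.integer(cal12$end[-46] - cal12$start[-46]) == 8L))

  expect_equal(nrow(build_calendar("2012-01-01", "2012-01-09")), 1)
  expect_error(build_calendar("2013-01-01", "2012-01-01"), "precede")
})

test_that("calendar periods tile each year without gaps or overlap", {
  cal <- build_calendar("2014-01-01", "2017-01-01")
  expect_identical(cal$start[-1], cal$end[-nrow(cal)])
  expect_true(all(vhicast:::doy_of(cal$start) %in% seq(1, 361, 8)))
})

test_that("compose_8day averages unmasked daily values per period", {
  # pixel with daily values 1..8 in one period -> mean 4.5
  v <- array(1:8, c(1, 1, 8))
  daily <- raster_cube(v, seq(as.Date("2013-01-01"), by = "day",
                              length.out = 8), "NDVI")
  cal <- build_calendar("2013-01-01", "2013-01-09")
  out <- compose_8day(daily, cal)
  expect_equal(as.numeric(out$values), 4.5)
  expect_equal(out$step, "composite_8day")
  expect_equal(out$dates, as.Date("2013-01-01"))

  # fully masked pixel-period propagates to a masked composite cell
  m <- array(FALSE, dim(v)); m[1, 1, ] <- TRUE
  masked <- raster_cube(v, daily$dates, "NDVI", mask = m)
  expect_true(compose_8day(masked, cal)$mask[1, 1, 1])

  # constant cube with scattered missingness still composites to the value
  cube <- random_cube(4, 4, 40, seed = 1, daily = TRUE, from = "2013-01-01")
  cube$values[] <- 7
  cube <- inject_missing(cube, 0.3, seed = 2)
  cal40 <- build_calendar("2013-01-01", "2013-02-10")
  out <- compose_8day(cube, cal40)
  expect_true(all(abs(out$values[!out$mask] - 7) < 1e-12))
})

test_that("compose_8day matches a brute-force per-period oracle exactly", {
  cube <- inject_missing(random_cube(5, 4, 60, seed = 8, daily = TRUE,
                                     from = "2013-01-01"), 0.2, seed = 9)
  cal <- build_calendar("2013-01-01", "2013-03-01")
  out <- compose_8day(cube, cal)
  for (p in seq_len(nrow(cal))) {
    sel <- which(cube$dates >= cal$start[p] & cube$dates < cal$end[p])
    for (r in 1:5) for (c in 1:4) {
      vals <- cube$values[r, c, sel]
      ok <- !cube$mask[r, c, sel]
      if (any(ok)) {
        # agreement up to summation order (vectorized vs serial sum)
        expect_equal(out$values[r, c, p], mean(vals[ok]), tolerance = 1e-12)
        expect_false(out$mask[r, c, p])
      } else {
        expect_true(out$mask[r, c, p])
      }
    }
  }
})

test_that("compose_8day commutes with constant shifts", {
  cube <- random_cube(3, 3, 20, seed = 10, daily = TRUE, from = "2013-01-01")
  cal <- build_calendar("2013-01-01", "2013-01-20")
  shifted <- cube; shifted$values <- cube$values + 2.5
  expect_equal(compose_8day(shifted, cal)$values,
               compose_8day(cube, cal)$values + 2.5)
})

test_that("gap filling follows the 1-D linear rule in both modes", {
  # temporal: series [1, missing, 3] -> [1, 2, 3]
  v <- array(c(1, NA, 3), c(1, 1, 3))
  cube <- raster_cube(v, seq(as.Date("2013-01-01"), by = "day",
                             length.out = 3), "NDVI")
  expect_equal(as.numeric(fill_gaps(cube, "temporal")$values), c(1, 2, 3))

  # spatial: row [4, missing, missing, 10] -> [4, 6, 8, 10]
  row <- array(c(4, NA, NA, 10), c(1, 4, 1))
  cube2 <- raster_cube(row, as.Date("2013-01-01"), "LST")
  expect_equal(as.numeric(fill_gaps(cube2, "spatial")$values),
               c(4, 6, 8, 10))

  # no masked cells -> bitwise identity
  clean <- random_cube(4, 4, 5, seed = 11)
  expect_identical(fill_gaps(clean, "spatial")$values, clean$values)
  expect_identical(fill_gaps(clean, "temporal")$values, clean$values)
})

test_that("gap filling preserves observations and brackets interior runs", {
  cube <- inject_missing(random_cube(6, 8, 12, seed = 12), 0.25, seed = 13)
  for (mode in c("spatial", "temporal")) {
    filled <- fill_gaps(cube, mode)
    expect_false(any(filled$mask))
    keep <- !cube$mask
    expect_identical(filled$values[keep], cube$values[keep])
    expect_true(all(filled$values >= min(cube$values[keep]) - 1e-12))
    expect_true(all(filled$values <= max(cube$values[keep]) + 1e-12))
  }
})

test_that("edge gaps extend the nearest neighbour", {
  v <- array(c(NA, NA, 5, 9, NA), c(1, 5, 1))
  cube <- raster_cube(v, as.Date("2013-01-01"), "LST")
  expect_equal(as.numeric(fill_gaps(cube, "spatial")$values),
               c(5, 5, 5, 9, 9))
})

test_that("fully masked rows fall back to column interpolation", {
  v <- matrix(runif(16), 4, 4)
  m <- matrix(FALSE, 4, 4); m[2, ] <- TRUE
  cube <- raster_cube(array(v, c(4, 4, 1)), as.Date("2013-01-01"), "NDVI",
                      mask = array(m, c(4, 4, 1)))
  filled <- fill_gaps(cube, "spatial")
  expect_equal(filled$values[2, 3, 1], (v[1, 3] + v[3, 3]) / 2)
})

test_that("entirely masked frames and series are validation errors", {
  v <- array(runif(8), c(2, 2, 2))
  m_all <- array(FALSE, dim(v)); m_all[, , 2] <- TRUE
  cube <- raster_cube(v, as.Date(c("2013-01-01", "2013-01-02")), "NDVI",
                      mask = m_all)
  expect_error(fill_gaps(cube, "spatial"), "frame 2")
  m_ser <- array(FALSE, dim(v)); m_ser[1, 2, ] <- TRUE
  cube2 <- raster_cube(v, cube$dates, "NDVI", mask = m_ser)
  expect_error(fill_gaps(cube2, "temporal"), "pixel \\(1, 2\\)")
})

test_that("smooth fields are recovered from 10% missingness", {
  cfg <- simulation_config(grid_size = c(12, 12),
                           start_date = "2013-01-01",
                           end_date = "2013-03-01", seed = 14)
  truth <- generate_daily_cubes(cfg)$ndvi
  holey <- inject_missing(truth, 0.1, seed = 15)
  filled <- fill_gaps(holey, "spatial")
  sel <- holey$mask
  err <- sqrt(mean((filled$values[sel] - truth$values[sel])^2))
  expect_lt(err, cfg$noise_sd + 0.05 * diff(range(truth$values)))
})
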