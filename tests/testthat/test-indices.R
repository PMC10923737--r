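test_that("compute_ndvi evaluates the band ratio and guards the domain", {
  expect_equal(compute_ndvi(red = 0.4, nir = 0.4), 0)
  expect_equal(compute_ndvi(red = 0, nir = 0.6), 1)
  expect_equal(compute_ndvi(red = 0.3, nir = 0.5), 0.25)
  expect_true(is.na(compute_ndvi(red = 0, nir = 0)))
  expect_error(compute_ndvi(matrix(0.1, 2, 2), matrix(0.1, 3, 3)), "shape")
  expect_error(compute_ndvi(-0.1, 0.5), "nonnegative")
})

test_that("normalization stats match brute-force enumeration in all scopes", {
  cube <- random_cube(4, 4, 5, seed = 21)

  si <- normalization_stats(cube, "image")
  expect_identical(si$minimum,
                   vapply(1:5, function(t) min(cube$values[, , t]),
                          numeric(1)))
  expect_identical(si$maximum,
                   vapply(1:5, function(t) max(cube$values[, , t]),
                          numeric(1)))

  sg <- normalization_stats(cube, "global")
  for (r in 1:4) for (c in 1:4) {
    expect_identical(sg$minimum[r, c], min(cube$values[r, c, ]))
    expect_identical(sg$maximum[r, c], max(cube$values[r, c, ]))
  }

  ss <- normalization_stats(cube, "global_scalar")
  expect_identical(ss$minimum, min(cube$values))
  expect_identical(ss$maximum, max(cube$values))

  const <- cube; const$values[] <- 7
  for (scope in c("image", "global", "global_scalar")) {
    s <- normalization_stats(const, scope)
    expect_true(all(s$minimum == 7) && all(s$maximum == 7))
  }

  # 2-frame 1-pixel cube [3, 9], global scope
  tiny <- make_composite_cube(array(c(3, 9), c(1, 1, 2)))
  st <- normalization_stats(tiny, "global")
  expect_equal(as.numeric(st$minimum), 3)
  expect_equal(as.numeric(st$maximum), 9)

  holey <- inject_missing(cube, 0.1, seed = 22)
  expect_error(normalization_stats(holey, "image"), "fill_gaps")
})

test_that("VCI anchors at the reference minimum and maximum", {
  v <- array(c(0.2, 0.8, 0.5, 0.35), c(1, 1, 4))
  ndvi <- make_composite_cube(v, "NDVI")
  vci <- compute_vci(ndvi, normalization_stats(ndvi, "global"))
  expect_equal(as.numeric(vci$values), c(0, 1, 0.5, 0.25))
  # degenerate range maps to the midpoint
  const <- make_composite_cube(array(0.4, c(2, 2, 3)), "NDVI")
  vc <- compute_vci(const, normalization_stats(const, "global"))
  expect_true(all(vc$values == 0.5))
})

test_that("TCI inverts the scaling so heat stress scores low", {
  v <- array(c(290, 310, 300), c(1, 1, 3))
  lst <- make_composite_cube(v, "LST")
  tci <- compute_tci(lst, normalization_stats(lst, "global"))
  expect_equal(as.numeric(tci$values), c(1, 0, 0.5))
})

test_that("VHI is the alpha-weighted blend of VCI and TCI", {
  vci <- make_composite_cube(array(0.6, c(2, 2, 2)), "VCI")
  tci <- make_composite_cube(array(0.4, c(2, 2, 2)), "TCI")
  expect_true(all(compute_vhi(vci, tci, 0.5)$values == 0.5))
  expect_identical(compute_vhi(vci, tci, 1)$values, vci$values)
  expect_identical(compute_vhi(vci, tci, 0)$values, tci$values)
  expect_error(compute_vhi(vci, tci, 1.2), "alpha")
  shifted <- make_composite_cube(array(0.4, c(2, 2, 2)), "TCI",
                                 from = "2014-01-01")
  expect_error(compute_vhi(vci, shifted), "misaligned")
})

test_that("VCI/TCI are monotone in their drivers under fixed stats", {
  cube <- random_cube(3, 3, 8, seed = 23)
  stats <- normalization_stats(cube, "global")
  x <- sort(runif(20, min(cube$values), max(cube$values)))
  pix <- function(v) {
    c2 <- cube; c2$values[2, 2, 1] <- v
    c2
  }
  vci_vals <- vapply(x, function(v)
    compute_vci(pix(v), stats)$values[2, 2, 1], numeric(1))
  tci_vals <- vapply(x, function(v)
    compute_tci(pix(v), stats)$values[2, 2, 1], numeric(1))
  expect_true(all(diff(vci_vals) >= 0))
  expect_true(all(diff(tci_vals) <= 0))
})

test_that("image-scope VCI attains 0 and 1 in every non-degenerate frame", {
  cube <- random_cube(5, 5, 6, seed = 24)
  vci <- compute_vci(cube, normalization_stats(cube, "image"))
  for (t in 1:6) {
    expect_equal(min(vci$values[, , t]), 0)
    expect_equal(max(vci$values[, , t]), 1)
  }
})

test_that("global-scope normalization is invertible", {
  cube <- random_cube(4, 4, 10, seed = 25)
  stats <- normalization_stats(cube, "global")
  vci <- compute_vci(cube, stats)
  rng <- stats$maximum - stats$minimum
  back <- array(as.vector(vci$values) *
                  as.vector(array(rng, dim(cube$values))) +
                  as.vector(array(stats$minimum, dim(cube$values))),
                dim(cube$values))
  expect_lt(max(abs(back - cube$values)), 1e-5)
})

test_that("frame-mean VHI varies more under global than image scope", {
  # image scope re-anchors each frame to [0, 1], absorbing range variation
  bench <- simulation_config(grid_size = c(8, 8), start_date = "2013-01-01",
                             end_date = "2016-01-01", seed = 26)
  cubes <- generate_daily_cubes(bench)
  cal <- build_calendar(bench$start_date, bench$end_date)
  nd8 <- fill_gaps(compose_8day(cubes$ndvi, cal))
  ls8 <- fill_gaps(compose_8day(cubes$lst, cal))
  vhi_of <- function(scope)
    compute_vhi(compute_vci(nd8, normalization_stats(nd8, scope)),
                compute_tci(ls8, normalization_stats(ls8, scope)), 0.5)
  fm <- function(v) apply(v$values, 3, mean)
  expect_gt(var(fm(vhi_of("global"))), var(fm(vhi_of("image"))))
})

test_that("drought classes follow the standard VHI thresholds", {
  expect_equal(as.character(classify_drought(0.75)), "none")
  expect_equal(as.character(classify_drought(0.40)), "mild")
  expect_equal(as.character(classify_drought(0.50)), "mild")   # boundary
  expect_equal(as.character(classify_drought(0.30)), "moderate")
  expect_equal(as.character(classify_drought(0.15)), "severe")
  expect_equal(as.character(classify_drought(0.05)), "extreme")
  expect_equal(as.character(classify_drought(0.10)), "extreme") # boundary
  expect_error(classify_drought(1.2), "\\[0, 1\\]")
  expect_error(classify_drought(-0.1), "\\[0, 1\\]")
})
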