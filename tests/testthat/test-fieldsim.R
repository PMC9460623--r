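test_that("layout geometry matches the applicator descriptions", {
  lin <- make_layout("linear")
  expect_equal(lin$n_antennas, 12)
  expect_equal(lin$n_channels, 4)
  # two rows of six, adjacent same-side spacing 20 mm
  top <- lin$positions[1:6, ]
  bot <- lin$positions[7:12, ]
  expect_true(all(top[, "y"] == top[1, "y"]))
  expect_true(all(bot[, "y"] == -top[1, "y"]))
  expect_equal(unname(diff(top[, "x"])), rep(20, 5))
  # channels group antennas in threes; antenna 5 -> channel 2
  expect_equal(lin$channel_of_antenna, rep(1:4, each = 3))
  expect_equal(lin$channel_of_antenna[5], 2)

  circ <- make_layout("circular")
  expect_equal(circ$n_channels, 12)
  ang <- atan2(circ$positions[, "y"], circ$positions[, "x"]) * 180 / pi
  expect_equal(diff(ang[1:7]), rep(30, 6), tolerance = 1e-12)
  radii <- sqrt(rowSums(circ$positions^2))
  expect_equal(radii, rep(radii[1], 12), tolerance = 1e-12)
})

test_that("antennas inside the breast are rejected", {
  ph <- generate_phantom(1, semi_axes_mm = c(44, 35))
  lay <- make_layout("linear")
  expect_error(simulate_unit_fields(ph, lay), "inside the breast")
})

test_that("single-antenna field decays as 1/sqrt(d) in lossless medium", {
  ph <- manual_phantom(11, 31, eps_r = 1, sigma = 0)
  lay <- single_antenna_layout(ph$grid, x = -20, y = 0)
  fs <- simulate_unit_fields(ph, lay)
  # pixels along the +x ray from the antenna (centre row, y = 0)
  co <- pixel_coords(ph$grid)
  row <- which(co$y == 0)
  mag <- sqrt(colSums(abs(fs$fields[[1]][, row, ])^2))
  d <- co$x + 20
  keep <- d >= 2
  expect_equal(mag[keep] * sqrt(d[keep]),
               rep((mag * sqrt(d))[keep][1], sum(keep)),
               tolerance = 1e-10)
})

test_that("two on-ray pixels obey the closed-form wave expression", {
  eps <- 30; sig <- 1.4
  ph <- manual_phantom(11, 31, eps_r = eps, sigma = sig)
  lay <- single_antenna_layout(ph$grid, x = -20, y = 0)
  fs <- simulate_unit_fields(ph, lay)
  co <- pixel_coords(ph$grid)
  row <- which(co$y == 0)
  i1 <- which(co$x == -10); i2 <- which(co$x == 5)
  d1 <- (co$x[i1] + 20) * 1e-3; d2 <- (co$x[i2] + 20) * 1e-3
  s1 <- fs$fields[[1]][2, row, i1]   # transverse component is +y here
  s2 <- fs$fields[[1]][2, row, i2]
  k <- medium_wavenumber(eps, sig)
  expected_ratio <- sqrt(d1 / d2) * exp(-1i * k * (d2 - d1))
  expect_equal(s2 / s1, expected_ratio, tolerance = 1e-9)
  # e^{+jwt} convention: decay beyond the geometric factor
  expect_lt(Im(k), 0)
  expect_lt(abs(s2 / s1), sqrt(d1 / d2))
  # phase difference accumulates as Re(k) * (d2 - d1)
  expect_equal(Arg(s1 / s2) %% (2 * pi), (Re(k) * (d2 - d1)) %% (2 * pi),
               tolerance = 1e-6)
})

test_that("a channel's field is the sum of its member antennas' fields", {
  ph <- generate_phantom(1)
  lin <- make_layout("linear")
  fs <- simulate_unit_fields(ph, lin)
  singles <- single_antenna_layout(ph$grid, lin$positions[1:3, "x"],
                                   lin$positions[1:3, "y"])
  fss <- simulate_unit_fields(ph, singles)
  expect_equal(fs$fields[[1]],
               fss$fields[[1]] + fss$fields[[2]] + fss$fields[[3]],
               tolerance = 1e-12)
})

test_that("symmetric layouts give mirror-symmetric field magnitudes", {
  ph <- manual_phantom(31, 31, eps_r = 20, sigma = 1.2)
  lay <- single_antenna_layout(ph$grid, x = c(14, -14), y = c(0, 0))
  fs <- simulate_unit_fields(ph, lay)
  m1 <- sqrt(apply(abs(fs$fields[[1]])^2, c(2, 3), sum))
  m2 <- sqrt(apply(abs(fs$fields[[2]])^2, c(2, 3), sum))
  expect_equal(m1, m2[, ncol(m2):1], tolerance = 1e-6)
})

test_that("field-set container round-trips bit-identically", {
  ph <- generate_phantom(1)
  fs <- simulate_unit_fields(ph, make_layout("linear"))
  path <- tempfile(fileext = ".json")
  write_fieldset(fs, path)
  back <- read_fieldset(path)
  expect_identical(back$fields, fs$fields)
  expect_equal(back$grid, fs$grid)
  expect_identical(back$scheme, fs$scheme)
  expect_identical(back$frequency, fs$frequency)
  expect_equal(back$layout$positions, fs$layout$positions,
               ignore_attr = TRUE)
  unlink(path)
})

test_that("channel-count mismatch in a container is a format error", {
  fs <- toy_fieldset(1, n_channels = 3)
  path <- tempfile(fileext = ".json")
  write_fieldset(fs, path)
  txt <- readLines(path)
  writeLines(gsub("\"n_channels\":3", "\"n_channels\":4", txt), path)
  expect_error(read_fieldset(path), "missing dataset")
  unlink(path)
})

test_that("a hand-written container loads to exactly its values", {
  # 8 x 8 grid, one channel, one component; four distinctive pixels
  path <- tempfile(fileext = ".json")
  re <- rep(0, 64); im <- rep(0, 64)
  re[1] <- 1.5; im[1] <- -2.25       # (row 1, col 1)
  re[10] <- -0.125                    # (row 2, col 2)
  im[64] <- 3.75
  writeLines(paste0(
    '{"container":"mhfocus_fieldset","version":1,"attrs":{',
    '"frequency_hz":2.45e9,"port_resistance_ohm":50,"pixel_mm":1,',
    '"n_rows":8,"n_cols":8,"scheme":"custom","n_channels":1,',
    '"n_components":1},"datasets":{"field_000":{"dim":[1,8,8],',
    '"storage":"complex","re":[', paste(re, collapse = ","),
    '],"im":[', paste(im, collapse = ","), ']}}}'), path)
  fs <- read_fieldset(path)
  expect_equal(fs$n_channels, 1)
  expect_identical(fs$fields[[1]][1, 1, 1], 1.5 - 2.25i)
  expect_identical(fs$fields[[1]][1, 2, 2], -0.125 + 0i)
  expect_identical(fs$fields[[1]][1, 8, 8], 0 + 3.75i)
  expect_identical(fs$fields[[1]][1, 3, 5], 0 + 0i)
  unlink(path)
})
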