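test_that("phase wrapping lands in (-180, 180]", {
  expect_equal(wrap_phase(0), 0)
  expect_equal(wrap_phase(-226.56), 133.44)
  expect_equal(wrap_phase(540), 180)
  expect_equal(wrap_phase(-180), 180)
  expect_equal(wrap_phase(180), 180)
  expect_equal(wrap_phase(c(359, -359, 720.5)), c(-1, 1, 0.5))
  expect_error(wrap_phase(Inf), "finite")
})

test_that("scheme constraints reproduce the printed phase rows", {
  expect_equal(linear_phase_vector(-48.46, -178.10),
               c(0, -48.46, -178.10, 133.44))
  expect_equal(linear_phase_vector(-100.00, 138.00),
               c(0, -100, 138, 38))
  expect_equal(linear_phase_vector(0, 0), c(0, 0, 0, 0))

  full <- circular_phase_vector(c(0, 0, -74.84, 34.11, 0, 0))
  expect_equal(full[7], -40.73)
  full <- circular_phase_vector(c(-31.33, 169.86, 0, 0, 0, 0))
  expect_equal(full[3], 138.53)
  expect_equal(circular_phase_vector(rep(0, 6)), rep(0, 12))
})

test_that("every printed phase row closes under its scheme constraint", {
  for (row in linear_phase_rows()) {
    tol <- sum(printed_tol(row[2:4]))
    expect_lt(abs(wrap_phase(row[4] - row[2] - row[3])), tol)
    expect_silent(excitation("linear", rep(1, 4), phases = row, tol = tol))
  }
  for (row in circular_phase_rows()) {
    for (k in c(3, 5, 7, 9, 11)) {
      tol <- sum(printed_tol(row[c(k - 1, k, k + 1)]))
      expect_lt(abs(wrap_phase(row[k] - row[k - 1] - row[k + 1])), tol)
    }
    expect_silent(excitation("circular", rep(1, 12), phases = row,
                             tol = 0.3))
  }
  expect_error(excitation("linear", rep(1, 4), phases = c(0, 10, 20, 90)),
               "constraint")
})

test_that("superposition matches hand computation and is linear", {
  fs <- toy_fieldset(3, n_channels = 2)
  e <- list(voltages = c(1, 2), phases = c(0, 90))
  got <- superpose(fs, e)
  expect_equal(got, fs$fields[[1]] + 2i * fs$fields[[2]],
               tolerance = 1e-12)

  # unit vector picks out one field; zero drive gives the zero field
  expect_equal(superpose(fs, list(voltages = c(1, 0), phases = c(0, 0))),
               fs$fields[[1]])
  expect_true(all(superpose(fs, list(voltages = c(0, 0),
                                     phases = c(0, 0))) == 0))

  # coefficient-wise additivity against a per-pixel oracle
  for (seed in 1:5) {
    set.seed(seed)
    v1 <- runif(2); p1 <- runif(2, -180, 180)
    v2 <- runif(2); p2 <- runif(2, -180, 180)
    c1 <- v1 * exp(1i * p1 * pi / 180)
    c2 <- v2 * exp(1i * p2 * pi / 180)
    cs <- c1 + c2
    lhs <- superpose(fs, list(voltages = Mod(cs),
                              phases = Arg(cs) * 180 / pi))
    rhs <- superpose(fs, list(voltages = v1, phases = p1)) +
      superpose(fs, list(voltages = v2, phases = p2))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  expect_error(superpose(fs, list(voltages = 1, phases = 0)), "channels")
})

test_that("heating potential implements 0.5 sigma |E|^2 componentwise", {
  ph <- manual_phantom(8, 8, sigma = 2.0)
  E <- array(0 + 0i, c(1, 8, 8)); E[1, 3, 4] <- 1 + 0i
  hp <- heating_potential(E, ph)
  expect_equal(hp$q0[3, 4], 1.0)

  ph2 <- manual_phantom(8, 8, sigma = 1.44)
  E2 <- array(0 + 0i, c(2, 8, 8)); E2[1, 2, 2] <- 3 + 4i
  expect_equal(heating_potential(E2, ph2)$q0[2, 2], 18.0)

  ph0 <- manual_phantom(8, 8, sigma = 0)
  E3 <- array(complex(real = rnorm(128), imaginary = rnorm(128)),
              c(2, 8, 8))
  expect_true(all(heating_potential(E3, ph0)$q0 == 0))
})

test_that("port power follows P = V^2 / R", {
  expect_equal(port_power(1), 0.02)
  expect_equal(port_power(0), 0)
  expect_equal(port_power(5), 0.5)
  expect_error(port_power(-1), ">= 0")
})

test_that("total-power scaling hits the 6 W budget over 12 antennas", {
  # linear channels all at 1 V: 12 antennas x 0.02 W = 0.24 W, factor 5
  exc <- excitation("linear", rep(1, 4), phases = c(0, 10, 20, 30))
  scaled <- scale_to_total_power(exc, 6)
  expect_equal(scaled$voltages, rep(5, 4))
  expect_equal(sum(3 * port_power(scaled$voltages)), 6)
  expect_equal(scaled$phases, exc$phases)

  # an already-6 W excitation is unchanged
  again <- scale_to_total_power(scaled, 6)
  expect_equal(again$voltages, scaled$voltages)

  set.seed(4)
  for (i in 1:5) {
    e <- excitation("circular", runif(12, 0.1, 9),
                    free_phases = runif(6, -180, 180))
    s <- scale_to_total_power(e, 6)
    expect_equal(sum(port_power(s$voltages)), 6, tolerance = 1e-12)
  }
  expect_error(scale_to_total_power(
    excitation("linear", rep(0, 4), phases = rep(0, 4))), "zero")
})

test_that("min-max normalization and its failure mode", {
  m <- matrix(c(1, 2, 3, 5), 2)
  expect_equal(normalize_hp(m), matrix(c(0, 0.25, 0.5, 1), 2))
  m2 <- matrix(c(0, 10, 2.5, 5), 2)
  expect_equal(normalize_hp(m2), m2 / 10)
  expect_equal(normalize_hp(normalize_hp(m)), normalize_hp(m))
  expect_error(normalize_hp(matrix(3, 4, 4)), "constant")
})

test_that("heating potential is invariant under a global phase shift", {
  lf <- linear_fixture()
  base <- c(0, -48.46, -178.10, 133.44)
  hp0 <- heating_potential(superpose(lf$fs, list(voltages = rep(1, 4),
                                                 phases = base)),
                           lf$phantom)
  for (shift in c(37, -120, 245)) {
    hp1 <- heating_potential(
      superpose(lf$fs, list(voltages = rep(1, 4), phases = base + shift)),
      lf$phantom)
    expect_equal(hp1$q0, hp0$q0, tolerance = 1e-10)
  }
})

test_that("excitation YAML round-trips to 1e-9", {
  exc <- excitation("circular", runif(12, 0, 9) + 0.123456789,
                    free_phases = c(-74.84123456, 34.11987654, 12.3, -120,
                                    55.5, 179.9))
  path <- tempfile(fileext = ".yaml")
  write_excitation(exc, path)
  back <- read_excitation(path)
  expect_equal(back$voltages, exc$voltages, tolerance = 1e-9)
  expect_equal(back$phases, exc$phases, tolerance = 1e-9)
  expect_identical(back$scheme, exc$scheme)
  unlink(path)
})
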