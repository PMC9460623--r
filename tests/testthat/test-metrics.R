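test_that("region energy fraction is the plain quotient of sums", {
  ph <- manual_phantom(8, 8, sigma = 1, breast = TRUE)
  q0 <- matrix(0, 8, 8)
  q0[1, 1] <- 10; q0[2, 2] <- 20          # region: 30
  q0[5, 5] <- 40; q0[6, 6] <- 50          # rest: 90 -> total 120
  region <- matrix(0, 8, 8); region[1:3, 1:3] <- 1
  expect_equal(omega_region(q0, ph, region), 25)
  expect_equal(omega_region(q0, ph, matrix(1, 8, 8)), 100)
  # out-of-breast energy enters neither sum
  ph2 <- ph; ph2$breast_mask[5, 5] <- FALSE
  expect_equal(omega_region(q0, ph2, region), 100 * 30 / 80)
  expect_error(omega_region(matrix(0, 8, 8), ph, region), "undefined")
})

test_that("dominant hotspot matches an exhaustive window-scan oracle", {
  set.seed(14)
  grid <- grid_spec(20, 20)
  ph <- manual_phantom(20, 20, sigma = 1.3, breast = TRUE)
  ph$grid <- grid
  target <- target_spec(c(0, 0), side_mm = 5)
  tmask <- build_mask(target, grid)
  k <- 5
  for (rep in 1:5) {
    q0 <- matrix(rexp(400), 20, 20)
    hs <- find_dominant_hotspot(q0, ph, target)
    # oracle: test every placement with a double loop
    tr <- range(which(rowSums(tmask) > 0))
    tc <- range(which(colSums(tmask) > 0))
    best <- -Inf; best_rc <- NULL
    for (r0 in 1:(20 - k + 1)) for (c0 in 1:(20 - k + 1)) {
      if (r0 <= tr[2] && r0 + k - 1 >= tr[1] &&
          c0 <= tc[2] && c0 + k - 1 >= tc[1]) next
      s <- sum(q0[r0:(r0 + k - 1), c0:(c0 + k - 1)])
      if (s > best + 1e-12) { best <- s; best_rc <- c(r0, c0) }
    }
    expect_equal(c(hs$row, hs$col), best_rc)
    expect_equal(hs$omega_hotspot, 100 * best / sum(q0))
    # no other disjoint window scores higher
    expect_gte(hs$omega_hotspot, 100 * best / sum(q0) - 1e-12)
  }

  # energy confined to the target leaves nothing for a hotspot
  q0 <- matrix(0, 20, 20); q0[tmask > 0] <- 1
  expect_equal(find_dominant_hotspot(q0, ph, target)$omega_hotspot, 0)

  # two identical peaks: the smallest-row, then smallest-column window wins
  q0 <- matrix(0, 20, 20); q0[2, 18] <- 5; q0[18, 2] <- 5
  hs <- find_dominant_hotspot(q0, ph, target)
  expect_equal(hs$row, 1)
  expect_equal(hs$omega_hotspot, 50)
})

test_that("psi reproduces every printed hotspot-to-target ratio", {
  for (tr in metric_triples()) {
    expect_equal(psi(tr[2], tr[1]), tr[3], tolerance = 0.01 / tr[3])
    expect_lt(abs(psi(tr[2], tr[1]) - tr[3]), 0.01)
  }
  expect_equal(psi(0, 5), 0)
  expect_error(psi(3, 0), "> 0")
})

test_that("average target deposition is the mean heating potential", {
  ph <- manual_phantom(20, 20, sigma = 2, breast = TRUE)
  ph$grid <- grid_spec(20, 20)
  target <- target_spec(c(0, 0), side_mm = 5)
  tmask <- build_mask(target, ph$grid)
  E <- array(complex(real = rnorm(800), imaginary = rnorm(800)),
             c(2, 20, 20))
  q0 <- 0.5 * ph$sigma * apply(abs(E)^2, c(2, 3), sum)
  expect_equal(p_av(E, ph, target), mean(q0[tmask > 0]) / 1000)

  # uniform map: P_av equals the constant level; quadratic in the drive
  Eu <- array(1 + 0i, c(1, 20, 20))
  expect_equal(p_av(Eu, ph, target), 1 / 1000)
  expect_equal(p_av(2 * Eu, ph, target), 4 / 1000)

  # printed-formula variant drops the half
  old <- options(mhfocus.pav_printed_formula = TRUE)
  expect_equal(p_av(Eu, ph, target), 2 / 1000)
  options(old)
})

test_that("end-to-end scoring matches a step-by-step hand computation", {
  set.seed(33)
  grid <- grid_spec(20, 20)
  bm <- (pixel_distances(grid, c(0, 0)) <= 9)
  ph <- manual_phantom(20, 20, sigma = 1.5, breast = TRUE)
  ph$grid <- grid
  ph$breast_mask <- bm
  ph$sigma[!bm] <- 0
  fields <- lapply(1:2, function(i)
    array(complex(real = rnorm(800), imaginary = rnorm(800)), c(2, 20, 20)))
  fs <- field_set(grid, fields, scheme = "custom")
  target <- target_spec(c(2, -1), side_mm = 5)
  exc <- excitation("custom", c(2, 1), phases = c(0, 135))

  rep1 <- evaluate_excitation(exc, fs, ph, target)

  # hand computation, step by step
  scale <- sqrt(6 / sum(c(2, 1)^2 / 50))
  cf <- scale * c(2, 1) * exp(1i * c(0, 135) * pi / 180)
  E <- cf[1] * fields[[1]] + cf[2] * fields[[2]]
  q0 <- 0.5 * ph$sigma * apply(abs(E)^2, c(2, 3), sum)
  tmask <- build_mask(target, grid)
  om_t <- 100 * sum(q0[tmask > 0 & bm]) / sum(q0[bm])
  expect_equal(rep1$omega_target, om_t, tolerance = 1e-10)
  expect_equal(rep1$p_av_kw_m3, mean(q0[tmask > 0]) / 1000,
               tolerance = 1e-10)
  expect_equal(rep1$psi, rep1$omega_hotspot / rep1$omega_target)
  expect_equal(sum(port_power(rep1$excitation$voltages)), 6)

  # energy fractions are drive-scale invariant; P_av is not
  rep2 <- evaluate_excitation(excitation("custom", 3 * c(2, 1),
                                         phases = c(0, 135)),
                              fs, ph, target)
  expect_equal(rep2$omega_target, rep1$omega_target, tolerance = 1e-10)
  expect_equal(rep2$omega_hotspot, rep1$omega_hotspot, tolerance = 1e-10)
  expect_equal(rep2$p_av_kw_m3, rep1$p_av_kw_m3, tolerance = 1e-10)

  expect_error(evaluate_excitation(excitation("custom", c(0, 0),
                                              phases = c(0, 0)),
                                   fs, ph, target), "zero")

  # metric ranges
  expect_gte(rep1$omega_target, 0); expect_lte(rep1$omega_target, 100)
  expect_gte(rep1$omega_hotspot, 0); expect_lte(rep1$omega_hotspot, 100)
  expect_gte(rep1$psi, 0)
})
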