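test_that("pristine_bragg closed forms", {
  m <- bragg_model()
  expect_equal(pristine_bragg(100, 100, m), 1.0)
  # distal 50%: Gaussian half maximum at sigma_d * sqrt(2 ln 2)
  expect_equal(pristine_bragg(100 + m$sigma_d * sqrt(2 * log(2)), 100, m),
               0.5)
  # numerically solved distal-50% depth matches R + 1.1774 sigma_d
  r50 <- stats::uniroot(function(w) pristine_bragg(w, 100, m) - 0.5,
                        c(100, 120), tol = 1e-12)$root
  expect_lt(abs(r50 - (100 + 1.17741002251547 * m$sigma_d)), 1e-9)
  # entrance plateau at w = 0, R = 100
  expect_equal(pristine_bragg(0, 100, m),
               0.35 + 0.65 * exp(-10000 / 72))
  expect_error(pristine_bragg(1, -5, m), "positive")
  expect_error(bragg_model(plateau = 1), "plateau")
})

test_that("wepl_profile applies the midpoint rule per column", {
  # uniform water, 1 mm: W at 1-based voxel k is k - 0.5
  g <- image_grid(array(1, c(3, 100, 3)), c(0, 0, 0), c(1, 1, 1),
                  quantity = "RSP")
  W <- wepl_profile(g, axis = 2)
  expect_equal(W$values[2, , 2], seq_len(100) - 0.5)

  # 50 mm water then 50 mm lung: exit WEPL = 50 + 13 = 63 exactly
  rspcol <- c(rep(1, 50), rep(0.26, 50))
  g2 <- image_grid(array(rep(rspcol, each = 1), c(1, 100, 1)),
                   c(0, 0, 0), c(1, 1, 1), quantity = "RSP")
  W2 <- wepl_profile(g2, axis = 2)
  exit <- W2$values[1, 100, 1] + 0.26 / 2
  expect_equal(exit, 63.0)

  # vacuum
  g3 <- uniform_grid(0, quantity = "RSP")
  expect_true(all(wepl_profile(g3, 2)$values == 0))

  # monotone along every ray, either entry side
  set.seed(2)
  g4 <- image_grid(array(runif(4 * 30 * 5), c(4, 30, 5)), c(0, 0, 0),
                   c(1, 2, 1), quantity = "RSP")
  for (e in c("+", "-")) {
    W4 <- wepl_profile(g4, 2, e)
    d <- apply(W4$values, c(1, 3), function(col)
      min(diff(if (e == "+") col else rev(col))))
    expect_true(all(d >= 0))
  }
  g4$values[1] <- -1
  expect_error(wepl_profile(g4, 2), "non-negative")
})

test_that("dose engine: single-ray proportionality, linearity, superposition", {
  rsp <- image_grid(array(1, c(21, 120, 21)), c(0, 0, 0), c(1, 1, 1),
                    quantity = "RSP")
  m <- bragg_model()
  one <- beam_spec(data.frame(u = 10, v = 10, range = 80, sigma = 5,
                              weight = 2))
  d1 <- compute_beam_dose(one, rsp, m)
  W <- wepl_profile(rsp, 2)
  ray <- d1$values[11, , 11]
  expected <- 2 * pristine_bragg(W$values[11, , 11], 80, m) *
    stats::dnorm(0, 0, 5)^2
  expect_equal(ray, expected, tolerance = 1e-12)

  two <- one; two$spots$weight <- 4
  d2 <- compute_beam_dose(two, rsp, m)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)

  pair <- beam_spec(data.frame(u = c(10, 10), v = c(10, 10),
                               range = c(80, 80), sigma = c(5, 5),
                               weight = c(2, 2)))
  dpair <- compute_beam_dose(pair, rsp, m)
  expect_equal(dpair$values, d2$values, tolerance = 1e-12)

  expect_error(compute_beam_dose(beam_spec(one$spots, axis = 5), rsp, m),
               "axis")
})

test_that("RSP scaling by k moves the distal-50% depth by 1/k", {
  m <- bragg_model()
  beam <- beam_spec(data.frame(u = 10, v = 10, range = 60, sigma = 6,
                               weight = 1))
  base <- image_grid(array(0.9, c(21, 140, 21)), c(0, 0, 0), c(1, 1, 1),
                     quantity = "RSP")
  d50 <- function(rsp) {
    dose <- compute_beam_dose(beam, rsp, m)
    prof <- dose$values[11, , 11]
    pk <- which.max(prof)
    lvl <- 0.5 * max(prof)
    k <- which(prof < lvl); k <- k[k > pk][1]
    ys <- grid_coords(dose, 2)
    f <- (prof[k - 1] - lvl) / (prof[k - 1] - prof[k])
    ys[k - 1] + f * (ys[k] - ys[k - 1])
  }
  ref <- d50(base)
  for (k in c(0.8, 1.1, 1.25)) {
    scaled <- base; scaled$values <- base$values * k
    expect_lt(abs(d50(scaled) - ref / k), 0.5)  # within half a voxel
  }
})

test_that("phantom generation is deterministic and class-exact", {
  spec <- phantom_spec("head", shape = c(60, 70, 60), spacing = c(2, 2, 2),
                       body_center = c(59, 58, 59), body_semi = c(46, 44, 46),
                       slab_y = c(104, 132), detector_depth = 118,
                       wedge_x = c(30, 90), wedge_z = c(30, 90),
                       wedge_proximal = 85, wedge_distal = c(106, 126),
                       hu_noise_sd = 2, seed = 7)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$density$values, b$density$values)

  # noise-free soft-tissue voxels carry exactly the table's soft HU
  spec0 <- phantom_spec("head", shape = c(60, 70, 60), spacing = c(2, 2, 2),
                        body_center = c(59, 58, 59),
                        body_semi = c(46, 44, 46),
                        slab_y = c(104, 132), detector_depth = 118,
                        wedge_x = c(30, 90), wedge_z = c(30, 90),
                        wedge_proximal = 85, wedge_distal = c(106, 126))
  p0 <- make_phantom(spec0)
  soft_core <- p0$classes == 3 & p0$density$values == 1.04
  expect_true(any(soft_core))
  expect_true(all(p0$ct$values[soft_core] == 40))

  # the wedge must intersect the detector plane
  expect_error(phantom_spec("head", detector_depth = 90), "detector")
})

test_that("thorax density histogram matches analytic ellipsoid volumes", {
  spec <- phantom_spec("thorax")
  ph <- make_phantom(spec)
  vox <- prod(spec$spacing)
  lung_n <- sum(ph$classes == 2)
  lung_analytic <- 2 * 4 / 3 * pi * prod(spec$lung_semi) / vox
  expect_lt(abs(lung_n - lung_analytic) / lung_analytic, 0.02)
  # dominant density modes at the class densities
  counts <- table(round(ph$density$values, 5))
  modes <- as.numeric(names(sort(counts, decreasing = TRUE)[1:4]))
  expect_setequal(round(sort(modes), 5),
                  round(sort(c(0.00121, 0.26, 1.04, 1.00)), 5))
})

test_that("distort_to_cbct applies affine, cupping, and seeded noise", {
  spec <- phantom_spec("head", shape = c(50, 60, 50),
                       spacing = c(2.5, 2.5, 2.5),
                       body_center = c(58, 58, 58), body_semi = c(45, 44, 45),
                       slab_y = c(104, 132), detector_depth = 118,
                       wedge_x = c(30, 88), wedge_z = c(30, 88),
                       wedge_proximal = 85, wedge_distal = c(106, 126))
  ph <- make_phantom(spec)
  ident <- cbct_distortion()
  expect_equal(distort_to_cbct(ph$ct, ph$classes, ident)$values,
               ph$ct$values)

  soft_up <- cbct_distortion(b = c(air = 0, lung = 0, soft = 40, bone = 0,
                                   water = 0))
  shifted <- distort_to_cbct(ph$ct, ph$classes, soft_up)
  soft <- ph$classes == 3
  expect_equal(shifted$values[soft], ph$ct$values[soft] + 40)
  expect_equal(shifted$values[!soft], ph$ct$values[!soft])

  # seeded noise: reproducible per seed, differs across seeds, and the
  # per-class mean difference obeys the sigma/sqrt(n) CLT bound
  n1 <- cbct_distortion(noise_sd = 5, seed = 1)
  n2 <- cbct_distortion(noise_sd = 5, seed = 2)
  c1 <- distort_to_cbct(ph$ct, ph$classes, n1)
  c1b <- distort_to_cbct(ph$ct, ph$classes, n1)
  c2 <- distort_to_cbct(ph$ct, ph$classes, n2)
  expect_identical(c1$values, c1b$values)
  expect_gt(mean(c1$values != c2$values), 0.99)
  nsoft <- sum(soft)
  expect_gt(nsoft, 1e4)
  dmean <- abs(mean(c1$values[soft]) - mean(c2$values[soft]))
  expect_lt(dmean, 2 * sqrt(2) * 3 * 5 / sqrt(nsoft))

  bad <- ph$classes; bad[1] <- 99L
  expect_error(distort_to_cbct(ph$ct, bad, ident), "class")
})

test_that("simulate_measurement samples, scales and bounds noise", {
  set.seed(4)
  vals <- array(runif(30 * 40 * 30, 50, 150), c(30, 40, 30))
  dose <- image_grid(vals, c(0, 0, 0), c(2, 2, 2), quantity = "dose")
  # lattice aligned with the grid: exact slice values
  pl <- simulate_measurement(dose, depth = 20, pitch = 2, n = c(30, 30),
                             noise = 0, center = c(29, 29))
  expect_equal(pl$values, vals[, 11, ], tolerance = 1e-12)

  u <- uniform_grid(120, shape = c(30, 30, 30), spacing = c(2, 2, 2))
  flat <- simulate_measurement(u, depth = 30, pitch = 7, n = 5, noise = 0)
  expect_true(all(flat$values == 120))

  # 1% multiplicative noise: CLT bound on the mean over 729 chambers
  noisy <- simulate_measurement(u, depth = 30, pitch = 2, n = 27,
                                noise = 0.01, seed = 9)
  expect_lt(abs(mean(noisy$values) - 120), 3 * 0.01 * 120 / sqrt(729))
  expect_error(simulate_measurement(u, depth = 500), "outside")
})
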