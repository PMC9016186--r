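test_that("extract_plane: aligned slice, linear field, constant field", {
  set.seed(6)
  vals <- array(runif(20 * 30 * 20, 0, 100), c(20, 30, 20))
  dose <- image_grid(vals, c(0, 0, 0), c(2, 2, 2), quantity = "dose")
  latt <- list(origin = c(0, 0), spacing = c(2, 2), n = c(20, 20))
  pl <- extract_plane(dose, depth = 20, axis = 2, lattice = latt)
  expect_equal(pl$values, vals[, 11, ], tolerance = 1e-12)

  # dose linear in depth: off-center plane is the slice average
  lin <- image_grid(array(rep(seq(0, 58, by = 2), each = 20), c(20, 30, 20)),
                    c(0, 0, 0), c(2, 2, 2), quantity = "dose")
  mid <- extract_plane(lin, depth = 21, axis = 2, lattice = latt)
  expect_equal(unique(round(as.numeric(mid$values), 10)), 21)

  u <- uniform_grid(77, shape = c(10, 10, 10), spacing = c(3, 3, 3))
  anyd <- extract_plane(u, depth = 13.7, axis = 2,
                        lattice = list(origin = c(3, 3), spacing = c(2, 2),
                                       n = c(5, 5)))
  expect_equal(as.numeric(anyd$values), rep(77, 25), tolerance = 1e-12)
  expect_error(extract_plane(u, depth = 99, axis = 2, lattice = latt),
               "outside")
})

test_that("best_match refines by parabola and handles plateaus", {
  mk <- function(depths, rates) structure(
    list(depths = depths, pass_rates = rates, step = diff(depths)[1],
         physical_depth = depths[ceiling(length(depths) / 2)],
         degenerate = FALSE),
    class = "range_sweep_result")
  expect_equal(as.numeric(best_match(mk(99:101, c(80, 95, 80)))), 100)
  expect_equal(as.numeric(best_match(mk(99:101, c(80, 95, 90)))), 100.25)
  pl <- best_match(mk(99:102, c(90, 95, 95, 90)))
  expect_equal(as.numeric(pl), 100.5)
  expect_true(attr(pl, "low_confidence"))
  expect_error(best_match(mk(99:102, rep(50, 4))), "equal")
  expect_error(best_match(mk(99:100, c(1, 2))), "3 candidate")
})

test_that("percent_range_error sign and scale", {
  # positive when the calculation's stopping power is too high, i.e.
  # the pattern is found at a shallower calculated plane
  expect_equal(percent_range_error(100, 100, 100), 0)
  expect_equal(percent_range_error(98.8, 100, 100), 1.2)
  expect_equal(percent_range_error(102.1, 100, 100), -2.1)
  expect_error(percent_range_error(100, 100, 0), "positive")
})

test_that("sweep on a synthetic wedge self-match peaks at the true depth", {
  # small analytic wedge dose: edge position moves linearly with depth
  ys <- seq(0, 58, by = 2)
  xs <- seq(0, 58, by = 2)
  # lateral edge at x = 30 + 1.5 (y - 30): a 3 mm depth shift moves the
  # pattern 4.5 mm laterally, beyond the 3 mm DTA
  dose_fun <- function(x, y) 200 / (1 + exp((x - 30 - 1.5 * (y - 30)) / 4))
  vals <- array(0, c(30, 30, 30))
  for (j in seq_along(ys)) vals[, j, ] <- outer(
    dose_fun(xs, ys[j]), rep(1, 30))
  dose <- image_grid(vals, c(0, 0, 0), c(2, 2, 2), quantity = "dose")
  meas <- simulate_measurement(dose, depth = 30, pitch = 4, n = c(14, 14),
                               noise = 0)
  sw <- sweep_depths(meas, dose, window = 10, step = 1,
                     params = gamma_params())
  expect_equal(sw$depths, 20:40)
  expect_equal(max(sw$pass_rates), 100)
  expect_equal(sw$pass_rates[sw$depths == 30], 100)
  # 3 mm off-peak planes match strictly worse
  expect_lt(sw$pass_rates[sw$depths == 27], 100)
  expect_lt(sw$pass_rates[sw$depths == 33], 100)
  expect_equal(as.numeric(best_match(sw)), 30, tolerance = 0.5)

  # shift equivariance: relabeling the measurement depth by delta leaves
  # the matched absolute depth alone, so the apparent depth offset
  # (best - physical) moves by -delta
  meas2 <- meas; meas2$depth <- meas$depth + 2
  sw2 <- sweep_depths(meas2, dose, window = 10, step = 1)
  off1 <- as.numeric(best_match(sw)) - meas$depth
  off2 <- as.numeric(best_match(sw2)) - meas2$depth
  expect_equal(off2 - off1, -2, tolerance = 0.5)

  # degenerate: uniform dose carries no range information
  u <- uniform_grid(150, shape = c(20, 20, 20), spacing = c(3, 3, 3))
  um <- simulate_measurement(u, depth = 28, pitch = 5, n = 5, noise = 0)
  expect_warning(swu <- sweep_depths(um, u, window = 6, step = 2),
                 "no range information")
  expect_true(swu$degenerate)
  expect_error(best_match(swu), "equal")
  expect_error(sweep_depths(um, u, window = 40), "outside")
})

test_that("wepl_to_detector: both methods agree in a flat phantom", {
  # laterally uniform RSP: sensitivity weighting and the central axis
  # must coincide
  rsp <- image_grid(array(1, c(15, 60, 15)), c(0, 0, 0), c(2, 2, 2),
                    quantity = "RSP")
  beam <- beam_spec(data.frame(u = c(10, 14, 18), v = c(14, 14, 14),
                               range = c(60, 60, 60), sigma = 5,
                               weight = 1))
  dose <- compute_beam_dose(beam, rsp)
  latt <- list(origin = c(4, 4), spacing = c(4, 4), n = c(6, 6))
  w_sens <- wepl_to_detector(rsp, beam, 50, dose = dose, lattice = latt)
  w_cax <- wepl_to_detector(rsp, beam, 50, method = "central_axis")
  expect_equal(w_sens, w_cax, tolerance = 0.02)
  expect_equal(w_cax, 51, tolerance = 0.02)  # RSP 1: WEPL ~ depth (+ edge half-voxel)
  u <- uniform_grid(5, shape = c(15, 60, 15), spacing = c(2, 2, 2))
  expect_error(wepl_to_detector(rsp, beam, 50, dose = u, lattice = latt),
               "sensitivity")
})

test_that("evaluate_range_uncertainty chains stages and reports provenance", {
  b <- head_bundle()
  ev <- evaluate_range_uncertainty(
    b$ph$ct, b$tab, b$rt, b$beam, b$meas0,
    overrides = list(list(mask = b$ph$base, value = 1.00)))
  expect_s3_class(ev, "range_sweep_result")
  expect_lt(abs(ev$range_error_pct), 0.25)
  expect_equal(ev$best_depth, b$spec$detector_depth, tolerance = 0.5)
  expect_identical(ev$provenance$modality, "CT")
  expect_gt(ev$wepl_to_detector, 50)
  # stage labeling of propagated errors
  bad_tab <- b$tab; bad_tab$hu <- NULL
  expect_error(evaluate_range_uncertainty(b$ph$ct, bad_tab, b$rt, b$beam,
                                          b$meas0),
               "density_from_hu")
})
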