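test_that("compute_dvh step functions and volumes", {
  g <- uniform_grid(200, shape = c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  sm <- structure_mask("t", mask, g)
  c1 <- compute_dvh(g, sm)
  expect_equal(dvh_metric(c1, "V100%", 200), 100)   # uniform at level
  expect_equal(c1$volume_pct[1], 100)
  expect_equal(c1$volume_cm3, 1.000)                # 1000 x 1 mm^3
  expect_equal(dvh_metric(c1, "Dmax"), 200)
  expect_equal(dvh_metric(c1, "Dmean"), 200)

  # two-level field: V(150) = 50
  vals <- array(100, c(10, 10, 10)); vals[1:5, , ] <- 200
  g2 <- image_grid(vals, c(0, 0, 0), c(1, 1, 1), quantity = "dose")
  c2 <- compute_dvh(g2, sm)
  expect_equal(stats::approx(c2$edges, c2$volume_pct, 150)$y, 50)

  # 95% at prescription, 5% at half: V100% = 95
  v3 <- array(200, c(10, 10, 10)); v3[, , 1][1:50] <- 100
  g3 <- image_grid(v3, c(0, 0, 0), c(1, 1, 1), quantity = "dose")
  expect_equal(dvh_metric(compute_dvh(g3, sm), "V100%", 200), 95)

  # uniform 0.99 x prescription: V100% = 0
  g4 <- uniform_grid(198, shape = c(10, 10, 10))
  expect_equal(dvh_metric(compute_dvh(g4, sm), "V100%", 200), 0)

  expect_error(compute_dvh(g, structure_mask("e", array(FALSE, c(10, 10, 10)), g)),
               "empty")
  gm <- uniform_grid(1, shape = c(9, 10, 10))
  expect_error(compute_dvh(gm, sm), "geometry")
  expect_error(dvh_metric(c1, "D50%"), "unknown")
})

test_that("DVH invariants hold on random dose/mask pairs", {
  for (seed in 1:6) {
    set.seed(seed)
    vals <- array(rgamma(8000, shape = 2, scale = 40), c(20, 20, 20))
    g <- image_grid(vals, c(0, 0, 0), c(1.5, 1.5, 1.5), quantity = "dose")
    mask <- array(runif(8000) < 0.4, c(20, 20, 20))
    if (!any(mask)) mask[1] <- TRUE
    sm <- structure_mask("r", mask, g)
    cv <- compute_dvh(g, sm, bin_width = 1)
    expect_equal(cv$volume_pct[1], 100)
    expect_true(all(diff(cv$volume_pct) <= 1e-12))
    expect_equal(cv$volume_pct[length(cv$volume_pct)], 0)
    expect_equal(cv$dmean, mean(vals[mask]))
    # Dmean reconstructed from the curve within one bin width
    mid <- cv$edges[-1] - diff(cv$edges) / 2
    recon <- -sum(mid * diff(cv$volume_pct)) / 100
    expect_lt(abs(recon - cv$dmean), 1)
    # halving the bin width moves V100% by less than one original bin
    presc <- stats::quantile(vals[mask], 0.4, names = FALSE)
    v_a <- dvh_metric(cv, "V100%", presc)
    v_b <- dvh_metric(compute_dvh(g, sm, bin_width = 0.5), "V100%", presc)
    binvol <- 100 * max(table(cut(vals[mask], cv$edges))) / sum(mask)
    expect_lt(abs(v_a - v_b), binvol + 1e-9)
  }
})

test_that("verify_daily identity fraction reproduces the planning dose", {
  b <- thorax_bundle()
  rep0 <- verify_daily(b$ph$ct, translation_transform(c(0, 0, 0)),
                       b$tab, b$rt, b$beam, b$ph$wedge,
                       prescription = 200, overrides = b$overrides,
                       fraction_label = "fx01")
  # planning-side V100% computed directly from the plan dose
  v100_plan <- dvh_metric(compute_dvh(b$dose, b$ph$wedge), "V100%", 200)
  v100_daily <- rep0$metrics[["wedge_ctv.V100%"]]
  expect_equal(v100_daily, v100_plan, tolerance = 1e-6)
  expect_false(any(vapply(rep0$flags, `[[`, TRUE, "triggered")))

  # threshold logic: an unreachable threshold always flags
  rep_flag <- verify_daily(b$ph$ct, translation_transform(c(0, 0, 0)),
                           b$tab, b$rt, b$beam, b$ph$wedge,
                           prescription = 200, overrides = b$overrides,
                           thresholds = list(target_v100_min = 99.9))
  expect_true(rep_flag$flags[[1]]$triggered)
  expect_equal(rep_flag$flags[[1]]$threshold, 99.9)
})

test_that("reports serialize losslessly and batch into trends", {
  b <- thorax_bundle()
  mk <- function(lbl, mod, v) structure(list(
    fraction = lbl, modality = mod, prescription = 200,
    metrics = list(`wedge_ctv.V100%` = v, `lung.Dmean` = 12.5),
    flags = list(list(metric = "wedge_ctv.V100%", threshold = 95,
                      triggered = v < 95)),
    provenance = list(table_modality = mod)),
    class = "verification_report")
  r <- mk("fx1", "CBCT", 97.25)
  p <- tempfile(fileext = ".json")
  write_report(r, p)
  back <- read_report(p)
  expect_equal(back$metrics, r$metrics)
  expect_equal(back$flags[[1]], r$flags[[1]])
  expect_identical(back$fraction, "fx1")

  reps <- c(lapply(1:28, function(i) mk(sprintf("cbct%02d", i), "CBCT",
                                        99 - i %% 5)),
            lapply(1:9, function(i) mk(sprintf("ct%d", i), "CT",
                                       c(99, 97, 95)[1 + i %% 3])))
  tr <- batch_report(reps)
  expect_equal(nrow(tr$table), 37)
  expect_equal(sum(tr$table$modality == "CBCT"), 28)
  expect_equal(sum(tr$table$modality == "CT"), 9)
  s <- tr$summary
  ct_row <- s[s$metric == "wedge_ctv.V100%" & s$modality == "CT", ]
  expect_equal(ct_row$min, 95)
  expect_true(ct_row$worst_fraction %in%
                tr$table$fraction[tr$table$modality == "CT" &
                                    tr$table$`wedge_ctv.V100%` == 95])

  ident <- batch_report(list(r, r, r))
  expect_equal(ident$summary$min, ident$summary$max)

  bad <- mk("x", "CT", 99); bad$prescription <- 180
  expect_error(batch_report(list(r, bad)), "prescription")
})

test_that("FOV truncation of the beam corridor is a hard error", {
  b <- thorax_bundle()
  # shift the daily image far laterally: the corridor then samples
  # outside the moving volume
  big_shift <- translation_transform(c(250, 0, 0))
  expect_error(
    verify_daily(b$ph$ct, big_shift, b$tab, b$rt, b$beam, b$ph$wedge,
                 prescription = 200, overrides = b$overrides),
    "field of view")
})
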