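# Shared fixtures.  The phantom/plan bundles are expensive (~1 min each)
# and deterministic, so they are built once per test run and cached in a
# session-level environment shared across test files.

.fx_cache <- local({
  # keep one cache per R session even if helpers are re-sourced
  if (!exists(".rangewedge_fixture_cache", envir = globalenv(),
              inherits = FALSE))
    assign(".rangewedge_fixture_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  get(".rangewedge_fixture_cache", envir = globalenv())
})

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# full head bundle: phantom, calibrations, RSP, optimized wedge beam,
# planned dose, noise-free + 1%-noise detector measurements
head_bundle <- function() fixture("head", function() {
  spec <- phantom_spec("head")
  ph <- make_phantom(spec)
  tab <- default_ct_table()
  rt <- default_rsp_table()
  dens <- apply_density_override(density_from_hu(ph$ct, tab), ph$base, 1.00)
  rsp <- rsp_from_density(dens, rt)
  beam <- build_wedge_beam(ph$wedge, rsp)
  dose <- attr(beam, "plan_dose")
  list(spec = spec, ph = ph, tab = tab, rt = rt, rsp = rsp, beam = beam,
       dose = dose,
       meas0 = simulate_measurement(dose, spec$detector_depth, noise = 0),
       meas1 = simulate_measurement(dose, spec$detector_depth,
                                    noise = 0.01, seed = 42))
})

thorax_bundle <- function() fixture("thorax", function() {
  spec <- phantom_spec("thorax")
  ph <- make_phantom(spec)
  tab <- default_ct_table()
  rt <- default_rsp_table()
  dens <- apply_density_override(density_from_hu(ph$ct, tab), ph$base, 1.00)
  rsp <- rsp_from_density(dens, rt)
  beam <- build_wedge_beam(ph$wedge, rsp, normalize = "D98")
  list(spec = spec, ph = ph, tab = tab, rt = rt, rsp = rsp, beam = beam,
       dose = attr(beam, "plan_dose"),
       overrides = list(list(mask = ph$base, value = 1.00)))
})

# small uniform grid helper
uniform_grid <- function(value = 0, shape = c(5, 5, 5), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), quantity = "dose") {
  image_grid(array(value, shape), origin, spacing, quantity = quantity)
}

# planar dose helper on a pitch-spaced lattice
make_plane <- function(values, pitch = 10, origin = c(0, 0), depth = 100,
                       axis = 2) {
  planar_dose(as.matrix(values), plane_axis = axis, depth = depth,
              origin = origin, spacing = rep(pitch, 2))
}

# random smooth dose plane pair for gamma property tests: reference on a
# coarse lattice, evaluated as a denser smooth field with a sub-pixel
# offset; both derive from one smooth 2D function
smooth_plane_pair <- function(seed, n_ref = 9, ref_pitch = 10,
                              eval_pitch = 2, offset = NULL) {
  set.seed(seed)
  a <- runif(6, -1, 1)
  f <- function(x, y) {
    100 + 40 * sin(a[1] + x / 37) * cos(a[2] + y / 29) +
      30 * sin(a[3] + (x + y) / 53) + 20 * cos(a[4] + (x - y) / 41) +
      a[5] * x / 10 + a[6] * y / 10
  }
  if (is.null(offset)) offset <- runif(2, -3, 3)
  rx <- (seq_len(n_ref) - 1) * ref_pitch
  ref_vals <- outer(rx, rx, f)
  ref_vals <- pmax(ref_vals, 0)
  margin <- 12
  ex <- seq(-margin, max(rx) + margin, by = eval_pitch)
  ev_vals <- pmax(outer(ex + offset[1], ex + offset[2], f), 0)
  list(ref = planar_dose(ref_vals, 2, 100, c(0, 0), rep(ref_pitch, 2)),
       eval = planar_dose(ev_vals, 2, 100, rep(-margin, 2),
                          rep(eval_pitch, 2)))
}
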