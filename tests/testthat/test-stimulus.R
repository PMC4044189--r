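test_that("dipole and signal counts follow density, pairing and coherence", {
  # paper-default field: 25 dots/deg^2 over a 14.4 deg square
  spec <- glass_spec()
  expect_identical(dipole_count(spec), as.integer(25 * 14.4^2 / 2))
  # dots come in pairs: odd raw totals round to the nearest even count
  small <- function(density) {
    glass_spec(dot_density = density, field_side = 2,
               aperture_outer_diam = 2, aperture_inner_diam = 0.2,
               edge_ramp = 0.3)
  }
  expect_identical(dipole_count(small(25)), 50L)
  expect_identical(dipole_count(small(0)), 0L)

  expect_identical(signal_dipole_count(100, 0.33), 33L)
  expect_identical(signal_dipole_count(100, 1.0), 100L)
  expect_identical(signal_dipole_count(2592, 0.33), 855L)  # round(855.36)
  # round-half-to-even
  expect_identical(signal_dipole_count(2, 0.25), 0L)
  expect_identical(signal_dipole_count(6, 0.25), 2L)
  expect_error(signal_dipole_count(100, 1.2), "coherence")
})

test_that("polar orientation is tangential for circular, radial for starburst", {
  expect_equal(polar_orientation(1, 0, "circular"), pi / 2)
  expect_equal(polar_orientation(0, 2, "starburst"), pi / 2)
  expect_equal(polar_orientation(1, 1, "circular"), 3 * pi / 4)
  expect_equal(polar_orientation(1, 1, "starburst"), pi / 4)
  expect_equal(polar_orientation(-1, 0, "starburst"), 0)
  expect_error(polar_orientation(0, 0, "circular"), "undefined")
})

test_that("sampled dipole fields honor coherence, bounds and determinism", {
  spec <- glass_spec(coherence = 0.33, field_side = 4, dot_density = 25,
                     aperture_outer_diam = 4)
  set.seed(11)
  f <- sample_dipole_field(spec)
  n <- dipole_count(spec)
  expect_equal(nrow(f), n)
  expect_equal(sum(f$is_signal), signal_dipole_count(n, 0.33))
  expect_true(all(abs(f$x_deg) <= 2 & abs(f$y_deg) <= 2))
  expect_true(all(f$orientation_rad >= 0 & f$orientation_rad < pi))
  expect_true(all(f$polarity %in% c(-1L, 1L)))

  # zero coherence: no signal dipoles
  set.seed(12)
  f0 <- sample_dipole_field(glass_spec(coherence = 0, field_side = 4,
                                       aperture_outer_diam = 4))
  expect_identical(sum(f0$is_signal), 0L)

  # full-coherence circular: every dipole exactly tangential to its radius
  set.seed(13)
  f1 <- sample_dipole_field(glass_spec(coherence = 1, form = "circular",
                                       field_side = 4,
                                       aperture_outer_diam = 4))
  radial <- atan2(f1$y_deg, f1$x_deg) %% pi
  expect_equal((f1$orientation_rad - radial) %% pi, rep(pi / 2, nrow(f1)))

  # determinism under a fixed seed
  set.seed(99); a <- sample_dipole_field(spec)
  set.seed(99); b <- sample_dipole_field(spec)
  expect_identical(a, b)
})

test_that("rendering puts Gaussian dots under the annular envelope", {
  spec <- glass_spec(pixels_per_degree = 50)

  # empty field: uniform mean luminance
  img0 <- render_pattern(empty_field(), spec)
  expect_true(all(img0 == 0.5))

  # one increment dipole on the plateau: peak near 1 at each dot center
  # (up to pixel-center discretization of the narrow Gaussian)
  f <- make_field(4, 0, 0, 1L)
  img <- render_pattern(f, spec)
  expect_gt(max(img), 0.95)
  # a decrement dipole mirrors it
  fd <- make_field(4, 0, 0, -1L)
  expect_lt(min(render_pattern(fd, spec)), 0.05)

  # inside the inner aperture radius everything is exactly background
  f_in <- make_field(0.3, 0, 0, 1L)
  img_in <- render_pattern(f_in, spec)
  ppd <- spec$pixels_per_degree
  coord <- (seq_len(nrow(img_in)) - 0.5) / ppd - spec$field_side / 2
  r <- sqrt(outer(rev(coord)^2, coord^2, "+"))
  expect_true(all(img_in[r < spec$aperture_inner_diam / 2] == 0.5))
  # ... and beyond the outer radius too
  f_out <- make_field(7.1, 0, 0, 1L)
  img_out <- render_pattern(f_out, spec)
  expect_true(all(img_out[r > spec$aperture_outer_diam / 2] == 0.5))

  # rendering is deterministic given the field
  expect_identical(render_pattern(f, spec), render_pattern(f, spec))

  # luminance stays in [0, 1] and the mean stays near background for a
  # full pattern
  set.seed(21)
  full <- render_pattern(sample_dipole_field(spec), spec)
  expect_true(all(full >= 0 & full <= 1))
  expect_lt(abs(mean(full) - 0.5), 0.01)

  # undersampled dots warn
  expect_warning(
    render_pattern(f, glass_spec(pixels_per_degree = 10)), "undersampled")
})

test_that("aperture envelope has the raised-cosine profile", {
  env <- aperture_envelope(c(0, 0.75, 1.125, 1.5, 4, 6.45, 6.825, 7.2, 9),
                           0.75, 7.2, 0.75)
  expect_equal(env, c(0, 0, 0.5, 1, 1, 1, 0.5, 0, 0))
  # monotone on the ramps
  r <- seq(0.75, 1.5, length.out = 50)
  expect_true(all(diff(aperture_envelope(r, 0.75, 7.2, 0.75)) >= 0))
})

test_that("pattern images and dipole tables round-trip to disk", {
  spec <- glass_spec(field_side = 3, aperture_outer_diam = 3,
                     aperture_inner_diam = 0.5, edge_ramp = 0.4,
                     pixels_per_degree = 40, coherence = 1)
  set.seed(31)
  f <- sample_dipole_field(spec)
  img <- render_pattern(f, spec)

  png_path <- withr::local_tempfile(fileext = ".png")
  write_pattern_png(img, png_path)
  back <- png::readPNG(png_path)
  expect_equal(dim(back), dim(img))
  expect_equal(back, round(255 * unclass(img)) / 255, tolerance = 1e-7,
               ignore_attr = TRUE)

  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_dipole_tsv(f, tsv_path)
  tab <- read.delim(tsv_path)
  expect_equal(names(tab),
               c("x_deg", "y_deg", "orientation_rad", "polarity", "is_signal"))
  expect_equal(tab$x_deg, f$x_deg, tolerance = 1e-12)
})
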