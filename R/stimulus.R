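#' Specification of a polar Glass pattern
#'
#' A Glass pattern is a field of randomly positioned dot pairs (dipoles).
#' When a proportion of dipoles (the coherence) share an orientation rule
#' defined relative to fixation -- tangential for circular form, radial for
#' starburst form -- a global polar structure is perceived. The defaults
#' describe a pattern of 25 dots/deg^2 over a 14.4 deg square field, dots
#' 0.14 deg apart with Gaussian profiles (sigma = 0.025 deg), displayed
#' through an annular aperture (outer diameter 14.4 deg, inner diameter
#' 1.5 deg) whose contrast ramps up/down over 0.75 deg following a raised
#' cosine.
#'
#' @param coherence Proportion of signal dipoles, in `[0, 1]`.
#' @param form Orientation rule: `"circular"` (tangential), `"starburst"`
#'   (radial), or `"random"` (all dipoles randomly oriented; equivalent to
#'   coherence 0 for rendering purposes).
#' @param dot_density Dots per squared degree of visual angle.
#' @param dipole_separation Distance between the two dots of a dipole
#'   (degrees).
#' @param dot_sigma Gaussian profile sigma of each dot (degrees).
#' @param field_side Side of the square placement field (degrees). Dipole
#'   centers are placed uniformly over this square; the annular aperture is
#'   applied afterwards as a contrast envelope.
#' @param aperture_outer_diam,aperture_inner_diam Outer and inner diameters
#'   of the annular aperture (degrees).
#' @param edge_ramp Width of the raised-cosine contrast ramp at each edge
#'   (degrees).
#' @param pixels_per_degree Raster resolution for rendering.
#' @return An object of class `glass_spec`.
#' @examples
#' spec <- glass_spec(coherence = 0.33, form = "circular")
#' dipole_count(spec)
#' @export
glass_spec <- function(coherence = 1,
                       form = c("circular", "starburst", "random"),
                       dot_density = 25,
                       dipole_separation = 0.14,
                       dot_sigma = 0.025,
                       field_side = 14.4,
                       aperture_outer_diam = 14.4,
                       aperture_inner_diam = 1.5,
                       edge_ramp = 0.75,
                       pixels_per_degree = 40) {
  form <- match.arg(form)
  if (!is.numeric(coherence) || length(coherence) != 1L ||
      is.na(coherence) || coherence < 0 || coherence > 1) {
    stop("`coherence` must be a single value in [0, 1]", call. = FALSE)
  }
  lens <- c(dot_density = dot_density, dipole_separation = dipole_separation,
            dot_sigma = dot_sigma, field_side = field_side,
            aperture_outer_diam = aperture_outer_diam,
            aperture_inner_diam = aperture_inner_diam,
            edge_ramp = edge_ramp, pixels_per_degree = pixels_per_degree)
  if (any(!is.finite(lens)) || any(lens[-1L] <= 0) || dot_density < 0) {
    stop("stimulus dimensions must be positive and finite", call. = FALSE)
  }
  if (aperture_inner_diam >= aperture_outer_diam) {
    stop("aperture inner diameter must be smaller than the outer diameter",
         call. = FALSE)
  }
  if (aperture_outer_diam > field_side) {
    stop("aperture must fit within the placement field", call. = FALSE)
  }
  structure(
    list(coherence = coherence, form = form, dot_density = dot_density,
         dipole_separation = dipole_separation, dot_sigma = dot_sigma,
         field_side = field_side, aperture_outer_diam = aperture_outer_diam,
         aperture_inner_diam = aperture_inner_diam, edge_ramp = edge_ramp,
         pixels_per_degree = pixels_per_degree),
    class = "glass_spec")
}

#' @export
print.glass_spec <- function(x, ...) {
  cat(sprintf(
    "Glass pattern spec: %s form, coherence %.2f\n", x$form, x$coherence))
  cat(sprintf("  %g dots/deg^2 over a %g deg square field (%d dipoles)\n",
              x$dot_density, x$field_side, dipole_count(x)))
  cat(sprintf("  dipole separation %g deg, dot sigma %g deg\n",
              x$dipole_separation, x$dot_sigma))
  cat(sprintf("  annulus %g-%g deg diameter, %g deg raised-cosine ramps\n",
              x$aperture_inner_diam, x$aperture_outer_diam, x$edge_ramp))
  invisible(x)
}

#' Number of dipoles implied by a pattern specification
#'
#' The dot total is the density times the placement-field area, forced to
#' the nearest even number since dots come in pairs; the dipole count is
#' half that.
#'
#' @param spec A [glass_spec()].
#' @return Non-negative integer dipole count.
#' @export
dipole_count <- function(spec) {
  stopifnot(inherits(spec, "glass_spec"))
  n_dots <- 2 * round(spec$dot_density * spec$field_side^2 / 2)
  as.integer(n_dots / 2)
}

#' Number of signal dipoles at a given coherence
#'
#' Coherence is the proportion of dipoles that follow the polar orientation
#' rule; e.g. a 33% coherence pattern has 33% signal dipoles. Rounding is
#' half-to-even (unbiased over coherence levels).
#'
#' @param n_dipoles Total dipole count.
#' @param coherence Proportion in `[0, 1]`.
#' @return Integer count, at most `n_dipoles`.
#' @export
signal_dipole_count <- function(n_dipoles, coherence) {
  if (!is.numeric(coherence) || length(coherence) != 1L || is.na(coherence) ||
      coherence < 0 || coherence > 1) {
    stop("`coherence` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_dipoles >= 0)
  as.integer(round(coherence * n_dipoles))
}

#' Polar orientation of a signal dipole at a visual-field location
#'
#' Starburst form orients dipoles radially (along the line to fixation);
#' circular form orients them tangentially (orthogonal to that line).
#' Orientations are axial: values lie in `[0, pi)` because a dipole is an
#' unordered dot pair.
#'
#' @param x,y Position relative to fixation (degrees).
#' @param form `"circular"` or `"starburst"`.
#' @return Orientation in radians, in `[0, pi)`.
#' @export
polar_orientation <- function(x, y, form = c("circular", "starburst")) {
  form <- match.arg(form)
  if (any(x == 0 & y == 0)) {
    stop("polar orientation is undefined at fixation (0, 0)", call. = FALSE)
  }
  ang <- atan2(y, x)
  if (form == "circular") ang <- ang + pi / 2
  ang %% pi
}

#' Sample a dipole field for a Glass pattern
#'
#' Dipole centers are uniform over the square placement field. Exactly
#' [signal_dipole_count()] dipoles are flagged as signal and receive the
#' polar orientation of their center ([polar_orientation()]); the remaining
#' noise dipoles receive independent uniform orientations in `[0, pi)`.
#' Each dipole's two dots are jointly a full contrast increment or
#' decrement with equal probability.
#'
#' @param spec A [glass_spec()].
#' @return An object of class `dipole_field`: a data frame with columns
#'   `x_deg`, `y_deg`, `orientation_rad`, `polarity` (+1/-1), `is_signal`.
#' @export
sample_dipole_field <- function(spec) {
  stopifnot(inherits(spec, "glass_spec"))
  n <- dipole_count(spec)
  form <- if (spec$form == "random") "circular" else spec$form
  coherence <- if (spec$form == "random") 0 else spec$coherence
  n_sig <- signal_dipole_count(n, coherence)
  half <- spec$field_side / 2
  x <- stats::runif(n, -half, half)
  y <- stats::runif(n, -half, half)
  # a center exactly at fixation has measure zero but would break the
  # orientation rule; nudge it
  at_origin <- x == 0 & y == 0
  x[at_origin] <- .Machine$double.eps
  ori <- stats::runif(n, 0, pi)
  is_signal <- rep(FALSE, n)
  if (n_sig > 0) {
    idx <- sample.int(n, n_sig)
    is_signal[idx] <- TRUE
    ori[idx] <- polar_orientation(x[idx], y[idx], form)
  }
  polarity <- sample(c(-1L, 1L), n, replace = TRUE)
  structure(
    data.frame(x_deg = x, y_deg = y, orientation_rad = ori,
               polarity = polarity, is_signal = is_signal),
    class = c("dipole_field", "data.frame"),
    field_side = spec$field_side)
}

#' Render a dipole field as a raster luminance image
#'
#' Each dipole contributes two Gaussian dots centered at plus/minus half the
#' dipole separation along its orientation axis, with amplitude
#' `polarity * 0.5` in normalized luminance, summed additively onto a 0.5
#' mean-luminance background. The deviation from 0.5 is then multiplied by
#' the annular raised-cosine envelope (zero inside the inner edge radius,
#' rising over one ramp width, a plateau, falling over the last ramp width
#' before the outer radius, zero beyond) and the result clipped to
#' `[0, 1]`.
#'
#' @param field A `dipole_field` from [sample_dipole_field()].
#' @param spec The matching [glass_spec()].
#' @return An object of class `pattern_image`: a numeric matrix of
#'   luminances in `[0, 1]` with attribute `degrees_per_pixel`. Rows index
#'   y (top of the matrix = top of the field), columns index x.
#' @export
render_pattern <- function(field, spec) {
  stopifnot(inherits(field, "dipole_field"), inherits(spec, "glass_spec"))
  ppd <- spec$pixels_per_degree
  if (spec$dot_sigma * ppd < 1) {
    warning(sprintf(
      "dot sigma (%.3f deg) spans < 1 pixel at %g px/deg; dots undersampled",
      spec$dot_sigma, ppd), call. = FALSE)
  }
  n_px <- max(1L, as.integer(round(spec$field_side * ppd)))
  # pixel-center coordinates in degrees, origin at fixation (field center)
  coord <- (seq_len(n_px) - 0.5) / ppd - spec$field_side / 2
  dev <- matrix(0, n_px, n_px)

  if (nrow(field) > 0) {
    half_sep <- spec$dipole_separation / 2
    dx <- cos(field$orientation_rad) * half_sep
    dy <- sin(field$orientation_rad) * half_sep
    dots_x <- c(field$x_deg + dx, field$x_deg - dx)
    dots_y <- c(field$y_deg + dy, field$y_deg - dy)
    amp <- rep(field$polarity * 0.5, 2)

    # stamp each Gaussian dot over a local +/- 4 sigma window
    r_px <- max(1L, as.integer(ceiling(4 * spec$dot_sigma * ppd)))
    two_s2 <- 2 * spec$dot_sigma^2
    # pixel index of each dot center: coord[i] covers ((i-1)/ppd, i/ppd]
    cx <- as.integer(floor((dots_x + spec$field_side / 2) * ppd)) + 1L
    cy <- as.integer(floor((dots_y + spec$field_side / 2) * ppd)) + 1L
    for (d in seq_along(dots_x)) {
      ix <- max(1L, cx[d] - r_px):min(n_px, cx[d] + r_px)
      iy <- max(1L, cy[d] - r_px):min(n_px, cy[d] + r_px)
      if (length(ix) == 0L || length(iy) == 0L) next
      gx <- exp(-(coord[ix] - dots_x[d])^2 / two_s2)
      gy <- exp(-(coord[iy] - dots_y[d])^2 / two_s2)
      dev[iy, ix] <- dev[iy, ix] + amp[d] * (gy %o% gx)
    }
  }

  r <- sqrt(outer(coord^2, coord^2, "+"))  # rows = y, cols = x
  env <- aperture_envelope(r, spec$aperture_inner_diam / 2,
                           spec$aperture_outer_diam / 2, spec$edge_ramp)
  img <- 0.5 + dev * env
  img[img < 0] <- 0
  img[img > 1] <- 1
  # flip so that row 1 is the top of the visual field
  img <- img[rev(seq_len(n_px)), , drop = FALSE]
  structure(img, class = c("pattern_image", "matrix", "array"),
            degrees_per_pixel = 1 / ppd)
}

#' Annular raised-cosine aperture envelope
#'
#' Contrast multiplier as a function of eccentricity: 0 for
#' `r <= inner_radius`, raised-cosine 0 to 1 over one ramp width, 1 on the
#' plateau, raised-cosine 1 to 0 over the ramp ending at `outer_radius`,
#' and 0 beyond.
#'
#' @param r Eccentricity (degrees); any numeric shape.
#' @param inner_radius,outer_radius Inner edge and outer edge radii
#'   (degrees).
#' @param ramp Ramp width (degrees).
#' @return Envelope values in `[0, 1]`, same shape as `r`.
#' @export
aperture_envelope <- function(r, inner_radius, outer_radius, ramp) {
  stopifnot(inner_radius >= 0, outer_radius > inner_radius + ramp, ramp > 0)
  env <- r * 0
  rise <- r > inner_radius & r < inner_radius + ramp
  env[rise] <- 0.5 * (1 - cos(pi * (r[rise] - inner_radius) / ramp))
  env[r >= inner_radius + ramp & r <= outer_radius - ramp] <- 1
  fall <- r > outer_radius - ramp & r < outer_radius
  env[fall] <- 0.5 * (1 + cos(pi * (r[fall] - (outer_radius - ramp)) / ramp))
  env
}

#' @export
print.pattern_image <- function(x, ...) {
  cat(sprintf("Glass pattern image: %d x %d pixels, %.4f deg/px\n",
              nrow(x), ncol(x), attr(x, "degrees_per_pixel")))
  cat(sprintf("  luminance range [%.3f, %.3f], mean %.4f\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
plot.pattern_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::image(t(unclass(x))[, rev(seq_len(nrow(x)))],
                  col = grDevices::grey.colors(256, 0, 1), zlim = c(0, 1),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Write a pattern image as an 8-bit grayscale PNG
#'
#' Luminance is quantized as `round(255 * value)`.
#'
#' @param image A `pattern_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_png <- function(image, path) {
  stopifnot(inherits(image, "pattern_image"))
  png::writePNG(round(255 * unclass(image)) / 255, path)
  invisible(path)
}

#' Write a dipole field as TSV
#'
#' @param field A `dipole_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dipole_tsv <- function(field, path) {
  stopifnot(inherits(field, "dipole_field"))
  utils::write.table(as.data.frame(field), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
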