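#' Radiograph container
#'
#' A minimal container for a 2-D grayscale radiograph: a numeric pixel matrix
#' (gray levels, nominally 0-255), the pixel spacing in mm/pixel, and an
#' identifier.
#'
#' @param pixels Numeric matrix of gray levels, `[row, col]`, row 1 at the top.
#' @param spacing Pixel spacing in mm/pixel (scalar, > 0).
#' @param id Optional identifier (character).
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, spacing, id = "") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stopf("apexfa_value_error", "spacing must be a positive scalar (mm/pixel)")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stopf("apexfa_value_error", "pixels must be finite and non-negative")
  }
  structure(list(pixels = pixels, spacing = spacing, id = as.character(id)),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph '%s': %d x %d px, %.3f mm/px, gray range [%.1f, %.1f]>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Phantom parameters for a synthetic periapical radiograph
#'
#' Parameters of the synthetic lesion phantom.  The lesion is an elliptical
#' radiolucency whose radial intensity profile rises from `interior_level` to
#' `exterior_level` along a logistic sigmoid; `transition_width` is the
#' 10 percent to 90 percent rise distance in mm, the operational definition of
#' the grayscale transition zone.  An optional corticated rim adds a bright
#' Gaussian overshoot just outside the edge.  The background carries
#' band-limited "trabecular" texture (white noise blurred at
#' `trabecular_sigma` mm) plus white pixel noise.
#'
#' @param image_size Integer `(rows, cols)` in pixels.
#' @param pixel_spacing mm per pixel.  Default 0.1 mm/px so a 1 mm fragment
#'   square is 10 x 10 px.
#' @param lesion_center `(row, col)` of the lesion center in pixels; default
#'   the image center.
#' @param lesion_diameter Greatest lesion diameter in mm; must lie in
#'   `[5, 15]` (the clinical inclusion range).
#' @param eccentricity Ellipse eccentricity in `[0, 1)`; 0 is a circle.
#' @param transition_width 10-90 percent rise distance in mm; must be
#'   < 1 mm so the transition zone fits centred in a 1 mm square.
#' @param cortication_amplitude Gray-level amplitude of the corticated rim
#'   (0 disables it).
#' @param cortication_sigma Radial width (mm) of the rim overshoot.
#' @param interior_level,exterior_level Gray levels of lesion interior and
#'   surrounding bone; interior must be darker (radiolucent).
#' @param trabecular_sigma Correlation length (mm) of background texture.
#' @param trabecular_amplitude Gray-level SD of background texture.
#' @param noise_sd Gray-level SD of white pixel noise.
#' @param interior_stripes Optional `list(amplitude, period_mm, angle)` adding
#'   an oriented sinusoidal texture to the lesion interior (used to build
#'   anisotropic phantoms).
#' @param seed RNG seed for the noise fields.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(220L, 220L),
                           pixel_spacing = 0.1,
                           lesion_center = NULL,
                           lesion_diameter = 10,
                           eccentricity = 0,
                           transition_width = 0.5,
                           cortication_amplitude = 0,
                           cortication_sigma = 0.15,
                           interior_level = 60,
                           exterior_level = 140,
                           trabecular_sigma = 0.3,
                           trabecular_amplitude = 0,
                           noise_sd = 0,
                           interior_stripes = NULL,
                           seed = 1L) {
  if (lesion_diameter < 5 || lesion_diameter > 15) {
    stopf("apexfa_value_error",
          "lesion_diameter must be within [5, 15] mm (got %.2f)", lesion_diameter)
  }
  if (transition_width <= 0 || transition_width >= 1) {
    stopf("apexfa_value_error",
          "transition_width must be in (0, 1) mm (got %.2f)", transition_width)
  }
  if (eccentricity < 0 || eccentricity >= 1) {
    stopf("apexfa_value_error", "eccentricity must be in [0, 1)")
  }
  if (interior_level >= exterior_level) {
    stopf("apexfa_value_error",
          "interior_level must be below exterior_level (radiolucent lesion)")
  }
  if (is.null(lesion_center)) lesion_center <- (image_size + 1) / 2
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing,
                 lesion_center = lesion_center,
                 lesion_diameter = lesion_diameter,
                 eccentricity = eccentricity,
                 transition_width = transition_width,
                 cortication_amplitude = cortication_amplitude,
                 cortication_sigma = cortication_sigma,
                 interior_level = interior_level,
                 exterior_level = exterior_level,
                 trabecular_sigma = trabecular_sigma,
                 trabecular_amplitude = trabecular_amplitude,
                 noise_sd = noise_sd,
                 interior_stripes = interior_stripes,
                 seed = seed),
            class = "phantom_params")
}

#' Generate a synthetic periapical lesion phantom
#'
#' Renders the elliptical radiolucency described by [phantom_params()] and
#' returns both the radiograph and the ground-truth 50-percent-intensity
#' contour.  With all noise amplitudes at zero the image is an exact analytic
#' sigmoid in the signed radial distance from the contour.
#'
#' @param params A [phantom_params()] object.
#' @return A list with elements `image` ([radiograph]), `contour`
#'   (n x 2 matrix of (row, col) vertices of the true 50 percent contour),
#'   and `truth` (list with the analytic lesion geometry).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  nr <- p$image_size[1]; nc <- p$image_size[2]
  sp <- p$pixel_spacing
  a <- p$lesion_diameter / 2                       # semi-major, mm
  b <- a * sqrt(1 - p$eccentricity^2)              # semi-minor, mm
  # reject lesions whose transition zone leaves the image
  margin_mm <- p$transition_width / 2 + 3 * p$cortication_sigma + 0.2
  cr <- p$lesion_center[1]; cc <- p$lesion_center[2]
  if ((cc - 1) * sp < a + margin_mm || (nc - cc) * sp < a + margin_mm ||
      (cr - 1) * sp < b + margin_mm || (nr - cr) * sp < b + margin_mm) {
    stopf("apexfa_sizing_error",
          "lesion (%.1f x %.1f mm + %.2f mm margin) does not fit in a %d x %d image at %.3f mm/px",
          2 * a, 2 * b, margin_mm, nr, nc, sp)
  }
  dy <- (seq_len(nr) - cr) * sp                    # mm, rows (major axis = cols)
  dx <- (seq_len(nc) - cc) * sp
  DX <- matrix(dx, nr, nc, byrow = TRUE)
  DY <- matrix(dy, nr, nc)
  # signed distance (mm) to the ellipse along the ray from the center:
  # local radius r(theta) = ab / sqrt((b cos)^2 + (a sin)^2)
  rr <- sqrt(DX^2 + DY^2)
  rloc <- a * b / sqrt((b * DX)^2 + (a * DY)^2) * pmax(rr, .Machine$double.eps)
  d_mm <- rr - rloc
  k <- 2 * log(9) / p$transition_width             # logistic rate: 10-90 over tw
  s <- stats::plogis(k * d_mm)                     # 0 inside, 1 outside
  img <- p$interior_level + (p$exterior_level - p$interior_level) * s
  if (p$cortication_amplitude > 0) {
    d0 <- p$transition_width / 2 + p$cortication_sigma
    img <- img + p$cortication_amplitude *
      exp(-(d_mm - d0)^2 / (2 * p$cortication_sigma^2))
  }
  if (!is.null(p$interior_stripes)) {
    st <- p$interior_stripes
    phase <- 2 * pi * (DX * cos(st$angle) + DY * sin(st$angle)) / st$period_mm
    img <- img + (1 - s) * st$amplitude * sin(phase)
  }
  with_local_seed(p$seed, {
    if (p$trabecular_amplitude > 0) {
      w <- matrix(stats::rnorm(nr * nc), nr, nc)
      w <- gaussian_blur(w, p$trabecular_sigma / sp)
      w <- w / stats::sd(w)
      img <- img + s * p$trabecular_amplitude * w
    }
    if (p$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, sd = p$noise_sd), nr, nc)
    }
  })
  img <- pmin(pmax(img, 0), 255)
  theta <- seq(0, 2 * pi, length.out = 361L)[-361L]
  r_theta <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  contour <- cbind(cr + r_theta * sin(theta) / sp,
                   cc + r_theta * cos(theta) / sp)
  list(image = radiograph(img, sp, id = sprintf("phantom_s%d", p$seed)),
       contour = contour,
       truth = list(center = c(cr, cc), semi_axes_mm = c(a = a, b = b),
                    transition_width = p$transition_width,
                    interior_level = p$interior_level,
                    exterior_level = p$exterior_level))
}
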