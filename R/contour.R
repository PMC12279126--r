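#' Trace the closed lesion contour enclosing a seed point
#'
#' Deterministic replacement for operator-guided semi-automatic contouring:
#' the edge map is morphologically closed (disc radius `close_mm`, grown up
#' to `max_close_mm` if needed) to bridge small gaps, the connected region of
#' non-edge pixels containing the seed is extracted, and its outer boundary
#' is smoothed with a periodic Gaussian filter.  The seed plays the role of
#' the operator's click inside the lesion.
#'
#' @param edges An `edge_map` from [canny()] (or a logical matrix).
#' @param seed_point `(row, col)` of a pixel inside the lesion.
#' @param spacing mm per pixel.
#' @param close_mm Initial morphological closing radius in mm (default 0.3).
#' @param max_close_mm Largest closing radius tried before giving up.
#' @param smooth_mm SD (mm of arc) of the periodic contour smoother.
#' @return A `lesion_contour`: list with `vertices` (n x 2 (row, col),
#'   ordered), `closed = TRUE`, and the closing radius used.
#' @export
trace_contour <- function(edges, seed_point, spacing = 0.1,
                          close_mm = 0.3, max_close_mm = 1.0,
                          smooth_mm = 0.3) {
  mask <- if (inherits(edges, "edge_map")) edges$mask else edges
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  sr <- round(seed_point[1]); sc <- round(seed_point[2])
  if (sr < 1 || sr > nr || sc < 1 || sc > nc) {
    stopf("apexfa_contour_error", "seed point outside the image")
  }
  radii <- unique(pmax(1L, round(seq(close_mm, max_close_mm, by = spacing) / spacing)))
  region <- NULL
  used_rad <- NA_real_
  for (rad in radii) {
    brush <- EBImage::makeBrush(2L * rad + 1L, "disc")
    closed <- EBImage::closing(mask * 1, brush) > 0
    if (closed[sr, sc]) next                       # seed swallowed by the closing
    lab <- EBImage::bwlabel(!closed)
    id <- lab[sr, sc]
    if (id == 0) next
    comp <- lab == id
    touches_border <- any(comp[1, ]) || any(comp[nr, ]) ||
      any(comp[, 1]) || any(comp[, nc])
    if (!touches_border) {
      region <- comp
      used_rad <- rad * spacing
      break
    }
  }
  if (is.null(region)) {
    stopf("apexfa_contour_error",
          "no closed region encloses the seed after gap closing up to %.2f mm",
          max_close_mm)
  }
  # outer boundary of the filled seed region, grown by one pixel so the
  # contour runs along the center of the 1-px edge line rather than its
  # inner side; the transition-zone locator later refines this to the
  # 50 percent intensity crossing
  filled <- EBImage::fillHull(region * 1) > 0
  filled <- EBImage::dilate(filled * 1, EBImage::makeBrush(3, "box")) > 0
  oc <- EBImage::ocontour(filled * 1)
  if (length(oc) == 0) stopf("apexfa_contour_error", "empty region boundary")
  verts <- oc[[which.max(vapply(oc, nrow, 1L))]] + 1  # 0-based -> 1-based
  verts <- verts[, c(1, 2), drop = FALSE]             # (dim1, dim2) = (row, col)
  sigma_pts <- smooth_mm / spacing                    # boundary samples ~1 px apart
  verts <- smooth_closed(verts, sigma_pts)
  # normalize orientation: counter-clockwise in (x = col, y = -row) display space
  if (poly_signed_area(verts) < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
  structure(list(vertices = verts, closed = TRUE,
                 close_radius_mm = used_rad, spacing = spacing),
            class = "lesion_contour")
}

#' @export
print.lesion_contour <- function(x, ...) {
  cat(sprintf("<lesion_contour: %d vertices, perimeter %.1f px>\n",
              nrow(x$vertices), poly_perimeter(x$vertices)))
  invisible(x)
}

#' Build the S1/S2/S3 regions of interest from a lesion contour
#'
#' S1 is the filled contour eroded by `inner_margin_mm` (the lesion interior
#' clear of the edge), S2 the filled contour dilated by `outer_margin_mm`
#' (interior plus the edge), and S3 is exactly the pixelwise set difference
#' S2 minus S1 (the boundary annulus).
#'
#' @param contour A `lesion_contour` (or an n x 2 vertex matrix).
#' @param image_size `(rows, cols)` of the target mask.
#' @param spacing mm per pixel.
#' @param inner_margin_mm,outer_margin_mm Margins in mm (defaults 0.5 each).
#' @return A `roi_masks`: list of logical matrices `s1`, `s2`, `s3` plus the
#'   margins used.
#' @export
build_rois <- function(contour, image_size, spacing = 0.1,
                       inner_margin_mm = 0.5, outer_margin_mm = 0.5) {
  verts <- if (inherits(contour, "lesion_contour")) contour$vertices else contour
  if (inner_margin_mm < 0 || outer_margin_mm < 0) {
    stopf("apexfa_value_error", "margins must be >= 0")
  }
  nr <- image_size[1]; nc <- image_size[2]
  fill <- fill_polygon(verts, nr, nc)
  disc <- function(mm) {
    rad <- round(mm / spacing)
    if (rad < 1) return(NULL)
    EBImage::makeBrush(2L * rad + 1L, "disc")
  }
  bi <- disc(inner_margin_mm); bo <- disc(outer_margin_mm)
  s1 <- if (is.null(bi)) fill else EBImage::erode(fill * 1, bi) > 0
  s2 <- if (is.null(bo)) fill else EBImage::dilate(fill * 1, bo) > 0
  if (!any(s1)) {
    stopf("apexfa_margin_error",
          "inner margin %.2f mm erodes the interior to nothing", inner_margin_mm)
  }
  s3 <- s2 & !s1
  structure(list(s1 = s1, s2 = s2, s3 = s3,
                 margins = c(inner_margin_mm = inner_margin_mm,
                             outer_margin_mm = outer_margin_mm)),
            class = "roi_masks")
}

#' @export
print.roi_masks <- function(x, ...) {
  cat(sprintf("<roi_masks: |S1|=%d |S2|=%d |S3|=%d px>\n",
              sum(x$s1), sum(x$s2), sum(x$s3)))
  invisible(x)
}

#' Export ROI masks as a PNG label image and the contour as JSON
#'
#' The label image stores 0 = background, 1 = S1, 2 = S3 (S2 is their union).
#'
#' @param rois A `roi_masks`.
#' @param contour A `lesion_contour`.
#' @param png_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_roi_labels <- function(rois, contour, png_path, json_path) {
  lab <- matrix(0, nrow(rois$s1), ncol(rois$s1))
  lab[rois$s1] <- 1
  lab[rois$s3] <- 2
  png::writePNG(lab / 255, png_path)
  jsonlite::write_json(list(vertices = unname(round(contour$vertices, 3)),
                            closed = TRUE),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, json_path))
}
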