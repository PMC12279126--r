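# Fragment analysis (FA): tile the lesion's grayscale transition zone with
# oriented 1 mm squares and reassemble the fragments into the striped S4
# image.  All geometry is done in continuous pixel coordinates (row, col),
# 1-based, pixel centers at integers.

#' Locate the grayscale transition zone along the lesion boundary
#'
#' For each sample of the contour, the intensity profile along the outward
#' normal is measured by bilinear interpolation.  After normalizing between
#' the inner and outer plateau levels, the 50 percent crossing defines the
#' transition centerline, and the distance between the 10 percent and
#' 90 percent crossings defines the local transition width.  The band mask is
#' the union of the per-normal 10-90 percent segments.
#'
#' @param image A [radiograph].
#' @param contour A `lesion_contour` (or vertex matrix).
#' @param probe_len_mm Length of the probed normal segment (default 2 mm);
#'   it must span the expected transition zone.
#' @param step_mm Arc-length spacing of contour samples (default 0.2 mm).
#' @param max_fail Maximum tolerated fraction of normals without a clean
#'   monotone crossing (default 0.2); failed samples are interpolated from
#'   their neighbours.
#' @return A `transition_band`: list with `centerline` (n x 2, closed,
#'   ordered as the contour), `local_width` (mm per centerline point),
#'   `band_mask` (logical matrix), and `spacing`.
#' @export
locate_transition <- function(image, contour, probe_len_mm = 2,
                              step_mm = 0.2, max_fail = 0.2) {
  stopifnot(inherits(image, "radiograph"))
  verts <- if (inherits(contour, "lesion_contour")) contour$vertices else contour
  sp <- image$spacing
  img <- image$pixels
  n <- max(16L, round(poly_perimeter(verts) * sp / step_mm))
  pts <- resample_closed(verts, n)
  ctr <- poly_centroid(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  tang <- nxt - prv
  tang <- tang / pmax(sqrt(rowSums(tang^2)), .Machine$double.eps)
  nrm <- cbind(tang[, 2], -tang[, 1])              # rotate tangent by 90 deg
  # orient normals outward (away from the centroid)
  flip <- rowSums(nrm * sweep(pts, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  half <- probe_len_mm / 2 / sp                     # px
  offs <- seq(-half, half, by = 0.25)               # px along the normal
  n_off <- length(offs)
  R <- outer(pts[, 1], rep(1, n_off)) + outer(nrm[, 1], offs)
  C <- outer(pts[, 2], rep(1, n_off)) + outer(nrm[, 2], offs)
  prof <- matrix(bilinear_sample(img, as.vector(R), as.vector(C)), n, n_off)
  # light smoothing along the profile
  sm <- prof
  sm[, 2:(n_off - 1)] <- (prof[, 1:(n_off - 2)] + prof[, 2:(n_off - 1)] +
                            prof[, 3:n_off]) / 3
  n_in <- max(2L, round(n_off * 0.15))
  i_lo <- rowMeans(sm[, seq_len(n_in), drop = FALSE], na.rm = TRUE)
  i_hi <- rowMeans(sm[, n_off - seq_len(n_in) + 1L, drop = FALSE], na.rm = TRUE)
  s50 <- s10 <- s90 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    u <- (sm[i, ] - i_lo[i]) / (i_hi[i] - i_lo[i])
    if (!is.finite(i_lo[i]) || !is.finite(i_hi[i]) || (i_hi[i] - i_lo[i]) < 5) next
    cross_up <- function(level, from = 1L, to = n_off) {
      for (k in seq(from, to - 1L)) {
        if (!is.na(u[k]) && !is.na(u[k + 1]) && u[k] < level && u[k + 1] >= level) {
          return(k + (level - u[k]) / (u[k + 1] - u[k]))
        }
      }
      NA_real_
    }
    k50 <- cross_up(0.5)
    if (is.na(k50)) next
    k10 <- NA_real_
    for (k in seq(floor(k50), 2L)) {
      if (!is.na(u[k]) && !is.na(u[k - 1]) && u[k] >= 0.1 && u[k - 1] < 0.1) {
        k10 <- k - 1 + (0.1 - u[k - 1]) / (u[k] - u[k - 1]); break
      }
    }
    k90 <- cross_up(0.9, from = ceiling(k50))
    if (is.na(k10) || is.na(k90)) next
    s50[i] <- offs[1] + (k50 - 1) * 0.25
    s10[i] <- offs[1] + (k10 - 1) * 0.25
    s90[i] <- offs[1] + (k90 - 1) * 0.25
  }
  bad <- is.na(s50)
  if (mean(bad) > max_fail) {
    stopf("apexfa_transition_error",
          "no monotone intensity crossing on %.0f%% of boundary normals (max %.0f%%)",
          100 * mean(bad), 100 * max_fail)
  }
  fill_circular <- function(v) {
    if (!any(is.na(v))) return(v)
    idx <- which(!is.na(v))
    for (i in which(is.na(v))) {
      d <- pmin(abs(idx - i), n - abs(idx - i))
      v[i] <- v[idx[which.min(d)]]
    }
    v
  }
  s50 <- fill_circular(s50); s10 <- fill_circular(s10); s90 <- fill_circular(s90)
  centerline <- pts + nrm * s50
  # light periodic smoothing; a wide window would shrink small closed
  # centerlines noticeably (radius bias ~ sigma^2 / 2r)
  centerline <- smooth_closed(centerline, 1)
  width_mm <- pmax((s90 - s10) * sp, sp)            # floor: one pixel quantum
  # rasterize the 10-90 band
  band <- matrix(FALSE, nrow(img), ncol(img))
  for (i in seq_len(n)) {
    seg <- seq(s10[i], s90[i], by = 0.5)
    rr <- round(pts[i, 1] + nrm[i, 1] * seg)
    cc <- round(pts[i, 2] + nrm[i, 2] * seg)
    ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
    band[cbind(rr[ok], cc[ok])] <- TRUE
  }
  structure(list(centerline = centerline, local_width = width_mm,
                 band_mask = band, spacing = sp),
            class = "transition_band")
}

#' @export
print.transition_band <- function(x, ...) {
  cat(sprintf("<transition_band: %d centerline pts, width %.2f [%.2f-%.2f] mm, %d band px>\n",
              nrow(x$centerline), stats::median(x$local_width),
              min(x$local_width), max(x$local_width), sum(x$band_mask)))
  invisible(x)
}

# point on closed polyline at arc position s (wrapped); P closed n x 2
polyline_point <- function(P, cum, s) {
  total <- cum[length(cum)]
  s <- s %% total
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= length(cum)] <- length(cum) - 1L
  t <- (s - cum[i]) / (cum[i + 1L] - cum[i])
  P[i, , drop = FALSE] * (1 - t) + P[i + 1L, , drop = FALSE] * t
}

square_polygon <- function(center, angle, side_px) {
  t <- c(cos(angle), sin(angle)) * side_px / 2      # (drow, dcol) along tangent
  m <- c(-sin(angle), cos(angle)) * side_px / 2     # normal
  rbind(center + t + m, center + t - m, center - t - m, center - t + m)
}

#' Tile the transition-zone centerline with oriented 1 mm squares
#'
#' Greedy arc-length march: starting from the topmost centerline point and
#' proceeding clockwise (as displayed), squares of side `side_mm` are centred
#' on the centerline with one side parallel to the local tangent
#' (central difference over +/- `side_mm / 2` of arc).  Each step advances by
#' exactly one chord of `side_mm`, so consecutive squares meet at the
#' centerline; if the final square overlaps the first by more than half a
#' pixel of area it is dropped.
#'
#' @param band A `transition_band` (or a closed centerline matrix).
#' @param spacing mm per pixel.
#' @param side_mm Square side in mm (default 1.0, the FA definition).
#' @param closure Closure rule for the ring: `"distribute"` (default)
#'   re-marches with a chord adjusted by at most half a square so an integer
#'   number of squares closes the ring symmetrically; `"drop"` marches with
#'   the exact `side_mm` chord and drops the final square when it overlaps
#'   the first by more than half a pixel of area, leaving the closure gap at
#'   one joint.
#' @return A `boundary_tiling`: list with `centers` (k x 2), `angles`
#'   (radians), `polys` (list of 4 x 2 corner matrices), `side_px`,
#'   `side_mm`, `order_origin`.
#' @export
tile_boundary <- function(band, spacing = NULL, side_mm = 1.0,
                          closure = c("distribute", "drop")) {
  closure <- match.arg(closure)
  if (inherits(band, "transition_band")) {
    P <- band$centerline
    spacing <- band$spacing
  } else {
    P <- band
    if (is.null(spacing)) stopf("apexfa_value_error", "spacing required")
  }
  side_px <- side_mm / spacing
  Pc <- rbind(P, P[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(Pc)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  extent <- sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
  if (total < side_px || extent < side_px) {
    stopf("apexfa_tiling_error",
          "centerline (arc %.2f mm, extent %.2f mm) is too small for a %.1f mm square",
          total * spacing, extent * spacing, side_mm)
  }
  # start at the topmost point (min row, ties by min col)
  i0 <- which(P[, 1] == min(P[, 1]))
  i0 <- i0[which.min(P[i0, 2])]
  # proceed clockwise as displayed (positive shoelace in (col,row) = clockwise
  # on screen with row increasing downward)
  if (poly_signed_area(P) < 0) {
    P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    i0 <- nrow(P) + 1L - i0
    Pc <- rbind(P, P[1, , drop = FALSE])
    seg <- sqrt(rowSums(diff(Pc)^2))
    cum <- c(0, cumsum(seg))
  }
  s0 <- cum[i0]
  tangent_at <- function(s) {
    h <- side_px / 2
    d <- polyline_point(Pc, cum, s + h) - polyline_point(Pc, cum, s - h)
    atan2(d[2], d[1])                                # angle in (row, col) plane
  }
  # advance from arc position s by one chord of the given length
  advance_chord <- function(s, chord_len) {
    c0 <- polyline_point(Pc, cum, s)
    lo <- s; hi <- s + chord_len
    chord <- function(sx) sqrt(sum((polyline_point(Pc, cum, sx) - c0)^2))
    while (chord(hi) < chord_len) {
      hi <- hi + chord_len / 4
      if (hi - s > 3 * chord_len) return(s + chord_len)  # degenerate polyline
    }
    for (it in 1:28) {
      mid <- (lo + hi) / 2
      if (chord(mid) < chord_len) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  march <- function(chord_len, n_steps = NULL) {
    svals <- s0
    s <- s0
    n_cap <- if (is.null(n_steps)) ceiling(total / side_px) + 5L else n_steps - 1L
    repeat {
      s_next <- advance_chord(s, chord_len)
      if (is.null(n_steps) && s_next - s0 >= total - side_px / 2) break
      if (length(svals) > n_cap) break
      svals <- c(svals, s_next)
      s <- s_next
    }
    svals
  }
  svals <- march(side_px)
  if (closure == "distribute") {
    # choose the square count that best matches an exact-side march, then
    # adjust the chord (by at most ~ side / 2) so n steps close the ring
    s_end <- advance_chord(svals[length(svals)], side_px)
    leftover <- (total - (s_end - s0)) / side_px
    n <- length(svals) + as.integer(leftover >= 0.5)   # round to nearest count
    gap_end <- function(chord_len) {
      sv <- march(chord_len, n_steps = n)
      (total - (advance_chord(sv[length(sv)], chord_len) - s0))
    }
    lo <- side_px * 0.8; hi <- side_px * 1.25
    for (it in 1:25) {
      mid <- (lo + hi) / 2
      if (gap_end(mid) > 0) lo <- mid else hi <- mid
    }
    svals <- march((lo + hi) / 2, n_steps = n)
  }
  centers <- lapply(svals, function(s) polyline_point(Pc, cum, s)[1, ])
  angles <- vapply(svals, tangent_at, 0)
  polys <- mapply(function(i) square_polygon(centers[[i]], angles[i], side_px),
                  seq_along(centers), SIMPLIFY = FALSE)
  if (closure == "drop" && length(polys) > 2 &&
      poly_intersection_area(polys[[length(polys)]], polys[[1]]) > 0.5) {
    k <- length(polys)
    polys <- polys[-k]; centers <- centers[-k]
    angles <- angles[-k]; svals <- svals[-k]
  }
  structure(list(centers = do.call(rbind, centers), angles = angles,
                 arc_pos = svals, polys = polys,
                 side_px = side_px, side_mm = side_mm, spacing = spacing,
                 order_origin = "topmost point, clockwise"),
            class = "boundary_tiling")
}

#' @export
print.boundary_tiling <- function(x, ...) {
  cat(sprintf("<boundary_tiling: %d squares of %.1f mm (%.1f px)>\n",
              length(x$polys), x$side_mm, x$side_px))
  invisible(x)
}

#' Geometric quality checks for a boundary tiling
#'
#' Computes the pairwise square-overlap areas (separately for
#' non-consecutive pairs, which must be disjoint, and consecutive pairs,
#' which may share a sub-pixel seam wedge on a curved boundary), the
#' adjacency gaps between consecutive squares, and the fraction of the
#' transition band covered by the union of squares.  Coverage is cell-based:
#' a band pixel counts as covered when its 1-pixel cell meets some square
#' (i.e. its center lies within half a pixel of the square union).
#'
#' @param tiling A `boundary_tiling`.
#' @param band The `transition_band` it was built from (optional; needed for
#'   coverage).
#' @return A list: `max_overlap_px2` (non-consecutive pairs),
#'   `max_consecutive_overlap_px2`, `max_gap_px` (polygon distance between
#'   consecutive squares), `coverage` (NA without a band), `n_squares`.
#' @export
tiling_qc <- function(tiling, band = NULL) {
  polys <- tiling$polys
  k <- length(polys)
  max_ov <- 0; max_ov_cons <- 0; max_gap <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      consecutive <- (j == i + 1L) || (i == 1L && j == k)
      # only nearby squares can interact
      if (sqrt(sum((tiling$centers[i, ] - tiling$centers[j, ])^2)) >
          2 * tiling$side_px) next
      ov <- poly_intersection_area(polys[[i]], polys[[j]])
      if (consecutive) {
        max_ov_cons <- max(max_ov_cons, ov)
        if (ov == 0) max_gap <- max(max_gap, poly_distance(polys[[i]], polys[[j]]))
      } else {
        max_ov <- max(max_ov, ov)
      }
    }
  }
  coverage <- NA_real_
  if (!is.null(band)) {
    idx <- which(band$band_mask, arr.ind = TRUE)
    inside <- rep(FALSE, nrow(idx))
    grow <- function(p, by) {
      ctr <- colMeans(p)
      f <- 1 + by / (tiling$side_px / 2)
      t(f * (t(p) - ctr) + ctr)
    }
    for (p in polys) {
      if (all(inside)) break
      pg <- grow(p, 0.5)
      rem <- which(!inside)
      inside[rem] <- point_in_convex(idx[rem, 1], idx[rem, 2], pg)
    }
    coverage <- mean(inside)
  }
  list(max_overlap_px2 = max_ov, max_consecutive_overlap_px2 = max_ov_cons,
       max_gap_px = max_gap, coverage = coverage, n_squares = k)
}

# vectorized point-in-convex-polygon (boundary counts as inside)
point_in_convex <- function(r, c, poly) {
  n <- nrow(poly)
  sgn <- NULL
  inside <- rep(TRUE, length(r))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1L, ]
    cr <- (b[2] - a[2]) * (r - a[1]) - (b[1] - a[1]) * (c - a[2])
    if (is.null(sgn)) {
      s_ref <- (b[2] - a[2]) * (poly[((i + 1L) %% n) + 1L, 1] - a[1]) -
        (b[1] - a[1]) * (poly[((i + 1L) %% n) + 1L, 2] - a[2])
      sgn <- sign(s_ref)
    }
    inside <- inside & (sgn * cr >= -1e-9)
  }
  inside
}

#' Extract oriented boundary fragments
#'
#' Each square is resampled on a `side_px` x `side_px` grid by bilinear
#' interpolation in the square's own frame, oriented so that the lesion
#' interior occupies the LEFT half of every fragment (columns run along the
#' outward normal).
#'
#' @param image A [radiograph].
#' @param tiling A `boundary_tiling` from [tile_boundary()].
#' @param interior_point `(row, col)` of a point inside the lesion (used to
#'   orient the outward normal); defaults to the tiling centroid.
#' @return A `fragment_set`: list with `fragments` (list of side x side
#'   matrices), `tiling`, `side_px` (integer).
#' @export
extract_fragments <- function(image, tiling, interior_point = NULL) {
  stopifnot(inherits(image, "radiograph"), inherits(tiling, "boundary_tiling"))
  img <- image$pixels
  side_px <- max(2L, round(tiling$side_mm / image$spacing))
  if (is.null(interior_point)) interior_point <- colMeans(tiling$centers)
  k <- nrow(tiling$centers)
  u <- (seq_len(side_px) - (side_px + 1) / 2) * tiling$side_px / side_px
  frags <- vector("list", k)
  for (i in seq_len(k)) {
    ang <- tiling$angles[i]
    tv <- c(cos(ang), sin(ang))                     # tangent (drow, dcol)
    nv <- c(-sin(ang), cos(ang))                    # normal
    # make the normal point outward
    if (sum(nv * (tiling$centers[i, ] - interior_point)) < 0) nv <- -nv
    # rows along the tangent, columns along the outward normal (interior left)
    R <- outer(u, rep(1, side_px)) * tv[1] + outer(rep(1, side_px), u) * nv[1] +
      tiling$centers[i, 1]
    C <- outer(u, rep(1, side_px)) * tv[2] + outer(rep(1, side_px), u) * nv[2] +
      tiling$centers[i, 2]
    vals <- bilinear_sample(img, as.vector(R), as.vector(C))
    if (any(is.na(vals))) {
      stopf("apexfa_extraction_error",
            "square %d exceeds the image bounds", i)
    }
    frags[[i]] <- matrix(vals, side_px, side_px)
  }
  structure(list(fragments = frags, tiling = tiling, side_px = side_px,
                 order_origin = tiling$order_origin),
            class = "fragment_set")
}

#' Reassemble fragments into the striped S4 image
#'
#' Fragments are concatenated left to right in centerline order (topmost
#' point, clockwise).  Because every fragment has the dark lesion interior on
#' its left half and brighter bone on its right, the reassembled image shows
#' the characteristic light and dark vertical stripes.
#'
#' @param frags A `fragment_set`.
#' @return An `s4_image`: list with `pixels` (side_px x n*side_px matrix) and
#'   `provenance` (fragment order).
#' @export
reassemble <- function(frags) {
  stopifnot(inherits(frags, "fragment_set"))
  f <- frags$fragments
  if (length(f) < 1) stopf("apexfa_assembly_error", "no fragments")
  sizes <- vapply(f, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(sizes)) != 1) {
    stopf("apexfa_assembly_error", "fragments differ in size: %s",
          paste(unique(sizes), collapse = ", "))
  }
  structure(list(pixels = do.call(cbind, f),
                 provenance = list(n_fragments = length(f),
                                   side_px = frags$side_px,
                                   order_origin = frags$order_origin)),
            class = "s4_image")
}

#' @export
print.s4_image <- function(x, ...) {
  cat(sprintf("<s4_image: %d x %d px (%d fragments)>\n",
              nrow(x$pixels), ncol(x$pixels), x$provenance$n_fragments))
  invisible(x)
}

#' Export a tiling as JSON (centers, angles, order)
#' @param tiling A `boundary_tiling`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_tiling_json <- function(tiling, path) {
  jsonlite::write_json(list(centers = unname(round(tiling$centers, 3)),
                            angles = round(tiling$angles, 5),
                            side_mm = tiling$side_mm,
                            order_origin = tiling$order_origin),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
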