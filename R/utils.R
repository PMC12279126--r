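# Internal numerical and geometric utilities shared across modules.
# Conventions: images are plain numeric matrices indexed [row, col], 1-based,
# row 1 at the top when displayed; continuous coordinates place pixel centers
# at integer (row, col).

#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Stage seeds derived from a master seed; kept well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# fast grouped sum for small non-negative integer groups 0..(nbins-1)
tapply_sum <- function(x, group, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  out
}

stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "apexfa_error")))
}

#' @noRd
# Vectorized bilinear interpolation; coordinates outside the image yield NA.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  val <- img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
  out[ok] <- val
  out
}

gaussian_kernel <- function(sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with edge replication, implemented as shifted adds.
conv_sep <- function(img, kernel) {
  pad <- (length(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  idx_rep <- function(n) c(rep(1L, pad), seq_len(n), rep(n, pad))
  padded <- img[idx_rep(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * padded[seq_len(nr) + (k - 1L), , drop = FALSE]
  }
  padded <- out[, idx_rep(nc), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * padded[, seq_len(nc) + (k - 1L), drop = FALSE]
  }
  out
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep(img, gaussian_kernel(sigma))
}

# ---- polygon helpers -------------------------------------------------------
# Polygons are n x 2 matrices of (row, col) vertices, implicitly closed
# (last vertex connects back to the first).

poly_signed_area <- function(p) {
  # Shoelace in (x = col, y = row) coordinates.  With row increasing
  # downwards, a positive value means the vertices run clockwise on screen.
  x <- p[, 2]; y <- p[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_perimeter <- function(p) {
  d <- sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2))
  sum(d)
}

poly_centroid <- function(p) colMeans(p)

# Resample a closed polyline to n points at uniform arc length.
resample_closed <- function(p, n) {
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= nrow(q)] <- nrow(q) - 1L
  t <- (s - cum[i]) / pmax(seg[i], .Machine$double.eps)
  q[i, , drop = FALSE] * (1 - t) + q[i + 1L, , drop = FALSE] * t
}

# Circular (periodic) smoothing of a closed polyline with a Gaussian window
# measured in vertices.
smooth_closed <- function(p, sigma_pts) {
  if (sigma_pts <= 0) return(p)
  n <- nrow(p)
  radius <- min(max(1L, ceiling(3 * sigma_pts)), n %/% 2L)
  w <- exp(-(seq(-radius, radius))^2 / (2 * sigma_pts^2))
  w <- w / sum(w)
  sm <- function(v) {
    out <- numeric(n)
    for (k in seq_along(w)) {
      sh <- k - radius - 1L
      out <- out + w[k] * v[((seq_len(n) - 1L + sh) %% n) + 1L]
    }
    out
  }
  cbind(sm(p[, 1]), sm(p[, 2]))
}

# Scanline even-odd fill of a closed polygon into a logical mask.
fill_polygon <- function(p, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  y1 <- p[, 1]; x1 <- p[, 2]
  y2 <- c(y1[-1], y1[1]); x2 <- c(x1[-1], x1[1])
  rmin <- max(1L, floor(min(y1))); rmax <- min(nrow, ceiling(max(y1)))
  for (r in rmin:rmax) {
    cross <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(cross)) next
    t <- (r - y1[cross]) / (y2[cross] - y1[cross])
    xs <- sort(x1[cross] + t * (x2[cross] - x1[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k]); b <- floor(xs[k + 1])
      if (a <= b) mask[r, max(1L, a):min(ncol, b)] <- TRUE
    }
  }
  mask
}

# Sutherland-Hodgman clipping of a convex subject polygon by a convex clip
# polygon; returns the intersection polygon (possibly 0 rows).
clip_convex <- function(subject, clip) {
  # ensure clip is counter-clockwise in (x=col, y=row) math orientation
  if (poly_signed_area(clip) > 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[e, ]; b <- clip[(e %% nc) + 1L, ]
    ex <- b[2] - a[2]; ey <- b[1] - a[1]
    inside <- function(p) (ex * (p[, 1] - a[1]) - ey * (p[, 2] - a[2])) <= 1e-12
    inp <- out
    flags <- inside(inp)
    res <- matrix(numeric(0), 0, 2)
    np <- nrow(inp)
    for (i in seq_len(np)) {
      j <- (i %% np) + 1L
      pi_ <- inp[i, ]; pj <- inp[j, ]
      fi <- flags[i]; fj <- flags[j]
      if (fi) res <- rbind(res, pi_)
      if (xor(fi, fj)) {
        di <- ex * (pi_[1] - a[1]) - ey * (pi_[2] - a[2])
        dj <- ex * (pj[1] - a[1]) - ey * (pj[2] - a[2])
        t <- di / (di - dj)
        res <- rbind(res, pi_ + t * (pj - pi_))
      }
    }
    out <- res
  }
  out
}

poly_intersection_area <- function(p, q) {
  inter <- clip_convex(p, q)
  if (nrow(inter) < 3) return(0)
  abs(poly_signed_area(inter))
}

# Minimum distance between the vertices/edges of two convex polygons
# (0 when they touch or overlap).
poly_distance <- function(p, q) {
  if (poly_intersection_area(p, q) > 0) return(0)
  seg_pt <- function(a, b, pts) {
    ab <- b - a
    t <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) /
                           sum(ab^2)))
    proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2])
    sqrt(rowSums((pts - proj)^2))
  }
  d <- Inf
  np <- nrow(p); nq <- nrow(q)
  for (i in seq_len(np)) {
    a <- p[i, ]; b <- p[(i %% np) + 1L, ]
    d <- min(d, seg_pt(a, b, q))
  }
  for (i in seq_len(nq)) {
    a <- q[i, ]; b <- q[(i %% nq) + 1L, ]
    d <- min(d, seg_pt(a, b, p))
  }
  d
}
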