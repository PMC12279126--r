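#' Canny edge detection
#'
#' Full Canny chain: Gaussian smoothing, central-difference gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis in which weak edge pixels survive only when
#' 8-connected to a strong pixel.
#'
#' Thresholds are interpreted on the 0-255 gray-level scale, in units of gray
#' levels per pixel of gradient magnitude; images whose maximum exceeds 255
#' (e.g. 16-bit input) are rescaled to 0-255 before the chain so that the
#' default 35/50 double threshold is meaningful across bit depths.
#'
#' @param image A [radiograph] or a numeric matrix.
#' @param sigma Gaussian smoothing SD in pixels (default 1.4).
#' @param low,high Lower/upper hysteresis thresholds (defaults 35 and 50).
#' @return An `edge_map`: list with `mask` (logical matrix, same shape as the
#'   image) and the parameters used.
#' @export
canny <- function(image, sigma = 1.4, low = 35, high = 50) {
  img <- if (inherits(image, "radiograph")) image$pixels else image
  stopifnot(is.matrix(img))
  if (low >= high) stopf("apexfa_value_error", "low must be < high")
  if (sigma <= 0) stopf("apexfa_value_error", "sigma must be > 0")
  mx <- max(img)
  if (mx > 255) img <- img * (255 / mx)
  sm <- gaussian_blur(img, sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  gx <- (shift(sm, 0, 1) - shift(sm, 0, -1)) / 2   # along columns
  gy <- (shift(sm, 1, 0) - shift(sm, -1, 0)) / 2   # along rows
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                              # (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi                 # direction mod pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: horizontal gradient -> compare left/right neighbours, etc.
  n1 <- matrix(0, nr, nc); n2 <- matrix(0, nr, nc)
  for (s in 0:3) {
    dd <- switch(s + 1L,
                 c(0L, 1L),     # 0 deg gradient: neighbours along columns
                 c(1L, 1L),     # 45 deg
                 c(1L, 0L),     # 90 deg: along rows
                 c(1L, -1L))    # 135 deg
    sel <- sector == s
    a <- shift(mag, dd[1], dd[2]); b <- shift(mag, -dd[1], -dd[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  nms <- mag >= n1 & mag > n2 & mag > 0             # one strict side breaks plateaus
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  mask <- weak
  if (any(strong) && any(weak & !strong)) {
    lab <- EBImage::bwlabel(weak)
    keep <- unique(lab[strong])
    mask <- matrix(lab %in% keep[keep > 0], nr, nc)
  } else if (!any(strong)) {
    mask <- matrix(FALSE, nr, nc)
  }
  structure(list(mask = mask, sigma = sigma, low = low, high = high),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map %d x %d: %d edge px (sigma=%.2f, low=%g, high=%g)>\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$sigma, x$low, x$high))
  invisible(x)
}
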