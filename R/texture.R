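# MaZda-convention texture features: histogram statistics on raw gray
# levels, GLCM statistics S(d,theta)* on mu +/- k sigma normalized,
# G-level-quantized ROIs, and GLRLM run statistics.  Angles are measured in
# image coordinates with theta = 0 horizontal (along a row); co-occurrence
# matrices are symmetric and normalized to sum 1; logarithms are natural
# with 0 log 0 = 0.

#' Quantize a region of interest to G gray levels
#'
#' Intensities in the ROI are clipped to `mu +/- clip_k * sigma` (mean and SD
#' over the ROI) and binned uniformly to `G` levels `0 .. G-1`.  A
#' zero-variance ROI maps every pixel to level `floor(G / 2)`.
#'
#' @param image Numeric matrix or [radiograph].
#' @param roi_mask Logical matrix; pixels outside the ROI are ignored.
#' @param G Number of gray levels (default 64; a power of two).
#' @param clip_k Clip width in SDs (default 3).
#' @return A `quantized_roi`: list with `levels` (integer matrix, NA outside
#'   the ROI), `G`, and the normalization `(mu, sigma)`.
#' @export
quantize <- function(image, roi_mask, G = 64L, clip_k = 3) {
  img <- if (inherits(image, "radiograph")) image$pixels else image
  stopifnot(is.matrix(img), is.logical(roi_mask), all(dim(img) == dim(roi_mask)))
  if (G < 2) stopf("apexfa_value_error", "G must be >= 2")
  if (!any(roi_mask)) stopf("apexfa_value_error", "empty ROI")
  v <- img[roi_mask]
  mu <- mean(v); sg <- stats::sd(v)
  lev <- matrix(NA_integer_, nrow(img), ncol(img))
  if (!is.finite(sg) || sg == 0) {
    lev[roi_mask] <- as.integer(G %/% 2)
  } else {
    # clip window intersected with the observed range, so a very wide
    # clip_k degrades to plain min-max binning
    lo <- max(mu - clip_k * sg, min(v)); hi <- min(mu + clip_k * sg, max(v))
    x <- pmin(pmax(v, lo), hi)
    q <- floor((x - lo) / (hi - lo) * G)
    lev[roi_mask] <- as.integer(pmin(q, G - 1))
  }
  structure(list(levels = lev, G = as.integer(G),
                 normalization = c(mu = mu, sigma = sg), clip_k = clip_k),
            class = "quantized_roi")
}

glcm_offset <- function(d, theta) {
  switch(as.character(theta),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stopf("apexfa_value_error", "theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence probabilities at offset distance `d` and angle
#' `theta`; both pixels of a pair must lie inside the ROI.
#'
#' @param q A `quantized_roi`.
#' @param d Offset distance in pixels (>= 1).
#' @param theta Angle in degrees, one of 0, 45, 90, 135.
#' @return A `G x G` matrix summing to 1.
#' @export
glcm <- function(q, d, theta) {
  stopifnot(inherits(q, "quantized_roi"))
  if (d < 1) stopf("apexfa_value_error", "d must be >= 1")
  off <- glcm_offset(as.integer(d), theta)
  lev <- q$levels; G <- q$G
  nr <- nrow(lev); nc <- ncol(lev)
  r_lo <- max(1L, 1L - off[1]); r_hi <- min(nr, nr - off[1])
  c_lo <- max(1L, 1L - off[2]); c_hi <- min(nc, nc - off[2])
  if (r_lo > r_hi || c_lo > c_hi) {
    stopf("apexfa_glcm_error", "no valid pixel pairs at d=%d, theta=%s", d, theta)
  }
  r1 <- r_lo:r_hi
  c1 <- c_lo:c_hi
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    stopf("apexfa_glcm_error", "no valid pixel pairs at d=%d, theta=%s", d, theta)
  }
  idx <- a[ok] * G + b[ok] + 1L
  counts <- tabulate(idx, nbins = G * G)
  P <- matrix(counts, G, G, byrow = TRUE)           # row = first pixel level
  P <- P + t(P)                                     # count both directions
  P / sum(P)
}

#' The 11 MaZda GLCM statistics
#'
#' Computes angular second moment, contrast, correlation, sum of squares,
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance and difference entropy from a normalized
#' co-occurrence matrix.  Names are prefixed `"S(d,theta)"` so, e.g., the
#' contrast at distance 5 and angle 0 is `S(5,0)Contrast`.
#'
#' @param P Normalized `G x G` co-occurrence matrix (sums to 1).
#' @param d,theta Offset used (only for naming).
#' @return Named numeric vector of 11 features.
#' @export
glcm_features <- function(P, d = 1, theta = 0) {
  if (abs(sum(P) - 1) > 1e-8) {
    stopf("apexfa_contract_error", "co-occurrence matrix must be normalized")
  }
  G <- nrow(P)
  i <- matrix(0:(G - 1), G, G)                      # level of first pixel
  j <- t(i)
  px <- rowSums(P)
  mu <- sum((0:(G - 1)) * px)                       # symmetric: mux = muy
  sg2 <- sum(((0:(G - 1)) - mu)^2 * px)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # distributions of i+j (0..2G-2) and |i-j| (0..G-1)
  pv <- as.vector(P)
  psum <- as.vector(tapply_sum(pv, as.vector(i + j), 2 * G - 1L))
  pdif <- as.vector(tapply_sum(pv, as.vector(abs(i - j)), G))
  ksum <- 0:(2 * G - 2); kdif <- 0:(G - 1)
  sum_avg <- sum(ksum * psum)
  feats <- c(
    AngScMom = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Correlat = if (sg2 > 0) (sum(i * j * P) - mu^2) / sg2 else 0,
    SumOfSqs = sum((i - mu)^2 * P),
    InvDfMom = sum(P / (1 + (i - j)^2)),
    SumAverg = sum_avg,
    SumVarnc = sum((ksum - sum_avg)^2 * psum),
    SumEntrp = -sum(xlogx(psum)),
    Entropy = -sum(xlogx(P)),
    DifVarnc = sum((kdif - sum(kdif * pdif))^2 * pdif),
    DifEntrp = -sum(xlogx(pdif))
  )
  names(feats) <- paste0(sprintf("S(%d,%d)", d, theta), names(feats))
  feats
}

#' Gray-level run-length features
#'
#' Builds the run-length matrix of maximal constant-level runs inside the
#' ROI along the given direction (runs break at ROI boundaries) and returns
#' the five classical statistics: short-run emphasis, long-run emphasis,
#' gray-level nonuniformity, run-length nonuniformity, and run fraction
#' (runs per ROI pixel).  Names carry the direction, e.g. `R(0)ShrtREmph`.
#'
#' @param q A `quantized_roi`.
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @return Named numeric vector of 5 features.
#' @export
glrlm_features <- function(q, theta = 0) {
  stopifnot(inherits(q, "quantized_roi"))
  lev <- q$levels
  if (!any(!is.na(lev))) stopf("apexfa_value_error", "empty ROI")
  nr <- nrow(lev); nc <- ncol(lev)
  # split the ROI into maximal lines along the direction; runs break at NA
  # (outside-ROI) pixels, so NAs are replaced by unique sentinels first
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  key <- switch(as.character(theta),
                "0"   = ri,            # along a row
                "90"  = ci,            # along a column
                "45"  = ri + ci,       # anti-diagonal
                "135" = ri - ci,       # diagonal
                stopf("apexfa_value_error", "theta must be one of 0, 45, 90, 135"))
  v <- as.integer(lev)
  na_idx <- is.na(v)
  v[na_idx] <- -seq_len(sum(na_idx))                # sentinel: breaks all runs
  lines <- split(v, as.vector(key))                 # within-line order preserved
  run_len <- integer(0); run_lev <- integer(0)
  for (ln in lines) {
    r <- rle(ln)
    keep <- r$values >= 0
    if (any(keep)) {
      run_len <- c(run_len, r$lengths[keep])
      run_lev <- c(run_lev, r$values[keep])
    }
  }
  R <- length(run_len)
  if (R == 0) stopf("apexfa_value_error", "ROI contains no runs")
  np <- sum(!is.na(lev))
  rj <- tabulate(run_len)                           # runs of each length
  ri <- tabulate(run_lev + 1L, nbins = q$G)         # runs of each level
  jj <- seq_along(rj)
  feats <- c(ShrtREmph = sum(rj / jj^2) / R,
             LngREmph = sum(rj * jj^2) / R,
             GLevNonUn = sum(ri^2) / R,
             RLNonUni = sum(rj^2) / R,
             Fraction = R / np)
  names(feats) <- paste0(sprintf("R(%d)", as.integer(theta)), names(feats))
  feats
}

#' Histogram features of raw ROI intensities
#'
#' Mean, variance, skewness, excess kurtosis (population moments) and the
#' 1/10/50/90/99 percentiles of the unquantized gray levels in the ROI.
#'
#' @param image Numeric matrix or [radiograph].
#' @param roi_mask Logical matrix.
#' @return Named numeric vector of 9 features.
#' @export
histogram_features <- function(image, roi_mask) {
  img <- if (inherits(image, "radiograph")) image$pixels else image
  if (!any(roi_mask)) stopf("apexfa_value_error", "empty ROI")
  v <- img[roi_mask]
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sk <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - m)^4) / m2^2 - 3 else 0
  qs <- stats::quantile(v, c(0.01, 0.1, 0.5, 0.9, 0.99), names = FALSE)
  c(HistMean = m, HistVariance = m2, HistSkewness = sk, HistKurtosis = ku,
    HistPerc01 = qs[1], HistPerc10 = qs[2], HistPerc50 = qs[3],
    HistPerc90 = qs[4], HistPerc99 = qs[5])
}

texture_features_roi <- function(image, roi_mask, G = 64L, clip_k = 3,
                                 d_set = 1:5, thetas = c(0, 45, 90, 135)) {
  img <- if (inherits(image, "radiograph")) image$pixels else image
  # crop to the ROI bounding box: big speedup, identical features
  idx <- which(roi_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("apexfa_value_error", "empty ROI")
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  image <- img[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  roi_mask <- roi_mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  q <- quantize(image, roi_mask, G = G, clip_k = clip_k)
  out <- histogram_features(image, roi_mask)
  for (d in d_set) {
    for (th in thetas) {
      f <- tryCatch(glcm_features(glcm(q, d, th), d, th),
                    apexfa_glcm_error = function(e) {
                      warning(conditionMessage(e), call. = FALSE)
                      v <- rep(NA_real_, 11)
                      names(v) <- paste0(sprintf("S(%d,%d)", d, th),
                                         c("AngScMom", "Contrast", "Correlat",
                                           "SumOfSqs", "InvDfMom", "SumAverg",
                                           "SumVarnc", "SumEntrp", "Entropy",
                                           "DifVarnc", "DifEntrp"))
                      v
                    })
      out <- c(out, f)
    }
  }
  for (th in thetas) out <- c(out, glrlm_features(q, th))
  out
}

#' Extract the full per-patient feature row over ROIs S1-S4
#'
#' Histogram, GLCM (all `d` in `d_set` x four angles x 11 statistics) and
#' GLRLM (four directions x 5 statistics) features for each ROI, with names
#' prefixed `S1_` / `S2_` / `S3_` / `S4_`.
#'
#' @param image A [radiograph].
#' @param rois A `roi_masks` (S1-S3).
#' @param s4 An `s4_image` from [reassemble()].
#' @param G,clip_k Quantization settings (see [quantize()]).
#' @param d_set GLCM offset distances (default 1:5).
#' @return Named numeric vector (one feature-table row).
#' @export
extract_all <- function(image, rois, s4, G = 64L, clip_k = 3, d_set = 1:5) {
  stopifnot(inherits(rois, "roi_masks"), inherits(s4, "s4_image"))
  rows <- list(
    S1 = texture_features_roi(image, rois$s1, G, clip_k, d_set),
    S2 = texture_features_roi(image, rois$s2, G, clip_k, d_set),
    S3 = texture_features_roi(image, rois$s3, G, clip_k, d_set),
    S4 = texture_features_roi(s4$pixels, matrix(TRUE, nrow(s4$pixels), ncol(s4$pixels)),
                              G, clip_k, d_set)
  )
  out <- unlist(lapply(names(rows), function(p) {
    v <- rows[[p]]
    names(v) <- paste0(p, "_", names(v))
    v
  }))
  out
}

#' Feature-name schema
#'
#' Lists every feature name produced by [extract_all()] together with its
#' provenance (ROI, family, distance, angle).
#'
#' @param d_set GLCM offset distances (default 1:5).
#' @return A data.frame with columns name, roi, family, d, theta.
#' @export
feature_schema <- function(d_set = 1:5) {
  rois <- c("S1", "S2", "S3", "S4")
  hist_n <- c("HistMean", "HistVariance", "HistSkewness", "HistKurtosis",
              "HistPerc01", "HistPerc10", "HistPerc50", "HistPerc90", "HistPerc99")
  glcm_n <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
              "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc", "DifEntrp")
  glrlm_n <- c("ShrtREmph", "LngREmph", "GLevNonUn", "RLNonUni", "Fraction")
  out <- list()
  for (roi in rois) {
    out[[length(out) + 1L]] <- data.frame(
      name = paste0(roi, "_", hist_n), roi = roi, family = "histogram",
      d = NA_integer_, theta = NA_integer_)
    for (d in d_set) for (th in c(0L, 45L, 90L, 135L)) {
      out[[length(out) + 1L]] <- data.frame(
        name = paste0(roi, sprintf("_S(%d,%d)", d, th), glcm_n),
        roi = roi, family = "glcm", d = d, theta = th)
    }
    for (th in c(0L, 45L, 90L, 135L)) {
      out[[length(out) + 1L]] <- data.frame(
        name = paste0(roi, sprintf("_R(%d)", th), glrlm_n),
        roi = roi, family = "glrlm", d = NA_integer_, theta = th)
    }
  }
  do.call(rbind, out)
}
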