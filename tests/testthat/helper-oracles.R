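# Independent brute-force oracles used to validate the vectorized
# implementations.  These are deliberately naive (double loops, direct
# textbook formulas) and share no code with the package internals.

oracle_glcm <- function(lev, d, theta, G) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, G, G)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- lev[r, c]; b <- lev[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(P) {
  G <- nrow(P)
  asm <- contrast <- corr_num <- ssq <- idm <- ent <- 0
  mux <- 0
  for (a in 1:G) for (b in 1:G) mux <- mux + (a - 1) * P[a, b]
  sgx <- 0
  for (a in 1:G) for (b in 1:G) sgx <- sgx + (a - 1 - mux)^2 * P[a, b]
  for (a in 1:G) {
    for (b in 1:G) {
      p <- P[a, b]
      asm <- asm + p^2
      contrast <- contrast + (a - b)^2 * p
      corr_num <- corr_num + (a - 1) * (b - 1) * p
      ssq <- ssq + (a - 1 - mux)^2 * p
      idm <- idm + p / (1 + (a - b)^2)
      if (p > 0) ent <- ent - p * log(p)
    }
  }
  psum <- numeric(2 * G - 1)
  pdif <- numeric(G)
  for (a in 1:G) for (b in 1:G) {
    psum[a + b - 1] <- psum[a + b - 1] + P[a, b]
    pdif[abs(a - b) + 1] <- pdif[abs(a - b) + 1] + P[a, b]
  }
  sav <- sum((0:(2 * G - 2)) * psum)
  svar <- sum(((0:(2 * G - 2)) - sav)^2 * psum)
  sent <- -sum(ifelse(psum > 0, psum * log(psum), 0))
  dmean <- sum((0:(G - 1)) * pdif)
  dvar <- sum(((0:(G - 1)) - dmean)^2 * pdif)
  dent <- -sum(ifelse(pdif > 0, pdif * log(pdif), 0))
  c(AngScMom = asm, Contrast = contrast,
    Correlat = if (sgx > 0) (corr_num - mux^2) / sgx else 0,
    SumOfSqs = ssq, InvDfMom = idm, SumAverg = sav, SumVarnc = svar,
    SumEntrp = sent, Entropy = ent, DifVarnc = dvar, DifEntrp = dent)
}

# pixel-stepping run scanner (independent of the rle-based implementation)
oracle_glrlm <- function(lev, theta, G) {
  nr <- nrow(lev); nc <- ncol(lev)
  step <- switch(as.character(theta),
                 "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0), "135" = c(-1, -1))
  starts <- switch(as.character(theta),
    "0"   = cbind(seq_len(nr), 1),
    "90"  = cbind(nr, seq_len(nc)),
    "45"  = rbind(cbind(nr, seq_len(nc)), if (nr > 1) cbind(seq_len(nr - 1), 1)),
    "135" = rbind(cbind(nr, seq_len(nc)), if (nr > 1) cbind(seq_len(nr - 1), nc)))
  run_len <- integer(0); run_lev <- integer(0)
  for (s in seq_len(nrow(starts))) {
    r <- starts[s, 1]; c <- starts[s, 2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- lev[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (len > 0) { run_len <- c(run_len, len); run_lev <- c(run_lev, cur) }
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (len > 0) { run_len <- c(run_len, len); run_lev <- c(run_lev, cur) }
  }
  R <- length(run_len)
  np <- sum(!is.na(lev))
  sre <- sum(1 / run_len^2) / R
  lre <- sum(run_len^2) / R
  gln <- sum(table(run_lev)^2) / R
  rln <- sum(table(run_len)^2) / R
  c(ShrtREmph = sre, LngREmph = lre, GLevNonUn = gln,
    RLNonUni = rln, Fraction = R / np)
}

oracle_hist <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  c(mean = m, variance = m2,
    skewness = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# unweighted case/control rank AUC by full double loop
oracle_rank_auc <- function(marker, case) {
  mi <- marker[case]; mj <- marker[!case]
  s <- 0
  for (a in mi) for (b in mj) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(mi) * length(mj))
}

# closed-form chord-count oracle for a circle-like centerline of perimeter L
# (mm), square side s (mm): number of side-length chords that fit around the
# equivalent circle, rounded to the nearest integer
oracle_square_count <- function(perimeter_mm, side_mm = 1) {
  R <- perimeter_mm / (2 * pi)
  steps <- 2 * pi / (2 * asin(min(side_mm / (2 * R), 1)))
  floor(steps) + as.integer(steps - floor(steps) >= 0.5)
}

# convenience: phantom -> contour -> band -> tiling chain with the
# generator-matched segmentation settings used across geometry tests
phantom_chain <- function(lesion_diameter = 10, transition_width = 0.5, ...,
                          low = 4, high = 8) {
  sz <- ceiling((lesion_diameter + 6) / 0.1)
  ph <- generate_phantom(phantom_params(image_size = c(sz, sz),
                                        lesion_diameter = lesion_diameter,
                                        transition_width = transition_width,
                                        ...))
  ctr <- (dim(ph$image$pixels) + 1) / 2
  edges <- canny(ph$image, low = low, high = high)
  contour <- trace_contour(edges, ctr, spacing = ph$image$spacing)
  band <- locate_transition(ph$image, contour)
  tiling <- tile_boundary(band)
  list(phantom = ph, center = ctr, edges = edges, contour = contour,
       band = band, tiling = tiling)
}
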