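# Texture features: quantization bins, GLCM/GLRLM/histogram closed forms
# and brute-force-oracle equivalence, naming conventions, and the
# gray-level-shift invariance property.

test_that("quantization bins behave on exact, constant and random ROIs", {
  img <- matrix(c(0, 1, 2, 3), 2, 2)
  q <- quantize(img, matrix(TRUE, 2, 2), G = 4L, clip_k = 100)
  expect_identical(sort(as.integer(q$levels)), 0:3)
  const <- quantize(matrix(7, 3, 3), matrix(TRUE, 3, 3), G = 64L)
  expect_true(all(const$levels == 32L))
  set.seed(1)
  v <- matrix(rnorm(400, 100, 20), 20, 20)
  mask <- matrix(runif(400) < 0.7, 20, 20)
  q2 <- quantize(v, mask, G = 16L, clip_k = 2)
  # independent re-binning oracle
  x <- v[mask]
  lo <- mean(x) - 2 * sd(x); hi <- mean(x) + 2 * sd(x)
  xx <- pmin(pmax(x, lo), hi)
  oracle_lev <- pmin(floor((xx - lo) / (hi - lo) * 16), 15)
  expect_identical(as.integer(q2$levels[mask]), as.integer(oracle_lev))
})

test_that("GLCM of the alternating-column image matches hand enumeration", {
  img <- matrix(rep(c(0, 1), each = 4, times = 2), 4, 4)   # columns 0,1,0,1
  q <- quantize(img, matrix(TRUE, 4, 4), G = 2L, clip_k = 100)
  P <- glcm(q, 1, 0)
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(P[1, 1] + P[2, 2], 0)
  f <- glcm_features(P, 1, 0)
  expect_equal(unname(f["S(1,0)Contrast"]), 1)
  # constant ROI: single diagonal entry
  qc <- quantize(matrix(5, 4, 4), matrix(TRUE, 4, 4), G = 8L)
  Pc <- glcm(qc, 1, 0)
  expect_equal(max(Pc), 1)
  fc <- glcm_features(Pc, 1, 0)
  expect_equal(unname(fc["S(1,0)Contrast"]), 0)
  expect_equal(unname(fc["S(1,0)AngScMom"]), 1)
  expect_equal(unname(fc["S(1,0)Entropy"]), 0)
})

test_that("GLCM features equal the brute-force oracle to 1e-12", {
  set.seed(7)
  for (rep in 1:20) {
    G <- sample(c(4L, 8L, 16L), 1)
    lev <- matrix(sample(0:(G - 1), 256, TRUE), 16, 16)
    mask <- matrix(runif(256) < 0.85, 16, 16)
    lev[!mask] <- NA
    q <- structure(list(levels = lev, G = G,
                        normalization = c(mu = 0, sigma = 1), clip_k = 3),
                   class = "quantized_roi")
    for (d in sample(1:5, 2)) {
      for (th in c(0, 45, 90, 135)) {
        P <- glcm(q, d, th)
        Po <- oracle_glcm(lev, d, th, G)
        expect_lt(max(abs(P - Po)), 1e-12)
        f <- glcm_features(P, d, th)
        fo <- oracle_glcm_features(P)
        expect_lt(max(abs(unname(f) - unname(fo))), 1e-12)
      }
    }
  }
})

test_that("GLRLM features equal the run-scanner oracle", {
  # closed forms first
  row8 <- structure(list(levels = matrix(3L, 1, 8), G = 8L,
                         normalization = c(mu = 0, sigma = 1), clip_k = 3),
                    class = "quantized_roi")
  f <- glrlm_features(row8, 0)
  expect_equal(unname(f["R(0)Fraction"]), 1 / 8)
  expect_equal(unname(f["R(0)LngREmph"]), 64)
  alt <- structure(list(levels = matrix(rep(c(0L, 1L), 4), 1, 8), G = 2L,
                        normalization = c(mu = 0, sigma = 1), clip_k = 3),
                   class = "quantized_roi")
  fa_ <- glrlm_features(alt, 0)
  expect_equal(unname(fa_["R(0)ShrtREmph"]), 1)
  set.seed(8)
  for (rep in 1:20) {
    G <- 4L
    lev <- matrix(sample(0:3, 256, TRUE), 16, 16)
    mask <- matrix(runif(256) < 0.8, 16, 16)
    lev[!mask] <- NA
    q <- structure(list(levels = lev, G = G,
                        normalization = c(mu = 0, sigma = 1), clip_k = 3),
                   class = "quantized_roi")
    for (th in c(0, 45, 90, 135)) {
      f <- glrlm_features(q, th)
      fo <- oracle_glrlm(lev, th, G)
      expect_equal(unname(f), unname(fo), tolerance = 1e-12)
    }
  }
})

test_that("histogram features match direct moment formulas", {
  cst <- histogram_features(matrix(42, 5, 5), matrix(TRUE, 5, 5))
  expect_equal(unname(cst["HistMean"]), 42)
  expect_equal(unname(cst["HistVariance"]), 0)
  sym <- matrix(c(1, 2, 2, 3), 2, 2)
  fs <- histogram_features(sym, matrix(TRUE, 2, 2))
  expect_equal(unname(fs["HistSkewness"]), 0)
  set.seed(9)
  v <- matrix(rgamma(300, 2, 1) * 20, 15, 20)
  mask <- matrix(runif(300) < 0.9, 15, 20)
  f <- histogram_features(v, mask)
  o <- oracle_hist(v[mask])
  expect_equal(unname(f[c("HistMean", "HistVariance", "HistSkewness",
                          "HistKurtosis")]), unname(o), tolerance = 1e-12)
  expect_equal(unname(f["HistPerc50"]), unname(median(v[mask])))
})

test_that("feature rows are deterministic, fully named, and schema-stable", {
  ch <- phantom_chain(lesion_diameter = 8, transition_width = 0.5)
  rois <- build_rois(ch$contour, dim(ch$phantom$image$pixels), 0.1)
  fr <- extract_fragments(ch$phantom$image, ch$tiling, interior_point = ch$center)
  s4 <- reassemble(fr)
  f1 <- extract_all(ch$phantom$image, rois, s4)
  f2 <- extract_all(ch$phantom$image, rois, s4)
  expect_identical(f1, f2)
  schema <- feature_schema()
  expect_setequal(names(f1), schema$name)
  expect_true(all(paste0(c("S1", "S2", "S3", "S4"), "_S(5,0)Contrast")
                  %in% names(f1)))
  expect_false(any(duplicated(names(f1))))
})

test_that("features are invariant to a constant gray-level shift", {
  set.seed(10)
  img <- matrix(runif(900, 50, 150), 30, 30)
  mask <- matrix(TRUE, 30, 30)
  q1 <- quantize(img, mask, G = 32L)
  q2 <- quantize(img + 40, mask, G = 32L)
  expect_identical(q1$levels, q2$levels)
  f1 <- glcm_features(glcm(q1, 2, 45), 2, 45)
  f2 <- glcm_features(glcm(q2, 2, 45), 2, 45)
  expect_equal(f1, f2, tolerance = 1e-14)
})

test_that("degenerate ROI contracts hold", {
  expect_error(quantize(matrix(1, 3, 3), matrix(FALSE, 3, 3)),
               class = "apexfa_value_error")
  narrow <- structure(list(levels = matrix(0L, 1, 3), G = 4L,
                           normalization = c(mu = 0, sigma = 1), clip_k = 3),
                      class = "quantized_roi")
  expect_error(glcm(narrow, 5, 90), class = "apexfa_glcm_error")
  expect_error(glcm_features(matrix(1, 2, 2)), class = "apexfa_contract_error")
})
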