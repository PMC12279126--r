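# Fragment analysis: transition-zone localization against generator ground
# truth, tiling geometry (counts, non-overlap, touching, coverage),
# oriented fragment extraction, and S4 reassembly.

test_that("transition width and centerline recover the generator truth", {
  for (w in c(0.3, 0.6)) {
    ch <- phantom_chain(lesion_diameter = 10, transition_width = w)
    expect_lt(abs(median(ch$band$local_width) - w) / w, 0.10)
    ctr <- ch$center
    rad <- sqrt(rowSums(sweep(ch$band$centerline, 2, ctr)^2))
    expect_true(all(abs(rad - 50) < 1))        # within 1 px of the true radius
  }
})

test_that("a hard step edge collapses the width to about a pixel quantum", {
  img <- matrix(60, 160, 160)
  ctr <- c(80.5, 80.5)
  ri <- matrix(seq_len(160), 160, 160); ci <- t(ri)
  img[sqrt((ri - ctr[1])^2 + (ci - ctr[2])^2) > 40] <- 140
  rad <- radiograph(img, 0.1)
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  verts <- cbind(ctr[1] + 40 * sin(th), ctr[2] + 40 * cos(th))
  band <- locate_transition(rad, verts)
  # bilinear sampling spreads a hard step over ~1 px; widths must collapse
  # towards the pixel-spacing quantum (0.1 mm), far below any real zone
  expect_lt(median(band$local_width), 0.22)
  expect_gte(min(band$local_width), 0.1)       # floored at one quantum
})

test_that("tiling counts match the chord-count oracle across the size range", {
  for (D in c(5, 8, 12, 15)) {
    ch <- phantom_chain(lesion_diameter = D, transition_width = 0.4)
    per_mm <- apexfa:::poly_perimeter(ch$band$centerline) * 0.1
    n_or <- oracle_square_count(per_mm)
    expect_lte(abs(length(ch$tiling$polys) - n_or), 1)
    qc <- tiling_qc(ch$tiling)
    expect_lt(qc$max_overlap_px2, 1e-6)        # non-consecutive: disjoint
    expect_lte(qc$max_gap_px, 0.5)             # consecutive: touching
  }
})

test_that("a 10 mm circular lesion takes ~31 one-mm squares", {
  ch <- phantom_chain(lesion_diameter = 10, transition_width = 0.5)
  expect_equal(length(ch$tiling$polys), 31)
})

test_that("centerline shorter than one square fails to tile", {
  th <- seq(0, 2 * pi, length.out = 50)[-50]
  tiny <- cbind(20 + 3 * sin(th), 20 + 3 * cos(th))   # 0.6 mm diameter ring
  expect_error(tile_boundary(tiny, spacing = 0.1),
               class = "apexfa_tiling_error")
})

test_that("fragments equal direct crops for axis-aligned squares", {
  set.seed(9)
  img <- radiograph(matrix(runif(100 * 100, 0, 255), 100, 100), 0.1)
  centers <- rbind(c(30.5, 40.5), c(60.5, 20.5))
  tiling <- structure(list(centers = centers, angles = c(0, 0),
                           arc_pos = c(0, 1),
                           polys = lapply(1:2, function(i)
                             apexfa:::square_polygon(centers[i, ], 0, 10)),
                           side_px = 10, side_mm = 1, spacing = 0.1,
                           order_origin = "manual"),
                      class = "boundary_tiling")
  fr <- extract_fragments(img, tiling, interior_point = c(30.5, 0))
  crop <- img$pixels[26:35, 36:45]
  expect_lt(max(abs(fr$fragments[[1]] - crop)), 1)
})

test_that("every fragment has the dark interior on its left half", {
  ch <- phantom_chain(lesion_diameter = 8, transition_width = 0.5)
  fr <- extract_fragments(ch$phantom$image, ch$tiling,
                          interior_point = ch$center)
  halves <- vapply(fr$fragments, function(f) {
    hw <- ncol(f) %/% 2
    mean(f[, seq_len(hw)]) < mean(f[, ncol(f) - seq_len(hw) + 1])
  }, TRUE)
  expect_true(all(halves))
})

test_that("rotating the radiograph by 90 deg permutes but preserves fragments", {
  ch <- phantom_chain(lesion_diameter = 8, transition_width = 0.5)
  img <- ch$phantom$image
  rot <- radiograph(t(img$pixels)[ncol(img$pixels):1, ], img$spacing)
  ch2_contour <- trace_contour(canny(rot, low = 4, high = 8),
                               (dim(rot$pixels) + 1) / 2, spacing = 0.1)
  band2 <- locate_transition(rot, ch2_contour)
  til2 <- tile_boundary(band2)
  fr1 <- extract_fragments(img, ch$tiling, interior_point = ch$center)
  fr2 <- extract_fragments(rot, til2, interior_point = (dim(rot$pixels) + 1) / 2)
  expect_equal(length(fr1$fragments), length(fr2$fragments))
  # compare order-free summary statistics of the two fragment multisets
  s1 <- sort(vapply(fr1$fragments, mean, 0))
  s2 <- sort(vapply(fr2$fragments, mean, 0))
  expect_lt(max(abs(s1 - s2)), 0.75)
})

test_that("reassembly concatenates fragments into the striped S4 image", {
  frag <- matrix(runif(100), 10, 10)
  fs <- structure(list(fragments = list(frag, frag + 1, frag + 2, frag + 3, frag + 4),
                       side_px = 10, order_origin = "manual"),
                  class = "fragment_set")
  s4 <- reassemble(fs)
  expect_equal(dim(s4$pixels), c(10L, 50L))
  one <- structure(list(fragments = list(frag), side_px = 10,
                        order_origin = "manual"), class = "fragment_set")
  expect_identical(reassemble(one)$pixels, frag)
  bad <- structure(list(fragments = list(frag, frag[1:5, 1:5]), side_px = 10,
                        order_origin = "manual"), class = "fragment_set")
  expect_error(reassemble(bad), class = "apexfa_assembly_error")
})

test_that("S4 column means are periodic with the fragment width", {
  ch <- phantom_chain(lesion_diameter = 10, transition_width = 0.5)
  fr <- extract_fragments(ch$phantom$image, ch$tiling,
                          interior_point = ch$center)
  s4 <- reassemble(fr)
  cm <- colMeans(s4$pixels)
  side <- fr$side_px
  prof <- matrix(cm, nrow = side)              # one column per fragment
  # identical fragments on a symmetric phantom: profiles agree across blocks
  spread <- apply(prof, 1, function(x) diff(range(x)))
  expect_lt(max(spread), 3)
  # and the profile actually ramps dark -> light within each fragment
  expect_gt(mean(prof[side, ]) - mean(prof[1, ]), 60)
})

test_that("squares beyond the image bounds raise an extraction error", {
  img <- radiograph(matrix(100, 40, 40), 0.1)
  centers <- rbind(c(5, 5))
  tiling <- structure(list(centers = centers, angles = 0, arc_pos = 0,
                           polys = list(apexfa:::square_polygon(c(5, 5), 0, 10)),
                           side_px = 10, side_mm = 1, spacing = 0.1,
                           order_origin = "manual"),
                      class = "boundary_tiling")
  expect_error(extract_fragments(img, tiling, interior_point = c(20, 20)),
               class = "apexfa_extraction_error")
})
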