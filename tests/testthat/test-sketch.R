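test_that("cells render homogeneously at their illumination", {
  lab <- finalize_mask_for_test(rasterize_ellipsoid(c(20, 20), c(10, 10), 4))
  sk <- render_sketch(lab, sketch_style(illumination = 0.7, background = 0),
                      seed = 1)
  expect_true(all(sk[lab == 1L] == 0.7))
  expect_true(all(sk[lab == 0L] == 0))
})

test_that("overlapping cells are dimmed 10% per extra cell", {
  lab <- array(0L, c(6, 6))
  lab[2:5, 2:4] <- 1L
  lab[2:5, 3:5] <- 2L               # columns 3:4 covered by both
  nov <- array(0L, c(6, 6))
  nov[2:5, 2:4] <- nov[2:5, 2:4] + 1L
  nov[2:5, 3:5] <- nov[2:5, 3:5] + 1L
  attr(lab, "n_overlap") <- nov
  sk <- render_sketch(lab, sketch_style(illumination = 0.8, background = 0))
  expect_true(all(sk[2:5, 3:4] == 0.8 * 0.9))
  expect_true(all(sk[2:5, c(2, 5)] == 0.8))
})

test_that("depth and radial decay scale intensities linearly", {
  lab <- array(1L, c(5, 4, 4))
  sk <- render_sketch(lab, sketch_style(illumination = 0.8, background = 0,
                                        decay = list(type = "z-linear", factor = 0.5)))
  expect_true(all(sk[1, , ] == 0.8))          # top slice unscaled
  expect_true(all(sk[5, , ] == 0.4))          # deepest slice halved
  expect_true(all(abs(sk[3, , ] - 0.6) < 1e-12))
  rad <- render_sketch(array(1L, c(21, 21)),
                       sketch_style(illumination = 0.8, background = 0,
                                    decay = list(type = "radial", factor = 0.5)))
  expect_equal(rad[11, 11], 0.8 * 0.5)        # darkest at the organism center
  expect_equal(rad[11, 1], 0.8, tolerance = 0.05)
})

test_that("nucleoli darken small circles strictly inside their cell", {
  lab <- finalize_mask_for_test(rasterize_ellipsoid(c(30, 30), c(15, 15), 10))
  sk <- render_sketch(lab, sketch_style(illumination = 0.8, background = 0,
                                        nucleoli = list(count = c(1, 2),
                                                        darkness = 0.25,
                                                        radius = c(2, 3))),
                      seed = 3)
  expect_true(all(sk[lab == 0L] == 0))
  dark <- sk < 0.8 & lab == 1L
  expect_true(any(dark))
  expect_true(all(sk[dark] == 0.8 * 0.25))
})

test_that("mean-intensity mode copies the reference per cell", {
  lab <- array(0L, c(8, 8)); lab[2:4, 2:4] <- 1L
  ref <- array(0.1, c(8, 8)); ref[2:4, 2:4] <- seq(0.3, 0.5, length.out = 9)
  sk <- render_sketch(lab, sketch_style(background = 0), reference = ref,
                      mode = "mean-intensity")
  expect_equal(unique(sk[lab == 1L]), mean(ref[lab == 1L]))
  expect_error(render_sketch(lab, mode = "mean-intensity"), "reference")
})

test_that("membrane rendering marks exactly the disagreeing boundary", {
  lab <- array(0L, c(10, 12))
  lab[3:8, 2:6] <- 1L
  lab[3:8, 7:11] <- 2L                       # touching rectangles
  sk <- render_membrane_sketch(lab, width = 1,
                               sketch_style(illumination = 0.9, background = 0))
  # brute-force neighbour-disagreement scan
  bf <- array(FALSE, dim(lab))
  for (i in 1:10) for (j in 1:12) {
    if (lab[i, j] == 0L) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > 10 || jj < 1 || jj > 12) next
      if (lab[ii, jj] != lab[i, j]) bf[i, j] <- TRUE
    }
  }
  expect_identical(sk == 0.9, bf)
  # the shared seam itself is the two adjacent columns
  expect_true(all(sk[3:8, 6:7] == 0.9))
  expect_true(all(sk[4:7, c(3, 4, 5)] == 0))  # interior stays dark
  single <- array(0L, c(8, 8)); single[3:6, 3:6] <- 1L
  out <- render_membrane_sketch(single, width = 1,
                                sketch_style(illumination = 0.9, background = 0))
  expect_true(all(out[c(3, 6), 3:6] == 0.9) && all(out[3:6, c(3, 6)] == 0.9))
  expect_true(all(out[4:5, 4:5] == 0))
  expect_error(render_membrane_sketch(single, width = 0), "width")
})

test_that("sketch smoothing is mass-preserving and identity at sigma 0", {
  set.seed(2)
  sk <- array(0, c(33, 33))
  sk[12:22, 12:22] <- runif(121, 0.3, 0.9)   # interior-supported content
  expect_identical(smooth_sketch(sk, 0), sk)
  const <- array(0.4, c(9, 9))
  expect_equal(smooth_sketch(const, 2), const)
  sm <- smooth_sketch(sk, 1.5)
  expect_equal(sum(sm), sum(sk), tolerance = 1e-3)
  expect_error(smooth_sketch(sk, -1), "non-negative")
})
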