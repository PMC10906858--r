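test_that("intensity histograms count exactly", {
  img <- matrix(c(0, 0.15, 0.15, 0.32, 0.55, 0.55, 0.55, 0.95,
                  1, 1, 0.25, 0.25, 0.25, 0.25, 0.72, 0.72), 4, 4)
  h <- intensity_histogram(img, n_bins = 10, value_range = c(0, 1))
  # hand count: bins 1..10 cover [0,.1), [.1,.2), ..., [.9,1]
  counts <- c(1, 2, 4, 1, 0, 3, 0, 2, 0, 3)
  expect_equal(h$p, counts / 16)
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(h$n, 16)
  hc <- intensity_histogram(array(0.42, 50), n_bins = 8)
  expect_equal(sum(hc$p == 1), 1)                 # constant image: one full bin
  expect_error(intensity_histogram(numeric(0)), "empty")
  expect_error(intensity_histogram(img, n_bins = 1), "bins")
})

test_that("distribution distances match hand evaluation and brute force", {
  P <- c(0.5, 0.5); Q <- c(0.9, 0.1)
  expect_equal(bhattacharyya(P, Q), -log(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)
  expect_equal(bhattacharyya(P, Q), 0.1116, tolerance = 1e-3)
  expect_equal(kl_divergence(P, Q), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-6)
  expect_equal(kl_divergence(P, Q), 0.5108, tolerance = 1e-3)
  expect_equal(bhattacharyya(P, P), 0)
  expect_equal(kl_divergence(P, P), 0)
  expect_equal(bhattacharyya(P, Q), bhattacharyya(Q, P))
  expect_false(isTRUE(all.equal(kl_divergence(P, Q), kl_divergence(Q, P))))
  expect_identical(bhattacharyya(c(1, 0), c(0, 1)), Inf)
  expect_identical(kl_divergence(c(1, 0), c(0, 1)), Inf)
  # epsilon smoothing keeps partially-overlapping supports finite
  expect_true(is.finite(kl_divergence(c(0.5, 0.5, 0), c(0.5, 0, 0.5))))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(5); p <- p / sum(p)
    q <- runif(5); q <- q / sum(q)
    expect_equal(bhattacharyya(p, q), bf_bhattacharyya(p, q), tolerance = 1e-9)
    expect_equal(kl_divergence(p, q), bf_kl(p, q), tolerance = 1e-6)
  }
  expect_error(bhattacharyya(c(0.5, 0.5), c(1, 0, 0)), "bins")
})

test_that("both PSNR conventions evaluate their formulas", {
  x <- matrix(0.5, 2, 2); ref <- matrix(0.6, 2, 2)   # MSE = 0.01
  expect_equal(psnr(x, ref, "paper"), 40)
  expect_equal(psnr(x, ref, "standard"), 20)
  expect_identical(psnr(x, x), Inf)
  set.seed(4)
  a <- matrix(runif(25), 5, 5); b <- matrix(runif(25), 5, 5)
  expect_equal(psnr(a, b, "paper"), bf_psnr(a, b, 20), tolerance = 1e-9)
  expect_equal(psnr(a, b, "standard"), bf_psnr(a, b, 10), tolerance = 1e-9)
  # monotone decrease with growing noise amplitude
  base <- matrix(0.5, 8, 8); eps <- matrix(rnorm(64), 8, 8)
  ps <- sapply(c(0.01, 0.05, 0.1, 0.2), function(s) psnr(base + s * eps, base))
  expect_true(all(diff(ps) < 0))
  expect_error(psnr(a, matrix(0, 2, 2)), "shape")
})

test_that("ZNCC matches the per-pixel definition and its bounds", {
  set.seed(6)
  a <- matrix(runif(9), 3, 3); b <- matrix(runif(9), 3, 3)
  expect_equal(zncc(a, b), bf_zncc(a, b), tolerance = 1e-9)
  expect_equal(zncc(a, a), 1)
  expect_equal(zncc(a, 2 * a + 3), 1)               # affine-positive invariance
  expect_equal(zncc(a, -a), -1)
  expect_error(zncc(a, matrix(1, 3, 3)), "constant")
})

test_that("IoU handles the canonical cases and brute force agrees", {
  m <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3) > 0        # 2x2 block, columns 1:2
  shifted <- matrix(c(0, 0, 1, 1, 1, 1), 2, 3) > 0  # same block shifted a column
  expect_equal(iou(m, shifted), 1 / 3)
  expect_equal(iou(m, m), 1)
  expect_equal(as.numeric(iou(m, !m & FALSE)), 0)
  empty <- matrix(FALSE, 2, 3)
  expect_true(isTRUE(attr(iou(empty, empty), "empty_union")))
  set.seed(7)
  for (i in 1:10) {
    p <- matrix(runif(25) > 0.5, 5, 5); g <- matrix(runif(25) > 0.5, 5, 5)
    if (!any(p | g)) next
    expect_equal(as.numeric(iou(p, g)), bf_iou(p, g), tolerance = 1e-9)
  }
})

test_that("instance matching is greedy by overlap with unique predictions", {
  gt <- array(0L, c(6, 6)); gt[1:3, 1:3] <- 1L; gt[5:6, 5:6] <- 2L
  pred <- array(0L, c(6, 6)); pred[1:3, 2:4] <- 7L; pred[5:6, 5] <- 9L
  res <- matched_instance_iou(pred, gt)
  expect_equal(res$gt_label, c(1L, 2L))
  expect_equal(res$pred_label, c(7L, 9L))
  expect_equal(res$iou[1], 6 / 12)
  expect_equal(res$iou[2], 2 / 4)
  # one prediction cannot serve two ground-truth cells
  pred2 <- array(0L, c(6, 6)); pred2[1:6, 1:6] <- 3L
  res2 <- matched_instance_iou(pred2, gt)
  expect_equal(sum(!is.na(res2$pred_label)), 1L)
  expect_equal(sum(res2$iou == 0), 1L)
})
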