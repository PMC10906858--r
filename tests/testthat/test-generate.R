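test_that("the oracle denoiser reproduces the smoothed sketch exactly", {
  # degenerate but exact regression anchor: when the denoiser knows the
  # true noise, the backward pass inverts the forward pass
  sch <- tiny_schedule(30)
  toy <- small_toy(1)
  sm <- smooth_sketch(toy[[1]]$sketch, 1)
  cfg <- generation_config(t_start = 12, sigma = 1, seed = 5)
  smp <- generate_annotated_image(toy[[1]]$sketch, toy[[1]]$labels,
                                  oracle_denoiser(sm, sch), sch, cfg)
  expect_lt(max(abs(smp$image - clip01(sm))), 1e-6)
  expect_identical(smp$labels, toy[[1]]$labels)     # annotation untouched
  expect_equal(smp$provenance$t_start, 12L)
})

test_that("generation is deterministic per seed and validates inputs", {
  sch <- tiny_schedule(30)
  toy <- small_toy(1)
  fit <- ddpm(list(toy[[1]]$image), sch, epochs = 5, seed = 1)
  cfg <- generation_config(t_start = 10, sigma = 1, seed = 11)
  a <- generate_annotated_image(toy[[1]]$sketch, toy[[1]]$labels, fit, sch, cfg)
  b <- generate_annotated_image(toy[[1]]$sketch, toy[[1]]$labels, fit, sch, cfg)
  expect_identical(a$image, b$image)
  expect_error(generate_annotated_image(toy[[1]]$sketch, array(0L, c(3, 3)),
                                        fit, sch, cfg), "shape")
  expect_error(generate_annotated_image(toy[[1]]$sketch, toy[[1]]$labels, fit,
                                        sch, generation_config(t_start = 99)),
               "range")
})

test_that("dataset emission writes reproducible image/mask pairs + manifest", {
  sch <- tiny_schedule(30)
  toy <- small_toy(3)
  fit <- ddpm(lapply(toy, `[[`, "image"), sch, epochs = 5, seed = 1)
  cfg <- generation_config(t_start = 10, sigma = 1, seed = 21)
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  man <- generate_dataset(lapply(toy, `[[`, "labels"), fit, sch, cfg, 3, d1)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$image, man$mask)))
  expect_match(man$image[1], "images/0001\\.tif")
  expect_match(man$mask[1], "masks/0001_masks\\.tif")
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  # masks pass through bitwise
  for (i in 1:3) {
    expect_identical(read_label_tiff(man$mask[i]),
                     array(as.integer(toy[[i]]$labels), dim(toy[[i]]$labels)))
  }
  # same master seed, fresh directory: identical bytes
  generate_dataset(lapply(toy, `[[`, "labels"), fit, sch, cfg, 3, d2)
  for (i in 1:3) {
    expect_identical(readBin(man$image[i], "raw", 1e6),
                     readBin(file.path(d2, "images", sprintf("%04d.tif", i)),
                             "raw", 1e6))
  }
  # per-sample seeds differ but derive from the master seed
  expect_equal(length(unique(man$seed)), 3)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("patchwise application blends seamlessly", {
  set.seed(8)
  vol <- array(runif(32 * 40), c(32, 40))
  idp <- patchwise_apply(vol, identity, patch_shape = c(16, 16), overlap = 4)
  expect_lt(max(abs(idp - vol)), 1e-6)
  single <- patchwise_apply(vol, function(p) p^2, patch_shape = dim(vol))
  expect_equal(single, vol^2)
  plus <- patchwise_apply(vol, function(p) p + 1, patch_shape = c(16, 16),
                          overlap = 4)
  expect_lt(max(abs(plus - (vol + 1))), 1e-6)       # constant carries across seams
  vol3 <- array(runif(8 * 12 * 12), c(8, 12, 12))
  id3 <- patchwise_apply(vol3, identity, patch_shape = c(8, 8, 8), overlap = 2)
  expect_lt(max(abs(id3 - vol3)), 1e-6)
  expect_error(patchwise_apply(vol, identity, c(16, 16), overlap = 16), "overlap")
})

test_that("TIFF round trips preserve images and labels", {
  set.seed(3)
  img2 <- matrix(runif(48), 6, 8)
  f <- tempfile(fileext = ".tif")
  write_image_tiff(img2, f)
  expect_equal(read_image_tiff(f), img2, tolerance = 1e-6)
  img3 <- array(runif(4 * 5 * 6), c(4, 5, 6))
  write_image_tiff(img3, f)
  expect_equal(read_image_tiff(f), img3, tolerance = 1e-6)
  lab <- array(sample(0:7, 60, replace = TRUE), c(3, 4, 5))
  write_label_tiff(lab, f)
  expect_identical(read_label_tiff(f), array(as.integer(lab), dim(lab)))
})
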