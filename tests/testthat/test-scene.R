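test_that("presets read back the published simulation parameters", {
  cel <- scene_preset("celegans3d")
  expect_equal(cel$nucleus$scale, list(1, c(0.5, 1), 0.09))
  expect_equal(cel$nucleus$shrink_fraction, 0.10)
  expect_equal(cel$scene$roi, "centered-ellipsoid")

  trb <- scene_preset("tribolium3d")
  expect_equal(trb$nucleus$r_nuclei_range, c(5, 6))
  expect_equal(trb$nucleus$scale, list(1, 1, 1))
  expect_equal(trb$scene$n_layers, 13L)
  expect_equal(trb$scene$image_shape[1], 13L)

  stm <- scene_preset("stemcells2d")
  expect_equal(stm$nucleus$r_nuclei_range, c(30, 45))
  expect_equal(stm$nucleus$scale, list(c(0.75, 1), 1))
  expect_equal(stm$style$nucleoli$count, c(0, 2))
  expect_equal(stm$scene$overlap, "forbid")

  hel <- scene_preset("hela2d")
  expect_equal(hel$nucleus$r_nuclei_range, c(10, 20))
  expect_equal(hel$nucleus$scale, list(c(0.5, 1), 1))
  expect_equal(hel$scene$roi, "random-overlapping-circles")

  # the 10%-per-extra-cell overlap darkening is the style default
  expect_equal(sketch_style()$overlap_darkening, 0.10)
})

test_that("overlap-forbidden scenes place disjoint, contiguous labels", {
  rec <- scene_recipe(c(64, 64), n_cells = 20, overlap = "forbid")
  nuc <- nucleus_recipe(c(3, 5), scale = list(1, 1))
  lab <- simulate_scene(rec, nuc, seed = 1)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  expect_identical(ids, 1:20)
  expect_true(all(attr(lab, "n_overlap") <= 1L))   # empty pairwise intersections
  expect_equal(nrow(attr(lab, "cells")), 20)
  # empty scene
  empty <- simulate_scene(scene_recipe(c(16, 16), n_cells = 0), nuc, seed = 1)
  expect_true(all(empty == 0L))
  # determinism per seed
  expect_identical(unclass(simulate_scene(rec, nuc, seed = 3)),
                   unclass(simulate_scene(rec, nuc, seed = 3)))
})

test_that("infeasible packing is reported as a partial placement", {
  rec <- scene_recipe(c(12, 12), n_cells = 50, overlap = "forbid")
  nuc <- nucleus_recipe(c(3, 4), scale = list(1, 1))
  expect_warning(lab <- simulate_scene(rec, nuc, seed = 2), "placed")
  cells <- attr(lab, "cells")
  expect_lt(nrow(cells), 50)
  expect_identical(setdiff(sort(unique(as.integer(lab))), 0L),
                   seq_len(nrow(cells)))
})

test_that("the crowded-embryo recipe shrinks 10% of cells and scales radii", {
  cel <- scene_preset("celegans3d", image_shape = c(12, 96, 96), n_cells = 50)
  lab <- simulate_scene(cel$scene, cel$nucleus, seed = 4)
  cells <- attr(lab, "cells")
  # radii follow r_ref * (n_ref/n)^(1/d) with n = n_ref = 50 here
  expect_true(all(abs(cells$r - 10) < 1e-9))
  expect_equal(sum(cells$shrunken), round(0.10 * nrow(cells)))
})

test_that("overlapping placements record per-voxel multiplicity", {
  rec <- scene_recipe(c(24, 24), n_cells = 6, overlap = "allow")
  nuc <- nucleus_recipe(c(4, 6), scale = list(1, 1))
  lab <- simulate_scene(rec, nuc, seed = 8)
  nov <- attr(lab, "n_overlap")
  expect_true(any(nov > 1L))                       # crowded enough to overlap
  expect_true(all(nov[lab == 0L] == 0L))
})
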