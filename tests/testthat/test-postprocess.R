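# rasterize a sphere of given voxel radius at a (1-based) voxel-index centre
rasterize_sphere <- function(dims, center, radius_vox, value = 0.9) {
  arr <- array(0, dim = dims)
  ii <- seq_len(dims[1]); jj <- seq_len(dims[2]); kk <- seq_len(dims[3])
  d2 <- outer(outer((ii - center[1])^2, (jj - center[2])^2, "+"),
              (kk - center[3])^2, "+")
  arr[d2 <= radius_vox^2] <- value
  arr
}

all_true_lamella <- function(dims, vs) binary_mask(array(TRUE, dims), vs)

test_that("an all-zero map yields an empty particle set", {
  prob <- voxel_grid(array(0, dim = c(24, 24, 24)), 1.37)
  ps <- postprocess_probability_map(prob, all_true_lamella(c(24, 24, 24), 1.37))
  expect_s3_class(ps, "particle_set")
  expect_equal(nrow(ps), 0)
})

test_that("a single in-range sphere yields one particle at its centre", {
  dims <- c(48, 48, 48)
  # radius 13.3 voxels -> ~9,800 voxels, inside the 5,000-50,000 filter
  arr <- rasterize_sphere(dims, c(25, 24, 23), 13.3)
  n_vox <- sum(arr > 0)
  expect_gt(n_vox, 5000)
  expect_lt(n_vox, 50000)
  prob <- voxel_grid(arr, 1.37)
  ps <- postprocess_probability_map(prob, all_true_lamella(dims, 1.37))
  expect_equal(nrow(ps), 1)
  center_vox <- c(ps$x_nm, ps$y_nm, ps$z_nm) / 1.37 + 1
  expect_true(all(abs(center_vox - c(25, 24, 23)) <= 0.5))
  expect_equal(ps$score, 0.9)
})

test_that("the size filter keeps only in-range components", {
  dims <- c(110, 110, 60)
  # radii chosen to give ~4,000 / ~10,000 / ~60,000 voxel components
  arr <- rasterize_sphere(dims, c(20, 20, 30), 9.8) +
    rasterize_sphere(dims, c(55, 55, 30), 13.4) +
    rasterize_sphere(dims, c(88, 22, 30), 24.3)
  counts <- sort(as.integer(table(label_components_oracle <- {
    lab <- label_components(binary_mask(arr > 0.5, 1.37))
    lab[lab > 0]
  })))
  expect_lt(counts[1], 5000)
  expect_gt(counts[2], 5000); expect_lt(counts[2], 50000)
  expect_gt(counts[3], 50000)
  ps <- postprocess_probability_map(voxel_grid(pmin(arr, 1), 1.37),
                                    all_true_lamella(dims, 1.37))
  expect_equal(nrow(ps), 1)
  expect_true(all(abs(c(ps$x_nm, ps$y_nm, ps$z_nm) / 1.37 + 1 -
                        c(55, 55, 30)) <= 0.5))
})

test_that("the component labeller agrees with a flood-fill oracle", {
  set.seed(12)
  arr <- array(runif(20^3) > 0.7, dim = c(20, 20, 20))
  lab <- label_components(binary_mask(arr, 1))
  expect_equal(max(lab), flood_fill_count(arr))
})

test_that("masking before or after thresholding is equivalent", {
  dims <- c(60, 60, 60)
  arr <- rasterize_sphere(dims, c(30, 30, 30), 13)
  lam <- binary_mask(rasterize_sphere(dims, c(30, 30, 38), 14, 1) > 0, 1.37)
  prob <- voxel_grid(arr, 1.37)
  # mask applied by the operation
  ps1 <- postprocess_probability_map(prob, lam)
  # mask applied to the map beforehand
  pre <- voxel_grid(arr * lam$data, 1.37)
  ps2 <- postprocess_probability_map(pre, NULL)
  expect_equal(as.data.frame(ps1), as.data.frame(ps2))
})

test_that("size-filter decisions are equivariant under voxel-size rescaling", {
  dims <- c(48, 48, 48)
  arr <- rasterize_sphere(dims, c(24, 24, 24), 13.3)
  # same physical object sampled at 2x the voxel size has 8x fewer voxels;
  # the rescaled count must produce the same accept decision
  ps_ref <- postprocess_probability_map(voxel_grid(arr, 1.37),
                                        all_true_lamella(dims, 1.37))
  dims2 <- c(24, 24, 24)
  arr2 <- rasterize_sphere(dims2, c(12.5, 12.5, 12.5), 13.3 / 2)
  ps_coarse <- postprocess_probability_map(voxel_grid(arr2, 2.74),
                                           all_true_lamella(dims2, 2.74))
  expect_equal(nrow(ps_ref), 1)
  expect_equal(nrow(ps_coarse), 1)
})

test_that("probability maps outside [0,1] or mismatched geometry are rejected", {
  bad <- voxel_grid(array(1.5, dim = c(8, 8, 8)), 1)
  expect_error(postprocess_probability_map(bad, all_true_lamella(c(8, 8, 8), 1)),
               "input error")
  ok <- voxel_grid(array(0.2, dim = c(8, 8, 8)), 1)
  expect_error(postprocess_probability_map(ok, all_true_lamella(c(9, 9, 9), 1)),
               "geometry mismatch")
})

test_that("curation ledgers reproduce published accounting", {
  # mitochondrial data set: 68 peaks, 2+3+3 discarded, 63 added manually
  mito <- apply_curation(curation_ledger(
    68, c(`organelle-interior` = 2, `surface-damage` = 3, `visual-reject` = 3),
    63))
  expect_equal(mito$final_count, 123)

  # seipin data set: 108 peaks, 26 discarded, 9 added manually
  seipin <- apply_curation(curation_ledger(108, c(mixed = 26), 9))
  expect_equal(seipin$final_count, 91)

  # identity: no discards, no additions
  expect_equal(apply_curation(curation_ledger(41))$final_count, 41)

  # discards exceeding peaks are a ledger error
  expect_error(curation_ledger(10, c(a = 11)), "ledger error")
})

test_that("particle-level curation discards and merges with provenance", {
  ps <- particle_set(data.frame(x_nm = c(1, 2, 3), y_nm = c(1, 2, 3),
                                z_nm = c(1, 2, 3), score = c(0.9, 0.8, 0.7)))
  manual <- particle_set(data.frame(x_nm = 10, y_nm = 10, z_nm = 10))
  res <- apply_curation(ps,
                        discard = data.frame(particle_id = 2,
                                             category = "visual-reject"),
                        manual_additions = manual)
  expect_equal(res$final_count, 3)  # 3 - 1 + 1
  expect_equal(res$ledger$n_peaks, 3)
  expect_equal(sum(res$ledger$discards), 1)
  expect_equal(res$ledger$n_manual_added, 1)
  expect_true("manual" %in% res$particles$source)
  expect_error(apply_curation(ps, discard = data.frame(particle_id = 99,
                                                       category = "x")),
               "unknown particle_id")
})
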