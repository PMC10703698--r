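plane_mask <- function(dims, vs, z_layer) {
  arr <- array(FALSE, dim = dims)
  arr[, , z_layer] <- TRUE
  binary_mask(arr, vs)
}

test_that("surface distance is centre distance minus the particle radius", {
  dims <- c(40, 40, 40)
  vs <- 1.0
  mask <- plane_mask(dims, vs, 10)  # plane at z = 9 nm
  ps <- particle_set(data.frame(
    x_nm = c(20, 20), y_nm = c(20, 20), z_nm = c(9, 31.5)))
  recs <- surface_distances(ps, mask, spatial_params(particle_radius = 12.5))
  # particle centred on a structure voxel: -12.5 nm exactly
  expect_equal(recs$surface_distance_nm[1], -12.5)
  # centre 22.5 nm above the plane: 22.5 - 12.5 = 10 nm
  expect_equal(recs$surface_distance_nm[2], 10.0, tolerance = 0.5)
  expect_equal(recs$surface_distance_nm, recs$center_distance_nm - 12.5)
})

test_that("distances agree with exhaustive nearest-voxel search", {
  set.seed(19)
  dims <- c(24, 24, 24)
  arr <- array(runif(prod(dims)) > 0.98, dim = dims)
  arr[12, 12, 12] <- TRUE
  mask <- binary_mask(arr, 1.37)
  centers <- matrix(runif(50 * 3, 2, 29), ncol = 3)
  ps <- particle_set(data.frame(x_nm = centers[, 1], y_nm = centers[, 2],
                                z_nm = centers[, 3]))
  recs <- surface_distances(ps, mask, spatial_params())
  oracle <- vapply(seq_len(50),
                   function(q) brute_force_distance(centers[q, ], mask),
                   numeric(1))
  # trilinear interpolation of the EDT vs exact search: within half a
  # voxel diagonal
  expect_true(all(abs(recs$center_distance_nm - oracle) <=
                    sqrt(3) / 2 * 1.37))
  # nearest-voxel sampling is available as a compatibility switch
  recs_nn <- surface_distances(ps, mask, spatial_params(), sampling = "nearest")
  expect_true(all(abs(recs_nn$center_distance_nm - oracle) <=
                    sqrt(3) / 2 * 1.37))
})

test_that("distances are invariant under whole-voxel translations", {
  dims <- c(32, 32, 32)
  arr <- array(FALSE, dim = dims)
  arr[10:12, 14:15, 8] <- TRUE
  shift <- c(3L, -2L, 5L)
  arr2 <- array(FALSE, dim = dims)
  arr2[10:12 + shift[1], 14:15 + shift[2], 8 + shift[3]] <- TRUE
  vs <- 1.37
  ps1 <- particle_set(data.frame(x_nm = 20, y_nm = 20, z_nm = 25))
  ps2 <- particle_set(data.frame(x_nm = 20 + shift[1] * vs,
                                 y_nm = 20 + shift[2] * vs,
                                 z_nm = 25 + shift[3] * vs))
  r1 <- surface_distances(ps1, binary_mask(arr, vs))
  r2 <- surface_distances(ps2, binary_mask(arr2, vs))
  expect_equal(r1$surface_distance_nm, r2$surface_distance_nm,
               tolerance = 1e-10)
})

test_that("an empty structure mask is an input error", {
  ps <- particle_set(data.frame(x_nm = 1, y_nm = 1, z_nm = 1))
  expect_error(surface_distances(ps, binary_mask(array(FALSE, c(8, 8, 8)), 1)),
               "input error")
})

test_that("fraction_within is inclusive at the boundary and monotone", {
  recs <- data.frame(surface_distance_nm = c(10, 49.9, 50.0, 50.1))
  fw <- fraction_within(recs, 50)
  expect_equal(fw$n_within, 3)
  expect_equal(fw$fraction, 3 / 4)

  # all-negative distances (overlapping particles) are all within
  expect_equal(fraction_within(
    data.frame(surface_distance_nm = c(-1, -20, -0.1)), 50)$fraction, 1.0)

  # monotone nondecreasing in the cutoff
  set.seed(3)
  d <- data.frame(surface_distance_nm = rnorm(200, 30, 25))
  fracs <- vapply(seq(0, 100, 5), function(ct) fraction_within(d, ct)$fraction,
                  numeric(1))
  expect_true(all(diff(fracs) >= 0))

  expect_error(fraction_within(data.frame(surface_distance_nm = numeric(0))),
               "input error")
})

test_that("dilation matches lattice-ball enumeration and is a semigroup", {
  dims <- c(31, 31, 31)
  arr <- array(FALSE, dim = dims)
  arr[16, 16, 16] <- TRUE
  m <- binary_mask(arr, 1)

  d10 <- dilate_mask(m, 10)
  expect_equal(sum(d10$data), lattice_ball_count(10))

  # at the published scale: 50 nm at 1.37 nm voxels
  dims2 <- c(81, 81, 81)
  arr2 <- array(FALSE, dim = dims2)
  arr2[41, 41, 41] <- TRUE
  d50 <- dilate_mask(binary_mask(arr2, 1.37), 50)
  expect_equal(sum(d50$data), lattice_ball_count(50 / 1.37))

  # empty in, empty out
  expect_equal(sum(dilate_mask(binary_mask(array(FALSE, c(8, 8, 8)), 1), 5)$data), 0)

  # sub-voxel radius warns and returns the input
  expect_warning(same <- dilate_mask(m, 0.5), "voxel")
  expect_identical(same$data, m$data)

  # dilation by r then s equals dilation by r + s within a voxel boundary
  dr <- dilate_mask(m, 4)
  drs <- dilate_mask(dr, 5)
  direct <- dilate_mask(m, 9)
  mismatch <- which(drs$data != direct$data)
  if (length(mismatch)) {
    dt <- distance_to_mask(m)$data[mismatch]
    expect_true(all(abs(dt - 9) <= sqrt(3)))
  }
  # exact-EDT iterated dilation can undershoot but never overshoot r + s
  expect_true(all(direct$data[drs$data]))
})

test_that("distance summaries report mean, sample sd and n", {
  r1 <- data.frame(tomo_id = "t1", surface_distance_nm = c(10, 10, 10))
  s1 <- summarize_distances(r1)
  expect_equal(s1$mean_nm, c(10, 10))
  expect_equal(s1$sd_nm, c(0, 0))

  r2 <- data.frame(tomo_id = "t1", surface_distance_nm = c(0, 20))
  s2 <- summarize_distances(r2)
  expect_equal(s2$mean_nm[1], 10)
  expect_equal(s2$sd_nm[1], sqrt(200), tolerance = 1e-12)  # 14.142...

  # single observation: sd is missing, not zero
  s3 <- summarize_distances(data.frame(tomo_id = "t1",
                                       surface_distance_nm = 5))
  expect_true(is.na(s3$sd_nm[1]))

  # per-tomogram split plus pooled row
  r4 <- data.frame(tomo_id = c("a", "a", "b"),
                   surface_distance_nm = c(1, 3, 10))
  s4 <- summarize_distances(r4)
  expect_equal(nrow(s4), 3)
  expect_equal(s4$mean_nm[s4$tomo_id == "pooled"], mean(c(1, 3, 10)))
})
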