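test_that("overlap fractions count pixels in both directions", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE   # 100 px
  b <- matrix(FALSE, 20, 20); b[6:15, 1:20] <- TRUE   # 200 px
  ov <- overlap_fractions(a, b)                       # overlap 50 px
  expect_equal(ov$overlap_pixels, 50)
  expect_equal(ov$frac_a_in_b, 0.5)
  expect_equal(ov$frac_b_in_a, 0.25)

  # identical and disjoint masks
  expect_equal(overlap_fractions(a, a)[c(1, 2)],
               list(frac_a_in_b = 1.0, frac_b_in_a = 1.0))
  d <- matrix(FALSE, 20, 20); d[15:20, 15:20] <- TRUE
  expect_equal(overlap_fractions(a, d)$frac_a_in_b, 0.0)

  # swapping arguments swaps the outputs
  ov_sw <- overlap_fractions(b, a)
  expect_equal(ov_sw$frac_a_in_b, ov$frac_b_in_a)
  expect_equal(ov_sw$frac_b_in_a, ov$frac_a_in_b)

  # empty mask: missing, not zero
  e <- matrix(FALSE, 20, 20)
  expect_true(is.na(overlap_fractions(e, a)$frac_a_in_b))
  expect_error(overlap_fractions(a, matrix(TRUE, 5, 5)), "input error")
})

test_that("puncta segmentation finds the rendered spots and honours min_area", {
  set.seed(77)
  centers <- cbind(runif(12, 15, 113), runif(12, 15, 113))
  # enforce separation so the truth count is unambiguous
  while (min(dist(centers)) < 12) {
    centers <- cbind(runif(12, 15, 113), runif(12, 15, 113))
  }
  img <- gemquant:::render_spots(c(128, 128), centers, sigma = 1.5) +
    matrix(abs(rnorm(128^2, 0, 0.02)), 128, 128)
  seg <- segment_puncta(img, min_area = 4)
  lab <- label_components(binary_mask(array(seg, c(128, 128, 1)), 1))
  expect_equal(max(lab), 12)

  # min_area larger than every spot: empty mask
  seg_big <- segment_puncta(img, min_area = 10000)
  expect_equal(sum(seg_big), 0)

  # constant image: threshold error
  expect_error(segment_puncta(matrix(1, 10, 10)), "threshold error")
})

test_that("per-grid normalization divides by the grid mean intensity", {
  expect_equal(per_grid_normalize(c(2, 4, 6), c("g1", "g1", "g1")),
               c(0.5, 1.0, 1.5))
  # a single cell on its grid normalizes to exactly 1
  expect_equal(per_grid_normalize(5, "g1"), 1.0)
  # different absolute scales, identical relative patterns
  x1 <- per_grid_normalize(c(1, 2, 3, 10, 20, 30),
                           c("a", "a", "a", "b", "b", "b"))
  expect_equal(x1[1:3], x1[4:6])
  expect_error(per_grid_normalize(c(0, 0), c("g", "g")),
               "normalization error")
  # batch correction factors multiply through
  x2 <- per_grid_normalize(c(2, 4), c("a", "a"), batch = c("b1", "b1"),
                           correction_factors = c(b1 = 2))
  expect_equal(x2, c(4 / 3, 8 / 3))
})

test_that("Kruskal-Wallis and Dunn agree with direct rank-formula computation", {
  x <- c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15)
  g <- rep(c("t0", "t30"), each = 5)
  res <- compare_to_baseline(x, g, baseline = "t0")

  # oracle: untied two-group formulas computed from scratch
  r <- rank(x)
  N <- 10
  H_oracle <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (N + 1)
  rbar <- tapply(r, g, mean)
  z_oracle <- (rbar[["t30"]] - rbar[["t0"]]) /
    sqrt(N * (N + 1) / 12 * (1 / 5 + 1 / 5))
  p_oracle <- 2 * pnorm(-abs(z_oracle))

  expect_equal(res$H, H_oracle, tolerance = 1e-9)
  expect_equal(res$comparisons$z, unname(z_oracle), tolerance = 1e-9)
  expect_equal(res$comparisons$p_adjusted, unname(p_oracle), tolerance = 1e-9)
})

test_that("identical groups are not significant and ranks ignore monotone maps", {
  x <- rep(c(3, 1, 4, 1, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  res <- compare_to_baseline(x, g)
  expect_gte(res$comparisons$p_adjusted, 0.9)

  # rank-based: any strictly monotone transform leaves the result unchanged
  set.seed(4)
  y <- c(rnorm(8), rnorm(8, 2), rnorm(8, 3))
  gg <- rep(c("t0", "t15", "t30"), each = 8)
  r1 <- compare_to_baseline(y, gg)
  r2 <- compare_to_baseline(exp(y), gg)
  expect_equal(r1$H, r2$H)
  expect_equal(r1$comparisons$p_adjusted, r2$comparisons$p_adjusted)
})

test_that("baseline comparisons detect a true shift with high power", {
  set.seed(8)
  hits <- vapply(1:10, function(rep) {
    y <- c(rnorm(40, 0, 1), rnorm(40, 1.2, 1), rnorm(40, 1.5, 1))
    g <- rep(c("t0", "t30", "t60"), each = 40)
    res <- compare_to_baseline(y, g)
    all(res$comparisons$p_adjusted < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("rank correlation behaves at the extremes and matches the formula", {
  expect_equal(rank_correlation(1:6, 6:1)$rho, -1)
  expect_equal(rank_correlation(1:6, (1:6)^3)$rho, +1)

  x <- c(3, 1, 4, 1.5, 5); y <- c(2, 6, 5, 3, 4)
  # brute-force Spearman from rank differences (no ties)
  dr <- rank(x) - rank(y)
  rho_oracle <- 1 - 6 * sum(dr^2) / (5 * (5^2 - 1))
  expect_equal(rank_correlation(x, y)$rho, rho_oracle, tolerance = 1e-12)

  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("recruitment timecourses follow first-order saturation", {
  cfg <- coloc_timecourse_config(n_cells = 6, timepoints = c(0, 30, 600),
                                 f_max = 0.8, tau = 30, puncta_per_cell = 50,
                                 seed = 15)
  sim <- simulate_coloc_timecourse(cfg)
  tt <- sim$truth

  # t = 0: nothing bound yet
  expect_true(all(tt$n_bound[tt$timepoint == 0] == 0))

  # t = tau: expected fraction f_max (1 - exp(-1)) = 0.632 f_max
  expect_equal(unique(tt$expected_frac[tt$timepoint == 30]),
               0.8 * (1 - exp(-1)), tolerance = 1e-12)

  # t = 20 tau: realized fraction within a binomial 99% interval of f_max
  late <- tt[tt$timepoint == 600, ]
  n_tot <- sum(late$n_puncta)
  phat <- sum(late$n_bound) / n_tot
  expect_lt(abs(phat - 0.8), 2.58 * sqrt(0.8 * 0.2 / n_tot))
})

test_that("image-level estimates recover the recruitment curve", {
  cfg <- coloc_timecourse_config(n_cells = 8, timepoints = c(0, 15, 30, 90),
                                 f_max = 0.7, tau = 30, puncta_per_cell = 30,
                                 seed = 33)
  sim <- simulate_coloc_timecourse(cfg)
  est <- vapply(seq_len(nrow(sim$truth)), function(q) {
    seg <- segment_puncta(sim$images[[q]], threshold = 0.2, min_area = 3)
    puncta_on_target_fraction(seg, sim$target_mask)$fraction
  }, numeric(1))
  by_time <- tapply(est, sim$truth$timepoint, mean, na.rm = TRUE)
  truth_by_time <- tapply(sim$truth$frac_bound, sim$truth$timepoint, mean)
  # spot merging perturbs counts slightly; the curve must track within 0.1
  expect_true(all(abs(by_time - truth_by_time) < 0.1))
})
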