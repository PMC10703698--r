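test_that("normalization sets the prebleach mean to 1 and is scale invariant", {
  tr <- frap_trace(times = seq(0, 2, 0.05),
                   intensities = c(rep(100, 10), seq(60, 90, length.out = 31)),
                   background = 20, n_prebleach = 10)
  norm <- normalize_trace(tr)
  expect_equal(mean(norm$intensities[1:10]), 1.0)

  scaled <- frap_trace(times = tr$times, intensities = tr$intensities * 3.7,
                       background = 20 * 3.7, n_prebleach = 10)
  expect_equal(normalize_trace(scaled)$intensities, norm$intensities,
               tolerance = 1e-12)

  bad <- frap_trace(times = 0:14, intensities = rep(5, 15), background = 10,
                    n_prebleach = 10)
  expect_error(normalize_trace(bad), "normalization error")
})

test_that("the recovery midpoint sits at one half-life", {
  # plateau 1, bleach depth 0.4: after one half-life the trace reads 0.7
  cfg <- frap_sim_config(true_half_life = 1.0, bleach_depth = 0.4,
                         plateau = 1.0, noise_sd = 0, background_level = 0,
                         n_frames = 100, seed = 1)
  tr <- simulate_frap_traces(cfg)[[1]]
  t_post0 <- tr$times[cfg$n_prebleach + 1]
  idx <- which(abs((tr$times - t_post0) - 1.0) < 1e-9)
  expect_equal(tr$intensities[idx], 0.7, tolerance = 1e-12)
})

test_that("noise-free traces recover the exact generating half-life", {
  cfg <- frap_sim_config(true_half_life = 1.0, noise_sd = 0, seed = 2)
  fit <- fit_recovery(normalize_trace(simulate_frap_traces(cfg)[[1]]))
  expect_equal(fit$half_life, 1.0, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(fit$half_life * fit$rate, log(2), tolerance = 1e-12)
  expect_gt(fit$plateau, fit$bleach_depth)
})

test_that("fitted half-life is exact across generating parameter values", {
  for (hl in c(0.3, 1.0, 2.5)) {
    cfg <- frap_sim_config(true_half_life = hl, bleach_depth = 0.3,
                           plateau = 0.85, noise_sd = 0,
                           n_frames = 300, seed = 5)
    fit <- fit_recovery(normalize_trace(simulate_frap_traces(cfg)[[1]]))
    expect_equal(fit$half_life, hl, tolerance = 1e-6)
    expect_equal(fit$plateau, 0.85 / 1.0, tolerance = 1e-6)
  }
})

test_that("a flat post-bleach trace is an identifiability error", {
  tr <- frap_trace(times = seq(0, 5, 0.05),
                   intensities = c(rep(1, 10), rep(0.4, 91)),
                   background = 0, n_prebleach = 10)
  expect_error(fit_recovery(tr), "identifiability")
})

test_that("aggregation reports mean, sd and failure counts", {
  f1 <- structure(list(half_life = 0.5), class = "frap_fit")
  f2 <- structure(list(half_life = 1.5), class = "frap_fit")
  agg <- aggregate_fits(list(f1, f2))
  expect_equal(agg$mean_half_life, 1.0)
  expect_equal(agg$sd_half_life, sqrt(0.5), tolerance = 1e-9)  # 0.7071

  agg1 <- aggregate_fits(list(f1))
  expect_true(is.na(agg1$sd_half_life))

  failed <- simpleError("identifiability error")
  agg2 <- aggregate_fits(list(f1, failed, f2))
  expect_equal(agg2$n_failed, 1)
  expect_equal(agg2$n_fits, 2)
  expect_error(aggregate_fits(list(failed)), "no successful fits")
})

test_that("mean-trace fitting recovers the half-life from noisy replicates", {
  cfg <- frap_sim_config(true_half_life = 1.0, noise_sd = 0.05,
                         n_traces = 50, seed = 6)
  traces <- lapply(simulate_frap_traces(cfg), normalize_trace)
  fit <- fit_recovery(mean_trace(traces))
  expect_equal(fit$half_life, 1.0, tolerance = 0.05)
})

test_that("FRAP traces round-trip through CSV", {
  cfg <- frap_sim_config(n_traces = 2, noise_sd = 0.02, seed = 9)
  traces <- simulate_frap_traces(cfg)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = tr$times, intensity = tr$intensities,
               background = tr$background, trace_id = tr$trace_id)
  }))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_frap_traces(path, n_prebleach = 10)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$intensities, traces[[1]]$intensities,
               tolerance = 1e-12)
  bad_path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = 1, intensity = 2), bad_path,
                   row.names = FALSE)
  expect_error(read_frap_traces(bad_path), "schema error")
})
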