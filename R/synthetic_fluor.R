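#' Configuration for a recruitment-timecourse simulation
#'
#' Emulates per-cell fluorescence images of punctate tag particles being
#' recruited to a target structure after induction. The expected fraction of
#' puncta on the target follows first-order saturation
#' `f(t) = f_max * (1 - exp(-t / tau))` — a stated modelling choice for the
#' generator, not a measured mechanism. Each punctum is rendered as a
#' Gaussian spot; a punctum is "on target" when its centre lies inside the
#' target mask.
#'
#' @param n_cells cells per timepoint.
#' @param timepoints sorted nonnegative times, minutes.
#' @param f_max asymptotic bound fraction in \[0, 1\].
#' @param tau recruitment time constant, minutes.
#' @param puncta_per_cell puncta rendered per cell.
#' @param image_shape pixel pair (nx, ny).
#' @param pixel_size nm/pixel.
#' @param spot_sigma Gaussian spot sd, pixels.
#' @param poisson_scale,gaussian_sd noise model: photon scaling for Poisson
#'   shot noise (0 disables) and additive Gaussian read noise sd.
#' @param seed integer seed.
#' @return A list of class `coloc_timecourse_config`.
#' @export
coloc_timecourse_config <- function(n_cells = 10L,
                                    timepoints = c(0, 15, 30, 60),
                                    f_max = 0.8, tau = 30,
                                    puncta_per_cell = 40L,
                                    image_shape = c(128L, 128L),
                                    pixel_size = 100,
                                    spot_sigma = 1.5,
                                    poisson_scale = 0, gaussian_sd = 0,
                                    seed = 1L) {
  if (f_max < 0 || f_max > 1) stop("config error: f_max must be in [0, 1]")
  if (any(timepoints < 0) || is.unsorted(timepoints)) {
    stop("config error: timepoints must be nonnegative and sorted")
  }
  if (tau <= 0) stop("config error: tau must be positive")
  structure(list(n_cells = as.integer(n_cells), timepoints = timepoints,
                 f_max = f_max, tau = tau,
                 puncta_per_cell = as.integer(puncta_per_cell),
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, spot_sigma = spot_sigma,
                 poisson_scale = poisson_scale, gaussian_sd = gaussian_sd,
                 seed = as.integer(seed)),
            class = "coloc_timecourse_config")
}

# internal: render Gaussian spots of unit amplitude at (x, y) pixel centres
render_spots <- function(shape, centers, sigma) {
  img <- matrix(0, shape[1], shape[2])
  if (!nrow(centers)) return(img)
  half <- ceiling(4 * sigma)
  for (q in seq_len(nrow(centers))) {
    cx <- centers[q, 1]; cy <- centers[q, 2]
    ii <- max(1, floor(cx - half)):min(shape[1], ceiling(cx + half))
    jj <- max(1, floor(cy - half)):min(shape[2], ceiling(cy + half))
    spot <- exp(-outer((ii - cx)^2, (jj - cy)^2, "+") / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + spot
  }
  img
}

#' Simulate a recruitment timecourse of punctate labels
#'
#' For every cell and timepoint, draws each punctum onto the target with
#' probability `f_max * (1 - exp(-t / tau))` (uniform position inside the
#' target mask) or off target (uniform outside), renders the puncta image,
#' and records the realized bound fraction in a truth table.
#'
#' @param config a [coloc_timecourse_config].
#' @return A list of class `coloc_timecourse` with `truth` (data frame:
#'   `cell_id`, `timepoint`, `n_puncta`, `n_bound`, `frac_bound`,
#'   `expected_frac`), `images` (list of puncta images, one per
#'   cell-timepoint, row order matching `truth`) and `target_mask` (logical
#'   matrix shared by all cells).
#' @export
simulate_coloc_timecourse <- function(config = coloc_timecourse_config()) {
  stopifnot(inherits(config, "coloc_timecourse_config"))
  set.seed(config$seed)
  sh <- config$image_shape
  # target: a centred disc covering ~15% of the field
  rad <- 0.22 * min(sh)
  cx <- (sh[1] + 1) / 2; cy <- (sh[2] + 1) / 2
  target <- outer((seq_len(sh[1]) - cx)^2, (seq_len(sh[2]) - cy)^2, "+") <=
    rad^2
  on_idx <- which(target)
  off_idx <- which(!target)
  truth <- list()
  images <- list()
  row <- 0L
  for (t in config$timepoints) {
    p_bound <- config$f_max * (1 - exp(-t / config$tau))
    for (cell in seq_len(config$n_cells)) {
      n <- config$puncta_per_cell
      bound <- stats::runif(n) < p_bound
      pick <- function(idx_pool, k) {
        idx <- idx_pool[sample.int(length(idx_pool), k, replace = TRUE)]
        ij <- arrayInd(idx, sh)
        # jitter within the pixel so spot centres are continuous
        ij + matrix(stats::runif(2 * k, -0.5, 0.5), k, 2)
      }
      centers <- matrix(0, n, 2)
      if (any(bound)) centers[bound, ] <- pick(on_idx, sum(bound))
      if (any(!bound)) centers[!bound, ] <- pick(off_idx, sum(!bound))
      img <- render_spots(sh, centers, config$spot_sigma)
      if (config$poisson_scale > 0) {
        img <- stats::rpois(length(img), img * config$poisson_scale) /
          config$poisson_scale
        img <- matrix(img, sh[1], sh[2])
      }
      if (config$gaussian_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, config$gaussian_sd),
                            sh[1], sh[2])
      }
      row <- row + 1L
      truth[[row]] <- data.frame(cell_id = cell, timepoint = t,
                                 n_puncta = n, n_bound = sum(bound),
                                 frac_bound = mean(bound),
                                 expected_frac = p_bound)
      images[[row]] <- img
    }
  }
  structure(list(truth = do.call(rbind, truth), images = images,
                 target_mask = target, config = config),
            class = "coloc_timecourse")
}

#' Configuration for simulated FRAP traces
#'
#' Each trace has `n_prebleach` prebleach frames at the full (unbleached)
#' intensity, an instantaneous bleach, and single-exponential recovery
#' `I(t) = plateau - (plateau - bleach_depth) * exp(-k t)` with
#' `k = ln(2) / true_half_life`, plus a constant background channel and
#' additive Gaussian noise. Frames are 50 ms apart by default.
#'
#' @param true_half_life ground-truth recovery half-life, s.
#' @param bleach_depth post-bleach intensity fraction.
#' @param plateau recovered plateau fraction (mobile fraction below 1
#'   models an immobile pool).
#' @param frame_interval s/frame (default 0.05).
#' @param n_prebleach prebleach frames (default 10).
#' @param n_frames total frames.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param background_level constant background, intensity units.
#' @param intensity_scale prebleach signal amplitude above background.
#' @param n_traces number of traces.
#' @param seed integer seed.
#' @return A list of class `frap_sim_config`.
#' @export
frap_sim_config <- function(true_half_life = 1.0, bleach_depth = 0.4,
                            plateau = 0.9, frame_interval = 0.05,
                            n_prebleach = 10L, n_frames = 200L,
                            noise_sd = 0.05, background_level = 0.1,
                            intensity_scale = 1.0, n_traces = 1L,
                            seed = 1L) {
  if (true_half_life <= 0) stop("true_half_life must be positive")
  if (n_prebleach < 1) stop("need at least one prebleach frame")
  if (n_frames <= n_prebleach + 3) stop("too few post-bleach frames")
  structure(list(true_half_life = true_half_life, bleach_depth = bleach_depth,
                 plateau = plateau, frame_interval = frame_interval,
                 n_prebleach = as.integer(n_prebleach),
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 background_level = background_level,
                 intensity_scale = intensity_scale,
                 n_traces = as.integer(n_traces), seed = as.integer(seed)),
            class = "frap_sim_config")
}

#' Simulate FRAP recovery traces
#'
#' @param config a [frap_sim_config].
#' @return A list of [frap_trace] objects (length `n_traces`).
#' @export
simulate_frap_traces <- function(config = frap_sim_config()) {
  stopifnot(inherits(config, "frap_sim_config"))
  set.seed(config$seed)
  k <- log(2) / config$true_half_life
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  pre <- seq_len(config$n_prebleach)
  t_post <- times[-pre] - times[config$n_prebleach + 1]
  model <- numeric(config$n_frames)
  model[pre] <- 1
  model[-pre] <- config$plateau -
    (config$plateau - config$bleach_depth) * exp(-k * t_post)
  lapply(seq_len(config$n_traces), function(i) {
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(config$n_frames, 0, config$noise_sd)
    } else 0
    frap_trace(times = times,
               intensities = config$intensity_scale * model +
                 config$background_level + noise,
               background = config$background_level,
               n_prebleach = config$n_prebleach,
               trace_id = i)
  })
}
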