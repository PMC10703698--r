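#' FRAP intensity trace
#'
#' A photobleaching timecourse: strictly increasing times (s), raw
#' intensities, a background channel (scalar or per-frame) and the number of
#' prebleach frames. The first `n_prebleach` frames precede the bleach; the
#' frame after them is the first post-bleach frame.
#'
#' @param times times in s, strictly increasing.
#' @param intensities measured intensities, arbitrary units.
#' @param background background intensity (scalar or per-frame vector).
#' @param n_prebleach number of prebleach frames (default 10).
#' @param trace_id optional identifier.
#' @param normalized logical flag set by [normalize_trace()].
#' @return A list of class `frap_trace`.
#' @export
frap_trace <- function(times, intensities, background = 0,
                       n_prebleach = 10L, trace_id = NULL,
                       normalized = FALSE) {
  if (length(times) != length(intensities)) {
    stop("times and intensities must have equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!length(background) %in% c(1L, length(times))) {
    stop("background must be scalar or per-frame")
  }
  if (n_prebleach < 1 || n_prebleach >= length(times)) {
    stop("n_prebleach must leave post-bleach frames")
  }
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 background = as.numeric(background),
                 n_prebleach = as.integer(n_prebleach),
                 trace_id = trace_id, normalized = normalized),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace%s> %d frames (%d prebleach), dt = %.3g s%s\n",
              if (is.null(x$trace_id)) "" else paste0(" ", x$trace_id),
              length(x$times), x$n_prebleach, stats::median(diff(x$times)),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Background-subtract and normalize a FRAP trace
#'
#' Single normalization: `I_norm(t) = (I(t) - B(t)) / mean_prebleach(I - B)`,
#' so the prebleach mean of the output is exactly 1.
#'
#' @param trace a [frap_trace].
#' @return A normalized [frap_trace] (background 0).
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  corr <- trace$intensities - trace$background
  pre_mean <- mean(corr[seq_len(trace$n_prebleach)])
  if (!is.finite(pre_mean) || pre_mean <= 0) {
    stop("normalization error: prebleach mean <= 0 after background subtraction")
  }
  frap_trace(times = trace$times, intensities = corr / pre_mean,
             background = 0, n_prebleach = trace$n_prebleach,
             trace_id = trace$trace_id, normalized = TRUE)
}

#' Fit a single-exponential recovery to a FRAP trace
#'
#' Least-squares fit of `I(t) = I_inf - (I_inf - I_0) * exp(-k (t - t0))` to
#' the post-bleach frames of a normalized trace, with `t0` the time of the
#' first post-bleach frame (the bleach event itself is not a fitted frame).
#' Initial values: `I_0` = first post-bleach intensity, `I_inf` = mean of
#' the final 10% of frames, `k` from a log-linear regression of
#' `I_inf - I(t)`. Optimization by Levenberg-Marquardt.
#'
#' @param trace a normalized [frap_trace] with at least 4 post-bleach frames.
#' @return An object of class `frap_fit` with components `rate` (k, 1/s),
#'   `half_life` (`ln(2)/k`, s), `bleach_depth` (I_0), `plateau` (I_inf),
#'   `r_squared`, `fitted`, `residuals`, `times` (post-bleach, absolute) and
#'   `data` (observed post-bleach intensities). Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  post <- (trace$n_prebleach + 1):length(trace$times)
  if (length(post) < 4) stop("need at least 4 post-bleach frames")
  t_abs <- trace$times[post]
  tt <- t_abs - t_abs[1]
  y <- trace$intensities[post]

  i0_init <- y[1]
  tail_n <- max(ceiling(0.1 * length(y)), 2)
  iinf_init <- mean(utils::tail(y, tail_n))
  amp <- iinf_init - y
  pos <- amp > 0 & tt > 0
  k_init <- if (sum(pos) >= 2) {
    max(-stats::coef(stats::lm(log(amp[pos]) ~ tt[pos]))[[2]], 1e-3)
  } else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ iinf - (iinf - i0) * exp(-k * tt),
      start = list(iinf = iinf_init, i0 = i0_init, k = k_init),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("identifiability error: recovery fit failed (", conditionMessage(e),
           "); post-bleach range [", signif(min(y), 4), ", ",
           signif(max(y), 4), "]")
    })
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0 || cf[["iinf"]] <= cf[["i0"]]) {
    stop("identifiability error: non-recovering trace (k = ",
         signif(cf[["k"]], 4), ", I_inf = ", signif(cf[["iinf"]], 4),
         ", I_0 = ", signif(cf[["i0"]], 4), ")")
  }
  fitted_vals <- cf[["iinf"]] - (cf[["iinf"]] - cf[["i0"]]) *
    exp(-cf[["k"]] * tt)
  res <- y - fitted_vals
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(rate = cf[["k"]], half_life = log(2) / cf[["k"]],
                 bleach_depth = cf[["i0"]], plateau = cf[["iinf"]],
                 r_squared = r2, fitted = fitted_vals, residuals = res,
                 times = t_abs, data = y, t_origin = t_abs[1],
                 trace_id = trace$trace_id),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> half-life %.3g s (k = %.3g 1/s), I0 = %.3g, Iinf = %.3g, R2 = %.4f\n",
              x$half_life, x$rate, x$bleach_depth, x$plateau, x$r_squared))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(rate = object$rate, half_life = object$half_life,
    bleach_depth = object$bleach_depth, plateau = object$plateau)
}

#' @export
summary.frap_fit <- function(object, ...) {
  cat("Single-exponential FRAP recovery fit\n")
  cat(sprintf("  recovery rate k     : %.4g 1/s\n", object$rate))
  cat(sprintf("  half-life ln(2)/k   : %.4g s\n", object$half_life))
  cat(sprintf("  bleach depth I_0    : %.4g\n", object$bleach_depth))
  cat(sprintf("  plateau I_inf       : %.4g\n", object$plateau))
  cat(sprintf("  mobile-range recovery (I_inf - I_0): %.4g\n",
              object$plateau - object$bleach_depth))
  cat(sprintf("  R-squared           : %.5f over %d post-bleach frames\n",
              object$r_squared, length(object$data)))
  invisible(object)
}

#' @export
predict.frap_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  tt <- times - object$t_origin
  object$plateau - (object$plateau - object$bleach_depth) *
    exp(-object$rate * pmax(tt, 0))
}

#' @export
residuals.frap_fit <- function(object, ...) object$residuals

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$times, x$data, pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "normalized intensity",
                 main = sprintf("FRAP recovery: half-life %.2g s", x$half_life),
                 ...)
  graphics::lines(x$times, x$fitted, col = "red", lwd = 2)
  invisible(x)
}

#' Aggregate per-trace FRAP fits
#'
#' Mean and sample sd of half-lives across successful per-trace fits;
#' failed fits are excluded and counted. Complements mean-trace fitting:
#' fitting the mean of normalized traces gives the headline half-life, while
#' the per-trace spread gives the `+/-` value.
#'
#' @param fits list of [fit_recovery()] results; elements may also be
#'   (caught) error conditions, which count as failures.
#' @return A list with `mean_half_life`, `sd_half_life` (`NA` for a single
#'   fit), `n_fits`, `n_failed`, `half_lives`.
#' @export
aggregate_fits <- function(fits) {
  ok <- vapply(fits, inherits, logical(1), "frap_fit")
  if (!any(ok)) stop("no successful fits to aggregate")
  hl <- vapply(fits[ok], `[[`, numeric(1), "half_life")
  list(mean_half_life = mean(hl),
       sd_half_life = if (length(hl) > 1) stats::sd(hl) else NA_real_,
       n_fits = length(hl), n_failed = sum(!ok), half_lives = hl)
}

#' Average normalized FRAP traces into a mean trace
#'
#' @param traces list of normalized [frap_trace] objects on a common time
#'   base.
#' @return A [frap_trace] of the frame-wise mean intensities.
#' @export
mean_trace <- function(traces) {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "frap_trace")))
  t0 <- traces[[1]]$times
  for (tr in traces) {
    if (!isTRUE(all.equal(tr$times, t0))) {
      stop("traces must share a common time base")
    }
  }
  m <- rowMeans(vapply(traces, `[[`, numeric(length(t0)), "intensities"))
  frap_trace(times = t0, intensities = m, background = 0,
             n_prebleach = traces[[1]]$n_prebleach, trace_id = "mean",
             normalized = all(vapply(traces, `[[`, logical(1), "normalized")))
}

#' Read FRAP traces from CSV
#'
#' Expected columns: `time_s`, `intensity`, `background` and optionally
#' `trace_id` (one trace per id).
#'
#' @param path CSV path.
#' @param n_prebleach prebleach frame count.
#' @return A list of [frap_trace] objects.
#' @export
read_frap_traces <- function(path, n_prebleach = 10L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "intensity", "background")
  absent <- setdiff(req, names(df))
  if (length(absent)) {
    stop("FRAP trace schema error, missing column(s): ",
         paste(absent, collapse = ", "))
  }
  if (is.null(df$trace_id)) df$trace_id <- "trace_1"
  lapply(split(df, df$trace_id), function(g) {
    frap_trace(g$time_s, g$intensity, g$background,
               n_prebleach = n_prebleach, trace_id = g$trace_id[1])
  })
}
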