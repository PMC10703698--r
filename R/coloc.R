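# internal: coerce mask input (binary_mask, logical matrix/array) to array
as_mask_array <- function(m) {
  if (inherits(m, "binary_mask")) return(m$data)
  if (is.logical(m)) return(m)
  stop("expected a binary_mask or a logical array")
}

#' Mutual overlap fractions of two segmentations
#'
#' Pixel-count overlap in both directions: `|A n B| / |A|` (the fraction of
#' the tag segmentation on the target) and `|A n B| / |B|` (the fraction of
#' the target covered by the tag). An empty mask makes its own fraction
#' missing (`NA`), never silently zero.
#'
#' @param mask_a,mask_b logical matrices/arrays or [binary_mask] objects of
#'   identical dimensions.
#' @return A list with `frac_a_in_b`, `frac_b_in_a` and `overlap_pixels`.
#' @export
overlap_fractions <- function(mask_a, mask_b) {
  a <- as_mask_array(mask_a)
  b <- as_mask_array(mask_b)
  if (!identical(dim(a), dim(b))) {
    stop("input error: mask geometries differ")
  }
  inter <- sum(a & b)
  list(frac_a_in_b = if (sum(a) > 0) inter / sum(a) else NA_real_,
       frac_b_in_a = if (sum(b) > 0) inter / sum(b) else NA_real_,
       overlap_pixels = inter)
}

# internal: Otsu threshold on a 256-bin histogram (maximizes between-class
# variance); standard global threshold for bimodal fluorescence images
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) stop("threshold error: constant image")
  nbins <- 256L
  h <- tabulate(pmin(floor((x - rng[1]) / diff(rng) * nbins) + 1L, nbins),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  mids[which.max(sigma_b)]
}

#' Segment punctate labels in a fluorescence image
#'
#' Global thresholding (Otsu's between-class-variance criterion by default,
#' or a fixed value) followed by a minimum-area filter on connected
#' components (8-connectivity). Deterministic.
#'
#' @param image nonnegative numeric matrix.
#' @param threshold `"otsu"` or a numeric threshold.
#' @param min_area minimum component area in pixels.
#' @return A logical matrix mask of the retained puncta.
#' @export
segment_puncta <- function(image, threshold = "otsu", min_area = 4) {
  stopifnot(is.matrix(image))
  if (min(image) < 0) stop("segment_puncta expects a nonnegative image")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image) else threshold
  bin <- image > thr
  if (!any(bin)) return(bin)
  lab <- label_components_cpp(as.logical(bin), c(dim(bin), 1L), 26L)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_area)
  matrix(lab %in% keep, nrow(image), ncol(image))
}

#' Fraction of puncta centred on a target mask
#'
#' Labels the puncta mask and counts components whose centroid falls inside
#' the target mask — the "on target" criterion for punctate labels.
#'
#' @param puncta_mask logical matrix of segmented puncta.
#' @param target_mask logical matrix of the target structure.
#' @return A list with `fraction`, `n_on_target`, `n_puncta`.
#' @export
puncta_on_target_fraction <- function(puncta_mask, target_mask) {
  stopifnot(identical(dim(puncta_mask), dim(target_mask)))
  lab <- matrix(label_components_cpp(as.logical(puncta_mask),
                                     c(dim(puncta_mask), 1L), 26L),
                nrow(puncta_mask), ncol(puncta_mask))
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(list(fraction = NA_real_, n_on_target = 0L, n_puncta = 0L))
  }
  idx <- which(lab > 0)
  ij <- arrayInd(idx, dim(lab))
  on <- vapply(seq_len(n_comp), function(lb) {
    sel <- lab[idx] == lb
    cen <- round(colMeans(ij[sel, , drop = FALSE]))
    target_mask[cen[1], cen[2]]
  }, logical(1))
  list(fraction = mean(on), n_on_target = sum(on), n_puncta = n_comp)
}

#' Per-grid intensity normalization
#'
#' Normalizes per-cell intensities against the mean intensity of all cells
#' on the same grid (or well), optionally followed by a per-batch
#' multiplicative correction factor to make experiment batches comparable.
#'
#' @param intensity numeric vector of per-cell intensities.
#' @param grid_id grouping vector (grid or well identifier).
#' @param batch optional batch identifier vector.
#' @param correction_factors optional named vector of per-batch
#'   multiplicative factors.
#' @return Numeric vector of normalized intensities.
#' @export
per_grid_normalize <- function(intensity, grid_id, batch = NULL,
                               correction_factors = NULL) {
  stopifnot(length(intensity) == length(grid_id))
  means <- tapply(intensity, grid_id, mean)
  if (any(means == 0)) {
    stop("normalization error: a grid has zero mean intensity")
  }
  out <- intensity / means[as.character(grid_id)]
  if (!is.null(batch) && !is.null(correction_factors)) {
    out <- out * correction_factors[as.character(batch)]
  }
  as.numeric(out)
}

#' Compare timepoint groups to a baseline
#'
#' Kruskal-Wallis test (with tie correction) across all groups, followed by
#' Dunn's z tests of every group against the baseline group only, two-sided,
#' with Bonferroni-type multiplicity adjustment over the baseline-comparison
#' family (p multiplied by the number of comparisons, capped at 1).
#'
#' Dunn's statistic for groups i, j uses the pooled mean ranks:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`, with tie
#' term `T = sum(t^3 - t) / (12 (N - 1))`.
#'
#' @param values numeric observations (e.g. per-cell overlap fractions).
#' @param group grouping vector (e.g. timepoint); coerced to factor.
#' @param baseline baseline group label; defaults to the first factor level.
#' @return A list of class `group_comparison`: `H`, `df`, `p_kruskal`, and a
#'   data frame `comparisons` with `group`, `n`, `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
compare_to_baseline <- function(values, group, baseline = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  ns <- table(group)
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (is.null(baseline)) baseline <- levels(group)[1]
  baseline <- as.character(baseline)
  if (!baseline %in% levels(group)) stop("unknown baseline group")

  kw <- stats::kruskal.test(values, group)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  others <- setdiff(levels(group), baseline)
  var_base <- (N * (N + 1) / 12 - tie_term)
  z <- vapply(others, function(g) {
    se <- sqrt(var_base * (1 / ns[[baseline]] + 1 / ns[[g]]))
    if (se == 0) return(0)
    (rbar[[g]] - rbar[[baseline]]) / se
  }, numeric(1))
  p_un <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(p_un * length(others), 1)
  structure(list(
    H = unname(kw$statistic), df = unname(kw$parameter),
    p_kruskal = kw$p.value, baseline = baseline,
    comparisons = data.frame(group = others, n = as.integer(ns[others]),
                             z = z, p_unadjusted = p_un, p_adjusted = p_adj,
                             row.names = NULL)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis H = %.4g, df = %d, p = %.3g\n",
              x$H, x$df, x$p_kruskal))
  cat(sprintf("  Dunn's tests vs baseline '%s' (two-sided, adjusted):\n",
              x$baseline))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Rank correlation between two measurements
#'
#' Spearman's rho (default; robust to the unknown intensity scale) or
#' Pearson's r, e.g. between tag expression level and enrichment at the
#' target.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return A list with `rho`, `p_value`, `n`, `method`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop("need paired vectors with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}
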