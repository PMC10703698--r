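#' Tomogram preprocessing parameters
#'
#' Defaults reproduce the EMAN2-style filter chain used to prepare tomograms
#' for particle detection: Gaussian low-pass at an absolute cutoff of 0.25
#' cycles/voxel, Gaussian high-pass at 5 voxels, zero-mean/unit-sd
#' normalization, and clamping at 3 sigma. The Gaussian is parameterized as
#' an amplitude `exp(-f^2 / (2 c^2))` with `c` the cutoff in cycles/voxel
#' (high-pass cutoff `c_h = 1 / highpass_cutoff_pixels`).
#'
#' @param lowpass_cutoff_abs low-pass cutoff, cycles/voxel.
#' @param highpass_cutoff_pixels high-pass cutoff, voxels (converted to
#'   `1/pixels` cycles/voxel).
#' @param clamp_nsigma clamp bound in sd units after normalization.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(lowpass_cutoff_abs = 0.25,
                              highpass_cutoff_pixels = 5,
                              clamp_nsigma = 3) {
  if (lowpass_cutoff_abs <= 0 || highpass_cutoff_pixels <= 0 ||
      clamp_nsigma <= 0) {
    stop("preprocess_params: cutoffs and clamp_nsigma must be positive")
  }
  structure(list(lowpass_cutoff_abs = lowpass_cutoff_abs,
                 highpass_cutoff_pixels = highpass_cutoff_pixels,
                 clamp_nsigma = clamp_nsigma),
            class = "preprocess_params")
}

# internal: 3D array of frequency magnitudes (cycles/voxel), FFT layout
frequency_magnitude <- function(dims) {
  fftfreq <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
  fx2 <- fftfreq(dims[1])^2
  fy2 <- fftfreq(dims[2])^2
  fz2 <- fftfreq(dims[3])^2
  sqrt(outer(as.vector(outer(fx2, fy2, "+")), fz2, "+")) |>
    array(dim = dims)
}

#' Preprocess a tomogram for detection
#'
#' Applies, in order: Fourier-space Gaussian low-pass, Gaussian high-pass,
#' zero-mean unit-sd normalization, and clamping to `+/- clamp_nsigma`.
#' No re-normalization is performed after clamping.
#'
#' @param volume a [voxel_grid].
#' @param params a [preprocess_params].
#' @return A [voxel_grid] of the filtered volume.
#' @export
preprocess_volume <- function(volume, params = preprocess_params()) {
  stopifnot(inherits(volume, "voxel_grid"), inherits(params, "preprocess_params"))
  arr <- volume$data
  if (!all(is.finite(arr))) stop("preprocess_volume: volume must be finite")
  f <- frequency_magnitude(dim(arr))
  c_lp <- params$lowpass_cutoff_abs
  c_hp <- 1 / params$highpass_cutoff_pixels
  H <- exp(-f^2 / (2 * c_lp^2)) * (1 - exp(-f^2 / (2 * c_hp^2)))
  out <- Re(stats::fft(stats::fft(arr) * H, inverse = TRUE)) / length(arr)
  s <- stats::sd(as.numeric(out))
  if (!is.finite(s) || s == 0) {
    stop("normalization error: filtered volume has zero variance")
  }
  out <- (out - mean(out)) / s
  ns <- params$clamp_nsigma
  out[out > ns] <- ns
  out[out < -ns] <- -ns
  voxel_grid(out, volume$voxel_size)
}

#' Geometric lamella slab specification
#'
#' A slab defined by a point on its front plane, a unit normal and a
#' thickness, mirroring how a lamella mask is drawn from the front and back
#' surfaces visible in a tomogram.
#'
#' @param point nm triple on the front plane.
#' @param normal direction vector (normalized internally; must be nonzero).
#' @param thickness slab thickness, nm (> 0).
#' @return A list of class `slab_spec`.
#' @export
slab_spec <- function(point, normal, thickness) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("slab_spec: normal must be nonzero")
  if (thickness <= 0) stop("slab_spec: thickness must be positive")
  structure(list(point = as.numeric(point),
                 normal = as.numeric(normal) / nrm,
                 thickness = thickness),
            class = "slab_spec")
}

#' Build a lamella slab mask on a voxel geometry
#'
#' The mask is true where the signed distance from the front plane, measured
#' along the normal, lies in `[0, thickness]`.
#'
#' @param dims voxel dimensions (nx, ny, nz).
#' @param voxel_size nm/voxel.
#' @param slab a [slab_spec].
#' @return A [binary_mask].
#' @export
build_slab_mask <- function(dims, voxel_size, slab) {
  stopifnot(inherits(slab, "slab_spec"))
  xs <- (axis_coords(dims[1], voxel_size) - slab$point[1]) * slab$normal[1]
  ys <- (axis_coords(dims[2], voxel_size) - slab$point[2]) * slab$normal[2]
  zs <- (axis_coords(dims[3], voxel_size) - slab$point[3]) * slab$normal[3]
  sd3 <- array(outer(as.vector(outer(xs, ys, "+")), zs, "+"), dim = dims)
  m <- sd3 >= 0 & sd3 <= slab$thickness
  if (!any(m)) stop("geometry error: slab does not intersect the volume")
  binary_mask(m, voxel_size)
}

#' Probability-map detection parameters
#'
#' Defaults reproduce the postprocessing applied to network probability
#' maps: threshold 0.5, a lamella mask, and a size filter keeping connected
#' components of 5,000-50,000 voxels at the 13.7 Angstrom reference pixel
#' size. Size bounds are physical-volume bounds: component voxel counts at
#' other voxel sizes are rescaled by `(voxel_size / reference_voxel_size)^3`
#' before comparison.
#'
#' @param prob_threshold binarization threshold in (0, 1).
#' @param min_component_voxels,max_component_voxels size-filter bounds at the
#'   reference voxel size.
#' @param reference_voxel_size nm (default 1.37, i.e. 13.7 Angstrom).
#' @param connectivity component connectivity; 26-neighbourhood by default.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(prob_threshold = 0.5,
                             min_component_voxels = 5000,
                             max_component_voxels = 50000,
                             reference_voxel_size = 1.37,
                             connectivity = c("face+edge+corner", "face")) {
  connectivity <- match.arg(connectivity)
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stop("prob_threshold must be in (0, 1)")
  }
  if (min_component_voxels <= 0 ||
      min_component_voxels >= max_component_voxels) {
    stop("size filter requires 0 < min < max")
  }
  structure(list(prob_threshold = prob_threshold,
                 min_component_voxels = min_component_voxels,
                 max_component_voxels = max_component_voxels,
                 reference_voxel_size = reference_voxel_size,
                 connectivity = connectivity),
            class = "detection_params")
}

#' Postprocess a detection probability map into particles
#'
#' Binarizes the map at `prob_threshold`, zeroes everything outside the
#' lamella, labels connected components, and retains components whose voxel
#' count — rescaled to the reference voxel size by
#' `(voxel_size / reference_voxel_size)^3` — lies within the size filter.
#' Each retained component yields one particle at its probability-weighted
#' centroid (sub-voxel, nm) with score = the component's maximum
#' probability.
#'
#' @param prob a [voxel_grid] of probabilities in \[0, 1\].
#' @param lamella a [binary_mask] on the same geometry, or `NULL` for no
#'   masking.
#' @param params a [detection_params].
#' @return A [particle_set] with `source = "detector"`.
#' @export
postprocess_probability_map <- function(prob, lamella = NULL,
                                        params = detection_params()) {
  stopifnot(inherits(prob, "voxel_grid"), inherits(params, "detection_params"))
  if (min(prob$data) < 0 || max(prob$data) > 1) {
    stop("input error: probability values outside [0, 1]")
  }
  arr <- prob$data
  if (!is.null(lamella)) {
    stopifnot(inherits(lamella, "binary_mask"))
    check_same_geometry(prob, lamella)
    arr <- arr * lamella$data
  }
  bin <- binary_mask(arr >= params$prob_threshold, prob$voxel_size)
  labels <- label_components(bin, params$connectivity)
  if (!any(labels > 0)) return(particle_set())
  vs <- prob$voxel_size
  scale3 <- (vs / params$reference_voxel_size)^3
  idx <- which(labels > 0)
  lab <- labels[idx]
  counts <- tabulate(lab)
  keep <- which(counts * scale3 >= params$min_component_voxels &
                counts * scale3 <= params$max_component_voxels)
  if (!length(keep)) return(particle_set())
  ijk <- arrayInd(idx, dim(arr))
  w <- arr[idx]
  rows <- lapply(keep, function(lb) {
    sel <- lab == lb
    wi <- w[sel]
    cen <- colSums(ijk[sel, , drop = FALSE] * wi) / sum(wi)
    data.frame(x_nm = (cen[1] - 1) * vs, y_nm = (cen[2] - 1) * vs,
               z_nm = (cen[3] - 1) * vs, score = max(wi),
               n_voxels = sum(sel))
  })
  df <- do.call(rbind, rows)
  df$source <- "detector"
  df$status <- "retained"
  particle_set(df)
}

#' Detect shell particles by normalized cross-correlation
#'
#' A matched-filter detector standing in for a trained network: the volume is
#' correlated (via FFT, circular boundary) with a zero-mean hollow-shell
#' kernel of the given outer radius, normalized locally over the kernel's
#' cubic support so scores lie in \[-1, 1\]. Local maxima above
#' `score_cutoff` are reduced greedily (highest score first, ties broken by
#' lexicographic coordinate order) so that retained centres are at least
#' `min_separation` apart.
#'
#' Particles are assumed to appear as negative-contrast shells, matching
#' [render_density_volume()]; the kernel carries negative shell contrast.
#'
#' @param volume a (preprocessed) [voxel_grid].
#' @param shell_radius outer shell radius, nm (at least 2 voxels).
#' @param min_separation minimum centre separation, nm.
#' @param score_cutoff correlation threshold in (0, 1).
#' @param shell_thickness shell thickness, nm.
#' @return A [particle_set] with correlation scores.
#' @export
detect_shells <- function(volume, shell_radius, min_separation,
                          score_cutoff = 0.5, shell_thickness = 4) {
  stopifnot(inherits(volume, "voxel_grid"))
  vs <- volume$voxel_size
  if (shell_radius < 2 * vs) {
    stop("resolution error: shell_radius must be at least 2 voxels")
  }
  dims <- dim(volume$data)
  rv <- shell_radius / vs
  rv_in <- max(shell_radius - shell_thickness, 0) / vs
  half <- ceiling(rv)
  side <- 2 * half + 1
  if (any(side > dims)) stop("volume too small for the shell kernel")

  # kernel and support window in FFT layout (centre wrapped to voxel 1,1,1)
  offs <- c(0:half, -half:-1)
  d2 <- outer(outer(offs^2, offs^2, "+"), offs^2, "+")
  kern_small <- ifelse(d2 >= rv_in^2 & d2 <= rv^2, -1, 0)
  supp_small <- array(1, dim = dim(kern_small))
  embed <- function(small) {
    big <- array(0, dim = dims)
    ix <- c(1:(half + 1), (dims[1] - half + 1):dims[1])
    iy <- c(1:(half + 1), (dims[2] - half + 1):dims[2])
    iz <- c(1:(half + 1), (dims[3] - half + 1):dims[3])
    big[ix, iy, iz] <- small
    big
  }
  n_supp <- side^3
  kern <- embed(kern_small - mean(kern_small))      # zero-mean over support
  supp <- embed(supp_small)
  sigma_k <- sqrt(sum(kern^2))

  v <- volume$data
  FV <- stats::fft(v)
  FV2 <- stats::fft(v^2)
  corr_k <- function(Fk) Re(stats::fft(FV * Conj(Fk), inverse = TRUE)) /
    length(v)
  Fkern <- stats::fft(kern)
  Fsupp <- stats::fft(supp)
  num <- corr_k(Fkern)
  s1 <- corr_k(Fsupp)                               # local sum of v
  s2 <- Re(stats::fft(FV2 * Conj(Fsupp), inverse = TRUE)) / length(v)
  local_var <- pmax(s2 - s1^2 / n_supp, 0)
  denom <- sigma_k * sqrt(local_var)
  score <- array(0, dim = dims)
  ok <- denom > 1e-12
  score[ok] <- num[ok] / denom[ok]
  score <- pmin(pmax(score, -1), 1)

  # local maxima over the 3x3x3 neighbourhood, interior only
  cand <- which(score >= score_cutoff)
  if (!length(cand)) return(particle_set())
  ijk <- arrayInd(cand, dims)
  interior <- ijk[, 1] > 1 & ijk[, 1] < dims[1] &
              ijk[, 2] > 1 & ijk[, 2] < dims[2] &
              ijk[, 3] > 1 & ijk[, 3] < dims[3]
  cand <- cand[interior]; ijk <- ijk[interior, , drop = FALSE]
  if (!length(cand)) return(particle_set())
  is_max <- vapply(seq_along(cand), function(q) {
    i <- ijk[q, 1]; j <- ijk[q, 2]; k <- ijk[q, 3]
    score[cand[q]] >= max(score[(i - 1):(i + 1), (j - 1):(j + 1),
                                (k - 1):(k + 1)])
  }, logical(1))
  cand <- cand[is_max]; ijk <- ijk[is_max, , drop = FALSE]
  sc <- score[cand]
  ord <- order(-sc, ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- ijk[ord, , drop = FALSE]; sc <- sc[ord]
  centers_nm <- (ijk - 1) * vs
  keep <- integer(0)
  min_sep2 <- min_separation^2
  for (q in seq_len(nrow(centers_nm))) {
    if (!length(keep) ||
        min(rowSums(sweep(centers_nm[keep, , drop = FALSE], 2,
                          centers_nm[q, ])^2)) >= min_sep2) {
      keep <- c(keep, q)
    }
  }
  particle_set(data.frame(
    x_nm = centers_nm[keep, 1], y_nm = centers_nm[keep, 2],
    z_nm = centers_nm[keep, 3], score = sc[keep],
    source = "detector", status = "retained", stringsAsFactors = FALSE))
}

#' Curation ledger
#'
#' Accounting record of a manual curation pass over detected peaks: the
#' number of detector peaks, per-category discard counts, and the number of
#' manually added particles. The three default categories are
#' organelle-interior, surface-damage and visual-reject.
#'
#' @param n_peaks detector peak count.
#' @param discards named numeric vector mapping category to discard count.
#' @param n_manual_added manually added particle count.
#' @return A list of class `curation_ledger`.
#' @export
curation_ledger <- function(n_peaks, discards = c(), n_manual_added = 0L) {
  discards <- unlist(discards)
  if (any(c(n_peaks, discards, n_manual_added) < 0)) {
    stop("curation ledger counts must be >= 0")
  }
  if (sum(discards) > n_peaks) {
    stop("ledger error: discards (", sum(discards), ") exceed peaks (",
         n_peaks, ")")
  }
  structure(list(n_peaks = as.integer(n_peaks),
                 discards = discards,
                 n_manual_added = as.integer(n_manual_added)),
            class = "curation_ledger")
}

#' Apply curation to detected particles
#'
#' Either reconciles a [curation_ledger] (final count =
#' `n_peaks - sum(discards) + n_manual_added`) or applies per-particle
#' discard annotations to a [particle_set] and merges manual additions,
#' emitting the ledger alongside the curated set.
#'
#' @param x a [curation_ledger] or a [particle_set].
#' @param ... passed to methods.
#' @return A list of class `curation_result` with elements `ledger`,
#'   `final_count` and (for particle input) `particles`.
#' @export
apply_curation <- function(x, ...) UseMethod("apply_curation")

#' @rdname apply_curation
#' @export
apply_curation.curation_ledger <- function(x, ...) {
  final <- x$n_peaks - sum(x$discards) + x$n_manual_added
  structure(list(ledger = x, final_count = as.integer(final)),
            class = "curation_result")
}

#' @param discard data frame with columns `particle_id` and `category`
#'   referencing particles of `x` to discard.
#' @param manual_additions optional [particle_set] of manually picked
#'   particles to merge (marked `source = "manual"`).
#' @rdname apply_curation
#' @export
apply_curation.particle_set <- function(x, discard = NULL,
                                        manual_additions = NULL, ...) {
  df <- as.data.frame(x)
  if (!is.null(discard) && nrow(discard)) {
    missing_ids <- setdiff(discard$particle_id, df$particle_id)
    if (length(missing_ids)) {
      stop("discard annotations reference unknown particle_id(s): ",
           paste(missing_ids, collapse = ", "))
    }
    m <- match(discard$particle_id, df$particle_id)
    df$status[m] <- paste0("discarded:", discard$category)
  }
  n_manual <- 0L
  if (!is.null(manual_additions) && nrow(manual_additions)) {
    add <- as.data.frame(manual_additions)
    add$source <- "manual"
    add$status <- "retained"
    add$particle_id <- max(df$particle_id, 0L) + seq_len(nrow(add))
    common <- intersect(names(df), names(add))
    df <- rbind(df[, common], add[, common])
    n_manual <- nrow(add)
  }
  disc <- df$status[startsWith(df$status, "discarded:")]
  discards <- table(sub("^discarded:", "", disc))
  ledger <- curation_ledger(n_peaks = nrow(x),
                            discards = stats::setNames(as.integer(discards),
                                                       names(discards)),
                            n_manual_added = n_manual)
  structure(list(ledger = ledger,
                 final_count = sum(df$status == "retained"),
                 particles = particle_set(df)),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  l <- x$ledger
  cat(sprintf("<curation_result> %d peaks - %d discarded + %d manual = %d final\n",
              l$n_peaks, sum(l$discards), l$n_manual_added, x$final_count))
  if (length(l$discards)) {
    for (nm in names(l$discards)) {
      cat(sprintf("  discarded %s: %d\n", nm, l$discards[[nm]]))
    }
  }
  invisible(x)
}
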