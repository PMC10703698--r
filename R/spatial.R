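#' Spatial analysis parameters
#'
#' @param particle_radius particle radius subtracted from centre distances,
#'   nm (default 12.5, a 25-nm shell particle).
#' @param proximity_cutoff "within" cutoff on surface distances, nm.
#' @param dilation_radius dilation applied to the proximity region for the
#'   volumetric enrichment denominator, nm.
#' @return A list of class `spatial_params`.
#' @export
spatial_params <- function(particle_radius = 12.5, proximity_cutoff = 50,
                           dilation_radius = 50) {
  if (particle_radius <= 0 || proximity_cutoff <= 0 || dilation_radius <= 0) {
    stop("spatial_params: all parameters must be positive")
  }
  structure(list(particle_radius = particle_radius,
                 proximity_cutoff = proximity_cutoff,
                 dilation_radius = dilation_radius),
            class = "spatial_params")
}

#' Particle-to-structure surface distances
#'
#' For each particle, the Euclidean distance from its centre to the nearest
#' structure voxel (from the exact distance transform of the structure mask,
#' sampled at the continuous particle centre by trilinear interpolation),
#' minus the particle radius. Negative surface distances indicate overlap
#' between the particle and the structure.
#'
#' @param particles a [particle_set].
#' @param structure a nonempty [binary_mask].
#' @param params a [spatial_params].
#' @param sampling `"trilinear"` (default) or `"nearest"` voxel sampling of
#'   the distance field at particle centres.
#' @return A data frame of class `distance_records` with columns
#'   `particle_id`, `tomo_id`, `center_distance_nm`, `surface_distance_nm`.
#' @export
surface_distances <- function(particles, structure,
                              params = spatial_params(),
                              sampling = c("trilinear", "nearest")) {
  stopifnot(inherits(particles, "particle_set"),
            inherits(structure, "binary_mask"))
  sampling <- match.arg(sampling)
  if (!any(structure$data)) {
    stop("input error: structure mask is empty")
  }
  dt <- distance_to_mask(structure)
  centers <- particle_centers(particles)
  idx <- nm_to_index(centers, structure$voxel_size)
  d <- dim(structure$data)
  if (nrow(centers) &&
      (any(idx < 0.5) || any(sweep(idx, 2, d + 0.5) > 0))) {
    stop("input error: particle centers fall outside the grid")
  }
  cd <- if (sampling == "trilinear") {
    trilinear_sample(dt$data, idx)
  } else {
    ri <- pmin(pmax(round(idx), 1), matrix(d, nrow(idx), 3, byrow = TRUE))
    dt$data[ri]
  }
  out <- data.frame(particle_id = particles$particle_id,
                    tomo_id = particles$tomo_id,
                    center_distance_nm = cd,
                    surface_distance_nm = cd - params$particle_radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("distance_records", "data.frame")
  out
}

#' Fraction of particles within a distance cutoff
#'
#' Fraction of surface distances less than or equal to `cutoff` (boundary
#' inclusive; negative distances — particles overlapping the structure —
#' always count as within).
#'
#' @param records a `distance_records` data frame (or any data frame with a
#'   `surface_distance_nm` column).
#' @param cutoff distance cutoff, nm.
#' @return A list with `fraction`, `n_within`, `n_total`.
#' @export
fraction_within <- function(records, cutoff = 50) {
  d <- records$surface_distance_nm
  if (is.null(d) || length(d) == 0) {
    stop("input error: empty distance record collection")
  }
  n_within <- sum(d <= cutoff)
  list(fraction = n_within / length(d), n_within = n_within,
       n_total = length(d))
}

#' Exact Euclidean dilation of a mask
#'
#' The dilated mask is true where the Euclidean distance transform of the
#' input mask is at most `radius` — an exact spherical structuring element
#' rather than an iterated discrete one.
#'
#' @param mask a [binary_mask] on isotropic voxels.
#' @param radius dilation radius, nm. A radius below the voxel size warns
#'   and returns the input unchanged.
#' @return A [binary_mask].
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius < mask$voxel_size) {
    warning("dilation radius below voxel size; returning input mask")
    return(mask)
  }
  if (!any(mask$data)) return(mask)
  dt <- distance_to_mask(mask)
  binary_mask(dt$data <= radius, mask$voxel_size)
}

#' Volumetric fold-enrichment of particles around a structure
#'
#' The relative labeling index: the fraction of particles within
#' `proximity_cutoff` (surface distance) of the structure, divided by the
#' fraction of the lamella volume occupied by the structure dilated by
#' `dilation_radius` and intersected with the lamella. Equals 1 in
#' expectation for uniformly placed particles.
#'
#' @param particles a [particle_set].
#' @param region the structure [binary_mask] (pre-dilation).
#' @param lamella the lamella [binary_mask] (the total imaged volume).
#' @param params a [spatial_params].
#' @return An [enrichment_result].
#' @export
volumetric_enrichment <- function(particles, region, lamella,
                                  params = spatial_params()) {
  stopifnot(inherits(region, "binary_mask"), inherits(lamella, "binary_mask"))
  check_same_geometry(region, lamella)
  if (!any(lamella$data)) stop("input error: lamella mask is empty")
  if (nrow(particles) == 0) stop("input error: no particles (n_total = 0)")
  dil <- dilate_mask(region, params$dilation_radius)
  region_voxels <- sum(dil$data & lamella$data)
  lamella_voxels <- sum(lamella$data)
  recs <- surface_distances(particles, region, params)
  fw <- fraction_within(recs, params$proximity_cutoff)
  enrichment_result(n_within = fw$n_within, n_total = fw$n_total,
                    region_voxels = region_voxels,
                    lamella_voxels = lamella_voxels)
}

#' Enrichment result
#'
#' Counts and fractions behind a fold-enrichment estimate. Either supply
#' voxel counts for the proximity region and lamella, or the volume
#' fraction directly. Identities `f_P = n_within / n_total`,
#' `f_V = region_voxels / lamella_voxels` and `fold = f_P / f_V` hold
#' exactly as stored.
#'
#' @param n_within particles within the proximity region.
#' @param n_total total particles.
#' @param region_voxels,lamella_voxels voxel counts of region-in-lamella and
#'   lamella (used for pooling); alternatively give `volume_fraction`.
#' @param volume_fraction `f_V` directly, in (0, 1].
#' @return A list of class `enrichment_result` with `n_within`, `n_total`,
#'   `particle_fraction`, `volume_fraction`, `fold` (and voxel counts when
#'   supplied).
#' @export
enrichment_result <- function(n_within, n_total, region_voxels = NULL,
                              lamella_voxels = NULL, volume_fraction = NULL) {
  if (n_total <= 0) stop("input error: n_total must be positive")
  if (is.null(volume_fraction)) {
    if (is.null(region_voxels) || is.null(lamella_voxels)) {
      stop("supply either voxel counts or volume_fraction")
    }
    if (lamella_voxels <= 0) stop("input error: empty lamella")
    volume_fraction <- region_voxels / lamella_voxels
  }
  if (volume_fraction <= 0) {
    stop("undefined-enrichment error: region volume fraction is zero")
  }
  f_P <- n_within / n_total
  structure(list(n_within = n_within, n_total = n_total,
                 region_voxels = region_voxels,
                 lamella_voxels = lamella_voxels,
                 particle_fraction = f_P,
                 volume_fraction = volume_fraction,
                 fold = f_P / volume_fraction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d/%d particles in region (f_P = %.3f)\n",
              x$n_within, x$n_total, x$particle_fraction))
  cat(sprintf("  region volume fraction f_V = %.4g (%.3g%%)\n",
              x$volume_fraction, 100 * x$volume_fraction))
  cat(sprintf("  fold enrichment = %.1f\n", x$fold))
  invisible(x)
}

#' Pool enrichment results across tomograms
#'
#' Sums particle counts and voxel volumes across tomograms before dividing —
#' not a mean of per-tomogram folds. All inputs must carry voxel counts.
#'
#' @param results list of [enrichment_result] objects with voxel counts.
#' @return A pooled [enrichment_result].
#' @export
pool_enrichment <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "enrichment_result")))
  if (any(vapply(results, function(r) is.null(r$region_voxels), logical(1)))) {
    stop("pooling requires per-tomogram voxel counts")
  }
  enrichment_result(
    n_within = sum(vapply(results, `[[`, numeric(1), "n_within")),
    n_total = sum(vapply(results, `[[`, numeric(1), "n_total")),
    region_voxels = sum(vapply(results, `[[`, numeric(1), "region_voxels")),
    lamella_voxels = sum(vapply(results, `[[`, numeric(1), "lamella_voxels")))
}

#' Summarize surface distances
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' surface distances, per tomogram and pooled. The sd is reported missing
#' for single-observation groups.
#'
#' @param records a `distance_records` data frame.
#' @return A data frame with one row per tomogram plus a `"pooled"` row;
#'   columns `tomo_id`, `n`, `mean_nm`, `sd_nm`.
#' @export
summarize_distances <- function(records) {
  d <- records$surface_distance_nm
  if (is.null(d) || length(d) == 0) {
    stop("input error: empty distance record collection")
  }
  one <- function(x, id) {
    data.frame(tomo_id = id, n = length(x), mean_nm = mean(x),
               sd_nm = if (length(x) > 1) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }
  groups <- split(d, records$tomo_id)
  per <- do.call(rbind, Map(one, groups, names(groups)))
  rownames(per) <- NULL
  rbind(per, one(d, "pooled"))
}
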