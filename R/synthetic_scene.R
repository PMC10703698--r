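#' Configuration for a synthetic tomographic scene
#'
#' Describes a slab-shaped lamella volume containing a segmented target
#' structure (a membrane plane, a sphere or a tube) decorated with
#' shell-shaped particles: `n_bound` particles at controlled surface
#' distances (normal with mean `bound_distance_mean` and sd
#' `bound_distance_sd`, truncated so that particles stay inside the lamella)
#' plus `n_background` particles placed uniformly in the lamella.
#'
#' @param volume_shape integer triple of voxel counts (nx, ny, nz).
#' @param voxel_size isotropic voxel size, nm/voxel.
#' @param lamella_thickness lamella slab thickness, nm; must exceed twice the
#'   particle radius so particles fit inside.
#' @param lamella_tilt tilt of the slab about the x axis, degrees.
#' @param structure_kind `"plane"`, `"sphere"` or `"tube"`.
#' @param structure_params list of geometry parameters in nm:
#'   `offset_nm` (plane, distance from the lamella mid-plane, default 0);
#'   `radius_nm` (sphere and tube).
#' @param n_bound,n_background particle counts.
#' @param bound_distance_mean,bound_distance_sd surface-distance
#'   distribution of bound particles, nm (distance from the particle surface
#'   to the structure; negative values mean overlap).
#' @param particle_radius particle radius, nm. Default 12.5 (a 25-nm shell).
#' @param seed integer seed; every draw in the generator is governed by it.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(volume_shape = c(96L, 96L, 96L),
                         voxel_size = 1.37,
                         lamella_thickness = 100,
                         lamella_tilt = 0,
                         structure_kind = c("plane", "sphere", "tube"),
                         structure_params = list(),
                         n_bound = 0L,
                         bound_distance_mean = 10,
                         bound_distance_sd = 6,
                         n_background = 0L,
                         particle_radius = 12.5,
                         seed = 1L) {
  structure_kind <- match.arg(structure_kind)
  if (length(volume_shape) != 3L || any(volume_shape < 1)) {
    stop("volume_shape must be three positive voxel counts")
  }
  if (length(voxel_size) != 1L || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (isotropic voxels only)")
  }
  if (lamella_thickness <= 2 * particle_radius) {
    stop("lamella_thickness must exceed 2 * particle_radius (",
         2 * particle_radius, " nm)")
  }
  if (bound_distance_sd < 0) stop("bound_distance_sd must be >= 0")
  if (n_bound < 0 || n_background < 0) stop("particle counts must be >= 0")
  structure(list(
    volume_shape = as.integer(volume_shape), voxel_size = voxel_size,
    lamella_thickness = lamella_thickness, lamella_tilt = lamella_tilt,
    structure_kind = structure_kind, structure_params = structure_params,
    n_bound = as.integer(n_bound),
    bound_distance_mean = bound_distance_mean,
    bound_distance_sd = bound_distance_sd,
    n_background = as.integer(n_background),
    particle_radius = particle_radius, seed = as.integer(seed)
  ), class = "scene_config")
}

# internal: scene geometry shared by mask construction and placement.
# Returns lamella normal, volume centre (nm) and axis coordinates.
scene_geometry <- function(config) {
  d <- config$volume_shape
  vs <- config$voxel_size
  centre <- (d - 1) / 2 * vs
  t_rad <- config$lamella_tilt * pi / 180
  normal <- c(0, -sin(t_rad), cos(t_rad))
  list(dims = d, vs = vs, centre = centre, normal = normal,
       xc = axis_coords(d[1], vs), yc = axis_coords(d[2], vs),
       zc = axis_coords(d[3], vs))
}

# internal: signed distance to the lamella mid-plane for every voxel,
# as an ny x nz matrix (constant along x since the normal has no x part)
lamella_plane_field <- function(geo) {
  outer((geo$yc - geo$centre[2]) * geo$normal[2],
        (geo$zc - geo$centre[3]) * geo$normal[3], "+")
}

# internal: replicate an ny x nz field across the x axis
replicate_x <- function(m2d, dims) {
  aperm(array(m2d, dim = c(dims[2], dims[3], dims[1])), c(3, 1, 2))
}

# internal: build the lamella slab mask
build_lamella_mask <- function(config) {
  geo <- scene_geometry(config)
  field <- lamella_plane_field(geo)
  m <- abs(field) <= config$lamella_thickness / 2
  binary_mask(replicate_x(m, geo$dims), config$voxel_size)
}

# internal: plane offset snapped to the nearest voxel-centre layer (only
# possible when untilted); keeps the rasterized membrane one voxel thick and
# placement geometry consistent with the rasterization
snap_plane_offset <- function(config, geo) {
  sp <- config$structure_params
  offset <- if (is.null(sp$offset_nm)) 0 else sp$offset_nm
  if (abs(geo$normal[2]) < 1e-12) {
    round((offset + geo$centre[3]) / geo$vs) * geo$vs - geo$centre[3]
  } else {
    offset
  }
}

# internal: rasterize the structure surface (half-voxel-thick shell)
build_structure_mask <- function(config) {
  geo <- scene_geometry(config)
  vs <- config$voxel_size
  half <- vs / 2 + 1e-9
  sp <- config$structure_params
  if (config$structure_kind == "plane") {
    offset <- snap_plane_offset(config, geo)
    field <- lamella_plane_field(geo)
    m <- abs(field - offset) < half
    arr <- replicate_x(m, geo$dims)
  } else if (config$structure_kind == "sphere") {
    R <- sp$radius_nm
    if (is.null(R)) stop("structure_params$radius_nm required for a sphere")
    d2xy <- outer((geo$xc - geo$centre[1])^2, (geo$yc - geo$centre[2])^2, "+")
    r <- sqrt(outer(as.vector(d2xy), (geo$zc - geo$centre[3])^2, "+"))
    arr <- array(abs(r - R) <= half, dim = geo$dims)
  } else {  # tube along x through the centre
    R <- sp$radius_nm
    if (is.null(R)) stop("structure_params$radius_nm required for a tube")
    rho <- sqrt(outer((geo$yc - geo$centre[2])^2,
                      (geo$zc - geo$centre[3])^2, "+"))
    arr <- replicate_x(abs(rho - R) <= half, geo$dims)
  }
  binary_mask(arr, vs)
}

# internal: is a point (nm) strictly inside the structure interior?
# Only spheres and tubes enclose a volume; a plane has no interior.
inside_structure_interior <- function(p, config, geo) {
  sp <- config$structure_params
  if (config$structure_kind == "sphere") {
    sqrt(sum((p - geo$centre)^2)) < sp$radius_nm
  } else if (config$structure_kind == "tube") {
    sqrt(sum((p[2:3] - geo$centre[2:3])^2)) < sp$radius_nm
  } else {
    FALSE
  }
}

# internal: a surface point and outward unit normal for bound placement
random_surface_point <- function(config, geo, margin) {
  sp <- config$structure_params
  if (config$structure_kind == "plane") {
    offset <- snap_plane_offset(config, geo)
    # in-plane basis for normal (0, n2, n3): e1 = x axis, e2 = n x e1
    e2 <- c(0, geo$normal[3], -geo$normal[2])
    ext <- (geo$dims - 1) * geo$vs
    a <- stats::runif(1, margin, ext[1] - margin)
    b <- stats::runif(1, -(ext[2] / 2 - margin), ext[2] / 2 - margin)
    p0 <- geo$centre + offset * geo$normal + e2 * b
    p0[1] <- a
    side <- sample(c(-1, 1), 1)
    list(point = p0, normal = side * geo$normal)
  } else if (config$structure_kind == "sphere") {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    list(point = geo$centre + sp$radius_nm * u, normal = u)
  } else {
    ext <- (geo$dims - 1) * geo$vs
    a <- stats::runif(1, margin, ext[1] - margin)
    phi <- stats::runif(1, 0, 2 * pi)
    u <- c(0, cos(phi), sin(phi))
    p0 <- c(a, geo$centre[2:3] + sp$radius_nm * u[2:3])
    list(point = p0, normal = u)
  }
}

# internal: nearest-voxel lookup of a mask at a point in nm
mask_at_point <- function(mask, p) {
  idx <- round(nm_to_index(p, mask$voxel_size))
  d <- dim(mask$data)
  if (any(idx < 1) || any(idx > d)) return(FALSE)
  mask$data[idx[1], idx[2], idx[3]]
}

#' Simulate a tomographic scene with ground truth
#'
#' Builds the lamella slab mask and structure mask from `config`, then places
#' `n_bound` particles at surface distances drawn from the configured
#' (truncated) normal and `n_background` particles uniformly in the lamella
#' outside the structure interior. Centres are hard-sphere constrained
#' (pairwise separation at least twice the particle radius) by rejection
#' sampling with up to 1000 retries per particle. Deterministic for a fixed
#' seed.
#'
#' @param config a [scene_config].
#' @return A list of class `scene_truth` with elements `particles` (a
#'   [particle_set] carrying `bound` and, for bound particles, the generated
#'   `surface_distance_nm`), `structure_mask`, `lamella_mask` and `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  geo <- scene_geometry(config)
  lamella <- build_lamella_mask(config)
  structure_mask <- build_structure_mask(config)
  if (!any(structure_mask$data & lamella$data)) {
    stop("geometry error: structure does not intersect the lamella")
  }
  rp <- config$particle_radius
  margin <- rp + 2 * config$voxel_size
  ext <- (geo$dims - 1) * geo$vs

  centers <- matrix(numeric(0), ncol = 3)
  bound <- logical(0)
  sdist <- numeric(0)

  place_ok <- function(p) {
    if (any(p < margin) || any(p > ext - margin)) return(FALSE)
    if (!mask_at_point(lamella, p)) return(FALSE)
    if (nrow(centers) &&
        min(sqrt(rowSums(sweep(centers, 2, p)^2))) < 2 * rp) return(FALSE)
    TRUE
  }

  for (i in seq_len(config$n_bound)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      d <- stats::rnorm(1, config$bound_distance_mean, config$bound_distance_sd)
      if (d <= -rp) next  # particle centre cannot cross the surface
      sp <- random_surface_point(config, geo, margin)
      p <- sp$point + (d + rp) * sp$normal
      if (inside_structure_interior(p, config, geo)) next
      if (place_ok(p)) {
        centers <- rbind(centers, p)
        bound <- c(bound, TRUE)
        sdist <- c(sdist, d)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place bound particle ", i,
           " after 1000 retries")
    }
  }

  for (i in seq_len(config$n_background)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      p <- stats::runif(3, margin, ext - margin)
      if (inside_structure_interior(p, config, geo)) next
      if (place_ok(p)) {
        centers <- rbind(centers, p)
        bound <- c(bound, FALSE)
        sdist <- c(sdist, NA_real_)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: could not place background particle ", i,
           " after 1000 retries")
    }
  }

  n <- nrow(centers)
  particles <- particle_set(data.frame(
    tomo_id = rep("synthetic_1", n),
    particle_id = seq_len(n),
    x_nm = centers[, 1], y_nm = centers[, 2], z_nm = centers[, 3],
    score = rep(NA_real_, n),
    source = rep("truth", n),
    status = rep("retained", n),
    bound = bound,
    surface_distance_nm = sdist,
    stringsAsFactors = FALSE
  ))
  structure(list(particles = particles, structure_mask = structure_mask,
                 lamella_mask = lamella, config = config),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %s structure, %d bound + %d background particles\n",
              x$config$structure_kind, sum(x$particles$bound),
              sum(!x$particles$bound)))
  invisible(x)
}

#' Configuration for a synthetic detection probability map
#'
#' Emulates the per-voxel particle-presence score a detection network emits:
#' spherical blobs of `blob_radius` at the true particle centres with peak
#' values drawn from `peak_prob_range`, plus decoy blobs sized to fall below,
#' inside, or above the connected-component size filter, plus Gaussian noise.
#' Blob values taper quadratically to 95% of the peak at the blob edge so the
#' map maximum sits at the particle centre.
#'
#' The default decoy radii correspond, at the 13.7 A reference pixel size, to
#' roughly 2,300 voxels (small), 12,500 voxels (valid) and 64,000 voxels
#' (large) against the 5,000-50,000 voxel filter.
#'
#' @param blob_radius blob radius in nm (default 13.7, i.e. 137 Angstrom).
#' @param peak_prob_range range (low, high) of blob peak values, inside
#'   (0.5, 1] so blobs survive the 0.5 threshold.
#' @param n_false_small,n_false_valid,n_false_large decoy blob counts below,
#'   within and above the size filter.
#' @param false_small_radius,false_valid_radius,false_large_radius decoy
#'   radii in nm.
#' @param noise_sd sd of additive Gaussian noise, probability units.
#' @param seed integer seed.
#' @return A list of class `prob_map_config`.
#' @export
prob_map_config <- function(blob_radius = 13.7,
                            peak_prob_range = c(0.8, 1.0),
                            n_false_small = 0L, n_false_valid = 0L,
                            n_false_large = 0L,
                            false_small_radius = 11,
                            false_valid_radius = 20,
                            false_large_radius = 34,
                            noise_sd = 0, seed = 1L) {
  if (peak_prob_range[1] <= 0.5 || peak_prob_range[2] > 1 ||
      peak_prob_range[1] > peak_prob_range[2]) {
    stop("peak_prob_range must be an increasing range inside (0.5, 1]")
  }
  structure(list(blob_radius = blob_radius,
                 peak_prob_range = peak_prob_range,
                 n_false_small = as.integer(n_false_small),
                 n_false_valid = as.integer(n_false_valid),
                 n_false_large = as.integer(n_false_large),
                 false_small_radius = false_small_radius,
                 false_valid_radius = false_valid_radius,
                 false_large_radius = false_large_radius,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "prob_map_config")
}

# internal: paint a tapered spherical blob into arr (max-combined).
# Peak at the centre; value peak * (1 - 0.05 (r/R)^2) inside r <= R.
paint_blob <- function(arr, centre_nm, radius_nm, peak, vs) {
  d <- dim(arr)
  ci <- nm_to_index(centre_nm, vs)
  rv <- radius_nm / vs
  lo <- pmax(floor(ci - rv), 1)
  hi <- pmin(ceiling(ci + rv), d)
  if (any(lo > hi)) return(arr)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  d2 <- outer(outer((ii - ci[1])^2, (jj - ci[2])^2, "+"), (kk - ci[3])^2, "+")
  blob <- ifelse(d2 <= rv^2, peak * (1 - 0.05 * d2 / rv^2), 0)
  sub <- arr[ii, jj, kk, drop = FALSE]
  arr[ii, jj, kk] <- pmax(sub, blob)
  arr
}

#' Render a synthetic detection probability map
#'
#' @param truth a `scene_truth` from [simulate_scene()].
#' @param config a [prob_map_config]; shares the truth's voxel geometry.
#' @return A [voxel_grid] with values in \[0, 1\].
#' @export
render_probability_map <- function(truth, config = prob_map_config()) {
  stopifnot(inherits(truth, "scene_truth"),
            inherits(config, "prob_map_config"))
  vs <- truth$config$voxel_size
  if (config$blob_radius < vs) {
    stop("resolution error: blob_radius smaller than one voxel")
  }
  set.seed(config$seed)
  dims <- truth$config$volume_shape
  arr <- array(0, dim = dims)
  centers <- particle_centers(truth$particles)
  for (i in seq_len(nrow(centers))) {
    peak <- stats::runif(1, config$peak_prob_range[1], config$peak_prob_range[2])
    arr <- paint_blob(arr, centers[i, ], config$blob_radius, peak, vs)
  }
  # decoys at uniform positions inside the lamella
  lam_idx <- which(truth$lamella_mask$data)
  decoys <- rbind(
    if (config$n_false_small > 0)
      cbind(config$false_small_radius, seq_len(config$n_false_small)),
    if (config$n_false_valid > 0)
      cbind(config$false_valid_radius, seq_len(config$n_false_valid)),
    if (config$n_false_large > 0)
      cbind(config$false_large_radius, seq_len(config$n_false_large))
  )
  if (!is.null(decoys)) {
    for (i in seq_len(nrow(decoys))) {
      vidx <- lam_idx[sample.int(length(lam_idx), 1)]
      ijk <- arrayInd(vidx, dims)
      centre_nm <- (as.numeric(ijk) - 1) * vs
      peak <- stats::runif(1, config$peak_prob_range[1],
                           config$peak_prob_range[2])
      arr <- paint_blob(arr, centre_nm, decoys[i, 1], peak, vs)
    }
  }
  if (config$noise_sd > 0) {
    arr <- arr + stats::rnorm(length(arr), 0, config$noise_sd)
  }
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  voxel_grid(arr, vs)
}

#' Render a synthetic density volume of hollow-shell particles
#'
#' Emulates the appearance of 25-nm shell particles in a tomogram:
#' negative-contrast hollow shells (outer radius = the scene's particle
#' radius) over a Gaussian noise background, with an optional missing-wedge
#' attenuation that zeroes a +/- wedge of directions about the beam (z) axis
#' in Fourier space. The wedge is off by default; detection must not rely on
#' it.
#'
#' @param truth a `scene_truth`.
#' @param contrast list with elements `inner_radius` (nm, default outer - 4),
#'   `shell_value` (default -1, negative contrast), `noise_sd` (default 0),
#'   `wedge_half_angle` (degrees, `NULL` = no missing wedge) and `seed`.
#' @return A [voxel_grid].
#' @export
render_density_volume <- function(truth, contrast = list()) {
  stopifnot(inherits(truth, "scene_truth"))
  outer_r <- truth$config$particle_radius
  inner_r <- if (is.null(contrast$inner_radius)) outer_r - 4 else
    contrast$inner_radius
  if (inner_r >= outer_r || inner_r < 0) {
    stop("shell inner radius must lie in [0, outer radius)")
  }
  shell_value <- if (is.null(contrast$shell_value)) -1 else contrast$shell_value
  noise_sd <- if (is.null(contrast$noise_sd)) 0 else contrast$noise_sd
  seed <- if (is.null(contrast$seed)) truth$config$seed else contrast$seed
  set.seed(seed)
  dims <- truth$config$volume_shape
  vs <- truth$config$voxel_size
  arr <- array(0, dim = dims)
  centers <- particle_centers(truth$particles)
  rv_out <- outer_r / vs
  rv_in <- inner_r / vs
  for (i in seq_len(nrow(centers))) {
    ci <- nm_to_index(centers[i, ], vs)
    lo <- pmax(floor(ci - rv_out), 1)
    hi <- pmin(ceiling(ci + rv_out), dims)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    d2 <- outer(outer((ii - ci[1])^2, (jj - ci[2])^2, "+"), (kk - ci[3])^2, "+")
    shell <- d2 >= rv_in^2 & d2 <= rv_out^2
    sub <- arr[ii, jj, kk, drop = FALSE]
    sub[shell] <- shell_value
    arr[ii, jj, kk] <- sub
  }
  if (noise_sd > 0) {
    arr <- arr + stats::rnorm(length(arr), 0, noise_sd)
  }
  if (!is.null(contrast$wedge_half_angle)) {
    wedge <- missing_wedge_mask(dims, contrast$wedge_half_angle)
    ft <- stats::fft(arr)
    ft[wedge] <- 0
    arr <- Re(stats::fft(ft, inverse = TRUE)) / length(arr)
  }
  voxel_grid(arr, vs)
}

#' Missing-wedge region in Fourier space
#'
#' Logical array (FFT layout) marking frequency directions within
#' `half_angle` degrees of the beam (z) axis in the x-z plane — the region a
#' +/-(90 - half_angle) degree tilt series about the y axis never samples.
#' The DC component is excluded so the volume mean is preserved.
#'
#' @param dims voxel dimensions (nx, ny, nz).
#' @param half_angle wedge half-angle, degrees.
#' @return Logical 3D array.
#' @export
missing_wedge_mask <- function(dims, half_angle) {
  fftfreq <- function(n) {
    f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    f
  }
  fx <- fftfreq(dims[1]); fz <- fftfreq(dims[3])
  ang <- atan2(abs(outer(fx, rep(1, dims[3]))),
               abs(outer(rep(1, dims[1]), fz)))  # angle from z axis, x-z plane
  fxz2 <- outer(fx^2, fz^2, "+")
  # pure-fy directions (fx = fz = 0) lie along the tilt axis: always sampled
  w2d <- ang < half_angle * pi / 180 & fxz2 > 0
  aperm(array(w2d, dim = c(dims[1], dims[3], dims[2])), c(1, 3, 2))
}
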