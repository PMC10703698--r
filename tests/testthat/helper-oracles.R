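# Independent brute-force oracles used to check the package's fast paths.

# nearest-structure-voxel distance (nm) by exhaustive search
brute_force_distance <- function(center_nm, mask) {
  idx <- which(mask$data)
  ijk <- arrayInd(idx, dim(mask$data))
  coords <- (ijk - 1) * mask$voxel_size
  sqrt(min(rowSums(sweep(coords, 2, center_nm)^2)))
}

# connected-component count by BFS flood fill in plain R (26-connectivity)
flood_fill_count <- function(arr) {
  d <- dim(arr)
  visited <- array(FALSE, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  n_comp <- 0L
  todo <- which(arr & !visited)
  while (length(todo)) {
    n_comp <- n_comp + 1L
    queue <- todo[1]
    visited[queue] <- TRUE
    while (length(queue)) {
      ijk <- arrayInd(queue, d)
      queue <- integer(0)
      for (q in seq_len(nrow(ijk))) {
        nb <- sweep(offs, 2, as.integer(ijk[q, ]), "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
        lin <- lin[arr[lin] & !visited[lin]]
        visited[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
    todo <- which(arr & !visited)
  }
  n_comp
}

# voxel count of a rasterized sphere (lattice points within radius, voxels)
lattice_ball_count <- function(radius_vox) {
  r <- ceiling(radius_vox)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  sum(g$x^2 + g$y^2 + g$z^2 <= radius_vox^2)
}

# a minimal scene_truth carrying hand-placed particle centres, for the
# renderers (bypasses hard-sphere placement)
manual_truth <- function(centers_nm, dims, voxel_size, particle_radius = 12.5,
                         seed = 1L) {
  cfg <- scene_config(volume_shape = dims, voxel_size = voxel_size,
                      lamella_thickness = max(3 * particle_radius, 40),
                      particle_radius = particle_radius, seed = seed)
  n <- nrow(centers_nm)
  structure(list(
    particles = particle_set(data.frame(
      x_nm = centers_nm[, 1], y_nm = centers_nm[, 2], z_nm = centers_nm[, 3],
      source = "truth", status = "retained")),
    structure_mask = gemquant:::build_structure_mask(cfg),
    lamella_mask = gemquant:::build_lamella_mask(cfg),
    config = cfg), class = "scene_truth")
}
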