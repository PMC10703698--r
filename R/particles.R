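#' Particle coordinate sets
#'
#' A `particle_set` is a data frame of particle records in the physical
#' (nm) tomogram frame, with one row per particle and columns:
#' `tomo_id`, `particle_id`, `x_nm`, `y_nm`, `z_nm`, `score`, `source`
#' (`"detector"`, `"manual"` or `"truth"`), `status` (`"retained"` or
#' `"discarded:<category>"`). Truth-table sets generated by
#' [simulate_scene()] additionally carry `bound` and `surface_distance_nm`.
#'
#' @param df data frame with at least `x_nm`, `y_nm`, `z_nm` columns; missing
#'   bookkeeping columns are filled with defaults.
#' @return A data frame of class `particle_set`.
#' @export
particle_set <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(tomo_id = character(), particle_id = integer(),
                     x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                     score = numeric(), source = character(),
                     status = character(), stringsAsFactors = FALSE)
  }
  req <- c("x_nm", "y_nm", "z_nm")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("particle_set: missing coordinate columns: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  if (is.null(df$tomo_id)) df$tomo_id <- rep("tomo_1", n)
  if (is.null(df$particle_id)) df$particle_id <- seq_len(n)
  if (is.null(df$score)) df$score <- rep(NA_real_, n)
  if (is.null(df$source)) df$source <- rep("detector", n)
  if (is.null(df$status)) df$status <- rep("retained", n)
  if (n > 0 && !all(is.finite(as.matrix(df[, req])))) {
    stop("particle_set: particle centers must be finite")
  }
  class(df) <- c("particle_set", "data.frame")
  df
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles (%d retained) in %d tomogram(s)\n",
              nrow(x), sum(x$status == "retained"),
              length(unique(x$tomo_id))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# internal: n x 3 matrix of centers in nm
particle_centers <- function(particles) {
  as.matrix(as.data.frame(particles)[, c("x_nm", "y_nm", "z_nm")])
}

#' Read or write particle tables
#'
#' Particle tables are CSV files with header columns `tomo_id, x_nm, y_nm,
#' z_nm, score, source, status` (additional columns such as `particle_id`,
#' `bound`, `surface_distance_nm` are preserved). Coordinates are physical
#' nm; tables written in voxel units can be converted by supplying
#' `voxel_size`, which multiplies the coordinate columns through.
#'
#' @param path CSV file path.
#' @param voxel_size optional nm/voxel factor applied to `x_nm`, `y_nm`,
#'   `z_nm` on read (for tables stored in voxel units).
#' @return For `read_particles`, a [particle_set].
#' @export
read_particles <- function(path, voxel_size = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("tomo_id", "x_nm", "y_nm", "z_nm", "score", "source", "status")
  absent <- setdiff(req, names(df))
  if (length(absent)) {
    stop("particle table schema error, missing column(s): ",
         paste(absent, collapse = ", "))
  }
  for (col in c("x_nm", "y_nm", "z_nm")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("malformed particle table row(s) ", paste(bad, collapse = ", "),
           ": non-numeric ", col)
    }
  }
  if (!is.null(voxel_size)) {
    df$x_nm <- df$x_nm * voxel_size
    df$y_nm <- df$y_nm * voxel_size
    df$z_nm <- df$z_nm * voxel_size
  }
  particle_set(df)
}

#' @param particles a [particle_set].
#' @rdname read_particles
#' @export
write_particles <- function(particles, path) {
  stopifnot(inherits(particles, "particle_set"))
  utils::write.csv(as.data.frame(particles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
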