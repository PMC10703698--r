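#' Read and write MRC2014 volumes
#'
#' Minimal MRC2014 I/O for tomograms, probability maps and masks. Maps are
#' written as mode 2 (32-bit float); modes 0 (int8), 1 (int16) and 2 are
#' accepted on read. The voxel size is taken from the cell dimensions in the
#' header (Angstrom) and reported in nm; it is preserved on round-trip.
#'
#' @param path MRC file path.
#' @param voxel_size optional nm/voxel override, required when the header
#'   carries no (or a zero) voxel size.
#' @return For `read_volume`, a [voxel_grid]; for `read_mask`, a
#'   [binary_mask] (data binarized at 0.5).
#' @export
read_volume <- function(path, voxel_size = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5 || nz > 1e5) {
    stop("not a readable MRC file (bad dimensions): ", path)
  }
  # skip to word 53 ('MAP ' magic); words consumed so far: 13
  seek(con, 52 * 4)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MAP ")) {
    warning("MRC file lacks 'MAP ' magic; attempting to read anyway: ", path)
  }
  seek(con, 1024)
  n <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode, " (expected 0, 1 or 2)")
  )
  if (length(data) != n) stop("truncated MRC data in ", path)
  vs_nm <- if (mxyz[1] > 0) cella[1] / mxyz[1] / 10 else 0
  if (is.null(voxel_size)) {
    if (!is.finite(vs_nm) || vs_nm <= 0) {
      stop("MRC header has no voxel size; supply voxel_size explicitly ",
           "(--voxel-size)")
    }
    voxel_size <- vs_nm
  }
  voxel_grid(array(data, dim = c(nx, ny, nz)), voxel_size)
}

#' @param volume a [voxel_grid] (or [binary_mask] for `write_mask`).
#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_grid") || inherits(volume, "binary_mask"))
  data <- volume$data
  if (is.logical(data)) data <- array(as.numeric(data), dim = dim(data))
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")                        # nx..mz (words 1-10)
  cella_A <- d * volume$voxel_size * 10              # cell in Angstrom
  writeBin(c(cella_A, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")  # mapc/mapr/maps
  dstats <- c(min(data), max(data), mean(data))
  writeBin(dstats, con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")      # ispg, nsymbt
  writeBin(rep(0L, 25), con, size = 4, endian = "little")    # extra
  writeBin(rep(0, 3), con, size = 4, endian = "little")      # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(c(68L, 65L, 0L, 0L), con, size = 1)               # machst (LE)
  writeBin(stats::sd(as.numeric(data)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")             # nlabl
  writeBin(raw(800), con)                                    # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, voxel_size = NULL) {
  g <- read_volume(path, voxel_size = voxel_size)
  binary_mask(g$data > 0.5, g$voxel_size)
}

#' @param mask a [binary_mask].
#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_volume(mask, path)
}
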