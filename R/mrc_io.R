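#' Read an MRC/CCP4 density map
#'
#' Minimal MRC2014 reader: mode 2 (32-bit float) maps with the standard
#' 1024-byte header, column/row/section order x,y,z.  The voxel size is
#' taken from the cell dimensions divided by the sampling grid; the origin
#' from the ORIGIN header words (falling back to NxSTART offsets).
#'
#' @param path path to an `.mrc`/`.map` file.
#' @return a `DensityMap`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", 10L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  m_grid <- hdr_int[8:10]
  cella <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  seek(con, 64L)  # mapc/mapr/maps at words 17-19
  mapcrs <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  seek(con, 196L)  # ORIGIN words 50-52
  orig <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  seek(con, 92L)   # NSYMBT at word 24
  nsymbt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2)")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order: ", paste(mapcrs, collapse = ","))
  seek(con, 1024L + nsymbt)
  n <- nx * ny * nz
  vals <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(vals) != n) stop("truncated MRC data block")
  voxel <- cella[1] / max(m_grid[1], 1L)
  if (all(orig == 0) && any(nstart != 0)) orig <- nstart * voxel
  new_density_map(array(vals, c(nx, ny, nz)), voxel, orig)
}

#' Write an MRC/CCP4 density map
#'
#' Emits an MRC2014 mode-2 (32-bit float) file with cell dimensions set
#' from the voxel size and the origin stored in the ORIGIN header words.
#'
#' @param m a `DensityMap`.
#' @param path output path.
#' @export
write_mrc <- function(m, path) {
  stopifnot(inherits(m, "DensityMap"))
  dims <- dim(m$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(dims)                         # NX NY NZ
  wi(2L)                           # MODE 2 = float32
  wi(c(0L, 0L, 0L))                # NXSTART..
  wi(dims)                         # MX MY MZ
  wf(dims * m$voxel_size)          # CELLA
  wf(c(90, 90, 90))                # CELLB
  wi(c(1L, 2L, 3L))                # MAPC MAPR MAPS
  wf(c(min(m$data), max(m$data), mean(m$data)))  # DMIN DMAX DMEAN
  wi(1L)                           # ISPG
  wi(0L)                           # NSYMBT
  wi(rep(0L, 25L))                 # EXTRA (words 26-49)
  wf(m$origin)                     # ORIGIN
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(m$data))            # RMS
  wi(0L)                           # NLABL
  writeBin(raw(800L), con)         # empty labels
  writeBin(as.numeric(m$data), con, size = 4L, endian = "little")
  invisible(path)
}
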