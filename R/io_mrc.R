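# MRC2014 volume I/O.
#
# Header: 1024 bytes = 256 four-byte words. Words used here (1-based):
#   1-3   nx, ny, nz (nx fastest-varying on disk)
#   4     mode (0 int8, 1 int16, 2 float32, 6 uint16)
#   8-10  mx, my, mz   11-13 cella (A)   17-19 mapc, mapr, maps
#   20-22 dmin, dmax, dmean   24 nsymbt   50-52 origin (A)
#   53    "MAP " magic   54 machine stamp   55 rms   56 nlabl
# Voxel size is cella / m{x,y,z}.

mrc_mode_info <- function(mode) {
  switch(as.character(mode),
    "0" = list(what = "integer", size = 1L, signed = TRUE),
    "1" = list(what = "integer", size = 2L, signed = TRUE),
    "2" = list(what = "numeric", size = 4L, signed = TRUE),
    "6" = list(what = "integer", size = 2L, signed = FALSE),
    NULL
  )
}

#' Read an MRC2014 volume
#'
#' Reads modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16); data are cast
#' to double. The voxel size is taken as `cella / mx` (x spacing); if the
#' header is anisotropic the x spacing is used and a warning is raised. Axis
#' order is normalized so the returned array is dimensioned `c(nx, ny, nz)`
#' regardless of the header's `mapc/mapr/maps` permutation.
#'
#' @param path path to an MRC file.
#' @return A [volume3d()].
#' @seealso [write_mrc()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop_fmt("MRC file does not exist: %s", path)
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < 1024) {
    stop_fmt("not a valid MRC file (smaller than the 1024-byte header): %s",
             path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  # endianness from the machine stamp (word 54); 0x44 = little, 0x11 = big
  st <- as.integer(hdr_raw[213])
  endian <- if (st == 0x11) "big" else "little"
  word_int <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                  "integer", size = 4L, endian = endian)
  word_flt <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                  "numeric", size = 4L, endian = endian)
  nx <- word_int(1); ny <- word_int(2); nz <- word_int(3)
  mode <- word_int(4)
  info <- mrc_mode_info(mode)
  if (is.null(info)) {
    stop_fmt("unsupported MRC mode %d in %s (supported: 0, 1, 2, 6)",
             mode, path)
  }
  if (nx < 1 || ny < 1 || nz < 1 || nx > 1e5 || ny > 1e5 || nz > 1e5) {
    stop_fmt("unreadable MRC header in %s (nx,ny,nz = %d,%d,%d)",
             path, nx, ny, nz)
  }
  mx <- word_int(8); my <- word_int(9); mz <- word_int(10)
  cella <- c(word_flt(11), word_flt(12), word_flt(13))
  perm <- c(word_int(17), word_int(18), word_int(19))
  nsymbt <- word_int(24)
  origin <- c(word_flt(50), word_flt(51), word_flt(52))

  nvox <- as.numeric(nx) * ny * nz
  need <- 1024 + nsymbt + nvox * info$size
  if (fsize < need) {
    stop_fmt("truncated MRC file %s: %d bytes, header implies %.0f",
             path, fsize, need)
  }
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  dat <- readBin(con, info$what, n = nvox, size = info$size,
                 signed = info$signed, endian = endian)
  dat <- as.double(dat)
  dims_file <- c(nx, ny, nz)
  arr <- array(dat, dim = dims_file)
  # normalize axis order: mapc/mapr/maps says which axis (1=x,2=y,3=z) varies
  # fastest/medium/slowest in the file
  if (all(sort(perm) == 1:3) && !all(perm == 1:3)) {
    arr <- aperm(arr, order(perm))
  }
  vsz <- cella / pmax(c(mx, my, mz), 1L)
  vsz[!is.finite(vsz) | vsz <= 0] <- NA
  if (all(is.na(vsz))) {
    voxel_size <- 1
  } else {
    voxel_size <- vsz[which(!is.na(vsz))[1]]
    ok <- stats::na.omit(vsz)
    if (max(ok) - min(ok) > 1e-4 * voxel_size) {
      warn_fmt("anisotropic voxel size in %s (%s A); using x spacing %.4g A",
               path, paste(signif(ok, 5), collapse = ", "), voxel_size)
    }
  }
  volume3d(arr, voxel_size = voxel_size, origin = origin)
}

#' Write a volume as MRC2014 (mode 2, float32)
#'
#' @param volume a [volume3d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path) {
  stopifnot(is_volume3d(volume))
  d <- dim(volume$data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_fmt("cannot open %s for writing: %s",
                                               path, conditionMessage(e)))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  dat <- as.vector(volume$data)
  wi(d)                               # nx ny nz
  wi(2L)                              # mode 2 = float32
  wi(c(0L, 0L, 0L))                   # nxstart
  wi(d)                               # mx my mz
  wf(d * volume$voxel_size)           # cella
  wf(c(90, 90, 90))                   # cellb
  wi(1:3)                             # mapc mapr maps
  wf(c(min(dat), max(dat), mean(dat)))# dmin dmax dmean
  wi(c(1L, 0L))                       # ispg, nsymbt
  wi(integer(25))                     # extra
  wf(volume$origin)                   # origin
  writeBin(charToRaw("MAP "), con)    # magic
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # machine stamp (LE)
  wf(stats::sd(dat))                  # rms
  wi(0L)                              # nlabl
  writeBin(raw(800), con)             # labels
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  invisible(path)
}
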