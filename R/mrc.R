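# MRC2014 I/O.  No installed R package reads this format, so the (simple,
# fixed-layout) header and the mode-2 float payload are handled directly.
# Only the standard axis order mapc/mapr/maps = 1/2/3 is supported; permuted
# axis orders raise an explicit error naming the order found.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 density map
#'
#' Supports mode 2 (float32) and the integer modes 0/1/6, which are converted
#' to scalar values. The physical origin is taken from the ORIGIN header
#' fields when any of them is nonzero, and otherwise from the start-voxel
#' fields (\code{nxstart * voxel_size}).
#'
#' @param path path to an MRC file.
#' @return A \code{density_map}.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < MRC_HEADER_BYTES)
    stop("not an MRC file (shorter than the 1024-byte header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", MRC_HEADER_BYTES)
  # guess endianness from the machine stamp (bytes 213-214): 0x44 = little
  endian <- if (as.integer(hdr_raw[213]) == 0x11) "big" else "little"
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "integer",
                                1, size = 4, endian = endian)
  dbl_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "numeric",
                                1, size = 4, endian = endian)
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  nxstart <- int_at(5); nystart <- int_at(6); nzstart <- int_at(7)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(dbl_at(11), dbl_at(12), dbl_at(13))
  mapc <- int_at(17); mapr <- int_at(18); maps <- int_at(19)
  nsymbt <- int_at(24)
  origin_field <- c(dbl_at(50), dbl_at(51), dbl_at(52))
  if (nx < 1 || ny < 1 || nz < 1 || nx > 1e5)
    stop("unreadable MRC header (bad dimensions) in: ", path)
  if (!all(c(mapc, mapr, maps) == 1:3))
    stop(sprintf(
      "unsupported MRC axis order mapc/mapr/maps = %d/%d/%d (only 1/2/3 is supported)",
      mapc, mapr, maps))
  voxel <- ifelse(c(mx, my, mz) > 0, cella / c(mx, my, mz), 1)
  n <- as.double(nx) * ny * nz
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE,
                             endian = endian)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "numeric", n, size = 4, endian = endian),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = endian)),
    stop("unsupported MRC mode ", mode, " (only 0, 1, 2, 6)"))
  if (length(vals) < n)
    stop("truncated MRC file: expected ", n, " voxels, got ", length(vals))
  origin <- if (any(origin_field != 0)) origin_field
            else c(nxstart, nystart, nzstart) * voxel
  density_map(array(vals, c(nx, ny, nz)), voxel, origin,
              label = basename(path))
}

#' Write a density map as MRC2014 (mode 2)
#'
#' Voxel size and origin are stored so that \code{read_map(write_map(m))}
#' reproduces the map exactly (values bitwise at float32 precision).
#'
#' @param map a \code{density_map}.
#' @param path output path.
#' @param origin_mode \code{"origin"} (default) stores the physical origin in
#'   the ORIGIN header fields; \code{"start"} stores it in the start-voxel
#'   fields instead (origin must then be an integer multiple of the voxel
#'   size), for compatibility with older CCP4-convention consumers.
#' @return Invisibly, \code{path}.
#' @export
write_map <- function(map, path, origin_mode = c("origin", "start")) {
  origin_mode <- match.arg(origin_mode)
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  start <- c(0L, 0L, 0L)
  origin_field <- map$origin
  if (origin_mode == "start") {
    start <- round(map$origin / map$voxel_size)
    if (max(abs(start * map$voxel_size - map$origin)) > 1e-4)
      stop("origin is not a voxel multiple; cannot use start-voxel fields")
    origin_field <- c(0, 0, 0)
  }
  wi(d)                               # nx ny nz
  wi(2L)                              # mode 2 = float32
  wi(start)                           # nxstart nystart nzstart
  wi(d)                               # mx my mz
  wf(d * map$voxel_size)              # cella
  wf(c(90, 90, 90))                   # cellb
  wi(1:3)                             # mapc mapr maps
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(0L)                              # ispg
  wi(0L)                              # nsymbt
  writeBin(raw(4 * 25), con)          # extra (words 26-50)
  wf(origin_field)                    # origin x y z
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(as.numeric(map$values)))
  wi(0L)                              # nlabl
  writeBin(raw(800), con)             # labels
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(path)
}
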