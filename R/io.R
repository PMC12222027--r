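#' Read and write density maps in MRC2014 format
#'
#' Minimal MRC2014 support for mode-2 (32-bit float) volumes, the format in
#' which cryo-EM maps are deposited. The voxel size is taken from the cell
#' dimensions divided by the sampling (`CELLA / MX`); only isotropic voxel
#' sizes and the standard x-fastest axis order (MAPC,MAPR,MAPS = 1,2,3) are
#' supported. Unsupported modes or dialects raise an explicit error naming
#' the offending field; a truncated file errors rather than returning a
#' partial map. `write_map()` then `read_map()` round-trips the grid
#' bit-identically (maps are stored as 32-bit floats, so write your grid
#' from `read_map()` output or accept float32 rounding).
#'
#' @param path file path.
#' @return `read_map()` returns a [density_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "double", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "double", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "double", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 100))           # EXTRA words 25-49
  invisible(readBin(con, "double", n = 3, size = 4, endian = "little")) # ORIGIN
  map_id <- rawToChar(readBin(con, "raw", n = 4))
  invisible(readBin(con, "raw", n = 4))             # MACHST
  invisible(readBin(con, "double", n = 1, size = 4, endian = "little")) # RMS
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little")) # NLABL
  invisible(readBin(con, "raw", n = 800))           # labels
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  if (!identical(substr(map_id, 1, 3), "MAP")) {
    stop("not an MRC2014 file: missing MAP identifier", call. = FALSE)
  }
  if (mode != 2L) {
    stop(sprintf("unsupported MRC mode %d (only mode 2, float32)", mode),
         call. = FALSE)
  }
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    stop(sprintf("unsupported axis order MAPC,MAPR,MAPS = %s (only 1,2,3)",
                 paste(mapcrs, collapse = ",")), call. = FALSE)
  }
  vsz <- cella / c(mx, my, mz)
  if (diff(range(vsz)) > 1e-4 * mean(vsz)) {
    stop(sprintf("unsupported anisotropic voxel size (%.4g, %.4g, %.4g A)",
                 vsz[1], vsz[2], vsz[3]), call. = FALSE)
  }
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  nvox <- as.numeric(nx) * ny * nz
  vals <- readBin(con, "double", n = nvox, size = 4, endian = "little")
  if (length(vals) < nvox) {
    stop(sprintf("truncated MRC file: expected %d voxels, read %d",
                 nvox, length(vals)), call. = FALSE)
  }
  density_map(array(vals, c(nx, ny, nz)), mean(vsz))
}

#' @param map a [density_map] to write.
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  stop_if_not_map(map)
  d <- dim(map$grid)
  vs <- map$voxel_size
  # float32 rounding now, so the header stats match the stored data
  vals <- readBin(writeBin(as.vector(map$grid), raw(), size = 4,
                           endian = "little"),
                  "double", n = prod(d), size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(c(d * vs, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  writeBin(c(min(vals), max(vals), mean(vals)), con, size = 4,
           endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")  # ISPG, NSYMBT
  writeBin(raw(8), con)                                   # EXTRA words 25-26
  writeBin(charToRaw("MRCO"), con)                        # EXTTYP
  writeBin(20140L, con, size = 4, endian = "little")      # NVERSION
  writeBin(raw(84), con)                                  # rest of EXTRA
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")  # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)        # MACHST (LE)
  writeBin(stats::sd(vals), con, size = 4, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")          # NLABL
  lab <- sprintf("%-80s", "flagmotor density map")
  writeBin(charToRaw(lab), con)
  writeBin(raw(720), con)
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read and write bead trajectories as CSV
#'
#' Trajectories are exchanged as plain CSV with header `t,x,y` (seconds,
#' nm, nm). `read_trajectory()` validates the header, reports non-numeric
#' rows with their line numbers, warns about (and ignores) extra columns,
#' and errors on non-monotone time stamps. `write_trajectory()` stores 9
#' significant digits, enough for a lossless round trip at assay precision.
#'
#' @param path CSV file path.
#' @return `read_trajectory()` returns a [bead_trajectory].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  need <- c("t", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning(sprintf("ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  num <- lapply(df[need], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    stop(sprintf("non-numeric values on line(s): %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  tryCatch(bead_trajectory(num$t, num$x, num$y),
           error = function(e) stop(conditionMessage(e), call. = FALSE))
}

#' @param traj a [bead_trajectory] to write.
#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  lines <- c("t,x,y",
             sprintf("%.9g,%.9g,%.9g", traj$t, traj$x, traj$y))
  writeLines(lines, path)
  invisible(path)
}
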