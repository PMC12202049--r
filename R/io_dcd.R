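# CHARMM/NAMD-style binary DCD trajectories. Fortran unformatted records
# (4-byte length markers around each payload); endianness auto-detected from
# the leading marker, which must read 84 one way or the other.

.dcd_record <- function(con, endian, what = "integer", size = 4) {
  len <- readBin(con, "integer", 1, 4, endian = endian)
  if (length(len) == 0) return(NULL)
  payload <- readBin(con, what, len %/% size, size, endian = endian)
  if (length(payload) < len %/% size) stop("truncated DCD record", call. = FALSE)
  end <- readBin(con, "integer", 1, 4, endian = endian)
  if (length(end) == 0 || end != len) stop("corrupt DCD record framing", call. = FALSE)
  payload
}

#' Read a DCD trajectory and append its frames to a system
#'
#' @param path DCD file path
#' @param system the `molsys` the trajectory belongs to; frame atom counts
#'   must match.
#' @return the system with frames appended
#' @export
read_dcd <- function(path, system) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", 1, 4, endian = "little")
  endian <- if (identical(first, 84L)) "little"
            else if (identical(.swap_int32(first), 84L)) "big"
            else stop("not a DCD file: bad leading record marker", call. = FALSE)
  hdr_raw <- readBin(con, "raw", 84)
  end <- readBin(con, "integer", 1, 4, endian = endian)
  if (!identical(end, 84L)) stop("corrupt DCD header framing", call. = FALSE)
  magic <- rawToChar(hdr_raw[1:4])
  if (magic != "CORD") stop("not a coordinate DCD (magic '", magic, "')", call. = FALSE)
  icntrl <- readBin(hdr_raw[5:84], "integer", 20, 4, endian = endian)
  nset <- icntrl[1]
  has_cell <- icntrl[11] == 1L
  .dcd_record(con, endian, "raw", 1)                      # title block
  natom <- .dcd_record(con, endian)[1]
  if (natom != n_atoms(system))
    stop("DCD frame atom count (", natom, ") does not match system (",
         n_atoms(system), ")", call. = FALSE)
  k <- 0L
  repeat {
    if (nset > 0 && k >= nset) break
    x <- tryCatch(.dcd_record(con, endian, "numeric", 4),
                  error = function(e) stop("truncated DCD at frame ", k + 1L,
                                           call. = FALSE))
    if (is.null(x)) break
    if (has_cell && length(x) == 12) # unit-cell record (6 doubles); skip
      x <- .dcd_record(con, endian, "numeric", 4)
    y <- .dcd_record(con, endian, "numeric", 4)
    z <- .dcd_record(con, endian, "numeric", 4)
    if (is.null(y) || is.null(z) || length(x) != natom ||
        length(y) != natom || length(z) != natom)
      stop("truncated DCD at frame ", k + 1L, call. = FALSE)
    system$frames[[length(system$frames) + 1L]] <- cbind(x, y, z, deparse.level = 0)
    k <- k + 1L
  }
  if (nset > 0 && k < nset)
    stop("truncated DCD: header promises ", nset, " frames, found ", k,
         call. = FALSE)
  system
}

.swap_int32 <- function(x) {
  r <- writeBin(as.integer(x), raw(), 4, endian = "little")
  readBin(rev(r), "integer", 1, 4, endian = "little")
}

#' Write a synthetic DCD trajectory
#'
#' CHARMM-style layout as read back by [read_dcd()]; used as the round-trip
#' oracle for the trajectory reader. Coordinates are stored as 32-bit floats.
#'
#' @param frames list of n x 3 coordinate matrices (all the same n)
#' @param path output path
#' @param endian `"little"` (default) or `"big"`
#' @export
write_dcd <- function(frames, path, endian = c("little", "big")) {
  endian <- match.arg(endian)
  if (!length(frames)) stop("no frames to write", call. = FALSE)
  n <- nrow(frames[[1]])
  for (fr in frames) stopifnot(is.matrix(fr), ncol(fr) == 3, nrow(fr) == n)
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(payload_writer, len) {
    writeBin(as.integer(len), con, 4, endian = endian)
    payload_writer()
    writeBin(as.integer(len), con, 4, endian = endian)
  }
  icntrl <- integer(20)
  icntrl[1] <- length(frames)   # nset
  icntrl[2] <- 0L; icntrl[3] <- 1L
  icntrl[20] <- 24L             # CHARMM version tag
  wrec(function() {
    writeBin(charToRaw("CORD"), con)
    writeBin(icntrl, con, 4, endian = endian)
  }, 84)
  title <- sprintf("%-80s", "synthetic trajectory written by molray")
  wrec(function() {
    writeBin(1L, con, 4, endian = endian)
    writeBin(charToRaw(title), con)
  }, 84)
  wrec(function() writeBin(as.integer(n), con, 4, endian = endian), 4)
  for (fr in frames)
    for (axis in 1:3)
      wrec(function() writeBin(as.numeric(fr[, axis]), con, 4, endian = endian),
           4 * n)
  invisible(path)
}
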