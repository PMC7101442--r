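#' Write and read streamlines in TrackVis .trk format
#'
#' Standard TrackVis v2 files: a 1000-byte header carrying the reference
#' grid dimensions, voxel size and track count, followed by each track as
#' an int32 point count plus float32 xyz triples. Points are stored in the
#' TrackVis "voxmm" convention — corner-origin voxel coordinates scaled by
#' the voxel size — so the affine applied to this package's physical-um,
#' voxel-centre coordinates is
#' `trk = ((p - origin) / spacing + 0.5) * spacing`, with micrometres
#' standing in for TrackVis' millimetres, identity orientation
#' (voxel order RAS). `read_streamlines` inverts the same affine.
#'
#' @param tracks a `streamline_set` from [track()].
#' @param path output `.trk` path.
#' @param reference a [voxel_grid()] defining dimensions/voxel size; every
#'   point must lie inside its physical bounds. An empty set is legal
#'   (`n_count = 0`); any NaN point is an error.
#' @return the path (`write`); a `streamline_set` (`read`, with the
#'   reference geometry in `$params`).
#' @export
write_streamlines <- function(tracks, path, reference) {
  stopifnot(inherits(tracks, "streamline_set"), inherits(reference, "voxel_grid"))
  d <- dim(reference$data); sp <- reference$spacing; or <- reference$origin
  for (p in tracks$tracks) {
    if (any(!is.finite(p))) stop("streamline contains NaN/Inf points")
    idx <- sweep(sweep(p, 2, or), 2, sp, "/")   # 0-based voxel-centre index
    if (any(idx < -0.5) || any(idx > rep(d, each = nrow(p)) - 0.5))
      stop("streamline point outside the reference volume bounds")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r[seq_len(min(length(r), n))], raw(max(0, n - length(r)))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(d), con, size = 2L, endian = "little")          # dim
  writeBin(as.numeric(sp), con, size = 4L, endian = "little")         # voxel_size
  writeBin(as.numeric(or), con, size = 4L, endian = "little")         # origin
  writeBin(0L, con, size = 2L, endian = "little")                     # n_scalars
  wchar("", 200)
  writeBin(0L, con, size = 2L, endian = "little")                     # n_properties
  wchar("", 200)
  m <- diag(c(sp, 1)); m[1:3, 4] <- or                                # vox_to_ras
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  wchar("", 444)                                                      # reserved
  wchar("RAS", 4)                                                     # voxel_order
  wchar("", 4)                                                        # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")    # orientation
  wchar("", 2)                                                        # pad1
  writeBin(raw(6), con)                                               # invert/swap flags
  writeBin(length(tracks$tracks), con, size = 4L, endian = "little")  # n_count
  writeBin(2L, con, size = 4L, endian = "little")                     # version
  writeBin(1000L, con, size = 4L, endian = "little")                  # hdr_size
  for (p in tracks$tracks) {
    writeBin(nrow(p), con, size = 4L, endian = "little")
    voxmm <- sweep(sweep(sweep(p, 2, or), 2, sp, "/") + 0.5, 2, sp, "*")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (magic != "TRACK") stop("not a TrackVis .trk file: ", path)
  d <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  sp <- readBin(con, "double", 3L, size = 4L, endian = "little")
  or <- readBin(con, "double", 3L, size = 4L, endian = "little")
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L + 64L + 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  invisible(readBin(con, "raw", 8L))
  tracks <- vector("list", n_count)
  for (t in seq_len(n_count)) {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    pts <- matrix(readBin(con, "double", np * (3L + n_scalars), size = 4L,
                          endian = "little"),
                  ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) invisible(readBin(con, "double", n_props, size = 4L,
                                       endian = "little"))
    tracks[[t]] <- sweep(sweep(sweep(pts, 2, sp, "/") - 0.5, 2, sp, "*"), 2, or, "+")
  }
  structure(list(tracks = tracks,
                 reasons = matrix(NA_character_, n_count, 2),
                 params = list(dim = d, voxel_size = sp, origin = or,
                               source = path),
                 n_omitted = 0L),
            class = "streamline_set")
}
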