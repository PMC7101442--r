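#' Write and read tensor fields as NRRD
#'
#' The field is stored as a 4D NRRD (`double`, raw little-endian) whose
#' first axis has length 7: the six upper-triangular tensor components in
#' the fixed order `xx, xy, xz, yy, yz, zz` (um^2) followed by the
#' descriptor count N. Grid spacing equals the window stride; the window
#' edge and the validity threshold travel in NRRD key/value fields
#' (`window_um`, `min_count`), which is why NRRD (arbitrary key/values,
#' bit-exact raw encoding) is used rather than NIfTI.
#'
#' @param field a [tensor_field()].
#' @param path output `.nrrd` path.
#' @return the path (`write`), or the reconstructed [tensor_field()]
#'   (`read`).
#' @export
write_tensor_field <- function(field, path) {
  stopifnot(inherits(field, "tensor_field"))
  nd <- dim(field$count)
  if (any(!is.finite(field$cm)))
    stop("tensor field contains non-finite components")
  header <- c(
    "NRRD0004",
    "# tensor field: 6 upper-triangular covariance components (um^2) + count",
    "type: double",
    "dimension: 4",
    sprintf("sizes: 7 %d %d %d", nd[1], nd[2], nd[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space origin: (%.17g,%.17g,%.17g)", field$origin[1],
            field$origin[2], field$origin[3]),
    sprintf("space directions: none (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            field$stride, field$stride, field$stride),
    "kinds: none space space space",
    sprintf("window_um:=%.17g", field$window),
    sprintf("min_count:=%d", field$min_count),
    "component_order:=xx xy xz yy yz zz count",
    "")
  payload <- array(0, c(7, nd))
  payload[1:6, , , ] <- field$cm
  payload[7, , , ] <- field$count
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.vector(payload), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_tensor_field
#' @export
read_tensor_field <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ln <- readBin(con, "raw", 1L)
    buf <- raw(0)
    while (length(ln) && ln != as.raw(10L)) { buf <- c(buf, ln); ln <- readBin(con, "raw", 1L) }
    line <- rawToChar(buf)
    if (!nzchar(line)) break
    lines <- c(lines, line)
  }
  if (!length(lines) || !startsWith(lines[1], "NRRD"))
    stop("not an NRRD file: ", path)
  getfield <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  getkv <- function(key) {
    hit <- grep(paste0("^", key, ":="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, ":="), "", hit[1])
  }
  sizes <- as.integer(strsplit(getfield("sizes"), " ")[[1]])
  stopifnot(length(sizes) == 4L, sizes[1] == 7L)
  origin <- as.numeric(strsplit(gsub("[()]", "", getfield("space origin")), ",")[[1]])
  dirs <- getfield("space directions")
  stride <- as.numeric(strsplit(gsub("[()]", "",
             strsplit(dirs, " ")[[1]][2]), ",")[[1]])[1]
  vals <- readBin(con, "double", n = prod(sizes), size = 8L, endian = "little")
  payload <- array(vals, sizes)
  cm <- payload[1:6, , , , drop = FALSE]
  dim(cm) <- c(6L, sizes[2:4])
  count <- array(as.integer(round(payload[7, , , ])), sizes[2:4])
  tensor_field(cm, count, origin = origin, stride = stride,
               window = as.numeric(getkv("window_um") %||% stride),
               min_count = as.integer(getkv("min_count") %||% 2L))
}
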