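#' Read and write 3D volumes as multi-page TIFF stacks
#'
#' Volumes are stored one z-slice per TIFF page (32-bit float). Because the
#' TIFF samples are kept in \[0, 1\], `write_volume` min-max scales the data
#' and records the scale together with spacing and origin in a plain-text
#' JSON sidecar (`<path>.meta.json`); `read_volume` undoes the scaling when
#' the sidecar is present, so the round trip is lossless at float32
#' precision (and exact for masks and label volumes, which are re-rounded).
#' TIFF pages are row-major (y, x); this reader/writer transposes to the
#' package's XYZ array order.
#'
#' @param path TIFF file path.
#' @param spacing micrometres per axis `(sx, sy, sz)`; overrides any sidecar
#'   value when given.
#' @param origin physical position of the first voxel centre (um); default
#'   sidecar value or `(0,0,0)`.
#' @param kind one of `"auto"`, `"scalar"`, `"mask"`, `"label"`; `"auto"`
#'   takes the kind recorded in the sidecar (else scalar).
#' @return `read_volume`: a [voxel_grid()] / [binary_mask()] /
#'   [label_volume()]. `write_volume`: the path, invisibly.
#' @export
read_volume <- function(path, spacing = NULL, origin = NULL, kind = "auto") {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("not a single-channel 3D TIFF stack: ", path)
  meta <- read_sidecar(paste0(path, ".meta.json"))
  if (is.null(spacing)) spacing <- meta$spacing %||% c(1, 1, 1)
  if (is.null(origin)) origin <- meta$origin %||% c(0, 0, 0)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  if (identical(kind, "auto")) kind <- meta$kind %||% "scalar"
  nz <- length(pages)
  d <- dim(pages[[1]])                     # (ny, nx)
  arr <- array(0, c(d[2], d[1], nz))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  if (!is.null(meta$scale))
    arr <- arr * (meta$scale[2] - meta$scale[1]) + meta$scale[1]
  switch(kind,
    mask   = binary_mask(array(as.integer(round(arr)), dim(arr)), spacing, origin),
    label  = label_volume(array(as.integer(round(arr)), dim(arr)), spacing, origin),
    scalar = voxel_grid(arr, spacing, origin),
    stop("unknown kind: ", kind))
}

#' @rdname read_volume
#' @param grid the [voxel_grid()] to write.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- grid$data
  lo <- min(arr); hi <- max(arr)
  scaled <- if (hi > lo) (arr - lo) / (hi - lo) else array(0, dim(arr))
  kind <- if (inherits(grid, "binary_mask")) "mask"
          else if (inherits(grid, "label_volume")) "label" else "scalar"
  pages <- lapply(seq_len(dim(arr)[3]), function(k) t(scaled[, , k]))
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE))
  write_sidecar(paste0(path, ".meta.json"),
                list(kind = kind, scale = c(lo, hi),
                     spacing = grid$spacing, origin = grid$origin,
                     shape = dim(arr)))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal flat key -> numeric/string JSON sidecar (kept dependency-free so
# installed-package I/O does not need jsonlite)
write_sidecar <- function(path, fields) {
  enc <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (length(v) == 1) format(v, digits = 17)
    else sprintf("[%s]", paste(format(v, digits = 17), collapse = ", "))
  }
  txt <- paste0("{\n", paste(sprintf('  "%s": %s', names(fields),
                                     vapply(fields, enc, character(1))),
                             collapse = ",\n"), "\n}\n")
  writeLines(txt, path)
  invisible(path)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  out <- list()
  m <- gregexpr('"([a-zA-Z_]+)"\\s*:\\s*(\\[[^]]*\\]|"[^"]*"|[-0-9.eE+]+)', txt)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
    key <- sub('^"([a-zA-Z_]+)".*', "\\1", piece)
    val <- sub('^"[a-zA-Z_]+"\\s*:\\s*', "", piece)
    out[[key]] <- if (startsWith(val, '"')) gsub('"', "", val)
      else as.numeric(strsplit(gsub("[][]", "", val), ",")[[1]])
  }
  out
}
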