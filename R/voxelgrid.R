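#' Voxel grids with physical geometry
#'
#' A `voxel_grid` couples a 3D numeric array with its physical geometry:
#' per-axis spacing (micrometres) and the physical position of the *centre*
#' of the first voxel (`origin`, micrometres, XYZ). The array is stored in
#' XYZ index order (`dim = c(nx, ny, nz)`, x fastest) and all public
#' functions in the package speak physical micrometre coordinates; the
#' array layout is an internal detail fixed here once.
#'
#' The voxel-centre convention: the centre of voxel with 0-based index
#' `(i, j, k)` sits at `origin + c(i * sx, j * sy, k * sz)`. R arrays are
#' 1-based, so [index_to_phys()] subtracts 1.
#'
#' @param data 3D numeric array, XYZ order.
#' @param spacing numeric length-3, micrometres per voxel along x, y, z;
#'   all strictly positive.
#' @param origin numeric length-3, physical position (micrometres) of the
#'   centre of voxel `[1,1,1]`.
#' @return An object of class `voxel_grid` (a list with elements `data`,
#'   `spacing`, `origin`).
#' @examples
#' g <- voxel_grid(array(0, c(8, 8, 4)), spacing = c(1.2, 1.2, 4))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (micrometres)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (micrometres)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  g <- voxel_grid(data, spacing, origin)
  vals <- unique(as.vector(g$data))
  if (!all(vals %in% c(0, 1)))
    stop("binary mask data must contain only 0 and 1")
  storage.mode(g$data) <- "integer"
  class(g) <- c("binary_mask", "voxel_grid")
  g
}

#' @rdname voxel_grid
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  g <- voxel_grid(data, spacing, origin)
  if (any(g$data < 0) || any(g$data != round(g$data)))
    stop("label volume data must be nonnegative integers (0 = background)")
  storage.mode(g$data) <- "integer"
  class(g) <- c("label_volume", "voxel_grid")
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%g, %g, %g) um, origin (%g, %g, %g) um\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Convert between voxel indices and physical coordinates
#'
#' The single place where the voxel-centre convention lives: the physical
#' coordinate of 1-based array index `(i, j, k)` is
#' `origin + (i-1, j-1, k-1) * spacing`. `phys_to_index` is its exact
#' inverse (real-valued; round to get the nearest voxel).
#'
#' @param grid a [voxel_grid()] (or anything with `spacing` and `origin`).
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param xyz n x 3 matrix (or length-3 vector) of physical coordinates, um.
#' @return n x 3 numeric matrix.
#' @export
index_to_phys <- function(grid, ijk) {
  ijk <- rbind3(ijk)
  sweep(sweep(ijk - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' @rdname index_to_phys
#' @export
phys_to_index <- function(grid, xyz) {
  xyz <- rbind3(xyz)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

# coerce vector or matrix to an n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L)
  else {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 3L)
    storage.mode(x) <- "double"
    x
  }
}

# physical coordinates of every voxel with value > 0 (n x 3, um)
mask_voxel_coords <- function(grid) {
  idx <- which(grid$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3L))
  index_to_phys(grid, idx)
}

#' Label 26-connected components of a binary mask
#'
#' Flood-fill labelling of the foreground under 26-connectivity.
#'
#' @param mask a [binary_mask()] (or voxel_grid with 0/1 data).
#' @return a [label_volume()] with components numbered 1..n in first-voxel
#'   order; attribute `n_components` holds n.
#' @export
label_components <- function(mask) {
  lab <- label_components_cpp(array(as.integer(mask$data != 0), dim(mask$data)))
  out <- label_volume(lab, mask$spacing, mask$origin)
  attr(out, "n_components") <- max(0L, max(lab))
  out
}
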