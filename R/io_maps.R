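#' Export 2D map slices as PNG images
#'
#' Scalar maps are min-max scaled to 8-bit grayscale, with the scaling
#' recorded in a plain-text sidecar (`<path>.scale.txt`: `min`, `max`,
#' slice and axis) so values can be recovered from pixel intensities;
#' RGB (DEC) maps are written as 8-bit color, channel = |component|.
#' NaN/invalid centres render black.
#'
#' @param map a [scalar_map()] or [rgb_map()].
#' @param path output `.png` path.
#' @param slice 1-based slice index along `axis`; required when the map's
#'   grid has more than one slice in that axis.
#' @param axis slicing axis (1 = x, 2 = y, 3 = z).
#' @return the path, invisibly.
#' @export
export_map <- function(map, path, slice = NULL, axis = 3L) {
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  pick_slice <- function(arr3, k) {
    switch(axis, arr3[k, , ], arr3[, k, ], arr3[, , k])
  }
  if (inherits(map, "scalar_map")) {
    nd <- dim(map$values)
    slice <- slice %||% if (nd[axis] == 1L) 1L else
      stop("`slice` is required for a multi-slice map")
    sl <- pick_slice(map$values, slice)
    if (all(!is.finite(sl))) stop("slice is entirely NaN")
    lo <- min(sl[is.finite(sl)]); hi <- max(sl[is.finite(sl)])
    img <- (sl - lo) / max(hi - lo, .Machine$double.eps)
    img[!is.finite(img)] <- 0
    img <- pmin(1, pmax(0, img))
    png::writePNG(t(img), path)
    writeLines(c(sprintf("min %.17g", lo), sprintf("max %.17g", hi),
                 sprintf("slice %d", slice), sprintf("axis %d", axis),
                 sprintf("what %s", map$what)),
               paste0(path, ".scale.txt"))
  } else if (inherits(map, "rgb_map")) {
    nd <- dim(map$rgb)[-1]
    slice <- slice %||% if (nd[axis] == 1L) 1L else
      stop("`slice` is required for a multi-slice map")
    chans <- lapply(1:3, function(ch) {
      sl <- pick_slice(array(map$rgb[ch, , , ], nd), slice)
      sl[!is.finite(sl)] <- 0
      t(pmin(1, pmax(0, sl)))
    })
    img <- array(0, c(dim(chans[[1]]), 3))
    for (ch in 1:3) img[, , ch] <- chans[[ch]]
    png::writePNG(img, path)
  } else stop("`map` must be a scalar_map or rgb_map")
  invisible(path)
}

# unit UV-sphere triangulation: list(vertices nx3, triangles mx3, 1-based)
unit_sphere_mesh <- function(n_theta = 8L, n_phi = 12L) {
  th <- seq(0, pi, length.out = n_theta + 1L)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  verts <- rbind(c(0, 0, 1))
  for (i in 2:n_theta)
    verts <- rbind(verts, cbind(sin(th[i]) * cos(ph), sin(th[i]) * sin(ph),
                                cos(th[i])))
  verts <- rbind(verts, c(0, 0, -1))
  ring <- function(i) 1L + (i - 2L) * n_phi + seq_len(n_phi)  # i in 2..n_theta
  tris <- list()
  r1 <- ring(2)
  for (j in seq_len(n_phi))
    tris[[length(tris) + 1L]] <- c(1L, r1[j], r1[j %% n_phi + 1L])
  if (n_theta > 2) for (i in 2:(n_theta - 1L)) {
    ra <- ring(i); rb <- ring(i + 1L)
    for (j in seq_len(n_phi)) {
      jn <- j %% n_phi + 1L
      tris[[length(tris) + 1L]] <- c(ra[j], rb[j], rb[jn])
      tris[[length(tris) + 1L]] <- c(ra[j], rb[jn], ra[jn])
    }
  }
  last <- nrow(verts)
  rl <- ring(n_theta)
  for (j in seq_len(n_phi))
    tris[[length(tris) + 1L]] <- c(last, rl[j %% n_phi + 1L], rl[j])
  list(vertices = verts, triangles = do.call(rbind, tris))
}

#' Export tensor glyphs as VTK polydata
#'
#' One ellipsoid surface per valid tensor-field centre: radii
#' `scale * sqrt(lambda_i)` along the eigenvectors `v_i` (the square roots
#' of the eigenvalues are the standard-deviation ellipsoid radii), colored
#' by the DEC of the principal eigenvector. Written as legacy ASCII VTK
#' polydata, loadable in ParaView. Centres with no descriptors are
#' skipped; a field with no valid centre yields a valid empty polydata.
#'
#' @param eigen an `eigen_field`.
#' @param path output `.vtk` path.
#' @param scale um of glyph radius per unit sqrt-eigenvalue; must be
#'   positive.
#' @param mesh_res angular resolution (rings) of each ellipsoid surface.
#' @return the path, invisibly.
#' @export
export_glyphs <- function(eigen, path, scale = 5, mesh_res = 8L) {
  stopifnot(inherits(eigen, "eigen_field"))
  if (scale <= 0) stop("`scale` must be positive")
  mesh <- unit_sphere_mesh(mesh_res, max(6L, mesh_res + 4L))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  ctr <- centre_coords(eigen)
  vecsf <- matrix(eigen$vectors, nrow = 9)
  valsf <- matrix(eigen$values, nrow = 3)
  ok <- which(as.vector(eigen$valid))
  pts <- vector("list", length(ok)); cols <- vector("list", length(ok))
  for (q in seq_along(ok)) {
    i <- ok[q]
    V <- matrix(vecsf[, i], 3, 3)
    radii <- scale * sqrt(pmax(0, valsf[, i]))
    xform <- V %*% diag(radii)
    pts[[q]] <- mesh$vertices %*% t(xform) +
      matrix(ctr[i, ], nv, 3, byrow = TRUE)
    cols[[q]] <- abs(V[, 1])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "standard-deviation ellipsoid glyphs",
               "ASCII", "DATASET POLYDATA"), con)
  npts <- length(ok) * nv
  writeLines(sprintf("POINTS %d float", npts), con)
  if (npts > 0) {
    allp <- do.call(rbind, pts)
    writeLines(sprintf("%.6g %.6g %.6g", allp[, 1], allp[, 2], allp[, 3]), con)
  }
  ntri <- length(ok) * nt
  writeLines(sprintf("POLYGONS %d %d", ntri, 4L * ntri), con)
  if (ntri > 0) {
    for (q in seq_along(ok)) {
      t0 <- mesh$triangles + (q - 1L) * nv - 1L   # 0-based
      writeLines(sprintf("3 %d %d %d", t0[, 1], t0[, 2], t0[, 3]), con)
    }
  }
  writeLines(sprintf("POINT_DATA %d", npts), con)
  writeLines("COLOR_SCALARS dec 3", con)
  if (npts > 0) {
    for (q in seq_along(ok)) {
      cl <- cols[[q]]
      writeLines(rep(sprintf("%.4f %.4f %.4f", cl[1], cl[2], cl[3]), nv), con)
    }
  }
  invisible(path)
}
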