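#' Oriented feature descriptor sets
#'
#' A descriptor is an oriented, midpoint-anchored vector summarising one
#' local structure: for the vasculature, the straight chord between two
#' adjacent skeleton-graph nodes; for cell populations, a cell's principal
#' ellipsoid axis. Descriptors are *axial* (sign-ambiguous): `v` and `-v`
#' describe the same structure, which every downstream consumer respects.
#'
#' @param df data frame with columns `mx, my, mz` (midpoint, um),
#'   `vx, vy, vz` (vector, um) and `source_id`.
#' @param kind `"vascular"` or `"cellular"`.
#' @return `descriptor_set`: the validated data frame with attributes
#'   `kind` and `bbox` (2 x 3 midpoint bounding box).
#' @export
descriptor_set <- function(df, kind = c("vascular", "cellular")) {
  kind <- match.arg(kind)
  need <- c("mx", "my", "mz", "vx", "vy", "vz", "source_id")
  if (!all(need %in% names(df))) stop("descriptor data frame needs columns: ",
                                      paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (nrow(df)) {
    num <- as.matrix(df[, 1:6])
    if (any(!is.finite(num))) stop("descriptors must be finite")
    if (any(sqrt(df$vx^2 + df$vy^2 + df$vz^2) <= 0))
      stop("descriptor vectors must have positive norm")
  }
  bbox <- if (nrow(df)) rbind(lo = c(min(df$mx), min(df$my), min(df$mz)),
                              hi = c(max(df$mx), max(df$my), max(df$mz)))
          else rbind(lo = c(0, 0, 0), hi = c(0, 0, 0))
  structure(df, kind = kind, bbox = bbox,
            class = c("descriptor_set", "data.frame"))
}

descriptor_midpoints <- function(d) unname(as.matrix(as.data.frame(d)[, c("mx", "my", "mz")]))
descriptor_vectors <- function(d) unname(as.matrix(as.data.frame(d)[, c("vx", "vy", "vz")]))

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d %s descriptors\n", nrow(x), attr(x, "kind")))
  invisible(x)
}

#' Vascular segment descriptors from a skeleton graph
#'
#' One descriptor per graph edge: the vector is the straight chord from one
#' node position to the other, the midpoint their average. The chord (not
#' the curved slab path) is the segment notion used throughout: segments
#' connect adjacent nodes. Long tortuous edges can optionally be subdivided
#' at their slab path so no chord exceeds `subdivide_um`.
#'
#' @param graph a [skeleton_graph()].
#' @param subdivide_um if finite, edges whose slab path is longer than this
#'   are split into consecutive chords over the voxel path.
#' @return a vascular [descriptor_set()]. Zero-length chords (coincident
#'   node positions) are dropped; their count is reported via a message and
#'   the `n_dropped` attribute.
#' @export
segments_from_graph <- function(graph, subdivide_um = Inf) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nodes <- graph$nodes; edges <- graph$edges
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    p1 <- unlist(nodes[nodes$id == edges$from[i], c("x", "y", "z")])
    p2 <- unlist(nodes[nodes$id == edges$to[i], c("x", "y", "z")])
    pts <- rbind(p1, p2)
    if (is.finite(subdivide_um) && edges$length_um[i] > subdivide_um &&
        length(graph$paths[[i]]) > 0) {
      path <- graph$paths[[i]]
      nseg <- max(1L, ceiling(edges$length_um[i] / subdivide_um))
      cuts <- round(seq(0, nrow(path), length.out = nseg + 1L))[-c(1, nseg + 1L)]
      pts <- rbind(p1, path[unique(cuts[cuts >= 1]), , drop = FALSE], p2)
    }
    for (k in seq_len(nrow(pts) - 1L)) {
      a <- pts[k, ]; b <- pts[k + 1L, ]
      rows[[length(rows) + 1L]] <-
        c((a + b) / 2, b - a, i)
    }
  }
  if (!length(rows)) {
    return(descriptor_set(data.frame(mx = numeric(0), my = numeric(0), mz = numeric(0),
                                     vx = numeric(0), vy = numeric(0), vz = numeric(0),
                                     source_id = numeric(0)), kind = "vascular"))
  }
  m <- do.call(rbind, rows)
  df <- data.frame(mx = m[, 1], my = m[, 2], mz = m[, 3],
                   vx = m[, 4], vy = m[, 5], vz = m[, 6], source_id = m[, 7])
  norm <- sqrt(df$vx^2 + df$vy^2 + df$vz^2)
  n_dropped <- sum(norm <= 0)
  if (n_dropped > 0) {
    message(n_dropped, " zero-length chord(s) dropped")
    df <- df[norm > 0, , drop = FALSE]
  }
  out <- descriptor_set(df, kind = "vascular")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Cell orientation descriptors from a label volume
#'
#' Per label: the 3x3 second central moment matrix of the voxel centre
#' coordinates (physical um) is eigen-decomposed; the descriptor vector is
#' the principal eigenvector scaled by `2 * sqrt(5 * lambda_1)` — for a
#' solid ellipsoid the variance along a semi-axis `a` is `a^2 / 5`, so this
#' scaling makes the descriptor magnitude the cell's long diameter. The
#' midpoint is the cell centroid. Cells whose moment matrix is nearly
#' isotropic, `(lambda_1 - lambda_2)/lambda_1 < degenerate_tol`, have no
#' meaningful axis (spheres) and are excluded from the returned set but
#' counted in the `n_degenerate` attribute; labels smaller than
#' `min_voxels` are skipped (`n_too_small` attribute).
#'
#' @param labels a [label_volume()].
#' @param min_voxels smallest label size (voxels) given a descriptor.
#' @param degenerate_tol relative eigenvalue gap below which a cell is
#'   treated as orientation-degenerate.
#' @return a cellular [descriptor_set()].
#' @export
cell_axes_from_labels <- function(labels, min_voxels = 10L, degenerate_tol = 0.05) {
  stopifnot(inherits(labels, "label_volume"))
  fg <- which(labels$data > 0L)
  if (!length(fg)) stop("label volume has no nonzero labels")
  by_label <- split(fg, labels$data[fg])
  rows <- list(); n_degen <- 0L; n_small <- 0L
  for (id_chr in names(by_label)) {
    id <- as.integer(id_chr)
    lin <- by_label[[id_chr]]
    if (length(lin) < min_voxels) { n_small <- n_small + 1L; next }
    xyz <- index_to_phys(labels, arrayInd(lin, dim(labels$data)))
    ctr <- colMeans(xyz)
    cc <- sweep(xyz, 2, ctr)
    mom <- crossprod(cc) / nrow(cc)          # population second central moments
    e <- eigen(mom, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    if (lam[1] <= 0 || (lam[1] - lam[2]) / lam[1] < degenerate_tol) {
      n_degen <- n_degen + 1L; next
    }
    v1 <- e$vectors[, 1]
    k <- which.max(abs(v1)); if (v1[k] < 0) v1 <- -v1
    rows[[length(rows) + 1L]] <- c(ctr, v1 * 2 * sqrt(5 * lam[1]), id)
  }
  if (!length(rows)) stop("no label passed the size/degeneracy filters")
  m <- do.call(rbind, rows)
  out <- descriptor_set(data.frame(mx = m[, 1], my = m[, 2], mz = m[, 3],
                                   vx = m[, 4], vy = m[, 5], vz = m[, 6],
                                   source_id = m[, 7]), kind = "cellular")
  attr(out, "n_degenerate") <- n_degen
  attr(out, "n_too_small") <- n_small
  out
}

#' Read/write descriptor sets as CSV
#'
#' Columns `mx, my, mz, vx, vy, vz, source_id, kind` (um).
#'
#' @param d a [descriptor_set()].
#' @param path CSV file path.
#' @return `write_descriptors`: the path, invisibly; `read_descriptors`:
#'   a [descriptor_set()].
#' @export
write_descriptors <- function(d, path) {
  df <- as.data.frame(d)
  df$kind <- attr(d, "kind")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- read.csv(path)
  kind <- if ("kind" %in% names(df) && nrow(df)) df$kind[1] else "vascular"
  descriptor_set(df[setdiff(names(df), "kind")], kind = kind)
}
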