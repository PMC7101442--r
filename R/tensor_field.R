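#' Sliding-window variance-covariance tensor fields
#'
#' The central construction of the package: within each cubic sampling
#' window, every feature descriptor contributes its two endpoints
#' `midpoint +/- vector/2` re-centred on the window's pooled cloud (which by
#' the +/- construction has mean exactly zero), and the 3x3
#' variance-covariance matrix of that endpoint cloud becomes one voxel of a
#' tensor image. Windows slide on a regular grid of centres with spacing
#' `stride`; the window edge `window` may (and for smooth fields should)
#' exceed the stride so neighbouring windows overlap.
#'
#' A `tensor_field` stores, per window centre, the six upper-triangular
#' tensor components (order xx, xy, xz, yy, yz, zz, in um^2) and the
#' descriptor count N. Centres with `N < min_count` are flagged invalid:
#' a single segment defines a rank-1 matrix whose "dispersion" is not
#' statistically meaningful, and counts weight the field's significance.
#'
#' @param cm numeric array `c(6, n1, n2, n3)` of upper-triangular components,
#'   or `c(3, 3, n1, n2, n3)` of full symmetric matrices (validated
#'   symmetric, tolerance 1e-9, then packed).
#' @param count integer array `c(n1, n2, n3)` of descriptor counts.
#' @param origin physical position (um) of the first window centre.
#' @param stride centre-to-centre spacing, um.
#' @param window cubic window edge length, um.
#' @param min_count minimum N for a centre to be valid.
#' @return object of class `tensor_field` with elements `cm`, `count`,
#'   `valid`, `origin`, `stride`, `window`, `min_count`.
#' @export
tensor_field <- function(cm, count, origin, stride, window, min_count = 2L) {
  if (length(dim(cm)) == 5L) {
    stopifnot(dim(cm)[1] == 3L, dim(cm)[2] == 3L)
    nd <- dim(cm)[3:5]
    asym <- max(abs(cm[1, 2, , , ] - cm[2, 1, , , ]),
                abs(cm[1, 3, , , ] - cm[3, 1, , , ]),
                abs(cm[2, 3, , , ] - cm[3, 2, , , ]))
    if (is.finite(asym) && asym > 1e-9)
      stop("tensor matrices are not symmetric (max asymmetry ", format(asym), ")")
    packed <- array(0, c(6, nd))
    packed[1, , , ] <- cm[1, 1, , , ]; packed[2, , , ] <- cm[1, 2, , , ]
    packed[3, , , ] <- cm[1, 3, , , ]; packed[4, , , ] <- cm[2, 2, , , ]
    packed[5, , , ] <- cm[2, 3, , , ]; packed[6, , , ] <- cm[3, 3, , , ]
    cm <- packed
  }
  stopifnot(length(dim(cm)) == 4L, dim(cm)[1] == 6L)
  nd <- dim(cm)[2:4]
  count <- array(as.integer(count), nd)
  stopifnot(all(count >= 0L), stride > 0, window >= stride)
  structure(list(cm = cm, count = count,
                 valid = array(count >= min_count, nd),
                 origin = as.numeric(origin), stride = as.numeric(stride),
                 window = as.numeric(window), min_count = as.integer(min_count)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  nd <- dim(x$count)
  cat(sprintf("<tensor_field> %d x %d x %d centres, window %g um, stride %g um, %d valid (min N = %d)\n",
              nd[1], nd[2], nd[3], x$window, x$stride, sum(x$valid), x$min_count))
  invisible(x)
}

#' Compute the sliding-window covariance tensor field of a descriptor set
#'
#' For every window centre `c`, the descriptors whose *midpoints* fall in
#' the axis-aligned cube of edge `window` centred at `c` (half-open on the
#' high side, so a midpoint on the boundary belongs to exactly one window
#' along each axis) are pooled; their `2N` endpoints `+/- vector/2` form a
#' zero-mean cloud whose population covariance
#' `CM = (1/(2N)) * sum(p %*% t(p))` is the window's tensor. Membership is
#' decided by the midpoint alone, so a long segment spanning a window
#' boundary is never double-counted.
#'
#' @param descriptors a [descriptor_set()].
#' @param window cubic window edge, um (default 90, a mesoscale typical of
#'   DTI-sized voxels).
#' @param stride window-centre spacing, um (default 20).
#' @param min_count minimum descriptors per window for validity (default 2).
#' @param origin,dims optional centre-grid origin (um) and integer triple of
#'   grid sizes; by default the grid spans the descriptor bounding box.
#' @param sample_covariance if `TRUE` divide by `2N - 1` instead of `2N`.
#' @return a [tensor_field()].
#' @examples
#' d <- descriptor_set(data.frame(mx = 1, my = 1, mz = 1,
#'                                vx = 2, vy = 0, vz = 0, source_id = 1))
#' f <- compute_tensor_field(d, window = 10, stride = 10, min_count = 1)
#' matrix(f$cm[c(1, 2, 3, 2, 4, 5, 3, 5, 6), 1, 1, 1], 3, 3)  # diag(1, 0, 0)
#' @export
compute_tensor_field <- function(descriptors, window = 90, stride = 20,
                                 min_count = 2L, origin = NULL, dims = NULL,
                                 sample_covariance = FALSE) {
  stopifnot(window >= stride, stride > 0)
  m <- descriptor_midpoints(descriptors)
  v <- descriptor_vectors(descriptors)
  n <- nrow(m)
  if (is.null(origin) || is.null(dims)) {
    if (n == 0L) {
      origin <- c(0, 0, 0); dims <- c(1L, 1L, 1L)
    } else {
      lo <- apply(m, 2, min); hi <- apply(m, 2, max)
      origin <- lo
      dims <- pmax(1L, as.integer(floor((hi - lo) / stride + 1e-9)) + 1L)
    }
  }
  dims <- as.integer(dims)
  acc <- array(0, c(6, dims))
  cnt <- array(0L, dims)
  if (n > 0L) {
    half <- window / 2
    # centre k (1-based) lies at origin + (k-1)*stride; midpoint x belongs to
    # centre iff c - W/2 <= x < c + W/2, i.e. c in (x - W/2, x + W/2]
    klo <- khi <- matrix(0L, n, 3)
    for (ax in 1:3) {
      a <- (m[, ax] - origin[ax] - half) / stride
      b <- (m[, ax] - origin[ax] + half) / stride
      klo[, ax] <- pmax(1L, as.integer(floor(a)) + 2L)
      khi[, ax] <- pmin(dims[ax], as.integer(floor(b)) + 1L)
    }
    ut <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
    for (i in seq_len(n)) {
      if (any(klo[i, ] > khi[i, ])) next
      vi <- v[i, ]
      outer6 <- vi[ut[, 1]] * vi[ut[, 2]]
      ks <- seq.int(klo[i, 1], khi[i, 1])
      js <- seq.int(klo[i, 2], khi[i, 2])
      ls <- seq.int(klo[i, 3], khi[i, 3])
      for (l in ls) for (j in js) {
        acc[, ks, j, l] <- acc[, ks, j, l] + outer6
        cnt[ks, j, l] <- cnt[ks, j, l] + 1L
      }
    }
  }
  cm <- array(0, c(6, dims))
  pos <- which(cnt > 0L)
  if (length(pos)) {
    denom <- if (sample_covariance) pmax(1, 2 * cnt[pos] - 1) * 2 else 4 * cnt[pos]
    # endpoints are +/- v/2: sum over 2N points of p p^T equals sum(v v^T)/2
    for (q in 1:6) {
      plane <- acc[q, , , ][pos]
      tmp <- array(0, dims); tmp[pos] <- plane / denom
      cm[q, , , ] <- tmp
    }
  }
  tensor_field(cm, cnt, origin = origin, stride = stride, window = window,
               min_count = min_count)
}

# 3x3 symmetric matrix from the packed 6-vector
unpack_tensor <- function(six) {
  matrix(six[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
}

#' Eigen-decompose a tensor field
#'
#' Per valid centre, the symmetric eigen-system of CM: eigenvalues sorted
#' descending (um^2, negatives within -1e-9 clamped to zero), orthonormal
#' eigenvectors sign-normalised so each vector's largest-magnitude component
#' is nonnegative (eigenvectors of a covariance are axial; the convention
#' makes output deterministic).
#'
#' @param field a [tensor_field()].
#' @return object of class `eigen_field`: `values` array `c(3, dims)`,
#'   `vectors` array `c(3, 3, dims)` (column i of each 3x3 block = v_i),
#'   plus `valid`, `origin`, `stride`, `window`, `count`.
#' @export
eigendecompose <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  nd <- dim(field$count)
  M <- prod(nd)
  valsf <- matrix(NA_real_, 3, M)
  vecsf <- matrix(NA_real_, 9, M)
  valid <- field$valid
  idx <- which(valid)
  cmflat <- matrix(field$cm, nrow = 6)
  for (i in idx) {
    six <- cmflat[, i]
    if (any(!is.finite(six))) { valid[i] <- FALSE; next }
    e <- eigen(unpack_tensor(six), symmetric = TRUE)
    lam <- e$values
    lam[lam < 0 & lam > -1e-9] <- 0
    V <- e$vectors
    for (j in 1:3) {
      k <- which.max(abs(V[, j]))
      if (V[k, j] < 0) V[, j] <- -V[, j]
    }
    valsf[, i] <- lam
    vecsf[, i] <- as.vector(V)
  }
  structure(list(values = array(valsf, c(3, nd)),
                 vectors = array(vecsf, c(3, 3, nd)), valid = valid,
                 origin = field$origin, stride = field$stride,
                 window = field$window, count = field$count),
            class = "eigen_field")
}

#' @export
print.eigen_field <- function(x, ...) {
  nd <- dim(x$count)
  cat(sprintf("<eigen_field> %d x %d x %d centres, %d valid\n",
              nd[1], nd[2], nd[3], sum(x$valid)))
  invisible(x)
}

#' Extract one eigenvector as a vector map
#'
#' @param eigen an `eigen_field` from [eigendecompose()].
#' @param index which eigenvector (1 = principal, 2, 3).
#' @param scale_by_sqrt_lambda if `TRUE`, scale each unit vector by
#'   `sqrt(lambda_index)` so magnitude encodes spread (um).
#' @return object of class `vector_map`: array `c(3, dims)` in `$vec`
#'   (zero vectors at invalid centres), with `origin`, `stride`, `valid`.
#' @export
principal_vector_field <- function(eigen, index = 1L, scale_by_sqrt_lambda = FALSE) {
  stopifnot(inherits(eigen, "eigen_field"))
  index <- as.integer(index)
  if (!index %in% 1:3) stop("`index` must be 1, 2 or 3")
  nd <- dim(eigen$count)
  vecsf <- matrix(eigen$vectors, nrow = 9)
  valsf <- matrix(eigen$values, nrow = 3)
  rows <- (3L * (index - 1L) + 1L):(3L * index)
  outf <- matrix(0, 3, prod(nd))
  for (i in which(eigen$valid)) {
    vv <- vecsf[rows, i]
    if (scale_by_sqrt_lambda) vv <- vv * sqrt(max(0, valsf[index, i]))
    outf[, i] <- vv
  }
  structure(list(vec = array(outf, c(3, nd)), origin = eigen$origin,
                 stride = eigen$stride,
                 valid = eigen$valid),
            class = "vector_map")
}

# physical coordinates of the window-centre grid (list of per-axis vectors)
centre_axes <- function(field) {
  nd <- dim(field$count)
  lapply(1:3, function(ax) field$origin[ax] + (seq_len(nd[ax]) - 1) * field$stride)
}

# n x 3 matrix of all centre coordinates, in array order
centre_coords <- function(field) {
  nd <- dim(field$count)
  ax <- centre_axes(field)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}
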