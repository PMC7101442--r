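# Independent oracles and fixture builders shared across the test files.

# Naive per-window double loop: literally builds each window's 2N-point
# +/- endpoint cloud and takes its population covariance. Kept deliberately
# independent of compute_tensor_field's accumulation path.
naive_tensor_field <- function(d, window, stride, min_count, origin, dims) {
  m <- as.matrix(as.data.frame(d)[, c("mx", "my", "mz")])
  v <- as.matrix(as.data.frame(d)[, c("vx", "vy", "vz")])
  cm <- array(0, c(6, dims)); cnt <- array(0L, dims)
  for (k3 in seq_len(dims[3])) for (k2 in seq_len(dims[2])) for (k1 in seq_len(dims[1])) {
    ctr <- origin + (c(k1, k2, k3) - 1) * stride
    pts <- matrix(0, 0, 3); n <- 0L
    for (i in seq_len(nrow(m))) {
      if (all(m[i, ] >= ctr - window / 2) && all(m[i, ] < ctr + window / 2)) {
        pts <- rbind(pts, v[i, ] / 2, -v[i, ] / 2)
        n <- n + 1L
      }
    }
    if (n > 0) {
      C <- crossprod(pts) / (2 * n)
      cm[, k1, k2, k3] <- C[c(1, 2, 3, 5, 6, 9)]
    }
    cnt[k1, k2, k3] <- n
  }
  tensor_field(cm, cnt, origin, stride, window, min_count)
}

random_descriptor_set <- function(n, box = 100, vsd = 2) {
  descriptor_set(data.frame(
    mx = runif(n, 0, box), my = runif(n, 0, box), mz = runif(n, 0, box),
    vx = rnorm(n, 0, vsd), vy = rnorm(n, 0, vsd), vz = rnorm(n, 0, vsd),
    source_id = seq_len(n)))
}

# tube phantoms with known topology; branch angles chosen at 0/45/90 deg so
# the discrete medial axis tracks the continuous centreline closely
straight_tube_phantom <- function() {
  segs <- matrix(c(5, 10, 10, 55, 10, 10), 1, 6)
  list(segs = segs, shape = c(60, 20, 20),
       n_endpoints = 2L, n_junctions = 0L, n_edges = 1L,
       lengths = 50)
}

y_tube_phantom <- function() {
  J <- c(50, 40, 12)
  segs <- rbind(c(J, 50, 8, 12), c(J, 18, 72, 12), c(J, 82, 72, 12))
  list(segs = segs, shape = c(100, 100, 24),
       n_endpoints = 3L, n_junctions = 1L, n_edges = 3L,
       lengths = apply(segs, 1, function(s) sqrt(sum((s[4:6] - s[1:3])^2))))
}

h_tube_phantom <- function() {
  a <- c(10, 35, 10); b <- c(50, 35, 10)
  segs <- rbind(c(a, 10, 10, 10), c(a, 10, 60, 10),
                c(b, 50, 10, 10), c(b, 50, 60, 10), c(a, b))
  list(segs = segs, shape = c(60, 70, 20),
       n_endpoints = 4L, n_junctions = 2L, n_edges = 5L,
       lengths = apply(segs, 1, function(s) sqrt(sum((s[4:6] - s[1:3])^2))))
}

recover_tube_graph <- function(ph, radius = 3) {
  mask <- rasterize_tubes(ph$segs, radius, ph$shape)
  build_graph(skeletonize(mask), prune_below = 5)
}

# axial (sign-free) angle between unit vectors, degrees
axial_angle_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}

# a single-window eigen field with prescribed eigenvalues along the axes
diag_eigen_field <- function(lam, dims = c(1L, 1L, 1L), stride = 10) {
  cm <- array(0, c(6, dims))
  cm[1, , , ] <- lam[1]; cm[4, , , ] <- lam[2]; cm[6, , , ] <- lam[3]
  eigendecompose(tensor_field(cm, array(5L, dims), origin = c(0, 0, 0),
                              stride = stride, window = stride, min_count = 2L))
}
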