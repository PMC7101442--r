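test_that("single windows match hand-computed covariance", {
  # one descriptor with vector (2, 0, 0): endpoints +/-(1, 0, 0), so
  # CM = (1/2) (p p^T + (-p)(-p)^T) = diag(1, 0, 0) and N = 1
  d <- descriptor_set(data.frame(mx = 5, my = 5, mz = 5, vx = 2, vy = 0,
                                 vz = 0, source_id = 1))
  f <- compute_tensor_field(d, window = 10, stride = 10, min_count = 1)
  expect_equal(as.vector(f$cm[, 1, 1, 1]), c(1, 0, 0, 0, 0, 0))
  expect_equal(f$count[1, 1, 1], 1L)
  # two equal-length orthogonal descriptors -> diag(0.5, 0.5, 0), l1 = l2
  d2 <- descriptor_set(data.frame(mx = c(5, 5), my = c(5, 5), mz = c(5, 5),
                                  vx = c(2, 0), vy = c(0, 2), vz = c(0, 0),
                                  source_id = 1:2))
  f2 <- compute_tensor_field(d2, 10, 10, 2)
  expect_equal(as.vector(f2$cm[, 1, 1, 1]), c(0.5, 0, 0, 0.5, 0, 0))
  e2 <- eigendecompose(f2)
  expect_equal(e2$values[1, 1, 1, 1], e2$values[2, 1, 1, 1])
  # empty descriptor set -> all-invalid field, no error
  d0 <- descriptor_set(data.frame(mx = numeric(0), my = numeric(0),
                                  mz = numeric(0), vx = numeric(0),
                                  vy = numeric(0), vz = numeric(0),
                                  source_id = numeric(0)))
  f0 <- compute_tensor_field(d0, 10, 10, 2)
  expect_false(any(f0$valid))
  # a window with no descriptors is invalid with N = 0
  dfar <- descriptor_set(data.frame(mx = 0, my = 0, mz = 0, vx = 1, vy = 0,
                                    vz = 0, source_id = 1))
  ffar <- compute_tensor_field(dfar, 10, 10, 1, origin = c(0, 0, 0),
                               dims = c(4, 1, 1))
  expect_equal(ffar$count[4, 1, 1], 0L)
  expect_false(ffar$valid[4, 1, 1])
})

test_that("the sliding-window accumulation equals the naive double loop", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:400, 1)
    d <- random_descriptor_set(n)
    f <- compute_tensor_field(d, 40, 15, 2)
    nf <- naive_tensor_field(d, 40, 15, 2, f$origin, dim(f$count))
    expect_identical(f$count, nf$count)
    expect_lt(max(abs(f$cm - nf$cm)), 1e-12)
  }
})

test_that("rotating descriptors conjugates the pooled tensor", {
  set.seed(7)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  n <- 300
  m <- matrix(runif(3 * n, 0, 100), n, 3)
  v <- matrix(rnorm(3 * n), n, 3)
  mk <- function(m, v) descriptor_set(data.frame(
    mx = m[, 1], my = m[, 2], mz = m[, 3],
    vx = v[, 1], vy = v[, 2], vz = v[, 3], source_id = seq_len(nrow(m))))
  f1 <- compute_tensor_field(mk(m, v), 200, 200, 1,
                             origin = c(50, 50, 50), dims = c(1, 1, 1))
  f2 <- compute_tensor_field(mk(m %*% t(R), v %*% t(R)), 200, 200, 1,
                             origin = as.vector(c(50, 50, 50) %*% t(R)),
                             dims = c(1, 1, 1))
  C1 <- matrix(f1$cm[c(1, 2, 3, 2, 4, 5, 3, 5, 6), 1, 1, 1], 3, 3)
  C2 <- matrix(f2$cm[c(1, 2, 3, 2, 4, 5, 3, 5, 6), 1, 1, 1], 3, 3)
  expect_lt(max(abs(R %*% C1 %*% t(R) - C2)), 1e-9)
  # eigenvalues invariant, principal axis rotates (axial comparison)
  e1 <- eigendecompose(f1); e2 <- eigendecompose(f2)
  expect_equal(e1$values, e2$values, tolerance = 1e-9)
  expect_lt(axial_angle_deg(as.vector(R %*% e1$vectors[, 1, 1, 1, 1]),
                            e2$vectors[, 1, 1, 1, 1]), 1e-5)
})

test_that("eigendecomposition sorts, orthonormalizes and sign-normalizes", {
  e <- diag_eigen_field(c(3, 2, 1))
  expect_equal(as.vector(e$values[, 1, 1, 1]), c(3, 2, 1))
  expect_equal(e$vectors[, 1, 1, 1, 1], c(1, 0, 0))
  # conjugation by a random rotation preserves eigenvalues, rotates v1
  set.seed(5)
  A <- matrix(rnorm(9), 3, 3); R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  C <- R %*% diag(c(3, 2, 1)) %*% t(R)
  cm <- array(0, c(6, 1, 1, 1)); cm[, 1, 1, 1] <- C[c(1, 4, 7, 5, 8, 9)]
  er <- eigendecompose(tensor_field(cm, array(2L, c(1, 1, 1)), c(0, 0, 0), 1, 1))
  expect_equal(as.vector(er$values[, 1, 1, 1]), c(3, 2, 1), tolerance = 1e-9)
  expect_lt(axial_angle_deg(er$vectors[, 1, 1, 1, 1], as.vector(R[, 1])), 1e-6)
  V <- matrix(er$vectors[, , 1, 1, 1], 3, 3)
  expect_lt(max(abs(crossprod(V) - diag(3))), 1e-9)
  # identity tensor: eigenvalues all 1, any orthonormal triad accepted
  ei <- diag_eigen_field(c(1, 1, 1))
  expect_equal(as.vector(ei$values[, 1, 1, 1]), c(1, 1, 1))
  Vi <- matrix(ei$vectors[, , 1, 1, 1], 3, 3)
  expect_lt(max(abs(crossprod(Vi) - diag(3))), 1e-9)
  # sign convention: largest-magnitude component nonnegative
  expect_true(all(apply(V, 2, function(col) col[which.max(abs(col))] >= 0)))
})

test_that("eigenvector maps extract the requested axis with optional scaling", {
  nd <- c(2L, 2L, 2L)
  cm <- array(0, c(6, nd)); cm[1, , , ] <- 3; cm[4, , , ] <- 2; cm[6, , , ] <- 1
  e <- eigendecompose(tensor_field(cm, array(4L, nd), c(0, 0, 0), 10, 20))
  v1 <- principal_vector_field(e, 1)
  expect_equal(v1$vec[, 1, 1, 1], c(1, 0, 0))
  v3 <- principal_vector_field(e, 3)
  expect_equal(v3$vec[, 2, 2, 2], c(0, 0, 1))
  vs <- principal_vector_field(e, 1, scale_by_sqrt_lambda = TRUE)
  expect_equal(sqrt(sum(vs$vec[, 1, 1, 1]^2)), sqrt(3))
  expect_error(principal_vector_field(e, 4), "1, 2 or 3")
})

test_that("window growth never loses descriptors and phantoms have the right shape", {
  set.seed(11)
  d <- random_descriptor_set(200)
  f1 <- compute_tensor_field(d, 30, 15, 1)
  f2 <- compute_tensor_field(d, 60, 15, 1, origin = f1$origin,
                             dims = dim(f1$count))
  expect_true(all(f2$count >= f1$count))
  # noise-free uniform phantom: rank-1 tensors aligned with the truth
  u <- make_segment_cloud("uniform", list(bounds = rbind(c(0, 0, 0), c(100, 100, 100)),
                                          n = 400, segment_length = 10,
                                          direction = c(1, 1, 0) / sqrt(2),
                                          jitter_deg = 0, seed = 13))
  fu <- compute_tensor_field(u$descriptors, 50, 25, 2)
  eu <- eigendecompose(fu)
  lam <- matrix(eu$values, 3)[, as.vector(eu$valid)]
  expect_lt(max(abs(lam[2, ])), 1e-9)
  expect_lt(max(abs(lam[3, ])), 1e-9)
  vecs <- matrix(eu$vectors, 9)[1:3, as.vector(eu$valid), drop = FALSE]
  for (i in seq_len(ncol(vecs)))
    expect_lt(axial_angle_deg(vecs[, i], c(1, 1, 0) / sqrt(2)), 1e-6)
  # isotropic phantom: low anisotropy throughout
  iso <- make_segment_cloud("isotropic", list(bounds = rbind(c(0, 0, 0), c(200, 200, 200)),
                                              n = 1e4, segment_length = 10,
                                              seed = 21))
  fi <- compute_tensor_field(iso$descriptors, 90, 30, 2)
  fa <- fractional_anisotropy(eigendecompose(fi))
  expect_lt(median(fa$values[is.finite(fa$values)]), 0.15)
})
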