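test_that("fractional anisotropy matches closed forms", {
  expect_equal(fractional_anisotropy(diag_eigen_field(c(1, 1, 1)))$values[1, 1, 1], 0)
  expect_equal(fractional_anisotropy(diag_eigen_field(c(1, 0, 0)))$values[1, 1, 1], 1)
  expect_equal(fractional_anisotropy(diag_eigen_field(c(2, 1, 1)))$values[1, 1, 1],
               0.4082, tolerance = 1e-3)
  # all-zero triple is undefined
  expect_true(is.nan(fractional_anisotropy(diag_eigen_field(c(0, 0, 0)))$values[1, 1, 1]))
})

test_that("Westin coefficients partition unity in the sum-normalized convention", {
  w <- westin_coefficients(diag_eigen_field(c(1, 0, 0)))
  expect_equal(c(w$cl$values[1], w$cp$values[1], w$cs$values[1]), c(1, 0, 0))
  w <- westin_coefficients(diag_eigen_field(c(1, 1, 1)))
  expect_equal(c(w$cl$values[1], w$cp$values[1], w$cs$values[1]), c(0, 0, 1))
  w <- westin_coefficients(diag_eigen_field(c(3, 2, 1)))
  expect_equal(c(w$cl$values[1], w$cp$values[1], w$cs$values[1]),
               c(1 / 6, 1 / 3, 1 / 2), tolerance = 1e-12)
  # partition check over random spectra
  set.seed(4)
  for (i in 1:20) {
    lam <- sort(runif(3, 0.01, 5), decreasing = TRUE)
    w <- westin_coefficients(diag_eigen_field(lam))
    expect_equal(w$cl$values[1] + w$cp$values[1] + w$cs$values[1], 1,
                 tolerance = 1e-12)
    expect_true(all(c(w$cl$values[1], w$cp$values[1], w$cs$values[1]) >= 0))
  }
  # lambda1-normalized variant does not partition but stays in [0, 1]
  w1 <- westin_coefficients(diag_eigen_field(c(3, 2, 1)), normalization = "lambda1")
  expect_equal(c(w1$cl$values[1], w1$cp$values[1], w1$cs$values[1]),
               c(1 / 3, 1 / 3, 1 / 3))
  wz <- westin_coefficients(diag_eigen_field(c(0, 0, 0)))
  expect_true(is.nan(wz$cl$values[1]))
})

test_that("DEC maps encode |eigenvector| as RGB and permute with the axes", {
  e <- diag_eigen_field(c(3, 2, 1))
  m <- dec_map(e, 1)
  expect_equal(m$rgb[, 1, 1, 1], c(1, 0, 0))      # x-aligned -> red
  m3 <- dec_map(e, 3)
  expect_equal(m3$rgb[, 1, 1, 1], c(0, 0, 1))     # z-aligned -> blue
  # oblique unit vector gives equal channels 0.577
  C <- matrix(1, 3, 3) / 3 * 3                   # rank-1 along (1,1,1)
  cm <- array(0, c(6, 1, 1, 1)); cm[, 1, 1, 1] <- C[c(1, 4, 7, 5, 8, 9)]
  eo <- eigendecompose(tensor_field(cm, array(2L, c(1, 1, 1)), c(0, 0, 0), 1, 1))
  expect_equal(dec_map(eo, 1)$rgb[, 1, 1, 1], rep(1 / sqrt(3), 3),
               tolerance = 1e-9)
  # axis permutation of the tensor permutes the DEC channels exactly
  perm <- c(3, 1, 2)
  lam <- c(3, 2, 1)
  ep <- diag_eigen_field(lam[perm])
  mp <- dec_map(ep, 1)
  expect_equal(mp$rgb[perm == 1, 1, 1, 1], 1)
  # FA weighting scales channels by the FA value
  mw <- dec_map(e, 1, weight = "fa")
  fa <- fractional_anisotropy(e)$values[1, 1, 1]
  expect_equal(mw$rgb[1, 1, 1, 1], fa)
})

test_that("the cylindrical wall frame has the stated geometry", {
  e <- diag_eigen_field(c(1, 1, 1), dims = c(3L, 1L, 1L), stride = 10)
  # centres at x = 0, 10, 20 with the axis through the origin along z
  fr <- build_wall_frame(e, axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                         epi_radius = 20, endo_radius = 10)
  expect_false(fr$valid[1, 1, 1])                 # centre on the axis
  expect_equal(fr$r_hat[, 2, 1, 1], c(1, 0, 0))
  expect_equal(fr$l_hat[, 2, 1, 1], c(0, 0, 1))
  expect_equal(abs(fr$c_hat[2, 2, 1, 1]), 1)      # circumferential = +/-y
  # orthonormality everywhere valid
  for (i in 2:3) {
    M <- cbind(fr$c_hat[, i, 1, 1], fr$l_hat[, i, 1, 1], fr$r_hat[, i, 1, 1])
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
  }
  # depth: 0 at the epicardial radius, 1 at the endocardial radius
  expect_equal(fr$depth[3, 1, 1], 0)              # r = 20 = epi
  expect_equal(fr$depth[2, 1, 1], 1)              # r = 10 = endo
})

test_that("helix and transverse angles follow the wall-frame conventions", {
  mk_eigen <- function(v) {
    v <- v / sqrt(sum(v^2))
    C <- outer(v, v)
    cm <- array(0, c(6, 1, 1, 1)); cm[, 1, 1, 1] <- C[c(1, 4, 7, 5, 8, 9)]
    eigendecompose(tensor_field(cm, array(2L, c(1, 1, 1)),
                                origin = c(10, 0, 0), stride = 1, window = 1))
  }
  frame_at <- function(e) build_wall_frame(e, c(0, 0, 0), c(0, 0, 1), 20, 5)
  # at centre (10, 0, 0): r_hat = x, l_hat = z, c_hat = z x x = y
  ha_of <- function(v) {
    e <- mk_eigen(v)
    a <- helix_transverse_angles(e, frame_at(e))
    c(a$ha$values[1, 1, 1], a$ta$values[1, 1, 1])
  }
  expect_equal(ha_of(c(0, 1, 0)), c(0, 0))            # circumferential
  expect_equal(abs(ha_of(c(0, 0, 1))[1]), 90)         # longitudinal
  expect_equal(ha_of(c(0, 0, 1))[2], 0)
  expect_equal(ha_of(c(0, 1, 1)), c(45, 0))           # (c + l)/sqrt(2)
  # axial symmetry: v and -v give identical angles
  expect_equal(ha_of(c(0, 1, 0.4)), ha_of(-c(0, 1, 0.4)))
  # radial vector: HA undefined, |TA| = 90
  rad <- ha_of(c(1, 0, 0))
  expect_true(is.nan(rad[1]))
  expect_equal(abs(rad[2]), 90)
  # elevation toward r_hat is a positive transverse angle
  expect_gt(ha_of(c(0.5, 1, 0))[2], 0)
})

test_that("transmural profiles aggregate depth bins and fit the span", {
  spec <- helical_shell_spec(jitter_deg = 0, density = 1e-5, seed = 6)
  cloud <- make_segment_cloud("helical_shell", spec)
  f <- compute_tensor_field(cloud$descriptors, 90, 30, 2)
  e <- eigendecompose(f)
  fr <- build_wall_frame(e, spec$center, spec$axis, spec$outer, spec$inner,
                         margin = 45)
  ang <- helix_transverse_angles(e, fr)
  prof <- transmural_profile(ang$ha, fr, 10)
  expect_equal(nrow(prof), 10)
  expect_true(all(prof$count >= 0))
  got <- prof$count >= 10
  expect_lt(max(abs(prof$mean_ha[got] - (60 - 120 * prof$d[got]))), 5)
  expect_equal(attr(prof, "span_deg"), 120, tolerance = 5)
  # constant-direction field: flat profile, span ~ 0
  const <- make_segment_cloud("uniform",
    list(bounds = rbind(c(-400, -400, -50), c(400, 400, 50)), n = 3000,
         segment_length = 10, direction = c(0, 0, 1), jitter_deg = 0, seed = 2))
  fc <- compute_tensor_field(const$descriptors, 90, 45, 2)
  ec <- eigendecompose(fc)
  frc <- build_wall_frame(ec, c(0, 0, 0), c(0, 0, 1), 380, 60)
  angc <- helix_transverse_angles(ec, frc)
  profc <- transmural_profile(angc$ha, frc, 5)
  expect_equal(attr(profc, "span_deg"), 0, tolerance = 2)
  expect_true(all(abs(profc$mean_ha[profc$count > 0] - 90) < 1e-6))
  # single bin = one overall mean
  prof1 <- transmural_profile(ang$ha, fr, 1)
  expect_equal(nrow(prof1), 1)
  expect_equal(prof1$count, sum(is.finite(ang$ha$values) & fr$valid))
})

test_that("FA and Westin maps are rotation invariant", {
  set.seed(19)
  n <- 400
  m <- matrix(runif(3 * n, 0, 80), n, 3)
  v <- matrix(rnorm(3 * n, 0, c(4, 2, 1)), n, 3, byrow = TRUE)
  mk <- function(m, v) descriptor_set(data.frame(
    mx = m[, 1], my = m[, 2], mz = m[, 3], vx = v[, 1], vy = v[, 2],
    vz = v[, 3], source_id = seq_len(n)))
  A <- matrix(rnorm(9), 3, 3); R <- qr.Q(qr(A))
  f1 <- compute_tensor_field(mk(m, v), 160, 160, 1, origin = c(40, 40, 40),
                             dims = c(1, 1, 1))
  f2 <- compute_tensor_field(mk(m %*% t(R), v %*% t(R)), 160, 160, 1,
                             origin = as.vector(c(40, 40, 40) %*% t(R)),
                             dims = c(1, 1, 1))
  e1 <- eigendecompose(f1); e2 <- eigendecompose(f2)
  expect_equal(fractional_anisotropy(e1)$values, fractional_anisotropy(e2)$values,
               tolerance = 1e-9)
  w1 <- westin_coefficients(e1); w2 <- westin_coefficients(e2)
  for (k in c("cl", "cp", "cs"))
    expect_equal(w1[[k]]$values, w2[[k]]$values, tolerance = 1e-9)
})
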