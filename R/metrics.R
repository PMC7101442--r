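#' Scalar and RGB maps on the tensor-field centre grid
#'
#' Thin containers aligning derived per-centre values with the window-centre
#' grid of their source field: `scalar_map` holds one value per centre
#' (`NaN` where the field is invalid), `rgb_map` an RGB triple in
#' \[0, 1\]^3.
#'
#' @param values 3D array of per-centre values.
#' @param rgb array `c(3, dims)` of channels in \[0, 1\].
#' @param origin,stride centre-grid geometry (um).
#' @param what short label of the quantity mapped.
#' @return object of class `scalar_map` / `rgb_map`.
#' @export
scalar_map <- function(values, origin, stride, what = "scalar") {
  structure(list(values = values, origin = as.numeric(origin),
                 stride = as.numeric(stride), what = what),
            class = "scalar_map")
}

#' @rdname scalar_map
#' @export
rgb_map <- function(rgb, origin, stride, what = "dec") {
  stopifnot(dim(rgb)[1] == 3L)
  structure(list(rgb = rgb, origin = as.numeric(origin),
                 stride = as.numeric(stride), what = what),
            class = "rgb_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<scalar_map:%s> %s centres, %d finite, range [%.4g, %.4g]\n",
              x$what, paste(dim(x$values), collapse = " x "), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

eigenvalue_matrix <- function(eigen) matrix(eigen$values, nrow = 3)

#' Fractional anisotropy map
#'
#' The standard DTI anisotropy index of the eigenvalue triple,
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`,
#' 0 for an isotropic tensor and 1 in the single-line limit
#' `(lambda, 0, 0)`. Centres with an all-zero triple (or invalid) map to
#' `NaN`.
#'
#' @param eigen an `eigen_field` from [eigendecompose()].
#' @return a [scalar_map()] with values in \[0, 1\].
#' @export
fractional_anisotropy <- function(eigen) {
  lam <- eigenvalue_matrix(eigen)
  lbar <- colMeans(lam)
  num <- sqrt(colSums((lam - rep(lbar, each = 3))^2))
  den <- sqrt(colSums(lam^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, NaN)
  fa[!as.vector(eigen$valid)] <- NaN
  fa <- pmin(1, pmax(0, fa))
  scalar_map(array(fa, dim(eigen$count)), eigen$origin, eigen$stride, "FA")
}

#' Westin shape coefficients
#'
#' Linear, planar and spherical shape indices of the eigenvalue triple. The
#' sum-normalised convention is the default — `cl = (l1 - l2) / sum`,
#' `cp = 2 (l2 - l3) / sum`, `cs = 3 l3 / sum` — chosen because the three
#' indices then partition unity exactly, a property the test-suite checks.
#' `normalization = "lambda1"` gives the older variant dividing by `l1`
#' (`cl = (l1-l2)/l1`, `cp = (l2-l3)/l1`, `cs = l3/l1`), which does not
#' sum to 1.
#'
#' @param eigen an `eigen_field`.
#' @param normalization `"sum"` (default) or `"lambda1"`.
#' @return list of three [scalar_map()]s `cl`, `cp`, `cs`.
#' @export
westin_coefficients <- function(eigen, normalization = c("sum", "lambda1")) {
  normalization <- match.arg(normalization)
  lam <- eigenvalue_matrix(eigen)
  l1 <- lam[1, ]; l2 <- lam[2, ]; l3 <- lam[3, ]
  if (normalization == "sum") {
    den <- l1 + l2 + l3
    cl <- (l1 - l2) / den; cp <- 2 * (l2 - l3) / den; cs <- 3 * l3 / den
  } else {
    den <- l1
    cl <- (l1 - l2) / den; cp <- (l2 - l3) / den; cs <- l3 / den
  }
  bad <- !as.vector(eigen$valid) | !is.finite(den) | den <= 0
  cl[bad] <- NaN; cp[bad] <- NaN; cs[bad] <- NaN
  nd <- dim(eigen$count)
  list(cl = scalar_map(array(cl, nd), eigen$origin, eigen$stride, "Westin cl"),
       cp = scalar_map(array(cp, nd), eigen$origin, eigen$stride, "Westin cp"),
       cs = scalar_map(array(cs, nd), eigen$origin, eigen$stride, "Westin cs"))
}

#' Directionally encoded color (DEC) map
#'
#' RGB channels are the absolute values of the chosen eigenvector's X, Y, Z
#' components (X red, Y green, Z blue), optionally weighted by FA or by the
#' normalised descriptor count to fade statistically weak centres.
#'
#' @param eigen an `eigen_field`.
#' @param index eigenvector index (1, 2 or 3).
#' @param weight `"none"`, `"fa"` or `"count"`.
#' @return an [rgb_map()]; invalid centres are black.
#' @export
dec_map <- function(eigen, index = 1L, weight = c("none", "fa", "count")) {
  weight <- match.arg(weight)
  index <- as.integer(index)
  if (!index %in% 1:3) stop("`index` must be 1, 2 or 3")
  nd <- dim(eigen$count)
  vecsf <- matrix(eigen$vectors, nrow = 9)
  rows <- (3L * (index - 1L) + 1L):(3L * index)
  rgb <- abs(vecsf[rows, , drop = FALSE])
  w <- switch(weight,
    none = rep(1, prod(nd)),
    fa = as.vector(fractional_anisotropy(eigen)$values),
    count = { cnt <- as.vector(eigen$count); if (max(cnt) > 0) cnt / max(cnt) else cnt })
  w[!is.finite(w)] <- 0
  rgb <- rgb * rep(w, each = 3)
  rgb[, !as.vector(eigen$valid)] <- 0
  rgb_map(array(rgb, c(3, nd)), eigen$origin, eigen$stride,
          sprintf("DEC v%d (%s)", index, weight))
}

#' Cylindrical wall frame for transmural analysis
#'
#' An idealised ventricular wall: a cylinder around a user-supplied long
#' axis. At every tensor-field centre the local orthonormal triad is
#' radial `r_hat` (outward from the axis), longitudinal `l_hat` (the axis
#' direction) and circumferential `c_hat = l_hat x r_hat`; transmural depth
#' `d = (epi_radius - r) / (epi_radius - endo_radius)` runs from 0 at the
#' outer (epicardial) to 1 at the inner (endocardial) radius, clipped to
#' \[0, 1\]. Centres on the axis (radius below `tol`) are invalid.
#'
#' @param eigen an `eigen_field` (supplies the centre grid), or a
#'   `tensor_field`.
#' @param axis_point a point on the long axis, um.
#' @param axis_dir the long-axis direction.
#' @param epi_radius,endo_radius outer and inner wall radii, um.
#' @param tol minimum off-axis radius, um.
#' @param margin if positive, centres with radius outside
#'   `[endo_radius + margin, epi_radius - margin]` are flagged invalid.
#'   Transmural statistics are only unmixed for sampling windows lying
#'   fully inside the wall, so profile analyses typically pass half the
#'   tensor window here; the default 0 keeps every off-axis centre (depth
#'   clipped to \[0, 1\]).
#' @return object of class `wall_frame` with `c_hat`, `l_hat`, `r_hat`
#'   (arrays `c(3, dims)`), `depth`, `radius` and `valid`.
#' @export
build_wall_frame <- function(eigen, axis_point, axis_dir, epi_radius,
                             endo_radius, tol = 1e-6, margin = 0) {
  stopifnot(epi_radius > endo_radius, endo_radius >= 0)
  nd <- dim(eigen$count)
  ctr <- centre_coords(eigen)
  l <- axis_dir / sqrt(sum(axis_dir^2))
  rel <- sweep(ctr, 2, as.numeric(axis_point))
  ax <- rel %*% l
  rad_vec <- rel - ax %*% t(l)
  r <- sqrt(rowSums(rad_vec^2))
  ok <- r > tol
  if (margin > 0)
    ok <- ok & r >= endo_radius + margin & r <= epi_radius - margin
  rhat <- rad_vec / ifelse(r > 0, r, 1)
  chat <- cbind(l[2] * rhat[, 3] - l[3] * rhat[, 2],
                l[3] * rhat[, 1] - l[1] * rhat[, 3],
                l[1] * rhat[, 2] - l[2] * rhat[, 1])
  depth <- pmin(1, pmax(0, (epi_radius - r) / (epi_radius - endo_radius)))
  structure(list(c_hat = array(t(chat), c(3, nd)),
                 l_hat = array(rep(l, length(r)), c(3, nd)),
                 r_hat = array(t(rhat), c(3, nd)),
                 depth = array(depth, nd), radius = array(r, nd),
                 valid = array(ok, nd),
                 axis_point = as.numeric(axis_point), axis_dir = l,
                 epi_radius = epi_radius, endo_radius = endo_radius),
            class = "wall_frame")
}

#' Helix and transverse angle maps
#'
#' The principal eigenvector is expressed in the local wall frame. Its
#' projection on the wall-tangent plane (spanned by circumferential and
#' longitudinal) makes the helix angle HA with the circumferential
#' direction, signed so that a component along `+l_hat` is positive (fibres
#' running toward the antero-apex) and confined to `(-90, 90]` — the
#' eigenvector is axial, so `v` and `-v` give identical angles. The
#' transverse angle TA is the signed elevation of the vector out of the
#' tangent plane toward `+r_hat`. A vector parallel to `r_hat` has
#' undefined HA (`NaN`) and TA `+/-90` degrees.
#'
#' @param eigen an `eigen_field`.
#' @param frame a [build_wall_frame()] on the same centre grid.
#' @return list of two [scalar_map()]s, `ha` and `ta`, in degrees.
#' @export
helix_transverse_angles <- function(eigen, frame) {
  nd <- dim(eigen$count)
  stopifnot(identical(dim(frame$depth), nd))
  M <- prod(nd)
  vecsf <- matrix(eigen$vectors, nrow = 9)
  cf <- matrix(frame$c_hat, nrow = 3)
  lf <- matrix(frame$l_hat, nrow = 3)
  rf <- matrix(frame$r_hat, nrow = 3)
  ha <- ta <- rep(NaN, M)
  ok <- which(as.vector(eigen$valid) & as.vector(frame$valid))
  for (i in ok) {
    v <- vecsf[1:3, i]
    uc <- sum(v * cf[, i]); ul <- sum(v * lf[, i]); ur <- sum(v * rf[, i])
    # axial normalisation: make the circumferential component nonnegative,
    # breaking ties toward +l_hat then +r_hat
    if (uc < 0 || (uc == 0 && (ul < 0 || (ul == 0 && ur < 0)))) {
      uc <- -uc; ul <- -ul; ur <- -ur
    }
    tang <- sqrt(uc^2 + ul^2)
    if (tang <= 1e-12) {                  # parallel to the radial direction
      ta[i] <- 90
    } else {
      ha[i] <- atan2(ul, uc) * 180 / pi
      ta[i] <- atan2(ur, tang) * 180 / pi
    }
  }
  list(ha = scalar_map(array(ha, nd), eigen$origin, eigen$stride, "helix angle (deg)"),
       ta = scalar_map(array(ta, nd), eigen$origin, eigen$stride, "transverse angle (deg)"))
}

# circular mean of axial angles in degrees, range (-90, 90]: double the
# angles (period 180 -> 360), average on the circle, halve
axial_circular_mean <- function(deg) {
  th <- deg * pi / 90                     # 2 * angle in radians
  m <- atan2(mean(sin(th)), mean(cos(th))) * 90 / pi
  if (m <= -90) m <- m + 180
  if (m > 90) m <- m - 180
  m
}

#' Transmural helix-angle profile
#'
#' Bins helix-angle values by transmural depth and reports the
#' circular-aware (axial, 180-degree-periodic) mean per bin, together with
#' the fitted transmural span `HA(0) - HA(1)` from a robust linear fit of
#' HA against depth over all valid centres (M-estimation, falling back to
#' ordinary least squares if it fails to converge).
#'
#' @param ha the helix-angle [scalar_map()].
#' @param frame the matching [build_wall_frame()].
#' @param n_bins number of equal-width depth bins covering \[0, 1\].
#' @return object of class `transmural_profile`: data frame
#'   `d, mean_ha, count` with attributes `span_deg` (fitted span),
#'   `slope`, `intercept`.
#' @export
transmural_profile <- function(ha, frame, n_bins = 10L) {
  vals <- as.vector(ha$values)
  depth <- as.vector(frame$depth)
  ok <- is.finite(vals) & as.vector(frame$valid)
  if (!any(ok)) stop("no valid helix-angle values to profile")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(n_bins, pmax(1L, findInterval(depth[ok], edges, rightmost.closed = TRUE)))
  mean_ha <- rep(NaN, n_bins); count <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    count[b] <- sum(sel)
    if (count[b] > 0) mean_ha[b] <- axial_circular_mean(vals[ok][sel])
  }
  fit <- tryCatch(MASS::rlm(vals[ok] ~ depth[ok], maxit = 100),
                  error = function(e) lm(vals[ok] ~ depth[ok]),
                  warning = function(w) lm(vals[ok] ~ depth[ok]))
  cf <- coef(fit)
  out <- data.frame(d = mid, mean_ha = mean_ha, count = count)
  structure(out, span_deg = -unname(cf[2]), slope = unname(cf[2]),
            intercept = unname(cf[1]),
            class = c("transmural_profile", "data.frame"))
}

#' @rdname transmural_profile
#' @param profile a `transmural_profile`.
#' @param path CSV output path.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
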