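#' Phantom specifications
#'
#' Synthetic specimens with exact ground truth, emulating the two specimen
#' classes the pipeline targets: (a) tubular branching vasculature whose
#' local direction follows a prescribed helix-angle law across a
#' cylindrical wall, and (b) solid ellipsoidal cells with a prescribed
#' axial orientation distribution.
#'
#' `helical_shell_spec` describes a cylindrical shell (wall) of
#' micro-vessel segments. Transmural depth runs from `d = 0` at the outer
#' (epicardial) radius to `d = 1` at the inner (endocardial) radius, and the
#' default helix-angle law is linear, `HA(d) = ha_epi + d * (ha_endo -
#' ha_epi)` degrees, i.e. from `+60` to `-60` — the classic transmural
#' rotation of the ventricular wall. Segment direction at depth `d` is
#' `cos(HA) * c_hat + sin(HA) * l_hat` in the local
#' circumferential/longitudinal frame.
#'
#' @param inner,outer inner (endo) and outer (epi) wall radii, um.
#' @param height shell height along the long axis, um.
#' @param axis unit long-axis direction (default z).
#' @param center axis point at mid-height, um.
#' @param ha_epi,ha_endo helix angle (degrees) at depth 0 and 1.
#' @param ha_law optional function `d -> degrees` overriding the linear law.
#' @param segment_length descriptor length, um.
#' @param density segments per um^3 of wall.
#' @param jitter_deg s.d. of the random tilt applied to each segment
#'   direction (0 = noise-free).
#' @param seed integer seed making the phantom deterministic.
#' @return a spec list of the matching class.
#' @export
helical_shell_spec <- function(inner = 300, outer = 700, height = 200,
                               axis = c(0, 0, 1), center = c(0, 0, 0),
                               ha_epi = 60, ha_endo = -60, ha_law = NULL,
                               segment_length = 15, density = 2e-5,
                               jitter_deg = 0, seed = 1L) {
  stopifnot(inner > 0, outer > inner, height > 0, density > 0,
            segment_length > 0, jitter_deg >= 0)
  law <- ha_law %||% function(d) ha_epi + d * (ha_endo - ha_epi)
  dd <- seq(0, 1, length.out = 101)
  if (any(!is.finite(law(dd)))) stop("helix-angle law must be finite on [0, 1]")
  structure(list(inner = inner, outer = outer, height = height,
                 axis = axis / sqrt(sum(axis^2)), center = as.numeric(center),
                 ha_law = law, segment_length = segment_length,
                 density = density, jitter_deg = jitter_deg,
                 seed = as.integer(seed)),
            class = "helical_shell_spec")
}

#' @rdname helical_shell_spec
#' @param n number of cells.
#' @param semi_axes ellipsoid semi-axes `(a, b, c)` um, `a >= b >= c > 0`.
#' @param mean_dir mean axial orientation (unit vector).
#' @param kappa Watson concentration of the cell axis about `mean_dir`
#'   (0 = isotropic; large = tightly aligned). The distribution is axial:
#'   `u` and `-u` are the same orientation.
#' @param bounds 2 x 3 matrix (rows lo, hi) of the placement volume, um.
#' @param spacing voxel spacing of the rasterized label volume, um.
#' @export
cell_population_spec <- function(n = 50, semi_axes = c(10, 4, 4),
                                 mean_dir = c(0, 0, 1), kappa = 200,
                                 bounds = rbind(lo = c(0, 0, 0), hi = c(150, 150, 150)),
                                 spacing = c(1, 1, 1), seed = 1L) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            semi_axes[1] >= semi_axes[2], semi_axes[2] >= semi_axes[3],
            kappa >= 0, n >= 1)
  structure(list(n = as.integer(n), semi_axes = as.numeric(semi_axes),
                 mean_dir = mean_dir / sqrt(sum(mean_dir^2)), kappa = kappa,
                 bounds = bounds, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "cell_population_spec")
}

# rotation taking z-hat onto `axis` (Rodrigues); identity-safe
rotation_from_z <- function(axis) {
  z <- c(0, 0, 1)
  a <- axis / sqrt(sum(axis^2))
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  cth <- sum(z * a)
  if (abs(cth - 1) < 1e-12) return(diag(3))
  if (abs(cth + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# uniform directions on the unit sphere, n x 3
runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# axial Watson(mu, kappa) sample by rejection from the uniform sphere:
# density proportional to exp(kappa * (mu . u)^2)
rwatson <- function(n, mu, kappa) {
  if (kappa == 0) return(runif_sphere(n))
  out <- matrix(0, 0, 3)
  while (nrow(out) < n) {
    cand <- runif_sphere(max(64L, 2L * (n - nrow(out))))
    c2 <- (cand %*% mu)^2
    keep <- runif(nrow(cand)) < exp(kappa * (c2 - 1))
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# tilt each row of `dirs` by an angle ~ N(0, jitter_deg) about a random
# axis perpendicular to it
jitter_directions <- function(dirs, jitter_deg) {
  if (jitter_deg <= 0 || nrow(dirs) == 0) return(dirs)
  n <- nrow(dirs)
  th <- rnorm(n, 0, jitter_deg) * pi / 180
  rnd <- runif_sphere(n)
  out <- dirs
  for (i in seq_len(n)) {
    u <- dirs[i, ]
    perp <- rnd[i, ] - sum(rnd[i, ] * u) * u
    np <- sqrt(sum(perp^2))
    if (np < 1e-12) next
    perp <- perp / np
    out[i, ] <- cos(th[i]) * u + sin(th[i]) * perp
  }
  out
}

#' Generate a descriptor cloud with known ground truth
#'
#' Three generators: `"uniform"` (all segments share one direction inside a
#' box), `"isotropic"` (directions uniform on the sphere) and
#' `"helical_shell"` (segments fill a cylindrical wall, directions follow
#' the spec's helix-angle law). Deterministic for a fixed spec seed.
#'
#' @param kind `"uniform"`, `"isotropic"` or `"helical_shell"`.
#' @param spec for `"helical_shell"` a [helical_shell_spec()]; for the box
#'   kinds a list with `bounds` (2 x 3), `n`, `segment_length`,
#'   `direction` (uniform only), `jitter_deg`, `seed`.
#' @return list with `descriptors` (a [descriptor_set()]) and `truth`
#'   (data frame of true unit directions; for the shell also transmural
#'   depth `d` and true helix angle `ha_true` per descriptor).
#' @export
make_segment_cloud <- function(kind = c("uniform", "isotropic", "helical_shell"),
                               spec) {
  kind <- match.arg(kind)
  if (kind == "helical_shell") return(make_helical_cloud(spec))
  bounds <- spec$bounds
  n <- spec$n
  if (is.null(n) || n < 1) stop("spec$n must be at least 1")
  len <- spec$segment_length %||% 10
  jit <- spec$jitter_deg %||% 0
  with_local_seed(spec$seed %||% 1L, {
    mid <- sapply(1:3, function(ax) runif(n, bounds[1, ax], bounds[2, ax]))
    mid <- matrix(mid, ncol = 3)
    true_dir <- if (kind == "uniform") {
      dd <- spec$direction / sqrt(sum(spec$direction^2))
      matrix(dd, n, 3, byrow = TRUE)
    } else runif_sphere(n)
    dirs <- jitter_directions(true_dir, jit)
    v <- dirs * len
    list(descriptors = descriptor_set(
           data.frame(mx = mid[, 1], my = mid[, 2], mz = mid[, 3],
                      vx = v[, 1], vy = v[, 2], vz = v[, 3],
                      source_id = seq_len(n)), kind = "vascular"),
         truth = data.frame(ux = true_dir[, 1], uy = true_dir[, 2],
                            uz = true_dir[, 3]))
  })
}

make_helical_cloud <- function(spec) {
  stopifnot(inherits(spec, "helical_shell_spec"))
  vol <- pi * (spec$outer^2 - spec$inner^2) * spec$height
  n <- max(1L, round(spec$density * vol))
  R <- rotation_from_z(spec$axis)
  with_local_seed(spec$seed, {
    # uniform in the annular wall volume
    r <- sqrt(runif(n, spec$inner^2, spec$outer^2))
    th <- runif(n, 0, 2 * pi)
    z <- runif(n, -spec$height / 2, spec$height / 2)
    d <- (spec$outer - r) / (spec$outer - spec$inner)
    ha <- spec$ha_law(d)
    # local frame in shell coordinates: c_hat tangential, l_hat = z
    chat <- cbind(-sin(th), cos(th), 0)
    lhat <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
    dirs_local <- cos(ha * pi / 180) * chat + sin(ha * pi / 180) * lhat
    mids_local <- cbind(r * cos(th), r * sin(th), z)
    true_dir <- dirs_local %*% t(R)
    mids <- mids_local %*% t(R) + matrix(spec$center, n, 3, byrow = TRUE)
    dirs <- jitter_directions(true_dir, spec$jitter_deg)
    v <- dirs * spec$segment_length
    list(descriptors = descriptor_set(
           data.frame(mx = mids[, 1], my = mids[, 2], mz = mids[, 3],
                      vx = v[, 1], vy = v[, 2], vz = v[, 3],
                      source_id = seq_len(n)), kind = "vascular"),
         truth = data.frame(ux = true_dir[, 1], uy = true_dir[, 2],
                            uz = true_dir[, 3], d = d, ha_true = ha))
  })
}

#' Rasterize tube segments into a binary mask
#'
#' Sets every voxel whose centre lies within `radius` um of any segment
#' centreline. Deterministic.
#'
#' @param segments either a [descriptor_set()] (segments are
#'   `midpoint +/- vector/2`) or a 6-column matrix `(x0,y0,z0,x1,y1,z1)` of
#'   endpoint pairs in um.
#' @param radius tube radius, um; must be at least one voxel in the finest
#'   axis or the tube cannot be resolved on the grid.
#' @param shape integer grid dimensions `(nx, ny, nz)`.
#' @param spacing,origin grid geometry, um.
#' @return a [binary_mask()].
#' @export
rasterize_tubes <- function(segments, radius, shape, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  if (radius < min(spacing))
    stop("radius ", radius, " um is below the finest voxel size (",
         min(spacing), " um); the tube cannot be resolved on this grid")
  ep <- if (inherits(segments, "descriptor_set")) {
    m <- descriptor_midpoints(segments); v <- descriptor_vectors(segments)
    cbind(m - v / 2, m + v / 2)
  } else if (is.matrix(segments) && ncol(segments) == 6) segments
  else stop("`segments` must be a descriptor_set or an n x 6 endpoint matrix")
  shape <- as.integer(shape)
  mask <- array(0L, shape)
  grid <- voxel_grid(array(0, shape), spacing, origin)
  for (i in seq_len(nrow(ep))) {
    p0 <- ep[i, 1:3]; p1 <- ep[i, 4:6]
    lo <- pmin(p0, p1) - radius; hi <- pmax(p0, p1) + radius
    ilo <- pmax(1L, floor(phys_to_index(grid, lo)))
    ihi <- pmin(shape, ceiling(phys_to_index(grid, hi)))
    if (any(ilo > ihi)) next
    xs <- origin[1] + (seq.int(ilo[1], ihi[1]) - 1) * spacing[1]
    ys <- origin[2] + (seq.int(ilo[2], ihi[2]) - 1) * spacing[2]
    zs <- origin[3] + (seq.int(ilo[3], ihi[3]) - 1) * spacing[3]
    pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
    dvec <- p1 - p0; L2 <- sum(dvec^2)
    rel <- sweep(pts, 2, p0)
    t <- if (L2 > 0) pmin(1, pmax(0, rel %*% dvec / L2)) else matrix(0, nrow(pts), 1)
    near <- rel - t %*% t(dvec)
    inside <- sqrt(rowSums(near^2)) <= radius
    if (any(inside)) {
      sub <- as.matrix(expand.grid(i = seq.int(ilo[1], ihi[1]),
                                   j = seq.int(ilo[2], ihi[2]),
                                   k = seq.int(ilo[3], ihi[3]),
                                   KEEP.OUT.ATTRS = FALSE))[inside, , drop = FALSE]
      mask[sub] <- 1L
    }
  }
  binary_mask(mask, spacing, origin)
}

#' Generate a labelled volume of oriented ellipsoid cells
#'
#' Places `spec$n` solid ellipsoids with axial Watson-distributed long axes
#' inside the bounds, rejecting placements whose bounding spheres overlap a
#' previously placed cell (so each cell's moment ground truth stays exact),
#' and rasterizes them into a label volume. Errors if `n` cells cannot be
#' placed within `max_tries` rejections.
#'
#' @param spec a [cell_population_spec()].
#' @param max_tries placement attempts before giving up.
#' @return list with `labels` (a [label_volume()]) and `truth` (data frame
#'   of per-cell centroids and true unit axes).
#' @export
make_cell_volume <- function(spec, max_tries = 2000L) {
  stopifnot(inherits(spec, "cell_population_spec"))
  a <- spec$semi_axes[1]
  lo <- spec$bounds[1, ] + a; hi <- spec$bounds[2, ] - a
  if (any(hi <= lo)) stop("bounds too small for the cell size")
  with_local_seed(spec$seed, {
    centers <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(centers) < spec$n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", spec$n, " non-overlapping cells in ",
             max_tries, " attempts; enlarge bounds or reduce n")
      cand <- runif(3, lo, hi)
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * a))
        centers <- rbind(centers, cand)
    }
    axes <- rwatson(spec$n, spec$mean_dir, spec$kappa)
    shape <- as.integer(ceiling((spec$bounds[2, ] - spec$bounds[1, ]) / spec$spacing))
    lab <- array(0L, shape)
    grid <- voxel_grid(array(0, shape), spec$spacing, spec$bounds[1, ])
    for (i in seq_len(spec$n)) {
      ctr <- centers[i, ]
      R <- rotation_from_z(axes[i, ])      # maps local z (long axis) to world
      ilo <- pmax(1L, floor(phys_to_index(grid, ctr - a)))
      ihi <- pmin(shape, ceiling(phys_to_index(grid, ctr + a)))
      xs <- grid$origin[1] + (seq.int(ilo[1], ihi[1]) - 1) * spec$spacing[1]
      ys <- grid$origin[2] + (seq.int(ilo[2], ihi[2]) - 1) * spec$spacing[2]
      zs <- grid$origin[3] + (seq.int(ilo[3], ihi[3]) - 1) * spec$spacing[3]
      pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
      local <- sweep(pts, 2, ctr) %*% R    # world -> local (R is orthogonal)
      semi <- c(spec$semi_axes[2], spec$semi_axes[3], spec$semi_axes[1])
      # local z is the long axis; x, y carry the two short semi-axes
      inside <- (local[, 1] / semi[1])^2 + (local[, 2] / semi[2])^2 +
        (local[, 3] / semi[3])^2 <= 1
      if (any(inside)) {
        sub <- as.matrix(expand.grid(i = seq.int(ilo[1], ihi[1]),
                                     j = seq.int(ilo[2], ihi[2]),
                                     k = seq.int(ilo[3], ihi[3]),
                                     KEEP.OUT.ATTRS = FALSE))[inside, , drop = FALSE]
        lab[sub] <- i
      }
    }
    list(labels = label_volume(lab, spec$spacing, spec$bounds[1, ]),
         truth = data.frame(cx = centers[, 1], cy = centers[, 2],
                            cz = centers[, 3], ux = axes[, 1],
                            uy = axes[, 2], uz = axes[, 3]))
  })
}
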