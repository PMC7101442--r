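#' Deterministic RK2 streamline tractography
#'
#' Streamlines are integrated through the chosen eigenvector field with a
#' second-order Runge-Kutta (midpoint) scheme. Eigenvectors are axial, so
#' every lookup is sign-aligned with the current heading and tracking is
#' bidirectional from each seed (the two half-tracks are concatenated at
#' the seed). A single termination criterion applies: the track stops when
#' the angle between the previous and the new heading exceeds `max_angle`
#' degrees (plus the inevitable bookkeeping stops: leaving the field,
#' entering an invalid centre, or the `max_points` safety cap). No
#' anisotropy threshold is applied anywhere.
#'
#' One RK2 step from `x` with heading `h`:
#' `v_a = dir(x)` sign-aligned with `h`; midpoint `x_m = x + (step/2) v_a`;
#' `v_b = dir(x_m)` sign-aligned with `v_a`; terminate if
#' `angle(h, v_b) > max_angle`, else `x' = x + step * v_b`.
#'
#' `dir(.)` is the nearest-valid-centre eigenvector by default
#' (`interp = "trilinear"` blends the 8 surrounding centres with
#' per-corner sign correction). For analytic studies of the integrator,
#' `eigen` may also be a plain function mapping a length-3 position to a
#' direction (or `NULL` outside its domain).
#'
#' @param eigen an `eigen_field` from [eigendecompose()], or a function
#'   `x -> direction`.
#' @param index eigenvector index to follow (1 principal, 2, 3).
#' @param step integration step, um. The default, half the field stride,
#'   is stable for RK2 on the default 20 um grids.
#' @param max_angle termination angle, degrees (default 35).
#' @param seeds `"all"` (every valid centre) or an n x 3 matrix of seed
#'   points, um.
#' @param max_points hard cap on points per half-track.
#' @param interp `"nearest"` or `"trilinear"` (eigen-field input only).
#' @param seed_stride keep every k-th valid-centre seed (decimation for
#'   speed; default 1 = all).
#' @return object of class `streamline_set`: `tracks` (list of n x 3
#'   matrices), `reasons` (2-column matrix: backward/forward termination of
#'   each track, from `"angle"`, `"boundary"`, `"invalid_voxel"`,
#'   `"max_length"`), and the tracking parameters verbatim in `params`.
#' @export
track <- function(eigen, index = 1L, step = NULL, max_angle = 35,
                  seeds = "all", max_points = 10000L,
                  interp = c("nearest", "trilinear"), seed_stride = 1L) {
  interp <- match.arg(interp)
  if (is.function(eigen)) {
    dirfun <- function(x) {
      v <- eigen(x)
      if (is.null(v) || any(!is.finite(v))) return(list(v = NULL, why = "boundary"))
      list(v = v / sqrt(sum(v^2)), why = NULL)
    }
    if (is.null(step)) stop("`step` is required with a functional field")
    if (identical(seeds, "all")) stop("explicit seeds are required with a functional field")
  } else {
    stopifnot(inherits(eigen, "eigen_field"))
    if (is.null(step)) step <- eigen$stride / 2
    dirfun <- eigen_direction_fun(eigen, as.integer(index), interp)
  }
  stopifnot(step > 0, max_angle > 0)
  seed_mat <- if (identical(seeds, "all")) {
    ctr <- centre_coords(eigen)[as.vector(eigen$valid), , drop = FALSE]
    ctr[seq(1, nrow(ctr), by = max(1L, as.integer(seed_stride))), , drop = FALSE]
  } else rbind3(seeds)
  cos_max <- cos(max_angle * pi / 180)

  half_track <- function(x0, h) {
    pts <- vector("list", 64L); n <- 0L
    x <- x0
    reason <- "max_length"
    while (n < max_points) {
      la <- dirfun(x)
      if (is.null(la$v)) { reason <- la$why; break }
      va <- la$v
      if (sum(va * h) < 0) va <- -va
      lb <- dirfun(x + (step / 2) * va)
      if (is.null(lb$v)) { reason <- lb$why; break }
      vb <- lb$v
      if (sum(vb * va) < 0) vb <- -vb
      if (sum(vb * h) < cos_max) { reason <- "angle"; break }
      x <- x + step * vb
      n <- n + 1L
      if (n > length(pts)) pts <- c(pts, vector("list", length(pts)))
      pts[[n]] <- x
      h <- vb
    }
    list(pts = if (n) do.call(rbind, pts[seq_len(n)]) else matrix(numeric(0), ncol = 3),
         reason = reason)
  }

  tracks <- list(); reasons <- list()
  n_omitted <- 0L
  for (s in seq_len(nrow(seed_mat))) {
    x0 <- seed_mat[s, ]
    l0 <- dirfun(x0)
    if (is.null(l0$v)) { n_omitted <- n_omitted + 1L; next }
    fwd <- half_track(x0, l0$v)
    bwd <- half_track(x0, -l0$v)
    pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))), , drop = FALSE],
                 matrix(x0, 1, 3), fwd$pts)
    if (nrow(pts) < 2L) { n_omitted <- n_omitted + 1L; next }
    rsn <- c(bwd$reason, fwd$reason)
    # canonical orientation: eigenvectors are axial, so a global sign flip
    # would otherwise swap the two half-tracks; orient each polyline so its
    # first point is lexicographically smallest
    a <- pts[1, ]; b <- pts[nrow(pts), ]
    cmp <- (a > b) - (a < b)
    first_nz <- cmp[cmp != 0][1]
    if (length(first_nz) == 1L && !is.na(first_nz) && first_nz > 0L) {
      pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      rsn <- rev(rsn)
    }
    tracks[[length(tracks) + 1L]] <- unname(pts)
    reasons[[length(reasons) + 1L]] <- rsn
  }
  structure(list(tracks = tracks,
                 reasons = if (length(reasons)) do.call(rbind, reasons)
                           else matrix(character(0), ncol = 2),
                 params = list(step = step, max_angle = max_angle,
                               index = if (is.function(eigen)) NA_integer_ else as.integer(index),
                               seeds = if (identical(seeds, "all")) "all" else "list",
                               interp = interp, max_points = max_points),
                 n_omitted = n_omitted),
            class = "streamline_set")
}

# direction-lookup closure over an eigen field
eigen_direction_fun <- function(eigen, index, interp) {
  nd <- dim(eigen$count)
  vecsf <- matrix(eigen$vectors, nrow = 9)
  rows <- (3L * (index - 1L) + 1L):(3L * index)
  valid <- eigen$valid
  origin <- eigen$origin; stride <- eigen$stride
  lin <- function(k) k[1] + nd[1] * (k[2] - 1) + nd[1] * nd[2] * (k[3] - 1)
  if (interp == "nearest") {
    function(x) {
      k <- round((x - origin) / stride) + 1
      if (any(k < 1) || any(k > nd)) return(list(v = NULL, why = "boundary"))
      i <- lin(k)
      if (!valid[i]) return(list(v = NULL, why = "invalid_voxel"))
      list(v = vecsf[rows, i], why = NULL)
    }
  } else {
    function(x) {
      t <- (x - origin) / stride + 1
      if (any(t < 1) || any(t > nd)) return(list(v = NULL, why = "boundary"))
      k0 <- pmin(pmax(floor(t), 1), pmax(nd - 1, 1))
      f <- t - k0
      acc <- c(0, 0, 0); wtot <- 0; ref <- NULL; any_inside <- FALSE
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        k <- k0 + c(dx, dy, dz)
        if (any(k > nd)) next
        any_inside <- TRUE
        w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
        if (w <= 0) next
        i <- lin(k)
        if (!valid[i]) next
        v <- vecsf[rows, i]
        if (is.null(ref)) ref <- v
        if (sum(v * ref) < 0) v <- -v
        acc <- acc + w * v
        wtot <- wtot + w
      }
      if (wtot <= 0 || sqrt(sum(acc^2)) < 1e-12)
        return(list(v = NULL, why = if (any_inside) "invalid_voxel" else "boundary"))
      list(v = acc / sqrt(sum(acc^2)), why = NULL)
    }
  }
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x$tracks, nrow, integer(1))
  cat(sprintf("<streamline_set> %d tracks, %d points total, step %g um, max angle %g deg\n",
              length(x$tracks), sum(np), x$params$step, x$params$max_angle))
  invisible(x)
}

#' Polyline length of each streamline
#' @param tracks a `streamline_set`.
#' @return numeric vector of lengths, um.
#' @export
streamline_lengths <- function(tracks) {
  vapply(tracks$tracks, function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
}

#' Randomly subsample a streamline set
#'
#' Uniform sample without replacement of `round(fraction * n)` tracks —
#' display hygiene for dense all-voxel tractograms, where typically only a
#' 0.15 fraction is rendered. Deterministic for a fixed seed.
#'
#' @param tracks a `streamline_set`.
#' @param fraction in (0, 1].
#' @param seed integer seed.
#' @return a `streamline_set` with the sampled subset (original order).
#' @export
subsample <- function(tracks, fraction = 0.15, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(tracks$tracks)
  if (n == 0L) return(tracks)
  k <- round(fraction * n)
  keep <- sort(with_local_seed(seed, sample.int(n, k)))
  tracks$tracks <- tracks$tracks[keep]
  tracks$reasons <- tracks$reasons[keep, , drop = FALSE]
  tracks$params$subsample <- list(fraction = fraction, seed = as.integer(seed))
  tracks
}

#' Drop streamlines shorter than a length threshold
#' @param tracks a `streamline_set`.
#' @param min_length minimum polyline length, um.
#' @return the filtered `streamline_set`.
#' @export
filter_by_length <- function(tracks, min_length = 0) {
  stopifnot(min_length >= 0)
  keep <- streamline_lengths(tracks) >= min_length
  tracks$tracks <- tracks$tracks[keep]
  tracks$reasons <- tracks$reasons[keep, , drop = FALSE]
  tracks
}
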