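#' Pipeline configuration
#'
#' A single flat configuration drives the one-command pipeline
#' phantom -> mask -> skeleton -> graph -> descriptors -> tensor ->
#' metrics -> tracks. `default_config()` returns the full default tree
#' (values can be overridden by merging a user list or a YAML file via
#' [read_config()]); [validate_config()] reports out-of-range or
#' inconsistent parameters without running anything.
#'
#' @return `default_config`: a nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("phantom", "skeletonize", "graph", "descriptors",
               "tensor", "metrics", "track"),
    input = list(mask = NULL, spacing = c(1.2, 1.2, 4)),
    phantom = list(kind = "helical_shell",
                   inner = 35, outer = 75, height = 80,
                   ha_epi = 60, ha_endo = -60,
                   segment_length = 12, density = 8e-4, jitter_deg = 5,
                   tube_radius = 3, raster_spacing = c(2, 2, 2)),
    binarize = list(threshold = 0.5, min_object_voxels = 0),
    skeletonize = list(prune_below = 0),
    descriptors = list(subdivide_um = Inf),
    tensor = list(window = 90, stride = 20, min_count = 2),
    metrics = list(n_bins = 10),
    track = list(index = 1, step = NULL, max_angle = 35, seeds = "all",
                 fraction = 0.15, max_points = 10000, interp = "nearest",
                 min_length = 0)
  )
}

#' @rdname default_config
#' @param path YAML configuration file; keys override the defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(user[[k]]) && is.list(base[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' @rdname default_config
#' @param config a configuration list (see [default_config()]).
#' @return `validate_config`: data frame with columns `parameter` and
#'   `problem`; zero rows means the configuration is valid.
#' @export
validate_config <- function(config) {
  bad <- list()
  flag <- function(parameter, problem)
    bad[[length(bad) + 1L]] <<- data.frame(parameter = parameter, problem = problem)
  tn <- config$tensor
  if (tn$stride <= 0) flag("tensor.stride", "must be positive")
  if (tn$window < tn$stride)
    flag("tensor.window", sprintf("window (%g) smaller than stride (%g)",
                                  tn$window, tn$stride))
  if (tn$min_count < 0) flag("tensor.min_count", "must be >= 0")
  tr <- config$track
  if (tr$fraction <= 0 || tr$fraction > 1)
    flag("track.fraction", sprintf("%g outside (0, 1]", tr$fraction))
  if (tr$max_angle <= 0) flag("track.max_angle", "must be positive")
  if (!is.null(tr$step) && tr$step <= 0) flag("track.step", "must be positive")
  if (!tr$index %in% 1:3) flag("track.index", "must be 1, 2 or 3")
  if (any(config$input$spacing <= 0)) flag("input.spacing", "must be positive")
  ph <- config$phantom
  if (!is.null(ph$inner) && !is.null(ph$outer) && ph$inner >= ph$outer)
    flag("phantom.inner", "inner radius must be smaller than outer")
  unknown <- setdiff(config$stages,
                     c("phantom", "binarize", "skeletonize", "graph",
                       "descriptors", "tensor", "metrics", "track"))
  for (s in unknown) flag("stages", paste("unknown stage:", s))
  if (length(bad)) do.call(rbind, bad)
  else data.frame(parameter = character(0), problem = character(0))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing every intermediate
#' artifact in its standard on-disk format into `out_dir` along with the
#' configuration (`config.yaml`) and a run log (parameters, timings,
#' descriptor and track counts). A stage failure aborts with the failing
#' stage named; artifacts written up to that point are kept.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage products
#'   (`mask`, `skeleton`, `graph`, `descriptors`, `field`, `eigen`,
#'   `maps`, `tracks`) and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  problems <- validate_config(config)
  if (nrow(problems))
    stop("invalid configuration:\n",
         paste(sprintf("  %s: %s", problems$parameter, problems$problem),
               collapse = "\n"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  log_lines <- c(sprintf("microtract %s", as.character(utils::packageVersion("microtract"))),
                 sprintf("seed %d", config$seed))
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  state <- list(out_dir = out_dir)
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible())
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logf("stage %-12s %.2f s", name, proc.time()[3] - t0)
    res
  }

  run_stage("phantom", function() {
    ph <- config$phantom
    spec <- helical_shell_spec(inner = ph$inner, outer = ph$outer,
                               height = ph$height, ha_epi = ph$ha_epi,
                               ha_endo = ph$ha_endo,
                               segment_length = ph$segment_length,
                               density = ph$density,
                               jitter_deg = ph$jitter_deg,
                               seed = config$seed)
    cloud <- make_segment_cloud("helical_shell", spec)
    state$truth <<- cloud$truth
    state$spec <<- spec
    margin <- ph$tube_radius + 2 * max(ph$raster_spacing)
    ext <- c(spec$outer + margin, spec$outer + margin, spec$height / 2 + margin)
    shape <- ceiling(2 * ext / ph$raster_spacing)
    state$mask <<- rasterize_tubes(cloud$descriptors, ph$tube_radius,
                                   shape, ph$raster_spacing, origin = -ext)
    write_volume(state$mask, file.path(out_dir, "mask.tif"))
    logf("phantom: %d segments, mask %s voxels fg=%d",
         nrow(cloud$descriptors), paste(shape, collapse = "x"),
         sum(state$mask$data))
  })

  if (!("phantom" %in% config$stages)) {
    run_stage("binarize", function() {
      if (is.null(config$input$mask)) stop("no input mask path configured")
      vol <- read_volume(config$input$mask, spacing = config$input$spacing)
      state$mask <<- binarize_baseline(vol, config$binarize$threshold,
                                       config$binarize$min_object_voxels)
      write_volume(state$mask, file.path(out_dir, "mask.tif"))
    })
    if (is.null(state$mask) && !("binarize" %in% config$stages)) {
      if (is.null(config$input$mask)) stop("no input mask and phantom stage disabled")
      state$mask <- read_volume(config$input$mask,
                                spacing = config$input$spacing, kind = "mask")
    }
  }

  run_stage("skeletonize", function() {
    state$skeleton <<- skeletonize(state$mask)
    write_volume(state$skeleton, file.path(out_dir, "skel.tif"))
    logf("skeleton: %d voxels", sum(state$skeleton$data))
  })

  run_stage("graph", function() {
    state$graph <<- build_graph(state$skeleton,
                                prune_below = config$skeletonize$prune_below)
    write_graph_file(state$graph, file.path(out_dir, "graph.graphml"))
    logf("graph: %d nodes, %d edges", nrow(state$graph$nodes),
         nrow(state$graph$edges))
  })

  run_stage("descriptors", function() {
    state$descriptors <<- segments_from_graph(state$graph,
                                              config$descriptors$subdivide_um)
    write_descriptors(state$descriptors, file.path(out_dir, "descriptors.csv"))
    logf("descriptors: %d", nrow(state$descriptors))
  })

  run_stage("tensor", function() {
    tn <- config$tensor
    state$field <<- compute_tensor_field(state$descriptors, window = tn$window,
                                         stride = tn$stride,
                                         min_count = tn$min_count)
    write_tensor_field(state$field, file.path(out_dir, "tensor.nrrd"))
    state$eigen <<- eigendecompose(state$field)
    logf("tensor: %s centres, %d valid",
         paste(dim(state$field$count), collapse = "x"), sum(state$field$valid))
  })

  run_stage("metrics", function() {
    fa <- fractional_anisotropy(state$eigen)
    famap <- fa$values; famap[!is.finite(famap)] <- 0
    write_volume(voxel_grid(famap, rep(state$field$stride, 3),
                            state$field$origin),
                 file.path(out_dir, "fa.tif"))
    dec <- dec_map(state$eigen, 1)
    mid <- max(1L, dim(state$eigen$count)[3] %/% 2L)
    export_map(dec, file.path(out_dir, "dec.png"), slice = mid)
    state$maps <<- list(fa = fa, dec = dec)
    if (!is.null(state$spec)) {
      frame <- build_wall_frame(state$eigen, state$spec$center,
                                state$spec$axis, state$spec$outer,
                                state$spec$inner)
      angles <- helix_transverse_angles(state$eigen, frame)
      prof <- transmural_profile(angles$ha, frame, config$metrics$n_bins)
      write_profile(prof, file.path(out_dir, "profile.csv"))
      state$maps$ha <<- angles$ha
      state$maps$profile <<- prof
      logf("helix-angle span: %.1f deg", attr(prof, "span_deg"))
    }
  })

  run_stage("track", function() {
    tr <- config$track
    tracks <- track(state$eigen, index = tr$index, step = tr$step,
                    max_angle = tr$max_angle, seeds = tr$seeds,
                    max_points = tr$max_points, interp = tr$interp)
    if (tr$min_length > 0) tracks <- filter_by_length(tracks, tr$min_length)
    display <- if (tr$fraction < 1) subsample(tracks, tr$fraction, config$seed)
               else tracks
    ref <- track_reference(state$eigen)
    write_streamlines(display, file.path(out_dir, "tracks.trk"), ref)
    state$tracks <<- display
    logf("tracks: %d total, %d written", length(tracks$tracks),
         length(display$tracks))
  })

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(state)
}

# a voxel_grid covering the eigen-field centre grid (reference for .trk);
# padded by one stride so bidirectional tracks stay inside bounds
track_reference <- function(eigen) {
  nd <- dim(eigen$count)
  s <- eigen$stride
  voxel_grid(array(0, nd + 2L), rep(s, 3), eigen$origin - s)
}
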