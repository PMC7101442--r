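test_that("voxel grids enforce geometry invariants and map indices to physical um", {
  expect_error(voxel_grid(array(0, c(4, 4, 2)), spacing = c(0, 1, 1)), "positive")
  expect_error(voxel_grid(matrix(0, 4, 4), spacing = c(1, 1, 1)), "3D")
  g <- voxel_grid(array(0, c(8, 8, 4)), spacing = c(1.2, 1.2, 4), origin = c(3, -1, 0))
  expect_equal(index_to_phys(g, c(1, 1, 1)), matrix(c(3, -1, 0), 1, 3))
  expect_equal(index_to_phys(g, c(2, 3, 4)), matrix(c(3 + 1.2, -1 + 2.4, 12), 1, 3))
  # inverse identity on random indices
  set.seed(1)
  ijk <- cbind(sample(8, 20, TRUE), sample(8, 20, TRUE), sample(4, 20, TRUE))
  expect_equal(phys_to_index(g, index_to_phys(g, ijk)), ijk + 0,
               tolerance = 1e-12)
  expect_error(binary_mask(array(2, c(2, 2, 2)), c(1, 1, 1)), "0 and 1")
  expect_error(label_volume(array(-1, c(2, 2, 2)), c(1, 1, 1)), "nonnegative")
})

test_that("TIFF volume round trip preserves shape, spacing and intensities", {
  g <- voxel_grid(array(runif(5 * 6 * 7, -3, 10), c(5, 6, 7)),
                  spacing = c(1.2, 1.2, 4))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(g, f)
  g2 <- read_volume(f)
  expect_equal(dim(g2$data), c(5L, 6L, 7L))
  expect_equal(g2$spacing, c(1.2, 1.2, 4))
  expect_equal(g2$data, g$data, tolerance = 1e-6)  # float32 storage
  # masks round trip exactly, and explicit spacing overrides the sidecar
  mk <- binary_mask(array(as.integer(runif(4 * 4 * 3) > 0.5), c(4, 4, 3)), c(2, 2, 2))
  fm <- withr::local_tempfile(fileext = ".tif")
  write_volume(mk, fm)
  mk2 <- read_volume(fm, spacing = c(1, 1, 5))
  expect_identical(mk2$data, mk$data)
  expect_equal(mk2$spacing, c(1, 1, 5))
  expect_error(read_volume(file.path(tempdir(), "nope.tif")), "no such file")
  expect_error(read_volume(fm, spacing = c(0, 1, 1)), "positive")
})

test_that("NRRD tensor files use the fixed 7-component layout and round trip", {
  cm <- array(0, c(6, 1, 1, 1))
  cm[, 1, 1, 1] <- c(1, 0, 0, 2, 0, 3)      # diag(1, 2, 3)
  fld <- tensor_field(cm, array(5L, c(1, 1, 1)), origin = c(0, 0, 0),
                      stride = 20, window = 90, min_count = 2L)
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_tensor_field(fld, f)
  # the on-disk payload begins with the component vector (1,0,0,2,0,3,5)
  back <- read_tensor_field(f)
  expect_equal(as.vector(back$cm[, 1, 1, 1]), c(1, 0, 0, 2, 0, 3))
  expect_equal(back$count[1, 1, 1], 5L)
  expect_equal(back$window, 90)
  # random symmetric field round trips to 1e-12
  set.seed(3)
  d <- random_descriptor_set(120)
  fld2 <- compute_tensor_field(d, 40, 20, 2)
  f2 <- withr::local_tempfile(fileext = ".nrrd")
  write_tensor_field(fld2, f2)
  back2 <- read_tensor_field(f2)
  expect_lt(max(abs(back2$cm - fld2$cm)), 1e-12)
  expect_identical(back2$count, fld2$count)
  expect_equal(back2$origin, fld2$origin)
  # asymmetric full-matrix input is rejected before any write
  bad <- array(0, c(3, 3, 1, 1, 1))
  bad[, , 1, 1, 1] <- matrix(c(1, 5, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  expect_error(tensor_field(bad, array(1L, c(1, 1, 1)), c(0, 0, 0), 1, 1),
               "symmetric")
})

test_that("TrackVis files carry counts and round trip coordinates at float32 precision", {
  ref <- voxel_grid(array(0, c(30, 30, 10)), spacing = c(2, 2, 4))
  trks <- structure(list(
    tracks = list(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                  rbind(c(10, 10, 10), c(12, 11, 10), c(14, 12, 10))),
    reasons = matrix("boundary", 2, 2),
    params = list(step = 1, max_angle = 35), n_omitted = 0L),
    class = "streamline_set")
  f <- withr::local_tempfile(fileext = ".trk")
  write_streamlines(trks, f, ref)
  con <- file(f, "rb"); invisible(readBin(con, "raw", 988))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  close(con)
  expect_identical(n_count, 2L)
  back <- read_streamlines(f)
  expect_length(back$tracks, 2)
  for (i in 1:2)
    expect_equal(back$tracks[[i]], trks$tracks[[i]], tolerance = 1e-6)
  # out-of-bounds and NaN points are rejected
  bad <- trks; bad$tracks[[1]][2, 1] <- 500
  expect_error(write_streamlines(bad, f, ref), "bounds")
  nan <- trks; nan$tracks[[2]][1, 3] <- NaN
  expect_error(write_streamlines(nan, f, ref), "NaN")
  # empty set is legal with n_count = 0
  empty <- trks; empty$tracks <- list(); empty$reasons <- matrix(character(0), ncol = 2)
  write_streamlines(empty, f, ref)
  expect_length(read_streamlines(f)$tracks, 0)
})

test_that("skeleton graphs round trip through GraphML and CSV with attributes", {
  nodes <- data.frame(id = 1:3, x = c(0, 9, 9), y = c(0, 0, 5), z = c(1, 1, 1),
                      class = c("endpoint", "junction", "endpoint"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c(1L, 2L), to = c(2L, 3L),
                      length_um = c(9, 5), n_slab_voxels = c(8L, 4L))
  g <- skeleton_graph(nodes, edges)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(g, f)
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='node']"), 3)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='edge']"), 2)
  back <- read_graph_file(f)
  expect_equal(back$nodes[order(back$nodes$id), ], nodes,
               ignore_attr = TRUE)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(back$edges), key(edges))
  expect_equal(sort(back$edges$length_um), sort(edges$length_um))
  # CSV dialect writes a node and an edge table
  fc <- withr::local_tempfile(fileext = ".csv")
  write_graph_file(g, fc, dialect = "csv")
  backc <- read_graph_file(fc, dialect = "csv")
  expect_equal(backc$nodes, nodes, ignore_attr = TRUE)
  expect_equal(backc$edges, edges, ignore_attr = TRUE)
  # empty graph is a valid file with zero nodes
  g0 <- skeleton_graph(nodes[0, ], edges[0, ], list())
  write_graph_file(g0, f)
  expect_equal(nrow(read_graph_file(f)$nodes), 0)
})

test_that("map export writes DEC pixels and scalar sidecars as specified", {
  nd <- c(2L, 2L, 1L)
  rgb <- array(0, c(3, nd))
  rgb[, 1, 1, 1] <- c(1, 0, 0)
  rgb[, 2, 1, 1] <- c(0, 0, 1)
  m <- rgb_map(rgb, c(0, 0, 0), 10)
  f <- withr::local_tempfile(fileext = ".png")
  export_map(m, f, slice = 1)
  px <- png::readPNG(f)
  expect_equal(px[1, 1, ], c(1, 0, 0))       # pure x-direction -> red
  expect_equal(px[1, 2, ], c(0, 0, 1))       # pure z-direction -> blue
  # constant scalar map -> uniform image; sidecar records the true range
  sm <- scalar_map(array(0.5, c(3, 3, 1)), c(0, 0, 0), 10)
  fs <- withr::local_tempfile(fileext = ".png")
  export_map(sm, fs, slice = 1)
  expect_equal(length(unique(as.vector(png::readPNG(fs)))), 1)
  sm2 <- scalar_map(array(seq(0, 0.5, length.out = 9), c(3, 3, 1)), c(0, 0, 0), 10)
  export_map(sm2, fs, slice = 1)
  sidecar <- readLines(paste0(fs, ".scale.txt"))
  expect_match(sidecar[1], "^min 0$")
  expect_match(sidecar[2], "^max 0.5$")
  all_nan <- scalar_map(array(NaN, c(2, 2, 1)), c(0, 0, 0), 10)
  expect_error(export_map(all_nan, fs, slice = 1), "NaN")
})

test_that("glyph export produces ellipsoids with sqrt-eigenvalue radii", {
  e <- diag_eigen_field(c(4, 1, 1))
  f <- withr::local_tempfile(fileext = ".vtk")
  export_glyphs(e, f, scale = 2)
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET POLYDATA")
  npts <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  expect_gt(npts, 0)
  first <- grep("^POINTS", lines) + 1
  pts <- do.call(rbind, lapply(strsplit(lines[first:(first + npts - 1)], " "),
                               as.numeric))
  ctr <- sweep(pts, 2, c(0, 0, 0))
  # extent along x is scale*sqrt(4) = 4; along y and z scale*sqrt(1) = 2
  expect_equal(max(abs(ctr[, 1])), 4, tolerance = 1e-3)
  expect_equal(max(abs(ctr[, 2])), 2, tolerance = 1e-3)
  expect_equal(max(abs(ctr[, 3])), 2, tolerance = 1e-3)
  # isotropic tensor -> sphere: all vertices at equal radius
  es <- diag_eigen_field(c(2, 2, 2))
  export_glyphs(es, f, scale = 1)
  lines <- readLines(f)
  npts <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  first <- grep("^POINTS", lines) + 1
  pts <- do.call(rbind, lapply(strsplit(lines[first:(first + npts - 1)], " "),
                               as.numeric))
  expect_equal(sd(sqrt(rowSums(pts^2))), 0, tolerance = 1e-3)
  # zero valid centres -> empty polydata, still a valid file
  e0 <- eigendecompose(tensor_field(array(0, c(6, 1, 1, 1)), array(0L, c(1, 1, 1)),
                                    c(0, 0, 0), 1, 1))
  export_glyphs(e0, f, scale = 1)
  expect_match(readLines(f)[5], "^POINTS 0")
  expect_error(export_glyphs(e, f, scale = 0), "positive")
})
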