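#' Baseline threshold-and-clean binarization
#'
#' A deliberately simple segmentation stand-in: voxels at or above
#' `threshold` are foreground, then 26-connected components smaller than
#' `min_object_voxels` are removed. The tensor-field framework is
#' independent of how the binary mask was produced; any external
#' segmentation can be supplied instead via [read_volume()].
#'
#' @param volume a [voxel_grid()] of intensities.
#' @param threshold intensity cut (foreground is `>= threshold`).
#' @param min_object_voxels components with fewer voxels are dropped.
#' @return a [binary_mask()].
#' @export
binarize_baseline <- function(volume, threshold, min_object_voxels = 0L) {
  stopifnot(inherits(volume, "voxel_grid"))
  m <- array(as.integer(volume$data >= threshold), dim(volume$data))
  if (min_object_voxels > 0L && any(m > 0L)) {
    lab <- label_components_cpp(m)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_voxels)
    m <- array(as.integer(lab %in% keep & lab > 0L), dim(m))
  }
  binary_mask(m, volume$spacing, volume$origin)
}

#' Medial-axis thinning of a binary mask
#'
#' Lee-style 3D thinning: an iterative erosion that peels simple border
#' voxels from six directions per pass until only the unit-width centreline
#' remains. Deletions preserve topology ((26, 6) connectivity pair) and
#' branch end points, so the skeleton has the same number of 26-connected
#' components as the input mask. Runs on the voxel grid; spacing only
#' matters downstream.
#'
#' @param mask a [binary_mask()]; may be empty (empty skeleton returned).
#' @return the skeleton as a `skeleton_mask` (a [binary_mask()] subclass).
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  thin <- thin_mask_cpp(array(as.integer(mask$data != 0L), dim(mask$data)))
  out <- binary_mask(thin, mask$spacing, mask$origin)
  class(out) <- c("skeleton_mask", class(out))
  out
}

#' Classify skeleton voxels by neighbour count
#'
#' Counts each skeleton voxel's 26-neighbours that are themselves skeleton
#' voxels and classifies: end-point (fewer than 2 neighbours, which
#' includes isolated voxels), slab (exactly 2), junction (more than 2).
#'
#' @param skeleton a `skeleton_mask` from [skeletonize()].
#' @return integer array over the grid: 0 background, 1 end-point, 2 slab,
#'   3 junction; attribute `counts` holds the per-voxel neighbour counts.
#' @export
classify_voxels <- function(skeleton) {
  stopifnot(inherits(skeleton, "binary_mask"))
  nb <- neighbor_count_cpp(array(as.integer(skeleton$data != 0L), dim(skeleton$data)))
  cls <- array(0L, dim(skeleton$data))
  fg <- !is.na(nb)
  cls[fg & nb < 2L] <- 1L
  cls[fg & nb == 2L] <- 2L
  cls[fg & nb > 2L] <- 3L
  attr(cls, "counts") <- nb
  cls
}

#' Skeleton graphs
#'
#' @param nodes data frame `id, x, y, z, class` (positions um; class
#'   `"endpoint"`, `"junction"` or `"cycle"`).
#' @param edges data frame `from, to, length_um, n_slab_voxels`.
#' @param paths list (one per edge) of n x 3 matrices of slab voxel
#'   positions (um) along the edge, possibly 0-row.
#' @return object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, edges, paths = rep(list(matrix(numeric(0), ncol = 3)),
                                                     nrow(edges))) {
  stopifnot(all(c("id", "x", "y", "z", "class") %in% names(nodes)),
            all(c("from", "to", "length_um", "n_slab_voxels") %in% names(edges)),
            length(paths) == nrow(edges))
  if (nrow(edges) && any(edges$length_um <= 0))
    stop("edge lengths must be positive")
  structure(list(nodes = nodes, edges = edges, paths = paths),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes (%d junctions, %d endpoints), %d edges, total length %.4g um\n",
              nrow(x$nodes), sum(x$nodes$class == "junction"),
              sum(x$nodes$class == "endpoint"), nrow(x$edges),
              sum(x$edges$length_um)))
  invisible(x)
}

#' Build the node/branch graph of a skeleton
#'
#' End-point and junction voxels that touch (26-connectivity) are merged
#' into a single node placed at the cluster centroid — thinning routinely
#' leaves small clumps of mutually adjacent junction voxels at bifurcations
#' and merging them mirrors the behaviour of standard skeleton-analysis
#' tools. Edges are traced through slab-voxel chains between node clusters;
#' edge length is the sum of inter-voxel distances in physical um along the
#' path (entry node voxel, slabs, exit node voxel), honouring anisotropic
#' spacing. Isolated voxels become edge-less end-point nodes; slab-only
#' cycles get one promoted node (class `"cycle"`) and a self-loop so every
#' slab voxel belongs to exactly one edge path.
#'
#' @param skeleton a `skeleton_mask`.
#' @param prune_below if positive, terminal branches (edges ending in a
#'   degree-1 end-point node) shorter than this many um are removed.
#' @return a [skeleton_graph()].
#' @export
build_graph <- function(skeleton, prune_below = 0) {
  stopifnot(inherits(skeleton, "binary_mask"))
  d <- dim(skeleton$data)
  cls <- classify_voxels(skeleton)
  fg <- which(skeleton$data != 0L)
  if (!length(fg)) {
    return(skeleton_graph(
      data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), class = character(0)),
      data.frame(from = integer(0), to = integer(0), length_um = numeric(0),
                 n_slab_voxels = integer(0)),
      list()))
  }
  is_node <- array(cls == 1L | cls == 3L, d)
  node_lab <- label_components_cpp(array(as.integer(is_node), d))
  n_clusters <- max(node_lab)

  arr_ind <- function(lin) arrayInd(lin, d)
  phys <- function(lin) index_to_phys(skeleton, arr_ind(lin))
  # 26-neighbour linear indices that are skeleton voxels
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  neighbors <- function(lin) {
    ijk <- arr_ind(lin)[1, ]
    nb <- cbind(ijk[1] + off[, 1], ijk[2] + off[, 2], ijk[3] + off[, 3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lins <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    lins[skeleton$data[lins] != 0L]
  }
  path_length <- function(pts) {
    if (nrow(pts) < 2) return(0)
    sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
  }

  # nodes
  nodes <- data.frame(id = seq_len(n_clusters), x = 0, y = 0, z = 0,
                      class = "endpoint", stringsAsFactors = FALSE)
  for (c_id in seq_len(n_clusters)) {
    mem <- which(node_lab == c_id)
    pos <- phys(mem)
    nodes[c_id, c("x", "y", "z")] <- colMeans(pos)
    nodes$class[c_id] <- if (any(cls[mem] == 3L)) "junction" else "endpoint"
  }

  visited <- array(FALSE, d)
  efrom <- eto <- integer(0); elen <- numeric(0); enslab <- integer(0)
  paths <- list()
  add_edge <- function(from, to, pts_all, nslab, slab_pts) {
    efrom <<- c(efrom, from); eto <<- c(eto, to)
    elen <<- c(elen, path_length(pts_all)); enslab <<- c(enslab, nslab)
    paths[[length(paths) + 1L]] <<- slab_pts
  }

  node_voxels <- which(node_lab > 0L)
  contact_seen <- character(0)
  for (nv in node_voxels) {
    for (s in neighbors(nv)) {
      if (node_lab[s] > 0L) {
        a <- node_lab[nv]; b <- node_lab[s]
        if (a != b) {
          key <- paste(min(a, b), max(a, b))
          if (!(key %in% contact_seen)) {
            contact_seen <- c(contact_seen, key)
            add_edge(min(a, b), max(a, b), rbind(phys(nv), phys(s)), 0L,
                     matrix(numeric(0), ncol = 3))
          }
        }
        next
      }
      if (cls[s] != 2L || visited[s]) next
      # walk the slab chain
      chain <- s; visited[s] <- TRUE
      prev <- nv; cur <- s; end_cluster <- NA_integer_; end_voxel <- NA_integer_
      repeat {
        nbrs <- neighbors(cur)
        nxt <- nbrs[nbrs != prev]
        # prefer a node terminus; guard against odd geometry
        node_next <- nxt[node_lab[nxt] > 0L]
        if (length(node_next)) { end_cluster <- node_lab[node_next[1]]
                                 end_voxel <- node_next[1]; break }
        nxt <- nxt[cls[nxt] == 2L & !visited[nxt]]
        if (!length(nxt)) break        # dead end (shouldn't occur for slabs)
        prev <- cur; cur <- nxt[1]
        visited[cur] <- TRUE; chain <- c(chain, cur)
      }
      if (is.na(end_cluster)) next
      slab_pts <- phys(chain)
      add_edge(node_lab[nv], end_cluster,
               rbind(phys(nv), slab_pts, phys(end_voxel)),
               length(chain), slab_pts)
    }
  }

  # slab-only cycles: no end point or junction anywhere on the loop
  leftover <- which(cls == 2L & !visited)
  while (length(leftover)) {
    s <- leftover[1]
    chain <- s; visited[s] <- TRUE
    nb0 <- neighbors(s)
    prev <- s; cur <- nb0[1]
    while (cur != s) {
      visited[cur] <- TRUE; chain <- c(chain, cur)
      nbrs <- neighbors(cur); nxt <- nbrs[nbrs != prev][1]
      prev <- cur; cur <- nxt
    }
    nid <- nrow(nodes) + 1L
    p0 <- phys(s)
    nodes <- rbind(nodes, data.frame(id = nid, x = p0[1], y = p0[2], z = p0[3],
                                     class = "cycle", stringsAsFactors = FALSE))
    pts <- rbind(phys(chain), p0)
    add_edge(nid, nid, pts, length(chain) - 1L, phys(chain[-1]))
    leftover <- which(cls == 2L & !visited)
  }

  edges <- data.frame(from = efrom, to = eto, length_um = elen,
                      n_slab_voxels = enslab)
  g <- skeleton_graph(nodes, edges, paths)
  if (prune_below > 0) g <- prune_graph(g, prune_below)
  g
}

# Remove spurious short terminal branches (thinning artifacts at oblique
# junctions), then dissolve the degree-2 nodes this leaves behind by
# merging their two incident edges; iterate until stable.
prune_graph <- function(graph, min_um) {
  repeat {
    deg <- table(factor(c(graph$edges$from, graph$edges$to),
                        levels = graph$nodes$id))
    terminal <- graph$nodes$id[deg == 1 & graph$nodes$class == "endpoint"]
    drop <- which((graph$edges$from %in% terminal | graph$edges$to %in% terminal) &
                    graph$edges$length_um < min_um &
                    graph$edges$from != graph$edges$to)
    if (!length(drop)) break
    dropped_tips <- intersect(terminal, c(graph$edges$from[drop],
                                          graph$edges$to[drop]))
    graph$edges <- graph$edges[-drop, , drop = FALSE]
    graph$paths <- graph$paths[-drop]
    graph$nodes <- graph$nodes[!(graph$nodes$id %in% dropped_tips) |
                                 graph$nodes$id %in% c(graph$edges$from,
                                                       graph$edges$to), ,
                               drop = FALSE]
    graph <- dissolve_degree2(graph)
  }
  graph
}

# merge the two edges of every degree-2 pass-through node into one
dissolve_degree2 <- function(graph) {
  repeat {
    deg <- table(factor(c(graph$edges$from, graph$edges$to),
                        levels = graph$nodes$id))
    cand <- graph$nodes$id[deg == 2]
    # only dissolve nodes both of whose edges are distinct (not a self-loop)
    done <- TRUE
    for (n in cand) {
      ei <- which(graph$edges$from == n | graph$edges$to == n)
      if (length(ei) != 2L) next             # self-loop counted twice
      e1 <- graph$edges[ei[1], ]; e2 <- graph$edges[ei[2], ]
      a <- if (e1$from == n) e1$to else e1$from
      b <- if (e2$from == n) e2$to else e2$from
      npos <- unlist(graph$nodes[graph$nodes$id == n, c("x", "y", "z")])
      p1 <- graph$paths[[ei[1]]]     # orient a -> n
      if (e1$to != n && nrow(p1)) p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]
      p2 <- graph$paths[[ei[2]]]     # orient n -> b
      if (e2$from != n && nrow(p2)) p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
      merged <- data.frame(from = a, to = b,
                           length_um = e1$length_um + e2$length_um,
                           n_slab_voxels = e1$n_slab_voxels + e2$n_slab_voxels + 1L)
      graph$edges <- rbind(graph$edges[-ei, , drop = FALSE], merged)
      graph$paths <- c(graph$paths[-ei],
                       list(rbind(p1, matrix(npos, 1, 3), p2)))
      graph$nodes <- graph$nodes[graph$nodes$id != n, , drop = FALSE]
      done <- FALSE
      break
    }
    if (done) break
  }
  rownames(graph$edges) <- NULL
  graph
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b [binary_mask()]s of identical shape.
#' @return overlap fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$data), dim(b$data))) stop("mask shapes differ")
  na <- sum(a$data != 0L); nb <- sum(b$data != 0L)
  if (na + nb == 0L) return(1)
  2 * sum(a$data != 0L & b$data != 0L) / (na + nb)
}
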