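#' Build a regular source grid
#'
#' Constructs a regular cubic lattice of source nodes, the geometry on which
#' source-reconstructed power is analysed. Spatial adjacency joins pairs of
#' nodes whose Euclidean distance is at most \code{1.05 * spacing}, i.e.
#' face neighbours only (6-connectivity); the 1.05 factor absorbs
#' floating-point error in stored coordinates.
#'
#' @param shape integer vector of length 3, number of nodes along x, y, z.
#' @param spacing grid spacing in mm (single positive number).
#' @param roi_labels optional character vector of region labels, one per
#'   node, or \code{NULL}.
#' @return An object of class \code{source_space}: a list with
#'   \code{node_ids} (stable integer ids), \code{coords} (n x 3 matrix, mm),
#'   \code{spacing}, \code{roi_labels} (or \code{NULL}), and
#'   \code{adjacency}, a two-column integer matrix of undirected edges
#'   (each pair listed once, \code{from < to}).
#' @examples
#' sp <- make_grid(c(3, 3, 3), spacing = 10)
#' nrow(sp$coords)      # 27 nodes
#' nrow(sp$adjacency)   # 54 face-neighbour edges
#' @export
make_grid <- function(shape, spacing, roi_labels = NULL) {
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1) ||
      any(shape != round(shape)))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number", call. = FALSE)
  shape <- as.integer(shape)
  n <- prod(shape)
  ijk <- as.matrix(expand.grid(i = seq_len(shape[1]),
                               j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  coords <- (ijk - 1L) * spacing
  colnames(coords) <- c("x", "y", "z")
  if (!is.null(roi_labels)) {
    if (length(roi_labels) != n)
      stop("`roi_labels` must have one label per node (", n, ")",
           call. = FALSE)
    roi_labels <- as.character(roi_labels)
  }
  adjacency <- lattice_edges(shape)
  structure(list(node_ids = seq_len(n), coords = coords, spacing = spacing,
                 roi_labels = roi_labels, adjacency = adjacency),
            class = "source_space")
}

# Face-neighbour edges of a regular lattice, from < to, without computing
# all pairwise distances (equivalent to distance <= 1.05 * spacing).
lattice_edges <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  id <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  full <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  from <- integer(0); to <- integer(0)
  for (axis in 1:3) {
    keep <- full[[axis]] < shape[axis]
    a <- full[keep, , drop = FALSE]
    b <- a
    b[[axis]] <- b[[axis]] + 1L
    from <- c(from, id(a$i, a$j, a$k))
    to <- c(to, id(b$i, b$j, b$k))
  }
  edges <- cbind(from = from, to = to)
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

#' @export
print.source_space <- function(x, ...) {
  cat("Source space:", length(x$node_ids), "nodes,",
      nrow(x$adjacency), "adjacency edges, spacing", x$spacing, "mm\n")
  if (!is.null(x$roi_labels))
    cat("ROI labels:", length(unique(x$roi_labels)), "regions\n")
  invisible(x)
}

#' Restrict a source space to a set of regions
#'
#' Drops nodes outside the kept regions and induces the adjacency on the
#' survivors. Node ids are preserved so that downstream cluster reports can
#' reference the original grid.
#'
#' @param space a \code{source_space} with \code{roi_labels}.
#' @param keep character vector of region names to keep.
#' @return A \code{source_space} containing only the kept nodes.
#' @export
restrict_to_rois <- function(space, keep) {
  stopifnot(inherits(space, "source_space"))
  if (is.null(space$roi_labels))
    stop("source space has no ROI labels", call. = FALSE)
  valid <- unique(space$roi_labels)
  unknown <- setdiff(keep, valid)
  if (length(unknown))
    stop("unknown region name(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  sel <- space$roi_labels %in% keep
  ids <- space$node_ids[sel]
  in_keep <- space$adjacency[, 1L] %in% ids & space$adjacency[, 2L] %in% ids
  structure(list(node_ids = ids,
                 coords = space$coords[sel, , drop = FALSE],
                 spacing = space$spacing,
                 roi_labels = space$roi_labels[sel],
                 adjacency = space$adjacency[in_keep, , drop = FALSE]),
            class = "source_space")
}

#' Spatial neighbours of a node
#'
#' @param space a \code{source_space}.
#' @param node a node id present in the space.
#' @return Integer vector of node ids sharing an adjacency edge with
#'   \code{node} (possibly empty).
#' @export
spatial_neighbors <- function(space, node) {
  stopifnot(inherits(space, "source_space"))
  if (!(node %in% space$node_ids))
    stop("unknown node id: ", node, call. = FALSE)
  e <- space$adjacency
  sort(c(e[e[, 1L] == node, 2L], e[e[, 2L] == node, 1L]))
}

# Adjacency list indexed by position in space$node_ids; each element holds
# the *positions* (not ids) of the spatial neighbours. Used by the
# clustering engine.
adjacency_list <- function(space) {
  n <- length(space$node_ids)
  pos <- integer(max(space$node_ids))
  pos[space$node_ids] <- seq_len(n)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- integer(0)
  e <- space$adjacency
  if (nrow(e)) {
    a <- pos[e[, 1L]]; b <- pos[e[, 2L]]
    for (r in seq_along(a)) {
      out[[a[r]]] <- c(out[[a[r]]], b[r])
      out[[b[r]]] <- c(out[[b[r]]], a[r])
    }
  }
  out
}
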