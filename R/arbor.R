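#' Construct an arbor (rooted dendritic tree)
#'
#' An `arbor` is the unit of all single-cell morphometry: a rooted tree of 3-D
#' nodes with radii, in SWC node order (every parent precedes its children).
#' Node types follow the SWC convention used throughout: soma nodes carry type
#' 1, dendrite nodes type 3.
#'
#' @param nodes data.frame with columns `id` (integer), `parent` (integer, -1
#'   for the root), `x`, `y`, `z` (micrometers), `radius` (micrometers), and
#'   `type` (1 = soma, 3 = dendrite).
#' @return An object of class `arbor`.
#' @examples
#' nodes <- data.frame(id = 1:3, parent = c(-1L, 1L, 2L),
#'                     x = c(0, 10, 20), y = 0, z = 0,
#'                     radius = c(5, 0.4, 0.4), type = c(1L, 3L, 3L))
#' a <- arbor(nodes)
#' total_length(a)
#' @export
arbor <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  required <- c("id", "parent", "x", "y", "z", "radius", "type")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("arbor nodes missing columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- nodes[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$type <- as.integer(nodes$type)
  obj <- structure(list(nodes = nodes), class = "arbor")
  validate_arbor(obj)
  obj
}

#' Validate arbor invariants
#'
#' Checks: exactly one root, unique ids, each parent defined before its child,
#' non-negative radii. A connected acyclic tree follows from the
#' parent-before-child ordering plus a single root.
#'
#' @param x an `arbor`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_arbor <- function(x) {
  nodes <- x$nodes
  if (nrow(nodes) == 0) stop("arbor has no nodes")
  if (anyDuplicated(nodes$id)) stop("arbor node ids are not unique")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L) stop("arbor must have exactly one root, found ", length(roots))
  if (any(nodes$radius < 0)) stop("arbor radii must be non-negative")
  # parent must appear earlier in the table than the child
  pos <- match(nodes$parent, nodes$id)
  child_rows <- which(nodes$parent != -1L)
  if (anyNA(pos[child_rows])) stop("arbor has a parent id that is not a node id")
  if (any(pos[child_rows] >= child_rows)) {
    stop("arbor nodes must be ordered parent-before-child")
  }
  invisible(x)
}

#' @export
print.arbor <- function(x, ...) {
  n <- nrow(x$nodes)
  n_soma <- sum(x$nodes$type == 1L)
  cat(sprintf("<arbor> %d nodes (%d soma, %d dendrite), radial extent %.1f um\n",
              n, n_soma, sum(x$nodes$type == 3L), radial_extent(x)))
  invisible(x)
}

#' Soma center of an arbor
#'
#' Centroid of all soma-typed nodes; if the reconstruction has no soma node,
#' the root node stands in.
#'
#' @param arbor an `arbor`.
#' @return numeric xyz of length 3.
#' @export
soma_center <- function(arbor) {
  nodes <- arbor$nodes
  soma <- nodes[nodes$type == 1L, , drop = FALSE]
  if (nrow(soma) == 0) soma <- nodes[nodes$parent == -1L, , drop = FALSE]
  c(x = mean(soma$x), y = mean(soma$y), z = mean(soma$z))
}

#' Radial extent of an arbor
#'
#' Maximum Euclidean node distance from the soma center; the radial distance
#' used to normalize Sholl profiles and puncta positions.
#'
#' @param arbor an `arbor`.
#' @return micrometers.
#' @export
radial_extent <- function(arbor) {
  ctr <- soma_center(arbor)
  nodes <- arbor$nodes
  max(sqrt((nodes$x - ctr[1])^2 + (nodes$y - ctr[2])^2 + (nodes$z - ctr[3])^2))
}

# parent->child segment table; keeps only segments whose child is a dendrite
# node unless keep_soma, so soma-internal edges never count toward length or
# Sholl crossings.
arbor_segments <- function(arbor, keep_soma = FALSE) {
  nodes <- arbor$nodes
  child <- nodes[nodes$parent != -1L, , drop = FALSE]
  pidx <- match(child$parent, nodes$id)
  seg <- data.frame(
    child_id = child$id, parent_id = child$parent,
    x0 = nodes$x[pidx], y0 = nodes$y[pidx], z0 = nodes$z[pidx],
    x1 = child$x, y1 = child$y, z1 = child$z,
    child_type = child$type, parent_type = nodes$type[pidx]
  )
  if (!keep_soma) {
    seg <- seg[!(seg$child_type == 1L & seg$parent_type == 1L), , drop = FALSE]
  }
  seg
}

#' Read a neuron reconstruction from an SWC file
#'
#' Accepts the standard 7-column SWC layout (id, type, x, y, z, radius,
#' parent), `#` comment lines, and space or tab delimiters.
#'
#' @param path file path.
#' @return an `arbor`.
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#", header = FALSE,
                           col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  arbor(data.frame(id = raw$id, parent = raw$parent, x = raw$x, y = raw$y,
                   z = raw$z, radius = raw$radius, type = raw$type))
}

#' Write an arbor to an SWC file
#'
#' @param arbor an `arbor`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(arbor, path) {
  nodes <- arbor$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   nodes$id, nodes$type, nodes$x, nodes$y, nodes$z,
                   nodes$radius, nodes$parent)
  writeLines(c("# SWC: id type x y z radius parent", lines), path)
  invisible(path)
}
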