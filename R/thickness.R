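#' Pair each outer-surface node with its inner-surface counterpart
#'
#' The default pairing is topological: within every solid element the
#' all-outer face and the all-inner face are identified, and each outer node
#' is matched to the inner node it shares an element edge with (the same
#' column of a hexahedron, the opposite triangle vertex of a wedge). A node
#' shared by several elements must receive the same partner from all of
#' them. The `"nearest"` method instead pairs each outer node with the
#' closest inner node by Euclidean distance; it is a fallback for layers
#' whose element-local node ordering is unreliable.
#'
#' @param layer a [solid_shell_layer()].
#' @param method `"topological"` (default) or `"nearest"`.
#' @return A tibble with columns `node_id` (outer) and `inner_id`.
#' @export
pair_inner_outer <- function(layer, method = c("topological", "nearest")) {
  stopifnot(inherits(layer, "solid_shell_layer"))
  method <- match.arg(method)
  if (method == "nearest") {
    co <- coord_matrix(layer)
    pout <- co[as.character(layer$outer_nodes), , drop = FALSE]
    pin <- co[as.character(layer$inner_nodes), , drop = FALSE]
    nn <- nearest_index(pout, pin)
    return(tibble::tibble(node_id = layer$outer_nodes,
                          inner_id = layer$inner_nodes[nn]))
  }
  pair <- new.env(hash = TRUE, parent = emptyenv())
  conflicts <- integer(0)
  elems <- solid_element_nodes(layer$solids)
  for (v in elems) {
    if (length(v) == 8) { faces <- hexa_faces; edges <- hexa_edges }
    else { faces <- penta_faces; edges <- penta_edges }
    fo <- fi <- NULL
    for (fc in faces) {
      if (all(v[fc] %in% layer$outer_nodes)) fo <- fc
      if (all(v[fc] %in% layer$inner_nodes)) fi <- fc
    }
    for (lo in fo) {
      partner <- c(edges[edges[, 1] == lo, 2], edges[edges[, 2] == lo, 1])
      li <- intersect(partner, fi)
      if (length(li) != 1) {
        abort(sprintf("pair_inner_outer: node %d has %d inner partners in one element",
                      v[lo], length(li)))
      }
      key <- as.character(v[lo])
      prev <- pair[[key]]
      if (!is.null(prev) && prev != v[li]) conflicts <- c(conflicts, v[lo])
      pair[[key]] <- v[li]
    }
  }
  if (length(conflicts) > 0) {
    abort(paste0("pair_inner_outer: contradictory pairing across elements for node(s) ",
                 paste(sort(unique(conflicts)), collapse = ", ")))
  }
  unmatched <- layer$outer_nodes[
    !vapply(as.character(layer$outer_nodes),
            function(k) !is.null(pair[[k]]), logical(1))]
  if (length(unmatched) > 0) {
    abort(paste0("pair_inner_outer: outer node(s) in no element: ",
                 paste(head(unmatched, 5), collapse = ", ")))
  }
  tibble::tibble(
    node_id = layer$outer_nodes,
    inner_id = vapply(as.character(layer$outer_nodes),
                      function(k) pair[[k]], integer(1), USE.NAMES = FALSE))
}

# index of the nearest row of `ref` for each row of `q` (dense search; the
# meshes handled here are a few thousand nodes at most)
nearest_index <- function(q, ref, chunk = 512L) {
  out <- integer(nrow(q))
  r2 <- rowSums(ref^2)
  for (start in seq(1, nrow(q), by = chunk)) {
    sel <- start:min(start + chunk - 1L, nrow(q))
    d2 <- outer(rowSums(q[sel, , drop = FALSE]^2), r2, "+") -
      2 * q[sel, , drop = FALSE] %*% t(ref)
    out[sel] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Per-node cortical thickness of a solid layer
#'
#' For every outer-surface node, the vector `d` from its paired inner node
#' to the outer node is projected onto the outward unit surface normal
#' `n`: thickness = |d . n|. The projection corrects for element columns
#' that cross the cortical layer obliquely, where the raw inner-outer
#' distance |d| overestimates the true (perpendicular) thickness; the
#' correction factor `alpha = (d . n)/|d|` is returned per node so
#' near-tangent columns can be audited.
#'
#' @param layer a [solid_shell_layer()].
#' @param pairing passed to [pair_inner_outer()].
#' @param weighting passed to [vertex_normals()].
#' @param floor thickness floor in mm (default `1e-6`); nodes at or below it
#'   trigger a warning and are listed in the `qc` attribute.
#' @param alpha_flag nodes with `|alpha|` below this (near-tangent columns,
#'   default 0.2) are listed in the `qc` attribute.
#' @return A tibble with columns `node_id`, `inner_id`, `thickness` (mm) and
#'   `alpha`, one row per outer node, with a `qc` attribute (list of flagged
#'   node ids).
#' @examples
#' shell <- make_solid_shell(fixture_spec(level = 1, thickness = list(
#'   kind = "constant", t0 = 1), radius = 10))
#' summary(nodal_thickness(shell$layer)$thickness)
#' @export
nodal_thickness <- function(layer, pairing = c("topological", "nearest"),
                            weighting = c("area", "angle"),
                            floor = 1e-6, alpha_flag = 0.2) {
  pairs <- pair_inner_outer(layer, method = pairing)
  nrm <- vertex_normals(layer, weighting = match.arg(weighting))
  co <- coord_matrix(layer)
  pout <- co[as.character(pairs$node_id), , drop = FALSE]
  pin <- co[as.character(pairs$inner_id), , drop = FALSE]
  d <- pout - pin
  dn <- sqrt(rowSums(d^2))
  if (any(dn == 0)) {
    abort(paste0("nodal_thickness: zero inner-outer distance at node ",
                 paste(pairs$node_id[dn == 0], collapse = ", ")))
  }
  nm <- as.matrix(nrm[match(pairs$node_id, nrm$node_id), c("nx", "ny", "nz")])
  proj <- rowSums(d * nm)
  thickness <- abs(proj)
  alpha <- proj / dn
  low_t <- pairs$node_id[thickness <= floor]
  low_a <- pairs$node_id[abs(alpha) < alpha_flag]
  if (length(low_t) > 0) {
    warn(paste0("nodal_thickness: ", length(low_t),
                " node(s) at or below the thickness floor (",
                format(floor), " mm); see attr(, 'qc')"))
  }
  out <- tibble::tibble(node_id = pairs$node_id, inner_id = pairs$inner_id,
                        thickness = unname(thickness), alpha = unname(alpha))
  attr(out, "qc") <- list(below_floor = low_t, near_tangent = low_a)
  out
}

#' Summary statistics of a nodal scalar field
#'
#' @param field data frame with a `thickness` column (or any single numeric
#'   column named by `value`).
#' @param value name of the value column (default `"thickness"`).
#' @return A one-row tibble: `n`, `mean`, `sd`, `min`, `max`.
#' @export
thickness_summary <- function(field, value = "thickness") {
  v <- field[[value]]
  if (is.null(v) || length(v) == 0) {
    abort("thickness_summary: empty field")
  }
  tibble::tibble(n = length(v), mean = mean(v), sd = sd(v),
                 min = min(v), max = max(v))
}
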