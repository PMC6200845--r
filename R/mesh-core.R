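#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` holds the node table and face connectivity of a shell
#' mesh, typically the target cortical-bone surface. Faces are triangles or
#' quadrilaterals; quadrilaterals are split into two triangles internally
#' wherever per-triangle geometry is needed (normals, adjacency) while the
#' stored connectivity is preserved on output.
#'
#' @param nodes data frame with columns `node_id` (unique positive integers),
#'   `x`, `y`, `z` (finite coordinates, mm).
#' @param faces data frame with columns `elem_id`, `n1`, `n2`, `n3` and
#'   optionally `n4` (`NA` for triangles); all entries must reference existing
#'   node ids.
#' @param validate check the structural invariants (default `TRUE`).
#' @return An object of class `surface_mesh`: a list with tibbles `nodes` and
#'   `faces`.
#' @seealso [solid_shell_layer()], [read_mesh()], [vertex_normals()],
#'   [node_adjacency()]
#' @examples
#' tet <- surface_mesh(
#'   nodes = data.frame(node_id = 1:4,
#'                      x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1)),
#'   faces = data.frame(elem_id = 1:4,
#'                      n1 = c(1, 1, 1, 2), n2 = c(3, 2, 4, 3),
#'                      n3 = c(2, 4, 3, 4))
#' )
#' node_adjacency(tet)
#' @export
surface_mesh <- function(nodes, faces, validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)[, c("node_id", "x", "y", "z")]
  faces <- tibble::as_tibble(faces)
  if (!"n4" %in% names(faces)) faces$n4 <- NA_integer_
  faces <- faces[, c("elem_id", "n1", "n2", "n3", "n4")]
  nodes$node_id <- as.integer(nodes$node_id)
  for (col in c("n1", "n2", "n3", "n4")) faces[[col]] <- as.integer(faces[[col]])
  # normalise degenerate quads (n4 == n3 or n4 == 0) to triangles
  deg <- !is.na(faces$n4) & (faces$n4 == faces$n3 | faces$n4 == 0L)
  faces$n4[deg] <- NA_integer_
  mesh <- structure(list(nodes = nodes, faces = faces), class = "surface_mesh")
  if (validate) validate_surface_mesh(mesh)
  mesh
}

validate_surface_mesh <- function(mesh) {
  nodes <- mesh$nodes
  faces <- mesh$faces
  if (anyDuplicated(nodes$node_id)) {
    abort("surface_mesh: duplicated node ids")
  }
  if (any(nodes$node_id <= 0L)) abort("surface_mesh: node ids must be positive")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    abort("surface_mesh: non-finite node coordinates")
  }
  ref <- c(faces$n1, faces$n2, faces$n3, faces$n4)
  ref <- ref[!is.na(ref)]
  missing <- setdiff(ref, nodes$node_id)
  if (length(missing) > 0) {
    abort(paste0("surface_mesh: faces reference missing node ids: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  ntri <- sum(is.na(x$faces$n4))
  cat(sprintf("<surface_mesh> %d nodes, %d faces (%d tri, %d quad)\n",
              nrow(x$nodes), nrow(x$faces), ntri, nrow(x$faces) - ntri))
  invisible(x)
}

#' Construct a one-element-thick solid shell layer
#'
#' A `solid_shell_layer` is the source-side representation of cortical bone:
#' a single sheet of hexahedral (8-node) and pentahedral (6-node wedge) solid
#' elements whose two free surfaces are labelled *outer* (periosteal) and
#' *inner* (endosteal). The layer must be exactly one element thick: every
#' node lies on one of the two surfaces, and every element has exactly one
#' face entirely on each surface.
#'
#' @param nodes data frame with columns `node_id`, `x`, `y`, `z` (mm).
#' @param solids data frame with columns `elem_id`, `n1`..`n8`; wedges carry
#'   their six nodes in `n1`..`n6` (bottom triangle then top triangle) with
#'   `n7`, `n8` set to `NA`. Hexahedra are ordered bottom quad `n1`..`n4`,
#'   top quad `n5`..`n8`.
#' @param outer_nodes,inner_nodes integer vectors of node ids on the outer
#'   and inner surfaces.
#' @param validate check the structural invariants (default `TRUE`).
#' @return An object of class `solid_shell_layer`.
#' @seealso [pair_inner_outer()], [nodal_thickness()], [make_solid_shell()]
#' @export
solid_shell_layer <- function(nodes, solids, outer_nodes, inner_nodes,
                              validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)[, c("node_id", "x", "y", "z")]
  solids <- tibble::as_tibble(solids)
  for (col in c("n7", "n8")) if (!col %in% names(solids)) solids[[col]] <- NA_integer_
  solids <- solids[, c("elem_id", paste0("n", 1:8))]
  nodes$node_id <- as.integer(nodes$node_id)
  for (col in paste0("n", 1:8)) solids[[col]] <- as.integer(solids[[col]])
  layer <- structure(
    list(nodes = nodes, solids = solids,
         outer_nodes = sort(as.integer(outer_nodes)),
         inner_nodes = sort(as.integer(inner_nodes))),
    class = "solid_shell_layer")
  if (validate) validate_solid_shell_layer(layer)
  layer
}

#' @export
print.solid_shell_layer <- function(x, ...) {
  nw <- sum(is.na(x$solids$n7))
  cat(sprintf(
    "<solid_shell_layer> %d nodes (%d outer, %d inner), %d solids (%d hexa, %d penta)\n",
    nrow(x$nodes), length(x$outer_nodes), length(x$inner_nodes),
    nrow(x$solids), nrow(x$solids) - nw, nw))
  invisible(x)
}

# local faces/edges of the two supported element types; hexa is bottom quad
# 1-4 + top quad 5-8 with vertical edges i,i+4; wedge is bottom tri 1-3 +
# top tri 4-6 with vertical edges i,i+3
hexa_faces <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                   c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
hexa_edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                    c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                    c(1, 5), c(2, 6), c(3, 7), c(4, 8))
penta_faces <- list(c(1, 2, 3), c(4, 5, 6), c(1, 2, 5, 4),
                    c(2, 3, 6, 5), c(3, 1, 4, 6))
penta_edges <- rbind(c(1, 2), c(2, 3), c(3, 1),
                     c(4, 5), c(5, 6), c(6, 4),
                     c(1, 4), c(2, 5), c(3, 6))

solid_element_nodes <- function(solids) {
  lapply(seq_len(nrow(solids)), function(i) {
    v <- as.integer(solids[i, paste0("n", 1:8)])
    v[!is.na(v)]
  })
}

validate_solid_shell_layer <- function(layer) {
  nodes <- layer$nodes
  if (anyDuplicated(nodes$node_id)) abort("solid_shell_layer: duplicated node ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    abort("solid_shell_layer: non-finite node coordinates")
  }
  if (length(intersect(layer$outer_nodes, layer$inner_nodes)) > 0) {
    abort("solid_shell_layer: inner and outer node sets overlap")
  }
  elems <- solid_element_nodes(layer$solids)
  allref <- unique(unlist(elems))
  missing <- setdiff(allref, nodes$node_id)
  if (length(missing) > 0) {
    abort(paste0("solid_shell_layer: elements reference missing node ids: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  interior <- setdiff(allref, c(layer$outer_nodes, layer$inner_nodes))
  if (length(interior) > 0) {
    abort(paste0(
      "solid_shell_layer: layer is not one element thick; interior nodes: ",
      paste(head(interior, 5), collapse = ", ")))
  }
  is_out <- allref %in% layer$outer_nodes
  names(is_out) <- allref
  for (i in seq_along(elems)) {
    v <- elems[[i]]
    faces <- if (length(v) == 8) hexa_faces else penta_faces
    outer_faces <- sum(vapply(faces, function(f) all(v[f] %in% layer$outer_nodes), logical(1)))
    inner_faces <- sum(vapply(faces, function(f) all(v[f] %in% layer$inner_nodes), logical(1)))
    if (outer_faces != 1L || inner_faces != 1L) {
      abort(sprintf(
        "solid_shell_layer: element %d has %d outer and %d inner faces (expected one of each)",
        layer$solids$elem_id[i], outer_faces, inner_faces))
    }
  }
  invisible(layer)
}

# coordinates as a matrix indexed by node id (rownames = id)
coord_matrix <- function(mesh) {
  m <- as.matrix(mesh$nodes[, c("x", "y", "z")])
  rownames(m) <- as.character(mesh$nodes$node_id)
  m
}

# faces of a surface_mesh as a list of integer node-id vectors, quads split
# into two triangles (diagonal n1-n3)
triangulate_faces <- function(mesh) {
  f <- mesh$faces
  tri <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    if (is.na(f$n4[i])) {
      tri[[i]] <- list(c(f$n1[i], f$n2[i], f$n3[i]))
    } else {
      tri[[i]] <- list(c(f$n1[i], f$n2[i], f$n3[i]),
                       c(f$n1[i], f$n3[i], f$n4[i]))
    }
  }
  unlist(tri, recursive = FALSE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# reorder triangle windings so neighbouring triangles agree across shared
# edges (mesh must be orientable); returns the list of (possibly flipped)
# triangles
orient_consistently <- function(tris) {
  n <- length(tris)
  if (n == 0) return(tris)
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  edge_map <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    v <- tris[[i]]
    for (k in 1:3) {
      key <- edge_key(v[k], v[k %% 3 + 1])
      edge_map[[key]] <- c(edge_map[[key]], i)
    }
  }
  visited <- logical(n)
  for (seed in seq_len(n)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue) > 0) {
      i <- queue[[1]]
      queue <- queue[-1]
      v <- tris[[i]]
      for (k in 1:3) {
        a <- v[k]; b <- v[k %% 3 + 1]
        for (j in edge_map[[edge_key(a, b)]]) {
          if (j == i || visited[j]) next
          w <- tris[[j]]
          # consistent orientation: the shared edge must run in opposite
          # directions in the two triangles
          same_dir <- any(w == a & c(w[2:3], w[1]) == b)
          if (same_dir) tris[[j]] <- rev(w)
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  tris
}

#' Outward unit normals at mesh vertices
#'
#' Computes a per-node unit normal as the weighted average of incident face
#' normals. For a `surface_mesh` the face windings are first made mutually
#' consistent, and the global sign is then fixed so normals point outward:
#' by the sign of the enclosed volume for a closed surface, or, for an open
#' surface (where "outward" is underdetermined), so that the dominant
#' component of the mean normal is positive. Passing a mesh whose windings
#' are all flipped therefore returns the same outward normals. For a
#' `solid_shell_layer` the normals of the outer surface are computed, each
#' face oriented away from its parent element's centroid, so the result
#' always points out of the solid.
#'
#' @param mesh a [surface_mesh()] or [solid_shell_layer()].
#' @param weighting `"area"` (default) weights each incident face normal by
#'   the face area; `"angle"` weights by the incident corner angle.
#' @return A tibble with columns `node_id`, `nx`, `ny`, `nz`; each row a unit
#'   vector. For a `solid_shell_layer` only outer-surface nodes are returned.
#' @examples
#' sph <- icosphere_mesh(level = 2, radius = 10)
#' nrm <- vertex_normals(sph)
#' # radial direction is the exact normal of a sphere
#' max(abs(as.matrix(nrm[, 2:4]) - as.matrix(sph$nodes[, 2:4]) / 10))
#' @export
vertex_normals <- function(mesh, weighting = c("area", "angle")) {
  weighting <- match.arg(weighting)
  if (inherits(mesh, "solid_shell_layer")) {
    surf <- outer_surface_mesh(mesh)
    return(accumulate_normals(surf$tris, coord_matrix_from(surf$nodes),
                              surf$node_ids, weighting))
  }
  if (!inherits(mesh, "surface_mesh")) abort("vertex_normals: unsupported mesh type")
  co <- coord_matrix(mesh)
  tris <- orient_consistently(triangulate_faces(mesh))
  # global outward sign: signed volume if closed, dominant mean-normal axis
  # otherwise
  vol <- 0
  acc <- c(0, 0, 0)
  for (v in tris) {
    a <- co[as.character(v[1]), ]; b <- co[as.character(v[2]), ]
    cc <- co[as.character(v[3]), ]
    vol <- vol + sum(a * cross3(b, cc)) / 6
    acc <- acc + cross3(b - a, cc - a)
  }
  flip <- if (abs(vol) > 1e-9 * max(1, max(abs(co)))^3) {
    vol < 0
  } else {
    k <- which.max(abs(acc))
    acc[k] < 0
  }
  if (flip) tris <- lapply(tris, rev)
  accumulate_normals(tris, co, mesh$nodes$node_id, weighting)
}

coord_matrix_from <- function(nodes) {
  m <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(m) <- as.character(nodes$node_id)
  m
}

accumulate_normals <- function(tris, co, node_ids, weighting) {
  acc <- matrix(0, length(node_ids), 3,
                dimnames = list(as.character(node_ids), NULL))
  for (v in tris) {
    key <- as.character(v)
    a <- co[key[1], ]; b <- co[key[2], ]; cc <- co[key[3], ]
    fn <- cross3(b - a, cc - a)       # |fn| = 2 * area
    nf <- sqrt(sum(fn^2))
    if (nf == 0) next                 # zero-area sliver contributes nothing
    if (weighting == "area") {
      contrib <- rbind(fn, fn, fn) / 2
    } else {
      u <- fn / nf
      ang <- vapply(1:3, function(k) {
        p <- co[key[k], ]
        e1 <- co[key[k %% 3 + 1], ] - p
        e2 <- co[key[(k + 1) %% 3 + 1], ] - p
        acos(pmin(1, pmax(-1, sum(e1 * e2) /
                            sqrt(sum(e1^2) * sum(e2^2)))))
      }, numeric(1))
      contrib <- outer(ang, u)
    }
    present <- key %in% rownames(acc)
    for (k in which(present)) acc[key[k], ] <- acc[key[k], ] + contrib[k, ]
  }
  nrm <- sqrt(rowSums(acc^2))
  bad <- node_ids[nrm < 1e-300]
  if (length(bad) > 0) {
    abort(paste0("vertex_normals: degenerate (zero-area) vertex star at node ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  acc <- acc / nrm
  tibble::tibble(node_id = as.integer(node_ids),
                 nx = unname(acc[, 1]), ny = unname(acc[, 2]),
                 nz = unname(acc[, 3]))
}

# outer-surface triangles of a solid layer, each oriented away from its
# parent element centroid
outer_surface_mesh <- function(layer) {
  co <- coord_matrix(layer)
  elems <- solid_element_nodes(layer$solids)
  out_set <- layer$outer_nodes
  tris <- list()
  for (v in elems) {
    faces <- if (length(v) == 8) hexa_faces else penta_faces
    f <- NULL
    for (fc in faces) if (all(v[fc] %in% out_set)) { f <- v[fc]; break }
    if (is.null(f)) next
    ec <- colMeans(co[as.character(v), , drop = FALSE])
    fco <- co[as.character(f), , drop = FALSE]
    fc_ctr <- colMeans(fco)
    tl <- if (length(f) == 4) list(f[c(1, 2, 3)], f[c(1, 3, 4)]) else list(f)
    for (t3 in tl) {
      a <- co[as.character(t3[1]), ]
      fn <- cross3(co[as.character(t3[2]), ] - a, co[as.character(t3[3]), ] - a)
      if (sum(fn * (fc_ctr - ec)) < 0) t3 <- rev(t3)
      tris[[length(tris) + 1]] <- t3
    }
  }
  ids <- layer$outer_nodes
  list(tris = tris,
       nodes = layer$nodes[layer$nodes$node_id %in% ids, ],
       node_ids = ids)
}

#' Extract the outer surface of a solid layer as a surface mesh
#'
#' Collects the all-outer face of every solid element into a triangulated
#' `surface_mesh` (quadrilateral faces of hexahedra are kept as quads),
#' restricted to outer-surface nodes. Useful for morphing and projection,
#' which operate on the outer surface only.
#'
#' @param layer a [solid_shell_layer()].
#' @return A [surface_mesh()] whose nodes are the layer's outer nodes.
#' @export
outer_surface <- function(layer) {
  stopifnot(inherits(layer, "solid_shell_layer"))
  elems <- solid_element_nodes(layer$solids)
  out_set <- layer$outer_nodes
  rows <- list()
  for (i in seq_along(elems)) {
    v <- elems[[i]]
    faces <- if (length(v) == 8) hexa_faces else penta_faces
    for (fc in faces) {
      if (all(v[fc] %in% out_set)) {
        f <- v[fc]
        rows[[length(rows) + 1]] <-
          c(f, if (length(f) == 3) NA_integer_ else NULL)
        break
      }
    }
  }
  fm <- do.call(rbind, rows)
  faces <- tibble::tibble(elem_id = seq_len(nrow(fm)),
                          n1 = fm[, 1], n2 = fm[, 2], n3 = fm[, 3],
                          n4 = fm[, 4])
  surface_mesh(layer$nodes[layer$nodes$node_id %in% out_set, ], faces)
}

#' Edge adjacency of mesh nodes
#'
#' For every node, lists the node ids sharing a mesh edge with it.
#' Quadrilateral faces are split into two triangles first, so the quad
#' diagonal counts as an edge. The adjacency is symmetric, has no self-loops,
#' and each neighbour list is sorted ascending.
#'
#' @param mesh a [surface_mesh()].
#' @return A named list: one sorted integer vector of neighbour ids per node,
#'   named by node id.
#' @export
node_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tris <- triangulate_faces(mesh)
  adj <- new.env(hash = TRUE, parent = emptyenv())
  for (id in mesh$nodes$node_id) adj[[as.character(id)]] <- integer(0)
  for (v in tris) {
    for (k in 1:3) {
      a <- v[k]; b <- v[k %% 3 + 1]
      adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
      adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
    }
  }
  ids <- sort(mesh$nodes$node_id)
  out <- lapply(ids, function(id) {
    nb <- unique(adj[[as.character(id)]])
    sort(nb[nb != id])
  })
  names(out) <- as.character(ids)
  out
}
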