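# Small meshes built in code for the unit tests.

# n x m grid of unit-height hexahedra: inner nodes at z = 0, outer at z = h,
# optionally sheared so the element columns are oblique
slab_layer <- function(nx = 2, ny = 2, h = 2, shear = c(0, 0)) {
  xs <- seq(0, nx); ys <- seq(0, ny)
  grid <- expand.grid(x = xs, y = ys)
  nbot <- nrow(grid)
  nodes <- tibble::tibble(
    node_id = seq_len(2 * nbot),
    x = c(grid$x, grid$x + shear[1]),
    y = c(grid$y, grid$y + shear[2]),
    z = c(rep(0, nbot), rep(h, nbot)))
  nid <- function(i, j) (j - 1) * (nx + 1) + i     # 1-based grid index
  solids <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      b <- c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1))
      solids[[length(solids) + 1]] <-
        tibble::tibble(elem_id = length(solids) + 1L,
                       n1 = b[1], n2 = b[2], n3 = b[3], n4 = b[4],
                       n5 = b[1] + nbot, n6 = b[2] + nbot,
                       n7 = b[3] + nbot, n8 = b[4] + nbot)
    }
  }
  solid_shell_layer(nodes, dplyr::bind_rows(solids),
                    outer_nodes = nbot + seq_len(nbot),
                    inner_nodes = seq_len(nbot))
}

single_hexa_layer <- function() slab_layer(nx = 1, ny = 1)

tetra_mesh <- function() {
  surface_mesh(
    tibble::tibble(node_id = 1:4,
                   x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1)),
    tibble::tibble(elem_id = 1:4,
                   n1 = c(1, 1, 1, 2), n2 = c(3, 2, 4, 3), n3 = c(2, 4, 3, 4)))
}

flat_grid_mesh <- function(nx = 3, ny = 3, flip = FALSE) {
  grid <- expand.grid(x = seq(0, nx), y = seq(0, ny))
  nid <- function(i, j) (j - 1) * (nx + 1) + i
  faces <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      a <- nid(i, j); b <- nid(i + 1, j); cc <- nid(i + 1, j + 1); d <- nid(i, j + 1)
      faces[[length(faces) + 1]] <- c(a, b, cc)
      faces[[length(faces) + 1]] <- c(a, cc, d)
    }
  }
  fm <- do.call(rbind, faces)
  if (flip) fm <- fm[, c(1, 3, 2)]
  surface_mesh(
    tibble::tibble(node_id = seq_len(nrow(grid)),
                   x = grid$x, y = grid$y, z = 0),
    tibble::tibble(elem_id = seq_len(nrow(fm)),
                   n1 = fm[, 1], n2 = fm[, 2], n3 = fm[, 3]))
}

# brute-force edge set of a triangulated mesh, as a sorted two-column matrix
brute_force_edges <- function(mesh) {
  f <- mesh$faces
  e <- list()
  for (i in seq_len(nrow(f))) {
    v <- as.integer(f[i, c("n1", "n2", "n3", "n4")])
    v <- v[!is.na(v)]
    tris <- if (length(v) == 3) list(v) else list(v[c(1, 2, 3)], v[c(1, 3, 4)])
    for (t3 in tris) {
      for (k in 1:3) {
        a <- t3[k]; b <- t3[k %% 3 + 1]
        e[[length(e) + 1]] <- c(min(a, b), max(a, b))
      }
    }
  }
  unique(do.call(rbind, e))
}

# standard transfer problem built from one fixture spec
transfer_problem <- function(spec, deformation = bulge_deformation(), ...) {
  src <- make_solid_shell(spec)
  pair <- make_target_pair(spec, deformation, ...)
  field <- nodal_thickness(src$layer)
  model <- fit_kriging(pair$landmarks_source, pair$landmarks_target)
  morphed <- morph_mesh(src$surface, model)
  src_nodes <- dplyr::inner_join(morphed$nodes,
                                 field[, c("node_id", "thickness")],
                                 by = "node_id")
  list(src = src, pair = pair, field = field, model = model,
       morphed = morphed, src_nodes = src_nodes)
}
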