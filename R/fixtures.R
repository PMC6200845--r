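# Synthetic two-surface shell fixtures with analytic ground truth. They
# stand in for proprietary anatomical FE meshes: an icosphere-tessellated
# sphere or ellipsoid carries a known spatially varying thickness field, and
# a differently tessellated copy deformed by a known smooth map plays the
# target anatomy, so extraction, morphing and projection can each be checked
# against exact values.

icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    mid_cache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      p <- V[i, ] + V[j, ]
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1]] <<- p
      id <- nv + length(newV)
      mid_cache[[key]] <- id
      id
    }
    newF <- matrix(0L, nrow(F) * 4, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(cc, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  list(V = V, F = F)
}

#' Icosphere surface mesh
#'
#' Near-uniform triangulation of a sphere by recursive subdivision of an
#' icosahedron: \eqn{10 \cdot 4^{level} + 2} nodes and
#' \eqn{20 \cdot 4^{level}} triangles.
#'
#' @param level subdivision level (0 = icosahedron).
#' @param radius sphere radius (mm).
#' @return A [surface_mesh()].
#' @export
icosphere_mesh <- function(level, radius = 1) {
  ic <- icosphere(level)
  surface_mesh(
    tibble::tibble(node_id = seq_len(nrow(ic$V)),
                   x = radius * ic$V[, 1], y = radius * ic$V[, 2],
                   z = radius * ic$V[, 3]),
    tibble::tibble(elem_id = seq_len(nrow(ic$F)),
                   n1 = ic$F[, 1], n2 = ic$F[, 2], n3 = ic$F[, 3]))
}

#' Specify a synthetic shell fixture
#'
#' Describes a closed two-surface shell: the tessellated base surface, the
#' analytic thickness field painted on it, and the seed fixing all
#' randomness. Defaults describe the reference fixture used throughout the
#' package tests: a 10 mm sphere at subdivision level 2 with the
#' latitudinal field \eqn{t(\theta) = 1.5 + 0.5\cos\theta} mm, which spans
#' 1–2 mm like real cortical bone does over most of a coxal surface.
#'
#' @param surface `"sphere"` or `"ellipsoid"`.
#' @param radius sphere radius (mm).
#' @param semi_axes length-3 positive semi-axes (mm) for the ellipsoid.
#' @param level icosphere subdivision level.
#' @param thickness list: `kind = "constant"` (`t0`), `kind = "latitudinal"`
#'   (`t0 + t1 * cos(theta)`, `theta` the polar angle), or `kind = "bumps"`
#'   (`t0` plus `n_bumps` Gaussian patches of amplitude `amp` and angular
#'   width `width`, placed by the seed).
#' @param n_landmarks control points sampled by farthest-point spacing.
#' @param noise_sd Gaussian noise sd (mm) added to target landmarks.
#' @param outlier optional list(`index`, `offset`): displace one target
#'   landmark by `offset` mm in a seeded random direction.
#' @param seed integer seed fixing every random choice.
#' @return A `fixture_spec` list.
#' @seealso [make_solid_shell()], [make_target_pair()]
#' @export
fixture_spec <- function(surface = c("sphere", "ellipsoid"),
                         radius = 10, semi_axes = c(10, 8, 6.5),
                         level = 2,
                         thickness = list(kind = "latitudinal",
                                          t0 = 1.5, t1 = 0.5),
                         n_landmarks = 24, noise_sd = 0, outlier = NULL,
                         seed = 1) {
  surface <- match.arg(surface)
  if (surface == "ellipsoid" && any(semi_axes <= 0)) {
    abort("fixture_spec: semi-axes must be positive")
  }
  if (surface == "sphere" && radius <= 0) abort("fixture_spec: radius must be positive")
  structure(list(surface = surface, radius = radius, semi_axes = semi_axes,
                 level = level, thickness = thickness,
                 n_landmarks = n_landmarks, noise_sd = noise_sd,
                 outlier = outlier, seed = as.integer(seed)),
            class = "fixture_spec")
}

# analytic thickness as a function of unit-sphere parameter points (rows)
thickness_function <- function(spec) {
  th <- spec$thickness
  if (th$kind == "constant") {
    t0 <- th$t0
    return(function(U) rep(t0, nrow(U)))
  }
  if (th$kind == "latitudinal") {
    t0 <- th$t0; t1 <- th$t1
    return(function(U) t0 + t1 * U[, 3])   # cos(theta) = z on the unit sphere
  }
  if (th$kind == "bumps") {
    set.seed(spec$seed + 101L)
    n <- th$n_bumps %||% 4L
    ctr <- matrix(rnorm(3 * n), n, 3)
    ctr <- ctr / sqrt(rowSums(ctr^2))
    amp <- th$amp %||% 0.5
    width <- th$width %||% 0.5
    t0 <- th$t0 %||% 1.5
    return(function(U) {
      ip <- U %*% t(ctr)
      ip[ip > 1] <- 1; ip[ip < -1] <- -1
      ang <- acos(ip)
      t0 + rowSums(amp * exp(-(ang^2) / (2 * width^2)))
    })
  }
  abort(paste0("fixture_spec: unknown thickness kind '", th$kind, "'"))
}

# surface point and outward analytic normal for unit-sphere parameters
surface_geometry <- function(spec, U) {
  if (spec$surface == "sphere") {
    list(p = spec$radius * U, n = U)
  } else {
    ax <- spec$semi_axes
    p <- sweep(U, 2, ax, "*")
    n <- sweep(U, 2, ax, "/")
    list(p = p, n = n / sqrt(rowSums(n^2)))
  }
}

#' Build a one-element-thick solid shell with an analytic thickness field
#'
#' The outer surface is the tessellated fixture surface; each inner node is
#' the outer node offset inward along the analytic surface normal by the
#' local thickness; one wedge element rises over every surface triangle.
#' The returned analytic field handle gives the exact thickness at any
#' unit-sphere parameter point and is the ground truth for
#' [nodal_thickness()].
#'
#' @param spec a [fixture_spec()].
#' @return A list of class `shell_fixture`: `layer`
#'   ([solid_shell_layer()]), `surface` (the outer [surface_mesh()]),
#'   `thickness_fun` (function of an n-by-3 matrix of unit vectors), and
#'   `u` (the outer nodes' parameter points).
#' @export
make_solid_shell <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ic <- icosphere(spec$level)
  U <- ic$V
  tf <- thickness_function(spec)
  tval <- tf(U)
  if (any(tval <= 0)) abort("make_solid_shell: thickness field not strictly positive")
  geom <- surface_geometry(spec, U)
  max_t <- 0.9 * if (spec$surface == "sphere") spec$radius else min(spec$semi_axes)
  if (any(tval >= max_t)) {
    abort("make_solid_shell: thickness exceeds the local curvature radius (self-intersecting shell)")
  }
  pout <- geom$p
  pin <- pout - tval * geom$n
  n <- nrow(U)
  nodes <- tibble::tibble(
    node_id = seq_len(2 * n),
    x = c(pout[, 1], pin[, 1]),
    y = c(pout[, 2], pin[, 2]),
    z = c(pout[, 3], pin[, 3]))
  # outward-wound faces on the parameter sphere
  F <- ic$F
  for (f in seq_len(nrow(F))) {
    a <- U[F[f, 1], ]; b <- U[F[f, 2], ]; cc <- U[F[f, 3], ]
    if (sum(cross3(b - a, cc - a) * (a + b + cc)) < 0) {
      F[f, ] <- F[f, c(1, 3, 2)]
    }
  }
  solids <- tibble::tibble(
    elem_id = seq_len(nrow(F)),
    n1 = F[, 1] + n, n2 = F[, 2] + n, n3 = F[, 3] + n,   # inner triangle
    n4 = F[, 1], n5 = F[, 2], n6 = F[, 3],               # outer triangle
    n7 = NA_integer_, n8 = NA_integer_)
  layer <- solid_shell_layer(nodes, solids,
                             outer_nodes = seq_len(n),
                             inner_nodes = n + seq_len(n))
  surface <- surface_mesh(
    nodes[seq_len(n), ],
    tibble::tibble(elem_id = seq_len(nrow(F)),
                   n1 = F[, 1], n2 = F[, 2], n3 = F[, 3]))
  structure(list(layer = layer, surface = surface,
                 thickness_fun = tf, u = U, spec = spec),
            class = "shell_fixture")
}

#' Smooth deformations for target fixtures
#'
#' Factories returning deformation functions (an n-by-3 matrix of points in,
#' the deformed matrix out) used by [make_target_pair()]:
#' `identity_deformation()` leaves points alone; `affine_deformation()`
#' applies `A %*% p + shift`; `bulge_deformation()` scales points radially
#' by `1 + amp * exp(-angle^2 / (2 * width^2))`, the angle measured from
#' `axis` — a smooth non-affine bulge emulating an anthropometry change.
#'
#' @param A 3x3 matrix; `shift` length-3 translation (mm).
#' @param amp relative bulge amplitude; `width` angular width (radians);
#'   `axis` bulge direction.
#' @return A function of class `deformation`.
#' @export
affine_deformation <- function(A, shift = c(0, 0, 0)) {
  force(A); force(shift)
  structure(function(P) sweep(P %*% t(A), 2, shift, "+"),
            class = c("deformation", "function"))
}

#' @rdname affine_deformation
#' @export
identity_deformation <- function() {
  structure(function(P) P, class = c("deformation", "function"))
}

#' @rdname affine_deformation
#' @export
bulge_deformation <- function(amp = 0.15, width = 0.6, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  force(amp); force(width)
  structure(function(P) {
    r <- sqrt(rowSums(P^2))
    u <- P / ifelse(r == 0, 1, r)
    ang <- acos(pmin(1, pmax(-1, u %*% axis)))
    P * as.vector(1 + amp * exp(-(ang^2) / (2 * width^2)))
  }, class = c("deformation", "function"))
}

#' Build a deformed, re-tessellated target fixture with ground truth
#'
#' Creates the target side of a transfer problem: the fixture surface is
#' re-tessellated (a different subdivision level and/or a seeded tangential
#' jitter, so target nodes do not coincide with source nodes), then pushed
#' through a known smooth deformation standing in for the anthropometry
#' difference. Matched landmark sets are sampled at farthest-point-spread
#' source surface nodes and exported in both frames, optionally corrupted
#' by Gaussian noise and a single injected outlier. Because the deformation
#' and the thickness field are analytic, the fixture carries exact ground
#' truth for the morph (deformed source node positions) and for the
#' projection (thickness at every target node).
#'
#' @param spec a [fixture_spec()].
#' @param deformation a deformation function (see [affine_deformation()]);
#'   default a radial bulge.
#' @param target_level subdivision level of the target tessellation
#'   (default: same as the source).
#' @param jitter tangential jitter amplitude for target vertices, as a
#'   fraction of mean edge length (default 0.25 when levels are equal so the
#'   tessellations differ; 0 otherwise).
#' @return A list of class `target_fixture`: `target` (deformed
#'   [surface_mesh()]), `truth` (tibble `node_id`, `thickness` — the
#'   analytic field at each target node), `landmarks_source`,
#'   `landmarks_target`, `source_truth` (tibble of the source outer nodes'
#'   ground-truth deformed coordinates), `deform`, and `u_target`.
#' @export
make_target_pair <- function(spec, deformation = bulge_deformation(),
                             target_level = spec$level,
                             jitter = if (target_level == spec$level) 0.25 else 0) {
  stopifnot(inherits(spec, "fixture_spec"))
  src <- make_solid_shell(spec)
  ic <- icosphere(target_level)
  Ut <- ic$V
  if (jitter > 0) {
    set.seed(spec$seed + 202L)
    edge <- sqrt(8 * pi / (sqrt(3) * nrow(ic$F)))   # mean edge on unit sphere
    noise <- matrix(rnorm(length(Ut), sd = jitter * edge / sqrt(2)),
                    nrow(Ut), 3)
    noise <- noise - Ut * rowSums(noise * Ut)       # tangential component
    Ut <- Ut + noise
    Ut <- Ut / sqrt(rowSums(Ut^2))
  }
  geom_t <- surface_geometry(spec, Ut)
  Pt <- deformation(geom_t$p)
  target <- surface_mesh(
    tibble::tibble(node_id = seq_len(nrow(Pt)),
                   x = Pt[, 1], y = Pt[, 2], z = Pt[, 3]),
    tibble::tibble(elem_id = seq_len(nrow(ic$F)),
                   n1 = ic$F[, 1], n2 = ic$F[, 2], n3 = ic$F[, 3]))
  truth <- tibble::tibble(node_id = seq_len(nrow(Pt)),
                          thickness = src$thickness_fun(Ut))
  # landmarks: farthest-point sample of the source outer nodes
  Xs <- as.matrix(src$surface$nodes[, c("x", "y", "z")])
  set.seed(spec$seed + 303L)
  sel <- farthest_point_sample(Xs, spec$n_landmarks)
  lm_src <- Xs[sel, , drop = FALSE]
  lm_tgt <- deformation(lm_src)
  if (spec$noise_sd > 0) {
    lm_tgt <- lm_tgt + matrix(rnorm(length(lm_tgt), sd = spec$noise_sd),
                              nrow(lm_tgt), 3)
  }
  if (!is.null(spec$outlier)) {
    k <- spec$outlier$index
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    lm_tgt[k, ] <- lm_tgt[k, ] + spec$outlier$offset * dir
  }
  labels <- sprintf("lm%02d", seq_len(nrow(lm_src)))
  src_truth_xyz <- deformation(Xs)
  structure(list(
    target = target,
    truth = truth,
    landmarks_source = tibble::tibble(label = labels, x = lm_src[, 1],
                                      y = lm_src[, 2], z = lm_src[, 3]),
    landmarks_target = tibble::tibble(label = labels, x = lm_tgt[, 1],
                                      y = lm_tgt[, 2], z = lm_tgt[, 3]),
    source_truth = tibble::tibble(node_id = src$surface$nodes$node_id,
                                  x = src_truth_xyz[, 1],
                                  y = src_truth_xyz[, 2],
                                  z = src_truth_xyz[, 3]),
    deform = deformation, u_target = Ut, spec = spec),
    class = "target_fixture")
}

farthest_point_sample <- function(X, k) {
  n <- nrow(X)
  if (k >= n) return(seq_len(n))
  sel <- sample.int(n, 1)
  d <- sqrt(rowSums(sweep(X, 2, X[sel, ])^2))
  while (length(sel) < k) {
    nxt <- which.max(d)
    sel <- c(sel, nxt)
    d <- pmin(d, sqrt(rowSums(sweep(X, 2, X[nxt, ])^2)))
  }
  sel
}

#' Write a complete fixture problem to disk
#'
#' Emits the source solid layer and the deformed target surface as LS-Dyna
#' keyword files, the matched landmark sets as CSV, the analytic target
#' thickness as CSV, and a JSON manifest recording the spec and seed.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory (created if needed).
#' @param deformation,target_level,jitter passed to [make_target_pair()].
#' @return Named character vector of the written paths, invisibly.
#' @export
export_fixture <- function(spec, outdir, deformation = bulge_deformation(),
                           target_level = spec$level,
                           jitter = if (target_level == spec$level) 0.25 else 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  src <- make_solid_shell(spec)
  pair <- make_target_pair(spec, deformation, target_level, jitter)
  paths <- c(
    source_mesh = file.path(outdir, "source.k"),
    target_mesh = file.path(outdir, "target.k"),
    landmarks_source = file.path(outdir, "landmarks_source.csv"),
    landmarks_target = file.path(outdir, "landmarks_target.csv"),
    truth = file.path(outdir, "target_truth_thickness.csv"),
    manifest = file.path(outdir, "manifest.json"))
  write_mesh(src$layer, paths["source_mesh"])
  write_mesh(pair$target, paths["target_mesh"])
  write_landmarks(pair$landmarks_source, paths["landmarks_source"])
  write_landmarks(pair$landmarks_target, paths["landmarks_target"])
  utils::write.csv(pair$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  manifest <- unclass(spec)
  manifest$target_level <- target_level
  manifest$jitter <- jitter
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
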