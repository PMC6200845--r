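#' Generalized covariance kernels for dual Kriging
#'
#' Radial kernels used in the fluctuation term of the Kriging map. The
#' default, `"logarithmic"`, is \eqn{K(h) = h^2 \log h} with the continuity
#' convention \eqn{K(0) = 0}; it is the thin-plate-spline kernel of 3D
#' landmark morphing. The alternative forms are exposed as options: linear
#' \eqn{h}, cubic \eqn{h^3}, Gaussian \eqn{e^{-(h/\epsilon)^2}},
#' multiquadric \eqn{\sqrt{h^2+\epsilon^2}} and inverse multiquadric.
#'
#' @param h non-negative distance(s), mm.
#' @param kind kernel name.
#' @param eps shape parameter of the Gaussian/multiquadric kernels (mm).
#' @return Numeric vector of kernel values.
#' @examples
#' kriging_covariance(c(0, 1, exp(1)))  # 0, 0, e^2
#' @export
kriging_covariance <- function(h,
                               kind = c("logarithmic", "linear", "cubic",
                                        "gaussian", "multiquadric",
                                        "inverse_multiquadric"),
                               eps = 1) {
  kind <- match.arg(kind)
  if (any(h < 0)) abort("kriging_covariance: negative distance")
  switch(kind,
         logarithmic = ifelse(h == 0, 0, h^2 * log(h)),
         linear = h,
         cubic = h^3,
         gaussian = exp(-(h / eps)^2),
         multiquadric = sqrt(h^2 + eps^2),
         inverse_multiquadric = 1 / sqrt(h^2 + eps^2))
}

pairwise_dist <- function(a, b = a) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

landmark_matrix <- function(lm) {
  if (is.matrix(lm)) return(lm)
  as.matrix(tibble::as_tibble(lm)[, c("x", "y", "z")])
}

#' Fit a dual-Kriging morph between two matched landmark sets
#'
#' Solves, independently for each output coordinate, the bordered linear
#' system of dual Kriging: an affine drift (constant + linear in x, y, z)
#' plus a radial fluctuation term \eqn{\sum_s b_s K(\|x - x_s\|)} over the
#' source control points, subject to the side conditions
#' \eqn{\sum_s b_s = 0} and \eqn{\sum_s b_s x_s = \sum_s b_s y_s =
#' \sum_s b_s z_s = 0} that make the problem well-posed. The fitted map
#' interpolates: every source landmark is carried exactly onto its matched
#' target landmark. When the correspondence is affine the fluctuation
#' coefficients vanish and the map reduces to the affine transform.
#'
#' @param source,target matched landmark tables (columns `label`, `x`, `y`,
#'   `z`, mm) with identical label sequences, or bare coordinate matrices.
#'   At least 5 non-coplanar points.
#' @param kind covariance kernel, see [kriging_covariance()].
#' @param eps kernel shape parameter; defaults to the median non-zero
#'   inter-landmark distance (only used by the Gaussian/multiquadric kinds).
#' @param rescale if `TRUE`, coordinates are centred and scaled to a unit
#'   bounding-box diagonal before the solve (numerical conditioning) and the
#'   map is expressed back in the original frame.
#' @return An object of class `kriging_model`. Use [apply_kriging()] or
#'   `predict()` to evaluate it, [tidy()] / [glance()] to inspect it.
#' @seealso [optimize_control_points()], [morph_quality()]
#' @export
fit_kriging <- function(source, target,
                        kind = c("logarithmic", "linear", "cubic", "gaussian",
                                 "multiquadric", "inverse_multiquadric"),
                        eps = NULL, rescale = FALSE) {
  kind <- match.arg(kind)
  labels <- if (is.data.frame(source) && "label" %in% names(source)) {
    if (is.data.frame(target) && "label" %in% names(target) &&
        !identical(source$label, target$label)) {
      abort("fit_kriging: source and target label sequences differ")
    }
    source$label
  } else NULL
  X <- landmark_matrix(source)
  Y <- landmark_matrix(target)
  n <- nrow(X)
  if (n != nrow(Y)) abort("fit_kriging: source and target sizes differ")
  if (n < 5) abort("fit_kriging: need at least 5 control points")
  if (anyDuplicated(X) > 0) {
    abort("fit_kriging: duplicated source control points")
  }
  ctr <- c(0, 0, 0); scl <- 1
  if (rescale) {
    ctr <- colMeans(X)
    rng <- apply(X, 2, function(v) diff(range(v)))
    scl <- sqrt(sum(rng^2))
    if (scl == 0) scl <- 1
    X <- sweep(X, 2, ctr) / scl
    Y <- sweep(Y, 2, ctr) / scl
  }
  D <- pairwise_dist(X)
  if (is.null(eps)) {
    nz <- D[D > 0]
    eps <- if (length(nz) > 0) stats::median(nz) else 1
  }
  K <- matrix(kriging_covariance(D, kind, eps), n, n)
  F <- cbind(1, X)
  M <- rbind(cbind(K, F), cbind(t(F), matrix(0, 4, 4)))
  rhs <- rbind(Y, matrix(0, 4, 3))
  coef <- tryCatch(
    solve(M, rhs),
    error = function(e) {
      abort(paste0("fit_kriging: singular Kriging system (rank deficiency; ",
                   "coplanar or near-duplicate control points): ",
                   conditionMessage(e)))
    })
  structure(
    list(kind = kind, eps = eps,
         b = coef[seq_len(n), , drop = FALSE],
         a = coef[n + 1:4, , drop = FALSE],
         source = X, labels = labels,
         center = ctr, scale = scl),
    class = "kriging_model")
}

#' @export
print.kriging_model <- function(x, ...) {
  cat(sprintf("<kriging_model> %d control points, %s covariance\n",
              nrow(x$source), x$kind))
  cat(sprintf("  max |b|: %.3g\n", max(abs(x$b))))
  invisible(x)
}

#' Evaluate a fitted Kriging morph at arbitrary points
#'
#' @param points data frame with columns `x`, `y`, `z` (other columns are
#'   preserved) or a coordinate matrix.
#' @param model a fitted [fit_kriging()] model.
#' @return Same shape as the input with morphed coordinates.
#' @export
apply_kriging <- function(points, model) {
  stopifnot(inherits(model, "kriging_model"))
  was_df <- is.data.frame(points)
  P <- if (was_df) as.matrix(points[, c("x", "y", "z")]) else points
  Ps <- sweep(P, 2, model$center) / model$scale
  G <- matrix(kriging_covariance(pairwise_dist(Ps, model$source),
                                 model$kind, model$eps),
              nrow(Ps), nrow(model$source))
  out <- cbind(1, Ps) %*% model$a + G %*% model$b
  out <- sweep(out * model$scale, 2, model$center, "+")
  if (was_df) {
    points$x <- out[, 1]; points$y <- out[, 2]; points$z <- out[, 3]
    tibble::as_tibble(points)
  } else {
    dimnames(out) <- dimnames(P)
    out
  }
}

#' @export
predict.kriging_model <- function(object, newdata, ...) {
  apply_kriging(newdata, object)
}

#' Morph a whole mesh with a fitted Kriging model
#'
#' @param mesh a [surface_mesh()] or [solid_shell_layer()].
#' @param model a [fit_kriging()] model.
#' @return The mesh with every node coordinate mapped; connectivity and node
#'   ids untouched.
#' @export
morph_mesh <- function(mesh, model) {
  mesh$nodes <- apply_kriging(mesh$nodes, model)
  mesh
}

#' @method tidy kriging_model
#' @export
tidy.kriging_model <- function(x, ...) {
  terms <- c("drift_const", "drift_x", "drift_y", "drift_z",
             if (!is.null(x$labels)) paste0("fluct_", x$labels)
             else paste0("fluct_", seq_len(nrow(x$b))))
  m <- rbind(x$a, x$b)
  tibble::tibble(term = terms, x = m[, 1], y = m[, 2], z = m[, 3])
}

#' @method glance kriging_model
#' @export
glance.kriging_model <- function(x, ...) {
  tibble::tibble(n_control = nrow(x$source), covariance = x$kind,
                 max_fluctuation = max(abs(x$b)),
                 side_condition_residual = max(abs(t(cbind(1, x$source)) %*% x$b)))
}

# shortest distance from each row of `q` to any row of `ref`; the argmin is
# found with the fast inner-product expansion, the distance itself
# recomputed directly so coincident points give exactly zero
nearest_dist <- function(q, ref, chunk = 512L) {
  out <- numeric(nrow(q))
  r2 <- rowSums(ref^2)
  for (start in seq(1, nrow(q), by = chunk)) {
    sel <- start:min(start + chunk - 1L, nrow(q))
    d2 <- outer(rowSums(q[sel, , drop = FALSE]^2), r2, "+") -
      2 * q[sel, , drop = FALSE] %*% t(ref)
    nn <- max.col(-d2, ties.method = "first")
    out[sel] <- sqrt(rowSums((q[sel, , drop = FALSE] -
                                ref[nn, , drop = FALSE])^2))
  }
  out
}

#' Quality of a morph against the target mesh
#'
#' For every target node, `q` is the distance to the nearest morphed-source
#' node (nearest-neighbour correspondence between the dissimilar meshes);
#' the morph quality is summarised as mean, SD and max of `q`. When matched
#' landmark sets are supplied, the control-point RMSE — the root mean squared
#' distance (mm) between matched landmark pairs after morphing — is also
#' reported.
#'
#' @param morphed a [surface_mesh()] (or node table) of morphed source
#'   outer-surface nodes.
#' @param target the target [surface_mesh()] (or node table), same frame.
#' @param landmarks_morphed,landmarks_target optional matched landmark
#'   tables after morphing.
#' @return An object of class `morph_quality`: list with the per-node tibble
#'   `q` (`node_id`, `q`) and scalars `mean_q`, `sd_q`, `max_q`, `rmse`
#'   (`NA` without landmarks). `glance()` returns the scalars as a one-row
#'   tibble.
#' @export
morph_quality <- function(morphed, target,
                          landmarks_morphed = NULL, landmarks_target = NULL) {
  mco <- mesh_or_nodes_matrix(morphed)
  tgt <- mesh_or_nodes_nodes(target)
  tco <- as.matrix(tgt[, c("x", "y", "z")])
  if (nrow(mco) == 0 || nrow(tco) == 0) abort("morph_quality: empty mesh")
  qv <- nearest_dist(tco, mco)
  rmse <- NA_real_
  if (!is.null(landmarks_morphed)) {
    a <- landmark_matrix(landmarks_morphed)
    b <- landmark_matrix(landmarks_target)
    rmse <- sqrt(mean(rowSums((a - b)^2)))
  }
  structure(list(q = tibble::tibble(node_id = tgt$node_id, q = qv),
                 mean_q = mean(qv), sd_q = sd(qv), max_q = max(qv),
                 rmse = rmse),
            class = "morph_quality")
}

mesh_or_nodes_nodes <- function(x) {
  if (inherits(x, "surface_mesh") || inherits(x, "solid_shell_layer")) x$nodes
  else tibble::as_tibble(x)
}

mesh_or_nodes_matrix <- function(x) {
  if (inherits(x, "solid_shell_layer")) {
    nd <- x$nodes[x$nodes$node_id %in% x$outer_nodes, ]
  } else {
    nd <- mesh_or_nodes_nodes(x)
  }
  as.matrix(nd[, c("x", "y", "z")])
}

#' @export
print.morph_quality <- function(x, ...) {
  cat(sprintf("<morph_quality> mean q %.3f +/- %.3f mm, max %.3f mm",
              x$mean_q, x$sd_q, x$max_q))
  if (!is.na(x$rmse)) cat(sprintf(", landmark RMSE %.3f mm", x$rmse))
  cat("\n")
  invisible(x)
}

#' @method glance morph_quality
#' @export
glance.morph_quality <- function(x, ...) {
  tibble::tibble(mean_q = x$mean_q, sd_q = x$sd_q, max_q = x$max_q,
                 rmse = x$rmse, n_target = nrow(x$q))
}

#' Greedy backward elimination of morphing control points
#'
#' Hand-picked landmarks can harm the morph when their correspondence is
#' inconsistent (digitisation error, ambiguous anatomy). Because the
#' dual-Kriging map interpolates whatever landmarks drive it, a retained
#' point's raw residual is always zero; the set is therefore scored by
#' cross-validation over *all* original landmark pairs: every retained
#' point contributes its leave-one-out error (the map refitted without it,
#' evaluated at it), and every removed point contributes its probe error
#' under the current fit. In each round the single removal that most
#' reduces this all-pairs RMSE is made permanent; the process stops when no
#' removal reduces it. A bad landmark is caught through the distortion it
#' inflicts on all the other points' cross-validated errors. RMSE ties are
#' broken by the lowest landmark index, and the accepted RMSE is
#' non-increasing across rounds by construction.
#'
#' @param source,target matched landmark tables (`label`, `x`, `y`, `z`).
#' @param kind,eps,rescale passed to [fit_kriging()].
#' @param min_points elimination never goes below this many retained points
#'   (default 5, the smallest solvable system).
#' @param min_improvement a removal is accepted only when it lowers the
#'   RMSE by more than this fraction of the current value (default 0.01,
#'   with an absolute floor of 1e-9 mm), so float-noise-level "gains" do
#'   not strip consistent landmarks.
#' @return A list of class `cp_optimization`: reduced `source` and `target`
#'   tibbles, integer `keep` indices into the originals, a `trace` tibble
#'   (`round`, `removed_label`, `rmse` after the removal) and scalars
#'   `initial_rmse`, `final_rmse`.
#' @export
optimize_control_points <- function(source, target, kind = "logarithmic",
                                    eps = NULL, rescale = FALSE,
                                    min_points = 5, min_improvement = 0.01) {
  source <- tibble::as_tibble(source)
  target <- tibble::as_tibble(target)
  n <- nrow(source)
  if (n < 6) abort("optimize_control_points: need at least 6 control points")
  Xall <- landmark_matrix(source)
  Yall <- landmark_matrix(target)
  fit_sub <- function(idx) {
    tryCatch(
      fit_kriging(Xall[idx, , drop = FALSE], Yall[idx, , drop = FALSE],
                  kind = kind, eps = eps, rescale = rescale),
      error = function(e) NULL)
  }
  # all-pairs cross-validated RMSE of a candidate retained set: LOO error
  # for retained points, probe error under the full candidate fit for
  # removed points
  score <- function(keep) {
    errs <- rep(NA_real_, n)
    m_keep <- fit_sub(keep)
    if (is.null(m_keep)) return(Inf)
    removed <- setdiff(seq_len(n), keep)
    if (length(removed) > 0) {
      pred <- apply_kriging(Xall[removed, , drop = FALSE], m_keep)
      errs[removed] <- rowSums((pred - Yall[removed, , drop = FALSE])^2)
    }
    for (j in keep) {
      m_j <- fit_sub(setdiff(keep, j))
      if (is.null(m_j)) return(Inf)
      pred <- apply_kriging(Xall[j, , drop = FALSE], m_j)
      errs[j] <- sum((pred - Yall[j, , drop = FALSE])^2)
    }
    sqrt(mean(errs))
  }
  keep <- seq_len(n)
  current <- score(keep)
  initial <- current
  trace <- list()
  round <- 0L
  while (length(keep) > min_points) {
    cand <- vapply(seq_along(keep),
                   function(i) score(keep[-i]), numeric(1))
    best <- which(cand == min(cand))[1]   # ties: lowest landmark index
    gate <- max(1e-9, min_improvement * current)
    if (!is.finite(cand[best]) || current - cand[best] <= gate) break
    round <- round + 1L
    removed <- keep[best]
    keep <- keep[-best]
    current <- cand[best]
    trace[[round]] <- tibble::tibble(
      round = round,
      removed_label = source$label[removed] %||% as.character(removed),
      removed_index = removed, rmse = current)
  }
  structure(
    list(source = source[keep, ], target = target[keep, ], keep = keep,
         trace = if (round > 0) dplyr::bind_rows(trace)
                 else tibble::tibble(round = integer(), removed_label = character(),
                                     removed_index = integer(), rmse = numeric()),
         initial_rmse = initial, final_rmse = current),
    class = "cp_optimization")
}

#' @export
print.cp_optimization <- function(x, ...) {
  cat(sprintf("<cp_optimization> %d -> %d control points, RMSE %.4g -> %.4g mm\n",
              length(x$keep) + nrow(x$trace), length(x$keep),
              x$initial_rmse, x$final_rmse))
  invisible(x)
}

#' @method tidy cp_optimization
#' @export
tidy.cp_optimization <- function(x, ...) x$trace

#' @method glance cp_optimization
#' @export
glance.cp_optimization <- function(x, ...) {
  tibble::tibble(n_initial = length(x$keep) + nrow(x$trace),
                 n_final = length(x$keep),
                 initial_rmse = x$initial_rmse, final_rmse = x$final_rmse)
}
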