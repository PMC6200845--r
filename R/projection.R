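#' Project a nodal thickness field onto a target mesh
#'
#' Each target node receives a weighted average of every source nodal
#' thickness, with weights \eqn{w_{ij} = q_{ij}^{-\beta}} where
#' \eqn{q_{ij}} is the distance (mm) from target node i to (morphed) source
#' node j:
#' \deqn{t_i^F(\beta) = \sum_j t_j q_{ij}^{-\beta} / \sum_j q_{ij}^{-\beta}.}
#' With \eqn{\beta = 0} every target node gets the plain mean of the source
#' thicknesses; as \eqn{\beta} grows the average converges on the nearest
#' source node. Weights are computed in log space and shifted by the
#' per-node maximum before exponentiation, so arbitrarily large \eqn{\beta}
#' cannot overflow; a target node coincident with a source node takes that
#' node's thickness exactly (the zero-distance limit; the mean, if several
#' sources coincide with it).
#'
#' @param target target [surface_mesh()] or node table (`node_id`, `x`,
#'   `y`, `z`).
#' @param source_nodes source node table (`node_id`, `x`, `y`, `z`),
#'   typically the morphed outer-surface nodes; may already carry a
#'   `thickness` column.
#' @param source_field optional tibble (`node_id`, `thickness`) joined onto
#'   `source_nodes` when the latter has no `thickness` column.
#' @param beta non-negative weighting exponent.
#' @return A `projection_result`: tibble with columns `node_id`,
#'   `thickness` (mm) and `n_sources` (how many source nodes carry
#'   non-negligible weight, for QC), with the `beta` used as an attribute.
#'   Every value lies between the source minimum and maximum (convex
#'   combination).
#' @seealso [beta_sweep()], [accuracy()], [smoothness()]
#' @export
project_thickness <- function(target, source_nodes, source_field = NULL,
                              beta) {
  if (beta < 0) abort("project_thickness: beta must be >= 0")
  tgt <- mesh_or_nodes_nodes(target)
  src <- tibble::as_tibble(source_nodes)
  if (!"thickness" %in% names(src)) {
    if (is.null(source_field)) {
      abort("project_thickness: source thickness missing (no thickness column, no source_field)")
    }
    src <- dplyr::inner_join(src, tibble::as_tibble(source_field),
                             by = "node_id")
  }
  if (nrow(src) == 0) abort("project_thickness: empty source")
  tv <- src$thickness
  S <- as.matrix(src[, c("x", "y", "z")])
  P <- as.matrix(tgt[, c("x", "y", "z")])
  np <- nrow(P)
  vals <- numeric(np)
  nsrc <- integer(np)
  if (beta == 0) {
    vals[] <- mean(tv)
    nsrc[] <- length(tv)
  } else {
    s2 <- rowSums(S^2)
    chunk <- 512L
    for (start in seq(1, np, by = chunk)) {
      sel <- start:min(start + chunk - 1L, np)
      D2 <- outer(rowSums(P[sel, , drop = FALSE]^2), s2, "+") -
        2 * P[sel, , drop = FALSE] %*% t(S)
      D <- sqrt(pmax(D2, 0))
      zero_rows <- which(apply(D, 1, function(r) any(r == 0)))
      logW <- -beta * log(D)
      rmax <- apply(logW, 1, max)
      W <- exp(logW - rmax)
      W[!is.finite(W)] <- 0        # rows with a coincident node, fixed below
      sw <- rowSums(W)
      vals[sel] <- (W %*% tv) / sw
      nsrc[sel] <- rowSums(W > 1e-12)
      for (r in zero_rows) {
        hit <- D[r, ] == 0
        vals[sel[r]] <- mean(tv[hit])
        nsrc[sel[r]] <- sum(hit)
      }
    }
  }
  out <- tibble::tibble(node_id = tgt$node_id, thickness = vals,
                        n_sources = nsrc)
  attr(out, "beta") <- beta
  class(out) <- c("projection_result", class(out))
  out
}

field_values <- function(x) {
  if (is.numeric(x)) x else tibble::as_tibble(x)$thickness
}

#' Accuracy of a projection relative to the nearest-neighbour anchor
#'
#' The large-\eqn{\beta} projection (default anchor \eqn{\beta = 50})
#' effectively performs a nearest-neighbour transfer and is assigned perfect
#' accuracy 1; the \eqn{\beta = 0} (uniform mean) projection anchors 0. For
#' any other projection,
#' \deqn{A(\beta) = 1 - \sum_i (t_i(\beta_{max}) - t_i(\beta))^2 /
#'                     \sum_i (t_i(\beta_{max}) - t_i(0))^2.}
#'
#' @param field_beta,field_0,field_betamax projected fields on the identical
#'   node set: numeric vectors, or tibbles with a `thickness` column.
#' @return Scalar accuracy. A constant source field makes the denominator
#'   zero; accuracy is then defined as 1 with a warning.
#' @export
accuracy <- function(field_beta, field_0, field_betamax) {
  tb <- field_values(field_beta)
  t0 <- field_values(field_0)
  tm <- field_values(field_betamax)
  if (length(tb) != length(t0) || length(tb) != length(tm)) {
    abort("accuracy: fields are on different node sets")
  }
  den <- sum((tm - t0)^2)
  if (den == 0) {
    warn("accuracy: reference fields identical (constant source?); A defined as 1")
    return(1)
  }
  1 - sum((tm - tb)^2) / den
}

#' Local first-order regression error of a nodal field
#'
#' Smoothness of a projected field is judged node by node: for node i, a
#' first-order model \eqn{\hat t_m = C_1 x_m + C_2 y_m + C_3 z_m + C_4} is
#' fitted by least squares to the thicknesses of the m edge-connected
#' neighbours of i, and the error is the squared norm of the residual,
#' \eqn{E_i = \|\hat t - t\|^2}. A field that varies linearly over the
#' surface (in particular a constant field) has \eqn{E_i = 0} everywhere;
#' noise around the local gradient inflates it. With fewer than 4 neighbours
#' or rank-deficient neighbour coordinates the minimum-norm least-squares
#' solution is used, which leaves the residual well-defined. An isolated
#' node gets \eqn{E_i = 0} with a warning.
#'
#' `regression_errors()` evaluates all nodes; `local_regression_error()` a
#' single one.
#'
#' @param mesh target [surface_mesh()] (adjacency comes from its edges).
#' @param field tibble (`node_id`, `thickness`) covering the mesh nodes.
#' @param node a node id.
#' @return `regression_errors()`: tibble `node_id`, `E`, `m` (neighbour
#'   count). `local_regression_error()`: scalar `E_i`.
#' @export
regression_errors <- function(mesh, field) {
  stopifnot(inherits(mesh, "surface_mesh"))
  adj <- node_adjacency(mesh)
  co <- coord_matrix(mesh)
  fv <- setNames(field_values(field), as.character(tibble::as_tibble(field)$node_id))
  ids <- as.integer(names(adj))
  E <- numeric(length(ids))
  m <- integer(length(ids))
  isolated <- integer(0)
  for (k in seq_along(ids)) {
    nb <- adj[[k]]
    m[k] <- length(nb)
    if (length(nb) == 0) {
      isolated <- c(isolated, ids[k])
      next
    }
    key <- as.character(nb)
    X <- cbind(co[key, , drop = FALSE], 1)
    t_nb <- fv[key]
    E[k] <- minnorm_residual2(X, t_nb)
  }
  if (length(isolated) > 0) {
    warn(paste0("regression_errors: isolated node(s) with no neighbours, E = 0: ",
                paste(head(isolated, 5), collapse = ", ")))
  }
  tibble::tibble(node_id = ids, E = E, m = m)
}

# squared residual norm of the minimum-norm least-squares fit t ~ X
minnorm_residual2 <- function(X, t) {
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% t) / sv$d[pos])
  sum((X %*% coef - t)^2)
}

#' @rdname regression_errors
#' @export
local_regression_error <- function(mesh, field, node) {
  err <- regression_errors(mesh, field)
  i <- match(node, err$node_id)
  if (is.na(i)) abort(paste0("local_regression_error: no node ", node))
  err$E[i]
}

#' Smoothness of a projection
#'
#' The per-node regression errors of a projection are compared to the two
#' anchors, the uniform (\eqn{\beta = 0}) projection whose errors all vanish
#' and the nearest-neighbour anchor (\eqn{\beta_{max}}, the noisiest
#' transfer). The normalised squared distance of the error vector to the
#' noisy anchor,
#' \eqn{\sum_i (E_i(\beta_{max}) - E_i(\beta))^2 /
#'      \sum_i (E_i(\beta_{max}) - E_i(0))^2},
#' is the *smoothness retention* (1 at \eqn{\beta = 0}, 0 at
#' \eqn{\beta_{max}}); the reported smoothness metric is its complement, so
#' that \eqn{S(0) = 0} and \eqn{S(\beta_{max}) = 1} — it measures how far
#' towards the noisy nearest-neighbour regime the projection has moved.
#'
#' @param E_beta,E_0,E_betamax per-node regression errors on the identical
#'   node set (numeric vectors or [regression_errors()] tibbles, `E`
#'   column).
#' @return Scalar reported smoothness \eqn{S}. A zero denominator (the
#'   anchors agree everywhere) yields S = 1 with a warning. The retention
#'   value is attached as attribute `"retention"`.
#' @export
smoothness <- function(E_beta, E_0, E_betamax) {
  eb <- if (is.numeric(E_beta)) E_beta else E_beta$E
  e0 <- if (is.numeric(E_0)) E_0 else E_0$E
  em <- if (is.numeric(E_betamax)) E_betamax else E_betamax$E
  if (length(eb) != length(e0) || length(eb) != length(em)) {
    abort("smoothness: error vectors are on different node sets")
  }
  den <- sum((em - e0)^2)
  if (den == 0) {
    warn("smoothness: anchor error vectors identical; S defined as 1")
    return(structure(1, retention = 0))
  }
  ratio <- sum((em - eb)^2) / den
  structure(1 - ratio, retention = ratio)
}

#' Sweep the weighting exponent and locate the accuracy/smoothness tradeoff
#'
#' Projects the source field onto the target at every \eqn{\beta} of the
#' grid, computes the accuracy \eqn{A(\beta)} and reported smoothness
#' \eqn{S(\beta)} metrics, and selects the tradeoff exponent where the
#' rising accuracy curve crosses the falling smoothness-retention curve
#' \eqn{1 - S(\beta)} (piecewise-linear interpolation between grid points;
#' the smallest crossing if there are several). The grid must contain 0 and
#' the nearest-neighbour anchor `beta_max`.
#'
#' @inheritParams project_thickness
#' @param betas exponent grid; default `c(0:4, 10, 25, 50)`.
#' @param beta_max nearest-neighbour anchor (default `max(betas)`).
#' @return An object of class `beta_sweep`: list with `table` (tibble
#'   `beta`, `accuracy`, `smoothness`, `retention`), `fields` (named list of
#'   projections), `errors` (named list of regression-error tibbles),
#'   `selected_beta` and `beta_max`. `tidy()` returns the table, `glance()`
#'   a one-row summary, `autoplot()` the tradeoff figure.
#' @export
beta_sweep <- function(target, source_nodes, source_field = NULL,
                       betas = c(0, 1, 2, 3, 4, 10, 25, 50),
                       beta_max = max(betas)) {
  betas <- sort(unique(betas))
  if (any(betas < 0)) abort("beta_sweep: negative beta in grid")
  if (!0 %in% betas) abort("beta_sweep: grid must contain beta = 0")
  if (!beta_max %in% betas) abort("beta_sweep: grid must contain beta_max")
  if (!inherits(target, "surface_mesh")) {
    abort("beta_sweep: target must be a surface_mesh (adjacency needed)")
  }
  key <- as.character(betas)
  fields <- lapply(betas, function(b)
    project_thickness(target, source_nodes, source_field, beta = b))
  names(fields) <- key
  errors <- lapply(fields, function(f) regression_errors(target, f))
  f0 <- fields[[as.character(0)]]
  fm <- fields[[as.character(beta_max)]]
  e0 <- errors[[as.character(0)]]
  em <- errors[[as.character(beta_max)]]
  A <- vapply(fields, function(f) accuracy(f, f0, fm), numeric(1))
  Sv <- lapply(errors, function(e) smoothness(e, e0, em))
  S <- vapply(Sv, as.numeric, numeric(1))
  ret <- vapply(Sv, function(s) attr(s, "retention"), numeric(1))
  tab <- tibble::tibble(beta = betas, accuracy = unname(A),
                        smoothness = unname(S), retention = unname(ret))
  structure(list(table = tab, fields = fields, errors = errors,
                 selected_beta = crossing_beta(tab),
                 beta_max = beta_max),
            class = "beta_sweep")
}

# smallest beta where accuracy meets the falling retention curve, by
# piecewise-linear interpolation on the grid
crossing_beta <- function(tab) {
  g <- tab$accuracy - tab$retention
  for (k in seq_len(nrow(tab))) {
    if (g[k] == 0) return(tab$beta[k])
    if (k < nrow(tab) && g[k] * g[k + 1] < 0) {
      w <- g[k] / (g[k] - g[k + 1])
      return(tab$beta[k] + w * (tab$beta[k + 1] - tab$beta[k]))
    }
  }
  warn("beta_sweep: accuracy and smoothness-retention curves do not cross; returning beta closest to equality")
  tab$beta[which.min(abs(g))]
}

#' @export
print.beta_sweep <- function(x, ...) {
  cat(sprintf("<beta_sweep> %d exponents, anchor beta = %g, selected beta = %.3g\n",
              nrow(x$table), x$beta_max, x$selected_beta))
  print(x$table)
  invisible(x)
}

#' @method tidy beta_sweep
#' @export
tidy.beta_sweep <- function(x, ...) x$table

#' @method glance beta_sweep
#' @export
glance.beta_sweep <- function(x, ...) {
  tibble::tibble(selected_beta = x$selected_beta, beta_max = x$beta_max,
                 n_betas = nrow(x$table),
                 n_target = nrow(x$fields[[1]]))
}

#' @method autoplot beta_sweep
#' @export
autoplot.beta_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table[, c("beta", "accuracy", "retention")],
                              c("accuracy", "retention"),
                              names_to = "metric", values_to = "value")
  long$metric <- dplyr::recode(long$metric, accuracy = "accuracy A",
                               retention = "smoothness retention 1 - S")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$beta, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_beta, linetype = 2) +
    ggplot2::labs(x = expression(beta), y = NULL, colour = NULL,
                  title = "Projection accuracy vs. smoothness",
                  subtitle = sprintf("tradeoff at beta = %.2f",
                                     object$selected_beta)) +
    ggplot2::theme_minimal()
}

#' Distribution plot of projected thickness fields
#'
#' Kernel-density curves of the nodal thickness values, one per projection,
#' for comparing how the exponent reshapes the transferred distribution
#' against the source.
#'
#' @param fields named list of projected fields (tibbles with `thickness`),
#'   e.g. `beta_sweep(...)$fields`; names become curve labels.
#' @return A ggplot object.
#' @export
plot_thickness_distribution <- function(fields) {
  df <- dplyr::bind_rows(
    lapply(names(fields), function(nm)
      tibble::tibble(set = nm,
                     thickness = field_values(fields[[nm]]))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$thickness, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "nodal thickness (mm)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
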