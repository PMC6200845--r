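toy_target <- function(n = 3) {
  tibble::tibble(node_id = seq_len(n), x = seq_len(n) * 10, y = 0, z = 0)
}

test_that("beta = 0 projects the plain source mean everywhere", {
  src <- tibble::tibble(node_id = 1:3, x = c(0, 50, 100), y = c(3, -8, 2),
                        z = 0, thickness = c(1, 2, 3))
  pr <- project_thickness(toy_target(5), src, beta = 0)
  expect_equal(pr$thickness, rep(2, 5))
  expect_equal(pr$n_sources, rep(3L, 5))
})

test_that("a coincident source node wins exactly at positive beta", {
  src <- tibble::tibble(node_id = 1:3, x = c(10, 0, 4), y = 0, z = 0,
                        thickness = c(1.5, 9, 4))
  pr <- project_thickness(tibble::tibble(node_id = 1L, x = 10, y = 0, z = 0),
                          src, beta = 4)
  expect_equal(pr$thickness, 1.5)
  expect_equal(pr$n_sources, 1L)
})

test_that("the weighted average matches a direct hand evaluation", {
  # sources at distances 1 and 2, thicknesses 1 and 3, beta = 1:
  # (1*1 + 3*0.5) / 1.5 = 5/3
  src <- tibble::tibble(node_id = 1:2, x = c(1, 2), y = 0, z = 0,
                        thickness = c(1, 3))
  pr <- project_thickness(tibble::tibble(node_id = 1L, x = 0, y = 0, z = 0),
                          src, beta = 1)
  expect_equal(pr$thickness, 5 / 3)
  expect_error(project_thickness(toy_target(), src, beta = -1), "beta")
  expect_error(project_thickness(toy_target(), src[0, ], beta = 1), "empty")
})

test_that("projections are convex combinations, permutation- and scale-invariant", {
  spec <- fixture_spec(level = 2)
  tp <- transfer_problem(spec)
  for (beta in c(0, 1, 4, 50)) {
    pr <- project_thickness(tp$pair$target, tp$src_nodes, beta = beta)
    expect_gte(min(pr$thickness), min(tp$src_nodes$thickness) - 1e-12)
    expect_lte(max(pr$thickness), max(tp$src_nodes$thickness) + 1e-12)
  }
  set.seed(99)
  perm <- sample(nrow(tp$src_nodes))
  pr1 <- project_thickness(tp$pair$target, tp$src_nodes, beta = 4)
  pr2 <- project_thickness(tp$pair$target, tp$src_nodes[perm, ], beta = 4)
  expect_equal(pr2$thickness, pr1$thickness, tolerance = 1e-12)
  scaled_tgt <- tp$pair$target
  scaled_tgt$nodes$x <- scaled_tgt$nodes$x * 3.7
  scaled_tgt$nodes$y <- scaled_tgt$nodes$y * 3.7
  scaled_tgt$nodes$z <- scaled_tgt$nodes$z * 3.7
  scaled_src <- tp$src_nodes
  scaled_src$x <- scaled_src$x * 3.7
  scaled_src$y <- scaled_src$y * 3.7
  scaled_src$z <- scaled_src$z * 3.7
  pr3 <- project_thickness(scaled_tgt, scaled_src, beta = 4)
  expect_equal(pr3$thickness, pr1$thickness, tolerance = 1e-12)
})

test_that("the beta = 50 projection is the nearest-neighbour transfer", {
  tp <- transfer_problem(fixture_spec(level = 2))
  pr <- project_thickness(tp$pair$target, tp$src_nodes, beta = 50)
  S <- as.matrix(tp$src_nodes[, c("x", "y", "z")])
  P <- as.matrix(tp$pair$target$nodes[, c("x", "y", "z")])
  nn <- apply(P, 1, function(p) which.min(colSums((t(S) - p)^2)))
  agree <- mean(abs(pr$thickness - tp$src_nodes$thickness[nn]) < 1e-9)
  expect_gte(agree, 0.99)
})

test_that("accuracy follows its formula and anchors", {
  expect_equal(accuracy(c(2, 2, 2), c(2, 2, 2), c(1, 2, 3)), 0)
  expect_equal(accuracy(c(1, 2, 3), c(2, 2, 2), c(1, 2, 3)), 1)
  # hand computation: 1 - 0.5/2
  expect_equal(accuracy(c(1.5, 2, 2.5), c(2, 2, 2), c(1, 2, 3)), 0.75)
  expect_warning(a <- accuracy(c(1, 1), c(2, 2), c(2, 2)), "identical")
  expect_equal(a, 1)
  expect_error(accuracy(1:3, 1:2, 1:3), "node sets")
})

test_that("regression error vanishes for constant and linear fields", {
  sph <- icosphere_mesh(2, 10)
  const <- tibble::tibble(node_id = sph$nodes$node_id, thickness = 1.77)
  E <- regression_errors(sph, const)
  expect_lt(max(E$E), 1e-12)
  lin <- tibble::tibble(node_id = sph$nodes$node_id,
                        thickness = 5 + 0.3 * sph$nodes$x - 0.1 * sph$nodes$y +
                          0.7 * sph$nodes$z)
  E <- regression_errors(sph, lin)
  expect_lt(max(E$E), 1e-12)
})

test_that("regression error equals an independent normal-equations solve", {
  # a node with 5 hand-placed neighbours and a nonlinear field
  nodes <- tibble::tibble(
    node_id = 1:6,
    x = c(0, 1, -1, 0.2, 0.5, -0.4),
    y = c(0, 0.1, 0.3, 1, -1, -0.8),
    z = c(0, 0.5, 0.2, -0.3, 0.4, 1))
  faces <- tibble::tibble(elem_id = 1:5,
                          n1 = 1L, n2 = 2:6, n3 = c(3:6, 2L))
  mesh <- surface_mesh(nodes, faces)
  fv <- c(0.5, 1.2, 0.9, 2.0, 0.3, 1.1)
  field <- tibble::tibble(node_id = 1:6, thickness = fv)
  E1 <- local_regression_error(mesh, field, node = 1)
  X <- cbind(as.matrix(nodes[2:6, c("x", "y", "z")]), 1)
  beta_hat <- solve(t(X) %*% X, t(X) %*% fv[2:6])
  expect_equal(E1, sum((X %*% beta_hat - fv[2:6])^2), tolerance = 1e-9)
})

test_that("fewer than four neighbours still yields a defined residual", {
  # single triangle: each node has two neighbours; 4-parameter model with
  # 2 observations -> minimum-norm fit interpolates, residual 0
  tri <- surface_mesh(
    tibble::tibble(node_id = 1:3, x = c(0, 1, 0), y = c(0, 0, 1), z = 0),
    tibble::tibble(elem_id = 1L, n1 = 1L, n2 = 2L, n3 = 3L))
  field <- tibble::tibble(node_id = 1:3, thickness = c(1, 5, 9))
  E <- regression_errors(tri, field)
  expect_equal(E$E, rep(0, 3))
  expect_equal(E$m, rep(2L, 3))
})

test_that("reported smoothness follows the prose orientation", {
  expect_equal(as.numeric(smoothness(c(0, 0), c(0, 0), c(2, 2))), 0)  # beta = 0
  expect_equal(as.numeric(smoothness(c(2, 2), c(0, 0), c(2, 2))), 1)  # anchor
  s <- smoothness(c(1, 1), c(0, 0), c(2, 2))
  expect_equal(attr(s, "retention"), 0.25)
  expect_equal(as.numeric(s), 0.75)
  expect_warning(s0 <- smoothness(c(1, 1), c(1, 1), c(1, 1)), "identical")
  expect_equal(as.numeric(s0), 1)
  expect_error(smoothness(1:3, 1:2, 1:3), "node sets")
})

test_that("the beta sweep anchors its metrics and accuracy is non-decreasing", {
  tp <- transfer_problem(fixture_spec(level = 2))
  sw <- beta_sweep(tp$pair$target, tp$src_nodes)
  tab <- sw$table
  expect_equal(tab$accuracy[tab$beta == 0], 0)
  expect_equal(tab$accuracy[tab$beta == 50], 1)
  expect_equal(tab$smoothness[tab$beta == 0], 0)
  expect_equal(tab$smoothness[tab$beta == 50], 1)
  expect_true(all(diff(tab$accuracy) >= -1e-9))
  # smoothness retention decays to 0 once past the bulls-eye regime
  tail_ret <- tab$retention[tab$beta >= 3]
  expect_true(all(diff(tail_ret) <= 1e-9))
  expect_true(is.finite(sw$selected_beta))
  expect_gte(sw$selected_beta, 0)
  expect_lte(sw$selected_beta, 50)
})

test_that("a two-point grid selects the straight-line crossing", {
  tp <- transfer_problem(fixture_spec(level = 1))
  sw <- beta_sweep(tp$pair$target, tp$src_nodes, betas = c(0, 50))
  # A goes (0,0)->(50,1) and retention (0,1)->(50,0): lines cross at 25
  expect_equal(sw$selected_beta, 25)
})

test_that("sweep rejects invalid grids", {
  tp <- transfer_problem(fixture_spec(level = 1))
  expect_error(beta_sweep(tp$pair$target, tp$src_nodes, betas = c(1, 50)),
               "contain beta = 0")
  expect_error(beta_sweep(tp$pair$target, tp$src_nodes, betas = c(0, 4),
                          beta_max = 50), "beta_max")
  expect_error(beta_sweep(tp$pair$target, tp$src_nodes, betas = c(-1, 0, 50)),
               "negative")
})

test_that("tidiers and autoplot expose the sweep", {
  tp <- transfer_problem(fixture_spec(level = 1))
  sw <- beta_sweep(tp$pair$target, tp$src_nodes, betas = c(0, 2, 50))
  expect_s3_class(tidy(sw), "tbl_df")
  expect_named(glance(sw), c("selected_beta", "beta_max", "n_betas", "n_target"))
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
})
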