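test_that("logarithmic covariance has its analytic values and rejects h < 0", {
  expect_equal(kriging_covariance(1), 0)
  expect_equal(kriging_covariance(0), 0)
  expect_equal(kriging_covariance(exp(1)), exp(2))
  expect_error(kriging_covariance(-0.1), "negative")
  # optional kinds behave as their formulas at a probe distance
  expect_equal(kriging_covariance(2, "linear"), 2)
  expect_equal(kriging_covariance(2, "cubic"), 8)
  expect_equal(kriging_covariance(2, "gaussian", eps = 2), exp(-1))
  expect_equal(kriging_covariance(3, "multiquadric", eps = 4), 5)
  expect_equal(kriging_covariance(3, "inverse_multiquadric", eps = 4), 0.2)
})

test_that("identity correspondence yields the identity map with zero fluctuation", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3) * 5
  m <- fit_kriging(X, X)
  expect_lt(max(abs(m$b)), 1e-9)
  expect_equal(m$a, rbind(0, diag(3)), tolerance = 1e-9, ignore_attr = TRUE)
  P <- matrix(rnorm(60), 20, 3)
  expect_equal(apply_kriging(P, m), P, tolerance = 1e-9)
})

test_that("affine correspondences are absorbed entirely by the drift", {
  set.seed(21)
  X <- matrix(rnorm(36), 12, 3) * 10
  A <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
  shift <- c(4, -7, 2)
  Y <- sweep(X %*% t(A), 2, shift, "+")
  m <- fit_kriging(X, Y)
  expect_lt(max(abs(m$b)), 1e-8)
  P <- matrix(rnorm(300), 100, 3) * 10
  truth <- sweep(P %*% t(A), 2, shift, "+")
  expect_lt(max(abs(apply_kriging(P, m) - truth)) / max(abs(truth)), 1e-6)
})

test_that("the fitted map interpolates arbitrary matched points exactly", {
  set.seed(31)
  X <- matrix(rnorm(36), 12, 3) * 10
  Y <- X + matrix(rnorm(36), 12, 3) * 2      # non-affine correspondence
  for (kind in c("logarithmic", "linear", "cubic", "multiquadric")) {
    m <- fit_kriging(X, Y, kind = kind)
    expect_lt(max(abs(apply_kriging(X, m) - Y)), 1e-8)
  }
})

test_that("side conditions hold after every fit", {
  set.seed(41)
  for (rep in 1:5) {
    X <- matrix(rnorm(45), 15, 3) * 8
    Y <- X + matrix(rnorm(45), 15, 3)
    m <- fit_kriging(X, Y)
    expect_lt(max(abs(t(cbind(1, X)) %*% m$b)), 1e-9)
  }
})

test_that("the morph is translation-equivariant", {
  set.seed(51)
  X <- matrix(rnorm(30), 10, 3) * 10
  Y <- X + matrix(rnorm(30), 10, 3)
  P <- matrix(rnorm(90), 30, 3) * 10
  v <- c(13.5, -8.25, 4.75)
  m0 <- fit_kriging(X, Y)
  m1 <- fit_kriging(sweep(X, 2, v, "+"), sweep(Y, 2, v, "+"))
  out0 <- apply_kriging(P, m0)
  out1 <- apply_kriging(sweep(P, 2, v, "+"), m1)
  expect_equal(out1, sweep(out0, 2, v, "+"), tolerance = 1e-9)
})

test_that("coordinate rescaling changes results by less than 1e-6", {
  set.seed(61)
  X <- matrix(rnorm(36), 12, 3) * 100
  Y <- X + matrix(rnorm(36), 12, 3) * 5
  P <- matrix(rnorm(60), 20, 3) * 100
  raw <- apply_kriging(P, fit_kriging(X, Y))
  scl <- apply_kriging(P, fit_kriging(X, Y, rescale = TRUE))
  expect_lt(max(abs(raw - scl)), 1e-6)
})

test_that("degenerate landmark sets are rejected with informative errors", {
  set.seed(71)
  X <- cbind(rnorm(8), rnorm(8), 0)          # coplanar
  expect_error(fit_kriging(X, X + 0.1), "singular|rank")
  X2 <- matrix(rnorm(30), 10, 3)
  X2[2, ] <- X2[1, ]                         # duplicated point
  expect_error(fit_kriging(X2, X2), "duplicated")
  expect_error(fit_kriging(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3)),
               "at least 5")
  ls <- tibble::tibble(label = letters[1:6], x = rnorm(6), y = rnorm(6), z = rnorm(6))
  lt <- ls; lt$label <- rev(lt$label)
  expect_error(fit_kriging(ls, lt), "label")
})

test_that("morph quality matches a brute-force all-pairs nearest-neighbour oracle", {
  spec <- fixture_spec(level = 2)
  tp <- transfer_problem(spec)
  mq <- morph_quality(tp$morphed, tp$pair$target,
                      apply_kriging(tp$pair$landmarks_source, tp$model),
                      tp$pair$landmarks_target)
  M <- as.matrix(tp$morphed$nodes[, c("x", "y", "z")])
  Tm <- as.matrix(tp$pair$target$nodes[, c("x", "y", "z")])
  q_brute <- apply(Tm, 1, function(p) sqrt(min(colSums((t(M) - p)^2))))
  expect_equal(mq$q$q, q_brute)
  expect_equal(mq$mean_q, mean(q_brute))
  expect_equal(mq$max_q, max(q_brute))
  # interpolation makes the landmark RMSE vanish
  expect_lt(mq$rmse, 1e-8)
  # identical meshes give all-zero quality
  mq0 <- morph_quality(tp$pair$target, tp$pair$target)
  expect_equal(mq0$mean_q, 0)
  expect_equal(mq0$max_q, 0)
})

test_that("affine-consistent landmarks survive optimization untouched", {
  spec <- fixture_spec(level = 1, seed = 3)
  pr <- make_target_pair(spec, affine_deformation(diag(c(0.8, 0.9, 1.1)),
                                                  c(5, -2, 1)), jitter = 0)
  opt <- optimize_control_points(pr$landmarks_source, pr$landmarks_target)
  expect_equal(nrow(opt$trace), 0)
  expect_lt(opt$final_rmse, 1e-8)
})

test_that("an injected 10 mm outlier landmark is eliminated in round 1", {
  spec <- fixture_spec(level = 2, seed = 7, outlier = list(index = 3, offset = 10))
  pr <- make_target_pair(spec, bulge_deformation())
  opt <- optimize_control_points(pr$landmarks_source, pr$landmarks_target)
  expect_gte(nrow(opt$trace), 1)
  expect_equal(opt$trace$removed_index[1], 3)
  expect_lt(opt$final_rmse, opt$initial_rmse)
  # accepted RMSE trace is monotone non-increasing
  expect_true(all(diff(c(opt$initial_rmse, opt$trace$rmse)) <= 0))
})
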