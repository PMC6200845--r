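test_that("icosphere subdivision has the exact combinatorics", {
  ico <- icosphere_mesh(0)
  expect_equal(nrow(ico$nodes), 12)
  expect_equal(nrow(ico$faces), 20)
  lvl2 <- icosphere_mesh(2, radius = 10)
  expect_equal(nrow(lvl2$nodes), 10 * 4^2 + 2)
  expect_equal(nrow(lvl2$faces), 20 * 4^2)
  expect_equal(sqrt(rowSums(as.matrix(lvl2$nodes[, c("x", "y", "z")])^2)),
               rep(10, 162))
})

test_that("generated layers satisfy every structural invariant", {
  for (spec in list(fixture_spec(level = 1),
                    fixture_spec(surface = "ellipsoid", level = 2, seed = 4),
                    fixture_spec(level = 2, thickness = list(kind = "bumps",
                                                             t0 = 1, amp = 0.3,
                                                             width = 0.5,
                                                             n_bumps = 3)))) {
    fx <- make_solid_shell(spec)
    expect_silent(cortimap:::validate_solid_shell_layer(fx$layer))
    expect_true(all(fx$thickness_fun(fx$u) > 0))
  }
  # a shell thicker than the sphere radius would self-intersect
  expect_error(make_solid_shell(fixture_spec(radius = 1, thickness = list(
    kind = "constant", t0 = 2))), "curvature")
})

test_that("same seed gives byte-identical fixture files, different seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  p1 <- export_fixture(fixture_spec(level = 1, seed = 5), d1)
  p2 <- export_fixture(fixture_spec(level = 1, seed = 5), d2)
  p3 <- export_fixture(fixture_spec(level = 1, seed = 6), d3)
  for (nm in setdiff(names(p1), "manifest")) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  expect_false(identical(readLines(p1[["landmarks_target"]]),
                         readLines(p3[["landmarks_target"]])))
})

test_that("identity deformation on the same tessellation reproduces the source", {
  spec <- fixture_spec(level = 2)
  fx <- make_solid_shell(spec)
  pair <- make_target_pair(spec, identity_deformation(), jitter = 0)
  expect_equal(as.matrix(pair$target$nodes[, c("x", "y", "z")]),
               as.matrix(fx$surface$nodes[, c("x", "y", "z")]))
  expect_equal(morph_quality(fx$surface, pair$target)$mean_q, 0)
})

test_that("affine deformations are recovered exactly from the landmarks", {
  spec <- fixture_spec(level = 2, seed = 3)
  A <- diag(c(0.85, 0.95, 1.08)) + matrix(c(0, 0.05, 0, 0, 0, 0.02, 0, 0, 0), 3, 3)
  pair <- make_target_pair(spec, affine_deformation(A, c(3, 1, -2)), jitter = 0)
  model <- fit_kriging(pair$landmarks_source, pair$landmarks_target)
  src <- make_solid_shell(spec)
  morphed <- apply_kriging(as.matrix(src$surface$nodes[, c("x", "y", "z")]),
                           model)
  truth <- as.matrix(pair$source_truth[, c("x", "y", "z")])
  expect_lt(max(abs(morphed - truth)) / max(abs(truth)), 1e-6)
})

test_that("the bulge morph lands within a tenth of the landmark spacing", {
  spec <- fixture_spec(level = 3)
  tp <- transfer_problem(spec)
  err <- sqrt(rowSums((as.matrix(tp$morphed$nodes[, c("x", "y", "z")]) -
                         as.matrix(tp$pair$source_truth[, c("x", "y", "z")]))^2))
  lm <- as.matrix(tp$pair$landmarks_source[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(lm))
  diag(d) <- Inf
  spacing <- mean(apply(d, 1, min))
  expect_lt(mean(err), spacing / 10)
})

test_that("landmark noise and outliers are applied as specified", {
  clean <- make_target_pair(fixture_spec(level = 1, seed = 9),
                            identity_deformation(), jitter = 0)
  noisy <- make_target_pair(fixture_spec(level = 1, seed = 9, noise_sd = 0.5),
                            identity_deformation(), jitter = 0)
  expect_equal(clean$landmarks_source, noisy$landmarks_source)
  shift <- as.matrix(noisy$landmarks_target[, c("x", "y", "z")]) -
    as.matrix(clean$landmarks_target[, c("x", "y", "z")])
  expect_true(all(abs(shift) > 0))
  expect_lt(max(abs(shift)), 0.5 * 5)   # gaussian, 5 sd
  out <- make_target_pair(fixture_spec(level = 1, seed = 9,
                                       outlier = list(index = 2, offset = 10)),
                          identity_deformation(), jitter = 0)
  d <- sqrt(rowSums((as.matrix(out$landmarks_target[, c("x", "y", "z")]) -
                       as.matrix(clean$landmarks_target[, c("x", "y", "z")]))^2))
  expect_equal(d[2], 10)
  expect_equal(d[-2], rep(0, length(d) - 1))
})
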