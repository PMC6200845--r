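test_that("minimal keyword file with one hexahedron parses to a solid layer", {
  k <- c("*KEYWORD",
         "$ comment line",
         "*NODE",
         "1,0,0,0", "2,1,0,0", "3,1,1,0", "4,0,1,0",
         "5,0,0,2", "6,1,0,2", "7,1,1,2", "8,0,1,2",
         "*ELEMENT_SOLID",
         "1,1,1,2,3,4,5,6,7,8",
         "*END")
  path <- withr::local_tempfile(fileext = ".k")
  writeLines(k, path)
  layer <- read_mesh(path)
  expect_s3_class(layer, "solid_shell_layer")
  expect_equal(nrow(layer$solids), 1)
  expect_equal(nrow(layer$nodes), 8)
  # derived surfaces: top quad at z = 2 is larger? equal area -> either
  # labelling is structurally valid
  expect_setequal(c(layer$outer_nodes, layer$inner_nodes), 1:8)
})

test_that("fixed-width node and element cards parse like comma-separated ones", {
  fw <- c("*KEYWORD", "*NODE",
          sprintf("%8d%16.6f%16.6f%16.6f", 1:8,
                  c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 2, 2, 2, 2)),
          "*ELEMENT_SOLID",
          sprintf("%8d%8d%8d%8d%8d%8d%8d%8d%8d%8d",
                  1, 1, 1, 2, 3, 4, 5, 6, 7, 8),
          "*END")
  path <- withr::local_tempfile(fileext = ".k")
  writeLines(fw, path)
  layer <- read_mesh(path)
  expect_equal(nrow(layer$nodes), 8)
  expect_equal(as.integer(layer$solids[1, paste0("n", 1:8)]), 1:8)
})

test_that("malformed cards raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".k")
  writeLines(c("*KEYWORD", "*NODE", "1,0,0,0", "2,oops,0,0", "*END"), path)
  expect_error(read_mesh(path), "line 4")
  writeLines(c("no keyword here"), path)
  expect_error(read_mesh(path), "no keyword")
})

test_that("keyword round trip preserves ids, coordinates and connectivity", {
  fx <- make_solid_shell(fixture_spec(level = 1))
  path <- withr::local_tempfile(fileext = ".k")
  write_mesh(fx$layer, path)
  back <- read_mesh(path)
  expect_equal(back$nodes$node_id, fx$layer$nodes$node_id)
  expect_equal(as.matrix(back$nodes[, c("x", "y", "z")]),
               as.matrix(fx$layer$nodes[, c("x", "y", "z")]),
               tolerance = 1e-8)
  expect_equal(back$solids, fx$layer$solids)
  expect_equal(back$outer_nodes, fx$layer$outer_nodes)
  expect_equal(back$inner_nodes, fx$layer$inner_nodes)

  spath <- withr::local_tempfile(fileext = ".k")
  write_mesh(fx$surface, spath)
  sback <- read_mesh(spath)
  expect_equal(sback$faces$n1, fx$surface$faces$n1)
  expect_equal(sback$faces$n3, fx$surface$faces$n3)
})

test_that("inner/outer sets are derivable from topology alone", {
  fx <- make_solid_shell(fixture_spec(level = 1))
  path <- withr::local_tempfile(fileext = ".k")
  write_mesh(fx$layer, path)
  # strip the explicit node-set cards and re-read
  lines <- readLines(path)
  i <- grep("^\\*SET_NODE_LIST", lines)[1]
  j <- grep("^\\*END", lines)
  writeLines(c(lines[seq_len(i - 1)], "*END"), path)
  back <- read_mesh(path)
  # the outer sphere has the larger area, so labelling must match
  expect_equal(back$outer_nodes, fx$layer$outer_nodes)
  expect_equal(back$inner_nodes, fx$layer$inner_nodes)
})

test_that("VTK and OBJ surfaces round trip", {
  sph <- icosphere_mesh(1, radius = 7)
  for (ext in c(".vtk", ".obj")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(sph, path)
    back <- read_mesh(path)
    expect_equal(as.matrix(back$nodes[, c("x", "y", "z")]),
                 as.matrix(sph$nodes[, c("x", "y", "z")]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(back$faces$n1, sph$faces$n1)
    expect_equal(back$faces$n3, sph$faces$n3)
  }
})

test_that("fixture shell at level 2 has the expected element count and structure", {
  layer <- make_solid_shell(fixture_spec(level = 2, seed = 1))$layer
  expect_equal(nrow(layer$solids), 320)
  # validator enforces exactly one inner and one outer face per element
  expect_silent(cortimap:::validate_solid_shell_layer(layer))
})

test_that("shell thickness cards echo values and round trip at 6+ significant digits", {
  mesh <- surface_mesh(
    tibble::tibble(node_id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1), z = 0),
    tibble::tibble(elem_id = 1:2, n1 = c(1, 2), n2 = c(2, 4), n3 = c(3, 3)))
  path <- withr::local_tempfile(fileext = ".k")

  tri <- surface_mesh(mesh$nodes[1:3, ], mesh$faces[1, ])
  write_shell_thickness(tri, tibble::tibble(node_id = 1:3,
                                            thickness = c(1, 2, 3)), path)
  back <- read_shell_thickness(path)
  expect_equal(back$field$thickness[order(back$field$node_id)], c(1, 2, 3))

  # uniform surrogate value on a 2-triangle mesh: every slot identical
  write_shell_thickness(mesh, tibble::tibble(node_id = 1:4,
                                             thickness = rep(1.77, 4)), path)
  txt <- readLines(path)
  tcards <- txt[grep("ELEMENT_SHELL_THICKNESS", txt) + c(2, 4)]
  expect_true(all(vapply(strsplit(tcards, ","),
                         function(v) all(as.numeric(v) == 1.77), logical(1))))

  # many-digit values survive
  field <- tibble::tibble(node_id = 1:4,
                          thickness = c(1.234567891, 0.2987654321, 8.33123456, 2.5))
  write_shell_thickness(mesh, field, path)
  back <- read_shell_thickness(path)
  got <- back$field$thickness[order(back$field$node_id)]
  expect_equal(got, field$thickness, tolerance = 1e-7)

  expect_error(
    write_shell_thickness(mesh, tibble::tibble(node_id = 1:3,
                                               thickness = 1:3), path),
    "node id 4")
})
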