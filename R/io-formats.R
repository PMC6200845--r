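#' Read a mesh from file
#'
#' Reads a surface mesh or a one-element-thick solid layer from LS-Dyna
#' keyword (`.k`, `.key`, `.dyn`), legacy ASCII VTK (`.vtk`) or Wavefront OBJ
#' (`.obj`) files. LS-Dyna files containing `*ELEMENT_SOLID` cards return a
#' [solid_shell_layer()] (inner/outer surface sets taken from
#' `*SET_NODE_LIST_TITLE` cards named `OUTER`/`INNER`, or derived from
#' element topology); all other inputs return a [surface_mesh()].
#'
#' @param path input file.
#' @param format one of `"auto"` (default: infer from the file extension),
#'   `"lsdyna"`, `"vtk"`, `"obj"`.
#' @return A [surface_mesh()] or [solid_shell_layer()], validated.
#' @seealso [write_mesh()], [write_shell_thickness()]
#' @export
read_mesh <- function(path, format = c("auto", "lsdyna", "vtk", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("read_mesh: file not found: ", path))
  if (format == "auto") format <- guess_format(path)
  switch(format,
         lsdyna = read_lsdyna(path),
         vtk = read_vtk(path),
         obj = read_obj(path))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         k = , key = , dyn = "lsdyna",
         vtk = "vtk",
         obj = "obj",
         abort(paste0("read_mesh: cannot infer format from extension '.",
                      ext, "'; pass format= explicitly")))
}

#' Write a mesh to file
#'
#' Writes a [surface_mesh()] (all formats) or a [solid_shell_layer()]
#' (LS-Dyna only; wedges are emitted as collapsed hexahedra and the surface
#' node sets as titled `*SET_NODE_LIST` cards, so the file round-trips).
#' LS-Dyna cards are written comma-separated; coordinates carry nine
#' significant digits.
#'
#' @param mesh mesh object.
#' @param path output file.
#' @param format `"auto"` (from extension), `"lsdyna"`, `"vtk"` or `"obj"`.
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "lsdyna", "vtk", "obj")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (inherits(mesh, "solid_shell_layer") && format != "lsdyna") {
    abort("write_mesh: solid layers can only be written in LS-Dyna format")
  }
  switch(format,
         lsdyna = write_lsdyna(mesh, path),
         vtk = write_vtk(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- unlist(strsplit(trimws(lines[-(1:2)]), "\\s+"))  # skip header/title
  toks <- toks[nzchar(toks)]
  ip <- which(toupper(toks) == "POINTS")
  if (length(ip) != 1) abort(paste0("VTK parse error in ", path, ": no POINTS"))
  np <- as.integer(toks[ip + 1])
  coords <- as.numeric(toks[(ip + 3):(ip + 2 + 3 * np)])
  if (anyNA(coords)) abort(paste0("VTK parse error in ", path, ": bad POINTS"))
  pm <- matrix(coords, ncol = 3, byrow = TRUE)
  ic <- which(toupper(toks) %in% c("POLYGONS", "CELLS"))
  if (length(ic) == 0) abort(paste0("VTK parse error in ", path, ": no POLYGONS"))
  ic <- ic[1]
  nc <- as.integer(toks[ic + 1])
  sz <- as.integer(toks[ic + 2])
  cell_toks <- as.integer(toks[(ic + 3):(ic + 2 + sz)])
  faces <- matrix(NA_integer_, nc, 4)
  pos <- 1
  for (i in seq_len(nc)) {
    k <- cell_toks[pos]
    if (!k %in% c(3L, 4L)) {
      abort(paste0("VTK parse error in ", path, ": only tri/quad cells supported"))
    }
    faces[i, seq_len(k)] <- cell_toks[(pos + 1):(pos + k)] + 1L  # 0- to 1-based
    pos <- pos + k + 1
  }
  surface_mesh(
    tibble::tibble(node_id = seq_len(np), x = pm[, 1], y = pm[, 2], z = pm[, 3]),
    tibble::tibble(elem_id = seq_len(nc), n1 = faces[, 1], n2 = faces[, 2],
                   n3 = faces[, 3], n4 = faces[, 4]))
}

write_vtk <- function(mesh, path) {
  # VTK uses dense 0-based indices; compact the node ids
  ids <- mesh$nodes$node_id
  remap <- setNames(seq_along(ids) - 1L, as.character(ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cortimap surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", length(ids))), con)
  writeLines(paste(fmt_num(mesh$nodes$x), fmt_num(mesh$nodes$y),
                   fmt_num(mesh$nodes$z)), con)
  f <- mesh$faces
  sizes <- ifelse(is.na(f$n4), 3L, 4L)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), sum(sizes + 1L)), con)
  for (i in seq_len(nrow(f))) {
    v <- as.integer(f[i, paste0("n", 1:4)])
    v <- v[!is.na(v)]
    writeLines(paste(c(length(v), remap[as.character(v)]), collapse = " "), con)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) {
    abort(paste0("OBJ parse error in ", path, ": need v and f records"))
  }
  vm <- t(vapply(strsplit(trimws(vl), "\\s+"),
                 function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- matrix(NA_integer_, length(fl), 4)
  for (i in seq_along(fl)) {
    t <- strsplit(trimws(fl[i]), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(t, "/"), `[`, character(1), 1))
    if (!length(idx) %in% c(3, 4) || anyNA(idx)) {
      abort(paste0("OBJ parse error in ", path, ": bad face '", fl[i], "'"))
    }
    faces[i, seq_along(idx)] <- idx
  }
  surface_mesh(
    tibble::tibble(node_id = seq_len(nrow(vm)),
                   x = vm[, 1], y = vm[, 2], z = vm[, 3]),
    tibble::tibble(elem_id = seq_len(nrow(faces)), n1 = faces[, 1],
                   n2 = faces[, 2], n3 = faces[, 3], n4 = faces[, 4]))
}

write_obj <- function(mesh, path) {
  ids <- mesh$nodes$node_id
  remap <- setNames(seq_along(ids), as.character(ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", fmt_num(mesh$nodes$x), fmt_num(mesh$nodes$y),
                   fmt_num(mesh$nodes$z)), con)
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    v <- as.integer(f[i, paste0("n", 1:4)])
    v <- v[!is.na(v)]
    writeLines(paste(c("f", remap[as.character(v)]), collapse = " "), con)
  }
  invisible(path)
}

#' Read or write a landmark table
#'
#' Landmarks (morphing control points) are stored as CSV with header
#' `label,x,y,z`; coordinates in mm. Two matched sets must share the same
#' label sequence.
#'
#' @param path CSV file.
#' @return `read_landmarks()`: a tibble with columns `label`, `x`, `y`, `z`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(paste0("landmark CSV ", path, " must have header label,x,y,z"))
  }
  tibble::as_tibble(df[, need])
}

#' @rdname read_landmarks
#' @param landmarks data frame with columns `label`, `x`, `y`, `z`.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks[, c("label", "x", "y", "z")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
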