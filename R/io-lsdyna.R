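# LS-Dyna keyword reader/writer. Covers the cards the mapping workflow
# needs: *NODE, *ELEMENT_SOLID, *ELEMENT_SHELL, *ELEMENT_SHELL_THICKNESS,
# *SET_NODE_LIST[_TITLE], *END. Cards may be comma-separated (what we write)
# or fixed-width; `$` lines are comments. Node ids are 1-based per the
# keyword standard.

lsdyna_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*\\$", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  is_kw <- grepl("^\\*", lines)
  if (!any(is_kw)) {
    abort(paste0("LS-Dyna parse error in ", path, ": no keyword cards found"))
  }
  starts <- which(is_kw)
  ends <- c(starts[-1] - 1, length(lines))
  blocks <- list()
  for (b in seq_along(starts)) {
    kw <- toupper(trimws(lines[starts[b]]))
    if (kw == "*END") break
    body_idx <- if (ends[b] > starts[b]) (starts[b] + 1):ends[b] else integer(0)
    blocks[[length(blocks) + 1]] <-
      list(keyword = kw, lines = lines[body_idx], lineno = lineno[body_idx])
  }
  blocks
}

# split one card line into fields: comma-separated, whitespace, or
# fixed-width (given the field widths) as a last resort
parse_card <- function(line, widths, min_fields, lineno, path) {
  if (grepl(",", line, fixed = TRUE)) {
    f <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  } else {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < min_fields) {
      # fixed-width slice
      pos <- cumsum(c(1, widths))
      f <- character(length(widths))
      for (k in seq_along(widths)) {
        f[k] <- trimws(substr(line, pos[k], pos[k + 1] - 1))
      }
    }
  }
  f <- f[nzchar(f)]
  v <- suppressWarnings(as.numeric(f))
  if (length(v) < min_fields || anyNA(v[seq_len(min_fields)])) {
    abort(sprintf("LS-Dyna parse error in %s at line %d: malformed card '%s'",
                  path, lineno, line))
  }
  v
}

parse_node_block <- function(block, path) {
  n <- length(block$lines)
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    v <- parse_card(block$lines[i], widths = c(8, 16, 16, 16),
                    min_fields = 4, block$lineno[i], path)
    out[i, ] <- v[1:4]
  }
  tibble::tibble(node_id = as.integer(out[, 1]),
                 x = out[, 2], y = out[, 3], z = out[, 4])
}

parse_solid_block <- function(block, path) {
  n <- length(block$lines)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- parse_card(block$lines[i], widths = rep(8, 10),
                    min_fields = 8, block$lineno[i], path)
    nd <- as.integer(v[-(1:2)])
    nd <- nd[!is.na(nd) & nd > 0]
    if (length(nd) == 8 && nd[3] == nd[4] && nd[7] == nd[8]) {
      nd <- nd[c(1, 2, 3, 5, 6, 7)]        # collapsed hexa -> wedge
    }
    if (!length(nd) %in% c(6, 8)) {
      abort(sprintf(
        "LS-Dyna parse error in %s at line %d: solid element with %d nodes",
        path, block$lineno[i], length(nd)))
    }
    rows[[i]] <- c(as.integer(v[1]), nd, rep(NA_integer_, 8 - length(nd)))
  }
  m <- do.call(rbind, rows)
  tibble::as_tibble(setNames(as.data.frame(m), c("elem_id", paste0("n", 1:8))))
}

parse_shell_block <- function(block, path, thickness = FALSE) {
  rows <- list()
  tvals <- list()
  i <- 1
  while (i <= length(block$lines)) {
    v <- parse_card(block$lines[i], widths = rep(8, 6),
                    min_fields = 5, block$lineno[i], path)
    nd <- as.integer(v[3:min(6, length(v))])
    nd <- nd[!is.na(nd)]
    if (length(nd) == 3) nd <- c(nd, NA_integer_)
    rows[[length(rows) + 1]] <- c(as.integer(v[1]), nd)
    if (thickness) {
      if (i + 1 > length(block$lines)) {
        abort(sprintf(
          "LS-Dyna parse error in %s at line %d: missing thickness card",
          path, block$lineno[i]))
      }
      tv <- parse_card(block$lines[i + 1], widths = rep(16, 4),
                       min_fields = 3, block$lineno[i + 1], path)
      tvals[[length(rows)]] <- tv
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  m <- do.call(rbind, rows)
  faces <- tibble::as_tibble(
    setNames(as.data.frame(m), c("elem_id", paste0("n", 1:4))))
  list(faces = faces, tvals = tvals)
}

parse_set_block <- function(block, titled, path) {
  title <- NA_character_
  body <- block$lines
  lineno <- block$lineno
  if (titled) {
    title <- trimws(body[1])
    body <- body[-1]; lineno <- lineno[-1]
  }
  # first card is the set id; remaining cards are node ids, 8 per card
  ids <- integer(0)
  for (i in seq_along(body)[-1]) {
    v <- parse_card(body[i], widths = rep(10, 8), min_fields = 1,
                    lineno[i], path)
    ids <- c(ids, as.integer(v[!is.na(v) & v > 0]))
  }
  list(title = title, ids = ids)
}

read_lsdyna <- function(path) {
  blocks <- lsdyna_blocks(path)
  nodes <- list(); solids <- list(); shells <- list()
  thick <- list(); sets <- list()
  for (b in blocks) {
    kw <- b$keyword
    if (kw == "*NODE") {
      nodes[[length(nodes) + 1]] <- parse_node_block(b, path)
    } else if (kw == "*ELEMENT_SOLID") {
      solids[[length(solids) + 1]] <- parse_solid_block(b, path)
    } else if (kw == "*ELEMENT_SHELL") {
      shells[[length(shells) + 1]] <- parse_shell_block(b, path)$faces
    } else if (kw == "*ELEMENT_SHELL_THICKNESS") {
      res <- parse_shell_block(b, path, thickness = TRUE)
      shells[[length(shells) + 1]] <- res$faces
      thick[[length(thick) + 1]] <- res
    } else if (kw %in% c("*SET_NODE_LIST", "*SET_NODE_LIST_TITLE")) {
      sets[[length(sets) + 1]] <-
        parse_set_block(b, titled = kw == "*SET_NODE_LIST_TITLE", path)
    } # other keywords (*KEYWORD, *PART, ...) are ignored
  }
  if (length(nodes) == 0) {
    abort(paste0("LS-Dyna parse error in ", path, ": no *NODE card"))
  }
  nodes <- dplyr::bind_rows(nodes)
  if (length(solids) > 0) {
    solids <- dplyr::bind_rows(solids)
    surf <- resolve_surfaces(nodes, solids, sets)
    return(solid_shell_layer(nodes, solids, surf$outer, surf$inner))
  }
  if (length(shells) == 0) {
    abort(paste0("LS-Dyna parse error in ", path, ": no element cards"))
  }
  mesh <- surface_mesh(nodes, dplyr::bind_rows(shells))
  if (length(thick) > 0) {
    mesh$thickness <- thickness_field_from_cards(thick)
  }
  mesh
}

thickness_field_from_cards <- function(thick_blocks) {
  ids <- integer(0); vals <- numeric(0)
  for (blk in thick_blocks) {
    f <- blk$faces
    for (i in seq_len(nrow(f))) {
      nd <- as.integer(f[i, paste0("n", 1:4)])
      nd <- nd[!is.na(nd)]
      tv <- blk$tvals[[i]][seq_along(nd)]
      keep <- !duplicated(nd) & !(nd %in% ids)   # triangles repeat node 3
      ids <- c(ids, nd[keep]); vals <- c(vals, tv[keep])
    }
  }
  ord <- order(ids)
  tibble::tibble(node_id = ids[ord], thickness = vals[ord])
}

# determine the inner/outer node sets of a solid layer: use explicit
# OUTER/INNER node-set cards when present, otherwise derive the two cap-node
# families from element topology and call the larger-area family "outer"
resolve_surfaces <- function(nodes, solids, sets) {
  titles <- toupper(vapply(sets, function(s) s$title %||% "", character(1)))
  i_out <- which(titles == "OUTER")
  i_in <- which(titles == "INNER")
  if (length(i_out) == 1 && length(i_in) == 1) {
    return(list(outer = sets[[i_out]]$ids, inner = sets[[i_in]]$ids))
  }
  derive_surfaces(nodes, solids)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

derive_surfaces <- function(nodes, solids) {
  elems <- lapply(seq_len(nrow(solids)), function(i) {
    v <- as.integer(solids[i, paste0("n", 1:8)])
    v[!is.na(v)]
  })
  all_ids <- sort(unique(unlist(elems)))
  parent <- seq_along(all_ids)
  idx <- function(id) match(id, all_ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  caps <- list()
  for (v in elems) {
    if (length(v) == 8) { bot <- v[1:4]; top <- v[5:8] } else { bot <- v[1:3]; top <- v[4:6] }
    bi <- idx(bot); ti <- idx(top)
    for (k in 2:length(bi)) union_(bi[1], bi[k])
    for (k in 2:length(ti)) union_(ti[1], ti[k])
    caps[[length(caps) + 1]] <- list(bot = bot, top = top)
  }
  roots <- vapply(seq_along(all_ids), find, integer(1))
  comp <- unique(roots)
  if (length(comp) != 2) {
    abort(sprintf(
      paste0("cannot derive inner/outer surfaces: found %d node families ",
             "instead of 2; supply *SET_NODE_LIST_TITLE cards named OUTER and INNER"),
      length(comp)))
  }
  fam <- list(all_ids[roots == comp[1]], all_ids[roots == comp[2]])
  # larger total cap area -> outer (true for a shell offset inward)
  co <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(co) <- as.character(nodes$node_id)
  area <- c(0, 0)
  poly_area <- function(ids) {
    p <- co[as.character(ids), , drop = FALSE]
    a <- 0
    for (k in 2:(nrow(p) - 1)) {
      a <- a + sqrt(sum(cross3(p[k, ] - p[1, ], p[k + 1, ] - p[1, ])^2)) / 2
    }
    a
  }
  for (cp in caps) {
    for (f in cp) {
      which_fam <- if (f[1] %in% fam[[1]]) 1 else 2
      area[which_fam] <- area[which_fam] + poly_area(f)
    }
  }
  if (area[1] >= area[2]) list(outer = fam[[1]], inner = fam[[2]])
  else list(outer = fam[[2]], inner = fam[[1]])
}

fmt_num <- function(x) sprintf("%.9g", x)

write_lsdyna <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("*KEYWORD", "$ written by cortimap", "*NODE"), con)
  nd <- mesh$nodes
  writeLines(paste(nd$node_id, fmt_num(nd$x), fmt_num(nd$y), fmt_num(nd$z),
                   sep = ","), con)
  if (inherits(mesh, "solid_shell_layer")) {
    writeLines("*ELEMENT_SOLID", con)
    s <- mesh$solids
    for (i in seq_len(nrow(s))) {
      v <- as.integer(s[i, paste0("n", 1:8)])
      v <- v[!is.na(v)]
      if (length(v) == 6) v <- v[c(1, 2, 3, 3, 4, 5, 6, 6)]  # wedge as collapsed hexa
      writeLines(paste(c(s$elem_id[i], 1L, v), collapse = ","), con)
    }
    write_node_set(con, "OUTER", 1L, mesh$outer_nodes)
    write_node_set(con, "INNER", 2L, mesh$inner_nodes)
  } else {
    writeLines("*ELEMENT_SHELL", con)
    f <- mesh$faces
    for (i in seq_len(nrow(f))) {
      v <- as.integer(f[i, paste0("n", 1:4)])
      if (is.na(v[4])) v[4] <- v[3]   # triangle: repeat third node
      writeLines(paste(c(f$elem_id[i], 1L, v), collapse = ","), con)
    }
  }
  writeLines("*END", con)
  invisible(path)
}

write_node_set <- function(con, title, sid, ids) {
  writeLines(c("*SET_NODE_LIST_TITLE", title, as.character(sid)), con)
  for (start in seq(1, length(ids), by = 8)) {
    chunk <- ids[start:min(start + 7, length(ids))]
    writeLines(paste(chunk, collapse = ","), con)
  }
}

#' Write a per-node thickness field as LS-Dyna shell cards
#'
#' Emits the mesh as `*NODE` plus `*ELEMENT_SHELL_THICKNESS` cards: for each
#' shell element, one card with its node ids followed by one card with the
#' thickness at each of its nodes. This is the LS-Dyna representation of a
#' shell part whose thickness varies with nodal resolution. Values are
#' written with nine significant digits and survive a read/write round trip
#' to at least six.
#'
#' @param mesh a [surface_mesh()].
#' @param field data frame with columns `node_id` and `thickness` (mm)
#'   covering every node referenced by a face of `mesh`.
#' @param path output file path.
#' @return The path, invisibly.
#' @seealso [read_shell_thickness()]
#' @export
write_shell_thickness <- function(mesh, field, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  field <- tibble::as_tibble(field)
  ref <- unique(stats::na.omit(unlist(mesh$faces[, paste0("n", 1:4)])))
  missing <- setdiff(ref, field$node_id)
  if (length(missing) > 0) {
    abort(paste0("write_shell_thickness: no thickness value for node id ",
                 paste(head(sort(missing), 5), collapse = ", ")))
  }
  tval <- setNames(field$thickness, as.character(field$node_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("*KEYWORD", "$ written by cortimap", "*NODE"), con)
  nd <- mesh$nodes
  writeLines(paste(nd$node_id, fmt_num(nd$x), fmt_num(nd$y), fmt_num(nd$z),
                   sep = ","), con)
  writeLines("*ELEMENT_SHELL_THICKNESS", con)
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    v <- as.integer(f[i, paste0("n", 1:4)])
    tri <- is.na(v[4])
    if (tri) v[4] <- v[3]
    writeLines(paste(c(f$elem_id[i], 1L, v), collapse = ","), con)
    tv <- tval[as.character(v)]
    writeLines(paste(fmt_num(tv), collapse = ","), con)
  }
  writeLines("*END", con)
  invisible(path)
}

#' Read back a nodal thickness field from an LS-Dyna file
#'
#' @param path file containing `*ELEMENT_SHELL_THICKNESS` cards.
#' @return A list with the `mesh` (a [surface_mesh()]) and the `field`
#'   (tibble `node_id`, `thickness`).
#' @export
read_shell_thickness <- function(path) {
  mesh <- read_lsdyna(path)
  if (!inherits(mesh, "surface_mesh") || is.null(mesh$thickness)) {
    abort(paste0(path, ": no *ELEMENT_SHELL_THICKNESS cards found"))
  }
  field <- mesh$thickness
  mesh$thickness <- NULL
  list(mesh = mesh, field = field)
}
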