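# ---------------------------------------------------------------------------
# File I/O: Gmsh MSH (ASCII v2.2 / v4.1) input, legacy-VTK output, ASCII /
# binary STL input (untagged geometry, display only).
# ---------------------------------------------------------------------------

GMSH_LINE <- 1L; GMSH_TRI <- 2L; GMSH_QUAD <- 3L; GMSH_TET <- 4L
GMSH_POINT <- 15L
gmsh_nnodes <- c(`1` = 2L, `2` = 3L, `3` = 4L, `4` = 4L, `5` = 8L,
                 `6` = 6L, `7` = 5L, `15` = 1L)

#' Read an ASCII Gmsh MSH mesh (v2.2 or v4.1)
#'
#' The file must contain exactly one volumetric element family: all
#' tetrahedra (3D; triangles are then boundary tags) or all triangles
#' (2D; lines are boundary tags). Boundary faces are tagged from the
#' physical groups of the lower-dimensional elements and renamed through
#' `patch_name_map`.
#'
#' @param path path to an ASCII `.msh` file.
#' @param patch_name_map named character vector or list mapping physical
#'   group names to patch labels (typically `origin`, `insertion`, `belly`).
#'   Unmapped group names are kept verbatim. An entry named `".default"`
#'   labels boundary faces that belong to no physical group; without it such
#'   faces raise an "untagged boundary" error.
#' @return a finalized [simplex_mesh][finalize_mesh] with patches assigned.
#' @examples
#' msh <- system.file("extdata", "single_tet_example.msh",
#'                    package = "fascitrace")
#' read_gmsh_msh(msh, c(prox = "origin", dist = "insertion", side = "belly"))
#' @export
read_gmsh_msh <- function(path, patch_name_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    if (is.na(i0)) return(NULL)
    i1 <- match(paste0("$End", name), lines)
    lines[seq.int(i0 + 1L, i1 - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("unsupported format: missing $MeshFormat")
  ver <- as.numeric(strsplit(trimws(fmt[1]), "\\s+")[[1]][1])
  if (!isTRUE(ver %in% c(2.2, 4.1)))
    stop("unsupported format: MSH version ", ver)

  phys <- parse_physical_names(sec("PhysicalNames"))

  if (ver == 2.2) {
    parsed <- parse_msh22(sec("Nodes"), sec("Elements"))
  } else {
    parsed <- parse_msh41(sec("Entities"), sec("Nodes"), sec("Elements"))
  }
  build_mesh_from_msh(parsed$coords, parsed$node_tags, parsed$elem_type,
                      parsed$elem_nodes, parsed$elem_phys, phys,
                      patch_name_map)
}

parse_physical_names <- function(txt) {
  if (is.null(txt)) return(data.frame(dim = integer(0), id = integer(0),
                                      name = character(0)))
  n <- as.integer(txt[1])
  rows <- txt[seq_len(n) + 1L]
  m <- regmatches(rows, regexec('^\\s*(\\d+)\\s+(\\d+)\\s+"(.*)"\\s*$', rows))
  data.frame(dim = as.integer(vapply(m, `[`, "", 2L)),
             id = as.integer(vapply(m, `[`, "", 3L)),
             name = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
}

num_fields <- function(lines) lapply(strsplit(trimws(lines), "\\s+"), as.numeric)

parse_msh22 <- function(nodes_txt, elems_txt) {
  if (is.null(nodes_txt) || is.null(elems_txt))
    stop("unsupported format: missing $Nodes/$Elements")
  nn <- as.integer(nodes_txt[1])
  nf <- num_fields(nodes_txt[seq_len(nn) + 1L])
  node_tags <- vapply(nf, `[`, 0, 1L)
  coords <- t(vapply(nf, function(v) v[2:4], numeric(3)))
  ne <- as.integer(elems_txt[1])
  ef <- num_fields(elems_txt[seq_len(ne) + 1L])
  elem_type <- vapply(ef, `[`, 0, 2L)
  ntags <- vapply(ef, `[`, 0, 3L)
  elem_phys <- ifelse(ntags >= 1, vapply(ef, `[`, 0, 4L), NA_real_)
  elem_nodes <- lapply(seq_len(ne), function(i)
    ef[[i]][-seq_len(3L + ntags[i])])
  list(coords = coords, node_tags = as.integer(node_tags),
       elem_type = as.integer(elem_type), elem_nodes = elem_nodes,
       elem_phys = as.integer(elem_phys))
}

parse_msh41 <- function(ent_txt, nodes_txt, elems_txt) {
  if (is.null(nodes_txt) || is.null(elems_txt))
    stop("unsupported format: missing $Nodes/$Elements")
  # entity (dim, tag) -> first physical tag
  ent_phys <- list()
  if (!is.null(ent_txt)) {
    counts <- num_fields(ent_txt[1])[[1]]
    k <- 2L
    for (d in 0:3) {
      for (j in seq_len(counts[d + 1L])) {
        v <- num_fields(ent_txt[k])[[1]]; k <- k + 1L
        tag <- v[1]
        npos <- if (d == 0L) 5L else 8L      # points: tag x y z nPhys
        nphys <- v[npos]
        if (isTRUE(nphys >= 1))
          ent_phys[[paste(d, tag)]] <- as.integer(v[npos + 1L])
      }
    }
  }
  hdr <- num_fields(nodes_txt[1])[[1]]
  nblocks <- hdr[1]
  node_tags <- integer(0); coords <- NULL
  k <- 2L
  for (b in seq_len(nblocks)) {
    bh <- num_fields(nodes_txt[k])[[1]]; k <- k + 1L
    nb <- bh[4]
    if (nb > 0) {
      tags <- as.integer(vapply(num_fields(nodes_txt[k:(k + nb - 1L)]),
                                `[`, 0, 1L))
      k <- k + nb
      xyz <- t(vapply(num_fields(nodes_txt[k:(k + nb - 1L)]),
                      function(v) v[1:3], numeric(3)))
      k <- k + nb
      node_tags <- c(node_tags, tags)
      coords <- rbind(coords, xyz)
    }
  }
  hdr <- num_fields(elems_txt[1])[[1]]
  nblocks <- hdr[1]
  elem_type <- integer(0); elem_phys <- integer(0); elem_nodes <- list()
  k <- 2L
  for (b in seq_len(nblocks)) {
    bh <- num_fields(elems_txt[k])[[1]]; k <- k + 1L
    d <- bh[1]; etag <- bh[2]; etype <- as.integer(bh[3]); nb <- bh[4]
    ph <- ent_phys[[paste(d, etag)]] %||% NA_integer_
    if (nb > 0) {
      rows <- num_fields(elems_txt[k:(k + nb - 1L)])
      k <- k + nb
      elem_type <- c(elem_type, rep.int(etype, nb))
      elem_phys <- c(elem_phys, rep.int(ph, nb))
      elem_nodes <- c(elem_nodes, lapply(rows, function(v) v[-1L]))
    }
  }
  list(coords = coords, node_tags = node_tags, elem_type = elem_type,
       elem_nodes = elem_nodes, elem_phys = elem_phys)
}

build_mesh_from_msh <- function(coords, node_tags, elem_type, elem_nodes,
                                elem_phys, phys, patch_name_map) {
  known <- elem_type %in% c(GMSH_LINE, GMSH_TRI, GMSH_TET, GMSH_POINT)
  if (any(!known)) stop("unsupported mesh: unknown/mixed element family")
  has_tet <- any(elem_type == GMSH_TET)
  if (has_tet) { vol_t <- GMSH_TET; bnd_t <- GMSH_TRI; dim <- 3L }
  else if (any(elem_type == GMSH_TRI)) { vol_t <- GMSH_TRI; bnd_t <- GMSH_LINE; dim <- 2L }
  else stop("unsupported mesh: no volumetric elements")

  remap <- rep(NA_integer_, max(node_tags))
  remap[node_tags] <- seq_along(node_tags)
  vol <- which(elem_type == vol_t)
  elements <- t(vapply(elem_nodes[vol], function(v) remap[v],
                       integer(dim + 1L)))
  used <- sort.int(unique(as.integer(elements)))
  node_renum <- rep(NA_integer_, length(node_tags))
  node_renum[used] <- seq_along(used)
  elements <- matrix(node_renum[elements], ncol = dim + 1L)
  nodes <- coords[used, seq_len(dim), drop = FALSE]

  bnd <- which(elem_type == bnd_t)
  map_label <- function(tag) {
    nm <- phys$name[match(tag, phys$id)]
    if (is.na(nm)) nm <- paste0("group", tag)
    lbl <- patch_name_map[[nm]] %||% nm
    as.character(lbl)
  }
  default <- if (!is.null(patch_name_map) && ".default" %in% names(patch_name_map))
    as.character(patch_name_map[[".default"]]) else NULL
  patch_faces <- list()
  if (length(bnd)) {
    tags <- elem_phys[bnd]
    if (anyNA(tags)) {
      if (is.null(default))
        stop("untagged boundary: boundary element without physical group")
      bnd <- bnd[!is.na(tags)]
      tags <- tags[!is.na(tags)]
    }
    for (tg in unique(tags)) {
      lbl <- map_label(tg)
      fm <- t(vapply(elem_nodes[bnd[tags == tg]],
                     function(v) node_renum[remap[v]], integer(dim)))
      patch_faces[[lbl]] <- rbind(patch_faces[[lbl]], fm)
    }
  }
  finalize_mesh(nodes, elements, patch_faces = patch_faces,
                patch_default = default)
}

# -- VTK output --------------------------------------------------------------

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

pad3 <- function(pts) {
  if (ncol(pts) == 2L) cbind(pts, 0) else pts
}

#' Write a mesh (and optionally tracts and cell vectors) as legacy VTK
#'
#' The volume mesh goes to `path` as an ASCII legacy-VTK unstructured grid;
#' per-element vectors are attached as cell data. Tract polylines, when
#' given, are written as a separate poly-data file `<stem>_tracts.vtk`.
#'
#' @param mesh a `simplex_mesh`.
#' @param path output file path (`.vtk`).
#' @param tracts optional list of tracts (or plain point matrices).
#' @param cell_vectors optional `n_el x dim` matrix of per-element vectors.
#' @return invisibly, the paths written.
#' @export
write_vtk <- function(mesh, path, tracts = NULL, cell_vectors = NULL) {
  write_vtk_mesh(mesh, path, cell_vectors = cell_vectors)
  out <- path
  if (!is.null(tracts)) {
    tp <- sub("(\\.vtk)?$", "_tracts.vtk", path)
    write_vtk_polylines(tracts, tp)
    out <- c(out, tp)
  }
  invisible(out)
}

#' @rdname write_vtk
#' @export
write_vtk_mesh <- function(mesh, path, cell_vectors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  pts <- pad3(mesh$nodes)
  n_el <- nrow(mesh$elements); m <- ncol(mesh$elements)
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "fascitrace mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID",
     sprintf("POINTS %d double", nrow(pts)))
  wl(apply(pts, 1L, function(p) paste(fmt_num(p), collapse = " ")))
  wl(sprintf("CELLS %d %d", n_el, n_el * (m + 1L)))
  wl(apply(mesh$elements, 1L,
           function(e) paste(c(m, e - 1L), collapse = " ")))
  wl(sprintf("CELL_TYPES %d", n_el))
  wl(as.character(rep.int(if (mesh$dim == 2L) 5L else 10L, n_el)))
  if (!is.null(cell_vectors)) {
    cv <- pad3(as.matrix(cell_vectors))
    if (nrow(cv) != n_el) stop("write failed: cell vector length mismatch")
    wl(sprintf("CELL_DATA %d", n_el), "VECTORS orientation double")
    wl(apply(cv, 1L, function(p) paste(fmt_num(p), collapse = " ")))
  }
  invisible(path)
}

#' @rdname write_vtk
#' @param scalars optional named list of per-tract numeric vectors written as
#'   cell data (e.g. length, pennation angle).
#' @export
write_vtk_polylines <- function(tracts, path, scalars = NULL) {
  pts_list <- lapply(tracts, function(tr) {
    p <- if (is.matrix(tr)) tr else tr$points
    pad3(as.matrix(p))
  })
  npts <- vapply(pts_list, nrow, 0L)
  offs <- cumsum(c(0L, head(npts, -1L)))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "fascitrace tracts", "ASCII",
     "DATASET POLYDATA", sprintf("POINTS %d double", sum(npts)))
  for (p in pts_list)
    wl(apply(p, 1L, function(q) paste(fmt_num(q), collapse = " ")))
  wl(sprintf("LINES %d %d", length(npts), sum(npts) + length(npts)))
  for (i in seq_along(pts_list))
    wl(paste(c(npts[i], seq_len(npts[i]) - 1L + offs[i]), collapse = " "))
  if (!is.null(scalars)) {
    wl(sprintf("CELL_DATA %d", length(npts)))
    for (nm in names(scalars)) {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(paste(fmt_num(scalars[[nm]]), collapse = " "))
    }
  }
  invisible(path)
}

# Minimal legacy-VTK readers used for round-trip checks.
read_vtk_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  vals <- as.numeric(unlist(strsplit(trimws(lines[i + seq_len(n)]), "\\s+")))
  matrix(vals[seq_len(3L * n)], ncol = 3L, byrow = TRUE)
}

read_vtk_n_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- grep("^LINES", lines)[1]
  as.integer(strsplit(lines[i], "\\s+")[[1]][2])
}

# -- STL input (untagged display geometry only) ------------------------------

#' Read an STL surface as untagged geometry
#'
#' Accepts ASCII and binary STL. The result is a raw triangle soup
#' (vertices welded exactly) intended for visualization; STL carries no
#' patch information, so it cannot be used as a solver input.
#'
#' @param path path to an `.stl` file.
#' @return list with `nodes` (x,y,z matrix) and `triangles` (index matrix).
#' @export
read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 80L)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") &&
    length(grep("facet", readLines(path, n = 20L, warn = FALSE))) > 0
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(s) as.numeric(s[2:4]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    v <- matrix(0, nt * 3L, 3L)
    for (i in seq_len(nt)) {
      f <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)
      v[(3L * i - 2L):(3L * i), ] <- matrix(f[4:12], 3L, 3L, byrow = TRUE)
    }
  }
  key <- apply(v, 1L, paste, collapse = "_")
  first <- !duplicated(key)
  nodes <- v[first, , drop = FALSE]
  tri <- matrix(match(key, key[first]), ncol = 3L, byrow = TRUE)
  list(nodes = nodes, triangles = tri)
}
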