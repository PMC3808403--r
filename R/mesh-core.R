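#' @importFrom stats approx predict smooth.spline sd setNames
#' @importFrom utils write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Simplicial mesh data model
#
# A simplex_mesh is a finalized volumetric mesh of triangles (dim 2) or
# tetrahedra (dim 3) with full face topology:
#   nodes          n_nodes x dim coordinates (mm)
#   elements       n_el x (dim+1) node indices (1-based)
#   faces          n_face x dim node indices, rows sorted ascending
#   face_owner     adjacent element whose outward normal the stored normal
#                  follows (lower element index of the two)
#   face_neighbor  second adjacent element, NA_integer_ on the boundary
#   elem_volume    element measure (mm^2 / mm^3), strictly positive
#   face_normal    integrated outward normal N (|N| = face measure), outward
#                  from the owner
#   elem_faces     n_el x (dim+1): global face index of the local face
#                  OPPOSITE local vertex i
#   elem_face_sign +1 where the element owns the face, -1 otherwise
#   patches        named list of boundary-face index sets ("origin",
#                  "insertion", "belly", or user labels)
# ---------------------------------------------------------------------------

#' Build a finalized simplicial mesh from nodes and elements
#'
#' Enumerates unique faces (sorted-node-tuple identity), assigns owner and
#' neighbor elements, computes volumes, centroids and integrated outward face
#' normals, and optionally tags boundary patches. Elements with negative
#' signed volume are reordered (two nodes swapped) rather than rejected.
#'
#' @param nodes numeric matrix, one coordinate row per node (2 or 3 columns).
#' @param elements integer matrix, one row per simplex, `ncol(nodes) + 1`
#'   node indices per row.
#' @param patch_faces optional named list; each entry is an integer matrix of
#'   node indices (one boundary face per row) to be tagged with that name.
#' @param patch_default optional label assigned to boundary faces not covered
#'   by `patch_faces`. When `patch_faces` is given but incomplete and no
#'   default is supplied, finalization fails with "untagged boundary".
#' @return an object of class `simplex_mesh`.
#' @export
finalize_mesh <- function(nodes, elements, patch_faces = NULL,
                          patch_default = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  n <- ncol(nodes)
  if (!n %in% c(2L, 3L))
    stop("unsupported mesh: spatial dimension must be 2 or 3")
  if (ncol(elements) != n + 1L)
    stop("unsupported mesh: elements must have ", n + 1L, " nodes each")
  if (nrow(elements) < 1L) stop("unsupported mesh: no elements")
  if (any(elements < 1L) || any(elements > nrow(nodes)))
    stop("element references an invalid node")

  # Orientation fix: positive signed volume, else swap first two nodes.
  sv <- signed_volumes(nodes, elements)
  hmax <- element_diameters(nodes, elements)
  degen <- abs(sv) <= 1e-12 * hmax^n
  if (any(degen))
    stop("degenerate element: ", paste(which(degen), collapse = ", "))
  neg <- sv < 0
  if (any(neg)) {
    tmp <- elements[neg, 1L]
    elements[neg, 1L] <- elements[neg, 2L]
    elements[neg, 2L] <- tmp
    sv <- signed_volumes(nodes, elements)
    if (any(sv <= 0)) stop("degenerate element: orientation fix failed")
  }

  n_el <- nrow(elements)
  # Local face i of an element is the face OPPOSITE local vertex i.
  local_faces <- vector("list", n + 1L)
  for (i in seq_len(n + 1L))
    local_faces[[i]] <- elements[, -i, drop = FALSE]
  all_faces <- do.call(rbind, local_faces)          # (n+1)*n_el rows
  all_faces <- t(apply(all_faces, 1L, sort.int))
  if (n == 2L) all_faces <- matrix(all_faces, ncol = 2L)
  key <- do.call(paste, c(as.data.frame(all_faces), sep = "_"))
  # element index and local face index for every row of all_faces
  row_elem <- rep.int(seq_len(n_el), times = n + 1L)
  row_local <- rep(seq_len(n + 1L), each = n_el)

  first <- !duplicated(key)
  faces <- all_faces[first, , drop = FALSE]
  face_id <- match(key, key[first])
  n_face <- nrow(faces)

  counts <- tabulate(face_id, nbins = n_face)
  if (any(counts > 2L)) stop("non-manifold mesh: face shared by >2 elements")

  face_owner <- integer(n_face)
  face_neighbor <- rep(NA_integer_, n_face)
  # owner = lower element index; rows are ordered by element already
  ord <- order(face_id, row_elem)
  fid_o <- face_id[ord]; elem_o <- row_elem[ord]
  pos_first <- !duplicated(fid_o)
  face_owner[fid_o[pos_first]] <- elem_o[pos_first]
  second <- duplicated(fid_o)
  face_neighbor[fid_o[second]] <- elem_o[second]
  if (any(face_owner == face_neighbor, na.rm = TRUE))
    stop("degenerate element: face repeated within one element")

  elem_faces <- matrix(face_id, nrow = n_el, ncol = n + 1L)
  elem_face_sign <- matrix(1, nrow = n_el, ncol = n + 1L)
  elem_face_sign[face_owner[elem_faces] != row_elem] <- -1
  dim(elem_face_sign) <- c(n_el, n + 1L)

  elem_centroid <- centroid_of(nodes, elements)
  face_centroid <- centroid_of(nodes, faces)
  face_normal <- face_normals(nodes, faces)
  # Orient outward from the owner.
  flip <- rowSums(face_normal *
                    (face_centroid - elem_centroid[face_owner, , drop = FALSE])) < 0
  face_normal[flip, ] <- -face_normal[flip, , drop = FALSE]
  face_area <- sqrt(rowSums(face_normal^2))

  mesh <- structure(list(
    dim = n, nodes = nodes, elements = elements,
    faces = faces, face_owner = face_owner, face_neighbor = face_neighbor,
    elem_volume = sv, elem_centroid = elem_centroid,
    face_centroid = face_centroid, face_normal = face_normal,
    face_area = face_area,
    elem_faces = elem_faces, elem_face_sign = elem_face_sign,
    patches = list()
  ), class = "simplex_mesh")

  if (!is.null(patch_faces) || !is.null(patch_default)) {
    ids <- lapply(patch_faces, function(fm) {
      fm <- as.matrix(fm)
      if (nrow(fm) == 0L) return(integer(0))
      fm <- t(apply(fm, 1L, sort.int))
      if (n == 2L) fm <- matrix(fm, ncol = 2L)
      k <- do.call(paste, c(as.data.frame(fm), sep = "_"))
      id <- match(k, key[first])
      if (anyNA(id)) stop("untagged boundary: patch face not found in mesh")
      id
    })
    mesh <- set_patches(mesh, ids %||% list(), default = patch_default)
  }
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boundary-face indices of a mesh
#' @param mesh a `simplex_mesh`.
#' @return integer vector of face indices with no neighbor element.
#' @export
boundary_faces <- function(mesh) which(is.na(mesh$face_neighbor))

#' Assign boundary patches
#'
#' @param mesh a `simplex_mesh`.
#' @param patches named list of boundary-face index vectors; sets must be
#'   disjoint and (together with `default`) cover all boundary faces.
#' @param default optional label for boundary faces listed in no patch.
#' @return the mesh with its `patches` replaced.
#' @export
set_patches <- function(mesh, patches, default = NULL) {
  bnd <- boundary_faces(mesh)
  patches <- lapply(patches, function(p) sort.int(unique(as.integer(p))))
  all_ids <- unlist(patches, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("patch overlap: patches are not disjoint")
  if (length(all_ids) && !all(all_ids %in% bnd))
    stop("untagged boundary: patch contains a non-boundary face")
  rest <- setdiff(bnd, all_ids)
  if (length(rest)) {
    if (is.null(default)) stop("untagged boundary: ", length(rest),
                               " boundary face(s) in no patch")
    patches[[default]] <- sort.int(c(patches[[default]] %||% integer(0), rest))
  }
  mesh$patches <- patches
  mesh
}

#' Select boundary faces by a centroid predicate
#'
#' @param mesh a `simplex_mesh`.
#' @param predicate function taking a face-centroid coordinate vector and
#'   returning `TRUE`/`FALSE`. Only boundary faces are tested.
#' @return integer vector of matching boundary-face indices.
#' @export
select_patch_faces <- function(mesh, predicate) {
  bnd <- boundary_faces(mesh)
  keep <- vapply(bnd, function(f) isTRUE(predicate(mesh$face_centroid[f, ])),
                 logical(1))
  out <- bnd[keep]
  if (!length(out)) stop("empty patch: predicate selected no boundary face")
  out
}

#' Patch label of a face
#' @param mesh a `simplex_mesh`.
#' @param face face index.
#' @return the patch name, or `NA_character_` for untagged/interior faces.
#' @export
face_patch <- function(mesh, face) {
  for (nm in names(mesh$patches))
    if (face %in% mesh$patches[[nm]]) return(nm)
  NA_character_
}

#' @export
print.simplex_mesh <- function(x, ...) {
  cat(sprintf("simplex_mesh: dim %d, %d nodes, %d elements, %d faces (%d boundary)\n",
              x$dim, nrow(x$nodes), nrow(x$elements), nrow(x$faces),
              length(boundary_faces(x))))
  if (length(x$patches))
    cat("patches:", paste(sprintf("%s[%d]", names(x$patches),
                                  lengths(x$patches)), collapse = ", "), "\n")
  invisible(x)
}

# -- geometric helpers -------------------------------------------------------

signed_volumes <- function(nodes, elements) {
  n <- ncol(nodes)
  p1 <- nodes[elements[, 1L], , drop = FALSE]
  if (n == 2L) {
    a <- nodes[elements[, 2L], , drop = FALSE] - p1
    b <- nodes[elements[, 3L], , drop = FALSE] - p1
    0.5 * (a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  } else {
    a <- nodes[elements[, 2L], , drop = FALSE] - p1
    b <- nodes[elements[, 3L], , drop = FALSE] - p1
    d <- nodes[elements[, 4L], , drop = FALSE] - p1
    (a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) -
     a[, 2L] * (b[, 1L] * d[, 3L] - b[, 3L] * d[, 1L]) +
     a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])) / 6
  }
}

element_diameters <- function(nodes, elements) {
  m <- ncol(elements)
  h <- 0
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    d <- nodes[elements[, i], , drop = FALSE] - nodes[elements[, j], , drop = FALSE]
    h <- pmax(h, sqrt(rowSums(d^2)))
  }
  h
}

centroid_of <- function(nodes, index_mat) {
  acc <- nodes[index_mat[, 1L], , drop = FALSE]
  for (i in seq_len(ncol(index_mat))[-1L])
    acc <- acc + nodes[index_mat[, i], , drop = FALSE]
  acc / ncol(index_mat)
}

# Integrated face normal (magnitude = face measure); orientation arbitrary
# here, fixed to outward-from-owner by the caller.
face_normals <- function(nodes, faces) {
  if (ncol(faces) == 2L) {           # 2D edge: rotate tangent by 90 degrees
    t_ <- nodes[faces[, 2L], , drop = FALSE] - nodes[faces[, 1L], , drop = FALSE]
    cbind(t_[, 2L], -t_[, 1L])
  } else {                           # 3D triangle: half cross product
    a <- nodes[faces[, 2L], , drop = FALSE] - nodes[faces[, 1L], , drop = FALSE]
    b <- nodes[faces[, 3L], , drop = FALSE] - nodes[faces[, 1L], , drop = FALSE]
    0.5 * cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  }
}
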