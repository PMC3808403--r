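# Fixtures are built in code; no binary files.

unit_triangle_mesh <- function() {
  finalize_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
                matrix(1:3, nrow = 1L))
}

single_tet_mesh <- function() {
  finalize_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                matrix(1:4, nrow = 1L))
}

two_triangle_mesh <- function() {
  finalize_mesh(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
}

# --- Gmsh fixture writers ---------------------------------------------------

# single tetrahedron, 4 tagged boundary triangles (groups prox/dist/side)
write_msh22_tet <- function(path, drop_group_on_face = FALSE) {
  tris <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  phys <- c(1, 1, 2, 3)  # prox, prox, dist, side
  lines <- c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    "$PhysicalNames", "3",
    '2 1 "prox"', '2 2 "dist"', '2 3 "side"',
    "$EndPhysicalNames",
    "$Nodes", "4",
    "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
    "$EndNodes",
    "$Elements", if (drop_group_on_face) "5" else "5",
    "1 4 2 99 1 1 2 3 4",
    unlist(lapply(seq_along(tris), function(i) {
      if (drop_group_on_face && i == 4L)
        paste(c(i + 1, 2, 0, tris[[i]]), collapse = " ")
      else
        paste(c(i + 1, 2, 2, phys[i], i, tris[[i]]), collapse = " ")
    })),
    "$EndElements")
  writeLines(lines, path)
  path
}

# same mesh in MSH 4.1 block format
write_msh41_tet <- function(path) {
  lines <- c(
    "$MeshFormat", "4.1 0 8", "$EndMeshFormat",
    "$PhysicalNames", "3",
    '2 1 "prox"', '2 2 "dist"', '2 3 "side"',
    "$EndPhysicalNames",
    "$Entities", "0 0 4 1",
    # surfaces: tag min(3) max(3) numPhys phys numCurves ...
    "1 0 0 0 1 1 1 1 1 0",
    "2 0 0 0 1 1 1 1 1 0",
    "3 0 0 0 1 1 1 1 2 0",
    "4 0 0 0 1 1 1 1 3 0",
    # volume: tag bbox numPhys phys numSurfaces ...
    "1 0 0 0 1 1 1 0 0",
    "$EndEntities",
    "$Nodes", "1 4 1 4",
    "3 1 0 4", "1", "2", "3", "4",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "$EndNodes",
    "$Elements", "5 5 1 5",
    "2 1 2 1", "1 1 2 3",
    "2 2 2 1", "2 1 2 4",
    "2 3 2 1", "3 1 3 4",
    "2 4 2 1", "4 2 3 4",
    "3 1 4 1", "5 1 2 3 4",
    "$EndElements")
  writeLines(lines, path)
  path
}

# --- independent tracer oracle ---------------------------------------------
# Analytic ray/face intersection: from p0 along constant velocity v inside a
# simplex, the exit is at the smallest positive t where the ray meets the
# plane of a face it is moving out of.
ray_exit_oracle <- function(mesh, element, p0, v) {
  n <- mesh$dim
  best_t <- Inf
  best_face <- NA_integer_
  for (i in seq_len(n + 1L)) {
    g <- mesh$elem_faces[element, i]
    N <- mesh$face_normal[g, ] * mesh$elem_face_sign[element, i]  # outward
    vn <- sum(v * N)
    if (vn <= 0) next
    a <- mesh$nodes[mesh$faces[g, 1L], ]
    t <- sum((a - p0) * N) / vn
    if (t >= -1e-12 && t < best_t) { best_t <- t; best_face <- i }
  }
  list(t = best_t, local_face = best_face,
       point = p0 + best_t * v)
}

# net interior flux out of the element set with centroid y < y_cut; by
# conservation this equals the inflow entering that set through its
# boundary faces
mesh_cut_flux <- function(mesh, field, y_cut) {
  in_S <- mesh$elem_centroid[, 2L] < y_cut
  int_f <- which(!is.na(mesh$face_neighbor))
  o_in <- in_S[mesh$face_owner[int_f]]
  n_in <- in_S[mesh$face_neighbor[int_f]]
  iface <- int_f[xor(o_in, n_in)]
  s <- ifelse(in_S[mesh$face_owner[iface]], 1, -1)
  sum(field$face_flux[iface] * s)
}

# local fluxes of a random_flux_simplex as a global per-face flux vector
global_flux <- function(fx) {
  ff <- numeric(nrow(fx$mesh$faces))
  ff[fx$mesh$elem_faces[1L, ]] <- fx$fluxes * fx$mesh$elem_face_sign[1L, ]
  ff
}

# Brute-force constant-vector reconstruction from face fluxes: least-squares
# solve of v . N_i = f_i over all faces.
lsq_vector_oracle <- function(mesh, element, fluxes) {
  n <- mesh$dim
  A <- mesh$face_normal[mesh$elem_faces[element, ], , drop = FALSE] *
    mesh$elem_face_sign[element, ]
  as.numeric(qr.solve(A, fluxes))
}

expect_vec_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}

discrete_turning_angle <- function(pts) {
  d <- diff(pts)
  len <- sqrt(rowSums(d^2))
  u <- d / len
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1L, , drop = FALSE])
  sum(acos(pmin(1, pmax(-1, dots))))
}
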