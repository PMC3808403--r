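test_that("finalize_mesh computes exact geometry on the unit right triangle", {
  m <- unit_triangle_mesh()
  expect_equal(m$elem_volume, 0.5)
  # integrated outward normals of faces opposite P1, P2, P3
  N <- m$face_normal[m$elem_faces[1L, ], ] * m$elem_face_sign[1L, ]
  expect_vec_equal(N[1L, ], c(1, 1))
  expect_vec_equal(N[2L, ], c(-1, 0))
  expect_vec_equal(N[3L, ], c(0, -1))
})

test_that("topology: shared faces, owner/neighbor, closed-polytope identity", {
  m <- two_triangle_mesh()
  expect_equal(nrow(m$faces), 5L)
  interior <- which(!is.na(m$face_neighbor))
  expect_length(interior, 1L)
  expect_equal(sort(c(m$face_owner[interior], m$face_neighbor[interior])),
               c(1L, 2L))
  # owner is the lower element index
  expect_true(all(m$face_owner[interior] < m$face_neighbor[interior],
                  na.rm = TRUE))
  for (msh in list(m, single_tet_mesh(), make_box3d(2, 1, 1, 0.5))) {
    for (e in seq_len(nrow(msh$elements))) {
      s <- colSums(msh$face_normal[msh$elem_faces[e, ], , drop = FALSE] *
                     msh$elem_face_sign[e, ])
      expect_lt(max(abs(s)), 1e-12)
    }
  }
})

test_that("negative orientation is repaired, degenerate elements rejected", {
  m <- finalize_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
                     matrix(c(1L, 3L, 2L), nrow = 1L))  # clockwise
  expect_equal(m$elem_volume, 0.5)
  expect_error(
    finalize_mesh(rbind(c(0, 0), c(1, 0), c(2, 0)), matrix(1:3, nrow = 1L)),
    "degenerate element")
  # edge (1,2) belongs to three triangles
  expect_error(
    finalize_mesh(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, -1)),
                  rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 2L, 5L))),
    "non-manifold")
})

test_that("select_patch_faces selects boundary faces only, errors when empty", {
  m <- make_rect2d(2, 1, 0.5)
  left <- select_patch_faces(m, function(p) abs(p[1]) < 1e-9)
  expect_true(all(is.na(m$face_neighbor[left])))
  expect_vec_equal(m$face_centroid[left, 1L], rep(0, length(left)))
  expect_error(select_patch_faces(m, function(p) FALSE), "empty patch")
  # predicate true only at an interior centroid still yields nothing
  int_c <- m$face_centroid[which(!is.na(m$face_neighbor))[1L], ]
  expect_error(
    select_patch_faces(m, function(p) sum(abs(p - int_c)) < 1e-12),
    "empty patch")
})

test_that("patch partition invariants", {
  m <- make_fan2d(4, 1, 3, 0.4)
  bnd <- boundary_faces(m)
  ids <- unlist(m$patches)
  expect_setequal(ids, bnd)
  expect_equal(anyDuplicated(ids), 0L)
  expect_error(set_patches(m, list(a = bnd[1:2], b = bnd[2:3])),
               "patch overlap")
  expect_error(set_patches(m, list(a = bnd[1:2])), "untagged boundary")
})

test_that("volume additivity on synthetic shapes", {
  expect_equal(sum(make_rect2d(10, 1, 0.25)$elem_volume), 10,
               tolerance = 1e-12)
  expect_equal(sum(make_fan2d(4, 1, 3, 0.3)$elem_volume), 7.5,
               tolerance = 1e-12)
  expect_equal(sum(make_box3d(1, 1, 1, 0.5)$elem_volume), 1,
               tolerance = 1e-12)
  # curved boundary: O(h^2) polygonal deficit toward 3*pi/4
  a1 <- sum(make_annulus_sector2d(1, 2, pi / 2, 0.2)$elem_volume)
  a2 <- sum(make_annulus_sector2d(1, 2, pi / 2, 0.05)$elem_volume)
  expect_lt(abs(a2 - 3 * pi / 4), abs(a1 - 3 * pi / 4))
  expect_equal(a2, 3 * pi / 4, tolerance = 1e-3)
})
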