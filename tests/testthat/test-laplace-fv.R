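test_that("uniform-flux bc balances exactly and respects area weighting", {
  # unequal attachment areas: A_o = 4, A_i = 2, Q = 2 -> g_o = -1/2, g_i = +1
  fan <- make_fan2d(4, 2, 3, 0.4)
  bc <- make_uniform_flux_bc(fan, "origin", "insertion", 2)
  g_o <- unique(round(bc$density[match(fan$patches$origin, bc$faces)], 12))
  g_i <- unique(round(bc$density[match(fan$patches$insertion, bc$faces)], 12))
  expect_equal(g_o, -2 / 4)
  expect_equal(g_i, 2 / 2)
  expect_lt(abs(sum(bc$flux)), 1e-12 * bc$total_inflow)
  # belly density exactly zero
  expect_true(all(bc$density[match(fan$patches$belly, bc$faces)] == 0))
  # unit cube walls of area 1: densities -1 / +1
  cube <- make_box3d(1, 1, 1, 0.5)
  bcu <- make_uniform_flux_bc(cube, "origin", "insertion", 1)
  expect_equal(unique(bcu$density[match(cube$patches$origin, bcu$faces)]), -1)
  expect_equal(unique(round(bcu$density[match(cube$patches$insertion,
                                              bcu$faces)], 12)), 1)
  # swapping labels negates all densities
  rev_bc <- make_uniform_flux_bc(fan, "insertion", "origin", 2)
  expect_vec_equal(rev_bc$density, -bc$density, 1e-12)
  expect_error(make_uniform_flux_bc(fan, "origin", "nope", 1), "empty patch")
})

test_that("unit-box solve yields the exact uniform field", {
  m <- make_box3d(1, 1, 1, 0.34)
  bc <- make_uniform_flux_bc(m, "origin", "insertion", 1)
  fld <- solve_potential(m, bc)
  dev <- sweep(fld$vectors, 2L, c(1, 0, 0))
  expect_lt(max(abs(dev)), 1e-8)
  expect_true(check_balance(m, fld)$pass)
  # boundary fluxes imposed exactly
  bnd <- boundary_faces(m)
  expect_equal(fld$face_flux[bnd][match(bc$faces, bnd)], bc$flux)
})

test_that("incompatible and degenerate boundary conditions are rejected", {
  m <- make_rect2d(2, 1, 0.5)
  bnd <- boundary_faces(m)
  g <- setNames(rep(0.1, length(bnd)), bnd)   # all outflow: sum g*A = 0.1*P
  expect_error(make_face_flux_bc(m, g), "incompatible boundary conditions")
  # disconnected mesh -> singular system
  two <- finalize_mesh(
    rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6)),
    rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  two <- set_patches(two, list(), default = "belly")
  bnd2 <- boundary_faces(two)
  f_in <- bnd2[1L]                      # a face of element 1
  f_out <- bnd2[length(bnd2)]           # a face of element 2
  g2 <- setNames(c(-1 / two$face_area[f_in], 1 / two$face_area[f_out]),
                 c(f_in, f_out))
  bc2 <- make_face_flux_bc(two, g2, renormalize = f_out)
  expect_error(solve_potential(two, bc2), "singular system")
})

test_that("element_vectors matches the least-squares oracle and flux identities", {
  # hand triangle: fluxes (1,-1,0) opposite P1,P2,P3 -> v = (1,0)
  m <- unit_triangle_mesh()
  ff <- numeric(3)
  ff[m$elem_faces[1L, ]] <- c(1, -1, 0) * m$elem_face_sign[1L, ]
  v <- element_vectors(m, ff)
  expect_vec_equal(v[1L, ], c(1, 0), 1e-12)
  expect_vec_equal(v[1L, ], lsq_vector_oracle(m, 1L, c(1, -1, 0)), 1e-12)
  # zero fluxes -> zero vector
  expect_vec_equal(element_vectors(m, numeric(3))[1L, ], c(0, 0))
  # translation invariance when fluxes balance
  mt <- finalize_mesh(m$nodes + 10, m$elements)
  expect_vec_equal(element_vectors(mt, ff)[1L, ], c(1, 0), 1e-12)
  # random simplices: reconstruction reproduces the generating vector and
  # all face fluxes (v . N_i = f_i)
  for (s in 1:25) for (d in c(2L, 3L)) {
    fx <- random_flux_simplex(d, 1000 + 7 * s + d)
    vv <- element_vectors(fx$mesh, global_flux(fx))[1L, ]
    expect_vec_equal(vv, fx$v, 1e-11)
    N <- fx$mesh$face_normal[fx$mesh$elem_faces[1L, ], , drop = FALSE] *
      fx$mesh$elem_face_sign[1L, ]
    expect_vec_equal(as.numeric(N %*% vv), fx$fluxes, 1e-11)
  }
  # imbalance above tolerance is an error
  bad <- ff; bad[1L] <- bad[1L] + 0.5
  expect_error(element_vectors(m, bad, tol_balance = 1e-3),
               "non-conservative")
})

test_that("check_balance flags hand-built imbalance", {
  m <- single_tet_mesh()
  ff <- numeric(4)
  ff[m$elem_faces[1L, ]] <- c(1, -1, 0, 0) * m$elem_face_sign[1L, ]
  fake <- list(face_flux = ff, bc = list(total_inflow = 1))
  rep0 <- check_balance(m, fake)
  expect_equal(rep0$residuals, 0)
  expect_true(rep0$pass)
  ff2 <- ff
  ff2[m$elem_faces[1L, 4L]] <- ff2[m$elem_faces[1L, 4L]] +
    0.5 * m$elem_face_sign[1L, 4L]
  rep1 <- check_balance(m, list(face_flux = ff2,
                                bc = list(total_inflow = 1)))
  expect_false(rep1$pass)
  expect_equal(rep1$max_norm, 0.5)
})

test_that("linearity, reversal and pin invariance of the solve", {
  m <- make_fan2d(4, 1, 3, 0.3)
  bc1 <- make_uniform_flux_bc(m, "origin", "insertion", 1)
  bc10 <- make_uniform_flux_bc(m, "origin", "insertion", 10)
  f1 <- solve_potential(m, bc1)
  f10 <- solve_potential(m, bc10)
  expect_lt(max(abs(f10$vectors - 10 * f1$vectors)), 1e-6)
  rev_bc <- make_uniform_flux_bc(m, "insertion", "origin", 1)
  fr <- solve_potential(m, rev_bc)
  expect_lt(max(abs(fr$vectors + f1$vectors)), 1e-7)
  fp <- solve_potential(m, bc1, pin_element = 17L, pin_value = 3)
  expect_lt(max(abs(fp$vectors - f1$vectors)), 1e-8)
  const <- fp$phi - f1$phi
  expect_lt(diff(range(const)), 1e-7)
  expect_equal(fp$phi[17L], 3)
})

test_that("annulus-sector solve converges to the 1/r closed form", {
  m <- make_annulus_sector2d(1, 2, pi / 2, 0.1)
  fld <- solve_potential(m, annulus_sector_bc(m, 1))
  orc <- annulus_closed_form(1, 2, pi / 2, 1)
  r_c <- sqrt(rowSums(m$elem_centroid^2))
  sp <- sqrt(rowSums(fld$vectors^2))
  expect_lt(max(abs(sp - orc$speed(r_c)) / orc$speed(r_c)), 0.05)
  # potential increases by ~ c*Theta across the sector
  th <- atan2(m$elem_centroid[, 2L], m$elem_centroid[, 1L])
  span <- max(fld$phi) - min(fld$phi)
  expect_equal(span, pi / 2, tolerance = 0.05)
})
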