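test_that("barycentric coordinates: vertices, centroid, hand case", {
  m <- unit_triangle_mesh()
  expect_vec_equal(barycentric_coords(m, 1L, c(0, 0)), c(1, 0, 0))
  expect_vec_equal(barycentric_coords(m, 1L, colMeans(m$nodes)),
                   rep(1 / 3, 3))
  expect_vec_equal(barycentric_coords(m, 1L, c(0, 0.5)), c(0.5, 0, 0.5))
  tet <- single_tet_mesh()
  expect_vec_equal(barycentric_coords(tet, 1L, c(0, 0, 1)), c(0, 0, 0, 1))
  expect_error(barycentric_coords(m, 1L, c(2, 2)), "point not in element")
})

test_that("intersection times follow the constant barycentric rates", {
  # lambda = (0.5, 0, 0.5), f = (1, -1, 0), nV = 1 -> t = (0.5, Inf, Inf)
  t_i <- intersection_times(c(0.5, 0, 0.5), c(1, -1, 0), V = 0.5, n = 2)
  expect_equal(t_i, c(0.5, Inf, Inf))
  # no decreasing coordinate -> all infinite (stagnation signal)
  expect_true(all(is.infinite(
    intersection_times(c(0.3, 0.3, 0.4), c(-1, 0, 0), 0.5, 2))))
  # doubling fluxes halves finite times
  expect_equal(intersection_times(c(0.5, 0, 0.5), c(2, -2, 0), 0.5, 2)[1L],
               0.25)
})

test_that("single-element advance matches the hand case", {
  m <- unit_triangle_mesh()
  ff <- numeric(3)
  ff[m$elem_faces[1L, ]] <- c(1, -1, 0) * m$elem_face_sign[1L, ]  # v = (1,0)
  fld <- list(face_flux = ff)
  st <- list(element = 1L, lambda = c(0.5, 0, 0.5), point = c(0, 0.5))
  adv <- advance_through_element(m, fld, st)
  expect_equal(adv$status, "boundary")
  expect_vec_equal(adv$point, c(0.5, 0.5), 1e-12)
  expect_equal(adv$tau, 0.5, tolerance = 1e-12)
  # flux scaling: same exit, tau / 10
  adv10 <- advance_through_element(m, list(face_flux = 10 * ff), st)
  expect_vec_equal(adv10$point, adv$point, 1e-12)
  expect_equal(adv10$tau, adv$tau / 10, tolerance = 1e-12)
  # zero-velocity element is stagnant
  expect_equal(advance_through_element(m, list(face_flux = numeric(3)),
                                       st)$status, "stagnant")
})

test_that("advance agrees with analytic ray-face intersection on random simplices", {
  # 1000 random simplices across 2D and 3D, random interior entry points
  worst <- 0
  for (s in 1:500) for (d in c(2L, 3L)) {
    fx <- random_flux_simplex(d, 20000 + 2 * s + d)
    m <- fx$mesh
    ff <- global_flux(fx)
    w <- (s %% 7 + 1) * seq_len(d + 1L)          # deterministic interior point
    lam <- w / sum(w)
    p0 <- as.numeric(lam %*% m$nodes[m$elements[1L, ], ])
    adv <- advance_through_element(m, list(face_flux = ff),
                                   list(element = 1L, lambda = lam,
                                        point = p0))
    orc <- ray_exit_oracle(m, 1L, p0, fx$v)
    scale <- max(abs(orc$point), orc$t)
    worst <- max(worst,
                 max(abs(adv$point - orc$point)) / scale,
                 abs(adv$tau - orc$t) / max(orc$t, 1e-300))
    expect_lt(max(abs(adv$point - orc$point)), 1e-9 * scale)
    expect_lt(abs(adv$tau - orc$t), 1e-9 * max(orc$t, scale))
  }
  expect_lt(worst, 1e-9)
})

test_that("tracts cross the strip and stay flux-consistent", {
  m <- make_rect2d(10, 1, 0.5)
  fld <- solve_potential(m, make_uniform_flux_bc(m, "origin", "insertion", 1))
  seeds <- seed_patch_centroids(m, "origin")
  for (s in seeds) {
    tr <- trace_fascicle(m, fld, s, direction = "downstream")
    expect_equal(tr$status, "reached-attachment")
    expect_equal(tr$start_patch, "origin")
    expect_equal(tr$end_patch, "insertion")
    expect_equal(fascicle_length(tr$points), 10, tolerance = 1e-9)
    expect_true(all(tr$tau > 0))
    # path consistency: consecutive points joined through shared faces
    expect_equal(nrow(tr$points), length(tr$trail) + 1L)
  }
  # upstream tracing returns origin -> insertion order too
  up <- trace_fascicle(m, fld, seed_patch_centroids(m, "insertion")[[1L]],
                       direction = "upstream")
  expect_equal(up$start_patch, "origin")
  expect_lt(up$points[1L, 1L], up$points[nrow(up$points), 1L])
  expect_error(
    trace_fascicle(m, fld, list(face = m$patches$belly[1L],
                                element = 1L, lambda = c(1, 0, 0),
                                point = m$nodes[1L, ]), "downstream"),
    "invalid seed")
})

test_that("potential decreases monotonically upstream along tracts (no cycles)", {
  m <- make_fan2d(4, 1, 3, 0.25)
  fld <- solve_potential(m, make_uniform_flux_bc(m, "origin", "insertion", 1))
  seeds <- seed_patch_centroids(m, "insertion", per_face = 2L)
  for (s in seeds[seq(1, length(seeds), by = 3L)]) {
    tr <- trace_fascicle(m, fld, s, direction = "upstream")
    expect_equal(tr$status, "reached-attachment")
    phi_trail <- fld$phi[tr$trail]
    # tract runs origin -> insertion: element potential must increase
    expect_true(all(diff(phi_trail) > -1e-12))
    # no element revisited
    expect_equal(anyDuplicated(tr$trail), 0L)
  }
})

test_that("seed placement is deterministic and validated", {
  m <- make_rect2d(4, 1, 0.5)
  s1 <- seed_patch_centroids(m, "origin")
  expect_length(s1, length(m$patches$origin))
  for (s in s1) expect_true(all(s$lambda >= 0) && abs(sum(s$lambda) - 1) < 1e-12)
  s3 <- seed_patch_centroids(m, "origin", per_face = 3L)
  expect_length(s3, 3L * length(m$patches$origin))
  pts <- do.call(rbind, lapply(s3[1:3], `[[`, "point"))
  expect_equal(anyDuplicated(round(pts, 9)), 0L)
  expect_error(seed_patch_centroids(m, "origin", per_face = 0L),
               "invalid density")
  expect_error(seed_patch_centroids(m, "nothere"), "empty patch")
})
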