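straight_tract <- function(n = 50, len = 10, dir = c(1, 0, 0), origin = 0) {
  s <- seq(0, len, length.out = n)
  origin + outer(s, dir / sqrt(sum(dir^2)))
}

test_that("smooth_resample: 100 equidistant points, straight lines preserved", {
  pts <- straight_tract(50, 10)[, 1:2]
  sm <- smooth_resample(pts)
  expect_equal(nrow(sm$points), 100L)
  expect_vec_equal(sm$points[1L, ], pts[1L, ], 1e-9)
  expect_vec_equal(sm$points[100L, ], pts[50L, ], 1e-9)
  expect_equal(sm$arc_length, 10, tolerance = 1e-6)
  ch <- sqrt(rowSums(diff(sm$points)^2))
  expect_lt((max(ch) - min(ch)) / mean(ch), 1e-6)
  # n_points configurable
  expect_equal(nrow(smooth_resample(pts, n_points = 25L)$points), 25L)
  expect_error(smooth_resample(pts[1:3, ]), "tract too short")
  expect_error(smooth_resample(matrix(1, 5, 2)), "degenerate tract")
})

test_that("smoothing reduces zigzag turning without inflating arc length", {
  n <- 60
  x <- seq(0, 10, length.out = n)
  y <- 0.01 * rep_len(c(1, -1), n)
  zig <- cbind(x, y)
  sm <- smooth_resample(zig)
  expect_lt(discrete_turning_angle(sm$points),
            discrete_turning_angle(zig))
  raw_len <- fascicle_length(zig)
  expect_lt(abs(sm$arc_length - raw_len) / raw_len, 0.01)
})

test_that("fascicle length: chord sums", {
  pts <- straight_tract(100, 99)          # 100 collinear points, 1 mm apart
  expect_equal(fascicle_length(pts), 99)
  th <- seq(0, pi / 2, length.out = 100)
  quarter <- cbind(cos(th), sin(th))
  expect_equal(fascicle_length(quarter), pi / 2, tolerance = 1e-3 * pi / 2)
  expect_error(fascicle_length(quarter[1L, , drop = FALSE]),
               "degenerate tract")
})

test_that("seed tangent normal averages patch-face normals", {
  m <- make_box3d(2, 1, 1, 0.5)
  f <- m$patches$insertion[1L]
  nh <- seed_tangent_normal(m, f)
  expect_vec_equal(nh, c(1, 0, 0), 1e-12)           # flat wall
  expect_error(seed_tangent_normal(m, which(!is.na(m$face_neighbor))[1L]),
               "not a boundary face")
  # right-angle crease: for the triangle (0,0)-(1,0)-(1,1) the unit normals
  # (0,-1), (1,0), (-1,1)/sqrt(2) average to (1,-1)/sqrt(2): 45 deg to
  # either wall
  crease <- finalize_mesh(rbind(c(0, 0), c(1, 0), c(1, 1)),
                          matrix(1:3, nrow = 1L))
  bottom <- select_patch_faces(crease, function(p) abs(p[2]) < 1e-9)
  nb <- seed_tangent_normal(crease, bottom[1L], same_patch = FALSE)
  expect_vec_equal(nb, c(1, -1) / sqrt(2), 1e-12)
  # isolated single-face patch: the face's own normal
  crease2 <- set_patches(crease, list(bottom = bottom), default = "belly")
  expect_vec_equal(seed_tangent_normal(crease2, bottom[1L]), c(0, -1), 1e-12)
})

test_that("pennation angle: parallel, in-plane, inclined", {
  nhat <- c(0, 0, 1)
  expect_equal(pennation_angle(straight_tract(10, 5, c(0, 0, 1)), nhat), 90)
  expect_equal(pennation_angle(straight_tract(10, 5, c(1, 0, 0)), nhat), 0)
  t30 <- straight_tract(10, 5, c(cos(pi / 6), 0, sin(pi / 6)))
  expect_equal(pennation_angle(t30, nhat), 30, tolerance = 1e-9)
  # rigid rotation invariance and scale invariance
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(pennation_angle(t30 %*% t(Rz), as.numeric(Rz %*% nhat)),
               30, tolerance = 1e-9)
  expect_equal(pennation_angle(5 * t30, nhat), 30, tolerance = 1e-9)
  expect_error(pennation_angle(t30[1:4, ], nhat), "degenerate tract head")
})

test_that("summarize_tracts emits per-tract rows plus aggregates", {
  mt <- data.frame(seed_id = 1:8, patch = "insertion", status = "reached-attachment",
                   length_mm = rep(7, 8), pennation_deg = rep(30, 8))
  tab <- summarize_tracts(mt)
  expect_equal(sum(tab$row_type == "tract"), 8L)
  expect_setequal(tab$row_type[tab$row_type != "tract"],
                  c("mean", "sd", "min", "max"))
  expect_equal(tab$length_mm[tab$row_type == "mean"], 7)
  expect_equal(tab$length_mm[tab$row_type == "sd"], 0)
  expect_error(summarize_tracts(mt[0, ]), "no tracts")
})
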