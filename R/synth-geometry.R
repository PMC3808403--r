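# ---------------------------------------------------------------------------
# Deterministic synthetic muscle geometries. The archetypes cover the
# architectural classes relevant for testing: parallel strip, fanned
# trapezoid, curved annulus sector (with a closed-form field oracle), and
# the 3D box used as the uniform-field verification case. All lengths in mm.
# ---------------------------------------------------------------------------

grid_triangulate <- function(X, Y_of) {
  # generic 2-triangle split of a structured (nx+1)x(ny+1) logical grid
  # whose node coordinates are supplied by the caller; diagonal alternates
  # with (i+j) parity for symmetry
  nx <- nrow(X) - 1L; ny <- ncol(X) - 1L
  nid <- matrix(seq_len((nx + 1L) * (ny + 1L)), nx + 1L, ny + 1L)
  tris <- matrix(0L, 2L * nx * ny, 3L)
  t <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid[i, j]; b <- nid[i + 1L, j]
    c_ <- nid[i + 1L, j + 1L]; d <- nid[i, j + 1L]
    if ((i + j) %% 2L == 0L) {
      tris[t + 1L, ] <- c(a, b, c_); tris[t + 2L, ] <- c(a, c_, d)
    } else {
      tris[t + 1L, ] <- c(a, b, d); tris[t + 2L, ] <- c(b, c_, d)
    }
    t <- t + 2L
  }
  list(nodes = cbind(as.vector(X), as.vector(Y_of)), tris = tris)
}

axis_patch_2d <- function(mesh, origin_pred, insertion_pred) {
  set_patches(mesh, list(
    origin = select_patch_faces(mesh, origin_pred),
    insertion = select_patch_faces(mesh, insertion_pred)
  ), default = "belly")
}

#' Rectangular 2D strip (parallel architecture)
#'
#' Crossed-diagonal triangulation of a `L x W` rectangle; origin patch at
#' `x = 0`, insertion at `x = L`, belly on the long sides.
#'
#' @param L,W strip length and width (mm).
#' @param h target edge length (mm).
#' @return a tagged `simplex_mesh`.
#' @export
make_rect2d <- function(L, W, h) {
  check_res(h, L, W)
  nx <- max(1L, ceiling(L / h)); ny <- max(1L, ceiling(W / h))
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(0, W, length.out = ny + 1L)
  nid <- matrix(seq_len((nx + 1L) * (ny + 1L)), nx + 1L, ny + 1L)
  nodes <- cbind(rep(xs, ny + 1L), rep(ys, each = nx + 1L))
  # crossed split: center node per cell, 4 triangles
  ctr0 <- nrow(nodes)
  ctrs <- cbind(rep((xs[-1L] + xs[-(nx + 1L)]) / 2, ny),
                rep((ys[-1L] + ys[-(ny + 1L)]) / 2, each = nx))
  nodes <- rbind(nodes, ctrs)
  tris <- matrix(0L, 4L * nx * ny, 3L)
  t <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid[i, j]; b <- nid[i + 1L, j]
    c_ <- nid[i + 1L, j + 1L]; d <- nid[i, j + 1L]
    m <- ctr0 + (j - 1L) * nx + i
    tris[t + 1L, ] <- c(a, b, m); tris[t + 2L, ] <- c(b, c_, m)
    tris[t + 3L, ] <- c(c_, d, m); tris[t + 4L, ] <- c(d, a, m)
    t <- t + 4L
  }
  mesh <- finalize_mesh(nodes, tris)
  axis_patch_2d(mesh,
                function(p) abs(p[1]) < 1e-9,
                function(p) abs(p[1] - L) < 1e-9)
}

#' Fanned 2D trapezoid (broad origin, narrow insertion)
#'
#' Mapped-grid triangulation of a trapezoid with base width `base_width`
#' at `y = 0` (origin) narrowing to `tip_width` at `y = height` (insertion).
#'
#' @param base_width,tip_width,height trapezoid dimensions (mm),
#'   `tip_width < base_width`.
#' @param h target edge length (mm).
#' @return a tagged `simplex_mesh`.
#' @export
make_fan2d <- function(base_width, tip_width, height, h) {
  if (base_width <= 0 || tip_width <= 0 || height <= 0 || h <= 0)
    stop("invalid geometry: dimensions must be positive")
  if (tip_width >= base_width) stop("not a fan: tip_width >= base_width")
  check_res(h, tip_width, height)
  ny <- max(1L, ceiling(height / h))
  nx <- max(1L, ceiling(base_width / h))
  ys <- seq(0, height, length.out = ny + 1L)
  halfw <- (base_width + (tip_width - base_width) * ys / height) / 2
  X <- outer(seq(-1, 1, length.out = nx + 1L), halfw)  # (nx+1) x (ny+1)
  Y <- matrix(ys, nx + 1L, ny + 1L, byrow = TRUE)
  g <- grid_triangulate(X, Y)
  mesh <- finalize_mesh(g$nodes, g$tris)
  axis_patch_2d(mesh,
                function(p) abs(p[2]) < 1e-9,
                function(p) abs(p[2] - height) < 1e-9)
}

#' Annulus-sector 2D geometry (curved architecture, analytic oracle)
#'
#' Structured polar-grid triangulation of the sector `r_inner <= r <=
#' r_outer`, `0 <= theta <= Theta`. Node coordinates follow the exact polar
#' formula. Origin patch on the `theta = 0` radial edge, insertion on
#' `theta = Theta`, belly on the two arcs. The exact harmonic field on this
#' shape is `phi = c theta`, `v = (c/r) e_theta` (see
#' [annulus_closed_form()]).
#'
#' @param r_inner,r_outer radii (mm), `0 < r_inner < r_outer`.
#' @param Theta sector angle (rad), in `(0, 2*pi)`.
#' @param h target edge length (mm).
#' @return a tagged `simplex_mesh`.
#' @export
make_annulus_sector2d <- function(r_inner, r_outer, Theta, h) {
  if (!(r_inner > 0 && r_outer > r_inner && Theta > 0 && Theta < 2 * pi))
    stop("invalid geometry: need 0 < r_inner < r_outer and 0 < Theta < 2*pi")
  check_res(h, r_outer - r_inner)
  nr <- max(1L, ceiling((r_outer - r_inner) / h))
  arc <- Theta * (r_inner + r_outer) / 2
  nt <- max(1L, ceiling(arc / h))
  rs <- seq(r_inner, r_outer, length.out = nr + 1L)
  ths <- seq(0, Theta, length.out = nt + 1L)
  X <- outer(rs, ths, function(r, th) r * cos(th))
  Y <- outer(rs, ths, function(r, th) r * sin(th))
  g <- grid_triangulate(X, Y)
  mesh <- finalize_mesh(g$nodes, g$tris)
  ang <- function(p) atan2(p[2], p[1])
  axis_patch_2d(mesh,
                function(p) abs(ang(p)) < 1e-9,
                function(p) abs(ang(p) - Theta) < 1e-9)
}

#' 3D box (parallelepiped verification geometry)
#'
#' Structured grid of cubes, each split into six tetrahedra (Kuhn split,
#' deterministic). Origin patch on the `x = 0` wall, insertion on `x = L`,
#' belly elsewhere. The compatible uniform-flux problem on this shape has
#' the exact uniform solution, making it the standard workflow check.
#'
#' @param L,W,H box dimensions (mm).
#' @param h target edge length (mm).
#' @return a tagged `simplex_mesh`.
#' @export
make_box3d <- function(L, W, H, h) {
  check_res(h, L, W, H)
  nx <- max(1L, ceiling(L / h)); ny <- max(1L, ceiling(W / h))
  nz <- max(1L, ceiling(H / h))
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(0, W, length.out = ny + 1L)
  zs <- seq(0, H, length.out = nz + 1L)
  nid <- array(seq_len((nx + 1L) * (ny + 1L) * (nz + 1L)),
               c(nx + 1L, ny + 1L, nz + 1L))
  nodes <- as.matrix(expand.grid(xs, ys, zs))
  colnames(nodes) <- NULL
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3L, byrow = TRUE)
  tets <- matrix(0L, 6L * nx * ny * nz, 4L)
  t <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    base <- c(i, j, k)
    corner <- function(off) nid[base[1] + off[1], base[2] + off[2],
                                base[3] + off[3]]
    for (p in seq_len(6L)) {
      off <- c(0L, 0L, 0L)
      vs <- integer(4L)
      vs[1L] <- corner(off)
      for (s in 1:3) {
        off[perms[p, s]] <- 1L
        vs[s + 1L] <- corner(off)
      }
      t <- t + 1L
      tets[t, ] <- vs
    }
  }
  mesh <- finalize_mesh(nodes, tets)
  set_patches(mesh, list(
    origin = select_patch_faces(mesh, function(p) abs(p[1]) < 1e-9),
    insertion = select_patch_faces(mesh, function(p) abs(p[1] - L) < 1e-9)
  ), default = "belly")
}

check_res <- function(h, ...) {
  dims <- c(...)
  if (any(dims <= 0) || h <= 0) stop("invalid geometry: nonpositive size")
  if (h >= min(dims)) stop("resolution too coarse: h >= smallest dimension")
  invisible(TRUE)
}

#' Random single-simplex tracer fixture
#'
#' A non-degenerate random simplex with face fluxes induced exactly by a
#' random constant unit vector `v` (`f_i = v . N_i`, so they sum to zero to
#' machine precision). Deterministic per seed; the caller's RNG state is
#' preserved.
#'
#' @param dim 2 or 3.
#' @param rng_seed integer seed.
#' @return list with `mesh` (single-element `simplex_mesh`), `fluxes`
#'   (local order: face `i` opposite vertex `i`), and the generating `v`.
#' @export
random_flux_simplex <- function(dim, rng_seed) {
  stopifnot(dim %in% c(2L, 3L))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(rng_seed)
  repeat {
    verts <- matrix(stats::runif((dim + 1L) * dim), dim + 1L, dim)
    vol <- abs(signed_volumes(verts, matrix(seq_len(dim + 1L), 1L)))
    if (vol > 1e-3) break
  }
  v <- stats::rnorm(dim)
  v <- v / sqrt(sum(v^2))
  mesh <- finalize_mesh(verts, matrix(seq_len(dim + 1L), 1L))
  fluxes <- as.numeric(mesh$face_normal[mesh$elem_faces[1L, ], ] %*% v) *
    mesh$elem_face_sign[1L, ]
  list(mesh = mesh, fluxes = fluxes, v = v)
}

#' Closed-form harmonic field on the annulus sector
#'
#' The potential `phi = c * theta` is harmonic on the sector with zero
#' normal gradient on the arcs and flux density `c / r` (signed) on the
#' radial edges; its gradient is `v = (c/r) e_theta` and streamlines are
#' circular arcs of length `r * Theta`.
#'
#' @param r_inner,r_outer,Theta sector geometry.
#' @param c_const field constant (nonzero).
#' @return list of functions: `phi(r, theta)`, `v(x, y)` (Cartesian),
#'   `speed(r)`, `edge_density(r, edge)` with edge `"origin"`/`"insertion"`
#'   giving the signed outward flux density, and `tract_length(r)`.
#' @export
annulus_closed_form <- function(r_inner, r_outer, Theta, c_const = 1) {
  stopifnot(c_const != 0)
  list(
    phi = function(r, theta) c_const * theta,
    v = function(x, y) {
      r2 <- x^2 + y^2
      cbind(-c_const * y / r2, c_const * x / r2)
    },
    speed = function(r) abs(c_const) / r,
    edge_density = function(r, edge = c("origin", "insertion")) {
      edge <- match.arg(edge)
      s <- if (edge == "origin") -1 else 1
      s * c_const / r
    },
    tract_length = function(r) r * Theta
  )
}

#' Exact per-face flux boundary condition for the annulus sector
#'
#' Builds the `boundary_flux` whose radial-edge face fluxes are the exact
#' integrals of the `c/r` density over each face (`c * log(r2/r1)`), signed
#' inflow at `theta = 0` and outflow at `theta = Theta`; arcs carry zero.
#'
#' @param mesh an annulus-sector mesh from [make_annulus_sector2d()].
#' @param c_const field constant.
#' @return a `boundary_flux`.
#' @export
annulus_sector_bc <- function(mesh, c_const = 1) {
  dens <- c()
  for (lbl in c("origin", "insertion")) {
    faces <- mesh$patches[[lbl]]
    radii <- sqrt(rowSums(mesh$nodes^2))
    r1 <- radii[mesh$faces[faces, 1L]]
    r2 <- radii[mesh$faces[faces, 2L]]
    flux <- abs(c_const * log(pmax(r1, r2) / pmin(r1, r2)))
    s <- if (lbl == "origin") -1 else 1
    d <- s * flux / mesh$face_area[faces]
    dens <- c(dens, setNames(d, faces))
  }
  make_face_flux_bc(mesh, dens)
}
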