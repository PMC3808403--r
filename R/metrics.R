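# ---------------------------------------------------------------------------
# Tract post-processing: spline smoothing + equidistant resampling, fascicle
# length, seed tangent-plane normal, pennation angle, summary tables.
# ---------------------------------------------------------------------------

tract_points <- function(x) {
  if (inherits(x, "tract")) x$points
  else if (inherits(x, "smoothed_tract")) x$points
  else as.matrix(x)
}

#' Smooth and resample a raw fascicle tract
#'
#' Raw element-wise tracts are locally non-smooth because of the linear
#' discretization. They are subsampled to about `subsample_target` control
#' points (endpoints always kept), fitted with a cubic smoothing spline per
#' coordinate under chord-length parameterization with endpoint
#' interpolation enforced, and resampled at `n_points` equidistant stations.
#'
#' @param tract a `tract` (status `reached-attachment`) or a point matrix
#'   with at least 4 rows.
#' @param n_points number of output points (default 100).
#' @param subsample_target approximate number of spline control points.
#' @param smoothing maximum allowed spline deviation from the raw polyline,
#'   in mm; the default is half the median raw segment length (the scale of
#'   mesh-induced noise). The spline's flexibility is chosen adaptively as
#'   the stiffest fit meeting this bound.
#' @return a `smoothed_tract`: `points` (`n_points x dim`), `arc_length`,
#'   and the source tract.
#' @export
smooth_resample <- function(tract, n_points = 100L, subsample_target = 30L,
                            smoothing = NULL) {
  pts <- tract_points(tract)
  # drop exact duplicate consecutive points (zero-length steps at corners)
  if (nrow(pts) > 1L) {
    seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    if (sum(seg) <= 0) stop("degenerate tract: zero length")
    pts <- pts[c(TRUE, seg > 0), , drop = FALSE]
  }
  m <- nrow(pts)
  if (m < 4L) stop("tract too short: need >= 4 distinct points")
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-m, , drop = FALSE])^2))
  if (is.null(smoothing)) smoothing <- 0.5 * stats::median(seg)

  keep <- unique(round(seq(1L, m, length.out = min(subsample_target, m))))
  ctrl <- pts[keep, , drop = FALSE]
  k <- nrow(ctrl)
  u <- c(0, cumsum(sqrt(rowSums((ctrl[-1L, , drop = FALSE] -
                                   ctrl[-k, , drop = FALSE])^2))))
  u <- u / u[k]

  n_dense <- max(25L * n_points, 1000L)
  ud <- seq(0, 1, length.out = n_dense)
  dim_n <- ncol(pts)
  fit_coord <- function(df_try) {
    sapply(seq_len(dim_n), function(d) {
      if (df_try >= k) {
        # interpolating cubic spline (smoothing limit)
        stats::spline(u, ctrl[, d], xout = ud, method = "natural")$y
      } else {
        f <- stats::smooth.spline(u, ctrl[, d], df = df_try,
                                  all.knots = TRUE, keep.data = FALSE)
        predict(f, ud)$y
      }
    })
  }
  eval_at <- function(curve, uu) {
    sapply(seq_len(dim_n), function(d)
      approx(ud, curve[, d], xout = uu, rule = 2)$y)
  }
  # smallest df whose deviation at the control stations is within bound
  df_grid <- unique(pmin(k, c(4L, 6L, 8L, 12L, 16L, 24L, k)))
  curve <- NULL
  for (df_try in df_grid) {
    cv <- fit_coord(df_try)
    # enforce endpoint interpolation with a linear blend
    d0 <- ctrl[1L, ] - cv[1L, ]
    d1 <- ctrl[k, ] - cv[n_dense, ]
    cv <- cv + outer(1 - ud, d0) + outer(ud, d1)
    dev <- max(sqrt(rowSums((eval_at(cv, u) - ctrl)^2)))
    curve <- cv
    if (dev <= smoothing) break
  }

  out <- resample_equidistant(curve, n_points)
  arc <- sum(sqrt(rowSums((out[-1L, , drop = FALSE] -
                             out[-n_points, , drop = FALSE])^2)))
  structure(list(points = out, arc_length = arc, n_points = n_points,
                 source = if (inherits(tract, "tract")) tract else NULL),
            class = "smoothed_tract")
}

# place n points on a dense polyline so that consecutive chord distances are
# equal (fixed-point iteration on the arc-length stations)
resample_equidistant <- function(dense, n) {
  nd <- nrow(dense)
  s <- c(0, cumsum(sqrt(rowSums((dense[-1L, , drop = FALSE] -
                                   dense[-nd, , drop = FALSE])^2))))
  stot <- s[nd]
  pick <- function(st) {
    sapply(seq_len(ncol(dense)), function(d)
      approx(s, dense[, d], xout = st, rule = 2, ties = "ordered")$y)
  }
  st <- seq(0, stot, length.out = n)
  for (it in 1:5) {
    out <- pick(st)
    ch <- sqrt(rowSums((out[-1L, , drop = FALSE] - out[-n, , drop = FALSE])^2))
    C <- c(0, cumsum(ch))
    if (max(ch) - min(ch) <= 1e-9 * mean(ch)) break
    st <- approx(C, st, xout = seq(0, C[n], length.out = n),
                 rule = 2, ties = "ordered")$y
  }
  out
}

#' Fascicle length of a tract
#'
#' Sum of Euclidean distances between consecutive tract points.
#'
#' @param tract a `smoothed_tract`, `tract`, or point matrix (>= 2 rows).
#' @return length in mm.
#' @export
fascicle_length <- function(tract) {
  pts <- tract_points(tract)
  m <- nrow(pts)
  if (is.null(m) || m < 2L) stop("degenerate tract: need >= 2 points")
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-m, , drop = FALSE])^2)))
}

#' Tangent-plane normal at a seed face
#'
#' Unit-normalized average of the outward unit normals of the seed face and
#' its neighboring boundary faces. Neighbor faces share at least one node
#' (`adjacency = "vertex"`, smoother) or a full sub-face
#' (`adjacency = "edge"`). By default the average is restricted to faces of
#' the seed face's own patch: the tangent plane belongs to the tendon
#' attachment surface, and letting belly faces beyond the attachment rim
#' tilt it would corrupt the pennation of rim seeds.
#'
#' @param mesh a `simplex_mesh`.
#' @param face boundary-face index containing the seed point.
#' @param adjacency `"vertex"` (default) or `"edge"`.
#' @param same_patch restrict neighbors to the seed face's patch (default
#'   `TRUE`; ignored when the face is untagged).
#' @return unit normal vector (length `dim`).
#' @export
seed_tangent_normal <- function(mesh, face, adjacency = c("vertex", "edge"),
                                same_patch = TRUE) {
  adjacency <- match.arg(adjacency)
  if (!is.na(mesh$face_neighbor[face])) stop("not a boundary face")
  bnd <- boundary_faces(mesh)
  if (same_patch) {
    pt <- face_patch(mesh, face)
    if (!is.na(pt)) bnd <- mesh$patches[[pt]]
  }
  fnodes <- mesh$faces[face, ]
  shared <- rowSums(matrix(mesh$faces[bnd, , drop = FALSE] %in% fnodes,
                           nrow = length(bnd)))
  need <- if (adjacency == "vertex") 1L else mesh$dim - 1L
  nb <- bnd[shared >= need]
  un <- mesh$face_normal[nb, , drop = FALSE] / mesh$face_area[nb]
  avg <- colMeans(un)
  avg / sqrt(sum(avg^2))
}

#' Pennation angle at the seed end of a tract
#'
#' For the first five inter-point steps past the seed point (5% of a
#' 100-point fascicle tract), the angle between the tangent plane at the
#' seed and the vector from the seed to tract point `k` is
#' `asin(|(p_k - p_1) . n| / |p_k - p_1|)`; the five angles are averaged.
#' The tract must be oriented with the measurement attachment first.
#'
#' @param tract a `smoothed_tract` (or point matrix, >= 6 points) whose
#'   first point is the seed point on the measurement attachment.
#' @param plane_normal unit normal of the tangent plane at the seed.
#' @return mean pennation angle in degrees, in `[0, 90]`.
#' @export
pennation_angle <- function(tract, plane_normal) {
  pts <- tract_points(tract)
  if (nrow(pts) < 6L) stop("degenerate tract head: need >= 6 points")
  nhat <- plane_normal / sqrt(sum(plane_normal^2))
  p1 <- pts[1L, ]
  ang <- vapply(2:6, function(k) {
    d <- pts[k, ] - p1
    len <- sqrt(sum(d^2))
    if (len == 0) stop("degenerate tract head: coincident points")
    asin(min(1, abs(sum(d * nhat)) / len)) * 180 / pi
  }, numeric(1))
  min(90, max(0, mean(ang)))
}

#' Per-tract metrics table with aggregates
#'
#' @param metrics a data frame (or list of rows) with columns `seed_id`,
#'   `patch`, `status`, `length_mm`, `pennation_deg`.
#' @return a data frame with one `tract` row per input plus `mean`, `sd`,
#'   `min`, `max` aggregate rows per patch label (column `row_type`).
#' @export
summarize_tracts <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- do.call(rbind, lapply(metrics, as.data.frame))
  if (is.null(metrics) || nrow(metrics) == 0L) stop("no tracts")
  metrics$row_type <- "tract"
  agg <- do.call(rbind, lapply(split(metrics, metrics$patch), function(gr) {
    data.frame(
      seed_id = NA_integer_, patch = gr$patch[1L], status = NA_character_,
      length_mm = c(mean(gr$length_mm), sd_or_zero(gr$length_mm),
                    min(gr$length_mm), max(gr$length_mm)),
      pennation_deg = c(mean(gr$pennation_deg), sd_or_zero(gr$pennation_deg),
                        min(gr$pennation_deg), max(gr$pennation_deg)),
      row_type = c("mean", "sd", "min", "max"))
  }))
  rownames(agg) <- NULL
  rbind(metrics[, names(agg)], agg)
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else sd(x)
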