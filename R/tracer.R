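# ---------------------------------------------------------------------------
# Flux-consistent barycentric streamline tracing.
#
# Inside a simplex with outward face fluxes f_i (face i opposite vertex i)
# summing to zero, the constant velocity is v = -(1/(nV)) sum_i f_i x_i and
# each barycentric coordinate evolves linearly, dlambda_i/dt = -f_i/(nV).
# The exit face is the one whose coordinate first reaches zero:
# t_i = lambda_i n V / f_i for f_i > 0, time of flight tau = min finite t_i,
# exit lambda' = lambda - tau f/(nV). Tracing element by element with the
# shared conservative face fluxes cannot terminate inside the volume or on
# the zero-flux belly surface.
# ---------------------------------------------------------------------------

#' Barycentric coordinates of a point in an element
#'
#' @param mesh a `simplex_mesh`.
#' @param element element index.
#' @param point coordinate vector inside (or on) the closed element; small
#'   violations are clipped, larger ones raise "point not in element".
#' @return barycentric vector of length `dim + 1`, ordered by local vertex,
#'   nonnegative and summing to one.
#' @export
barycentric_coords <- function(mesh, element, point) {
  vs <- mesh$nodes[mesh$elements[element, ], , drop = FALSE]
  n <- mesh$dim
  Tm <- t(vs[seq_len(n), , drop = FALSE]) - vs[n + 1L, ]
  lam <- solve(Tm, as.numeric(point) - vs[n + 1L, ])
  lam <- c(lam, 1 - sum(lam))
  if (min(lam) < -1e-7 || max(lam) > 1 + 1e-7)
    stop("point not in element")
  clip_lambda(lam)
}

clip_lambda <- function(lam, snap = 1e-12) {
  lam[lam < 0] <- 0
  lam[lam > 1] <- 1
  lam[lam < snap] <- 0
  lam / sum(lam)
}

bary_point <- function(mesh, element, lam) {
  as.numeric(lam %*% mesh$nodes[mesh$elements[element, ], , drop = FALSE])
}

# local outward fluxes of an element (face i opposite vertex i), with the
# residual neutralized so they sum to zero exactly (local copy only)
local_fluxes <- function(mesh, face_flux, element) {
  f <- face_flux[mesh$elem_faces[element, ]] * mesh$elem_face_sign[element, ]
  f - sum(f) / length(f)
}

#' Barycentric intersection times within one element
#'
#' @param lambda barycentric entry coordinates.
#' @param fluxes outward face fluxes of the element (summing to zero).
#' @param V element measure.
#' @param n spatial dimension.
#' @return per-coordinate times: `lambda_i * n * V / f_i` where `f_i > 0`
#'   (the coordinate is decreasing), `Inf` otherwise.
#' @export
intersection_times <- function(lambda, fluxes, V, n) {
  t_i <- rep(Inf, length(lambda))
  pos <- fluxes > 0
  t_i[pos] <- lambda[pos] * n * V / fluxes[pos]
  t_i
}

#' Advance a streamline through one element
#'
#' Computes the time of flight (minimum nonnegative intersection time), the
#' exit point on the face opposite the vanishing coordinate, and re-expresses
#' the state in the neighbor element (or reports a boundary hit). Ties within
#' `1e-12` relative are broken toward the lower local face index and the
#' next state is nudged toward the neighbor's interior.
#'
#' @param mesh a `simplex_mesh`.
#' @param field a `potential_field` (or any conservative per-face flux vector
#'   wrapped as `list(face_flux = ...)`).
#' @param state list with `element`, `lambda`, `point`.
#' @param flux_sign `+1` to follow the flux (downstream), `-1` upstream.
#' @return list with `status` (`"interior"`, `"boundary"`, `"stagnant"`),
#'   the exit `point`, time of flight `tau`, `face` (global index of the
#'   crossed face), and for interior exits the new `state`.
#' @export
advance_through_element <- function(mesh, field, state, flux_sign = 1) {
  e <- state$element
  n <- mesh$dim
  nV <- n * mesh$elem_volume[e]
  q <- flux_sign * local_fluxes(mesh, field$face_flux, e)
  t_i <- intersection_times(state$lambda, q, mesh$elem_volume[e], n)
  fin <- is.finite(t_i)
  if (!any(fin)) return(list(status = "stagnant", tau = NA_real_))
  tau <- min(t_i[fin])
  cand <- which(t_i <= tau * (1 + 1e-12) + 1e-300)
  tie <- length(cand) > 1L
  i_exit <- min(cand)
  lam_exit <- clip_lambda(state$lambda - tau * q / nV)
  lam_exit[i_exit] <- 0
  lam_exit <- lam_exit / sum(lam_exit)
  p_exit <- bary_point(mesh, e, lam_exit)
  g <- mesh$elem_faces[e, i_exit]
  if (is.na(mesh$face_neighbor[g]))
    return(list(status = "boundary", point = p_exit, tau = tau, face = g))
  e2 <- if (mesh$face_owner[g] == e) mesh$face_neighbor[g] else mesh$face_owner[g]
  lam2 <- barycentric_coords(mesh, e2, p_exit)
  if (tie) {  # nudge toward the interior of the next element
    k <- length(lam2)
    lam2 <- clip_lambda((1 - 1e-10) * lam2 + 1e-10 / k)
  }
  list(status = "interior", point = p_exit, tau = tau, face = g,
       state = list(element = e2, lambda = lam2, point = p_exit))
}

#' Trace one fascicle tract through the flux field
#'
#' Advances element by element from a seed on an attachment patch until the
#' streamline exits through a boundary face of an attachment patch. With a
#' zero-flux belly the tract cannot terminate inside the volume or on the
#' belly surface. Upstream tracts are reversed so every returned tract runs
#' in the downstream (origin-to-insertion) order.
#'
#' @param mesh a `simplex_mesh` with patches including `belly_patch`.
#' @param field a `potential_field`.
#' @param seed a seed state from [seed_patch_centroids()], or a list with
#'   `face`, `element`, `lambda`, `point`.
#' @param direction `"downstream"` (along the flux) or `"upstream"`.
#' @param max_steps traversal bound; default `10 *` element count.
#' @param belly_patch label of the impermeable patch (default `"belly"`).
#' @return a `tract`: ordered `points`, element `trail`, times of flight
#'   `tau`, `start_patch`, `end_patch`, `status`, `seed_face`, `seed_point`,
#'   and `seed_at` (`"start"` or `"end"` of the returned polyline).
#' @export
trace_fascicle <- function(mesh, field, seed,
                           direction = c("downstream", "upstream"),
                           max_steps = 10L * nrow(mesh$elements),
                           belly_patch = "belly") {
  direction <- match.arg(direction)
  seed_patch <- face_patch(mesh, seed$face)
  if (is.na(seed_patch) || identical(seed_patch, belly_patch))
    stop("invalid seed: seed must lie on an attachment patch face")
  flux_sign <- if (direction == "downstream") 1 else -1
  state <- list(element = seed$element, lambda = seed$lambda,
                point = seed$point)
  pts <- list(seed$point)
  trail <- integer(0)
  taus <- numeric(0)
  status <- "max-steps"
  end_patch <- NA_character_
  for (step in seq_len(max_steps)) {
    adv <- advance_through_element(mesh, field, state, flux_sign)
    if (adv$status == "stagnant") { status <- "stagnant"; break }
    trail <- c(trail, state$element)
    taus <- c(taus, adv$tau)
    pts[[length(pts) + 1L]] <- adv$point
    if (adv$status == "boundary") {
      hit_patch <- face_patch(mesh, adv$face)
      if (identical(hit_patch, belly_patch))
        stop("invalid termination: tract exited through a belly face ",
             "(internal consistency failure)")
      status <- "reached-attachment"
      end_patch <- hit_patch
      break
    }
    state <- adv$state
  }
  points <- do.call(rbind, pts)
  start_patch <- seed_patch
  seed_at <- "start"
  if (direction == "upstream") {
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
    trail <- rev(trail)
    taus <- rev(taus)
    tmp <- start_patch; start_patch <- end_patch; end_patch <- tmp
    seed_at <- "end"
  }
  structure(list(
    seed_id = seed$id %||% NA_integer_, seed_face = seed$face,
    seed_point = seed$point, seed_at = seed_at,
    points = points, trail = trail, tau = taus,
    start_patch = start_patch, end_patch = end_patch,
    status = status, direction = direction
  ), class = "tract")
}

#' @export
print.tract <- function(x, ...) {
  cat(sprintf("tract (seed %s): %d points, %d elements, %s -> %s [%s]\n",
              format(x$seed_id), nrow(x$points), length(x$trail),
              format(x$start_patch), format(x$end_patch), x$status))
  invisible(x)
}

#' Deterministic seeds on an attachment patch
#'
#' One seed per face at its centroid; for `per_face > 1`, additional seeds
#' at fixed interior barycentric offsets of the face (a deterministic blend
#' of the face centroid toward each face vertex in turn).
#'
#' @param mesh a `simplex_mesh`.
#' @param patch patch label.
#' @param per_face seeds per face (>= 1).
#' @return list of seed states (`id`, `face`, `element`, `lambda`, `point`).
#' @export
seed_patch_centroids <- function(mesh, patch, per_face = 1L) {
  if (per_face < 1L) stop("invalid density: per_face must be >= 1")
  faces <- mesh$patches[[patch]]
  if (is.null(faces) || !length(faces)) stop("empty patch: ", patch)
  n <- mesh$dim
  seeds <- list()
  sid <- 0L
  for (f in faces) {
    e <- mesh$face_owner[f]
    fnodes <- mesh$faces[f, ]
    # local (element) vertex indices of the face nodes
    loc <- match(fnodes, mesh$elements[e, ])
    for (j in seq_len(per_face)) {
      w <- rep(1 / n, n)
      if (j > 1L) {
        beta <- 0.5 * (j - 1) / per_face
        vtx <- ((j - 2L) %% n) + 1L
        w <- (1 - beta) * w
        w[vtx] <- w[vtx] + beta
      }
      lam <- numeric(n + 1L)
      lam[loc] <- w
      sid <- sid + 1L
      seeds[[sid]] <- list(id = sid, face = f, element = e, lambda = lam,
                           point = bary_point(mesh, e, lam), patch = patch)
    }
  }
  seeds
}
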