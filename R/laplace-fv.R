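# ---------------------------------------------------------------------------
# Cell-centered finite-volume Laplace solver with Neumann flux boundary
# conditions. Two-point orthogonal flux as the implicit part; deferred
# (over-relaxed decomposition) non-orthogonality correction from Green-Gauss
# flux-weighted cell gradients; pure-Neumann nullspace removed by mean-zero
# projection and a deterministic potential pin.
# ---------------------------------------------------------------------------

#' Uniform-flux attachment boundary conditions
#'
#' Imposes a spatially uniform flux density over each attachment patch: the
#' inflow patch receives density `-total_flux / A_inflow` (inflow = negative
#' outward flux), the outflow patch `+total_flux / A_outflow`, and every
#' other boundary face (the muscle belly) exactly zero. Outflow densities are
#' renormalized last so the global balance sum(g * A) is zero to machine
#' precision, which is the compatibility condition of the pure Neumann
#' problem.
#'
#' @param mesh a finalized `simplex_mesh` with patches assigned.
#' @param inflow_patch,outflow_patch patch labels (typically `"origin"` and
#'   `"insertion"`).
#' @param total_flux positive scalar; only sets the field magnitude, tract
#'   geometry is invariant to it.
#' @return a `boundary_flux` object: per-boundary-face density `g` and
#'   integrated flux `g * A` (positive = outflow).
#' @export
make_uniform_flux_bc <- function(mesh, inflow_patch, outflow_patch,
                                 total_flux = 1) {
  stopifnot(total_flux > 0)
  pin <- mesh$patches[[inflow_patch]]
  pout <- mesh$patches[[outflow_patch]]
  if (is.null(pin) || !length(pin)) stop("empty patch: ", inflow_patch)
  if (is.null(pout) || !length(pout)) stop("empty patch: ", outflow_patch)
  if (length(intersect(pin, pout))) stop("patch overlap")
  bnd <- boundary_faces(mesh)
  g <- setNames(numeric(length(bnd)), bnd)
  g[as.character(pin)] <- -total_flux / sum(mesh$face_area[pin])
  g[as.character(pout)] <- total_flux / sum(mesh$face_area[pout])
  finalize_bc(mesh, bnd, g, renorm = as.character(pout))
}

#' Per-face flux-density boundary conditions
#'
#' Extension point for non-uniform attachment conditions: supply an explicit
#' flux density per boundary face (positive = outflow). Faces omitted get
#' zero (belly). The densities must satisfy the global balance; faces listed
#' in `renormalize` absorb the floating-point closure error.
#'
#' @param mesh a finalized `simplex_mesh`.
#' @param density named numeric vector, names = boundary face indices.
#' @param renormalize optional integer vector of outflow faces whose
#'   densities are scaled to close the balance exactly.
#' @return a `boundary_flux` object.
#' @export
make_face_flux_bc <- function(mesh, density, renormalize = NULL) {
  bnd <- boundary_faces(mesh)
  g <- setNames(numeric(length(bnd)), bnd)
  idx <- names(density)
  if (!all(idx %in% names(g)))
    stop("untagged boundary: density given for a non-boundary face")
  g[idx] <- as.numeric(density)
  finalize_bc(mesh, bnd, g,
              renorm = if (!is.null(renormalize)) as.character(renormalize))
}

finalize_bc <- function(mesh, bnd, g, renorm = NULL) {
  flux <- g * mesh$face_area[bnd]
  inflow <- -sum(flux[flux < 0])
  if (inflow <= 0) stop("incompatible boundary conditions: no inflow")
  imb <- sum(flux)
  if (!is.null(renorm) && length(renorm)) {
    a_out <- sum(mesh$face_area[as.integer(renorm)])
    g[renorm] <- g[renorm] - imb / a_out
    flux <- g * mesh$face_area[bnd]
    imb <- sum(flux)
  }
  if (abs(imb) > 1e-12 * inflow)
    stop("incompatible boundary conditions: flux imbalance ",
         format(imb / inflow), " of inflow")
  structure(list(faces = bnd, density = unname(g), flux = unname(flux),
                 total_inflow = inflow), class = "boundary_flux")
}

#' @export
print.boundary_flux <- function(x, ...) {
  cat(sprintf("boundary_flux: %d faces, total inflow %g, balance %.3e\n",
              length(x$faces), x$total_inflow, sum(x$flux)))
  invisible(x)
}

# Geometric face coefficients for the two-point + deferred-correction split.
# Over-relaxed decomposition: N = a*d + k with a = |N|^2 / (N.d).
face_scheme <- function(mesh) {
  int_f <- which(!is.na(mesh$face_neighbor))
  o <- mesh$face_owner[int_f]
  q <- mesh$face_neighbor[int_f]
  d <- mesh$elem_centroid[q, , drop = FALSE] - mesh$elem_centroid[o, , drop = FALSE]
  N <- mesh$face_normal[int_f, , drop = FALSE]
  nd <- rowSums(N * d)
  if (any(nd <= 0)) stop("degenerate element: non-positive face decoupling")
  a <- rowSums(N^2) / nd
  list(int_f = int_f, owner = o, neigh = q, a = a, k = N - a * d)
}

#' Solve the Laplace equation for the fascicle potential field
#'
#' Cell-centered finite-volume solve of `div grad(phi) = 0` with the flux
#' boundary conditions in `bc`. Interior face fluxes use a two-point
#' orthogonal approximation plus an explicit non-orthogonality correction
#' that is re-assembled and re-solved until the two-norm of the per-element
#' flux-balance residual drops below `outer_tol` times the total inflow.
#' The inner symmetric system is solved by preconditioned conjugate
#' gradients at relative tolerance `inner_rtol`. The additive constant of
#' the pure Neumann problem is fixed by pinning one element's potential.
#'
#' @param mesh a finalized, connected `simplex_mesh`.
#' @param bc a `boundary_flux` (globally balanced).
#' @param inner_rtol relative tolerance of the inner conjugate-gradient
#'   solve (default `1e-8`).
#' @param outer_tol stopping tolerance of the non-orthogonality correction
#'   loop, relative to total inflow (default `1e-8`).
#' @param max_outer maximum correction iterations (default 50).
#' @param pin_element,pin_value element whose potential is fixed, and its
#'   value (defaults: element 1, value 0).
#' @return a `potential_field`: per-element potential `phi`, single-valued
#'   per-face flux `face_flux` (positive along the stored face normal),
#'   per-element orientation vectors `vectors`, and a solver `report`.
#' @export
solve_potential <- function(mesh, bc, inner_rtol = 1e-8, outer_tol = 1e-8,
                            max_outer = 50L, pin_element = 1L,
                            pin_value = 0) {
  n_el <- nrow(mesh$elements)
  Q <- bc$total_inflow
  if (abs(sum(bc$flux)) > 1e-10 * Q)
    stop("incompatible boundary conditions")
  if (!is_connected(mesh)) stop("singular system: mesh is disconnected")
  fs <- face_scheme(mesh)
  M <- Matrix::sparseMatrix(
    i = c(fs$owner, fs$neigh, fs$owner, fs$neigh),
    j = c(fs$owner, fs$neigh, fs$neigh, fs$owner),
    x = c(fs$a, fs$a, -fs$a, -fs$a),
    dims = c(n_el, n_el))
  # boundary flux accumulated per owner element
  bflux <- numeric(n_el)
  tmp <- rowsum(bc$flux, mesh$face_owner[bc$faces])
  bflux[as.integer(rownames(tmp))] <- tmp[, 1L]

  corr <- numeric(length(fs$int_f))
  phi <- numeric(n_el)
  resid <- Inf
  outer <- 0L
  inner_info <- list(iter = 0L, relres = NA_real_)
  converged <- FALSE
  repeat {
    outer <- outer + 1L
    b <- bflux + sgn_accum(corr, fs$owner, fs$neigh, n_el)
    b <- b - mean(b)
    # inner stopping rule: the requested relative tolerance, tightened so
    # the inner defect can never dominate the outer flux-balance target
    rtol_eff <- min(inner_rtol,
                    0.1 * outer_tol * Q / max(sqrt(sum(b^2)), 1e-300))
    sol <- pcg_solve(M, b, x0 = phi, rtol = rtol_eff)
    if (!sol$converged) stop("solver failure: inner PCG did not converge")
    phi <- sol$x
    inner_info <- list(iter = sol$iter, relres = sol$relres)
    # updated correction from Green-Gauss gradients of the current fluxes
    F_int <- fs$a * (phi[fs$neigh] - phi[fs$owner]) + corr
    grad <- green_gauss_gradients(mesh, fs, F_int, bc)
    corr_new <- rowSums(0.5 * (grad[fs$owner, , drop = FALSE] +
                               grad[fs$neigh, , drop = FALSE]) * fs$k)
    F_new <- fs$a * (phi[fs$neigh] - phi[fs$owner]) + corr_new
    r <- element_residuals(mesh, face_flux_vector(mesh, fs, F_new, bc))
    resid <- sqrt(sum(r^2)) / Q
    corr <- corr_new
    if (resid < outer_tol) { converged <- TRUE; break }
    if (outer >= max_outer) break
  }
  if (!converged)
    warning("non-orthogonality correction loop hit max_outer (residual ",
            format(resid), ")")
  F_int <- fs$a * (phi[fs$neigh] - phi[fs$owner]) + corr
  face_flux <- face_flux_vector(mesh, fs, F_int, bc)
  phi <- phi - phi[pin_element] + pin_value
  v <- element_vectors(mesh, face_flux, tol_balance = Inf)
  structure(list(
    phi = phi, face_flux = face_flux, vectors = v, bc = bc,
    tol_balance = outer_tol * Q,
    report = list(outer_iterations = outer, residual_two_norm = resid,
                  converged = converged, inner = inner_info)
  ), class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf(
    "potential_field: %d elements, outer iters %d, normalized residual %.3e\n",
    length(x$phi), x$report$outer_iterations, x$report$residual_two_norm))
  invisible(x)
}

# signed accumulation: + into owner, - into neighbor
sgn_accum <- function(vals, owner, neigh, n_el) {
  out <- numeric(n_el)
  t1 <- rowsum(vals, owner); out[as.integer(rownames(t1))] <- t1[, 1L]
  t2 <- rowsum(vals, neigh)
  out[as.integer(rownames(t2))] <- out[as.integer(rownames(t2))] - t2[, 1L]
  out
}

# full per-face flux vector (positive along the stored outward-from-owner
# normal): interior from the scheme, boundary prescribed exactly
face_flux_vector <- function(mesh, fs, F_int, bc) {
  ff <- numeric(nrow(mesh$faces))
  ff[fs$int_f] <- F_int
  ff[bc$faces] <- bc$flux
  ff
}

# Green-Gauss flux-weighted gradient: g_e = (1/V) sum_f F_f^out (c_f - c_e).
# Exact for fields with constant gradient, including at boundary elements
# (the prescribed boundary fluxes enter the sum).
green_gauss_gradients <- function(mesh, fs, F_int, bc) {
  n_el <- nrow(mesh$elements)
  ff <- face_flux_vector(mesh, fs, F_int, bc)
  g <- matrix(0, n_el, mesh$dim)
  fo <- mesh$face_owner
  fn <- mesh$face_neighbor
  for (d in seq_len(mesh$dim)) {
    w_o <- ff * (mesh$face_centroid[, d] - mesh$elem_centroid[fo, d])
    t1 <- rowsum(w_o, fo)
    g[as.integer(rownames(t1)), d] <- t1[, 1L]
    int_f <- fs$int_f
    w_n <- -ff[int_f] * (mesh$face_centroid[int_f, d] -
                           mesh$elem_centroid[fn[int_f], d])
    t2 <- rowsum(w_n, fn[int_f])
    ids <- as.integer(rownames(t2))
    g[ids, d] <- g[ids, d] + t2[, 1L]
  }
  g / mesh$elem_volume
}

# per-element sum of signed outward fluxes
element_residuals <- function(mesh, face_flux) {
  f_loc <- matrix(face_flux[mesh$elem_faces], nrow = nrow(mesh$elem_faces)) *
    mesh$elem_face_sign
  rowSums(f_loc)
}

#' Per-element orientation vectors from a conservative face-flux field
#'
#' Reconstructs the unique constant vector of each element from its outward
#' face fluxes: `v = -(1/(n V)) * sum_i f_i x_i`, with `f_i` the outward
#' flux through the face opposite vertex `i`. Any small per-element flux
#' imbalance is neutralized (`f_i - r_e/(n+1)`) first, which makes the
#' formula translation-invariant and the reconstruction exact
#' (`v . N_i = f_i` for all faces).
#'
#' @param mesh a finalized `simplex_mesh`.
#' @param face_flux per-face flux vector, positive along the stored normal.
#' @param tol_balance absolute tolerance on the per-element flux imbalance;
#'   the default scales with the largest flux magnitude.
#' @return `n_el x dim` matrix of element vectors.
#' @export
element_vectors <- function(mesh, face_flux,
                            tol_balance = 1e-6 * max(abs(face_flux), 1e-300)) {
  r <- element_residuals(mesh, face_flux)
  if (max(abs(r)) > tol_balance)
    stop("non-conservative flux field: max element imbalance ",
         format(max(abs(r))))
  n <- mesh$dim
  f_loc <- matrix(face_flux[mesh$elem_faces], nrow = nrow(mesh$elem_faces)) *
    mesh$elem_face_sign
  q <- f_loc - r / (n + 1)
  v <- matrix(0, nrow(mesh$elements), n)
  for (i in seq_len(n + 1L))
    v <- v + q[, i] * mesh$nodes[mesh$elements[, i], , drop = FALSE]
  -v / (n * mesh$elem_volume)
}

#' Conservation diagnostics of a solved field
#'
#' @param mesh a finalized `simplex_mesh`.
#' @param field a `potential_field`.
#' @param tol pass/fail threshold on the normalized residual two-norm
#'   (default `1e-8`, the stopping criterion of the solver).
#' @return a `balance_report` list: per-element residuals, their two-norm
#'   and max-norm normalized by total inflow, the global boundary balance,
#'   and `pass`.
#' @export
check_balance <- function(mesh, field, tol = 1e-8) {
  r <- element_residuals(mesh, field$face_flux)
  Q <- field$bc$total_inflow
  bnd <- boundary_faces(mesh)
  structure(list(
    residuals = r,
    two_norm = sqrt(sum(r^2)) / Q,
    max_norm = max(abs(r)) / Q,
    boundary_balance = sum(field$face_flux[bnd]) / Q,
    tol = tol,
    pass = sqrt(sum(r^2)) / Q <= tol
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf(
    "balance_report: ||r||2/Q = %.3e, max|r|/Q = %.3e, boundary = %.3e [%s]\n",
    x$two_norm, x$max_norm, x$boundary_balance,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

# Preconditioned (Jacobi) conjugate gradients on the singular consistent
# Neumann system; the constant nullspace is projected out of the iterates.
pcg_solve <- function(M, b, x0 = NULL, rtol = 1e-8, maxit = 20000L) {
  n <- length(b)
  dinv <- 1 / Matrix::diag(M)
  dinv[!is.finite(dinv)] <- 0
  x <- if (is.null(x0)) numeric(n) else x0 - mean(x0)
  b <- b - mean(b)
  r <- b - as.numeric(M %*% x)
  r <- r - mean(r)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iter = 0L, relres = 0, converged = TRUE))
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Mp <- as.numeric(M %*% p)
    alpha <- rz / sum(p * Mp)
    x <- x + alpha * p
    r <- r - alpha * Mp
    r <- r - mean(r)
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres < rtol)
      return(list(x = x - mean(x), iter = it, relres = relres,
                  converged = TRUE))
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iter = maxit, relres = sqrt(sum(r^2)) / bnorm,
       converged = FALSE)
}

# BFS connectivity over face adjacency; the pure Neumann system is singular
# beyond repair (per-component incompatibility) on a disconnected mesh.
is_connected <- function(mesh) {
  n_el <- nrow(mesh$elements)
  int_f <- which(!is.na(mesh$face_neighbor))
  if (!length(int_f)) return(n_el == 1L)
  o <- mesh$face_owner[int_f]; q <- mesh$face_neighbor[int_f]
  adj <- split(c(q, o), c(o, q))
  seen <- logical(n_el)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    nb <- unique(unlist(adj[as.character(queue)], use.names = FALSE))
    queue <- nb[!seen[nb]]
    seen[queue] <- TRUE
  }
  all(seen)
}
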