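#' Flow configuration
#'
#' Parameters of the conformalized mean curvature flow (cMCF) and its
#' constrained variants. `delta_t` is the implicit time step (default 5e-4,
#' appropriate for cell surfaces in voxel units), `t_min` the minimum number
#' of iterations the automatic stopping rule may return, `delta_thresh` the
#' threshold on the change of mean absolute Gaussian curvature between
#' iterations, and `renormalize` rescales total surface area to 1 and
#' recenters the centroid after every iteration (recommended numerics).
#'
#' @param delta_t implicit time step (> 0).
#' @param t_min minimum iterations (>= 1).
#' @param delta_thresh stopping threshold on `|d mean|K||`.
#' @param max_iters maximum iterations (>= t_min).
#' @param laplacian `"cotangent"` or `"robust"`.
#' @param renormalize logical.
#' @return a list of class `flow_config`.
#' @export
flow_config <- function(delta_t = 5e-4, t_min = 1, delta_thresh = 1e-5,
                        max_iters = 50, laplacian = "cotangent",
                        renormalize = TRUE) {
  stopifnot(delta_t > 0, t_min >= 1, max_iters >= t_min)
  structure(list(delta_t = delta_t, t_min = t_min,
                 delta_thresh = delta_thresh, max_iters = max_iters,
                 laplacian = laplacian, renormalize = renormalize),
            class = "flow_config")
}

# area-normalize to total area 1 and recenter the (area-weighted) centroid
normalize_mesh_vertices <- function(v, f) {
  mesh <- surface_mesh(v, f, drop_degenerate = FALSE)
  a <- face_areas(mesh)
  bc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
         v[f[, 3], , drop = FALSE]) / 3
  centroid <- colSums(bc * a) / sum(a)
  v <- sweep(v, 2, centroid)
  v / sqrt(sum(a))
}

#' Conformalized mean curvature flow
#'
#' Evolves a closed mesh by solving `(M_t - delta_t * L_0) v(t+1) = M_t v(t)`
#' per iteration: the Laplacian is frozen at `t = 0` (which preserves face
#' aspect ratios and hence conformality of the flow), while the barycentric
#' mass matrix is recomputed each step. Face connectivity never changes, so
#' the flow is bijective by construction. The mean absolute Gaussian
#' curvature per iteration is recorded; its elbow identifies the smooth
#' reference shape via [auto_stop()].
#'
#' @param mesh a closed `surface_mesh`.
#' @param config a [flow_config()].
#' @return a list of class `flow_result`: `snapshots` (vertex matrices,
#'   element 1 = input), `K_trace` (mean |K|, element 1 = input),
#'   `stop_iteration`, `broke_down` flag.
#' @export
cmcf <- function(mesh, config = flow_config()) {
  f <- mesh$faces
  v <- mesh$vertices
  if (config$renormalize) v <- normalize_mesh_vertices(v, f)
  ops0 <- build_operators(surface_mesh(v, f, drop_degenerate = FALSE),
                          config$laplacian)
  L0 <- ops0$L
  snapshots <- list(v)
  K_trace <- mean(abs(gaussian_curvature(surface_mesh(v, f, drop_degenerate = FALSE))))
  broke <- FALSE
  for (t in seq_len(config$max_iters)) {
    m <- surface_mesh(v, f, drop_degenerate = FALSE)
    M <- build_operators(m, config$laplacian)$M
    A <- M - config$delta_t * L0
    vnew <- tryCatch(as.matrix(Matrix::solve(A, M %*% v)),
                     error = function(e) NULL)
    if (is.null(vnew) || anyNA(vnew)) {
      warning("flow breakdown at iteration ", t, "; returning last valid iterate")
      broke <- TRUE
      break
    }
    if (config$renormalize) vnew <- normalize_mesh_vertices(vnew, f)
    v <- vnew
    snapshots[[t + 1]] <- v
    K_trace[t + 1] <- mean(abs(gaussian_curvature(
      surface_mesh(v, f, drop_degenerate = FALSE))))
  }
  stop_it <- auto_stop(K_trace, config$t_min, config$delta_thresh)
  structure(list(snapshots = snapshots, K_trace = K_trace,
                 stop_iteration = stop_it, faces = f, broke_down = broke),
            class = "flow_result")
}

#' Extract the mesh at a given flow iteration
#'
#' @param flow a `flow_result`.
#' @param iteration iteration number (0 = input; default the automatic stop).
#' @param template optional `surface_mesh` providing fields to carry over.
#' @return a `surface_mesh`.
#' @export
flow_mesh <- function(flow, iteration = flow$stop_iteration, template = NULL) {
  v <- flow$snapshots[[min(iteration, length(flow$snapshots) - 1L) + 1L]]
  m <- surface_mesh(v, flow$faces, drop_degenerate = FALSE)
  if (!is.null(template)) {
    m$vertex_fields <- template$vertex_fields
    m$face_fields <- template$face_fields
  }
  m
}

#' Automatic stopping iteration from a curvature trace
#'
#' The flow's mean absolute Gaussian curvature decreases steeply while
#' protrusions are absorbed and plateaus once the smooth cortical shape is
#' reached. The elbow is detected as the first iteration whose curvature
#' change falls below `delta_thresh` in magnitude; the returned iteration is
#' `max(t_min, t_K)`. The alternative literal reading (first iteration whose
#' change *exceeds* the threshold) is available via `mode = "exceed"`; on
#' monotonically flattening traces the default elbow rule is the meaningful
#' one (see the package vignette).
#'
#' @param K_trace mean |K| per iteration (element 1 = iteration 0).
#' @param t_min minimum iteration.
#' @param delta_thresh threshold.
#' @param mode `"elbow"` (default) or `"exceed"`.
#' @return integer stop iteration; if no crossing occurs, the last iteration.
#' @export
auto_stop <- function(K_trace, t_min = 1, delta_thresh = 1e-5,
                      mode = c("elbow", "exceed")) {
  mode <- match.arg(mode)
  if (length(K_trace) < 2) stop("K_trace must have length >= 2")
  d <- diff(K_trace)
  hit <- if (mode == "elbow") which(abs(d) < delta_thresh)
         else which(abs(d) > delta_thresh)
  tK <- if (length(hit)) hit[1] else length(K_trace) - 1L
  as.integer(max(t_min, tK))
}

#' Active-contour cMCF: mesh displacement under an external force
#'
#' Solves `(M_t - alpha_t * L_0) v(t+1) = M_t (v(t) + alpha * grad_p)` per
#' iteration. With `p` the signed distance function of a region (negative
#' inside), the mesh advances in approximately equal `alpha`-voxel steps
#' along the surface normal: positive `alpha` moves outward, negative inward,
#' while the frozen Laplacian regularises the evolving surface.
#'
#' @param mesh a `surface_mesh`.
#' @param force either a `volume_image`/array interpreted as a potential `p`
#'   whose gradient is sampled trilinearly at vertex positions, or a function
#'   `f(points) -> n x 3` returning the force vectors directly.
#' @param alpha_step signed step size in voxels per iteration.
#' @param n_iter number of iterations.
#' @param config a [flow_config()]; `delta_t` acts as the stiffness.
#' @return a `surface_mesh`.
#' @export
active_contour_cmcf <- function(mesh, force, alpha_step = 1, n_iter = 1,
                                config = flow_config(renormalize = FALSE)) {
  f <- mesh$faces
  v <- mesh$vertices
  L0 <- build_operators(mesh, config$laplacian)$L
  gradfun <- force_gradient_fun(force)
  for (t in seq_len(n_iter)) {
    m <- surface_mesh(v, f, drop_degenerate = FALSE)
    M <- build_operators(m, config$laplacian)$M
    g <- gradfun(v)
    A <- M - config$delta_t * L0
    v <- as.matrix(Matrix::solve(A, M %*% (v + alpha_step * g)))
  }
  out <- surface_mesh(v, f, drop_degenerate = FALSE)
  out$vertex_fields <- mesh$vertex_fields
  out
}

# build a function(points)->n x 3 unit-gradient sampler from a potential volume
force_gradient_fun <- function(force) {
  if (is.function(force)) return(force)
  vol <- force
  a <- vol_data(vol)
  g <- array_gradient(a)
  off <- if (inherits(vol, "volume_image")) vol$origin_offset else c(0, 0, 0)
  gx <- volume_image(g[[1]], origin_offset = off)
  gy <- volume_image(g[[2]], origin_offset = off)
  gz <- volume_image(g[[3]], origin_offset = off)
  d <- dim(a)
  function(pts) {
    pl <- sweep(as.matrix(pts), 2, off)
    oob <- pl[, 1] < 0 | pl[, 2] < 0 | pl[, 3] < 0 |
      pl[, 1] > d[1] - 1 | pl[, 2] > d[2] - 1 | pl[, 3] > d[3] - 1
    if (any(oob)) warning(sum(oob), " vertices left the force-field grid; clamped")
    gm <- cbind(sample_volume(gx, pts), sample_volume(gy, pts),
                sample_volume(gz, pts))
    nrm <- sqrt(rowSums(gm^2))
    gm / pmax(nrm, 1e-9)
  }
}

#' Topographic cMCF: flattening an open (d,u,v) sheet toward the plane
#'
#' Standard cMCF on interior vertices, while boundary vertices evolve with a
#' 1D line mass/Laplacian plus a corrective force that cancels all flux in
#' the u and v directions: the boundary keeps its (u,v) footprint exactly and
#' relaxes only in d, so the limit of the flow is the planar (u,v) rectangle
#' rather than a shrinking disk.
#'
#' Topographic meshes store coordinates as columns `(d, v, u)`.
#'
#' @param topo_mesh an open `surface_mesh` in (d,v,u) coordinates with a
#'   rectangular boundary.
#' @param config a [flow_config()] (renormalization is ignored; the sheet is
#'   not closed).
#' @return a `flow_result` (snapshots, `K_trace` = mean |d| per iteration,
#'   `stop_iteration` = last iteration).
#' @export
topographic_cmcf <- function(topo_mesh, config = flow_config(delta_t = 5e4,
                                                             max_iters = 10)) {
  f <- topo_mesh$faces
  v <- topo_mesh$vertices
  n <- nrow(v)
  bnd <- boundary_vertices(topo_mesh)
  if (!length(bnd)) stop("topographic cMCF expects an open sheet with boundary")
  # rectangular boundary check in the (v,u) plane
  uv <- v[bnd, c(2, 3), drop = FALSE]
  rng <- apply(v[, c(2, 3), drop = FALSE], 2, range)
  tol <- 1.5 * mean_edge_length(topo_mesh)
  on_edge <- (abs(uv[, 1] - rng[1, 1]) < tol) | (abs(uv[, 1] - rng[2, 1]) < tol) |
    (abs(uv[, 2] - rng[1, 2]) < tol) | (abs(uv[, 2] - rng[2, 2]) < tol)
  if (mean(on_edge) < 0.99) stop("boundary is not rectangular in (u,v)")
  L0 <- build_operators(topo_mesh, config$laplacian)$L
  # 1D boundary loop operators; bnd_ord fixes the row order of the line system
  bg <- boundary_loop_order(topo_mesh, bnd)
  bnd_ord <- unlist(bg)
  snapshots <- list(v)
  d_trace <- mean(abs(v[, 1]))
  for (t in seq_len(config$max_iters)) {
    m <- surface_mesh(v, f, drop_degenerate = FALSE)
    M <- build_operators(m, config$laplacian)$M
    lb <- line_operators(v, bg)
    A <- M - config$delta_t * L0
    # replace boundary rows with the 1D line system
    A <- replace_rows_sparse(A, bnd_ord, lb$Mb - config$delta_t * lb$Lb)
    rhs <- as.matrix(M %*% v)
    rhs[bnd_ord, ] <- as.matrix(lb$Mb %*% v[bnd_ord, , drop = FALSE])
    # corrective no-flux term in the u,v columns on the boundary
    corr <- as.matrix(-config$delta_t * (lb$Lb %*% v[bnd_ord, , drop = FALSE]))
    rhs[bnd_ord, 2:3] <- rhs[bnd_ord, 2:3] + corr[, 2:3]
    v <- as.matrix(Matrix::solve(A, rhs))
    snapshots[[t + 1]] <- v
    d_trace[t + 1] <- mean(abs(v[, 1]))
  }
  structure(list(snapshots = snapshots, K_trace = d_trace,
                 stop_iteration = length(snapshots) - 1L, faces = f,
                 broke_down = FALSE),
            class = "flow_result")
}

# order boundary vertices into a closed loop (list of index vectors per loop)
boundary_loop_order <- function(mesh, bnd = boundary_vertices(mesh)) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkeys <- names(tab)[tab == 1]
  be <- do.call(rbind, strsplit(bkeys, " "))
  be <- cbind(as.integer(be[, 1]), as.integer(be[, 2]))
  g <- igraph::graph_from_edgelist(matrix(as.character(be), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)
  loops <- lapply(seq_len(comp$no), function(ci) {
    vs <- igraph::V(g)[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, vs)
    # walk the cycle
    nm <- igraph::V(sub)$name
    adj <- igraph::as_adj_list(sub)
    ord <- integer(length(nm))
    ord[1] <- 1L
    prev <- -1L
    for (i in seq_len(length(nm) - 1)) {
      nbrs <- as.integer(adj[[ord[i]]])
      nxt <- nbrs[nbrs != prev][1]
      prev <- ord[i]
      ord[i + 1] <- nxt
    }
    as.integer(nm[ord])
  })
  loops
}

# 1D (cyclic line) mass and Laplacian over the boundary loops, indexed by the
# boundary vertex order used in the row replacement
line_operators <- function(v, loops) {
  bnd <- unlist(loops)
  nb <- length(bnd)
  pos <- match(bnd, bnd)
  ii <- jj <- ww <- c()
  mdiag <- numeric(nb)
  offset <- 0L
  for (loop in loops) {
    k <- length(loop)
    nxt <- c(2:k, 1)
    h <- sqrt(rowSums((v[loop[nxt], , drop = FALSE] - v[loop, , drop = FALSE])^2))
    h <- pmax(h, 1e-9)
    w <- 1 / h
    a <- offset + seq_len(k); b <- offset + nxt
    ii <- c(ii, a, b); jj <- c(jj, b, a); ww <- c(ww, w, w)
    mdiag[a] <- mdiag[a] + h / 2
    mdiag[b] <- mdiag[b] + h / 2
    offset <- offset + k
  }
  Lb <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nb, nb))
  Lb <- Lb - Matrix::Diagonal(nb, Matrix::rowSums(Lb))
  list(Mb = Matrix::Diagonal(nb, mdiag), Lb = Lb, bnd = bnd)
}

# overwrite rows `rows` of sparse matrix A (n x n) with the small system S
# (length(rows) x length(rows)) laid out on the same vertex indices
replace_rows_sparse <- function(A, rows, S) {
  n <- nrow(A)
  T <- as(A, "TsparseMatrix")
  keep <- !((T@i + 1L) %in% rows)
  St <- as(S, "TsparseMatrix")
  i2 <- rows[St@i + 1L]
  j2 <- rows[St@j + 1L]
  Matrix::sparseMatrix(i = c(T@i[keep] + 1L, i2),
                       j = c(T@j[keep] + 1L, j2),
                       x = c(T@x[keep], St@x), dims = c(n, n))
}
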