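#' Relaxation configuration for spherical area-distortion relaxation
#'
#' @param epsilon vertex step size (multiples of the sphere's mean edge
#'   length; the advection field is normalized so its median magnitude is one
#'   edge length).
#' @param max_iters maximum relaxation iterations.
#' @param stiffness implicit smoothing time step of the advecting
#'   active-contour flow (the field-standard regime is 0.1 with a slower
#'   5e-3 retry; smaller values advect with less smoothing).
#' @param criterion stopping criterion: `"equiareal"` (stop when the global
#'   area-distortion factor reaches 1), `"conformal_mips"` (iteration 0),
#'   `"isometric"` (minimum of `(1-theta)*Q + theta*log(lambda)`), or
#'   `"area_preserving_mips"`.
#' @param theta weight of the isometric criterion (0..1).
#' @param equi_tol tolerance on `|global lambda - 1|` for the equiareal stop.
#' @param patience iterations without improvement before stopping.
#' @param clamp cap on per-vertex displacement, in multiples of the mean edge
#'   length (the raw advection field is sharply peaked at protrusion rims;
#'   the cap keeps single steps bijective).
#' @return list of class `relax_config`.
#' @export
relax_config <- function(epsilon = 1, max_iters = 100, stiffness = 0.1,
                         criterion = c("equiareal", "conformal_mips",
                                       "isometric", "area_preserving_mips"),
                         theta = 0.5, equi_tol = 5e-3, patience = 10,
                         clamp = 3) {
  criterion <- match.arg(criterion)
  stopifnot(epsilon > 0, theta >= 0, theta <= 1)
  structure(list(epsilon = epsilon, max_iters = max_iters,
                 stiffness = stiffness, criterion = criterion, theta = theta,
                 equi_tol = equi_tol, patience = patience, clamp = clamp),
            class = "relax_config")
}

#' Quasi-conformal spherical parameterization of a closed genus-0 mesh
#'
#' Maps a closed genus-0 surface bijectively onto the unit sphere with a
#' conformal error close to 1. The map is computed by running conformalized
#' mean curvature flow to spherical convergence (the flow limit of a genus-0
#' surface is the round sphere and the flow preserves conformal structure),
#' projecting radially onto the unit sphere, and Moebius-centering so the
#' area centroid sits at the origin (which removes the conformal group's
#' translation freedom and equalises the parameterization). Any residual
#' flipped spherical triangles are repaired by local tangential smoothing.
#'
#' @param mesh a closed genus-0 `surface_mesh`.
#' @param delta_t cMCF time step used for the spherical flow (on the
#'   area-normalized mesh).
#' @param max_iters maximum cMCF iterations.
#' @param sphericity_tol stop the flow when `sd(radius)/mean(radius)` of the
#'   evolving shape falls below this.
#' @param laplacian Laplacian variant for the flow.
#' @return an object of class `sphere_param`: `sphere_vertices` (unit norm),
#'   `source` (the input mesh), `faces`, `conformal_error` (global Q of the
#'   map), `n_flipped`, `flow_iterations`.
#' @export
conformal_sphere_map <- function(mesh, delta_t = 5e-3, max_iters = 200,
                                 sphericity_tol = 2e-3,
                                 laplacian = "cotangent") {
  topo <- euler_genus(mesh)
  if (!topo$watertight || topo$genus != 0)
    stop("spherical parameterization requires genus-0 (got genus ",
         topo$genus, ", ", topo$n_boundaries, " boundaries)")
  f <- mesh$faces
  v <- normalize_mesh_vertices(mesh$vertices, f)
  L0 <- build_operators(surface_mesh(v, f, drop_degenerate = FALSE), laplacian)$L
  it <- 0L
  for (t in seq_len(max_iters)) {
    m <- surface_mesh(v, f, drop_degenerate = FALSE)
    M <- build_operators(m, laplacian)$M
    vnew <- tryCatch(
      as.matrix(Matrix::solve(M - delta_t * L0, M %*% v)),
      error = function(e) NULL)
    if (is.null(vnew) || anyNA(vnew)) break
    v <- normalize_mesh_vertices(vnew, f)
    it <- t
    r <- sqrt(rowSums(v^2))
    if (sd(r) / mean(r) < sphericity_tol) break
  }
  # radial projection + Moebius centering
  s <- v / sqrt(rowSums(v^2))
  s <- mobius_center(s, f)
  s <- repair_flipped(s, f)
  param <- structure(list(sphere_vertices = s, source = mesh, faces = f,
                          flow_iterations = it,
                          relax_trace = NULL),
                     class = "sphere_param")
  param$n_flipped <- count_flipped(param)
  param$conformal_error <- face_conformal_error(mesh, sphere_mesh(param))$global
  param
}

#' The spherical mesh of a parameterization
#'
#' @param param a `sphere_param`.
#' @return a `surface_mesh` on the unit sphere sharing the source topology.
#' @export
sphere_mesh <- function(param) {
  surface_mesh(param$sphere_vertices, param$faces, drop_degenerate = FALSE)
}

#' @export
print.sphere_param <- function(x, ...) {
  cat(sprintf("sphere_param: %d vertices | global Q %.4f | %d flipped faces\n",
              nrow(x$sphere_vertices), x$conformal_error, x$n_flipped))
  invisible(x)
}

# number of spherical faces whose orientation disagrees with outward
count_flipped <- function(param) {
  s <- param$sphere_vertices; f <- param$faces
  a <- s[f[, 1], , drop = FALSE]; b <- s[f[, 2], , drop = FALSE]
  cc <- s[f[, 3], , drop = FALSE]
  trip <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
    a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(trip <= 0)
}

# Moebius normalization: move the area centroid of the spherical mesh to the
# origin by repeated (damped) sphere inversions
mobius_center <- function(s, f, max_iters = 100, tol = 1e-6) {
  for (t in seq_len(max_iters)) {
    m <- surface_mesh(s, f, drop_degenerate = FALSE)
    a <- face_areas(m)
    bc <- (s[f[, 1], , drop = FALSE] + s[f[, 2], , drop = FALSE] +
           s[f[, 3], , drop = FALSE]) / 3
    c0 <- colSums(bc * a) / sum(a)
    if (sqrt(sum(c0^2)) < tol) break
    c0 <- -0.5 * c0   # damped inversion center
    nc2 <- sum(c0^2)
    vp <- sweep(s, 2, -c0)       # s + c0
    denom <- rowSums(vp^2)
    s <- (1 - nc2) * vp / denom
    s <- sweep(s, 2, -c0)
    s <- s / sqrt(rowSums(s^2))
  }
  s
}

# local tangential smoothing of vertices touching flipped spherical faces
repair_flipped <- function(s, f, max_passes = 50) {
  adj <- NULL
  for (p in seq_len(max_passes)) {
    a <- s[f[, 1], , drop = FALSE]; b <- s[f[, 2], , drop = FALSE]
    cc <- s[f[, 3], , drop = FALSE]
    trip <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    bad <- which(trip <= 0)
    if (!length(bad)) break
    if (is.null(adj)) {
      e <- mesh_edges(surface_mesh(s, f, drop_degenerate = FALSE))
      adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                                  x = 1, dims = c(nrow(s), nrow(s)))
    }
    vb <- unique(as.vector(f[bad, ]))
    nb <- as.matrix(adj[vb, , drop = FALSE] %*% s)
    deg <- Matrix::rowSums(adj[vb, , drop = FALSE])
    s[vb, ] <- 0.5 * s[vb, , drop = FALSE] + 0.5 * nb / deg
    s <- s / sqrt(rowSums(s^2))
  }
  s
}

#' Bijective area-distortion relaxation on the sphere
#'
#' Iteratively advects the spherical vertices so the per-face area-distortion
#' factor `lambda = (normalized source face area) / (normalized sphere face
#' area)` diffuses toward 1, while face connectivity and the spherical shape
#' are preserved. Each iteration: (1) normalize face areas to fractions;
#' (2) per-face `lambda`; (3) advection field `V = -grad(log lambda)` from
#' the mesh gradient operator; (4) rescale `V` so its median norm equals the
#' mean edge length; (5) average `lambda`, `V` onto vertices;
#' (6) project `V` into the tangent plane; (7) advect one active-contour cMCF
#' step of size `epsilon`; (8) re-center and renormalize onto the unit
#' sphere. The run stops at the configured criterion, when progress stalls,
#' or when a face collapses (interior angle reaching 0), in which case the
#' last valid iterate is returned with `collapsed = TRUE`.
#'
#' The full trajectory of (Q, lambda, MIPS, area-preserving MIPS, isometric)
#' is cached in `relax_trace`, so any of the four stopping points can be
#' extracted after the fact without re-running.
#'
#' @param param a `sphere_param` from [conformal_sphere_map()].
#' @param config a [relax_config()].
#' @return the updated `sphere_param` with `relax_trace`, `stop_iteration`,
#'   `area_distortion` (global lambda at the returned iterate), `collapsed`.
#' @export
relax_area_distortion <- function(param, config = relax_config()) {
  src <- param$source
  f <- param$faces
  s <- param$sphere_vertices
  aref <- face_areas(src)
  aref <- aref / sum(aref)
  trace <- list()
  snapshots <- list(s)
  collapsed <- FALSE
  for (t in seq_len(config$max_iters)) {
    sm <- surface_mesh(s, f, drop_degenerate = FALSE)
    asph <- face_areas(sm)
    asph_frac <- asph / sum(asph)
    lam_f <- aref / pmax(asph_frac, 1e-300)
    lam_v <- face_to_vertex(sm, log(lam_f), weights = asph)
    Vf <- -mesh_gradient(sm, lam_v)
    nrm <- sqrt(rowSums(Vf^2))
    lbar <- mean_edge_length(sm)
    med <- median(nrm)
    if (med < 1e-14) break
    Vf <- Vf * (lbar / med)
    Vv <- face_to_vertex(sm, Vf, weights = asph)
    # tangential projection: on the unit sphere the vertex normal is the position
    Vt <- Vv - rowSums(Vv * s) * s
    # cap the spiky rim displacements so a single step cannot fold faces
    vn <- sqrt(rowSums(Vt^2))
    Vt <- Vt * pmin(1, config$clamp * lbar / pmax(vn, 1e-300))
    ops <- build_operators(sm)
    A <- ops$M - config$stiffness * ops$L
    # backtracking on the step size: accept the first bijective candidate
    eps <- config$epsilon
    snew <- NULL
    repeat {
      cand_v <- tryCatch(
        as.matrix(Matrix::solve(A, ops$M %*% (s + eps * Vt))),
        error = function(e) NULL)
      if (!is.null(cand_v) && !anyNA(cand_v)) {
        cand_v <- sweep(cand_v, 2, colMeans(cand_v))
        cand_v <- cand_v / sqrt(rowSums(cand_v^2))
        cand <- structure(list(sphere_vertices = cand_v, faces = f),
                          class = "sphere_param")
        if (count_flipped(cand) == 0 && min_face_angle(cand_v, f) > 1e-6) {
          snew <- cand_v
          break
        }
      }
      eps <- eps / 2
      if (eps < config$epsilon / 16) break
    }
    if (is.null(snew)) { collapsed <- TRUE; break }
    s <- snew
    snapshots[[t + 1]] <- s
    met <- relax_metrics(src, s, f, config$theta)
    trace[[t]] <- met
    if (stop_reached(trace, config)) break
  }
  tr <- if (length(trace)) do.call(rbind, lapply(seq_along(trace), function(i)
    cbind(iteration = i, as.data.frame(trace[[i]])))) else NULL
  stop_it <- select_stop_iteration(tr, config)
  param$sphere_vertices <- snapshots[[stop_it + 1L]]
  param$relax_trace <- tr
  param$stop_iteration <- stop_it
  param$snapshots <- snapshots
  param$collapsed <- collapsed
  param$n_flipped <- count_flipped(param)
  param$conformal_error <- face_conformal_error(src, sphere_mesh(param))$global
  param$area_distortion <- face_area_distortion(src, sphere_mesh(param))$global
  param
}

min_face_angle <- function(v, f) {
  m <- surface_mesh(v, f, drop_degenerate = FALSE)
  a <- sqrt(rowSums((v[f[, 2], ] - v[f[, 3], ])^2))
  b <- sqrt(rowSums((v[f[, 1], ] - v[f[, 3], ])^2))
  cc <- sqrt(rowSums((v[f[, 1], ] - v[f[, 2], ])^2))
  ar <- face_areas(m)
  # smallest angle via sin rule: angle_i >= 2*area/(b*c)
  min(2 * ar / pmax(a * b, 1e-300), 2 * ar / pmax(b * cc, 1e-300),
      2 * ar / pmax(a * cc, 1e-300))
}

relax_metrics <- function(src, s, f, theta = 0.5) {
  sm <- surface_mesh(s, f, drop_degenerate = FALSE)
  ce <- face_conformal_error(src, sm)
  ad <- face_area_distortion(src, sm)
  mips_f <- ce$sigma2 / ce$sigma1 + ce$sigma1 / ce$sigma2
  p <- ce$sigma1 * ce$sigma2
  ap_f <- mips_f * (p + 1 / p)      # theta = 1 exponent
  a <- face_areas(src)
  ok <- is.finite(mips_f)
  list(Q = ce$global, lambda = ad$global,
       equiareal_obj = abs(ad$global - 1),
       mips = sum((mips_f * a)[ok]) / sum(a[ok]),
       area_preserving_mips = sum((ap_f * a)[ok]) / sum(a[ok]),
       isometric = (1 - theta) * ce$global + theta * log(ad$global))
}

stop_reached <- function(trace, config) {
  t <- length(trace)
  if (config$criterion == "conformal_mips") return(TRUE) # iteration 0 optimum
  if (config$criterion != "equiareal") return(FALSE)     # post-hoc selection
  if (trace[[t]]$equiareal_obj < config$equi_tol) return(TRUE)
  obj <- vapply(trace, function(m) m$equiareal_obj, 0)
  # stall detection: no improvement over the last `patience` iterations
  t > config$patience &&
    min(obj[(t - config$patience + 1):t]) >= min(obj[1:(t - config$patience)])
}

select_stop_iteration <- function(tr, config) {
  if (is.null(tr) || nrow(tr) == 0) return(0L)
  switch(config$criterion,
    equiareal = {
      i <- which(tr$equiareal_obj < config$equi_tol)
      if (length(i)) i[1] else which.min(tr$equiareal_obj)
    },
    conformal_mips = 0L,
    isometric = which.min(tr$isometric),
    area_preserving_mips = which.min(tr$area_preserving_mips))
}

#' Evaluate the four relaxation stopping objectives for a parameterization
#'
#' MIPS is `sigma2/sigma1 + sigma1/sigma2` (analytic minimum 2, reached by
#' conformal maps); the area-preserving MIPS multiplies it by
#' `(sigma1 sigma2 + 1/(sigma1 sigma2))^theta` with `theta = 1`; the
#' isometric objective is `(1 - theta) * Q + theta * log(lambda)` with
#' `theta = 0.5` by default; the equiareal objective is `|lambda - 1|`.
#'
#' @param param a `sphere_param`.
#' @param theta isometric weight.
#' @return named list of the four global objectives plus `Q` and `lambda`.
#' @export
evaluate_stopping_criteria <- function(param, theta = 0.5) {
  met <- relax_metrics(param$source, param$sphere_vertices, param$faces, theta)
  met[c("equiareal_obj", "mips", "area_preserving_mips", "isometric",
        "Q", "lambda")]
}
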