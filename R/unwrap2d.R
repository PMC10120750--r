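#' Optimal unwrapping axis by weighted PCA
#'
#' Finds the north-south axis that places high-weight surface regions away
#' from the poles of the equirectangular chart (where area distortion is
#' largest). The weighted second-moment matrix
#' `A = sum_i w_i (v_i - vbar_w)(v_i - vbar_w)^T` of the spherical vertex
#' coordinates is eigen-decomposed; the eigenvector of the smallest
#' eigenvalue becomes the pole axis, and sign fixes (first two eigenvectors
#' flipped to positive x/y components, third = cross product) make the frame
#' a proper rotation.
#'
#' @param param a `sphere_param` (or a `surface_mesh` on the unit sphere).
#' @param weights per-vertex non-negative weights (e.g. `|H|` of the
#'   reference surface); uniform by default.
#' @return list of class `rotation_frame` with `R` (3 x 3, det +1; columns =
#'   e1, e2, pole axis e3) and `eigenvalues`.
#' @export
optimal_axis <- function(param, weights = NULL) {
  v <- if (inherits(param, "sphere_param")) param$sphere_vertices
       else param$vertices
  n <- nrow(v)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  ctr <- colSums(v * w)
  vc <- sweep(v, 2, ctr)
  A <- crossprod(vc * sqrt(w))
  eig <- eigen(A, symmetric = TRUE)
  lam <- eig$values
  if (lam[3] < 1e-12 * lam[1] ||
      (lam[1] - lam[3]) < 1e-6 * max(lam[1], 1e-300)) {
    warning("degenerate weighted covariance; falling back to identity rotation")
    return(structure(list(R = diag(3), eigenvalues = lam),
                     class = "rotation_frame"))
  }
  e1 <- eig$vectors[, 1]; e2 <- eig$vectors[, 2]
  if (e1[1] < 0) e1 <- -e1
  if (e2[2] < 0) e2 <- -e2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- cbind(e1, e2, e3)
  structure(list(R = R, eigenvalues = lam), class = "rotation_frame")
}

#' Equirectangular UV mapping of a spherical parameterization
#'
#' Builds an `N x 2N` (or `N x (2N+1)` with a duplicated seam column) pixel
#' grid: the column coordinate u samples the equatorial circumference
#' (length 2*pi), the row coordinate v the pole-to-pole arc (length pi), so
#' the 1:2 aspect preserves the circumference-to-arc ratio. Each pixel's
#' unit direction (rotated by the chosen frame; v = 0 faces the +e3 pole,
#' u = 0 the +e1 azimuth) is matched to a spherical triangle and its
#' barycentric weights stored, through which any bijective partner mesh and
#' any per-vertex field can be looked up.
#'
#' @param param a `sphere_param`.
#' @param N number of rows (>= 32).
#' @param rotation a `rotation_frame` from [optimal_axis()] (identity if
#'   omitted).
#' @param partner mesh whose vertex coordinates fill `xyz_lookup` (defaults
#'   to the parameterization's source mesh).
#' @param seam_duplicate use 2N+1 columns with identical first/last column
#'   (for grids that will be triangulated and stitched).
#' @return object of class `uv_grid`: `xyz_lookup` (N x cols x 3), `bary`
#'   (list `face`, `mu`), `rotation`, `n_fallback` (pixels with no containing
#'   face, matched to the nearest face).
#' @export
uv_map <- function(param, N = 256, rotation = NULL, partner = param$source,
                   seam_duplicate = FALSE) {
  stopifnot(N >= 32)
  if (is.null(rotation)) rotation <- structure(list(R = diag(3)),
                                               class = "rotation_frame")
  cols <- if (seam_duplicate) 2L * N + 1L else 2L * N
  theta <- (seq_len(N) - 0.5) / N * pi                   # polar from +e3
  phi <- if (seam_duplicate) (seq_len(cols) - 1) / (cols - 1) * 2 * pi
         else (seq_len(cols) - 0.5) / cols * 2 * pi
  st <- sin(theta); ct <- cos(theta)
  dir_local <- cbind(as.vector(outer(st, cos(phi))),
                     as.vector(outer(st, sin(phi))),
                     rep(ct, length(phi)))
  dirs <- dir_local %*% t(rotation$R)
  bl <- sphere_bary_lookup(param, dirs)
  f <- param$faces
  xyz <- vapply(1:3, function(d) {
    vals <- partner$vertices[, d]
    rowSums(cbind(vals[f[bl$face, 1]], vals[f[bl$face, 2]],
                  vals[f[bl$face, 3]]) * bl$mu)
  }, numeric(nrow(dirs)))
  structure(list(xyz_lookup = array(xyz, c(N, cols, 3)),
                 bary = list(face = matrix(bl$face, N, cols),
                             mu = array(bl$mu, c(N, cols, 3))),
                 face_topology = f,
                 rotation = rotation, N = N, cols = cols,
                 seam_duplicate = seam_duplicate,
                 n_fallback = sum(bl$fallback),
                 param_vertex_count = nrow(param$sphere_vertices)),
            class = "uv_grid")
}

#' @export
print.uv_grid <- function(x, ...) {
  cat(sprintf("uv_grid: %d x %d | %d nearest-face fallbacks\n",
              x$N, x$cols, x$n_fallback))
  invisible(x)
}

# match arbitrary unit directions to spherical faces of a parameterization
sphere_bary_lookup <- function(param, dirs) {
  s <- param$sphere_vertices
  f <- param$faces
  nn <- .cpp_nn_index(dirs, s)$index
  cand <- vertex_face_ring(f, nrow(s))
  bl <- .cpp_sphere_bary(dirs, nn, s, f, cand$ptr, cand$idx)
  # degenerate (near-zero-area) candidate triangles can leave a pixel
  # unmatched: collapse it onto its nearest vertex
  miss <- which(is.na(bl$face))
  if (length(miss)) {
    vface <- integer(nrow(s))
    vface[f[, 3]] <- seq_len(nrow(f))
    vface[f[, 2]] <- seq_len(nrow(f))
    vface[f[, 1]] <- seq_len(nrow(f))
    for (q in miss) {
      vtx <- nn[q]
      fi <- vface[vtx]
      bl$face[q] <- fi
      bl$mu[q, ] <- as.numeric(f[fi, ] == vtx)
      bl$fallback[q] <- 1L
    }
  }
  bl
}

# CSR candidate face lists: all faces within the 2-ring of each vertex
vertex_face_ring <- function(f, nv) {
  # vertex -> incident faces
  vi <- c(f[, 1], f[, 2], f[, 3])
  fi <- rep(seq_len(nrow(f)), 3)
  ord <- order(vi)
  vi <- vi[ord]; fi <- fi[ord]
  # build 2-ring face sets: faces incident to any vertex of any incident face
  idx <- vector("list", nv)
  inc_full <- split(fi, factor(vi, levels = seq_len(nv)))
  for (v in seq_len(nv)) {
    f1 <- inc_full[[v]]
    if (!length(f1)) { idx[[v]] <- integer(0); next }
    vs <- unique(as.vector(f[f1, , drop = FALSE]))
    idx[[v]] <- unique(unlist(inc_full[vs]))
  }
  lens <- lengths(idx)
  list(ptr = c(0L, cumsum(lens)), idx = as.integer(unlist(idx)))
}

#' Pull a per-vertex field (or partner mesh) back onto a UV grid
#'
#' Uses the grid's stored barycentric correspondence, so a pixel marked on
#' the UV image maps back to a unique surface point and vice versa.
#'
#' @param uv_grid a `uv_grid`.
#' @param partner per-vertex numeric vector, or a `surface_mesh` in vertex
#'   correspondence with the parameterization (returns a 3-channel lookup).
#' @return N x cols matrix (or N x cols x 3 array for a mesh).
#' @export
pullback_field <- function(uv_grid, partner) {
  fidx <- uv_grid$bary$face
  mu <- uv_grid$bary$mu
  if (inherits(partner, "surface_mesh")) {
    if (nrow(partner$vertices) != uv_grid$param_vertex_count)
      stop("partner vertex count does not match the parameterization")
    out <- vapply(1:3, function(d)
      pullback_field(uv_grid, partner$vertices[, d]), matrix(0, uv_grid$N,
                                                             uv_grid$cols))
    return(array(out, c(uv_grid$N, uv_grid$cols, 3)))
  }
  if (length(partner) != uv_grid$param_vertex_count)
    stop("field length does not match the parameterization vertex count")
  ft <- uv_grid$face_topology
  vals <- matrix(0, uv_grid$N, uv_grid$cols)
  idx <- as.vector(fidx)
  vals[] <- partner[ft[idx, 1]] * as.vector(mu[, , 1]) +
    partner[ft[idx, 2]] * as.vector(mu[, , 2]) +
    partner[ft[idx, 3]] * as.vector(mu[, , 3])
  vals
}

#' UV pixel coordinates of unit directions
#'
#' Inverse of the pixel-to-direction mapping of [uv_map()]: returns
#' fractional (row, col) positions of 3D directions on the same grid, used
#' for round-trip checks and for projecting point tracks into the chart.
#'
#' @param dirs n x 3 matrix of directions (normalized internally).
#' @param uv_grid a `uv_grid`.
#' @return n x 2 matrix (row, col), 1-based fractional pixel coordinates.
#' @export
uv_coords_of_directions <- function(dirs, uv_grid) {
  d <- as.matrix(dirs)
  d <- d / sqrt(rowSums(d^2))
  dl <- d %*% uv_grid$rotation$R    # back to local frame
  theta <- acos(pmax(pmin(dl[, 3], 1), -1))
  phi <- atan2(dl[, 2], dl[, 1]) %% (2 * pi)
  row <- theta / pi * uv_grid$N + 0.5
  col <- if (uv_grid$seam_duplicate) phi / (2 * pi) * (uv_grid$cols - 1) + 1
         else phi / (2 * pi) * uv_grid$cols + 0.5
  cbind(row = row, col = col)
}
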