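#' Topographic (d,u,v) coordinate space
#'
#' Builds the curvilinear volume normal to a (u,v)-parameterized reference
#' surface: the reference sheet (the UV lookup of Sref) is propagated in
#' Cartesian space in equidistant steps of `alpha` voxels along the steepest
#' gradient of the signed distance function of the voxelized reference,
#' outward for `D_out` steps (auto-chosen so the space encapsulates the cell
#' surface) and inward for `D_in` steps, with per-iteration 2D smoothing of
#' each propagated sheet to maintain bijectivity. The result is a
#' `(D_in + D_out + 1) x rows x cols` lookup table of Cartesian coordinates
#' establishing the bijection `(d,u,v) <-> (x,y,z)`; slice `d_zero_index`
#' equals the input UV lookup bit-identically.
#'
#' @param ref_uv_grid a `uv_grid` whose `xyz_lookup` samples the reference
#'   surface (partner = reference mesh).
#' @param cell_binary binary `volume_image` of the full cell (used to choose
#'   `D_out` and as the propagation frame).
#' @param alpha step size in voxels (default 0.5).
#' @param D_in inward steps (default: half the maximum internal depth of the
#'   reference, in alpha-steps).
#' @param D_out outward steps (default: auto so that
#'   `D_out * alpha >= max surface distance + 2`).
#' @param smooth_window box-filter window (pixels) applied to each
#'   propagated sheet (5 = default; 0 disables).
#' @param closing_radius morphological closing radius for voxelizing the
#'   reference sheet (in upsampled voxels).
#' @param upsample integer factor by which the reference signed-distance
#'   grid is upsampled so that one UV pixel spans less than one grid voxel;
#'   reduces staircase noise in the propagated sheets.
#' @return object of class `topographic_space`.
#' @export
build_topographic_space <- function(ref_uv_grid, cell_binary, alpha = 0.5,
                                    D_in = NULL, D_out = NULL,
                                    smooth_window = 5, closing_radius = 2,
                                    upsample = 2) {
  look0 <- ref_uv_grid$xyz_lookup
  nr <- dim(look0)[1]; nc <- dim(look0)[2]
  pts0 <- matrix(look0, ncol = 3)
  # voxelize the reference sheet on a padded, upsampled copy of the cell frame
  cb <- vol_data(cell_binary)
  off <- cell_binary$origin_offset
  pad <- 8L
  s <- max(1L, as.integer(upsample))
  dims <- (dim(cb) + 2L * pad) * s
  offp <- off - pad
  refb <- array(0, dims)
  idx <- round(sweep(pts0, 2, offp) * s) + 1
  ok <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= dims[1] & idx[, 2] <= dims[2] & idx[, 3] <= dims[3]
  refb[idx[ok, , drop = FALSE]] <- 1
  refb <- binary_dilate(refb, closing_radius)
  refb <- binary_fill_holes(refb)
  refb <- binary_erode(refb, closing_radius) * 1
  phi <- signed_distance(refb) / s      # distances in original voxel units
  g <- array_gradient(gaussian_smooth_3d(phi, 1))
  # upsampled working grids: index = (coord - offp) * s
  scale_vol <- function(a) {
    v <- volume_image(a, origin_offset = offp)
    attr(v, "grid_scale") <- s
    v
  }
  gvols <- lapply(g, scale_vol)
  phivol <- scale_vol(phi)
  unit_step <- function(P) {
    gm <- cbind(sample_volume(gvols[[1]], P), sample_volume(gvols[[2]], P),
                sample_volume(gvols[[3]], P))
    gm / pmax(sqrt(rowSums(gm^2)), 1e-9)
  }
  # choose D_out to encapsulate the cell: largest signed distance of any cell
  # voxel above the reference surface
  cellpts <- which(cb != 0, arr.ind = TRUE) - 1
  cellpts <- sweep(cellpts, 2, -off)
  if (is.null(D_out)) {
    surf <- cb != 0 & !binary_erode(cb, 1.5)
    sp <- which(surf, arr.ind = TRUE) - 1
    sp <- sweep(sp, 2, -off)
    dmax <- max(sample_volume(phivol, sp), 0)
    D_out <- as.integer(ceiling((dmax + 2) / alpha))
  }
  if (is.null(D_in)) {
    din_max <- max(distance_transform(1 - refb)) / s
    D_in <- as.integer(ceiling(0.5 * din_max / alpha))
  }
  D <- D_in + D_out + 1L
  lookup <- array(NA_real_, c(D, nr, nc, 3))
  lookup[D_in + 1L, , , ] <- look0
  # box filtering acts tangentially only: the normal component of the
  # smoothing displacement is removed so curved sheets are not eroded
  smooth_tangential <- function(P) {
    Ps <- smooth_sheet(P, nr, nc, smooth_window)
    n <- unit_step(P)
    disp <- Ps - P
    Ps - rowSums(disp * n) * n
  }
  P <- pts0
  for (d in seq_len(D_out)) {
    P <- P + alpha * unit_step(P)
    P <- smooth_tangential(P)
    lookup[D_in + 1L + d, , , ] <- array(P, c(nr, nc, 3))
  }
  P <- pts0
  for (d in seq_len(D_in)) {
    P <- P - alpha * unit_step(P)
    P <- smooth_tangential(P)
    lookup[D_in + 1L - d, , , ] <- array(P, c(nr, nc, 3))
  }
  # d-monotonicity audit: signed distance along each trajectory must increase
  phis <- apply(lookup, 1, function(sl) sample_volume(phivol, matrix(sl, ncol = 3)))
  nonmono <- sum(apply(phis, 1, function(tr) any(diff(tr) <= 1e-3)))
  structure(list(lookup = lookup, alpha = alpha, D_in = D_in, D_out = D_out,
                 d_zero_index = D_in + 1L, rows = nr, cols = nc,
                 n_nonmonotone = nonmono, phi = phivol),
            class = "topographic_space")
}

#' @export
print.topographic_space <- function(x, ...) {
  cat(sprintf("topographic_space: %d x %d x %d (alpha %.2f, D_in %d, D_out %d)\n",
              dim(x$lookup)[1], x$rows, x$cols, x$alpha, x$D_in, x$D_out))
  invisible(x)
}

# separable box smoothing of a sheet of 3D points stored as (rows*cols) x 3;
# periodic across the u (column) seam, clamped at the pole rows
smooth_sheet <- function(P, nr, nc, window) {
  if (window <= 1) return(P)
  r <- floor(window / 2)
  for (ch in 1:3) {
    img <- matrix(P[, ch], nr, nc)
    acc <- matrix(0, nr, nc)
    for (o in -r:r) acc <- acc + img[, ((seq_len(nc) - 1 + o) %% nc) + 1]
    img <- acc / (2 * r + 1)
    acc <- matrix(0, nr, nc)
    for (o in -r:r) acc <- acc + img[pmin(pmax(seq_len(nr) + o, 1), nr), ]
    P[, ch] <- acc / (2 * r + 1)
  }
  P
}

#' Resample a Cartesian volume into topographic coordinates
#'
#' Trilinear interpolation of the volume at the Cartesian coordinates
#' indexed by the topographic lookup.
#'
#' @param topo_space a `topographic_space`.
#' @param volume a `volume_image` (or 3D array in the same frame).
#' @return 3D array with dimensions (d, v, u); out-of-grid samples are 0 and
#'   counted in attribute `"n_outside"`.
#' @export
resample_volume <- function(topo_space, volume) {
  dm <- dim(topo_space$lookup)
  pts <- matrix(topo_space$lookup, ncol = 3)
  vals <- sample_volume(volume, pts, fill = 0)
  out <- array(vals, dm[1:3])
  attr(out, "n_outside") <- attr(vals, "n_outside")
  out
}

#' Topographic surface mesh from a topographic binary
#'
#' Marching cubes at isovalue 0.5 (after Gaussian sigma = 1 smoothing)
#' followed by isotropic clustering remeshing (largest component kept). The
#' mesh lives in (d, v, u) grid coordinates with `d` expressed in
#' alpha-steps relative to the reference slice; the Cartesian twin is
#' obtained by interpolating the lookup table at the vertex coordinates.
#'
#' @param topo_binary (d, v, u) binary array from [resample_volume()].
#' @param topo_space the `topographic_space` that produced it.
#' @param target_fraction remesh fraction of the marching-cubes vertex count.
#' @return list of class `topographic_mesh`: `mesh` (in (d,v,u), column 1 =
#'   d in alpha-steps relative to the reference), `cartesian_twin`
#'   (a `surface_mesh` in (x,y,z)).
#' @export
topographic_mesh <- function(topo_binary, topo_space, target_fraction = 0.5) {
  if (sum(topo_binary != 0) == 0) stop("empty topographic binary")
  mc <- marching_cubes(topo_binary, iso = 0.5, smooth_sigma = 1)
  n_target <- max(100, round(target_fraction * nrow(mc$vertices)))
  m <- if (n_target < nrow(mc$vertices) - 1) acvd_remesh(mc, n_target) else mc
  twin_v <- lookup_interp(topo_space, m$vertices)
  mesh <- m
  mesh$vertices[, 1] <- mesh$vertices[, 1] - (topo_space$d_zero_index - 1)
  structure(list(mesh = mesh,
                 cartesian_twin = surface_mesh(twin_v, m$faces,
                                               drop_degenerate = FALSE),
                 d_zero_index = topo_space$d_zero_index,
                 alpha = topo_space$alpha),
            class = "topographic_mesh")
}

# trilinear interpolation of the 4D lookup at (d,v,u) grid coordinates
# (0-based, d absolute in the lookup array)
lookup_interp <- function(space, pts_grid) {
  dm <- dim(space$lookup)
  pts <- as.matrix(pts_grid)
  # tolerate floating-point overshoot at the grid boundary
  eps <- 1e-6
  for (ax in 1:3) {
    ok <- !is.na(pts[, ax])
    near_hi <- ok & pts[, ax] > dm[ax] - 1 & pts[, ax] < dm[ax] - 1 + eps
    near_lo <- ok & pts[, ax] < 0 & pts[, ax] > -eps
    pts[near_hi, ax] <- dm[ax] - 1
    pts[near_lo, ax] <- 0
  }
  out <- matrix(0, nrow(pts), 3)
  for (ch in 1:3) {
    out[, ch] <- .cpp_trilinear(as.numeric(space$lookup[, , , ch]), dm[1:3],
                                pts, NA_real_)
  }
  out
}

#' Convert between topographic and Cartesian coordinates
#'
#' The forward direction interpolates the lookup table; the inverse searches
#' the nearest lookup node and refines to sub-voxel accuracy by local
#' Gauss-Newton iterations on the trilinear interpolant. Points outside the
#' space extent are flagged (`NA` rows plus the `"outside"` attribute), not
#' silently clamped.
#'
#' @param points_duv n x 3 matrix of (d, v, u): d in alpha-steps relative to
#'   the reference slice, v/u 0-based pixel coordinates.
#' @param topo_space a `topographic_space`.
#' @return n x 3 coordinate matrix.
#' @export
topo_to_cartesian <- function(points_duv, topo_space) {
  p <- as.matrix(points_duv)
  p[, 1] <- p[, 1] + (topo_space$d_zero_index - 1)
  out <- lookup_interp(topo_space, p)
  outside <- rowSums(is.na(out)) > 0
  attr(out, "outside") <- which(outside)
  out
}

#' @rdname topo_to_cartesian
#' @param points_xyz n x 3 Cartesian coordinates.
#' @export
cartesian_to_topo <- function(points_xyz, topo_space) {
  dm <- dim(topo_space$lookup)
  nodes <- matrix(topo_space$lookup, ncol = 3)
  p <- as.matrix(points_xyz)
  nn <- .cpp_nn_index(p, nodes)
  id <- nn$index - 1L
  d0 <- id %% dm[1]
  v0 <- (id %/% dm[1]) %% dm[2]
  u0 <- id %/% (dm[1] * dm[2])
  guess <- cbind(d0, v0, u0)
  # Gauss-Newton refinement on the trilinear interpolant
  for (it in 1:4) {
    X <- lookup_interp(topo_space, guess)
    resid <- p - X
    h <- 0.5
    for (ax in 1:3) {
      gp <- guess; gp[, ax] <- pmin(gp[, ax] + h, dm[ax] - 1)
      gm <- guess; gm[, ax] <- pmax(gm[, ax] - h, 0)
      Jax <- (lookup_interp(topo_space, gp) - lookup_interp(topo_space, gm)) /
        (gp[, ax] - gm[, ax] + 1e-12)
      if (ax == 1) J1 <- Jax else if (ax == 2) J2 <- Jax else J3 <- Jax
    }
    # solve 3x3 per point via Cramer
    delta <- solve_3x3_rows(J1, J2, J3, resid)
    delta[!is.finite(delta)] <- 0
    delta <- pmin(pmax(delta, -2), 2)
    guess <- guess + delta
    guess[, 1] <- pmin(pmax(guess[, 1], 0), dm[1] - 1)
    guess[, 2] <- pmin(pmax(guess[, 2], 0), dm[2] - 1)
    guess[, 3] <- pmin(pmax(guess[, 3], 0), dm[3] - 1)
  }
  X <- lookup_interp(topo_space, guess)
  resid2 <- sqrt(rowSums((p - X)^2))
  outside <- resid2 > 2 | nn$distance > 4 * max(topo_space$alpha, 1)
  guess[, 1] <- guess[, 1] - (topo_space$d_zero_index - 1)
  attr(guess, "outside") <- which(outside)
  attr(guess, "residual") <- resid2
  guess
}

# per-row 3x3 linear solves: columns J1,J2,J3 are the Jacobian columns
solve_3x3_rows <- function(J1, J2, J3, b) {
  det <- J1[, 1] * (J2[, 2] * J3[, 3] - J2[, 3] * J3[, 2]) -
    J2[, 1] * (J1[, 2] * J3[, 3] - J1[, 3] * J3[, 2]) +
    J3[, 1] * (J1[, 2] * J2[, 3] - J1[, 3] * J2[, 2])
  rep_col <- function(Ja, Jb, Jc) {
    Ja[, 1] * (Jb[, 2] * Jc[, 3] - Jb[, 3] * Jc[, 2]) -
      Jb[, 1] * (Ja[, 2] * Jc[, 3] - Ja[, 3] * Jc[, 2]) +
      Jc[, 1] * (Ja[, 2] * Jb[, 3] - Ja[, 3] * Jb[, 2])
  }
  cbind(rep_col(b, J2, J3) / det, rep_col(J1, b, J3) / det,
        rep_col(J1, J2, b) / det)
}
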