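#' Per-face mapping distortion between two meshes with shared topology
#'
#' Each triangle pair is isometrically embedded in 2D and the affine 2x2
#' transform `J` between the embeddings is recovered; the singular values
#' `sigma1 <= sigma2` of `J` quantify the local stretch. The conformal error
#' per face is `Q = sigma2/sigma1` (1 = angle-preserving) and the global
#' error is the source-area-weighted mean. The area distortion per face is
#' the ratio of normalized area fractions
#' `lambda = (a_A/sum(a_A)) / (a_B/sum(a_B))` (1 = area-fraction-preserving);
#' the global value is the plain mean. Both conventions of the area factor
#' are exposed: `area_distortion_lambda` (source over target, the relaxation
#' convention) and `area_fraction_ratio` (its reciprocal, the convention of
#' per-motif summary tables).
#'
#' @param mesh_A source `surface_mesh`.
#' @param mesh_B target `surface_mesh` (same faces).
#' @return `face_conformal_error`: list with `per_face` Q, `global` (weighted
#'   mean), `sigma1`, `sigma2`, `skipped` (degenerate faces).
#' @export
face_conformal_error <- function(mesh_A, mesh_B) {
  sv <- mapping_singular_values(mesh_A, mesh_B)
  Q <- sv$sigma2 / sv$sigma1
  a <- face_areas(mesh_A)
  ok <- is.finite(Q) & a > 1e-12
  list(per_face = Q,
       global = sum((Q * a)[ok]) / sum(a[ok]),
       sigma1 = sv$sigma1, sigma2 = sv$sigma2,
       skipped = sum(!ok))
}

#' @rdname face_conformal_error
#' @export
face_area_distortion <- function(mesh_A, mesh_B) {
  aA <- face_areas(mesh_A)
  aB <- face_areas(mesh_B)
  lam <- (aA / sum(aA)) / (aB / sum(aB))
  flagged <- !is.finite(lam)
  list(per_face = lam, global = mean(lam[is.finite(lam)]),
       area_distortion_lambda = mean(lam[is.finite(lam)]),
       area_fraction_ratio = mean((1 / lam)[is.finite(lam)]),
       flagged = sum(flagged))
}

# singular values of the per-face 2D affine map A -> B (shared topology)
mapping_singular_values <- function(mesh_A, mesh_B) {
  if (!identical(dim(mesh_A$faces), dim(mesh_B$faces)))
    stop("meshes must share face topology")
  f <- mesh_A$faces
  emb <- function(mesh) {
    v <- mesh$vertices
    ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    l1 <- sqrt(rowSums(ab^2))
    dt <- rowSums(ab * ac)
    cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
    ncr <- sqrt(rowSums(cr^2))
    # B' = (l1, 0); C' = (dt/l1, ncr/l1)
    list(b1 = l1, c1 = dt / pmax(l1, 1e-300), c2 = ncr / pmax(l1, 1e-300))
  }
  X <- emb(mesh_A); Y <- emb(mesh_B)
  # J = Y2 %*% solve(X2) with X2 = [[b1,c1],[0,c2]]
  det <- X$b1 * X$c2
  a11 <- Y$b1 * X$c2 / det
  a12 <- (-Y$b1 * X$c1 + X$b1 * Y$c1) / det
  a21 <- rep(0, length(det))
  a22 <- X$b1 * Y$c2 / det
  s1 <- a11^2 + a12^2 + a21^2 + a22^2
  s2 <- (a11 * a22 - a12 * a21)^2
  disc <- sqrt(pmax(s1^2 - 4 * s2, 0))
  sig2 <- sqrt(pmax((s1 + disc) / 2, 0))
  sig1 <- sqrt(pmax((s1 - disc) / 2, 0))
  list(sigma1 = sig1, sigma2 = sig2)
}

#' Distortion metrics of a UV chart from its 3D lookup
#'
#' Computes per-pixel differential areas `dA = |dS/du x dS/dv| du dv`,
#' conformal error from the 2x3 Jacobian, and area distortion
#' `lambda = pixel fraction / (dA / sum(dA))`. Gradients use central
#' differences, periodic across the u seam and one-sided at the pole rows.
#'
#' @param uv_grid a `uv_grid` (see [uv_map()]) or a rows x cols x 3 lookup
#'   array.
#' @return list with matrices `dA`, `Q`, `lambda`, and `global_Q`
#'   (dA-weighted), `global_lambda` (plain mean), `total_area`.
#' @export
uv_jacobian_metrics <- function(uv_grid) {
  xyz <- if (inherits(uv_grid, "uv_grid")) uv_grid$xyz_lookup else uv_grid
  nr <- dim(xyz)[1]; nc <- dim(xyz)[2]
  du <- 2 * pi / nc
  dv <- pi / nr
  gu <- array(0, dim(xyz)); gv <- array(0, dim(xyz))
  for (c in 1:3) {
    # u direction: periodic columns
    gu[, , c] <- (xyz[, c(2:nc, 1), c] - xyz[, c(nc, 1:(nc - 1)), c]) / (2 * du)
    # v direction: one-sided at poles
    ip <- pmin(seq_len(nr) + 1L, nr); im <- pmax(seq_len(nr) - 1L, 1L)
    gv[, , c] <- (xyz[ip, , c] - xyz[im, , c]) / ((ip - im) * dv)
  }
  crossn <- sqrt((gu[, , 2] * gv[, , 3] - gu[, , 3] * gv[, , 2])^2 +
                 (gu[, , 3] * gv[, , 1] - gu[, , 1] * gv[, , 3])^2 +
                 (gu[, , 1] * gv[, , 2] - gu[, , 2] * gv[, , 1])^2)
  dA <- crossn * du * dv
  E <- gu[, , 1]^2 + gu[, , 2]^2 + gu[, , 3]^2
  G <- gv[, , 1]^2 + gv[, , 2]^2 + gv[, , 3]^2
  Fc <- gu[, , 1] * gv[, , 1] + gu[, , 2] * gv[, , 2] + gu[, , 3] * gv[, , 3]
  tr <- E + G
  disc <- sqrt(pmax(tr^2 - 4 * (E * G - Fc^2), 0))
  lam2 <- (tr + disc) / 2
  lam1 <- pmax((tr - disc) / 2, 1e-300)
  Q <- sqrt(lam2 / lam1)
  npix <- nr * nc
  lambda <- (1 / npix) / (dA / sum(dA))
  list(dA = dA, Q = Q, lambda = lambda,
       global_Q = sum(Q * dA) / sum(dA),
       global_lambda = mean(lambda),
       total_area = sum(dA))
}

#' Geometrical difference between two meshes
#'
#' Chamfer distance (symmetric mean Euclidean nearest-vertex distance),
#' max-sliced 1-Wasserstein distance between the vertex clouds (50 random
#' projections, averaged over 10 seeded evaluations), and percentage
#' differences in total surface area and voxelized volume.
#'
#' @param mesh_A,mesh_B `surface_mesh`es (vertex counts may differ).
#' @param n_projections,n_evals sliced-Wasserstein settings.
#' @param seed RNG seed for the projections.
#' @param volume compute the (slower) voxelized volume difference.
#' @return list of class `mesh_comparison` with `chamfer`,
#'   `sliced_wasserstein`, `delta_area_pct`, `delta_volume_pct`.
#' @export
compare_meshes <- function(mesh_A, mesh_B, n_projections = 50, n_evals = 10,
                           seed = 1, volume = FALSE) {
  va <- mesh_A$vertices; vb <- mesh_B$vertices
  dab <- .cpp_nn_index(va, vb)$distance
  dba <- .cpp_nn_index(vb, va)$distance
  cd <- mean(dab) + mean(dba)
  sw <- mean(vapply(seq_len(n_evals), function(e) {
    set.seed(seed + e)
    pr <- matrix(rnorm(3 * n_projections), ncol = 3)
    pr <- pr / sqrt(rowSums(pr^2))
    max(vapply(seq_len(n_projections), function(p) {
      w1_1d(va %*% pr[p, ], vb %*% pr[p, ])
    }, 0))
  }, 0))
  dA <- (mesh_area(mesh_A) - mesh_area(mesh_B)) / mesh_area(mesh_B) * 100
  dV <- NA_real_
  if (volume) {
    volA <- voxel_volume_robust(mesh_A)
    volB <- voxel_volume_robust(mesh_B)
    if (!is.na(volA) && !is.na(volB)) dV <- (volA - volB) / volB * 100
  }
  structure(list(chamfer = cd, sliced_wasserstein = sw,
                 delta_area_pct = dA, delta_volume_pct = dV),
            class = "mesh_comparison")
}

# 1D Wasserstein-1 between two empirical measures via quantile functions
w1_1d <- function(x, y, n_quantiles = 512) {
  q <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  mean(abs(quantile(x, q, names = FALSE, type = 4) -
           quantile(y, q, names = FALSE, type = 4)))
}

# voxelized volume with the smallest closing radius that succeeds
voxel_volume_robust <- function(mesh) {
  for (r in c(0, 1, 3, 5)) {
    vol <- tryCatch(voxelize(mesh, dilation_radius = r), error = function(e) NULL)
    if (!is.null(vol)) {
      out <- sum(vol_data(vol))
      attr(out, "dilation_radius") <- r
      return(out)
    }
  }
  NA_real_
}

#' @export
print.mesh_comparison <- function(x, ...) {
  cat(sprintf("chamfer %.3f vox | SW1 %.3f vox | dA %.2f%% | dV %s\n",
              x$chamfer, x$sliced_wasserstein, x$delta_area_pct,
              ifelse(is.na(x$delta_volume_pct), "n/a",
                     sprintf("%.2f%%", x$delta_volume_pct))))
  invisible(x)
}
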