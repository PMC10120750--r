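#' Height image of a topographic binary
#'
#' Approximates the topographic surface as a single-valued height field
#' `d = f(u,v)`: each (u,v) column of the binary is scanned along d and the
#' pixel value is the length of the longest contiguous foreground run.
#' Internal structures disconnected from the main cell body do not extend
#' the run and are thereby suppressed.
#'
#' @param topo_binary (d, v, u) binary array.
#' @return rows x cols numeric matrix of heights (in d-slices).
#' @export
approximate_height_image <- function(topo_binary) {
  d <- dim(topo_binary)
  out <- matrix(0, d[2], d[3])
  bin <- topo_binary != 0
  for (j in seq_len(d[3])) {
    sl <- bin[, , j, drop = FALSE]   # d x v
    dim(sl) <- d[1:2]
    out[, j] <- apply(sl, 2, longest_run)
  }
  out
}

longest_run <- function(x) {
  if (!any(x)) return(0)
  r <- rle(as.logical(x))
  max(r$lengths[r$values])
}

#' Asymmetric least-squares reference surface
#'
#' Fits a smooth baseline `d_ref = f_smooth(u,v)` beneath the rugged height
#' image by asymmetric Whittaker smoothing: weighted penalized least squares
#' with a 2D Laplacian penalty, where pixels above the current fit get
#' weight `p` and pixels below get `1 - p`. With `p < 0.5` upward
#' excursions (protrusions) are suppressed and the fit tracks the lower
#' envelope (the cortex). The image is downsampled for speed and extra
#' smoothness, solved iteratively, and resized back.
#'
#' @param approx_d height image from [approximate_height_image()].
#' @param p asymmetry (default 0.25).
#' @param lam Laplacian regularization weight (default 1).
#' @param n_iter reweighting iterations (default 10).
#' @param downsample integer downsampling factor (default 8, the reference
#'   configuration; strong downsampling doubles as smoothness
#'   regularization of the baseline).
#' @return list of class `reference_height_field`: `d_ref` (full resolution),
#'   `approx_d`, `als_params`, `residual`.
#' @export
als_reference_surface <- function(approx_d, p = 0.25, lam = 1, n_iter = 10,
                                  downsample = 8) {
  y <- resize_bilinear(approx_d, ceiling(nrow(approx_d) / downsample),
                       ceiling(ncol(approx_d) / downsample))
  nr <- nrow(y); nc <- ncol(y)
  n <- nr * nc
  L <- grid_laplacian(nr, nc)
  P <- lam * Matrix::crossprod(L)
  z <- as.vector(y)
  w <- rep(1 - p, n)
  for (it in seq_len(n_iter)) {
    A <- Matrix::Diagonal(n, w) + P
    z <- as.vector(Matrix::solve(A, w * as.vector(y)))
    w_new <- ifelse(as.vector(y) > z, p, 1 - p)
    if (all(w_new == w) && it > 1) break
    w <- w_new
  }
  d_ref <- resize_bilinear(matrix(z, nr, nc), nrow(approx_d), ncol(approx_d))
  structure(list(d_ref = d_ref, approx_d = approx_d,
                 als_params = list(p = p, lam = lam, n_iter = n_iter,
                                   downsample = downsample),
                 residual = sqrt(mean((as.vector(y) - z)^2))),
            class = "reference_height_field")
}

# 5-point Laplacian on an nr x nc grid (u columns periodic, v rows clamped)
grid_laplacian <- function(nr, nc) {
  n <- nr * nc
  id <- function(i, j) i + nr * (j - 1L)
  ii <- jj <- xx <- NULL
  i <- rep(seq_len(nr), nc)
  j <- rep(seq_len(nc), each = nr)
  ctr <- id(i, j)
  up <- id(pmax(i - 1L, 1L), j)
  dn <- id(pmin(i + 1L, nr), j)
  lf <- id(i, ((j - 2L) %% nc) + 1L)
  rt <- id(i, (j %% nc) + 1L)
  ii <- rep(ctr, 5)
  jj <- c(ctr, up, dn, lf, rt)
  xx <- c(rep(-4, n), rep(1, 4 * n))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# bilinear resize of a matrix
resize_bilinear <- function(img, nr, nc) {
  sr <- (seq_len(nr) - 0.5) / nr * nrow(img) + 0.5
  sc <- (seq_len(nc) - 0.5) / nc * ncol(img) + 0.5
  sr <- pmin(pmax(sr, 1), nrow(img))
  sc <- pmin(pmax(sc, 1), ncol(img))
  r0 <- pmin(floor(sr), nrow(img) - 1L); r1 <- r0 + 1
  c0 <- pmin(floor(sc), ncol(img) - 1L); c1 <- c0 + 1
  fr <- sr - r0; fc <- sc - c0
  img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    img[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    img[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    img[r1, c1, drop = FALSE] * outer(fr, fc)
}

#' Affinity configuration for label spreading on a mesh
#'
#' @param gamma weight of the geodesic-distance affinity versus the
#'   convexity (dihedral-angle) affinity (default 0.9).
#' @param clamp label-spreading clamping ratio (default 0.99).
#' @param n_iter diffusion iterations.
#' @param binarize_threshold probability threshold used when re-binarizing
#'   between iterations (two-class mode).
#' @return list of class `affinity_config`.
#' @export
affinity_config <- function(gamma = 0.9, clamp = 0.99, n_iter = 20,
                            binarize_threshold = 0.25) {
  stopifnot(gamma >= 0, gamma <= 1)
  structure(list(gamma = gamma, clamp = clamp, n_iter = n_iter,
                 binarize_threshold = binarize_threshold),
            class = "affinity_config")
}

# sparse 1-ring affinity matrix: gamma * distance kernel + (1-gamma) *
# dihedral (normal-angle) kernel, diagonal 1
mesh_affinity <- function(mesh, gamma = 0.9) {
  e <- mesh_edges(mesh)
  v <- mesh$vertices
  n <- nrow(v)
  d <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  Ad <- exp(-d^2 / (2 * mean(d)^2))
  nv <- vertex_normals(mesh)
  cosang <- rowSums(nv[e[, 1], , drop = FALSE] * nv[e[, 2], , drop = FALSE])
  Dc <- (1 - cosang) / 2
  Ac <- exp(-Dc^2 / (2 * max(mean(Dc), 1e-12)^2))
  w <- gamma * Ad + (1 - gamma) * Ac
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(n)),
                            j = c(e[, 2], e[, 1], seq_len(n)),
                            x = c(w, w, rep(1, n)), dims = c(n, n))
  A
}

#' Label spreading over an affinity matrix
#'
#' Graph diffusion of seed labels: `F <- clamp * S F + (1 - clamp) * Y` with
#' `S` the symmetrically normalized affinity and `Y` the one-hot seed
#' matrix. The label set of the result never exceeds the seed set. With
#' `binary = TRUE` the two-class (foreground vs background) variant is run:
#' unlabelled vertices seed the background class and the foreground
#' probability is re-binarized at `rebinarize` before each iteration.
#'
#' @param A sparse affinity matrix (e.g. from the combined
#'   distance/convexity kernel used by [binary_protrusions()]).
#' @param seeds integer seed labels (0 = unlabelled).
#' @param clamp clamping ratio.
#' @param n_iter iterations.
#' @param rebinarize probability threshold (`NA` = no re-binarization).
#' @param binary run the two-class variant.
#' @return integer label vector.
#' @export
label_spread <- function(A, seeds, clamp = 0.99, n_iter = 20,
                         rebinarize = NA, binary = FALSE) {
  n <- nrow(A)
  labs <- sort(setdiff(unique(seeds), 0L))
  if (!length(labs)) return(integer(n))
  dg <- Matrix::rowSums(A)
  S <- Matrix::Diagonal(n, 1 / sqrt(dg)) %*% A %*% Matrix::Diagonal(n, 1 / sqrt(dg))
  if (binary) {
    Y <- cbind(as.numeric(seeds > 0), as.numeric(seeds == 0))
    Fm <- Y
    for (it in seq_len(n_iter)) {
      if (!is.na(rebinarize)) {
        p <- Fm[, 1] / pmax(Fm[, 1] + Fm[, 2], 1e-12)
        Fm <- cbind(as.numeric(p >= rebinarize), as.numeric(p < rebinarize))
      }
      Fm <- as.matrix(clamp * (S %*% Fm) + (1 - clamp) * Y)
    }
    p <- Fm[, 1] / pmax(Fm[, 1] + Fm[, 2], 1e-12)
    return(as.integer(p >= if (is.na(rebinarize)) 0.5 else rebinarize))
  }
  Y <- Matrix::sparseMatrix(i = which(seeds > 0),
                            j = match(seeds[seeds > 0], labs),
                            x = 1, dims = c(n, length(labs)))
  Fm <- as.matrix(Y)
  for (it in seq_len(n_iter)) {
    Fm <- as.matrix(clamp * (S %*% Fm) + (1 - clamp) * Y)
  }
  best <- max.col(Fm, ties.method = "first")
  conf <- Fm[cbind(seq_len(n), best)]
  out <- ifelse(conf > 1e-8, labs[best], 0L)
  as.integer(out)
}

# connected components of a vertex subset on the mesh graph; returns
# membership (0 outside subset) and per-component Cartesian areas
mesh_subset_components <- function(mesh, subset) {
  e <- mesh_edges(mesh)
  keep <- subset[e[, 1]] & subset[e[, 2]]
  g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  n <- nrow(mesh$vertices)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  memb <- comp$membership
  memb[!subset] <- 0L
  va <- face_to_vertex_area(mesh)
  areas <- tapply(va[subset], memb[subset], sum)
  list(membership = memb, areas = areas)
}

#' Topography-guided binary protrusion segmentation
#'
#' Thresholds the protrusion height `h = d - d_ref` at its mean, removes
#' small components, diffuses the binary with two-class label spreading on
#' the combined distance/convexity affinity (re-binarizing each iteration),
#' and removes remaining small components.
#'
#' @param topo_mesh a `topographic_mesh` (or its `(d,v,u)` mesh).
#' @param ref_field a `reference_height_field`, or `NULL` for the flat cMCF
#'   reference `d_ref = 0` (which under-segments dense protrusions).
#' @param cfg an [affinity_config()].
#' @param min_area_initial,min_area_final component area thresholds
#'   (voxel^2).
#' @return integer per-vertex binary (0/1).
#' @export
binary_protrusions <- function(topo_mesh, ref_field = NULL,
                               cfg = affinity_config(),
                               min_area_initial = 200, min_area_final = 500) {
  mesh <- if (inherits(topo_mesh, "topographic_mesh")) topo_mesh$mesh else topo_mesh
  d <- mesh$vertices[, 1]
  if (is.null(ref_field)) {
    dref_v <- 0
  } else {
    # height-image values are 1-based top indices along d; express them
    # relative to the reference slice like the mesh d coordinate
    img <- ref_field$d_ref - if (inherits(topo_mesh, "topographic_mesh"))
      topo_mesh$d_zero_index else 0
    dref_v <- bilinear_at(img, mesh$vertices[, 2] + 1, mesh$vertices[, 3] + 1)
  }
  h <- d - dref_v
  fg <- h >= mean(h)
  fg <- drop_small_components(mesh, fg, min_area_initial)
  if (!any(fg)) {
    warning("empty protrusion segmentation")
    return(integer(length(h)))
  }
  A <- mesh_affinity(mesh, cfg$gamma)
  out <- label_spread(A, as.integer(fg), clamp = cfg$clamp,
                      n_iter = cfg$n_iter, rebinarize = cfg$binarize_threshold,
                      binary = TRUE)
  out <- drop_small_components(mesh, out > 0, min_area_final)
  as.integer(out)
}

drop_small_components <- function(mesh, subset, min_area) {
  if (!any(subset)) return(subset)
  cs <- mesh_subset_components(mesh, subset)
  keep <- as.integer(names(cs$areas)[cs$areas >= min_area])
  subset & cs$membership %in% keep
}

bilinear_at <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Topography-guided instance segmentation of protrusions
#'
#' Identifies protrusion tops as connected regions of high topographic mean
#' curvature: `H` is computed from the signed distance transform of the
#' topographic binary; voxels restricted to a surface shell (dilation(2)
#' minus erosion(2)) are clustered into 3 classes (k-means on sigma=1
#' smoothed `H` for blebs/filopodia; Gaussian-mixture on sigma = 1,3,5
#' features for lamellipodia; both fitted on 10,000 sampled voxels with a
#' fixed seed) and the highest-mean class kept. Components below 500 voxels
#' are dropped, the rest labelled, expanded by 3 voxels, transferred to the
#' mesh, intersected with the binary segmentation, diffused 10 iterations
#' (no re-binarization), and re-masked.
#'
#' @param topo_binary (d, v, u) binary array.
#' @param topo_mesh a `topographic_mesh`.
#' @param binary_seg per-vertex binary from [binary_protrusions()].
#' @param motif_mode `"blebs_filopodia"` or `"lamellipodia"`.
#' @param cfg an [affinity_config()].
#' @param min_voxels,min_mesh_area size filters (voxels; voxel^2).
#' @param ref_field optional `reference_height_field`; when supplied,
#'   instances whose vertices all lie below the reference surface (internal
#'   or sub-cortical structures) are removed.
#' @param seed sampling seed for the clusterers.
#' @return list of class `label_field`: `vertex_labels`, `voxel_labels`,
#'   `H` (volume).
#' @export
instance_protrusions <- function(topo_binary, topo_mesh, binary_seg,
                                 motif_mode = c("blebs_filopodia",
                                                "lamellipodia"),
                                 cfg = affinity_config(n_iter = 10),
                                 min_voxels = 500, min_mesh_area = 100,
                                 ref_field = NULL, seed = 7) {
  motif_mode <- match.arg(motif_mode)
  bin <- topo_binary != 0
  H <- mean_curvature_from_sdf(bin * 1, smooth_sigma = 0)
  shell <- binary_dilate(bin, 2) & !binary_erode(bin, 2)
  H1 <- gaussian_smooth_3d(H, 1)
  idx <- which(shell)
  ns <- min(10000L, length(idx))
  sub <- idx[local_seed_sample(length(idx), ns, seed)]
  if (motif_mode == "blebs_filopodia") {
    km <- local_kmeans(matrix(H1[sub], ncol = 1), 3, seed)
    cls_mean <- km$centers[, 1]
    assign_all <- apply(abs(outer(H1[idx], as.vector(km$centers), "-")), 1,
                        which.min)
  } else {
    feats <- cbind(H1[sub], gaussian_smooth_3d(H, 3)[sub],
                   gaussian_smooth_3d(H, 5)[sub])
    mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
    gm <- tryCatch(mclust::Mclust(feats, G = 3, verbose = FALSE),
                   error = function(e) NULL)
    if (is.null(gm) || gm$G < 2) {
      warning("degenerate clustering; falling back to Otsu threshold")
      th <- otsu_thresholds(H1[idx], 2)[1]
      high <- H1[idx] > th
      return(finish_instances(high, idx, bin, topo_mesh, binary_seg, cfg,
                              min_voxels, min_mesh_area, H, ref_field))
    }
    featall <- cbind(H1[idx], gaussian_smooth_3d(H, 3)[idx],
                     gaussian_smooth_3d(H, 5)[idx])
    assign_all <- mclust::predict.Mclust(gm, featall)$classification
    cls_mean <- tapply(featall[, 1], assign_all, mean)[as.character(1:gm$G)]
  }
  if (length(unique(cls_mean)) < 2) {
    warning("degenerate clustering; falling back to Otsu threshold")
    th <- otsu_thresholds(H1[idx], 2)[1]
    high <- H1[idx] > th
  } else {
    high <- assign_all == which.max(cls_mean)
  }
  finish_instances(high, idx, bin, topo_mesh, binary_seg, cfg, min_voxels,
                   min_mesh_area, H, ref_field)
}

finish_instances <- function(high, idx, bin, topo_mesh, binary_seg, cfg,
                             min_voxels, min_mesh_area, H, ref_field = NULL) {
  vol <- array(0, dim(bin))
  vol[idx[high]] <- 1
  lab <- label_components_3d(vol)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  lab[!(lab %in% keep)] <- 0L
  # relabel consecutively
  lab[] <- match(lab, c(0L, keep), nomatch = 1L) - 1L
  lab <- expand_labels_3d(lab, 3)
  mesh <- topo_mesh$mesh
  vcoord <- mesh$vertices
  vcoord[, 1] <- vcoord[, 1] + attr_d_zero(topo_mesh)
  vidx <- round(vcoord) + 1
  dmn <- dim(lab)
  vidx[, 1] <- pmin(pmax(vidx[, 1], 1), dmn[1])
  vidx[, 2] <- pmin(pmax(vidx[, 2], 1), dmn[2])
  vidx[, 3] <- pmin(pmax(vidx[, 3], 1), dmn[3])
  vlab <- lab[vidx]
  vlab[binary_seg == 0] <- 0L
  vseed <- vlab                     # curvature-top seeds before diffusion
  # size filter on Cartesian area
  va <- face_to_vertex_area(topo_mesh$cartesian_twin)
  for (l in setdiff(unique(vlab), 0L)) {
    if (sum(va[vlab == l]) < min_mesh_area) vlab[vlab == l] <- 0L
  }
  if (any(vlab > 0)) {
    A <- mesh_affinity(mesh, cfg$gamma)
    vlab <- label_spread(A, vlab, clamp = cfg$clamp, n_iter = cfg$n_iter,
                         rebinarize = NA)
    vlab[binary_seg == 0] <- 0L
  }
  if (!is.null(ref_field) && any(vlab > 0)) {
    # the protrusive definition applied per instance: a protrusion is seeded
    # by its top, so the *seed* region must rise clearly above the mean
    # height h_bar relative to the reference (the diffused skirt is allowed
    # to reach downhill). Instances whose tops sit at cortex level (surface
    # undulations, internal structures whose d never exceeds d_ref) are
    # removed.
    img <- ref_field$d_ref - if (!is.null(topo_mesh$d_zero_index))
      topo_mesh$d_zero_index else 0
    drefv <- bilinear_at(img, mesh$vertices[, 2] + 1, mesh$vertices[, 3] + 1)
    h <- mesh$vertices[, 1] - drefv
    # a top must stand out from the reference by more than the typical
    # surface deviation (robust MAD, insensitive to the protrusions
    # themselves), not merely reach the mean height
    hcut <- mean(h) + mad(h)
    for (l in setdiff(unique(vlab), 0L)) {
      sel <- if (any(vseed == l)) vseed == l else vlab == l
      if (mean(h[sel]) < hcut) vlab[vlab == l] <- 0L
    }
  }
  # each instance must be connected on the mesh graph: satellite crumbs left
  # by diffusion and masking are dropped
  for (l in setdiff(unique(vlab), 0L)) {
    cs <- mesh_subset_components(mesh, vlab == l)
    if (length(cs$areas) > 1) {
      keep <- as.integer(names(cs$areas)[which.max(cs$areas)])
      vlab[vlab == l & cs$membership != keep] <- 0L
    }
  }
  structure(list(vertex_labels = as.integer(vlab), voxel_labels = lab, H = H),
            class = "label_field")
}

attr_d_zero <- function(topo_mesh) {
  if (!is.null(topo_mesh$d_zero_index)) return(topo_mesh$d_zero_index - 1)
  -min(0, floor(min(topo_mesh$mesh$vertices[, 1])))
}

# expand positive labels into background by n 6-connected dilation steps
expand_labels_3d <- function(lab, n) {
  d <- dim(lab)
  for (s in seq_len(n)) {
    bg <- lab == 0L
    for (ax in 1:3) for (dir in c(-1L, 1L)) {
      shifted <- shift_array(lab, ax, dir)
      fill <- bg & lab == 0L & shifted > 0L
      lab[fill] <- shifted[fill]
      # deterministic tie-break within a pass: keep the smaller label
      tie <- bg & shifted > 0L & lab > 0L & shifted < lab
      lab[tie] <- shifted[tie]
    }
  }
  lab
}

shift_array <- function(a, ax, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx
  src[[ax]] <- pmin(pmax(idx[[ax]] - dir, 1L), d[ax])
  out <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  # do not wrap: zero the border row that would have wrapped
  if (dir == 1L) {
    if (ax == 1) out[1, , ] <- 0L
    if (ax == 2) out[, 1, ] <- 0L
    if (ax == 3) out[, , 1] <- 0L
  } else {
    if (ax == 1) out[d[1], , ] <- 0L
    if (ax == 2) out[, d[2], ] <- 0L
    if (ax == 3) out[, , d[3]] <- 0L
  }
  dim(out) <- d
  out
}

# deterministic k-means (seeded, restarted once)
local_kmeans <- function(x, k, seed = 7) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  kmeans(x, centers = k, nstart = 3, iter.max = 50)
}

#' Multi-class Otsu thresholds
#'
#' Exhaustive search for the `k - 1` thresholds maximizing between-class
#' variance on a 128-bin histogram.
#'
#' @param x numeric data.
#' @param k number of classes (2 or 3).
#' @return numeric vector of `k - 1` thresholds (increasing).
#' @export
otsu_thresholds <- function(x, k = 3) {
  x <- x[is.finite(x)]
  br <- seq(min(x), max(x), length.out = 129)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), 128)
  p <- h / sum(h)
  mids <- (br[-1] + br[-129]) / 2
  cum_p <- cumsum(p); cum_m <- cumsum(p * mids)
  between <- function(lo, hi) {   # class = bins (lo, hi]
    w <- cum_p[hi] - if (lo > 0) cum_p[lo] else 0
    if (w <= 0) return(0)
    m <- (cum_m[hi] - if (lo > 0) cum_m[lo] else 0) / w
    w * m^2
  }
  if (k == 2) {
    best <- -Inf; tbest <- 1L
    for (t in 1:127) {
      v <- between(0, t) + between(t, 128)
      if (v > best) { best <- v; tbest <- t }
    }
    return(mids[tbest])
  }
  best <- -Inf; t1b <- 1L; t2b <- 2L
  for (t1 in 1:126) for (t2 in (t1 + 1):127) {
    v <- between(0, t1) + between(t1, t2) + between(t2, 128)
    if (v > best) { best <- v; t1b <- t1; t2b <- t2 }
  }
  c(mids[t1b], mids[t2b])
}

#' One-call topography-guided protrusion segmentation
#'
#' Chains the segmentation stages on a pipeline result: height image, ALS
#' reference surface, binary protrusion segmentation, and instance
#' segmentation. Surface-area thresholds are defined at the reference chart
#' size of 1024 x 512 pixels (200 / 500 / 100 voxel^2) and are scaled by the
#' relative grid area for smaller charts; the two-class diffusion runs 5
#' iterations on grids at or below 512 rows, matching the grid-dependent
#' practice for bleb-scale charts.
#'
#' @param unwrap an `unwrap_result` from [run_unwrap()].
#' @param motif_mode passed to [instance_protrusions()].
#' @param gamma affinity mixing weight.
#' @return list: `binary` (per-vertex 0/1), `instances` (a `label_field`),
#'   `ref_field`, `height_image`.
#' @export
segment_protrusions <- function(unwrap, motif_mode = "blebs_filopodia",
                                gamma = 0.9) {
  stopifnot(isTRUE(unwrap$success))
  tb <- unwrap$topo_binary
  tm <- unwrap$topo_mesh
  hi <- approximate_height_image(tb)
  als <- als_reference_surface(hi)
  scale <- (nrow(hi) / 512)^2
  n_diff <- if (nrow(hi) <= 512) 5 else 20
  bin <- binary_protrusions(tm, als,
                            affinity_config(gamma = gamma, n_iter = n_diff),
                            min_area_initial = max(4, 200 * scale),
                            min_area_final = max(8, 500 * scale))
  inst <- instance_protrusions(tb, tm, bin, motif_mode,
                               cfg = affinity_config(gamma = gamma,
                                                     n_iter = 10),
                               min_voxels = 500, min_mesh_area = 100,
                               ref_field = als)
  list(binary = bin, instances = inst, ref_field = als, height_image = hi)
}
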