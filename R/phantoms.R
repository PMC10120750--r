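#' Icosphere with adjustable resolution
#'
#' Subdivides each icosahedron face into `k^2` triangles and projects onto
#' the unit sphere, giving `10 k^2 + 2` near-uniform vertices.
#'
#' @param k subdivisions per icosahedron edge (k = 1 gives the icosahedron).
#' @param radius sphere radius.
#' @return a `surface_mesh`.
#' @export
icosphere <- function(k = 16, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (k == 1) {
    m <- surface_mesh(radius * v, f)
    return(orient_outward(m))
  }
  # barycentric lattice on each face, vertices deduplicated by rounded key
  verts <- list(); faceout <- list()
  keymap <- new.env(hash = TRUE)
  nextid <- 0L
  getid <- function(p) {
    key <- paste(sprintf("%.10f", p), collapse = "_")
    id <- keymap[[key]]
    if (is.null(id)) {
      nextid <<- nextid + 1L
      keymap[[key]] <- nextid
      verts[[nextid]] <<- p
      id <- nextid
    }
    id
  }
  for (fi in seq_len(nrow(f))) {
    A <- v[f[fi, 1], ]; B <- v[f[fi, 2], ]; C <- v[f[fi, 3], ]
    grid <- matrix(0L, k + 1, k + 1)
    for (i in 0:k) for (j in 0:(k - i)) {
      p <- (A * (k - i - j) + B * i + C * j) / k
      p <- p / sqrt(sum(p^2))
      grid[i + 1, j + 1] <- getid(p)
    }
    for (i in 0:(k - 1)) for (j in 0:(k - 1 - i)) {
      faceout[[length(faceout) + 1]] <-
        c(grid[i + 1, j + 1], grid[i + 2, j + 1], grid[i + 1, j + 2])
      if (j < k - 1 - i)
        faceout[[length(faceout) + 1]] <-
          c(grid[i + 2, j + 1], grid[i + 2, j + 2], grid[i + 1, j + 2])
    }
  }
  m <- surface_mesh(radius * do.call(rbind, verts), do.call(rbind, faceout))
  orient_outward(m)
}

#' Phantom specification
#'
#' Describes a synthetic cell-like surface: a sphere base decorated with
#' protrusions (blebs: smooth hemispherical caps; ridges: elongated crests
#' emulating lamellipodial folds; spikes: tall thin cones emulating
#' filopodia), and optional topological defects (holes: removed patches;
#' handles: welded tubes raising the genus). Every phantom is reproducible
#' bit-identically from its spec.
#'
#' @param base_radius sphere radius in voxels (default 30).
#' @param protrusions list of lists with `kind` ("bleb", "ridge" or "spike"),
#'   `center_direction` (unit 3-vector, optional: defaults to well-separated
#'   directions), `height` (voxels) and `width` (angular radius, radians).
#' @param n_protrusions convenience: make this many default blebs.
#' @param defects list with optional `holes` (count) and `handle` (logical).
#' @param mesh_k icosphere resolution parameter (vertex count = 10 k^2 + 2).
#' @param seed integer seed fixing all randomness.
#' @param allow_overlap permit overlapping protrusions (for deliberately
#'   fused/conjoined phantoms used to exercise watershed refinement).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(base_radius = 30, protrusions = NULL,
                         n_protrusions = 5, defects = list(), mesh_k = 45,
                         seed = 0, allow_overlap = FALSE) {
  if (is.null(protrusions)) {
    dirs <- well_separated_directions(n_protrusions, seed)
    protrusions <- lapply(seq_len(n_protrusions), function(i) {
      list(kind = "bleb", center_direction = dirs[i, ],
           height = 0.25 * base_radius, width = 0.45)
    })
  }
  for (p in protrusions) {
    if (!p$kind %in% c("bleb", "ridge", "spike"))
      stop("unknown protrusion kind: ", p$kind)
  }
  # non-overlap check at the stated separation
  if (length(protrusions) > 1 && !allow_overlap) {
    dirs <- t(vapply(protrusions, function(p) p$center_direction, numeric(3)))
    widths <- vapply(protrusions, function(p) p$width, 0)
    for (i in seq_len(nrow(dirs) - 1)) for (j in (i + 1):nrow(dirs)) {
      ang <- acos(pmin(1, pmax(-1, sum(dirs[i, ] * dirs[j, ]))))
      if (ang < widths[i] + widths[j])
        stop("overlapping protrusions ", i, " and ", j)
    }
  }
  structure(list(base_radius = base_radius, protrusions = protrusions,
                 defects = defects, mesh_k = mesh_k, seed = seed),
            class = "phantom_spec")
}

# deterministic well-separated unit directions (spherical Fibonacci lattice,
# rotated by a seed-derived angle)
well_separated_directions <- function(n, seed = 0) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * i + seed * 0.7391
  cbind(r * cos(th), r * sin(th), z)
}

#' Generate a phantom cell mesh with ground-truth protrusion labels
#'
#' @param spec a [phantom_spec()].
#' @return a `surface_mesh` with `vertex_fields$gt_label` (0 = cortex,
#'   1..n protrusion instances) and attribute `"watertight"`.
#' @export
make_cell_mesh <- function(spec) {
  base <- icosphere(spec$mesh_k, 1)
  d <- base$vertices  # unit directions
  radial <- rep(spec$base_radius, nrow(d))
  label <- integer(nrow(d))
  for (i in seq_along(spec$protrusions)) {
    p <- spec$protrusions[[i]]
    cd <- p$center_direction / sqrt(sum(p$center_direction^2))
    ang <- acos(pmax(pmin(d %*% cd, 1), -1))[, 1]
    bump <- switch(p$kind,
      bleb = ifelse(ang < p$width, p$height * cos(pi / 2 * ang / p$width)^2, 0),
      spike = p$height * exp(-(ang / (p$width / 2))^2),
      ridge = ridge_bump(d, cd, p))
    radial <- radial + bump
    label[bump > 0.2 * p$height] <- i
  }
  v <- d * radial
  mesh <- surface_mesh(v, base$faces, vertex_fields = list(gt_label = label))
  watertight <- TRUE
  if (!is.null(spec$defects$holes) && spec$defects$holes > 0) {
    w <- spec$defects$hole_width
    mesh <- punch_holes(mesh, spec$defects$holes, spec$seed,
                        width = if (is.null(w)) 0 else w)
    watertight <- FALSE
  }
  if (isTRUE(spec$defects$handle)) mesh <- weld_handle(mesh)
  attr(mesh, "watertight") <- watertight
  mesh
}

# elongated crest: Gaussian profile across a great-circle arc
ridge_bump <- function(d, cd, p) {
  # tangent direction for the crest, orthogonal to cd
  ref <- if (abs(cd[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * cd) * cd
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(cd[2] * t1[3] - cd[3] * t1[2], cd[3] * t1[1] - cd[1] * t1[3],
          cd[1] * t1[2] - cd[2] * t1[1])
  x <- (d %*% t1)[, 1]   # along the crest
  y <- (d %*% t2)[, 1]   # across the crest
  z <- (d %*% cd)[, 1]
  along <- atan2(x, z)
  across <- asin(pmin(1, pmax(-1, y)))
  len <- if (is.null(p$length)) 3 * p$width else p$length
  p$height * exp(-(across / (p$width / 2))^2) *
    exp(-pmax(0, abs(along) - len / 2)^2 / (p$width / 2)^2) * (z > 0)
}

# remove faces at deterministic locations: one face per hole, or every face
# within `width` radians of the hole direction for large defects
punch_holes <- function(mesh, n_holes, seed = 0, width = 0) {
  dirs <- well_separated_directions(max(n_holes, 3), seed + 17)[seq_len(n_holes), ,
                                                                drop = FALSE]
  bc <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
         mesh$vertices[mesh$faces[, 3], ]) / 3
  bcn <- bc / sqrt(rowSums(bc^2))
  drop <- integer(0)
  for (i in seq_len(n_holes)) {
    ca <- (bcn %*% dirs[i, ])[, 1]
    drop <- c(drop, if (width > 0) which(ca > cos(width)) else which.max(ca))
  }
  mesh$faces <- mesh$faces[-unique(drop), , drop = FALSE]
  mesh
}

# weld a tube between two removed faces, raising the genus by one
weld_handle <- function(mesh) {
  bc <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
         mesh$vertices[mesh$faces[, 3], ]) / 3
  bcn <- bc / sqrt(rowSums(bc^2))
  f1 <- which.max(bcn[, 3])
  cand <- which(bcn %*% bcn[f1, ] < cos(0.35) & bcn %*% bcn[f1, ] > cos(0.55))
  f2 <- cand[which.max((bcn %*% bcn[f1, ])[cand])]
  a <- mesh$faces[f1, ]; b <- mesh$faces[f2, ]
  # order loop b to face loop a (nearest-vertex greedy), reverse orientation
  b <- b[order(apply(mesh$vertices[b, ], 1, function(p)
    which.min(colSums((t(mesh$vertices[a, ]) - p)^2))))]
  mesh$faces <- mesh$faces[-c(f1, f2), , drop = FALSE]
  tube <- NULL
  for (i in 1:3) {
    j <- i %% 3 + 1
    tube <- rbind(tube, c(a[i], b[i], a[j]), c(b[i], b[j], a[j]))
  }
  mesh$faces <- rbind(mesh$faces, tube)
  mesh
}

#' Synthetic intensity volumes for a phantom
#'
#' Produces the binary cell mask and optional fluorescence-like channels: a
#' membrane-proximal shell at a chosen depth beneath the surface, optionally
#' amplitude-coupled to mean curvature (emulating curvature-sensing readouts
#' such as Septins).
#'
#' @param spec a [phantom_spec()] (or a `surface_mesh` already built from one).
#' @param channels character vector from `c("binary", "shell", "curved_shell")`.
#' @param shell_depth depth of the shell beneath the surface (voxels).
#' @param shell_sigma Gaussian thickness of the shell (voxels).
#' @param curvature_gain relative amplitude coupling to normalized H.
#' @return named list of `volume_image`s (plus the mesh in `$mesh`).
#' @export
make_volume <- function(spec, channels = c("binary", "shell"), shell_depth = 2,
                        shell_sigma = 1.5, curvature_gain = 1) {
  mesh <- if (inherits(spec, "surface_mesh")) spec else make_cell_mesh(spec)
  bin <- voxelize(mesh, dilation_radius = 5)
  out <- list(mesh = mesh)
  if ("binary" %in% channels) out$binary <- bin
  if (any(c("shell", "curved_shell") %in% channels)) {
    d_in <- distance_transform(1 - vol_data(bin))  # depth beneath surface
    shell <- exp(-(d_in - shell_depth)^2 / (2 * shell_sigma^2)) *
      (vol_data(bin) != 0)
    if ("shell" %in% channels)
      out$shell <- volume_image(shell, origin_offset = bin$origin_offset)
    if ("curved_shell" %in% channels) {
      H <- mean_curvature_from_sdf(bin)
      Hn <- H / max(abs(quantile(H[vol_data(bin) != 0], c(0.01, 0.99))))
      out$curved_shell <- volume_image(shell * (1 + curvature_gain * pmax(-1, pmin(1, Hn))),
                                       origin_offset = bin$origin_offset)
    }
  }
  out
}

#' Synthetic blebbing movie with ground truth
#'
#' Bleb heights oscillate sinusoidally with per-bleb phase. Returns per-frame
#' meshes plus per-frame equirectangular label and mean-curvature-like images
#' rendered analytically from the ground truth (suitable for exercising the
#' 2D tracking machinery), ground-truth bounding-box tracks, and the event
#' (crest) times per bleb.
#'
#' @param spec a [phantom_spec()].
#' @param n_frames number of frames.
#' @param period oscillation period in frames (>= 4).
#' @param N UV grid rows (images are N x 2N).
#' @param phase_shift per-bleb phase increment (radians); 0 = synchronous.
#' @param bleach_rate optional exponential intensity decay per frame applied
#'   to the returned H images.
#' @return list with `meshes`, `uv_labels`, `uv_H`, `gt_tracks`
#'   (per-bleb data frame of frame + box), `event_times`, `period`.
#' @export
make_bleb_movie <- function(spec, n_frames = 30, period = 10, N = 64,
                            phase_shift = 0, bleach_rate = 0) {
  stopifnot(period >= 4)
  base <- icosphere(spec$mesh_k, 1)
  dirs <- t(vapply(spec$protrusions, function(p) p$center_direction, numeric(3)))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  widths <- vapply(spec$protrusions, function(p) p$width, 0)
  heights <- vapply(spec$protrusions, function(p) p$height, 0)
  phases <- phase_shift * (seq_len(nrow(dirs)) - 1)
  # equirectangular pixel directions
  vv <- (seq_len(N) - 0.5) / N * pi        # polar angle from +z
  uu <- (seq_len(2 * N) - 0.5) / (2 * N) * 2 * pi
  dirgrid <- array(0, c(N, 2 * N, 3))
  dirgrid[, , 1] <- outer(sin(vv), cos(uu))
  dirgrid[, , 2] <- outer(sin(vv), sin(uu))
  dirgrid[, , 3] <- matrix(cos(vv), N, 2 * N)
  meshes <- vector("list", n_frames)
  uv_labels <- vector("list", n_frames)
  uv_H <- vector("list", n_frames)
  gt <- NULL
  for (t in seq_len(n_frames)) {
    amp <- 0.5 + 0.5 * sin(2 * pi * (t - 1) / period + phases)
    radial <- rep(spec$base_radius, nrow(base$vertices))
    lab_img <- matrix(0L, N, 2 * N)
    H_img <- matrix(0.02, N, 2 * N)
    for (i in seq_len(nrow(dirs))) {
      ang <- acos(pmax(pmin(base$vertices %*% dirs[i, ], 1), -1))[, 1]
      radial <- radial + ifelse(ang < widths[i],
                                amp[i] * heights[i] * cos(pi / 2 * ang / widths[i])^2, 0)
      ca <- dirgrid[, , 1] * dirs[i, 1] + dirgrid[, , 2] * dirs[i, 2] +
        dirgrid[, , 3] * dirs[i, 3]
      pang <- acos(pmax(pmin(ca, 1), -1))
      inside <- pang < widths[i] * (0.4 + 0.6 * amp[i])
      lab_img[inside] <- i
      H_img[inside] <- H_img[inside] + 0.25 * amp[i]
      # ground-truth box in (row=v, col=u) pixels
      wpix <- which(inside, arr.ind = TRUE)
      if (nrow(wpix)) {
        gt <- rbind(gt, data.frame(bleb = i, frame = t,
                                   vmin = min(wpix[, 1]), vmax = max(wpix[, 1]),
                                   umin = min(wpix[, 2]), umax = max(wpix[, 2]),
                                   amplitude = amp[i]))
      }
    }
    if (bleach_rate > 0) H_img <- H_img * exp(-bleach_rate * (t - 1))
    meshes[[t]] <- surface_mesh(base$vertices * radial, base$faces,
                                drop_degenerate = FALSE)
    uv_labels[[t]] <- lab_img
    uv_H[[t]] <- H_img
  }
  # analytic crest frames: sin(2*pi*(t-1)/period + phase) maximal
  event_times <- lapply(seq_len(nrow(dirs)), function(i) {
    m <- -2:ceiling(n_frames / period + 1)
    tt <- round(1 + period * ((pi / 2 - phases[i]) / (2 * pi) + m))
    sort(tt[tt >= 1 & tt <= n_frames])
  })
  list(meshes = meshes, uv_labels = uv_labels, uv_H = uv_H,
       gt_tracks = gt, event_times = event_times, period = period)
}
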