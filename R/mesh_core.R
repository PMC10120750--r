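#' Triangle surface mesh
#'
#' The basic mesh container used throughout the package. Vertices are 3D
#' points in voxel units (columns x, y, z); faces are 1-based vertex-index
#' triples with consistent outward orientation for closed meshes. Named
#' per-vertex and per-face scalar fields (curvature, fluorescence intensity,
#' segmentation labels, ...) travel with the mesh.
#'
#' @param vertices numeric matrix (n x 3).
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param vertex_fields named list of per-vertex vectors/matrices.
#' @param face_fields named list of per-face vectors.
#' @param drop_degenerate drop zero-area faces during construction.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_fields = list(),
                         face_fields = list(), drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index invalid vertices")
  mesh <- structure(list(vertices = vertices, faces = faces,
                         vertex_fields = vertex_fields,
                         face_fields = face_fields),
                    class = "surface_mesh")
  if (drop_degenerate && nrow(faces) > 0L) {
    a <- face_areas(mesh)
    keep <- a > 1e-12
    if (!all(keep)) {
      mesh$faces <- mesh$faces[keep, , drop = FALSE]
      mesh$face_fields <- lapply(mesh$face_fields, function(f) f[keep])
    }
  }
  for (nm in names(mesh$vertex_fields)) {
    f <- mesh$vertex_fields[[nm]]
    len <- if (is.matrix(f)) nrow(f) else length(f)
    if (len != nrow(vertices))
      stop("vertex field '", nm, "' length does not match vertex count")
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (length(x$vertex_fields))
    cat("  vertex fields:", paste(names(x$vertex_fields), collapse = ", "), "\n")
  if (length(x$face_fields))
    cat("  face fields:", paste(names(x$face_fields), collapse = ", "), "\n")
  invisible(x)
}

#' Per-face areas, normals and related helpers
#'
#' @param mesh a `surface_mesh`.
#' @return `face_areas`: numeric vector of triangle areas. `face_normals`:
#'   m x 3 matrix of unit normals. `vertex_normals`: n x 3 area-weighted unit
#'   vertex normals. `mean_edge_length`: scalar.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  cr / pmax(nrm, 1e-300)
}

#' @rdname face_areas
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], mesh$faces[, c])
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc
    }
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' @rdname face_areas
#' @export
mean_edge_length <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  mean(sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2)))
}

# unique undirected edges as a 2-column matrix (sorted pairs)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Read and write surface meshes (ASCII OBJ / PLY)
#'
#' Plain-text Wavefront OBJ and ASCII PLY are supported. PLY per-vertex
#' properties beyond x,y,z are loaded into `vertex_fields`. OBJ 1-based
#' indices map directly onto the package's 1-based face convention.
#'
#' @param path file path ending in `.obj` or `.ply`.
#' @return `read_mesh` returns a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") read_obj(path)
  else if (ext == "ply") read_ply(path)
  else stop("unsupported mesh format: ", ext)
}

#' @rdname read_mesh
#' @param mesh a `surface_mesh` to write.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") write_obj(mesh, path)
  else if (ext == "ply") write_ply(mesh, path)
  else stop("unsupported mesh format: ", ext)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  parse_num <- function(ls, what) {
    toks <- strsplit(trimws(sub("^[vf] +", "", ls)), "[ \t]+")
    n <- vapply(toks, length, 1L)
    if (any(n < 3))
      stop("malformed OBJ ", what, " at line: ", ls[which(n < 3)[1]])
    toks
  }
  v <- t(vapply(parse_num(vlines, "vertex"),
                function(t) as.numeric(t[1:3]), numeric(3)))
  if (anyNA(v)) stop("malformed OBJ vertex line: ",
                     vlines[which(apply(is.na(v), 1, any))[1]])
  f <- t(vapply(parse_num(flines, "face"), function(t) {
    as.integer(sub("/.*", "", t[1:3]))
  }, integer(3)))
  if (anyNA(f)) stop("malformed OBJ face line: ",
                     flines[which(apply(is.na(f), 1, any))[1]])
  surface_mesh(v, f, drop_degenerate = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "ply") stop("malformed PLY at line 1")
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("malformed PLY: missing end_header")
  header <- lines[seq_len(endh)]
  nV <- as.integer(sub(".*vertex +", "", grep("^element vertex", header, value = TRUE)[1]))
  nF <- as.integer(sub(".*face +", "", grep("^element face", header, value = TRUE)[1]))
  # per-vertex property names in order
  velem <- grep("^element vertex", header)
  felem <- grep("^element face", header)
  props <- header[(velem + 1):(felem - 1)]
  props <- grep("^property", props, value = TRUE)
  pnames <- vapply(strsplit(props, " +"), function(t) t[length(t)], "")
  vdat <- do.call(rbind, lapply(strsplit(trimws(lines[endh + seq_len(nV)]), "[ \t]+"),
                                as.numeric))
  if (ncol(vdat) != length(pnames)) stop("malformed PLY vertex block")
  colnames(vdat) <- pnames
  fdat <- lapply(strsplit(trimws(lines[endh + nV + seq_len(nF)]), "[ \t]+"),
                 as.integer)
  f <- t(vapply(fdat, function(t) t[2:4] + 1L, integer(3)))
  extra <- setdiff(pnames, c("x", "y", "z"))
  vf <- lapply(extra, function(p) vdat[, p])
  names(vf) <- extra
  surface_mesh(vdat[, c("x", "y", "z")], f, vertex_fields = vf,
               drop_degenerate = FALSE)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vf <- mesh$vertex_fields
  vf <- vf[vapply(vf, function(f) is.numeric(f) && !is.matrix(f), TRUE)]
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("property float %s", names(vf)),
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  vdat <- cbind(mesh$vertices, do.call(cbind, vf))
  writeLines(apply(vdat, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

#' Discrete Laplacian and mass matrix of a triangle mesh
#'
#' Builds the cotangent Laplacian `L` (negative semi-definite, rows summing to
#' zero) and the barycentric (lumped) mass matrix `M` (diagonal, entry =
#' one-third of incident face area). The `"robust"` variant clamps negative
#' cotangent weights at zero and adds a small diagonal mass regularisation,
#' which stabilises flows on meshes with obtuse/sliver triangles; it is used
#' automatically (with a warning) when non-manifold edges are detected.
#'
#' @param mesh a `surface_mesh`.
#' @param laplacian_kind `"cotangent"` (default) or `"robust"`.
#' @return a list of class `mesh_operators` with sparse matrices `M` and `L`.
#' @export
build_operators <- function(mesh, laplacian_kind = c("cotangent", "robust")) {
  laplacian_kind <- match.arg(laplacian_kind)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  # non-manifold check: every undirected edge in <= 2 faces
  e_all <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  if (any(table(key) > 2) && laplacian_kind == "cotangent") {
    warning("non-manifold edges detected; using robust (clamped) Laplacian")
    laplacian_kind <- "robust"
  }
  # cotangent weights: for each face corner, cot of the angle opposite edge jk
  ii <- jj <- ww <- vector("list", 3)
  corn <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (c in 1:3) {
    i0 <- f[, corn[[c]][1]]; j0 <- f[, corn[[c]][2]]; k0 <- f[, corn[[c]][3]]
    u <- v[j0, , drop = FALSE] - v[i0, , drop = FALSE]
    w <- v[k0, , drop = FALSE] - v[i0, , drop = FALSE]
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    cotan <- rowSums(u * w) / pmax(sqrt(rowSums(cr^2)), 1e-300)
    if (laplacian_kind == "robust") cotan <- pmax(cotan, 0)
    ii[[c]] <- j0; jj[[c]] <- k0; ww[[c]] <- cotan / 2
  }
  i <- c(unlist(ii), unlist(jj))
  j <- c(unlist(jj), unlist(ii))
  w <- c(unlist(ww), unlist(ww))
  L <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  L <- L - Matrix::Diagonal(n, Matrix::rowSums(L))
  a <- face_areas(mesh)
  mdiag <- numeric(n)
  for (c in 1:3) {
    acc <- rowsum(a / 3, f[, c])
    mdiag[as.integer(rownames(acc))] <- mdiag[as.integer(rownames(acc))] + acc
  }
  if (laplacian_kind == "robust") mdiag <- mdiag + 1e-10 * mean(mdiag)
  structure(list(M = Matrix::Diagonal(n, mdiag), L = L,
                 laplacian_kind = laplacian_kind),
            class = "mesh_operators")
}

#' Discrete Gaussian curvature (angle deficit)
#'
#' `K(v) = 2*pi - sum of incident triangle angles` at interior vertices;
#' boundary vertices use a `pi` deficit and are flagged in the
#' `"boundary"` attribute. Gauss-Bonnet holds: `sum(K) = 2*pi*chi` on closed
#' meshes.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric per-vertex curvature vector.
#' @export
gaussian_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  angsum <- numeric(n)
  for (c in 1:3) {
    i0 <- f[, c]; j0 <- f[, c %% 3 + 1]; k0 <- f[, (c + 1) %% 3 + 1]
    u <- v[j0, , drop = FALSE] - v[i0, , drop = FALSE]
    w <- v[k0, , drop = FALSE] - v[i0, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
    ok <- nu > 1e-12 & nw > 1e-12   # zero-area/degenerate contributions excluded
    ang <- ifelse(ok, acos(pmin(1, pmax(-1, rowSums(u * w) / (nu * nw)))), 0)
    acc <- rowsum(ang, i0)
    angsum[as.integer(rownames(acc))] <- angsum[as.integer(rownames(acc))] + acc
  }
  bvert <- boundary_vertices(mesh)
  K <- 2 * pi - angsum
  K[bvert] <- pi - angsum[bvert]
  attr(K, "boundary") <- bvert
  K
}

# indices of vertices on boundary edges (edges incident to exactly one face)
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkeys <- names(tab)[tab == 1]
  if (!length(bkeys)) return(integer(0))
  unique(as.integer(unlist(strsplit(bkeys, " "))))
}

#' Euler characteristic, genus and boundary census
#'
#' Computes `chi = #V - #E + #F`, the number of boundary loops `b` (edges
#' incident to exactly one face, grouped into loops), the genus from
#' `chi = 2 - 2g` for closed meshes or `chi = 2 - 2g - b` for open ones, and a
#' watertight flag (closed and every edge shared by exactly two faces).
#'
#' @param mesh a `surface_mesh`.
#' @return list with `chi`, `genus`, `n_boundaries`, `watertight`.
#' @export
euler_genus <- function(mesh) {
  f <- mesh$faces
  used <- sort(unique(as.vector(f)))
  nV <- length(used)
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  nE <- length(tab)
  chi <- nV - nE + nrow(f)
  bkeys <- names(tab)[tab == 1]
  nb <- 0L
  if (length(bkeys)) {
    be <- do.call(rbind, strsplit(bkeys, " "))
    g <- igraph::graph_from_edgelist(be, directed = FALSE)
    nb <- igraph::count_components(g)
  }
  genus <- as.integer(round((2 - chi - nb) / 2))
  list(chi = chi, genus = genus, n_boundaries = nb,
       watertight = (nb == 0L) && all(tab == 2))
}

#' Triangle quality: radius ratio
#'
#' Twice the ratio of inradius to circumradius per face, in (0, 1]; an
#' equilateral triangle scores exactly 1, slivers approach 0. Degenerate
#' triangles score 0.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric per-face quality vector.
#' @export
radius_ratio <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- sqrt(rowSums((v[f[, 2], , drop = FALSE] - v[f[, 3], , drop = FALSE])^2))
  b <- sqrt(rowSums((v[f[, 1], , drop = FALSE] - v[f[, 3], , drop = FALSE])^2))
  cc <- sqrt(rowSums((v[f[, 1], , drop = FALSE] - v[f[, 2], , drop = FALSE])^2))
  s <- (a + b + cc) / 2
  area <- face_areas(mesh)
  r_in <- area / pmax(s, 1e-300)
  r_circ <- a * b * cc / pmax(4 * area, 1e-300)
  q <- 2 * r_in / pmax(r_circ, 1e-300)
  q[area <= 1e-12] <- 0
  pmin(q, 1)
}

#' Per-face gradient of a per-vertex scalar
#'
#' Standard first-order finite-element gradient on each triangle:
#' `grad f = (1 / 2A) * sum_i f_i (n x e_i)` with `e_i` the edge opposite
#' vertex `i`.
#'
#' @param mesh a `surface_mesh`.
#' @param values per-vertex numeric vector.
#' @return m x 3 matrix of per-face gradient vectors.
#' @export
mesh_gradient <- function(mesh, values) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  A <- face_areas(mesh)
  g <- matrix(0, nrow(f), 3)
  for (c in 1:3) {
    i0 <- f[, c]
    jj <- f[, c %% 3 + 1]; kk <- f[, (c + 1) %% 3 + 1]
    e <- v[kk, , drop = FALSE] - v[jj, , drop = FALSE]  # edge opposite vertex c
    ne <- cbind(n[, 2] * e[, 3] - n[, 3] * e[, 2],
                n[, 3] * e[, 1] - n[, 1] * e[, 3],
                n[, 1] * e[, 2] - n[, 2] * e[, 1])
    g <- g + values[i0] * ne
  }
  g / pmax(2 * A, 1e-300)
}

# average a per-face quantity (vector or matrix) onto vertices, area-weighted
face_to_vertex <- function(mesh, fvals, weights = face_areas(mesh)) {
  n <- nrow(mesh$vertices)
  fvals <- as.matrix(fvals)
  out <- matrix(0, n, ncol(fvals))
  wsum <- numeric(n)
  for (c in 1:3) {
    idx <- mesh$faces[, c]
    acc <- rowsum(fvals * weights, idx)
    rid <- as.integer(rownames(acc))
    out[rid, ] <- out[rid, ] + acc
    wacc <- rowsum(weights, idx)
    wsum[rid] <- wsum[rid] + wacc
  }
  out <- out / pmax(wsum, 1e-300)
  if (ncol(out) == 1) out[, 1] else out
}

# midpoint (1-to-4) subdivision; repeats until mean edge length < target
subdivide_mesh <- function(mesh, target_edge = 1, max_rounds = 8) {
  for (r in seq_len(max_rounds)) {
    if (mean_edge_length(mesh) < target_edge) break
    v <- mesh$vertices; f <- mesh$faces
    e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(ekey)
    mid_id <- match(ekey, uk) + nrow(v)
    ue <- do.call(rbind, strsplit(uk, " "))
    ue <- cbind(as.integer(ue[, 1]), as.integer(ue[, 2]))
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    newf <- rbind(cbind(f[, 1], m12, m31),
                  cbind(f[, 2], m23, m12),
                  cbind(f[, 3], m31, m23),
                  cbind(m12, m23, m31))
    mesh <- surface_mesh(rbind(v, mids), newf, drop_degenerate = FALSE)
  }
  mesh
}

#' Total surface area and enclosed volume of a closed mesh
#'
#' Volume uses the signed divergence-theorem sum over faces (requires a
#' consistently oriented closed mesh); the absolute value is returned.
#'
#' @param mesh a `surface_mesh`.
#' @return scalar.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
          a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6)
}
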