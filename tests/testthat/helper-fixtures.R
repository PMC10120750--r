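# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# solid ball binary of radius r centred in a cube grid
ball_binary <- function(r, pad = 6) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  a <- array(0, c(n, n, n))
  a[rowSums(sweep(co, 2, ctr)^2) <= r^2] <- 1
  volume_image(a)
}

# parametric torus mesh (closed, genus 1)
torus_mesh <- function(R = 10, r = 3, nu = 24, nv = 16) {
  iu <- seq_len(nu); iv <- seq_len(nv)
  th <- 2 * pi * (iu - 1) / nu
  ph <- 2 * pi * (iv - 1) / nv
  v <- NULL
  for (j in iv) for (i in iu) {
    v <- rbind(v, c((R + r * cos(ph[j])) * cos(th[i]),
                    (R + r * cos(ph[j])) * sin(th[i]),
                    r * sin(ph[j])))
  }
  id <- function(i, j) ((j - 1) %% nv) * nu + ((i - 1) %% nu) + 1
  f <- NULL
  for (j in iv) for (i in iu) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i, j + 1)),
               c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(v, f)
}

# small bumpy phantom + full pipeline run, shared across test files
small_phantom_spec <- function(k = 3, seed = 1) {
  phantom_spec(base_radius = 16, mesh_k = 24, seed = seed, n_protrusions = k)
}

small_pipeline <- function() {
  fixture("small_pipeline", function() {
    spec <- small_phantom_spec()
    mesh <- make_cell_mesh(spec)
    res <- run_unwrap(mesh, pipeline_config(N = 64))
    list(spec = spec, mesh = mesh, res = res)
  })
}

# identity spherical parameterization of an icosphere (no flow needed)
identity_sphere_param <- function(k = 24) {
  ic <- icosphere(k, 1)
  structure(list(sphere_vertices = ic$vertices, source = ic,
                 faces = ic$faces, conformal_error = 1, n_flipped = 0),
            class = "sphere_param")
}

# independent 1D asymmetric Whittaker smoother (dense solve), used as an
# oracle for the 2D ALS on separable profiles
als_1d_oracle <- function(y, p = 0.25, lam = 1, n_iter = 10) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lam * t(D) %*% D
  w <- rep(1 - p, n)
  z <- y
  for (it in seq_len(n_iter)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

# identity spherical parameterization of a sphere of radius r centred at ctr
sphere_space_fixture <- function() {
  fixture("sphere_space", function() {
    ic <- icosphere(24, 1)
    ctr <- c(30, 30, 30)            # coordinate of voxel index (31,31,31)
    src <- surface_mesh(sweep(ic$vertices * 20, 2, -ctr), ic$faces)
    param <- structure(list(sphere_vertices = ic$vertices, source = src,
                            faces = ic$faces), class = "sphere_param")
    uv <- uv_map(param, N = 64)
    a <- array(0, c(61, 61, 61))
    co <- as.matrix(expand.grid(1:61, 1:61, 1:61)) - 1   # voxel coordinates
    a[rowSums(sweep(co, 2, ctr)^2) <= 26^2] <- 1
    cellb <- volume_image(a)
    ts <- build_topographic_space(uv, cellb, alpha = 0.5)
    list(uv = uv, cellb = cellb, ts = ts, ctr = ctr)
  })
}


# heavy shared fixture: default-scale phantom unwrapped at segmentation grade
seg_pipeline <- function() {
  fixture("seg_pipeline", function() {
    spec <- phantom_spec(seed = 1, n_protrusions = 5)
    mesh <- make_cell_mesh(spec)
    res <- run_unwrap(mesh, segmentation_pipeline_config())
    seg <- segment_protrusions(res)
    list(spec = spec, mesh = mesh, res = res, seg = seg)
  })
}

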