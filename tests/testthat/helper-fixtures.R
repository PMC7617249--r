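# Shared fixtures, computed lazily and cached for the session so that
# expensive objects (phantoms, registrations) are built once even when used
# by several test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small random warp on a small space, reused by cost-oracle tests.
small_setup <- function(shape = 12, voxel = 2, knot = 8, sd = 0.8, seed = 3) {
  set.seed(seed)
  sp <- warp_space(rep(shape, 3), voxel)
  g <- knot_grid(sp, knot)
  w <- warp_field(g, matrix(rnorm(3 * g$M, sd = sd), 3))
  list(space = sp, grid = g, warp = w)
}

rand_image <- function(shape = 12, voxel = 2, seed = 10) {
  set.seed(seed)
  image3d(array(runif(prod(rep(shape, 3))), rep(shape, 3)), voxel)
}

rand_tensor <- function(shape = 10, voxel = 2, seed = 11, base = 1.5e-3,
                        sd = 0.3e-3) {
  set.seed(seed)
  n3 <- prod(rep(shape, 3))
  a <- array(rnorm(n3 * 6, sd = sd), c(rep(shape, 3), 6))
  a[, , , c(1, 4, 6)] <- a[, , , c(1, 4, 6)] + base
  tensor_volume(a, voxel)
}

# Independent dense residual-Jacobian column for the MSE cost: direct
# per-spline B-spline products, no shared code with the assembly engine.
dense_bspline_products <- function(grid, vox, m, ord = c(0, 0, 0)) {
  cnt <- grid$counts
  mx <- m %% cnt[1]
  my <- (m %/% cnt[1]) %% cnt[2]
  mz <- m %/% (cnt[1] * cnt[2])
  t1 <- vox[, 1] / grid$spacing_vox[1] + 1
  t2 <- vox[, 2] / grid$spacing_vox[2] + 1
  t3 <- vox[, 3] / grid$spacing_vox[3] + 1
  bspline3(t1 - mx, ord[1]) * bspline3(t2 - my, ord[2]) *
    bspline3(t3 - mz, ord[3])
}

# Finite-difference gradient of a scalar function of the warp coefficients.
fd_warp_grad <- function(fn, w, idx, eps = 1e-5) {
  M <- w$grid$M
  vapply(idx, function(i) {
    d <- (i - 1) %/% M + 1
    m <- (i - 1) %% M + 1
    wp <- w; wm <- w
    wp$coeffs[d, m] <- wp$coeffs[d, m] + eps
    wm$coeffs[d, m] <- wm$coeffs[d, m] - eps
    (fn(wp) - fn(wm)) / (2 * eps)
  }, numeric(1))
}
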