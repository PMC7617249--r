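# Scalar MSE cost: robust scaling, closed-form cases, brute-force oracle
# equality, finite-difference gradients and the dense Gauss-Newton Hessian
# oracle.

test_that("robust scaling normalises the median and is scale-equivariant", {
  const <- image3d(array(2.5, c(6, 6, 6)))
  expect_equal(robust_scale(const), 1 / 2.5)
  set.seed(1)
  img <- image3d(array(runif(6^3, 0.5, 2), c(6, 6, 6)))
  img2 <- img
  img2$data <- img$data * 2
  expect_equal(robust_scale(img), 2 * robust_scale(img2))
  # 1% extreme outliers barely move the factor
  dirty <- img
  dirty$data[sample(6^3, 2)] <- 1e4
  expect_lt(abs(robust_scale(dirty) / robust_scale(img) - 1), 0.05)
  # all-zero image has no defined scale
  expect_error(robust_scale(image3d(array(0, c(4, 4, 4)))), "all-zero")
})

test_that("MSE closed forms: identical pair and constant offset", {
  f <- rand_image(10, 1, seed = 2)
  id <- warp_field(knot_grid(space_of(f), 5))
  expect_equal(mse_cost(f, f, id, sym_weight = 2), 0)
  g <- f
  g$data <- f$data + 0.7
  expect_equal(mse_cost(f, g, id, sym_weight = 2), 2 * 0.7^2, tolerance = 1e-12)
  # identity warp has |J| = 1, so the computed weight is exactly 2
  expect_equal(mse_cost(f, g, id), 2 * 0.7^2, tolerance = 1e-12)
})

test_that("MSE equals a literal voxel-loop evaluation of the cost", {
  su <- small_setup(shape = 16, voxel = 2, knot = 10, sd = 1.2, seed = 31)
  f <- rand_image(16, 2, seed = 32)
  g <- rand_image(16, 2, seed = 33)
  C <- mse_cost(f, g, su$warp, sym_weight = 1)
  sc <- spline_prep(g$data)
  tot <- 0
  N <- 16^3
  for (k in 0:(N - 1)) {
    x <- c(k %% 16, (k %/% 16) %% 16, k %/% 256)
    phi <- apply_warp(su$warp, matrix(x, 1))          # world mm
    gv <- spline_sample(sc, phi / 2)                  # voxel = world / 2
    if (gv$inside) tot <- tot + (f$data[k + 1] - gv$value)^2
  }
  expect_equal(C, tot / N, tolerance = 1e-10)
})

test_that("zero-weight mask voxels contribute exactly nothing", {
  su <- small_setup(shape = 10, voxel = 2, knot = 8, sd = 0.6, seed = 41)
  f <- rand_image(10, 2, seed = 42)
  g <- rand_image(10, 2, seed = 43)
  set.seed(44)
  keep <- array(as.numeric(runif(10^3) > 0.3), c(10, 10, 10))
  m <- image3d(keep, 2)
  C_masked <- mse_cost(f, g, su$warp, ref_mask = m, sym_weight = 1)
  # direct recomputation of the masked sum from per-voxel terms
  vox <- space_grid(su$space)
  phi <- apply_warp(su$warp, vox)
  fs <- spline_sample(spline_prep(f$data), vox)
  gs <- spline_sample(spline_prep(g$data), phi / 2)
  term <- (fs$value - gs$value)^2
  term[!gs$inside] <- 0
  expect_identical(C_masked, sum(as.numeric(keep) * 1 * term) / length(term))
})

test_that("MSE gradient matches central finite differences", {
  su <- small_setup(shape = 12, voxel = 2, knot = 8, sd = 0.8, seed = 51)
  f <- rand_image(12, 2, seed = 52)
  g <- rand_image(12, 2, seed = 53)
  gh <- mse_grad_hess(f, g, su$warp, sym_weight = 1)
  set.seed(54)
  idx <- sample(3 * su$grid$M, 30)
  fd <- fd_warp_grad(function(w) mse_cost(f, g, w, sym_weight = 1),
                     su$warp, idx)
  expect_lt(max(abs(fd - gh$grad[idx])) / max(abs(gh$grad)), 1e-4)
})

test_that("GN Hessian equals the dense residual-Jacobian oracle", {
  su <- small_setup(shape = 12, voxel = 2, knot = 10, sd = 0.8, seed = 61)
  f <- rand_image(12, 2, seed = 62)
  g <- rand_image(12, 2, seed = 63)
  gh <- mse_grad_hess(f, g, su$warp, sym_weight = 1)
  # explicit residual Jacobian, column by column, from first principles:
  # d r(x) / d w_(m,d) = -sqrt(1/N) dg/dx_d(phi(x)) b_m(x)
  vox <- space_grid(su$space)
  N <- nrow(vox)
  phi <- apply_warp(su$warp, vox)
  sc <- spline_prep(g$data)
  gr <- vapply(1:3, function(a) {
    dv <- c(0L, 0L, 0L); dv[a] <- 1L
    spline_sample(sc, phi / 2, dv)$value / 2    # world gradient (voxel 2 mm)
  }, numeric(N))
  inside <- spline_sample(sc, phi / 2)$inside
  gr[!inside, ] <- 0
  M <- su$grid$M
  Jr <- matrix(0, N, 3 * M)
  for (m in 0:(M - 1)) {
    b <- dense_bspline_products(su$grid, vox, m)
    for (d in 1:3)
      Jr[, (d - 1) * M + m + 1] <- -sqrt(1 / N) * gr[, d] * b
  }
  Ho <- 2 * crossprod(Jr)
  expect_lt(max(abs(gh$H - Ho)) / max(abs(Ho)), 1e-12)
  # gradient from the same oracle
  r <- sqrt(1 / N) * (as.numeric(f$data) - spline_sample(sc, phi / 2)$value)
  r[!inside] <- 0
  expect_lt(max(abs(gh$grad - 2 * as.numeric(crossprod(Jr, r)))) /
              max(abs(gh$grad)), 1e-12)
  # PSD check
  ev <- eigen(as.matrix(gh$H), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(abs(ev)))
})

test_that("constant moving image gives zero gradient and Hessian", {
  su <- small_setup(shape = 8, voxel = 2, knot = 8, sd = 0.5, seed = 71)
  f <- rand_image(8, 2, seed = 72)
  g <- image3d(array(0.6, c(8, 8, 8)), 2)
  gh <- mse_grad_hess(f, g, su$warp, sym_weight = 1)
  # the image gradient of a constant volume vanishes (up to round-off in
  # the interpolation coefficients), and with it every Hessian entry
  expect_lt(max(abs(gh$grad)), 1e-12)
  expect_lt(max(abs(gh$H)), 1e-24)
})

test_that("cost is invariant to joint rescaling after robust scaling", {
  su <- small_setup(shape = 8, voxel = 2, knot = 8, sd = 0.4, seed = 81)
  f <- rand_image(8, 2, seed = 82)
  g <- rand_image(8, 2, seed = 83)
  scale_pair <- function(f, g, k) {
    f$data <- f$data * k
    g$data <- g$data * k
    f$data <- f$data * robust_scale(f)
    g$data <- g$data * robust_scale(g)
    mse_cost(f, g, su$warp, sym_weight = 1)
  }
  expect_equal(scale_pair(f, g, 1), scale_pair(f, g, 37.5), tolerance = 1e-12)
})
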