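# Optimiser: schedule constants, Nyquist subsampling, the damped
# Gauss-Newton machinery, determinism, and the fit-object methods.

test_that("default schedule reproduces the documented hyperparameters", {
  s <- default_schedule(1)
  expect_equal(s$knot_mm, c(16, 8, 4, 2, 1))
  expect_equal(s$fwhm_mm[s$knot_mm == 16], 4)   # quarter of warp resolution
  expect_equal(s$fwhm_mm[s$knot_mm == 8], 2)
  expect_equal(s$lambda_reg[s$knot_mm == 1], 0.18)
  expect_equal(s$lambda_reg[s$knot_mm == 2], 0.21)
  expect_equal(s$lambda_reg[s$knot_mm == 4], 0.25)
  expect_equal(default_schedule(4)$knot_mm, c(16, 8, 4))
})

test_that("subsampling obeys the Nyquist rule and its clamps", {
  expect_equal(subsample_for(0, 8), 2)          # floor: knot / 4
  expect_equal(subsample_for(1000, 8), 8)       # ceiling: knot
  s <- subsample_for(4, 16)
  expect_true(s >= 4 && s <= 16)
  expect_lte(s, 4 / 2 + 4)                      # within the clamped band
  # a sinusoid at the retained band limit survives smoothing + subsampling
  # without aliasing: frequencies above the new Nyquist are suppressed
  n <- 64
  x <- 0:(n - 1)
  hi <- sin(2 * pi * x / 2.5)                   # above Nyquist of step 2
  arr <- array(rep(hi, n * n), c(n, n, n))
  sm <- mmreg:::gauss_smooth(arr, fwhm_mm = 4, voxel_size = 1)
  # interior response (edge rows see a renormalised, one-sided kernel)
  expect_lt(max(abs(sm[17:48, 1, 1])) / max(abs(arr[, 1, 1])), 0.01)
})

test_that("conjugate gradients match a dense solve on a GN system", {
  su <- small_setup(shape = 10, voxel = 2, knot = 10, sd = 0.5, seed = 91)
  f <- rand_image(10, 2, seed = 92)
  g <- rand_image(10, 2, seed = 93)
  gh <- mse_grad_hess(f, g, su$warp, sym_weight = 1)
  H <- gh$H + 0.1 * mean(Matrix::diag(gh$H)) *
    Matrix::Diagonal(3 * su$grid$M)
  b <- gh$grad
  sol <- mmreg:::.pcg(H, b, tol = 1e-10, maxit = 2000)
  expect_true(sol$ok)
  dense <- solve(as.matrix(H), b)
  expect_lt(max(abs(sol$x - dense)) / max(abs(dense)), 1e-6)
})

test_that("registering an image to itself keeps the identity warp", {
  spec <- phantom_spec(shape = 16, n_blobs = 4, noise_sd = 0, seed = 21,
                       warp_amplitude_vox = 0)
  ph <- make_scalar_phantom(spec)
  fit <- mmreg(ref_scalar = ph$image, mov_scalar = ph$image,
               schedule = default_schedule(8))
  d <- warp_to_volume(fit$warp)
  expect_lt(mean(sqrt(rowSums(matrix(d, ncol = 3)^2))), 0.05)
  expect_equal(fit$diffeo$frac_nonpos, 0)
})

test_that("accepted total-cost sequence is monotone within levels", {
  spec <- phantom_spec(shape = 16, n_blobs = 5, seed = 22,
                       warp_amplitude_vox = 1.5, warp_knot_mm = 8)
  ph <- make_scalar_phantom(spec)
  mov <- warp_forward(ph, make_ground_truth_warp(spec))
  fit <- mmreg(ref_scalar = ph$image, mov_scalar = mov$image,
               schedule = default_schedule(8))
  for (lv in split(fit$trace, fit$trace$level)) {
    acc <- lv$total[lv$accepted]
    if (length(acc) > 1) expect_true(all(diff(acc) < 0))
  }
  expect_gt(sum(fit$trace$accepted), 0)
})

test_that("registration is deterministic", {
  spec <- phantom_spec(shape = 16, n_blobs = 5, seed = 23,
                       warp_amplitude_vox = 1.5, warp_knot_mm = 8)
  ph <- make_scalar_phantom(spec)
  mov <- warp_forward(ph, make_ground_truth_warp(spec))
  run <- function() mmreg(ref_scalar = ph$image, mov_scalar = mov$image,
                          schedule = default_schedule(8))
  f1 <- run()
  f2 <- run()
  vox <- space_grid(f1$space)
  dd <- abs(warp_displacement(f1$warp, vox) - warp_displacement(f2$warp, vox))
  expect_lt(max(dd), 1e-3)
})

test_that("inverse-consistency error: identity pair and exact inverses", {
  sp <- warp_space(c(12, 12, 12), 1)
  g <- knot_grid(sp, 6)
  id <- warp_field(g)
  e0 <- ic_error(id, id)
  expect_equal(e0$mean_mm, 0)
  expect_equal(e0$max_mm, 0)
  # backward = numerical inverse of forward: near-zero error
  su <- small_setup(shape = 12, voxel = 1, knot = 6, sd = 0.4, seed = 24)
  vox <- space_grid(su$space)
  world <- xform_pts(su$space$affine, vox)
  xin <- invert_warp_at(su$warp, world, tol = 1e-8)
  inv_disp <- xform_pts(su$space$affine, xin) - world
  wb <- fit_warp_to_displacement(knot_grid(su$space, 3), vox, inv_disp)
  e <- ic_error(su$warp, wb)
  expect_lt(e$mean_mm, 0.02)
})

test_that("fit object methods behave", {
  spec <- phantom_spec(shape = 16, n_blobs = 4, seed = 25,
                       warp_amplitude_vox = 1, warp_knot_mm = 8)
  ph <- make_scalar_phantom(spec)
  mov <- warp_forward(ph, make_ground_truth_warp(spec))
  fit <- mmreg(ref_scalar = ph$image, mov_scalar = mov$image,
               schedule = default_schedule(8),
               log_file = file.path(tempdir(), "fit.jsonl"))
  expect_s3_class(fit, "mmreg_fit")
  expect_equal(dim(coef(fit)), c(3, fit$warp$grid$M))
  expect_output(print(fit), "registration fit")
  s <- summary(fit)
  expect_output(print(s), "Per-level")
  pc <- predict(fit, type = "coords")
  expect_equal(dim(pc), c(prod(fit$space$shape), 3))
  pi <- predict(fit, type = "image")
  expect_s3_class(pi, "image3d")
  # warped moving image approximates the reference inside the mask
  msk <- ph$mask$data > 0.5
  expect_lt(mean(abs(pi$data[msk] - ph$image$data[msk])),
            0.1 * diff(range(ph$image$data)))
  r <- residuals(fit)
  expect_true(all(is.finite(r$data)))
  # JSON-lines log has one record per Gauss-Newton step
  log <- readLines(file.path(tempdir(), "fit.jsonl"))
  expect_equal(length(log), nrow(fit$trace))
  rec <- jsonlite::fromJSON(log[1])
  expect_true(all(c("level", "iter", "Cs", "Cr", "total") %in% names(rec)))
})
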