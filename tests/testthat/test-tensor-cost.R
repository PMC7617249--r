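# Tensor cost: finite-strain rotation properties, closed-form Frobenius
# cases, equivalence with per-element MSE, gradients including the rotation
# term, and finite-strain tensor resampling.

rotmat <- function(axis, th) {
  c1 <- cos(th); s1 <- sin(th)
  if (axis == 3) matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3)
  else if (axis == 1) matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3)
  else matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3)
}

test_that("finite-strain rotation: identity, rotations and SPD Jacobians", {
  expect_equal(finite_strain_rotation(diag(3)), diag(3))
  Q <- rotmat(3, 0.7) %*% rotmat(1, -0.3)
  expect_equal(finite_strain_rotation(Q), Q, tolerance = 1e-12)
  # symmetric positive-definite J carries no rotation
  expect_equal(finite_strain_rotation(diag(c(2, 1, 1))), diag(3),
               tolerance = 1e-12)
  S <- crossprod(matrix(c(1, .2, 0, .1, 1.5, 0, 0, .3, 0.8), 3)) + diag(3)
  expect_equal(finite_strain_rotation(S), diag(3), tolerance = 1e-10)
  expect_error(finite_strain_rotation(diag(c(-1, 1, 1))), "determinant")
})

test_that("polar factor is a proper rotation across random Jacobians", {
  set.seed(1)
  n <- 10000
  J <- matrix(0, n, 9)
  k <- 0
  while (k < n) {
    A <- diag(3) + matrix(rnorm(9, sd = 0.45), 3)
    if (det(A) > 0.2 && det(A) < 5) {
      k <- k + 1
      J[k, ] <- as.numeric(A)
    }
  }
  R <- finite_strain_rotation(J)
  worst_orth <- 0
  worst_det <- 0
  for (i in seq_len(n)) {
    Ri <- matrix(R[i, ], 3)
    worst_orth <- max(worst_orth, max(abs(crossprod(Ri) - diag(3))))
    worst_det <- max(worst_det, abs(det(Ri) - 1))
  }
  expect_lt(worst_orth, 1e-10)
  expect_lt(worst_det, 1e-10)
})

test_that("Frobenius cost closed forms: identical and isotropic pairs", {
  mk_iso <- function(v, n = 10) {
    a <- array(0, c(n, n, n, 6))
    a[, , , c(1, 4, 6)] <- v
    tensor_volume(a, 2)
  }
  Fv <- mk_iso(1)
  Gv <- mk_iso(0.4)
  id <- warp_field(knot_grid(space_of(Fv), 8))
  expect_equal(msfn_cost(Fv, Fv, id), 0)
  expect_equal(msfn_cost(Fv, Gv, id, sym_weight = 2), 2 * 3 * (1 - 0.4)^2,
               tolerance = 1e-12)
})

test_that("Frobenius cost equals the sum of nine per-element MSE costs", {
  su <- small_setup(shape = 10, voxel = 2, knot = 8, sd = 0.5, seed = 21)
  Fr <- rand_tensor(10, 2, seed = 22, base = 1.5, sd = 0.3)
  G <- rand_tensor(10, 2, seed = 23, base = 1.5, sd = 0.3)
  C <- msfn_cost(Fr, G, su$warp, sym_weight = 1)
  # per-element MSE with linear interpolation on the rotated reference
  vox <- space_grid(su$space)
  phi <- apply_warp(su$warp, vox)
  J <- warp_jacobian(su$warp, vox)
  mult <- c(1, 2, 2, 1, 2, 1)
  tot <- 0
  for (k in 1:6) {
    Gk <- trilinear_sample(G$data[, , , k], phi / 2)
    RFk <- numeric(nrow(vox))
    for (i in seq_len(nrow(vox))) {
      R <- finite_strain_rotation(matrix(J[i, ], 3))
      Fm <- matrix(c(Fr$data[, , , 1][i], Fr$data[, , , 2][i], Fr$data[, , , 3][i],
                     Fr$data[, , , 2][i], Fr$data[, , , 4][i], Fr$data[, , , 5][i],
                     Fr$data[, , , 3][i], Fr$data[, , , 5][i], Fr$data[, , , 6][i]), 3)
      RF <- R %*% Fm %*% t(R)
      RFk[i] <- RF[c(1, 1, 1, 2, 2, 3)[k], c(1, 2, 3, 2, 3, 3)[k]]
    }
    term <- (RFk - Gk$value)^2
    term[!Gk$inside] <- 0
    tot <- tot + mult[k] * sum(term * Gk$inside) / nrow(vox)
  }
  expect_equal(C, tot, tolerance = 1e-10)
})

test_that("tensor gradient matches finite differences, rotation included", {
  su <- small_setup(shape = 10, voxel = 2, knot = 8, sd = 0.6, seed = 31)
  Fr <- rand_tensor(10, 2, seed = 32, base = 1.5, sd = 0.3)
  G <- rand_tensor(10, 2, seed = 33, base = 1.5, sd = 0.3)
  gh <- msfn_grad_hess(Fr, G, su$warp, sym_weight = 1)
  set.seed(34)
  idx <- sample(3 * su$grid$M, 20)
  fd <- fd_warp_grad(function(w) msfn_cost(Fr, G, w, sym_weight = 1),
                     su$warp, idx)
  expect_lt(max(abs(fd - gh$grad[idx])) / max(abs(gh$grad)), 1e-3)
})

test_that("disabling the rotation term changes the gradient of an
           anisotropic field", {
  su <- small_setup(shape = 10, voxel = 2, knot = 8, sd = 0.6, seed = 41)
  Fr <- rand_tensor(10, 2, seed = 42, base = 1.5, sd = 0.4)
  G <- rand_tensor(10, 2, seed = 43, base = 1.5, sd = 0.4)
  g_on <- msfn_grad_hess(Fr, G, su$warp, sym_weight = 1)
  g_off <- msfn_grad_hess(Fr, G, su$warp, sym_weight = 1,
                          rotation_term = FALSE)
  expect_gt(sqrt(sum((g_on$grad - g_off$grad)^2)), 0)
  # identical constant isotropic fields sit at the global minimum
  mk_iso <- function(v, n = 8) {
    a <- array(0, c(n, n, n, 6))
    a[, , , c(1, 4, 6)] <- v
    tensor_volume(a, 2)
  }
  id <- warp_field(knot_grid(warp_space(c(8, 8, 8), 2), 8))
  gh0 <- msfn_grad_hess(mk_iso(1), mk_iso(1), id, sym_weight = 1)
  expect_lt(max(abs(gh0$grad)), 1e-12)
})

test_that("GN tensor Hessian equals a finite-difference residual Jacobian", {
  su <- small_setup(shape = 8, voxel = 2, knot = 8, sd = 0.5, seed = 51)
  Fr <- rand_tensor(8, 2, seed = 52, base = 1.5, sd = 0.3)
  G <- rand_tensor(8, 2, seed = 53, base = 1.5, sd = 0.3)
  gh <- msfn_grad_hess(Fr, G, su$warp, sym_weight = 1)
  resids <- function(w) {
    p <- mmreg:::.msfn_parts(Fr, G, w, NULL, NULL, 1, NULL)
    rt <- mmreg:::cpp_rotation_terms(p$J, p$Fv)
    as.numeric((rt$RFRt - p$Gv) *
                 (sqrt(p$w * p$sw / p$N) %o% sqrt(c(1, 2, 2, 1, 2, 1))))
  }
  r0 <- resids(su$warp)
  eps <- 1e-6
  M <- su$grid$M
  Jr <- matrix(0, length(r0), 3 * M)
  for (i in seq_len(3 * M)) {
    wp <- su$warp
    d <- (i - 1) %/% M + 1
    m <- (i - 1) %% M + 1
    wp$coeffs[d, m] <- wp$coeffs[d, m] + eps
    Jr[, i] <- (resids(wp) - r0) / eps
  }
  Ho <- 2 * crossprod(Jr)
  expect_lt(max(abs(gh$H - Ho)) / max(abs(Ho)), 1e-5)
})

test_that("tensor resampling: identity, rigid rotation, eigenvalue
           preservation", {
  Fr <- rand_tensor(10, 2, seed = 61, base = 1.5e-3, sd = 0.3e-3)
  sp <- space_of(Fr)
  id <- warp_field(knot_grid(sp, 8))
  out <- resample_tensors(Fr, id)
  expect_equal(out$data, Fr$data, tolerance = 1e-9)
  # nonrigid smooth warp: eigenvalues equal those of the interpolated
  # pre-rotation tensors (reorientation is an orthogonal conjugation)
  su <- small_setup(shape = 10, voxel = 2, knot = 10, sd = 0.8, seed = 62)
  out2 <- resample_tensors(Fr, su$warp)
  vox <- space_grid(sp)
  phi <- apply_warp(su$warp, vox)
  pre <- vapply(1:6, function(k)
    trilinear_sample(Fr$data[, , , k], phi / 2)$value, numeric(nrow(vox)))
  ev_pre <- mmreg:::cpp_tensor_eigen(pre)$L
  ev_post <- mmreg:::cpp_tensor_eigen(matrix(out2$data, ncol = 6))$L
  inside <- attr(phi, "inside") &
    trilinear_sample(Fr$data[, , , 1], phi / 2)$inside
  expect_lt(max(abs(ev_pre[inside, ] - ev_post[inside, ])), 1e-10)
})

test_that("a global rigid rotation is undone by the reorientation", {
  # moving tensors constructed as G(phi(x)) = R F R^T; resampling must
  # reproduce the reference exactly (interior voxels)
  n <- 12
  sp <- warp_space(c(n, n, n), 1)
  grid <- knot_grid(sp, 4)
  Q <- rotmat(3, 0.15)
  ctr <- xform_pts(sp$affine, matrix((n - 1) / 2, 1, 3))
  # rigid warp about the centre: phi(x) = Q (x - c) + c
  voxk <- space_grid(warp_space(grid$counts, 1))
  kvox <- sweep(voxk, 2, c(1, 1, 1)) * rep(grid$spacing_vox, each = nrow(voxk))
  kw <- xform_pts(sp$affine, kvox)
  disp <- sweep(kw, 2, as.numeric(ctr)) %*% t(Q) +
    matrix(ctr, nrow(kw), 3, byrow = TRUE) - kw
  wq <- warp_field(grid, t(disp))
  # tensor components linear in position, so trilinear interpolation is
  # exact and the only error sources are the rotation handling itself and
  # the fixed-point inversion tolerance
  vox <- space_grid(sp)
  slope <- matrix(c(2, -1, 1, 0.5, -0.8, 1.2,
                    1, 2, -0.5, 0.3, 1.1, -0.9,
                    -1, 0.5, 2, -0.2, 0.7, 0.4), 3, 6) * 1e-5
  comp <- matrix(rep(c(1.5, 0.1, 0.05, 1.4, 0.08, 1.6) * 1e-3,
                     each = nrow(vox)), ncol = 6) + vox %*% slope
  Fr <- tensor_volume(array(comp, c(n, n, n, 6)), 1)
  mov <- warp_forward(list(tensor = Fr), wq)
  out <- resample_tensors(mov$tensor, wq)
  core <- array(FALSE, c(n, n, n))
  core[4:9, 4:9, 4:9] <- TRUE
  for (k in 1:6) {
    d <- abs(out$data[, , , k] - Fr$data[, , , k])
    expect_lt(max(d[core]), 1e-7)
  }
})
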