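# Evaluation metrics: Jaccard and modified Hausdorff against brute-force
# oracles, tensor similarity closed forms, and distortion measures.

test_that("Jaccard closed forms", {
  a <- array(FALSE, c(20, 12, 12))
  a[3:12, 2:11, 2:11] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b <- array(FALSE, c(20, 12, 12))
  b[8:17, 2:11, 2:11] <- TRUE             # same cube shifted 5 voxels in x
  expect_equal(jaccard(a, b), 500 / 1500)
  d <- array(FALSE, c(20, 12, 12))
  d[18:19, 1:2, 1:2] <- TRUE
  expect_equal(jaccard(a, d), 0)
  expect_true(is.na(jaccard(a & FALSE, d & FALSE)))
})

test_that("MHD closed forms: identical regions and parallel slabs", {
  a <- array(FALSE, c(16, 8, 8))
  a[4, 2:7, 2:7] <- TRUE                   # unit-thickness slab
  expect_equal(mhd(a, a), 0)
  b <- array(FALSE, c(16, 8, 8))
  b[9, 2:7, 2:7] <- TRUE                   # 5 voxels away
  expect_equal(mhd(a, b), 5)
  expect_equal(mhd(a, b, voxel_size = 2), 10)
  expect_error(mhd(a, a & FALSE), "nonempty")
})

test_that("JI and MHD match brute-force oracles on random label pairs", {
  set.seed(3)
  for (rep in 1:50) {
    n <- c(10, 10, 10)
    mk <- function() {
      a <- array(FALSE, n)
      ctr <- runif(3, 3, 7)
      rad <- runif(1, 1.5, 3.5)
      vox <- space_grid(warp_space(n))
      a[rowSums(sweep(vox, 2, ctr)^2) <= rad^2] <- TRUE
      a
    }
    A <- mk()
    B <- mk()
    if (sum(A) == 0 || sum(B) == 0) next
    # JI oracle: direct set counting
    expect_identical(jaccard(A, B), sum(A & B) / sum(A | B))
    # MHD oracle: O(N^2) double loop over surface voxels
    sa <- mmreg:::.surface_voxels(A)
    sb <- mmreg:::.surface_voxels(B)
    da <- vapply(seq_len(nrow(sa)), function(i)
      sqrt(min(rowSums(sweep(sb, 2, sa[i, ])^2))), numeric(1))
    db <- vapply(seq_len(nrow(sb)), function(i)
      sqrt(min(rowSums(sweep(sa, 2, sb[i, ])^2))), numeric(1))
    expect_lt(abs(mhd(A, B) - max(mean(da), mean(db))), 1e-9)
  }
})

test_that("tensor similarity: identical fields, shape coefficients, and
           orthogonal eigenvectors", {
  Fr <- rand_tensor(6, 1, seed = 4, base = 1.5e-3, sd = 0.2e-3)
  sim <- dti_similarity(Fr, Fr)
  expect_lt(max(abs(sim$maps$OVL - 1), na.rm = TRUE), 1e-10)
  expect_equal(sim$n_excluded, 0L)
  # closed-form CL / CP: eigenvalues (1,0,0) -> CL = 1; (1,1,0) -> CP = 1
  lin <- array(0, c(2, 2, 2, 6))
  lin[, , , 1] <- 1                              # diag(1, 0, 0)
  pla <- array(0, c(2, 2, 2, 6))
  pla[, , , c(1, 4)] <- 1                        # diag(1, 1, 0)
  sim_l <- dti_similarity(tensor_volume(lin, 1), tensor_volume(lin, 1))
  expect_equal(unique(as.numeric(sim_l$maps$CL)), 1)
  sim_p <- dti_similarity(tensor_volume(pla, 1), tensor_volume(pla, 1))
  expect_equal(unique(as.numeric(sim_p$maps$CP)), 1)
  # V1 of the moving field perpendicular to V1 of the reference: CLV1 = 0
  linY <- array(0, c(2, 2, 2, 6))
  linY[, , , 4] <- 1                             # diag(0, 1, 0)
  sim_perp <- dti_similarity(tensor_volume(lin, 1), tensor_volume(linY, 1))
  expect_equal(unique(as.numeric(sim_perp$maps$CLV1)), 0)
  # bounds: OVL in [0,1], CLV1 <= CL, CPV3 <= CP
  G <- rand_tensor(6, 1, seed = 5, base = 1.5e-3, sd = 0.2e-3)
  s2 <- dti_similarity(Fr, G)
  expect_true(all(s2$maps$OVL >= -1e-12 & s2$maps$OVL <= 1 + 1e-12))
  expect_true(all(s2$maps$CLV1 <= s2$maps$CL + 1e-12))
  expect_true(all(s2$maps$CPV3 <= s2$maps$CP + 1e-12))
})

test_that("zero-trace tensors are excluded and counted", {
  a <- array(0, c(3, 3, 3, 6))
  a[, , , c(1, 4, 6)] <- 1e-3
  a[1, 1, 1, ] <- 0
  tv <- tensor_volume(a, 1)
  sim <- dti_similarity(tv, tv, mask = array(TRUE, c(3, 3, 3)))
  expect_equal(sim$n_excluded, 1L)
  expect_true(is.na(sim$maps$OVL[1, 1, 1]))
})

test_that("CVAR closed forms and lower bound", {
  expect_equal(cvar(diag(3)), 1)
  expect_equal(cvar(diag(c(2, 1, 1))), 4^(1 / 3))
  th <- 0.5
  Q <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(cvar(Q), 1, tolerance = 1e-12)
  expect_equal(cvar(2.7 * Q), 1, tolerance = 1e-12)  # scaled rotation
  set.seed(6)
  J <- matrix(rep(as.numeric(diag(3)), 500), 500, byrow = TRUE) +
    matrix(rnorm(4500, sd = 0.3), 500)
  expect_true(all(cvar(J) >= 1 - 1e-12))
})

test_that("distortion of identity and of an anisotropic stretch", {
  sp <- warp_space(c(10, 10, 10), 1)
  g <- knot_grid(sp, 5)
  d0 <- distortion(warp_field(g))
  expect_equal(d0$logj_range, 0)
  expect_equal(d0$mean_cvar, 1)
  # global stretch J = diag(2, 1, 1): CVAR = 4^(1/3), log|J| range 0
  knots <- space_grid(warp_space(g$counts, 1))
  kw <- xform_pts(sp$affine,
                  sweep(knots, 2, c(1, 1, 1)) * rep(g$spacing_vox,
                                                    each = nrow(knots)))
  ws <- warp_field(g, t(cbind(kw[, 1], 0 * kw[, 1], 0 * kw[, 1])))
  ds <- distortion(ws)
  expect_equal(ds$mean_cvar, 4^(1 / 3), tolerance = 1e-10)
  expect_lt(ds$logj_range, 1e-10)
})

test_that("label_overlap tabulates per-label JI and MHD", {
  la <- array(0L, c(8, 8, 8))
  la[2:4, 2:4, 2:4] <- 1L
  la[6:7, 6:7, 6:7] <- 2L
  lb <- la
  lb[2:4, 2:4, 2:4] <- 0L
  lb[3:5, 2:4, 2:4] <- 1L
  tab <- label_overlap(la, lb)
  expect_equal(tab$label, c(1, 2))
  expect_equal(tab$jaccard[2], 1)
  expect_equal(tab$jaccard[1], sum(la == 1 & lb == 1) / sum(la == 1 | lb == 1))
})
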