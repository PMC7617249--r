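## Deterministic synthetic phantoms: multi-blob scalar volumes with labels
## and a brain-like mask, tensor volumes with prolate tracts and oblate
## sheets, known diffeomorphic ground-truth warps, and the forward
## simulation that produces a "moving subject" from them.  Every generator
## is fully determined by the seed in the spec.

## Run expr with a local RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Specification of a synthetic phantom
#'
#' @param shape voxel counts per axis (default 48^3).
#' @param voxel_mm voxel size in mm.
#' @param n_blobs number of Gaussian blob structures in the scalar phantom.
#' @param noise_sd additive Gaussian noise, as a fraction of the clean
#'   intensity range (applied to the scalar image only).
#' @param bias_amplitude standard deviation of the log bias field's spline
#'   coefficients used by [warp_forward()] when a bias is requested.
#' @param warp_amplitude_vox maximum ground-truth displacement in voxels.
#' @param warp_knot_mm knot spacing of the ground-truth warp.
#' @param seed RNG seed; the seed fully determines every generated volume.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = 48, voxel_mm = 1, n_blobs = 25,
                         noise_sd = 0.02, bias_amplitude = 0.15,
                         warp_amplitude_vox = 4, warp_knot_mm = 12,
                         seed = 1) {
  structure(list(shape = as.integer(rep_len(shape, 3)),
                 voxel_mm = voxel_mm, n_blobs = n_blobs,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 warp_amplitude_vox = warp_amplitude_vox,
                 warp_knot_mm = warp_knot_mm, seed = seed),
            class = "phantom_spec")
}

## Voxel-coordinate grid and a centred spherical mask profile.
.phantom_geom <- function(spec) {
  n <- spec$shape
  sp <- warp_space(n, spec$voxel_mm)
  vox <- space_grid(sp)
  ctr <- (n - 1) / 2
  rel <- sweep(vox, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  rmax <- min(n - 1) / 2
  list(space = sp, vox = vox, rel = rel, r = r, rmax = rmax)
}

#' Generate a scalar phantom with labels and mask
#'
#' A smooth multi-blob volume inside a spherical head-like mask.  Blob
#' centres are rejection-sampled so that blob supports (within two standard
#' deviations) are disjoint; the integer label volume marks exactly those
#' supports, so each labelled region coincides with its analytic support.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` ([image3d()]), `labels` (integer [image3d()]),
#'   `mask` ([image3d()]), and `blobs` (the sampled blob table).
#' @export
make_scalar_phantom <- function(spec) {
  g <- .phantom_geom(spec)
  n <- spec$shape
  .with_seed(spec$seed, {
    ## spherical mask with a soft rim
    r0 <- 0.88 * g$rmax
    r1 <- 0.98 * g$rmax
    mask <- ifelse(g$r <= r0, 1,
                   ifelse(g$r >= r1, 0, 0.5 * (1 + cos(pi * (g$r - r0) / (r1 - r0)))))
    ## disjoint blobs
    blobs <- NULL
    tries <- 0
    while ((is.null(blobs) || nrow(blobs) < spec$n_blobs) && tries < 4000) {
      tries <- tries + 1
      sd_new <- stats::runif(1, 0.045, 0.10) * min(n)
      ctr_new <- (n - 1) / 2 + stats::runif(3, -0.55, 0.55) * r0
      ok <- TRUE
      if (!is.null(blobs)) {
        dd <- sqrt(colSums((t(blobs[, 1:3, drop = FALSE]) - ctr_new)^2))
        ok <- all(dd > 2 * (blobs[, 4] + sd_new))
      }
      if (sqrt(sum((ctr_new - (n - 1) / 2)^2)) + 2 * sd_new > r0) ok <- FALSE
      if (ok) blobs <- rbind(blobs, c(ctr_new, sd_new, stats::runif(1, 0.5, 1.2)))
    }
    colnames(blobs) <- c("cx", "cy", "cz", "sd", "amp")
    img <- rep(0.3, nrow(g$vox))
    lab <- integer(nrow(g$vox))
    for (b in seq_len(nrow(blobs))) {
      d2 <- rowSums(sweep(g$vox, 2, blobs[b, 1:3])^2)
      img <- img + blobs[b, "amp"] * exp(-d2 / (2 * blobs[b, "sd"]^2))
      lab[d2 <= (2 * blobs[b, "sd"])^2] <- b
    }
    img <- img * mask
    lab[mask <= 0] <- 0L
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img),
                                sd = spec$noise_sd * diff(range(img)))
    list(image = image3d(array(img, n), spec$voxel_mm),
         labels = image3d(array(lab, n), spec$voxel_mm),
         mask = image3d(array(mask, n), spec$voxel_mm),
         blobs = as.data.frame(blobs))
  })
}

#' Generate a tensor phantom
#'
#' A diffusion-tensor field with a prolate (cigar-shaped, high linear
#' coefficient) tract following a circular arc, an oblate (plate-shaped,
#' high planar coefficient) sheet, and an isotropic background; eigenvalues
#' span a physiological range (about 0.3e-3 to 1.7e-3 mm^2/s).  The field is
#' a convex combination of SPD tensors and is therefore SPD everywhere.
#'
#' @param spec a [phantom_spec()].
#' @return a [tensor_volume()].
#' @export
make_tensor_phantom <- function(spec) {
  g <- .phantom_geom(spec)
  n <- spec$shape
  iso <- 0.7e-3
  ## prolate torus-arc: circle of radius Rc in the plane z = z_t
  Rc <- 0.45 * g$rmax
  z_t <- 0.25 * g$rmax
  rho <- sqrt(g$rel[, 1]^2 + g$rel[, 2]^2)
  d_t <- sqrt((rho - Rc)^2 + (g$rel[, 3] - z_t)^2)
  rt <- 0.14 * g$rmax
  w_t <- exp(-pmax(d_t - rt, 0)^2 / (2 * (0.35 * rt)^2))
  w_t[d_t <= rt] <- 1
  tang <- cbind(-g$rel[, 2], g$rel[, 1], 0) / pmax(rho, 1e-6)
  ## oblate sheet: slab around z = -z_t with normal along z
  d_s <- abs(g$rel[, 3] + z_t)
  hs <- 0.12 * g$rmax
  w_s <- exp(-pmax(d_s - hs, 0)^2 / (2 * (0.35 * hs)^2))
  w_s[d_s <= hs] <- 1
  w_s <- w_s * (1 - w_t)                 # tract takes precedence
  ## assemble per-voxel tensors: prolate lam (1.7, 0.3, 0.3)e-3 along tang;
  ## oblate lam (1.2, 1.2, 0.3)e-3 with V3 = z
  D <- matrix(0, nrow(g$vox), 6)
  D[, c(1, 4, 6)] <- iso
  l_para <- 1.7e-3; l_perp <- 0.3e-3
  ## prolate: D = l_perp I + (l_para - l_perp) t t^T
  pr <- cbind(tang[, 1]^2, tang[, 1] * tang[, 2], tang[, 1] * tang[, 3],
              tang[, 2]^2, tang[, 2] * tang[, 3], tang[, 3]^2)
  Dp <- (l_para - l_perp) * pr
  Dp[, c(1, 4, 6)] <- Dp[, c(1, 4, 6)] + l_perp
  ## oblate: D = l_in (I - n n^T) + l_out n n^T, n = e_z
  Do <- matrix(0, nrow(g$vox), 6)
  Do[, c(1, 4)] <- 1.2e-3
  Do[, 6] <- 0.3e-3
  for (k in 1:6) {
    D[, k] <- w_t * Dp[, k] + w_s * Do[, k] +
      (1 - w_t - w_s) * (if (k %in% c(1, 4, 6)) iso else 0)
  }
  tensor_volume(array(D, c(n, 6)), spec$voxel_mm)
}

#' Generate a known diffeomorphic ground-truth warp
#'
#' Draws smooth random B-spline coefficients, scales the field so the
#' maximum displacement equals the requested amplitude, and verifies that
#' the Jacobian determinant stays above 0.2 everywhere; errors if the
#' requested amplitude cannot be realised without approaching folding.
#'
#' @param spec a [phantom_spec()].
#' @return a [warp_field()] on the phantom's space.
#' @export
make_ground_truth_warp <- function(spec) {
  g <- .phantom_geom(spec)
  grid <- knot_grid(g$space, spec$warp_knot_mm)
  amp_mm <- spec$warp_amplitude_vox * spec$voxel_mm
  if (amp_mm == 0) return(warp_field(grid))
  .with_seed(spec$seed + 1000L, {
    co <- array(stats::rnorm(3 * grid$M), c(3, grid$counts))
    ## soften: average neighbouring knots along each axis (twice)
    smooth1 <- function(a, ax) {
      n <- dim(a)[ax + 1]
      idx <- function(i) pmin(pmax(i, 1), n)
      sl <- function(i) {
        ii <- list(TRUE, TRUE, TRUE, TRUE)
        ii[[ax + 1]] <- idx(i)
        do.call(`[`, c(list(a), ii, list(drop = FALSE)))
      }
      out <- a
      for (i in seq_len(n)) {
        ii <- list(TRUE, TRUE, TRUE, TRUE)
        ii[[ax + 1]] <- i
        val <- (sl(i - 1) + 2 * sl(i) + sl(i + 1)) / 4
        out <- do.call(`[<-`, c(list(out), ii, list(val)))
      }
      out
    }
    for (rep in 1:2) for (ax in 1:3) co <- smooth1(co, ax)
    w <- warp_field(grid, matrix(co, 3))
    d <- warp_displacement(w, g$vox)
    mx <- max(sqrt(rowSums(d^2)))
    w$coeffs <- w$coeffs * (amp_mm / mx)
    chk <- check_diffeomorphic(w)
    if (chk$min_det <= 0.2)
      stop("requested warp amplitude cannot be realised without ",
           "near-folding (min |J| = ", signif(chk$min_det, 3), ")")
    w
  })
}

#' Simulate the moving subject from a phantom and a known warp
#'
#' Generates the moving dataset by pulling each phantom volume through the
#' inverse of the ground-truth warp (fixed-point inversion), so that
#' registering the moving data back to the reference should recover the
#' warp: scalars are spline-interpolated, labels nearest-neighbour, masks
#' linear, and tensors are reoriented with the finite-strain rotation so
#' that the moving tensors satisfy `G(phi(x)) = R F R^T` exactly at
#' convergence.  A known multiplicative bias can be applied, in which case
#' the moving scalar satisfies `g(phi(x)) = b(x) f(x)`.
#'
#' @param phantom output of [make_scalar_phantom()] (or a list with any of
#'   `image`, `labels`, `mask`), optionally with an element `tensor`.
#' @param warp the ground-truth [warp_field()].
#' @param bias optional [bias_field()] to bake into the moving scalar.
#' @return list with the moving counterparts of the supplied volumes.
#' @export
warp_forward <- function(phantom, warp, bias = NULL) {
  sp <- warp$grid$space
  vox <- space_grid(sp)
  world <- xform_pts(sp$affine, vox)
  xin <- invert_warp_at(warp, world)       # phi(xin) = world(y)
  out <- list()
  if (!is.null(phantom$image)) {
    src <- phantom$image
    val <- spline_sample(spline_prep(src$data), xin)$value
    if (!is.null(bias)) val <- val * evaluate_bias(bias, xin)
    out$image <- image3d(array(val, sp$shape), sp$voxel_size, sp$affine)
  }
  if (!is.null(phantom$labels)) {
    out$labels <- image3d(array(nearest_sample(phantom$labels$data, xin),
                                sp$shape), sp$voxel_size, sp$affine)
  }
  if (!is.null(phantom$mask)) {
    out$mask <- image3d(array(trilinear_sample(phantom$mask$data, xin)$value,
                              sp$shape), sp$voxel_size, sp$affine)
  }
  if (!is.null(phantom$tensor)) {
    J <- warp_jacobian(warp, xin)
    Rm <- cpp_polar_rotations(J)
    Fs <- vapply(1:6, function(k)
      trilinear_sample(phantom$tensor$data[, , , k], xin)$value,
      numeric(nrow(xin)))
    out$tensor <- tensor_volume(array(.conj_tensors(Rm, Fs),
                                      c(sp$shape, 6)),
                                sp$voxel_size, sp$affine)
  }
  out
}
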