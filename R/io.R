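## File formats: NIfTI volumes (scalar, label, 6-component tensor, 3-volume
## displacement warp), FLIRT-style plain-text 4x4 affines, and YAML pyramid
## configuration.

#' Read a NIfTI volume
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param type `"scalar"` (3D intensities), `"tensor"` (4D with exactly six
#'   upper-triangle components in `dtifit` order -- other component counts
#'   are rejected), `"label"` (3D integers) or `"warp"` (4D with three mm
#'   displacement volumes).
#' @return an [image3d()], [tensor_volume()], or for `"warp"` a
#'   `warp_volume` (dense displacement field; see [warp_volume()]).
#' @export
read_nifti <- function(path, type = c("scalar", "tensor", "label", "warp")) {
  type <- match.arg(type)
  im <- RNifti::readNifti(path)
  A <- structure(RNifti::xform(im), imagedim = NULL, code = NULL)
  A <- matrix(as.numeric(A), 4, 4)
  if (abs(det(A)) <= .Machine$double.eps)
    stop("non-invertible affine in ", path)
  vs <- RNifti::pixdim(im)[1:3]
  dat <- as.array(im)
  attributes(dat) <- list(dim = dim(dat))
  if (type == "scalar" || type == "label") {
    if (length(dim(dat)) == 4 && dim(dat)[4] == 1) dat <- dat[, , , 1]
    if (length(dim(dat)) != 3)
      stop(path, ": expected a 3D volume, got ",
           paste(dim(dat), collapse = "x"))
    if (type == "label") dat <- array(as.integer(round(dat)), dim(dat))
    return(image3d(dat, vs, A))
  }
  if (length(dim(dat)) != 4)
    stop(path, ": expected a 4D volume, got ",
         paste(dim(dat), collapse = "x"))
  if (type == "tensor") {
    if (dim(dat)[4] != 6)
      stop(path, ": tensor volumes must have exactly 6 components ",
           "(dtifit upper-triangle layout); got ", dim(dat)[4],
           " -- full 9-component layouts are not accepted")
    return(tensor_volume(dat, vs, A))
  }
  if (dim(dat)[4] != 3)
    stop(path, ": displacement warps must have 3 volumes; got ", dim(dat)[4])
  warp_volume(dat, warp_space(dim(dat)[1:3], vs, A))
}

#' Write a volume as NIfTI
#'
#' Data are stored as float32 with the object's affine in both the sform
#' and qform (labels are rounded back to integers on reading).
#'
#' @param obj an [image3d()], [tensor_volume()], [warp_field()] /
#'   `warp_volume` (written as a 4D relative mm displacement field), or a
#'   plain array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param space required [warp_space()] when `obj` is a plain array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(obj, path, space = NULL) {
  if (inherits(obj, "warp_field")) obj <- warp_volume(
    array(warp_to_volume(obj), c(obj$grid$space$shape, 3)), obj$grid$space)
  if (inherits(obj, "warp_volume")) {
    dat <- obj$disp
    A <- obj$space$affine
    vs <- obj$space$voxel_size
    dtype <- "float"
  } else if (inherits(obj, "image3d") || inherits(obj, "tensor_volume")) {
    dat <- obj$data
    A <- obj$affine
    vs <- obj$voxel_size
    dtype <- "float"
  } else if (is.array(obj)) {
    stopifnot(!is.null(space))
    dat <- obj
    A <- space$affine
    vs <- space$voxel_size
    dtype <- "float"
  } else stop("cannot write object of class ", paste(class(obj), collapse = "/"))
  im <- RNifti::asNifti(dat)
  RNifti::pixdim(im) <- vs
  im <- RNifti::`sform<-`(im, structure(A, code = 2L))
  im <- RNifti::`qform<-`(im, structure(A, code = 2L))
  RNifti::writeNifti(im, path, datatype = dtype)
  invisible(path)
}

#' Dense displacement-field warp
#'
#' A warp represented by per-voxel relative displacements in mm (the on-disk
#' interchange form) rather than B-spline coefficients.  Displacements
#' between voxel centres are evaluated by cubic-spline interpolation of the
#' field.
#'
#' @param disp 4D array `(nx, ny, nz, 3)` of mm displacements.
#' @param space the [warp_space()] the field lives on.
#' @return an object of class `warp_volume` with the same evaluation
#'   interface as [apply_warp()] via [warp_volume_displacement()].
#' @export
warp_volume <- function(disp, space) {
  stopifnot(length(dim(disp)) == 4, dim(disp)[4] == 3,
            all(dim(disp)[1:3] == space$shape))
  structure(list(disp = disp, space = space), class = "warp_volume")
}

#' Displacement of a dense warp volume at arbitrary points
#'
#' @param wv a [warp_volume()].
#' @param vox `N x 3` matrix of 0-based voxel coordinates in the warp space.
#' @return `N x 3` matrix of mm displacements.
#' @export
warp_volume_displacement <- function(wv, vox) {
  vapply(1:3, function(d)
    spline_sample(spline_prep(wv$disp[, , , d]), vox)$value,
    numeric(nrow(vox)))
}

#' Read a FLIRT-format affine matrix
#'
#' Four whitespace-delimited rows of four numbers; the last row must be
#' (0, 0, 0, 1) and the matrix must be invertible.
#'
#' @param path text file.
#' @return a 4x4 matrix.
#' @export
read_affine <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4)
    stop(path, ": expected 4 rows, found ", length(lines))
  M <- matrix(0, 4, 4)
  for (i in 1:4) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 4 || anyNA(v))
      stop(path, ": line ", i, " is not 4 numbers: '", lines[i], "'")
    M[i, ] <- v
  }
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-6)
    stop(path, ": last row must be 0 0 0 1")
  if (abs(det(M)) <= .Machine$double.eps)
    stop(path, ": matrix is singular")
  M
}

#' Write a FLIRT-format affine matrix
#'
#' @param M 4x4 matrix.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_affine <- function(M, path) {
  stopifnot(is.matrix(M), all(dim(M) == 4))
  writeLines(apply(M, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "  ")), path)
  invisible(path)
}

#' Read a pyramid configuration file
#'
#' YAML with a `levels` list (fields `knot_mm`, optional `fwhm_mm`,
#' `subsample_mm`, `lambda_reg`) and optional top-level `lambda_scalar`,
#' `lambda_tensor`, `bias`, `bias_spacing`, `bias_bending`, `sym_weight`.
#' Missing per-level fields are filled by the default rules
#' (FWHM = knot / 4, Nyquist-safe subsampling, default regularisation
#' weights).
#'
#' @param path YAML file.
#' @return list with `schedule` (a `pyramid_schedule`) and `options`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$levels)) stop(path, ": config must contain 'levels'")
  lev <- lapply(cfg$levels, function(l) {
    if (is.null(l$knot_mm)) stop(path, ": every level needs knot_mm")
    k <- l$knot_mm
    fw <- if (is.null(l$fwhm_mm)) k / 4 else l$fwhm_mm
    data.frame(knot_mm = k, fwhm_mm = fw,
               subsample_mm = if (is.null(l$subsample_mm))
                 subsample_for(fw, k) else l$subsample_mm,
               lambda_reg = if (is.null(l$lambda_reg))
                 round(0.18 / 0.85^log2(k), 2) else l$lambda_reg)
  })
  sched <- do.call(rbind, lev)
  class(sched) <- c("pyramid_schedule", "data.frame")
  opts <- cfg[setdiff(names(cfg), "levels")]
  list(schedule = sched, options = opts)
}

#' Write a pyramid configuration file
#'
#' @param schedule a `pyramid_schedule` data frame.
#' @param path output YAML file.
#' @param options optional named list of top-level options.
#' @return `path`, invisibly.
#' @export
write_config <- function(schedule, path, options = list()) {
  cfg <- c(options,
           list(levels = lapply(seq_len(nrow(schedule)), function(i)
             as.list(schedule[i, , drop = FALSE]))))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
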