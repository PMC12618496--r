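# Final imaging preprocessing: resampling to the target anisotropic grid,
# spatial shape standardization by centered padding/cropping, and per-scan
# z-score intensity normalization. Inputs are assumed co-registered and
# skull-stripped upstream (external tools); volumes are carried in a fixed
# RAS-like axis convention so flips in augmentation are well-defined.

#' A 4-channel volume stack
#'
#' @param data 4D array (x, y, z, channel) in T1, T1C, T2, FLAIR order, or
#'   a 3D array for a single channel.
#' @param spacing voxel spacing in mm (length 3, positive).
#' @param affine optional 4x4 grid-to-world matrix.
#' @param mask optional binary lesion mask on the same grid (3D).
#' @return a `volume_stack`.
#' @export
volume_stack <- function(data, spacing = c(1, 1, 4), affine = NULL, mask = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  if (any(spacing <= 0)) stop("volume_stack: spacing must be positive")
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(data)[1:3]))
    mask <- (mask > 0) * 1L
    dim(mask) <- dim(data)[1:3]
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine,
                 mask = mask),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_stack: %dx%dx%d voxels, %d channel(s), spacing %s mm%s\n",
              d[1], d[2], d[3], d[4], paste(x$spacing, collapse = "x"),
              if (is.null(x$mask)) "" else sprintf(", lesion mask (%d voxels)", sum(x$mask))))
  invisible(x)
}

# trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based); coordinates are clamped to the valid range
trilinear <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2]); zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1); y0 <- pmin(floor(yi), d[2] - 1); z0 <- pmin(floor(zi), d[3] - 1)
  if (d[1] == 1) x0 <- rep(1, length(xi))
  if (d[2] == 1) y0 <- rep(1, length(yi))
  if (d[3] == 1) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(a, b, cc) vol[cbind(a, b, cc)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

nearest3 <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  xi <- pmin(pmax(round(xi), 1), d[1])
  yi <- pmin(pmax(round(yi), 1), d[2])
  zi <- pmin(pmax(round(zi), 1), d[3])
  vol[cbind(xi, yi, zi)]
}

#' Resample a volume stack to a target voxel spacing
#'
#' Intensities are interpolated trilinearly, the lesion mask (if present)
#' by nearest neighbour. The output grid preserves the world-space extent
#' to within one voxel: `n_out = round(n_in * spacing_in / spacing_out)`.
#'
#' @param stack a [volume_stack()].
#' @param target_spacing mm triple (default `c(1, 1, 4)`).
#' @return the resampled `volume_stack`.
#' @export
resample <- function(stack, target_spacing = c(1, 1, 4)) {
  if (any(target_spacing <= 0)) stop("resample: non-positive target spacing")
  din <- dim(stack$data)[1:3]
  sp_in <- stack$spacing
  n_out <- pmax(1L, as.integer(round(din * sp_in / target_spacing)))
  if (all(n_out == din) && all(abs(sp_in - target_spacing) < 1e-9)) {
    return(stack)
  }
  # voxel-center alignment: world extents of input and output grids coincide
  coord <- function(axis) ((seq_len(n_out[axis]) - 0.5) * target_spacing[axis] /
                             sp_in[axis]) + 0.5
  gx <- coord(1); gy <- coord(2); gz <- coord(3)
  grid <- expand.grid(x = gx, y = gy, z = gz)
  nch <- dim(stack$data)[4]
  out <- array(0, dim = c(n_out, nch))
  for (ch in seq_len(nch)) {
    out[, , , ch] <- array(trilinear(stack$data[, , , ch], grid$x, grid$y, grid$z), n_out)
  }
  mask <- NULL
  if (!is.null(stack$mask)) {
    mask <- array(nearest3(stack$mask, grid$x, grid$y, grid$z), n_out)
  }
  aff <- stack$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] %*% diag(target_spacing / sp_in)
  volume_stack(out, spacing = target_spacing, affine = aff, mask = mask)
}

# per-axis centered pad/crop index bookkeeping; extra voxel on trailing side
pad_crop_axis <- function(n_in, n_out) {
  if (n_in == n_out) return(list(src = seq_len(n_in), dst = seq_len(n_out)))
  if (n_in < n_out) {
    lead <- (n_out - n_in) %/% 2
    list(src = seq_len(n_in), dst = seq_len(n_in) + lead)
  } else {
    lead <- (n_in - n_out) %/% 2
    list(src = seq_len(n_out) + lead, dst = seq_len(n_out))
  }
}

#' Standardize the spatial shape by centered zero-padding or cropping
#'
#' Each axis is handled independently; odd pad/crop amounts put the extra
#' voxel on the trailing side. The mask is transformed identically.
#'
#' @param stack a [volume_stack()].
#' @param target_shape voxel triple (default `c(160, 192, 40)`).
#' @export
standardize_shape <- function(stack, target_shape = c(160, 192, 40)) {
  din <- dim(stack$data)[1:3]
  if (all(din == target_shape)) return(stack)
  nch <- dim(stack$data)[4]
  ax <- lapply(1:3, function(a) pad_crop_axis(din[a], target_shape[a]))
  out <- array(0, dim = c(target_shape, nch))
  out[ax[[1]]$dst, ax[[2]]$dst, ax[[3]]$dst, ] <-
    stack$data[ax[[1]]$src, ax[[2]]$src, ax[[3]]$src, , drop = FALSE]
  mask <- NULL
  if (!is.null(stack$mask)) {
    mask <- array(0L, dim = target_shape)
    mask[ax[[1]]$dst, ax[[2]]$dst, ax[[3]]$dst] <-
      stack$mask[ax[[1]]$src, ax[[2]]$src, ax[[3]]$src]
  }
  volume_stack(out, spacing = stack$spacing, affine = stack$affine, mask = mask)
}

#' Z-score normalize each channel of a scan
#'
#' Per channel: subtract the mean and divide by the standard deviation
#' over all voxels (or over mask voxels with `use_mask = TRUE`). Applied
#' before zero-padding in the standard pipeline so padding background does
#' not bias the statistics. A zero-variance channel becomes all zeros with
#' a warning.
#'
#' @param stack a [volume_stack()].
#' @param use_mask restrict statistics to mask voxels.
#' @export
zscore <- function(stack, use_mask = FALSE) {
  nch <- dim(stack$data)[4]
  out <- stack$data
  for (ch in seq_len(nch)) {
    v <- stack$data[, , , ch]
    sel <- if (use_mask && !is.null(stack$mask)) v[stack$mask > 0] else as.numeric(v)
    m <- mean(sel)
    s <- stats::sd(sel)
    if (!is.finite(s) || s == 0) {
      warning("zscore: zero-variance channel ", ch, " set to all zeros")
      out[, , , ch] <- 0
    } else {
      out[, , , ch] <- (v - m) / s
    }
  }
  volume_stack(out, spacing = stack$spacing, affine = stack$affine, mask = stack$mask)
}

#' Standard preprocessing chain
#'
#' [resample()] to the target spacing, [zscore()] (before padding so
#' synthetic background does not bias statistics), then
#' [standardize_shape()].
#'
#' @param stack a [volume_stack()].
#' @param target_spacing,target_shape see the component operations.
#' @export
prep_volume <- function(stack, target_spacing = c(1, 1, 4),
                        target_shape = c(160, 192, 40)) {
  standardize_shape(zscore(resample(stack, target_spacing)), target_shape)
}
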