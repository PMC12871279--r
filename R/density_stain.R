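## density stain: a stain-like total-mRNA volume image from transcript
## positions, used in place of PolyT for cytoplasmic segmentation

#' Construct a volume image
#'
#' A dense z/y/x grid with a micrometre origin and per-axis voxel size.
#' `values` is indexed `[z, y, x]`; `origin` and `voxel_size` are given
#' in `(x, y, z)` order in micrometres and refer to the minimum corner.
#'
#' @param values numeric array `[z, y, x]`, finite, non-negative for
#'   count/stain images.
#' @param origin numeric length-3 `(x, y, z)` in um.
#' @param voxel_size numeric length-3 `(x, y, z)` in um, all `> 0`.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(values, origin = c(0, 0, 0), voxel_size = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop_merscape("values must be a 3D [z,y,x] array",
                  class = "merscape_config_error")
  if (any(!is.finite(values)))
    stop_merscape("non-finite voxel values", class = "merscape_config_error")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0))
    stop_merscape("voxel_size must be > 0", class = "merscape_config_error")
  structure(list(values = values, origin = rep_len(as.numeric(origin), 3L),
                 voxel_size = voxel_size),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d z x %d y x %d x voxels, voxel %s um, total %.3g\n",
              d[1L], d[2L], d[3L],
              paste(signif(x$voxel_size, 3), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Default smoothing parameters for the density stain
#'
#' Gaussian sigma of 1 voxel in z and 3 in x/y, followed by a 3D median
#' filter with windows of 2 (z) and 10 (x/y) voxels. Units are voxels at
#' the binning resolution. `window_mode` controls whether the median
#' windows are full widths (even values rounded up to the next odd
#' integer for centering) or half-width radii.
#'
#' @param sigma_z,sigma_xy Gaussian sigmas, voxels.
#' @param median_window_z,median_window_xy median windows, voxels.
#' @param window_mode `"full"` (default) or `"radius"`.
#' @return a list of class `density_params`.
#' @export
density_params <- function(sigma_z = 1, sigma_xy = 3,
                           median_window_z = 2, median_window_xy = 10,
                           window_mode = c("full", "radius")) {
  window_mode <- match.arg(window_mode)
  stopifnot(sigma_z >= 0, sigma_xy >= 0,
            median_window_z >= 0, median_window_xy >= 0)
  structure(list(sigma_z = sigma_z, sigma_xy = sigma_xy,
                 median_window_z = median_window_z,
                 median_window_xy = median_window_xy,
                 window_mode = window_mode),
            class = "density_params")
}

#' Bin transcripts into a volume image
#'
#' Counts transcripts per voxel on a half-open grid `[a, b)` aligned
#' with the imaging (DAPI) frame. Out-of-bounds transcripts are dropped
#' (clipping), so the voxel sum equals the number of in-bounds
#' transcripts.
#'
#' @param spots a [spot_table].
#' @param origin `(x, y, z)` um of the grid's minimum corner.
#' @param dim_zyx integer grid dimensions `(z, y, x)`.
#' @param voxel_size `(x, y, z)` um per voxel.
#' @return a [volume_image] of counts.
#' @export
bin_transcripts <- function(spots, origin = c(0, 0, 0),
                            dim_zyx, voxel_size = c(1, 1, 1)) {
  dim_zyx <- as.integer(rep_len(dim_zyx, 3L))
  if (any(dim_zyx <= 0L))
    stop_merscape("zero-size grid", class = "merscape_config_error")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  vals <- array(0, dim = dim_zyx)
  if (nrow(spots)) {
    ix <- floor((spots$x - origin[1L]) / voxel_size[1L])
    iy <- floor((spots$y - origin[2L]) / voxel_size[2L])
    iz <- floor((spots$z - origin[3L]) / voxel_size[3L])
    ok <- ix >= 0 & ix < dim_zyx[3L] & iy >= 0 & iy < dim_zyx[2L] &
          iz >= 0 & iz < dim_zyx[1L]
    if (any(ok)) {
      lin <- 1L + iz[ok] + dim_zyx[1L] * (iy[ok] + dim_zyx[2L] * ix[ok])
      tab <- tabulate(lin, nbins = prod(dim_zyx))
      vals[] <- tab
    }
  }
  volume_image(vals, origin = origin, voxel_size = voxel_size)
}

## reflect-padding index lookup: positions 1..n extended symmetrically
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p < n, p + 1L, 2L * n - p - 1L)
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## 1D convolution along the given axis of a 3D array, reflect padding
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1L]
  m <- matrix(a, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  r <- (length(kernel) - 1L) %/% 2L
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    out <- out + kernel[k] * m[idx, , drop = FALSE]
  }
  a[] <- out
  aperm(a, order(perm))
}

#' Gaussian blur of a volume image (separable, reflect padding)
#' @param img a [volume_image].
#' @param sigma_z,sigma_xy sigmas in voxels.
#' @return a [volume_image].
#' @export
gaussian_blur <- function(img, sigma_z = 1, sigma_xy = 3) {
  v <- img$values
  v <- convolve_axis(v, gaussian_kernel(sigma_z), 1L)
  v <- convolve_axis(v, gaussian_kernel(sigma_xy), 2L)
  v <- convolve_axis(v, gaussian_kernel(sigma_xy), 3L)
  volume_image(v, img$origin, img$voxel_size)
}

odd_window <- function(w, mode) {
  w <- max(0, w)
  if (mode == "radius") return(2L * as.integer(ceiling(w)) + 1L)
  w <- as.integer(ceiling(w))
  if (w < 1L) 1L else if (w %% 2L == 0L) w + 1L else w
}

#' 3D median filter with a centered box window (reflect padding)
#' @param img a [volume_image].
#' @param window_zyx full window sizes `(z, y, x)` in voxels (odd).
#' @return a [volume_image].
#' @export
median_filter3d <- function(img, window_zyx) {
  v <- img$values
  d <- dim(v)
  w <- as.integer(rep_len(window_zyx, 3L))
  if (all(w <= 1L)) return(img)
  r <- (w - 1L) %/% 2L
  offs <- expand.grid(dz = -r[1L]:r[1L], dy = -r[2L]:r[2L], dx = -r[3L]:r[3L])
  n_vox <- prod(d)
  iz <- rep(seq_len(d[1L]), times = d[2L] * d[3L])
  iy <- rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L])
  ix <- rep(seq_len(d[3L]), each = d[1L] * d[2L])
  block <- max(1L, floor(2e7 / nrow(offs)))
  out <- numeric(n_vox)
  for (start in seq(1L, n_vox, by = block)) {
    sel <- start:min(start + block - 1L, n_vox)
    stackm <- matrix(0, nrow = nrow(offs), ncol = length(sel))
    for (o in seq_len(nrow(offs))) {
      zz <- reflect_index(iz[sel] + offs$dz[o], d[1L])
      yy <- reflect_index(iy[sel] + offs$dy[o], d[2L])
      xx <- reflect_index(ix[sel] + offs$dx[o], d[3L])
      stackm[o, ] <- v[cbind(zz, yy, xx)]
    }
    out[sel] <- matrixStats::colMedians(stackm)
  }
  volume_image(array(out, d), img$origin, img$voxel_size)
}

#' Smooth a binned transcript image into a stain-like density
#'
#' Gaussian convolution (default sigma 1 voxel in z, 3 in x/y) followed
#' by a 3D median filter (default windows 2 in z, 10 in x/y, rounded up
#' to odd for centering). The result emulates a cytoplasmic stain for
#' segmentation backends.
#'
#' @param img a [volume_image] of binned counts.
#' @param p a [density_params] object.
#' @return a [volume_image]; an attribute `params` echoes `p` verbatim.
#' @export
smooth_density <- function(img, p = density_params()) {
  g <- gaussian_blur(img, sigma_z = p$sigma_z, sigma_xy = p$sigma_xy)
  w <- c(odd_window(p$median_window_z, p$window_mode),
         odd_window(p$median_window_xy, p$window_mode),
         odd_window(p$median_window_xy, p$window_mode))
  out <- median_filter3d(g, w)
  attr(out, "params") <- p
  out
}
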