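# Minimal BOLD preprocessing: spatial smoothing, brain masking, mean time
# courses. Motion correction and tissue segmentation are accepted as inputs
# (motion parameter file, optional mask file), not performed here.

# 1D Gaussian convolution operator with reflective boundary, as an n x n
# matrix; rows sum to 1 so constants are preserved.
gauss_operator <- function(n, sigma_vox) {
  if (sigma_vox <= 0 || n == 1L) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- -r:r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (m in seq_along(off)) {
    j <- idx + off[m]
    # reflect about the edges (symmetric half-sample reflection)
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    j <- pmin(pmax(j, 1L), n)
    K[cbind(idx, j)] <- K[cbind(idx, j)] + k[m]
  }
  K
}

apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- K %*% matrix(a, nrow = d[axis])
  dim(m) <- dp
  aperm(m, order(perm))
}

#' Spatially smooth a 4D series with a Gaussian kernel
#'
#' Per-frame separable 3D Gaussian convolution. The kernel width is given as
#' full width at half maximum in mm (sigma = FWHM / sqrt(8 ln 2)), converted
#' to voxels per axis using the voxel size. Boundaries are handled by
#' reflection so the mean image is not darkened at the edges. `fwhm_mm = 0`
#' returns the input unchanged.
#'
#' @param img An [image4d()].
#' @param fwhm_mm Kernel FWHM in mm (default 8, the conventional width for
#'   CVR mapping at 3T resolutions).
#' @return Smoothed `image4d`.
#' @export
gaussian_smooth <- function(img, fwhm_mm = 8) {
  stopifnot(inherits(img, "image4d"))
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(img)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  sigma_vox <- sigma_mm / img$voxel_size
  d <- dim(img$data)
  out <- img$data
  for (ax in 1:3) {
    if (sigma_vox[ax] * 4 < 0.5) next   # kernel narrower than half a voxel
    K <- gauss_operator(d[ax], sigma_vox[ax])
    out <- apply_axis(out, K, ax)
  }
  image4d(out, voxel_size = img$voxel_size, tr = img$tr, template = img$template)
}

# connected components of a 3D logical array under 6-connectivity
label_components <- function(mask3d) {
  d <- dim(mask3d)
  lin <- which(mask3d)
  if (length(lin) == 0L) return(array(0L, d))
  pos <- arrayInd(lin, d)
  id <- integer(prod(d)); id[lin] <- seq_along(lin)
  edges <- integer(0)
  for (ax in 1:3) {
    step <- c(1L, d[1], d[1] * d[2])[ax]
    ok <- pos[, ax] < d[ax]
    nb <- lin[ok] + step
    has <- id[nb] > 0L
    if (any(has)) edges <- c(edges, rbind(id[lin[ok]][has], id[nb][has]))
  }
  g <- igraph::make_graph(edges, n = length(lin), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[lin] <- comp
  out
}

#' Compute a brain mask from a 4D series
#'
#' Thresholds the temporal-mean image at a fraction of its robust maximum
#' (98th percentile), keeps the largest 6-connected component, and fills
#' interior holes (background components not touching the volume border).
#' The pipeline only needs the brain/background split for whole-brain
#' averaging and relative normalisation, so an intensity mask suffices; a
#' user-supplied mask can be passed instead for full fidelity.
#'
#' @param img An [image4d()].
#' @param threshold_frac Threshold as a fraction of the robust max (default 0.5).
#' @param mask Optional logical/0-1 array on the BOLD grid; when given it is
#'   validated and returned unchanged.
#' @return A 3D logical array of class `brain_mask`.
#' @export
compute_brain_mask <- function(img, threshold_frac = 0.5, mask = NULL) {
  stopifnot(inherits(img, "image4d"))
  d3 <- dim(img$data)[1:3]
  if (!is.null(mask)) {
    m <- array(as.logical(mask != 0), dim = dim(mask))
    if (!identical(dim(m), d3)) stop("supplied mask grid does not match the BOLD grid")
    if (!any(m)) stop("supplied mask is empty")
    class(m) <- c("brain_mask", class(m))
    return(m)
  }
  mi <- rowMeans(matrix(img$data, prod(d3)))
  dim(mi) <- d3
  thr <- threshold_frac * quantile(mi, 0.98, names = FALSE)
  m <- mi > thr
  if (!any(m) || all(m)) stop("mask empty or full: image has no brain/background contrast")
  lab <- label_components(m)
  tab <- tabulate(lab[lab > 0L])
  m <- lab == which.max(tab)
  # fill holes: background components not touching the border belong inside
  bg <- label_components(!m)
  border <- array(FALSE, d3)
  border[c(1, d3[1]), , ] <- TRUE; border[, c(1, d3[2]), ] <- TRUE
  border[, , c(1, d3[3])] <- TRUE
  outside <- unique(bg[border & !m])
  m <- m | !(bg %in% outside & bg > 0L)
  dim(m) <- d3
  class(m) <- c("brain_mask", class(m))
  m
}

#' Mean time course over a mask
#'
#' @param img An [image4d()].
#' @param mask 3D logical array on the BOLD grid.
#' @param region Label for the averaged region (default "whole-brain").
#' @return A `mean_timecourse`: list with `values` (one per frame), `tr` and
#'   `region`.
#' @export
mean_timecourse <- function(img, mask, region = "whole-brain") {
  stopifnot(inherits(img, "image4d"))
  d <- dim(img$data)
  if (!identical(dim(mask), d[1:3])) stop("mask grid does not match the BOLD grid")
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask is empty")
  Y <- matrix(img$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  structure(list(values = colMeans(Y), tr = img$tr, region = region,
                 n_voxels = length(idx)),
            class = "mean_timecourse")
}

#' @export
print.mean_timecourse <- function(x, ...) {
  cat(sprintf("<mean_timecourse> %s: %d frames, TR %.3g s (%d voxels)\n",
              x$region, length(x$values), x$tr, x$n_voxels))
  invisible(x)
}
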