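# Global-threshold bone segmentation: individual histogram analysis via the
# maximum between-class-variance criterion, largest-component retention in
# place of the operator's semiautomatic delineation, and iso-surface
# extraction of the resulting 1-bit model.

#' Select a global bone threshold by histogram analysis
#'
#' Builds a 256-bin histogram over the observed intensity range and returns
#' the threshold maximising the between-class variance of the two-class
#' split (Otsu's criterion); ties are broken towards the lower threshold.
#' The candidate thresholds are the 255 interior bin boundaries; the value
#' returned is the boundary itself, so `voxel >= threshold` reproduces the
#' selected split exactly.
#'
#' @param volume a [density_volume()].
#' @param bins number of histogram bins (default 256).
#' @return Threshold in density units.
#' @export
select_threshold <- function(volume, bins = 256L) {
  v <- as.numeric(volume$voxels)
  rng <- range(v)
  if (diff(rng) <= 0)
    stop_condylometry("constant volume: no histogram structure")
  bw <- diff(rng) / bins
  idx <- pmin(pmax(floor((v - rng[1]) / bw), 0), bins - 1)
  counts <- as.numeric(tabulate(idx + 1L, nbins = bins))
  centers <- rng[1] + (seq_len(bins) - 0.5) * bw
  n <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * centers)
  mtot <- m0[bins]
  k <- seq_len(bins - 1)          # split after bin k
  w0k <- w0[k]; w1k <- n - w0k
  valid <- w0k > 0 & w1k > 0
  sb <- rep(-Inf, bins - 1)
  mu0 <- m0[k][valid] / w0k[valid]
  mu1 <- (mtot - m0[k][valid]) / w1k[valid]
  sb[valid] <- w0k[valid] * w1k[valid] * (mu0 - mu1)^2
  kbest <- which.max(sb)          # which.max takes the first (lowest) maximum
  rng[1] + kbest * bw
}

#' Segment a volume into a 1-bit bone model
#'
#' Thresholds the volume (`voxel >= threshold`) and retains only the largest
#' 26-connected foreground component, the automated counterpart of manually
#' delineating the mandible.  The threshold actually used is recorded on the
#' result for audit.
#'
#' @param volume a [density_volume()].
#' @param threshold `"auto"` (the default, calls [select_threshold()]) or a
#'   numeric threshold in density units.
#' @return A [binary_model()].
#' @export
#' @examples
#' \donttest{
#' ph <- build_phantom(phantom_params(), spacing = 0.5)
#' model <- segment(ph$volume)
#' model$threshold_used
#' }
segment <- function(volume, threshold = "auto") {
  stopifnot(inherits(volume, "density_volume"))
  thr <- if (identical(threshold, "auto")) select_threshold(volume)
         else as.numeric(threshold)
  mask <- volume$voxels >= thr
  if (!any(mask))
    stop_condylometry(sprintf(
      "threshold %.6g leaves no foreground voxels", thr))
  labels <- .cc_label26(as.logical(mask), dim(mask))
  ncomp <- attr(labels, "n_components")
  if (ncomp > 1L) {
    sizes <- tabulate(labels, nbins = ncomp)
    keep <- which.max(sizes)
    mask <- array(labels == keep, dim(mask))
  }
  binary_model(mask, volume$spacing, volume$origin, threshold_used = thr)
}

# separable Gaussian smoothing of a 3-D array, sigma in voxels, replicate
# padding via row-renormalised banded matrices
.gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    offs <- -r:r
    w <- exp(-offs^2 / (2 * s^2))
    n <- d[ax]
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (j in seq_along(offs)) {
      i <- seq_len(n)
      tgt <- i + offs[j]
      ok <- tgt >= 1 & tgt <= n
      rows <- c(rows, i[ok]); cols <- c(cols, tgt[ok])
      vals <- c(vals, rep(w[j], sum(ok)))
    }
    K <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
    K <- K / Matrix::rowSums(K)
    arr <- .apply_axis(arr, ax, K)
  }
  arr
}

# multiply axis `ax` of a 3-D array by matrix K (n_out x n_in)
.apply_axis <- function(arr, ax, K) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[ax])
  out <- as.matrix(K %*% m)
  d2 <- d[perm]; d2[1] <- nrow(K)
  out <- array(out, d2)
  aperm(out, order(perm))
}

#' Extract a triangulated iso-surface from a binary model
#'
#' Runs a marching-tetrahedra iso-surface (level 0.5) on the model's
#' occupancy field.  The raw 0/1 field is first smoothed with a small
#' Gaussian (0.7 voxel), which removes the orientation aliasing of
#' binary-field iso-surfacing (a sizeable surface-area overestimate on
#' oblique surfaces) while conserving volume; the raw mask is blended back
#' in as a lower bound (`0.55 * mask`) so that no foreground voxel can
#' vanish.  Vertices are returned in world mm.
#'
#' @param model a [binary_model()].
#' @param smooth_sigma smoothing bandwidth in voxels (default 0.7).
#' @return A [surface_mesh()] with provenance (`threshold_used`, `voxel`).
#' @export
extract_surface <- function(model, smooth_sigma = 0.7) {
  stopifnot(inherits(model, "binary_model"))
  mask <- model$mask
  d <- dim(mask)
  if (any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
      any(mask[, , c(1, d[3])]))
    stop_condylometry("mask touches the volume border; cannot close surface")
  field <- array(as.numeric(mask), d)
  if (smooth_sigma > 0) {
    field <- .gauss_smooth3(field, rep(smooth_sigma, 3))
    field <- pmax(field, 0.55 * mask)
  }
  res <- .marching_tetrahedra(as.numeric(field), d, 0.5)
  if (nrow(res$vertices) == 0)
    stop_condylometry("empty iso-surface")
  verts <- sweep(res$vertices, 2, model$spacing, "*")
  verts <- sweep(verts, 2, model$origin, "+")
  surface_mesh(verts, res$faces,
               provenance = list(threshold_used = model$threshold_used,
                                 voxel = max(model$spacing)))
}
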