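# Pooled-histogram Otsu threshold over a whole 3D stack (one global value,
# not per slice).
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stopf("segmentation error: stack has no intensity contrast")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[n_bins]
  mu_t <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mu_t * w0[valid] - tot * mu[-n_bins][valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  (mids[k] + mids[k + 1L]) / 2
}

gauss_smooth <- function(stack, voxel_size, sigma_um) {
  sigma_vox <- sigma_um / voxel_size
  cpp_gauss3d(stack, dim(stack), sigma_vox)
}

#' Segment the nucleus from a DAPI-like stack
#'
#' The nuclear periphery is defined by the edge of the DAPI signal: the stack
#' is Gaussian-smoothed, thresholded with a single pooled-histogram Otsu
#' value, interior cavities are filled and the largest 6-connected component
#' is retained (ties broken deterministically by raster-scan order of the
#' first voxel).
#'
#' @param stack numeric 3D array, `dim = c(nx, ny, nz)`.
#' @param voxel_size micrometres per voxel along x, y, z.
#' @param sigma_um Gaussian smoothing scale in micrometres (default 0.2).
#' @param nucleus_id identifier for the resulting model.
#' @return a [nucleus_model()] with an empty chromocenter mask.
#' @export
segment_nucleus <- function(stack, voxel_size = c(0.08, 0.08, 0.2),
                            sigma_um = 0.2, nucleus_id = "nucleus_1") {
  if (!is.array(stack) || length(dim(stack)) != 3L || !any(is.finite(stack)))
    stopf("`stack` must be a non-empty numeric 3D array")
  sm <- gauss_smooth(stack, voxel_size, sigma_um)
  thr <- otsu_threshold(as.vector(sm))
  fg <- array(sm > thr, dim(stack))
  if (!any(fg)) stopf("segmentation error: empty foreground after threshold")
  fg <- cpp_fill_holes(fg, dim(fg))
  lab <- cpp_label3d(fg, dim(fg))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes) # first maximum: deterministic tie-break
  nucleus_model(array(lab == keep, dim(fg)), voxel_size,
                nucleus_id = nucleus_id, validate = FALSE)
}

#' Segment chromocenters as high-intensity DAPI regions
#'
#' Chromocenters are identified as voxels whose smoothed intensity exceeds
#' `mean + k * SD`, both statistics computed within the nuclear mask. When an
#' alternative channel is supplied (e.g. MeCP2 immunofluorescence in ectopic
#' MeCP2-expressing cells, where chromocenter identification uses the
#' antibody staining), thresholding applies to that channel instead. The
#' threshold multiplier `k` has no counterpart measurement in the microscopy
#' protocol ("high-intensity" signals); it is an explicit tunable defaulting
#' to 2 and is recorded per nucleus in pipeline manifests.
#'
#' @param stack DAPI-like intensity stack matching the nucleus grid.
#' @param nucleus a [nucleus_model()].
#' @param k SD multiplier above the in-mask mean (default 2, must be > 0).
#' @param alt_channel optional stack to threshold instead of `stack`.
#' @param sigma_um smoothing scale before thresholding.
#' @return the nucleus with its `chromocenters` label array replaced; an
#'   empty mask (all zero) is permitted and downstream chromocenter
#'   distances are then reported missing.
#' @export
segment_chromocenters <- function(stack, nucleus, k = 2, alt_channel = NULL,
                                  sigma_um = 0.12) {
  assert_scalar_num(k, "k")
  if (k <= 0) stopf("`k` must be strictly positive")
  channel <- alt_channel %||% stack
  if (!identical(dim(channel), dim(nucleus$mask)))
    stopf("channel dimensions differ from the nuclear mask")
  sm <- gauss_smooth(channel, nucleus$voxel_size, sigma_um)
  inmask <- sm[nucleus$mask]
  thr <- mean(inmask) + k * sd(inmask)
  cc <- array(sm > thr & nucleus$mask, dim(nucleus$mask))
  nucleus$chromocenters <- cpp_label3d(cc, dim(cc))
  nucleus
}

#' Detect FISH spots and report sub-voxel centroids
#'
#' Voxels above a robust background threshold (median + `k_mad` * MAD of the
#' smoothed in-mask intensities) are grouped into 6-connected components;
#' each component yields one spot whose centroid is the intensity-weighted
#' mean of its voxel centres (sub-voxel precision). Spots whose centroid
#' falls outside the nuclear mask are discarded. An empty result is allowed.
#'
#' @param stack FISH spot channel matching the nucleus grid.
#' @param nucleus a [nucleus_model()].
#' @param k_mad robust threshold multiplier (default 7).
#' @param sigma_um light smoothing before detection.
#' @param min_voxels discard components smaller than this many voxels.
#' @return data.frame with `locus_id`, `x_um`, `y_um`, `z_um`, `n_voxels`,
#'   `peak` (ordered deterministically by first voxel in raster order).
#' @export
detect_spots <- function(stack, nucleus, k_mad = 7, sigma_um = 0.1,
                         min_voxels = 2L) {
  if (!identical(dim(stack), dim(nucleus$mask)))
    stopf("stack dimensions differ from the nuclear mask")
  sm <- gauss_smooth(stack, nucleus$voxel_size, sigma_um)
  inmask <- sm[nucleus$mask]
  # floor the robust spread at a fraction of the dynamic range so that a
  # near-noise-free stack does not connect spots through vanishing tails
  med <- median(inmask)
  thr <- med + max(k_mad * mad(inmask), 0.1 * (max(inmask) - med))
  fg <- array(sm > thr & nucleus$mask, dim(stack))
  lab <- cpp_label3d(fg, dim(fg))
  n <- max(lab)
  if (n == 0L)
    return(data.frame(locus_id = character(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      n_voxels = integer(), peak = numeric()))
  out <- vector("list", n)
  dims <- dim(stack)
  for (l in seq_len(n)) {
    lin <- which(lab == l)
    if (length(lin) < min_voxels) next
    wgt <- sm[lin] - median(inmask)
    wgt[wgt < 0] <- 0
    vox <- cbind((lin - 1) %% dims[1],
                 ((lin - 1) %/% dims[1]) %% dims[2],
                 (lin - 1) %/% (as.numeric(dims[1]) * dims[2])) + 1L
    ctr <- colSums(voxel_center(vox, nucleus$voxel_size) * wgt) / sum(wgt)
    out[[l]] <- data.frame(x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
                           n_voxels = length(lin), peak = max(stack[lin]))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(x_um = numeric(), y_um = numeric(),
                                      z_um = numeric(), n_voxels = integer(),
                                      peak = numeric())
  if (nrow(res)) {
    vox <- point_to_voxel(res[, c("x_um", "y_um", "z_um")], nucleus)
    lin <- voxel_linear(vox, dim(nucleus$mask))
    keep <- !is.na(lin) & nucleus$mask[lin]
    res <- res[keep, , drop = FALSE]
  }
  if (nrow(res))
    res <- cbind(locus_id = sprintf("spot_%03d", seq_len(nrow(res))), res)
  else res <- cbind(locus_id = character(), res)
  rownames(res) <- NULL
  res
}
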