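#' Construct a nucleus model
#'
#' Bundles one nucleus's binary voxel mask, its chromocenter label mask and
#' the physical voxel size. This is the container every distance operation
#' consumes; it can come from segmentation ([segment_nucleus()]) or directly
#' from label-mask inputs, bypassing images entirely.
#'
#' @param mask logical 3D array, `dim = c(nx, ny, nz)`; `TRUE` inside the
#'   nucleus. Must be a single 6-connected component.
#' @param voxel_size numeric length-3, micrometres per voxel along x, y, z
#'   (default `c(0.08, 0.08, 0.2)`, the confocal acquisition grid).
#' @param chromocenters integer 3D array of the same dimension labelling
#'   chromocenter voxels (0 = none), or `NULL` for no chromocenters.
#' @param nucleus_id character identifier.
#' @param validate check invariants (single component, containment). Skipping
#'   is useful when constructing many synthetic nuclei whose invariants hold
#'   by construction.
#' @return an object of class `nucleus_model`.
#' @export
nucleus_model <- function(mask, voxel_size = c(0.08, 0.08, 0.2),
                          chromocenters = NULL, nucleus_id = "nucleus_1",
                          validate = TRUE) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stopf("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stopf("`voxel_size` must be three strictly positive numbers (um)")
  if (is.null(chromocenters)) {
    chromocenters <- array(0L, dim(mask))
  } else {
    if (!identical(dim(chromocenters), dim(mask)))
      stopf("chromocenter mask dimensions differ from nuclear mask")
    storage.mode(chromocenters) <- "integer"
  }
  if (validate) {
    if (!any(mask)) stopf("nuclear mask is empty")
    if (any(chromocenters > 0 & !mask))
      stopf("chromocenter mask extends outside the nuclear mask")
    lab <- cpp_label3d(mask, dim(mask))
    if (max(lab) > 1L)
      stopf("nuclear mask has %d connected components; expected 1", max(lab))
  }
  structure(list(nucleus_id = nucleus_id, mask = mask,
                 chromocenters = chromocenters, voxel_size = voxel_size),
            class = "nucleus_model")
}

#' @export
print.nucleus_model <- function(x, ...) {
  d <- dim(x$mask)
  vol <- sum(x$mask) * prod(x$voxel_size)
  ncc <- length(setdiff(unique(as.vector(x$chromocenters)), 0L))
  cat(sprintf(
    "<nucleus_model '%s'> grid %dx%dx%d, voxel %.3gx%.3gx%.3g um\n",
    x$nucleus_id, d[1], d[2], d[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  volume %.1f um^3, %d chromocenter(s)\n", vol, ncc))
  invisible(x)
}

# physical xyz (um, rows of a matrix) -> 1-based voxel subscripts; NA outside grid
point_to_voxel <- function(points, nucleus) {
  points <- as.matrix(points)
  d <- dim(nucleus$mask)
  v <- nucleus$voxel_size
  idx <- floor(sweep(points, 2, v, "/")) + 1
  outside <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
    idx[, 3] < 1 | idx[, 3] > d[3]
  idx[outside, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

voxel_linear <- function(vox, dims) {
  vox[, 1] + as.numeric(dims[1]) * (vox[, 2] - 1L) +
    as.numeric(dims[1]) * dims[2] * (vox[, 3] - 1L)
}

# centre coordinates (um) of 1-based voxel subscripts
voxel_center <- function(vox, voxel_size) {
  sweep(vox - 0.5, 2, voxel_size, "*")
}

#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are stored page-per-z-slice with rows = y and columns = x; in
#' memory they are arrays with `dim = c(nx, ny, nz)`.
#'
#' @param path file path.
#' @return `read_stack()` returns a numeric 3D array.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  arr
}

#' @rdname read_stack
#' @param stack numeric 3D array `dim = c(nx, ny, nz)` with values in `[0, 1]`
#'   (integer label arrays are rescaled to labels/255 on write).
#' @export
write_stack <- function(stack, path) {
  stack <- pmin(pmax(stack, 0), 1)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) t(stack[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
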