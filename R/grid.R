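# Volume geometry: voxel grid, mask, coordinate lookups.

#' Define a voxel grid with an analysis mask
#'
#' The default mask is the largest ellipsoid inscribed in the grid (a
#' desk-scale stand-in for a brain mask); searchlights and pattern sites are
#' restricted to in-mask voxels.
#'
#' @param dims Integer vector of length 3 (voxels per axis).
#' @param voxel_size_mm Isotropic voxel edge length in millimetres.
#' @param mask Optional logical array of dimension `dims`; `NULL` selects
#'   the inscribed ellipsoid.
#' @return A `volume_grid`: list with `dims`, `voxel_size_mm`, `mask`,
#'   `in_mask` (linear indices), `coords` (in-mask voxel coordinates,
#'   V x 3) and `vol_index` (array mapping voxel to in-mask column or 0).
#' @export
volume_grid <- function(dims = c(20, 20, 20), voxel_size_mm = 3,
                        mask = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  if (is.null(mask)) {
    ctr <- (dims + 1) / 2
    semi <- pmax(dims / 2 - 0.5, 0.5)
    g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                     z = seq_len(dims[3]))
    inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
      ((g$z - ctr[3]) / semi[3])^2 <= 1
    mask <- array(inside, dim = dims)
  }
  stopifnot(identical(dim(mask), dims))
  if (!any(mask)) stop("mask is empty")
  in_mask <- which(mask)
  coords <- arrayInd(in_mask, dims)
  vol_index <- array(0L, dim = dims)
  vol_index[in_mask] <- seq_along(in_mask)
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm, mask = mask,
                 in_mask = in_mask, coords = coords,
                 vol_index = vol_index),
            class = "volume_grid")
}

#' Number of in-mask voxels
#' @param grid A `volume_grid`.
#' @export
n_voxels <- function(grid) length(grid$in_mask)

# Expand an in-mask vector into a full 3D array (0 outside the mask).
unmask <- function(values, grid, fill = 0) {
  out <- array(fill, dim = grid$dims)
  out[grid$in_mask] <- values
  out
}
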