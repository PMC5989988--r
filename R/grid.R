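#' Voxel grid geometry
#'
#' A `voxel_grid` describes the regular lattice on which tractography seeds
#' and parcellation masks live: the number of voxels along each axis and the
#' physical edge lengths (mm) of a voxel. Voxel indices are 0-based and a
#' point in mm belongs to voxel `floor(coord / edge)` (half-open boxes), so
#' voxel `(0,0,0)` spans `[0, edge)` on every axis.
#'
#' @param shape integer vector of length 3, voxel counts per axis (each >= 1).
#' @param voxel_edges numeric vector of length 3, voxel edge lengths in mm
#'   (each > 0); a scalar is recycled for isotropic voxels.
#' @return An object of class `voxel_grid` with fields `shape`, `voxel_edges`
#'   and `voxel_volume` (mm^3).
#' @examples
#' g <- voxel_grid(c(10, 10, 10), 2)
#' g$voxel_volume  # 8 mm^3
#' @export
voxel_grid <- function(shape, voxel_edges) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three voxel counts, each >= 1")
  if (length(voxel_edges) == 1L) voxel_edges <- rep(voxel_edges, 3L)
  voxel_edges <- as.numeric(voxel_edges)
  if (length(voxel_edges) != 3L || any(!is.finite(voxel_edges)) ||
      any(voxel_edges <= 0))
    stop("`voxel_edges` must be three positive lengths (mm)")
  structure(
    list(shape = shape, voxel_edges = voxel_edges,
         voxel_volume = prod(voxel_edges)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, edges %s mm, V_voxel = %g mm^3\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$voxel_edges, 4), collapse = " x "),
              x$voxel_volume))
  invisible(x)
}

#' Map points (mm) to 0-based voxel indices
#'
#' @param grid a [voxel_grid()].
#' @param points numeric matrix with 3 columns (x, y, z in mm) or a length-3
#'   vector.
#' @return Integer matrix with 3 columns of 0-based voxel indices.
#' @export
point_to_voxel <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  idx <- floor(sweep(points, 2L, grid$voxel_edges, "/"))
  storage.mode(idx) <- "integer"
  idx
}

#' @keywords internal
voxel_in_grid <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  idx[, 1] >= 0L & idx[, 1] < grid$shape[1] &
    idx[, 2] >= 0L & idx[, 2] < grid$shape[2] &
    idx[, 3] >= 0L & idx[, 3] < grid$shape[3]
}

# 0-based (i,j,k) -> 1-based linear key used for set membership on the grid
#' @keywords internal
voxel_key <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  1L + idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3])
}

#' @keywords internal
key_to_voxel <- function(grid, key) {
  k <- key - 1L
  i <- k %% grid$shape[1]
  k <- k %/% grid$shape[1]
  j <- k %% grid$shape[2]
  cbind(i, j, k %/% grid$shape[2])
}

#' Per-voxel scalar field (e.g. fractional anisotropy)
#'
#' @param grid a [voxel_grid()].
#' @param values numeric array matching `grid$shape`, or a scalar recycled to
#'   a constant field.
#' @param range optional length-2 numeric giving the admissible value range;
#'   defaults to `c(0, 1)`, appropriate for fractional anisotropy.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(grid, values, range = c(0, 1)) {
  if (length(values) == 1L) values <- array(values, dim = grid$shape)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("`values` must be an array matching the grid shape")
  vals <- values[is.finite(values)]
  if (any(vals < range[1] - 1e-12) || any(vals > range[2] + 1e-12))
    stop(sprintf("scalar field values outside [%g, %g]", range[1], range[2]))
  structure(list(grid = grid, values = values, range = range),
            class = "scalar_field")
}

#' @keywords internal
field_at_keys <- function(field, keys) {
  as.numeric(field$values[keys])
}
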