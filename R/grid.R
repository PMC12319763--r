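#' Define a volumetric sampling grid
#'
#' A `volume_grid` describes an axis-aligned voxel grid: its shape in voxels,
#' the voxel size in millimetres, and the world-space position of the first
#' voxel centre. World coordinates of voxel index `(i, j, k)` (1-based) are
#' `origin + (index - 1) * voxel_size`.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm positive numeric vector of length 3 (mm). A scalar is
#'   recycled to all axes.
#' @param origin_mm numeric vector of length 3, world position of the first
#'   voxel centre (mm).
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(40, 40, 40), 1)
#' voxel_to_world(g, c(1, 1, 1))
#' @export
volume_grid <- function(shape, voxel_size_mm = c(1.8, 1.8, 1.8),
                        origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 integers, all >= 1")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be 3 positive values")
  if (length(origin_mm) != 3L) stop("'origin_mm' must have length 3")
  structure(list(shape = shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels at %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param grid a [volume_grid()].
#' @param index integer vector of length 3 (1-based voxel index) or a matrix
#'   with one index per row.
#' @return World coordinates in mm (vector or matrix matching the input).
#' @export
voxel_to_world <- function(grid, index) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.matrix(index))
    return(sweep(sweep(index - 1, 2, grid$voxel_size_mm, `*`),
                 2, grid$origin_mm, `+`))
  grid$origin_mm + (index - 1) * grid$voxel_size_mm
}

#' @rdname voxel_to_world
#' @param world world coordinates in mm.
#' @export
world_to_voxel <- function(grid, world) {
  stopifnot(inherits(grid, "volume_grid"))
  (world - grid$origin_mm) / grid$voxel_size_mm + 1
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

empty_volume <- function(grid, value = 0)
  array(value, dim = grid$shape)

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x")))
  invisible(TRUE)
}
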