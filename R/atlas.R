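#' @importFrom stats aov approx convolve dgamma lm mauchly.test median pnorm
#'   pt predict qnorm quantile rlnorm rnorm runif sd shapiro.test
#'   friedman.test setNames ecdf
#' @importFrom utils head modifyList write.table read.delim
NULL

# Nuclei, their parent regions, and the condition wiring used by the phantom.
# Hand movement drives the ipsilateral cuneate analogue and the contralateral
# VPL / S1-hand analogues; face movement drives bilateral trigeminal / VPM /
# S1-face analogues.
.nucleus_parents <- c(
  left_cuneate = "brainstem", right_cuneate = "brainstem",
  spinal_trigeminal_left = "brainstem", spinal_trigeminal_right = "brainstem",
  vpl_left = "thalamus", vpl_right = "thalamus", vpm = "thalamus",
  s1_hand_left = "s1", s1_hand_right = "s1", s1_face = "s1"
)

.default_wiring <- list(
  left_hand  = c("left_cuneate", "vpl_right", "s1_hand_right"),
  right_hand = c("right_cuneate", "vpl_left", "s1_hand_left"),
  face       = c("spinal_trigeminal_left", "spinal_trigeminal_right",
                 "vpm", "s1_face")
)

# Adjacent nucleus pairs across which activity patterns may leak
.adjacent_pairs <- list(
  c("left_cuneate", "spinal_trigeminal_left"),
  c("right_cuneate", "spinal_trigeminal_right")
)

box_mask <- function(grid, x, y, z) {
  m <- array(FALSE, dim = grid$shape)
  m[x, y, z] <- TRUE
  m
}

mirror_x <- function(mask) mask[dim(mask)[1]:1, , , drop = FALSE]

#' Default phantom geometry
#'
#' Computes, from a grid shape, the voxel-index boxes that place three region
#' slabs (brainstem, thalamus, S1 stacked along z) and ten small nuclei:
#' bilateral cuneate and spinal trigeminal nuclei (face-adjacent neighbours in
#' the brainstem slab), bilateral VPL plus a midline VPM in the thalamus slab,
#' and bilateral S1 hand areas plus a midline S1 face area in the cortical
#' slab. Left/right structures are exact mirror images across the mid-x plane.
#'
#' @param grid a [volume_grid()] with an even number of voxels along x,
#'   `shape >= c(12, 8, 9)`.
#' @return Named list of `list(x =, y =, z =)` voxel index ranges, one per
#'   mask name.
#' @export
default_phantom_geometry <- function(grid) {
  n <- grid$shape
  if (n[1] %% 2L != 0L)
    stop("phantom geometry needs an even voxel count along x for exact ",
         "left/right mirror symmetry")
  if (n[1] < 12L || n[2] < 8L || n[3] < 9L)
    stop("grid too small for the default phantom geometry (need >= 12 x 8 x 9)")
  mx <- n[1] %/% 2L
  my <- n[2] %/% 2L
  zb <- n[3] %/% 3L                 # brainstem slab: 1..zb
  zt <- (2L * n[3]) %/% 3L          # thalamus slab: zb+1..zt; S1: zt+1..nz
  mid3 <- function(lo, hi) {        # central run of <= 3 slices in a slab
    len <- min(3L, hi - lo + 1L)
    s <- lo + (hi - lo + 1L - len) %/% 2L
    s:(s + len - 1L)
  }
  nyc <- my:(my + 1L)
  list(
    brainstem = list(x = (mx - 4L):(mx + 5L), y = (my - 2L):(my + 3L), z = 1L:zb),
    thalamus  = list(x = (mx - 4L):(mx + 5L), y = (my - 2L):(my + 3L), z = (zb + 1L):zt),
    s1        = list(x = (mx - 5L):(mx + 6L), y = (my - 3L):(my + 4L), z = (zt + 1L):n[3]),
    left_cuneate            = list(x = (mx - 1L):mx,        y = nyc, z = mid3(1L, zb)),
    right_cuneate           = list(x = (mx + 1L):(mx + 2L), y = nyc, z = mid3(1L, zb)),
    spinal_trigeminal_left  = list(x = (mx - 3L):(mx - 2L), y = nyc, z = mid3(1L, zb)),
    spinal_trigeminal_right = list(x = (mx + 3L):(mx + 4L), y = nyc, z = mid3(1L, zb)),
    vpl_left  = list(x = (mx - 3L):(mx - 2L), y = nyc, z = mid3(zb + 1L, zt)),
    vpl_right = list(x = (mx + 3L):(mx + 4L), y = nyc, z = mid3(zb + 1L, zt)),
    vpm       = list(x = mx:(mx + 1L),        y = nyc, z = mid3(zb + 1L, zt)),
    s1_hand_left  = list(x = (mx - 4L):(mx - 3L), y = nyc, z = mid3(zt + 1L, n[3])),
    s1_hand_right = list(x = (mx + 3L):(mx + 4L), y = nyc, z = mid3(zt + 1L, n[3])),
    s1_face       = list(x = (mx - 1L):(mx + 2L), y = nyc, z = mid3(zt + 1L, n[3]))
  )
}

#' Build the phantom atlas
#'
#' Constructs the named boolean masks of the somatosensory phantom on a voxel
#' grid and validates their structural invariants: every nucleus is nonempty
#' and contained in its parent region; the left and right cuneate masks are
#' mirror images across the midline; each cuneate shares at least one
#' face-adjacent voxel pair with the ipsilateral spinal trigeminal nucleus
#' (the two nuclei abut without a gap, as in the dorsal medulla); and nucleus
#' masks are pairwise disjoint.
#'
#' @param grid a [volume_grid()].
#' @param geometry optional named list of voxel boxes (as returned by
#'   [default_phantom_geometry()]); entries replace the defaults.
#' @return A `phantom_atlas`: list with `grid`, `masks` (named logical
#'   arrays), `nuclei`, `regions`, `parents`, `wiring`, `adjacent_pairs`.
#' @examples
#' atlas <- build_phantom_atlas(volume_grid(c(40, 40, 40), 1))
#' names(atlas$masks)
#' @export
build_phantom_atlas <- function(grid, geometry = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  geo <- default_phantom_geometry(grid)
  if (!is.null(geometry)) {
    unknown <- setdiff(names(geometry), names(geo))
    if (length(unknown))
      stop("unknown mask in geometry config: ", paste(unknown, collapse = ", "))
    geo <- modifyList(geo, geometry)
  }
  masks <- lapply(names(geo), function(nm) {
    b <- geo[[nm]]
    if (min(b$x) < 1L || max(b$x) > grid$shape[1] ||
        min(b$y) < 1L || max(b$y) > grid$shape[2] ||
        min(b$z) < 1L || max(b$z) > grid$shape[3])
      stop(sprintf("mask '%s' extends outside the grid", nm))
    box_mask(grid, b$x, b$y, b$z)
  })
  names(masks) <- names(geo)

  nuclei <- names(.nucleus_parents)
  for (nm in nuclei) {
    if (!any(masks[[nm]]))
      stop(sprintf("nucleus mask '%s' is empty", nm))
    if (any(masks[[nm]] & !masks[[.nucleus_parents[[nm]]]]))
      stop(sprintf("nucleus mask '%s' is not contained in its parent region '%s'",
                   nm, .nucleus_parents[[nm]]))
  }
  for (i in seq_along(nuclei)[-1]) for (j in seq_len(i - 1L)) {
    if (any(masks[[nuclei[i]]] & masks[[nuclei[j]]]))
      stop(sprintf("nucleus masks '%s' and '%s' overlap",
                   nuclei[i], nuclei[j]))
  }
  if (!identical(masks$left_cuneate, mirror_x(masks$right_cuneate)))
    stop("left_cuneate and right_cuneate are not mirror images across the midline")
  for (pair in .adjacent_pairs) {
    if (count_adjacent_pairs(masks[[pair[1]]], masks[[pair[2]]]) < 1L)
      stop(sprintf("masks '%s' and '%s' are not face-adjacent", pair[1], pair[2]))
  }

  structure(list(grid = grid, masks = masks,
                 nuclei = nuclei,
                 regions = c("brainstem", "thalamus", "s1"),
                 parents = .nucleus_parents,
                 wiring = .default_wiring,
                 adjacent_pairs = .adjacent_pairs),
            class = "phantom_atlas")
}

#' Count face-adjacent voxel pairs between two masks
#'
#' Scans the six face-neighbour directions and counts ordered voxel pairs
#' `(a, b)` with `a` in `mask_a`, `b` in `mask_b`, differing by one step along
#' a single axis.
#'
#' @param mask_a,mask_b logical 3-D arrays of equal shape.
#' @return Integer count of face-adjacent pairs.
#' @export
count_adjacent_pairs <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  d <- dim(mask_a)
  n <- 0L
  shift_and <- function(axis) {
    idx_lo <- lapply(d, seq_len)
    idx_hi <- idx_lo
    idx_lo[[axis]] <- seq_len(d[axis] - 1L)
    idx_hi[[axis]] <- 2L:d[axis]
    a_lo <- do.call(`[`, c(list(mask_a), idx_lo))
    b_hi <- do.call(`[`, c(list(mask_b), idx_hi))
    a_hi <- do.call(`[`, c(list(mask_a), idx_hi))
    b_lo <- do.call(`[`, c(list(mask_b), idx_lo))
    sum(a_lo & b_hi) + sum(a_hi & b_lo)
  }
  for (ax in 1:3) if (d[ax] > 1L) n <- n + shift_and(ax)
  n
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf("phantom_atlas on a %s grid: %d masks\n",
              paste(x$grid$shape, collapse = "x"), length(x$masks)))
  sizes <- vapply(x$masks, sum, numeric(1))
  print(sizes)
  invisible(x)
}
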