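#' Voxel grid geometry
#'
#' Describes a regular voxel grid in a standard-space RAS world frame
#' (+x right, +y anterior, +z superior) with the world origin conventionally
#' at the anterior commissure. Voxel indices are 1-based (R convention);
#' world coordinates are voxel-center positions in mm,
#' `world = origin + (index - 1) * voxel_size`. By default the grid is
#' centered on the world origin.
#'
#' @param shape Integer voxel counts `(nx, ny, nz)`.
#' @param voxel_size Voxel edge lengths in mm (scalar or length 3;
#'   default 1 mm isotropic).
#' @param origin World coordinate (mm) of the center of voxel (1,1,1);
#'   default centers the grid on (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1), origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %g x %g x %g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @rdname volume_grid
#' @param grid A `volume_grid`.
#' @return `grid_affine()`: the 4x4 voxel-to-world transform (1-based voxel
#'   index convention).
#' @export
grid_affine <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  A <- diag(4)
  diag(A)[1:3] <- grid$voxel_size
  A[1:3, 4] <- grid$origin - grid$voxel_size # index 1 maps to origin
  A
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' `voxel_to_world()` maps 1-based (possibly fractional) voxel indices to
#' world mm; `world_to_voxel()` is its inverse. Inputs may be length-3
#' vectors or n x 3 matrices.
#'
#' @param grid A `volume_grid`.
#' @param ijk,xyz Coordinates (length-3 vector or n x 3 matrix).
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$voxel_size, "/") + 1
}

.check_volume <- function(grid, vol, what = "volume") {
  if (!identical(dim(vol), as.integer(grid$shape)))
    stop(sprintf("%s dimensions (%s) do not match grid shape (%s)",
                 what, paste(dim(vol), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  invisible(vol)
}

#' Tissue probability maps
#'
#' One volume per tissue class, each voxel holding the probability that the
#' voxel belongs to that class. Probabilities are in \[0, 1\] and sum to at
#' most 1 per voxel; the deficit from 1 is implicitly ambient/sinus air.
#'
#' @param grid A `volume_grid`.
#' @param maps Named list of 3-D arrays (one per tissue class) matching the
#'   grid shape.
#' @return An object of class `probability_maps`.
#' @export
probability_maps <- function(grid, maps) {
  stopifnot(inherits(grid, "volume_grid"), is.list(maps), length(maps) >= 1,
            !is.null(names(maps)))
  for (cls in names(maps)) {
    .check_volume(grid, maps[[cls]], paste0("map '", cls, "'"))
    rng <- range(maps[[cls]])
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop(sprintf("probabilities for '%s' outside [0, 1]", cls))
  }
  tot <- Reduce(`+`, maps)
  if (max(tot) > 1 + 1e-6)
    stop("per-voxel probabilities sum to more than 1")
  structure(list(grid = grid, maps = maps, classes = names(maps)),
            class = "probability_maps")
}

#' @export
print.probability_maps <- function(x, ...) {
  cat("probability_maps:", paste(x$classes, collapse = ", "), "\n")
  print(x$grid)
  invisible(x)
}

#' Integer label atlas
#'
#' A parcellation volume (0 = unlabeled) with a lookup table mapping label
#' ids to region names, in the style of a Desikan-Killiany cortical
#' parcellation.
#'
#' @param grid A `volume_grid`.
#' @param labels Integer 3-D array matching the grid.
#' @param lookup Data frame with columns `label` (integer) and `region`
#'   (character). Every nonzero label present in `labels` must appear.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(grid, labels, lookup) {
  stopifnot(inherits(grid, "volume_grid"))
  .check_volume(grid, labels, "labels")
  stopifnot(is.data.frame(lookup), all(c("label", "region") %in% names(lookup)))
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, lookup$label)
  if (length(missing) > 0)
    stop("labels missing from lookup: ", paste(missing, collapse = ", "))
  if (anyDuplicated(lookup$label)) stop("duplicate label ids in lookup")
  structure(list(grid = grid, labels = labels,
                 lookup = lookup[order(lookup$label), , drop = FALSE]),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("label_atlas with", nrow(x$lookup), "regions\n")
  print(x$grid)
  invisible(x)
}

#' Region volumes from a label atlas
#'
#' One row per region in the lookup table (regions absent from the volume get
#' 0); volume = voxel count x voxel volume.
#'
#' @param atlas A `label_atlas`.
#' @return Data frame with columns `label`, `region`, `n_voxels`,
#'   `volume_mm3`.
#' @export
region_volumes <- function(atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  vv <- prod(atlas$grid$voxel_size)
  counts <- tabulate(atlas$labels[atlas$labels > 0L],
                     nbins = max(atlas$lookup$label))
  n <- counts[atlas$lookup$label]
  n[is.na(n)] <- 0L
  data.frame(label = atlas$lookup$label, region = atlas$lookup$region,
             n_voxels = as.integer(n), volume_mm3 = n * vv,
             row.names = NULL)
}
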