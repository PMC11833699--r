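#' Synthetic layered-head phantom
#'
#' Generates tissue probability maps, a hemispheric label atlas and a head
#' mask for a five-layer spherical head: soft tissue (scalp) over skull over
#' cerebrospinal fluid over a gray-matter shell over a white-matter core.
#' The skull and everything inside it are concentric spheres centered on the
#' world origin. The outer scalp sphere may be offset posterior-inferiorly
#' (`scalp_offset`, default `c(0, -6, -5)` mm) so that the extracerebral
#' soft-tissue layer is thinnest over the forehead and vertex and thickest
#' over the occiput and skull base — a first-order stand-in for the thin
#' frontal scalp versus the thick nuchal musculature and basal structures of
#' real anatomy, which is what makes the treatment-paradigm entry sites
#' genuinely inequivalent on this phantom. Set `scalp_offset = c(0, 0, 0)`
#' for a fully concentric head.
#'
#' Boundaries are crisp indicators by default; `sigma > 0` smooths every
#' probability map with an isotropic Gaussian (then renormalizes voxels
#' whose total exceeds 1), emulating probabilistic segmentation boundaries.
#' The generator is deterministic given its arguments.
#'
#' @param radii Named vector of sphere radii (mm), ordered
#'   soft_tissue > skull > csf > gray_matter > white_matter.
#' @param scalp_offset Center offset of the outer scalp sphere, mm (RAS).
#' @param voxel_size Voxel edge, mm (default 1).
#' @param shape Grid shape; default fits the scalp sphere with a 2-voxel
#'   margin.
#' @param sigma Gaussian boundary-smoothing standard deviation, mm
#'   (0 = crisp).
#' @param lobes If TRUE the gray-matter atlas is split into octant "lobe"
#'   labels per hemisphere instead of a single label per hemisphere.
#' @return List with `probmaps` ([probability_maps()]), `atlas`
#'   ([label_atlas()]) and `head_mask` (logical array).
#' @export
make_layered_head <- function(radii = c(soft_tissue = 84, skull = 72,
                                        csf = 65, gray_matter = 62,
                                        white_matter = 53),
                              scalp_offset = c(0, -6, -5),
                              voxel_size = 1, shape = NULL, sigma = 0,
                              lobes = FALSE) {
  req <- c("soft_tissue", "skull", "csf", "gray_matter", "white_matter")
  if (!identical(names(radii), req))
    stop("radii must be named ", paste(req, collapse = " > "))
  if (any(diff(radii) >= 0) || any(radii <= 0))
    stop("radii must be positive and strictly decreasing outer -> inner")
  if (max(abs(scalp_offset)) + radii["skull"] >= radii["soft_tissue"])
    stop("scalp_offset so large that the skull pierces the scalp")
  extent <- radii[["soft_tissue"]] + max(abs(scalp_offset)) + 2 * voxel_size
  if (is.null(shape)) shape <- rep(2 * ceiling(extent / voxel_size) + 1, 3)
  grid <- volume_grid(shape, voxel_size)

  cx <- grid$origin[1] + (seq_len(shape[1]) - 1) * grid$voxel_size[1]
  cy <- grid$origin[2] + (seq_len(shape[2]) - 1) * grid$voxel_size[2]
  cz <- grid$origin[3] + (seq_len(shape[3]) - 1) * grid$voxel_size[3]
  X <- array(cx, shape)
  Y <- array(rep(cy, each = shape[1]), shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), shape)
  r_origin <- sqrt(X^2 + Y^2 + Z^2)
  r_scalp <- sqrt((X - scalp_offset[1])^2 + (Y - scalp_offset[2])^2 +
                  (Z - scalp_offset[3])^2)

  in_scalp <- r_scalp <= radii[["soft_tissue"]]
  in_skull <- r_origin <= radii[["skull"]]
  in_csf <- r_origin <= radii[["csf"]]
  in_gm <- r_origin <= radii[["gray_matter"]]
  in_wm <- r_origin <= radii[["white_matter"]]

  maps <- list(
    soft_tissue = (in_scalp & !in_skull) * 1,
    skull = (in_skull & !in_csf) * 1,
    csf = (in_csf & !in_gm) * 1,
    gray_matter = (in_gm & !in_wm) * 1,
    white_matter = in_wm * 1
  )
  maps <- lapply(maps, function(m) array(m, shape))
  if (sigma > 0) {
    maps <- lapply(maps, .gauss_smooth3d, sigma = sigma,
                   voxel_size = grid$voxel_size)
    tot <- Reduce(`+`, maps)
    excess <- tot > 1
    if (any(excess))
      maps <- lapply(maps, function(m) { m[excess] <- m[excess] / tot[excess]; m })
  }
  probmaps <- probability_maps(grid, maps)
  head_mask <- Reduce(`+`, maps) > 0.01

  # atlas over the gray-matter shell
  gm_vox <- maps$gray_matter > 0.5
  labels <- array(0L, shape)
  if (!lobes) {
    # strict inequalities leave the midline plane unlabeled, keeping the
    # hemispheres mirror images of each other
    labels[gm_vox & X < 0] <- 1L
    labels[gm_vox & X > 0] <- 2L
    lookup <- data.frame(label = 1:2,
                         region = c("gm_left_hemisphere", "gm_right_hemisphere"))
  } else {
    hemi <- ifelse(X < 0, 0L, 4L)
    oct <- 1L + (Y >= 0) * 2L + (Z >= 0) * 1L
    lobe_names <- c("inferior_posterior", "superior_posterior",
                    "inferior_anterior", "superior_anterior")
    lab <- hemi + oct
    labels[gm_vox] <- lab[gm_vox]
    lookup <- data.frame(
      label = 1:8,
      region = c(paste0("gm_left_", lobe_names), paste0("gm_right_", lobe_names)))
  }
  atlas <- label_atlas(grid, labels, lookup)
  list(probmaps = probmaps, atlas = atlas, head_mask = head_mask)
}

# separable Gaussian smoothing along each axis (truncated at 3 sigma)
.gauss_smooth3d <- function(vol, sigma, voxel_size) {
  for (ax in 1:3) {
    s <- sigma / voxel_size[ax]
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half):half / s)^2)
    k <- k / sum(k)
    vol <- .conv_axis(vol, k, ax)
  }
  vol
}

.conv_axis <- function(vol, k, ax) {
  d <- dim(vol)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dp <- dim(v)
  m <- matrix(v, nrow = dp[1])
  half <- (length(k) - 1) / 2
  padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  out <- matrix(0, nrow(m), ncol(m))
  for (q in seq_along(k))
    out <- out + k[q] * padded[q:(q + nrow(m) - 1), , drop = FALSE]
  v <- array(out, dp)
  aperm(v, order(perm))
}

#' Synthetic planar slab phantom
#'
#' Stacks planar tissue layers along +z starting at the low-z face of the
#' grid; voxels beyond the last layer are air. The workhorse medium for
#' physics validation (Beer-Lambert decay, layered depth profiles).
#'
#' @param layers Data frame with columns `class` and `thickness_mm`, ordered
#'   from the illuminated (low z) side.
#' @param shape Grid shape (default 41 x 41 x 61).
#' @param voxel_size Voxel edge, mm.
#' @return A [probability_maps()] object.
#' @export
make_slab <- function(layers, shape = c(41, 41, 61), voxel_size = 1) {
  stopifnot(is.data.frame(layers),
            all(c("class", "thickness_mm") %in% names(layers)),
            all(layers$thickness_mm > 0))
  grid <- volume_grid(shape, voxel_size)
  nz_needed <- sum(layers$thickness_mm) / grid$voxel_size[3]
  if (nz_needed > shape[3])
    stop("layer thicknesses exceed the grid extent in z")
  maps <- list()
  z0 <- 0
  for (q in seq_len(nrow(layers))) {
    cls <- layers$class[q]
    z1 <- z0 + layers$thickness_mm[q]
    k0 <- floor(z0 / grid$voxel_size[3]) + 1
    k1 <- ceiling(z1 / grid$voxel_size[3])
    m <- if (is.null(maps[[cls]])) array(0, shape) else maps[[cls]]
    m[, , k0:k1] <- 1
    maps[[cls]] <- m
    z0 <- z1
  }
  # later layers overwrite earlier ones at shared boundary voxels
  if (nrow(layers) > 1) {
    occupied <- array(0, shape)
    for (q in rev(seq_len(nrow(layers)))) {
      cls <- layers$class[q]
      m <- maps[[cls]]
      m[occupied > 0] <- 0
      occupied <- occupied + m
      maps[[cls]] <- m
    }
  }
  probability_maps(grid, maps)
}

#' Synthetic ocular slab phantom
#'
#' A layered stand-in for the trans-ocular illumination path: eyelid skin,
#' cornea, aqueous humour, lens, vitreous body, sclera/retina, orbital fat,
#' stacked along +z with literature-plausible default thicknesses.
#'
#' @param thicknesses Named vector of layer thicknesses, mm, in path order.
#' @inheritParams make_slab
#' @return A [probability_maps()] object.
#' @export
make_eye_slab <- function(thicknesses = c(eyelid_skin = 3, cornea = 1,
                                          aqueous = 3, lens = 4,
                                          vitreous = 17, sclera_retina = 1,
                                          orbital_fat = 12),
                          shape = c(31, 31, 51), voxel_size = 1) {
  make_slab(data.frame(class = names(thicknesses),
                       thickness_mm = as.numeric(thicknesses)),
            shape = shape, voxel_size = voxel_size)
}
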