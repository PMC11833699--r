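#' Remove small extracranial artifact components from a head mask
#'
#' Labels the connected components of a logical volume and removes those
#' smaller than `min_component_voxels`, emulating the size-and-connectedness
#' rule used to strip metal artifacts and noise specks around the scalp and
#' skull. The largest component is always retained, so a head can never be
#' deleted by an aggressive threshold. The output is a subset of the input.
#'
#' @param mask Logical 3-D array.
#' @param min_component_voxels Minimum component size to keep.
#' @param connectivity Voxel neighbourhood: 6 (faces), 18 (faces + edges) or
#'   26 (faces + edges + corners).
#' @return Logical array of the same shape.
#' @export
clean_extracranial <- function(mask, min_component_voxels = 10L,
                               connectivity = c(26L, 18L, 6L)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  connectivity <- as.integer(connectivity)[1]
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (!any(mask)) return(mask)
  lab <- cpp_label_components(as.vector(mask), dim(mask), connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_voxels)
  keep <- union(keep, which.max(sizes)) # largest always survives
  out <- array(lab %in% keep, dim = dim(mask))
  out & mask
}

#' Label connected components of a 3-D mask
#'
#' @inheritParams clean_extracranial
#' @return Integer array of component labels (0 = background), numbered in
#'   first-encounter order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  array(cpp_label_components(as.vector(mask), dim(mask), connectivity),
        dim = dim(mask))
}

#' Build a multispectral optical phantom from tissue probability maps
#'
#' Maps per-voxel optical parameters (mua, mus, g, n) at each requested
#' wavelength by probability-weighted mixing of the library's tissue optics
#' (see [mix_properties()] for the mixing rule; the probability deficit from
#' 1 is treated as air). Voxels whose total tissue probability (excluding the
#' `air` class) does not exceed `head_threshold` are outside the head mask
#' and forced inert (mua = mus = 0, n = 1).
#'
#' @param probmaps A [probability_maps()] object.
#' @param lib A [spectral_library()].
#' @param wavelengths Wavelengths to map, nm.
#' @param head_threshold Total-tissue-probability threshold for the head
#'   mask (default 0.01, robust to probabilistic-map noise).
#' @return An object of class `optical_phantom` with fields `grid`,
#'   `wavelengths`, per-wavelength lists `mua`, `mus`, `g`, `n` (3-D arrays,
#'   names = wavelength), and `head_mask`.
#' @export
build_phantom <- function(probmaps, lib, wavelengths,
                          head_threshold = 0.01) {
  stopifnot(inherits(probmaps, "probability_maps"),
            inherits(lib, "spectral_library"), length(wavelengths) >= 1)
  classes <- probmaps$classes
  for (cls in classes) {
    if (!cls %in% lib$tissue_classes)
      stop("tissue class missing from spectral library: ", cls)
    for (wl in wavelengths) {
      ok <- tryCatch({ optics_lookup(lib, cls, wl); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop(sprintf("%s@%g missing from spectral library", cls, wl))
    }
  }
  shape <- probmaps$grid$shape
  tissue_classes <- setdiff(classes, "air")
  total <- Reduce(`+`, probmaps$maps[tissue_classes])
  head_mask <- total > head_threshold
  total_all <- Reduce(`+`, probmaps$maps)
  deficit <- pmax(0, 1 - total_all)

  out <- list(grid = probmaps$grid, wavelengths = as.numeric(wavelengths),
              mua = list(), mus = list(), g = list(), n = list(),
              head_mask = head_mask, classes = classes)
  for (wl in wavelengths) {
    key <- as.character(wl)
    props <- lapply(classes, function(cls) optics_lookup(lib, cls, wl))
    names(props) <- classes
    mua <- array(0, shape); mus <- array(0, shape)
    gnum <- array(0, shape); gden <- array(0, shape); gplain <- array(0, shape)
    nvol <- deficit * 1
    for (cls in classes) {
      p <- props[[cls]]; w <- probmaps$maps[[cls]]
      mua <- mua + w * p$mua
      mus <- mus + w * p$mus
      nvol <- nvol + w * p$n
      gnum <- gnum + w * p$mus * p$g
      gplain <- gplain + w * p$g
    }
    gden <- mus
    g <- ifelse(gden > 0, gnum / gden, gplain / pmax(total_all + deficit, .Machine$double.eps))
    # ambient voxels are inert air
    mua[!head_mask] <- 0
    mus[!head_mask] <- 0
    g[!head_mask] <- 0
    nvol[!head_mask] <- 1
    out$mua[[key]] <- mua
    out$mus[[key]] <- mus
    out$g[[key]] <- g
    out$n[[key]] <- nvol
  }
  structure(out, class = "optical_phantom")
}

#' @export
print.optical_phantom <- function(x, ...) {
  cat(sprintf("optical_phantom: %d wavelengths (%s nm), %d head voxels\n",
              length(x$wavelengths), paste(x$wavelengths, collapse = ", "),
              sum(x$head_mask)))
  print(x$grid)
  invisible(x)
}

#' Retrieve one parameter volume of a phantom
#'
#' @param phantom An `optical_phantom`.
#' @param param One of "mua", "mus", "g", "n".
#' @param wavelength Wavelength, nm (must be one of `phantom$wavelengths`).
#' @return 3-D array.
#' @export
phantom_volume <- function(phantom, param = c("mua", "mus", "g", "n"),
                           wavelength) {
  stopifnot(inherits(phantom, "optical_phantom"))
  param <- match.arg(param)
  key <- as.character(wavelength)
  if (!key %in% names(phantom[[param]]))
    stop("wavelength ", wavelength, " nm not mapped in this phantom")
  phantom[[param]][[key]]
}

# evaluate the interpolant for one profile line; s = arc length at nodes
.interp_eval <- function(s_nodes, v_nodes, s_out, method) {
  if (method == "linear") {
    stats::approx(s_nodes, v_nodes, xout = s_out, rule = 1)$y
  } else {
    # natural cubic spline: C2 cubic Hermite interpolant whose interior
    # tangents solve the natural (zero second derivative at the ends)
    # conditions; reduces to weighted finite-difference tangents.
    stats::spline(s_nodes, v_nodes, xout = s_out, method = "natural")$y
  }
}

#' Sparse annotation of a phantom
#'
#' A set of annotated voxels (each resolved to a tissue class from the
#' library or to explicit optical properties) plus profile lines: ordered
#' point sequences along which the annotated optical parameters are
#' interpolated through the phantom, emulating expert sparse labeling of
#' fine structures (orbital tissues, sinuses) whose boundaries probabilistic
#' segmentation blurs.
#'
#' @param points Data frame with columns `i`, `j`, `k` (1-based voxel
#'   indices) and either `tissue` (library class name) or the explicit
#'   columns `mua`, `mus`, `g`, `n`.
#' @param profile_lines List of integer vectors indexing rows of `points`;
#'   each line needs at least 2 points.
#' @return An object of class `sparse_annotation`.
#' @export
sparse_annotation <- function(points, profile_lines) {
  stopifnot(is.data.frame(points), all(c("i", "j", "k") %in% names(points)))
  has_tissue <- "tissue" %in% names(points)
  has_props <- all(c("mua", "mus", "g", "n") %in% names(points))
  if (!has_tissue && !has_props)
    stop("points need a 'tissue' column or explicit mua/mus/g/n columns")
  if (!is.list(profile_lines) || length(profile_lines) == 0)
    stop("at least one profile line is required")
  for (ln in profile_lines) {
    if (length(ln) < 2) stop("each profile line needs at least 2 points")
    if (any(ln < 1 | ln > nrow(points))) stop("profile line indexes unknown points")
  }
  structure(list(points = points, profile_lines = profile_lines),
            class = "sparse_annotation")
}

#' Interpolate sparse annotations into a phantom
#'
#' Along each profile line (a polyline through annotated voxel centers) each
#' optical parameter is replaced by the interpolant between the annotated
#' node values, sampled at the voxel centers the line traverses. Node voxels
#' take the node values exactly. `"hermite"` uses the natural cubic Hermite
#' interpolant (zero second derivative at the line ends, C2-continuous
#' interior — the spline family that preserves gradient continuity at tissue
#' boundaries); `"linear"` is piecewise linear.
#'
#' @param phantom An `optical_phantom`.
#' @param ann A [sparse_annotation()].
#' @param lib A [spectral_library()]; required when annotation points name
#'   tissue classes rather than explicit properties.
#' @param method `"hermite"` (default) or `"linear"`.
#' @return The modified `optical_phantom`.
#' @export
annotate_and_interpolate <- function(phantom, ann, lib = NULL,
                                     method = c("hermite", "linear")) {
  stopifnot(inherits(phantom, "optical_phantom"),
            inherits(ann, "sparse_annotation"))
  method <- match.arg(method)
  shape <- phantom$grid$shape
  pts <- ann$points
  if (any(pts$i < 1 | pts$i > shape[1] | pts$j < 1 | pts$j > shape[2] |
          pts$k < 1 | pts$k > shape[3]))
    stop("annotation point outside the grid")
  use_tissue <- "tissue" %in% names(pts)
  if (use_tissue && is.null(lib))
    stop("a spectral library is required to resolve tissue-class annotations")

  vs <- phantom$grid$voxel_size
  for (wl in phantom$wavelengths) {
    key <- as.character(wl)
    # node property values at this wavelength
    node_props <- if (use_tissue) {
      t(vapply(pts$tissue, function(tis) {
        p <- optics_lookup(lib, tis, wl)
        c(p$mua, p$mus, p$g, p$n)
      }, numeric(4)))
    } else {
      as.matrix(pts[, c("mua", "mus", "g", "n")])
    }
    colnames(node_props) <- c("mua", "mus", "g", "n")

    for (ln in ann$profile_lines) {
      P <- as.matrix(pts[ln, c("i", "j", "k")])
      Pmm <- sweep(P, 2, vs, "*") # voxel centers in grid mm (up to a shift)
      seg <- sqrt(rowSums((Pmm[-1, , drop = FALSE] -
                           Pmm[-nrow(Pmm), , drop = FALSE])^2))
      if (any(seg == 0)) stop("profile line contains repeated points")
      s_nodes <- c(0, cumsum(seg))
      # walk the polyline, collecting the voxels it traverses with their arc length
      step <- min(vs) / 4
      s_samp <- sort(unique(c(seq(0, s_nodes[length(s_nodes)], by = step),
                              s_nodes)))
      # position of each sample along the polyline
      pos <- matrix(NA_real_, length(s_samp), 3)
      for (q in seq_len(nrow(P) - 1)) {
        inseg <- s_samp >= s_nodes[q] & s_samp <= s_nodes[q + 1]
        f <- (s_samp[inseg] - s_nodes[q]) / (s_nodes[q + 1] - s_nodes[q])
        pos[inseg, ] <- (1 - f) %o% Pmm[q, ] + f %o% Pmm[q + 1, ]
      }
      vox <- round(sweep(pos, 2, vs, "/")) # back to 1-based indices
      vox_key <- vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3])
      # each traversed voxel is parameterized by the sample closest to its
      # center, so axis-aligned lines hit voxel centers exactly
      d2 <- rowSums((pos - sweep(vox, 2, vs, "*"))^2)
      ord <- order(vox_key, d2)
      keep <- ord[!duplicated(vox_key[ord])]
      vox <- vox[keep, , drop = FALSE]
      s_vox <- s_samp[keep]
      # node voxels take the node arc length exactly
      node_key <- P[, 1] + shape[1] * (P[, 2] + shape[2] * P[, 3])
      m <- match(vox_key[keep], node_key)
      s_vox[!is.na(m)] <- s_nodes[m[!is.na(m)]]
      idx <- cbind(vox[, 1], vox[, 2], vox[, 3])
      for (param in c("mua", "mus", "g", "n")) {
        vals <- .interp_eval(s_nodes, node_props[, param], s_vox, method)
        vol <- phantom[[param]][[key]]
        vol[idx] <- vals
        phantom[[param]][[key]] <- vol
      }
    }
  }
  phantom
}

#' Resample a volume under a rigid transform
#'
#' Applies a given 4x4 rigid (rotation + translation) world-space transform
#' to a volume defined on `grid`, resampling on the same grid: the output at
#' world position x equals the input at `solve(transform) %*% x`. Only
#' application is provided; estimating the transform is the job of upstream
#' registration tools.
#'
#' @param volume 3-D array on `grid`.
#' @param grid A `volume_grid`.
#' @param transform 4x4 rigid matrix (checked: orthonormal rotation block
#'   with determinant +1, to tolerance 1e-6).
#' @param interp `"nearest"` (preserves the input's value set) or
#'   `"trilinear"`.
#' @param fill Value for samples falling outside the grid (default 0).
#' @return Resampled 3-D array.
#' @export
apply_rigid_transform <- function(volume, grid, transform,
                                  interp = c("nearest", "trilinear"),
                                  fill = 0) {
  stopifnot(inherits(grid, "volume_grid"))
  .check_volume(grid, volume)
  interp <- match.arg(interp)
  transform <- as.matrix(transform)
  if (!identical(dim(transform), c(4L, 4L)))
    stop("transform must be a 4x4 matrix")
  R <- transform[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6 ||
      max(abs(transform[4, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("transform is not rigid (rotation + translation)")

  shape <- grid$shape
  ijk <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  xyz <- voxel_to_world(grid, ijk)
  inv <- solve(transform)
  src <- xyz %*% t(inv[1:3, 1:3]) + matrix(inv[1:3, 4], nrow(xyz), 3,
                                           byrow = TRUE)
  v <- world_to_voxel(grid, src)
  out <- rep(fill, nrow(v))
  if (interp == "nearest") {
    r <- round(v)
    ok <- r[, 1] >= 1 & r[, 1] <= shape[1] & r[, 2] >= 1 & r[, 2] <= shape[2] &
          r[, 3] >= 1 & r[, 3] <= shape[3]
    out[ok] <- volume[r[ok, , drop = FALSE]]
  } else {
    f0 <- floor(v)
    fr <- v - f0
    ok <- f0[, 1] >= 1 & f0[, 1] + 1 <= shape[1] &
          f0[, 2] >= 1 & f0[, 2] + 1 <= shape[2] &
          f0[, 3] >= 1 & f0[, 3] + 1 <= shape[3]
    f0k <- f0[ok, , drop = FALSE]
    frk <- fr[ok, , drop = FALSE]
    acc <- numeric(sum(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) frk[, 1] else 1 - frk[, 1]) *
             (if (dy) frk[, 2] else 1 - frk[, 2]) *
             (if (dz) frk[, 3] else 1 - frk[, 3])
      acc <- acc + wgt * volume[cbind(f0k[, 1] + dx, f0k[, 2] + dy,
                                      f0k[, 3] + dz)]
    }
    out[ok] <- acc
  }
  array(out, shape)
}
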