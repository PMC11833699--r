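#' Optical properties of a tissue
#'
#' Bundle of the four wavelength-dependent optical parameters used throughout
#' the package: the absorption coefficient `mua` (mm^-1), the scattering
#' coefficient `mus` (mm^-1), the scattering anisotropy `g` (mean cosine of
#' the single-scattering deflection, dimensionless) and the refractive index
#' `n`.
#'
#' @param mua Absorption coefficient, mm^-1 (>= 0).
#' @param mus Scattering coefficient, mm^-1 (>= 0).
#' @param g Scattering anisotropy in \[-1, 1\]. The transport engine
#'   additionally clamps `g` to at most 0.999 when sampling deflections.
#' @param n Refractive index (>= 1).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mua = 0.02, mus = 8, g = 0.9, n = 1.37)
#' @export
optical_properties <- function(mua, mus, g, n) {
  stopifnot(is.numeric(mua), is.numeric(mus), is.numeric(g), is.numeric(n),
            length(mua) == 1, length(mus) == 1, length(g) == 1, length(n) == 1)
  if (mua < 0) stop("mua must be >= 0")
  if (mus < 0) stop("mus must be >= 0")
  if (g < -1 || g > 1) stop("g must lie in [-1, 1]")
  if (n < 1) stop("n must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical_properties: mua=%g mm^-1, mus=%g mm^-1, g=%g, n=%g\n",
              x$mua, x$mus, x$g, x$n))
  invisible(x)
}

#' Reduced scattering coefficient
#'
#' The reduced (transport-corrected) scattering coefficient
#' `mus' = (1 - g) * mus`, the effective isotropic scattering rate of a
#' forward-peaked medium.
#'
#' @param props An [optical_properties()] object.
#' @return Reduced scattering coefficient, mm^-1.
#' @export
reduced_scattering <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  (1 - props$g) * props$mus
}

#' Effective attenuation coefficient
#'
#' The diffusion-theory decay rate of diffuse fluence far from sources,
#' `mueff = sqrt(3 * mua * (mua + mus'))` with `mus' = (1 - g) * mus`.
#' It is zero exactly when `mua` is zero: a non-absorbing medium scatters
#' light but does not attenuate the total diffuse energy.
#'
#' @param props An [optical_properties()] object.
#' @return Effective attenuation coefficient, mm^-1.
#' @export
effective_attenuation <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  musp <- reduced_scattering(props)
  sqrt(3 * props$mua * (props$mua + musp))
}

.validate_library_entries <- function(entries) {
  if (!is.list(entries) || length(entries) == 0)
    stop("spectral library needs at least one tissue class")
  for (tissue in names(entries)) {
    nodes <- entries[[tissue]]
    if (!is.list(nodes) || length(nodes) == 0)
      stop(sprintf("tissue class '%s' has no wavelength entries", tissue))
    wl <- suppressWarnings(as.numeric(names(nodes)))
    if (anyNA(wl) || any(wl <= 0))
      stop(sprintf("tissue class '%s' has non-positive or non-numeric wavelength nodes", tissue))
    for (k in names(nodes)) {
      p <- nodes[[k]]
      req <- c("mua", "mus", "g", "n")
      if (!all(req %in% names(p)))
        stop(sprintf("entry %s@%s is missing one of mua/mus/g/n", tissue, k))
      # round-trips through optical_properties() to enforce the invariants
      optical_properties(p$mua, p$mus, p$g, p$n)
    }
  }
  if ("air" %in% names(entries)) {
    for (k in names(entries$air)) {
      p <- entries$air[[k]]
      if (p$mua != 0 || p$mus != 0 || p$n != 1)
        stop("the 'air' class must have mua = 0, mus = 0, n = 1")
    }
  }
  invisible(entries)
}

#' Spectral tissue-optics library
#'
#' A mapping (tissue class, wavelength in nm) -> optical properties; the
#' single source of truth for tissue optics in phantom synthesis. Between
#' tabulated wavelength nodes each property is linearly interpolated;
#' extrapolation outside the node range is refused.
#'
#' @param entries Nested list `tissue -> wavelength (as character) -> list
#'   with mua, mus, g, n`.
#' @return An object of class `spectral_library`.
#' @seealso [default_spectral_library()], [read_spectral_library()]
#' @export
spectral_library <- function(entries) {
  .validate_library_entries(entries)
  structure(list(entries = entries, tissue_classes = names(entries)),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("spectral_library with", length(x$tissue_classes), "tissue classes:\n")
  for (tissue in x$tissue_classes) {
    wl <- sort(as.numeric(names(x$entries[[tissue]])))
    cat(sprintf("  %-14s @ %s nm\n", tissue, paste(wl, collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a spectral library as JSON
#'
#' File schema: `{tissue: {"<wavelength_nm>": {"mua": .., "mus": .., "g": ..,
#' "n": ..}}}` with mua/mus in mm^-1. The reader validates the schema and all
#' property invariants before returning.
#'
#' @param path Path to a JSON file.
#' @return A `spectral_library`.
#' @export
read_spectral_library <- function(path) {
  if (!file.exists(path)) stop("spectral library file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  spectral_library(raw)
}

#' @rdname read_spectral_library
#' @param lib A `spectral_library` to serialize.
#' @export
write_spectral_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  jsonlite::write_json(lib$entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default spectral library
#'
#' Literature-plausible optical parameters for the head tissue classes
#' (gray_matter, white_matter, csf, skull, soft_tissue, air) and the ocular
#' extension set (cornea, aqueous, lens, vitreous, orbital_fat, muscle,
#' sclera_retina, eyelid_skin) at 670, 810, 850, 980 and 1070 nm. These are
#' configurable defaults shipped with the package, not measurements: replace
#' them with your own library file for quantitative work on real anatomy.
#'
#' @return A `spectral_library`.
#' @export
default_spectral_library <- function() {
  path <- system.file("extdata", "default_optics.json", package = "nirdosim",
                      mustWork = TRUE)
  read_spectral_library(path)
}

#' Look up optical properties at a wavelength
#'
#' Returns the stored entry when `wavelength` is a library node, otherwise
#' linearly interpolates each property between the two bracketing nodes.
#' Wavelengths outside the tissue's node range are refused.
#'
#' @param lib A `spectral_library`.
#' @param tissue Tissue class name.
#' @param wavelength Wavelength, nm.
#' @return An [optical_properties()] object.
#' @export
optics_lookup <- function(lib, tissue, wavelength) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!tissue %in% lib$tissue_classes)
    stop("unknown tissue class: ", tissue)
  nodes <- lib$entries[[tissue]]
  wl <- as.numeric(names(nodes))
  ord <- order(wl)
  wl <- wl[ord]
  nodes <- nodes[ord]
  hit <- which(wl == wavelength)
  if (length(hit) == 1) {
    p <- nodes[[hit]]
    return(optical_properties(p$mua, p$mus, p$g, p$n))
  }
  if (wavelength < wl[1] || wavelength > wl[length(wl)])
    stop(sprintf("wavelength %g nm outside library range [%g, %g] for %s",
                 wavelength, wl[1], wl[length(wl)], tissue))
  hi <- which(wl > wavelength)[1]
  lo <- hi - 1
  f <- (wavelength - wl[lo]) / (wl[hi] - wl[lo])
  a <- nodes[[lo]]; b <- nodes[[hi]]
  optical_properties(
    mua = (1 - f) * a$mua + f * b$mua,
    mus = (1 - f) * a$mus + f * b$mus,
    g   = (1 - f) * a$g + f * b$g,
    n   = (1 - f) * a$n + f * b$n
  )
}

#' Mix optical properties of a heterogeneous voxel
#'
#' Probability-weighted averaging of tissue optical parameters within one
#' voxel. `mua`, `mus` and `n` are arithmetic weighted means; the anisotropy
#' `g` is averaged with weights `w_i * mus_i` (anisotropy is only physically
#' meaningful where scattering occurs), falling back to the plain weighted
#' mean when the total scattering weight is zero. A weight deficit
#' (sum of weights < 1) is assigned to the `air` class (mua = 0, mus = 0,
#' n = 1, g taken as 0), so background and sinus voxels stay inert.
#'
#' @param weights Named numeric vector of tissue fractions in \[0, 1\];
#'   the sum must not exceed 1 (+1e-6).
#' @param lib A `spectral_library`.
#' @param wavelength Wavelength, nm.
#' @return An [optical_properties()] object.
#' @export
mix_properties <- function(weights, lib, wavelength) {
  if (length(weights) == 0) stop("empty weights")
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a named vector of tissue classes")
  if (any(weights < 0) || any(weights > 1))
    stop("weights must lie in [0, 1]")
  if (sum(weights) > 1 + 1e-6)
    stop("weights sum exceeds 1")
  deficit <- max(0, 1 - sum(weights))
  props <- lapply(names(weights), function(tis)
    optics_lookup(lib, tis, wavelength))
  w <- as.numeric(weights)
  mua <- sum(w * vapply(props, `[[`, numeric(1), "mua"))
  mus <- sum(w * vapply(props, `[[`, numeric(1), "mus"))
  n <- sum(w * vapply(props, `[[`, numeric(1), "n")) + deficit * 1
  gs <- vapply(props, `[[`, numeric(1), "g")
  muss <- vapply(props, `[[`, numeric(1), "mus")
  sw <- sum(w * muss) # air contributes zero scattering weight
  g <- if (sw > 0) sum(w * muss * gs) / sw else sum(w * gs) / max(sum(w) + deficit, .Machine$double.eps)
  optical_properties(mua = mua, mus = mus, g = g, n = n)
}

#' Unpolarized Fresnel reflectance at a refractive-index step
#'
#' Average of the s- and p-polarized Fresnel reflectances for a ray crossing
#' from index `n1` into `n2` with incidence cosine `cos_incident`. Beyond the
#' critical angle the function reports total internal reflection.
#'
#' @param n1,n2 Refractive indices (>= 1).
#' @param cos_incident Cosine of the incidence angle, in (0, 1\].
#' @return List with `R` (reflectance in \[0, 1\]), `cos_transmitted`
#'   (NA under total internal reflection) and logical `tir`.
#' @export
fresnel <- function(n1, n2, cos_incident) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (cos_incident <= 0 || cos_incident > 1)
    stop("cos_incident must lie in (0, 1]")
  if (n1 == n2)
    return(list(R = 0, cos_transmitted = cos_incident, tir = FALSE))
  sin2i <- 1 - cos_incident^2
  sin2t <- (n1 / n2)^2 * sin2i
  if (sin2t >= 1)
    return(list(R = 1, cos_transmitted = NA_real_, tir = TRUE))
  ct <- sqrt(1 - sin2t)
  rs <- ((n1 * cos_incident - n2 * ct) / (n1 * cos_incident + n2 * ct))^2
  rp <- ((n1 * ct - n2 * cos_incident) / (n1 * ct + n2 * cos_incident))^2
  list(R = (rs + rp) / 2, cos_transmitted = ct, tir = FALSE)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Draws deflection cosines from the Henyey-Greenstein phase function by
#' inverse-CDF sampling (uniform on \[-1, 1\] when `g = 0`); the first moment
#' of the distribution is `g`. Uses the same generator as the transport
#' engine, so a fixed seed reproduces the engine's deflections bit for bit.
#'
#' @param n Number of draws.
#' @param g Anisotropy, clamped to \[-0.999, 0.999\] at sampling time.
#' @param seed Integer seed.
#' @return Numeric vector of `n` deflection cosines in \[-1, 1\].
#' @export
sample_hg <- function(n, g, seed = 1L) {
  stopifnot(n >= 1, g >= -1, g <= 1)
  cpp_sample_hg(as.integer(n), g, as.numeric(seed))
}
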