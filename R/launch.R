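#' Sample launch states from a source
#'
#' Draws photon launch positions and directions from an illumination source
#' using the same sampling code as the transport engine: positions uniform
#' over the emitting surface with collimated (surface-normal) directions for
#' disk and rectangular emitters, isotropic directions for point emitters.
#' Each packet starts with weight 1 at time 0.
#'
#' @param src A [source_spec()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return `n` x 6 matrix, columns `x, y, z, ux, uy, uz` (world mm / unit
#'   direction).
#' @export
sample_launch <- function(src, n, seed = 1L) {
  stopifnot(inherits(src, "source_spec"), n >= 1)
  eng <- list(kind = src$kind, center = src$center,
              direction = src$direction, e1 = src$e1, e2 = src$e2,
              radius = src$radius_mm, width = src$width_mm,
              height = src$height_mm)
  out <- cpp_sample_launch(eng, as.integer(n), as.numeric(seed))
  colnames(out) <- c("x", "y", "z", "ux", "uy", "uz")
  out
}
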