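#' Monte Carlo simulation configuration
#'
#' @param n_photons Photon packets to launch (total, shared across sources
#'   in proportion to their power).
#' @param seed Integer seed; a run is bit-reproducible given
#'   (seed, n_photons, single thread).
#' @param time_gate_ns Width of one time gate, ns (default 0.3, the temporal
#'   resolution used for time-resolved recording).
#' @param n_gates Number of time gates; 0 records steady state only. When
#'   gating is on, arrivals later than the last gate accumulate in one extra
#'   overflow gate so that the gate sum always equals the steady-state tally.
#' @param weight_threshold Packet weight below which Russian roulette
#'   triggers (default 1e-4; 0 disables roulette).
#' @param roulette_survival Roulette survival probability (default 0.1);
#'   survivors are reweighted by 1/probability, keeping the estimator
#'   unbiased.
#' @param ambient_n Refractive index outside the grid (default 1).
#' @param max_path_mm Safety cap on the total path length of one packet;
#'   capped packets are tallied separately.
#' @param emission `"collimated"` (surface-normal, default) or `"cosine"`
#'   (cosine-weighted lobe about the surface normal) for disk/rect sources;
#'   clinical LED divergence profiles are rarely specified, so collimated
#'   emission is the default and the lobe a sensitivity option.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_photons = 1e5, seed = 1L, time_gate_ns = 0.3,
                       n_gates = 0L, weight_threshold = 1e-4,
                       roulette_survival = 0.1, ambient_n = 1,
                       max_path_mm = 20000,
                       emission = c("collimated", "cosine")) {
  emission <- match.arg(emission)
  stopifnot(n_photons >= 1, time_gate_ns > 0, n_gates >= 0,
            weight_threshold >= 0, ambient_n >= 1, max_path_mm > 0)
  if (weight_threshold > 0 &&
      (roulette_survival <= 0 || roulette_survival >= 1))
    stop("roulette_survival must lie in (0, 1)")
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 time_gate_ns = time_gate_ns, n_gates = as.integer(n_gates),
                 weight_threshold = weight_threshold,
                 roulette_survival = roulette_survival,
                 ambient_n = ambient_n, max_path_mm = max_path_mm,
                 emission = emission),
            class = "sim_config")
}

# per-source sub-seed, derived deterministically and kept well below 2^53
.sub_seed <- function(seed, idx) {
  (as.numeric(seed) %% 2^31) * 4096 + idx
}

.src_to_engine <- function(src, grid, cosine = FALSE) {
  corner <- grid$origin - grid$voxel_size # low corner of voxel (1,1,1)
  list(kind = src$kind, center = src$center - corner,
       direction = src$direction, e1 = src$e1, e2 = src$e2,
       radius = src$radius_mm, width = src$width_mm, height = src$height_mm,
       cosine = cosine)
}

#' Run the voxel Monte Carlo photon transport
#'
#' Launches photon packets from each source (allocation proportional to
#' source power), propagates them through the phantom with
#' Henyey-Greenstein scattering, continuous absorption along the path
#' (track-length fluence estimator), Fresnel reflection/refraction at voxel
#' faces where the refractive index changes (including entry from and escape
#' to ambient air) and Russian roulette for low-weight packets, and records
#' per-voxel fluence (optionally per time gate).
#'
#' Fluence is reported per launched unit of source energy, in mm^-2
#' (track-length sum / voxel volume / launched weight); multiply by the
#' total source power via [scale_to_physical()] for mW/mm^2. The absorbed
#' volume is `fluence * mua * voxel volume`, the fraction of launched energy
#' absorbed per voxel.
#'
#' @param phantom An `optical_phantom`.
#' @param sources A `source_spec` or list of them; every source wavelength
#'   must be mapped in the phantom.
#' @param config A [sim_config()].
#' @param per_source Keep per-source fluence/absorbed volumes (needed by
#'   [energy_flow()] and [response_matrix()]); costs one volume per source.
#' @return An object of class `sim_result` with fields `fluence`, `absorbed`
#'   (3-D arrays), optional `gates` (nvox x (n_gates + 1) matrix, last
#'   column = late-arrival overflow), the scalar fractions
#'   `absorbed_fraction`, `escaped_fraction`, `capped_fraction`,
#'   `roulette_net`, per-source summaries, and an echo of grid, sources and
#'   config.
#' @export
run_mc <- function(phantom, sources, config = sim_config(),
                   per_source = FALSE) {
  stopifnot(inherits(phantom, "optical_phantom"), inherits(config, "sim_config"))
  if (inherits(sources, "source_spec")) sources <- list(sources)
  stopifnot(length(sources) >= 1,
            all(vapply(sources, inherits, logical(1), "source_spec")))
  for (src in sources) {
    if (!as.character(src$wavelength) %in% names(phantom$mua))
      stop("source wavelength ", src$wavelength,
           " nm is not mapped in the phantom")
  }
  grid <- phantom$grid
  shape <- grid$shape
  nvox <- prod(shape)
  vv <- prod(grid$voxel_size)

  powers <- vapply(sources, source_power, numeric(1))
  if (any(powers <= 0)) stop("all sources must have positive power")
  share <- powers / sum(powers)
  nph <- round(config$n_photons * share)
  nph[nph < 1] <- 1

  fluence <- numeric(nvox)
  gates <- NULL
  gated <- config$n_gates > 0
  if (gated) gates <- matrix(0, nvox, config$n_gates + 1)
  per_src <- vector("list", length(sources))
  scal <- data.frame(source = seq_along(sources), wavelength = NA_real_,
                     n_photons = NA_real_, power_mw = powers,
                     absorbed_fraction = NA_real_, escaped_fraction = NA_real_,
                     capped_fraction = NA_real_, roulette_net = NA_real_)

  for (sidx in seq_along(sources)) {
    src <- sources[[sidx]]
    key <- as.character(src$wavelength)
    res <- cpp_mc_run(
      as.vector(phantom$mua[[key]]), as.vector(phantom$mus[[key]]),
      as.vector(phantom$g[[key]]), as.vector(phantom$n[[key]]),
      shape, grid$voxel_size,
      .src_to_engine(src, grid, cosine = config$emission == "cosine"),
      nph[sidx], .sub_seed(config$seed, sidx),
      config$time_gate_ns, config$n_gates,
      config$weight_threshold, config$roulette_survival,
      config$max_path_mm, config$ambient_n)
    fl <- res$fluence / (vv * nph[sidx]) # per-photon fluence, mm^-2
    fluence <- fluence + share[sidx] * fl
    if (gated) gates <- gates + share[sidx] * res$gates / (vv * nph[sidx])
    scal$wavelength[sidx] <- src$wavelength
    scal$n_photons[sidx] <- nph[sidx]
    scal$absorbed_fraction[sidx] <- res$absorbed / nph[sidx]
    scal$escaped_fraction[sidx] <- res$escaped / nph[sidx]
    scal$capped_fraction[sidx] <- res$capped / nph[sidx]
    scal$roulette_net[sidx] <- (res$roulette_killed - res$roulette_boosted) / nph[sidx]
    if (per_source) {
      mua <- phantom$mua[[key]]
      per_src[[sidx]] <- list(
        fluence = array(fl, shape),
        absorbed = array(fl * as.vector(mua) * vv, shape))
    }
  }

  # absorbed per voxel: with one wavelength this is fluence * mua * voxel
  # volume; mixed wavelengths need the per-source volumes to recombine.
  wls <- unique(vapply(sources, `[[`, numeric(1), "wavelength"))
  if (length(wls) == 1) {
    absorbed <- fluence * as.vector(phantom$mua[[as.character(wls)]]) * vv
  } else {
    if (!per_source) stop("mixed-wavelength runs need per_source = TRUE")
    absorbed <- numeric(nvox)
    for (sidx in seq_along(sources))
      absorbed <- absorbed + share[sidx] * as.vector(per_src[[sidx]]$absorbed)
  }

  structure(list(
    grid = grid, fluence = array(fluence, shape),
    absorbed = array(absorbed, shape), gates = gates,
    absorbed_fraction = sum(share * scal$absorbed_fraction),
    escaped_fraction = sum(share * scal$escaped_fraction),
    capped_fraction = sum(share * scal$capped_fraction),
    roulette_net = sum(share * scal$roulette_net),
    per_source = if (per_source) per_src else NULL,
    source_summary = scal, sources = sources, config = config),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("sim_result: %d source(s), %g photons\n",
                     "  absorbed %.4f  escaped %.4f  capped %.2g  roulette net %.2g\n"),
              length(x$sources), sum(x$source_summary$n_photons),
              x$absorbed_fraction, x$escaped_fraction, x$capped_fraction,
              x$roulette_net))
  invisible(x)
}

#' Scale a simulation result to physical units
#'
#' Multiplies the per-launched-energy tallies by the total source power
#' (sum of power density x emitting area over all sources), yielding the
#' fluence-rate volume in mW/mm^2 and the absorbed-power volume in mW.
#' Exactly linear in source power.
#'
#' @param result A `sim_result`.
#' @param sources Sources to take the power from (default: those recorded in
#'   the result).
#' @return List with `fluence_mw_mm2`, `absorbed_mw` (3-D arrays) and
#'   `total_power_mw`.
#' @export
scale_to_physical <- function(result, sources = result$sources) {
  stopifnot(inherits(result, "sim_result"))
  if (length(sources) == 0) stop("no sources to scale by")
  total <- sum(vapply(sources, source_power, numeric(1)))
  if (total <= 0) stop("total source power must be positive")
  list(fluence_mw_mm2 = result$fluence * total,
       absorbed_mw = result$absorbed * total,
       total_power_mw = total)
}
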