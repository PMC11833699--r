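#' Read and write volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the package's axis-aligned RAS grid
#' convention. `write_volume()` stores a 3-D array with the grid geometry in
#' the NIfTI affine; `read_volume()` returns the array plus a reconstructed
#' [volume_grid()] and refuses volumes whose affine is not axis-aligned
#' (rotated acquisitions must be resampled upstream).
#'
#' @param volume 3-D array.
#' @param grid A `volume_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  .check_volume(grid, volume)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- grid$voxel_size # before the xforms, which scale by it
  aff <- structure(diag(4), code = 2L)
  diag(aff)[1:3] <- grid$voxel_size
  aff[1:3, 4] <- grid$origin
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @return `read_volume()`: list with `volume` (array) and `grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  R <- aff[1:3, 1:3]
  if (max(abs(R - diag(diag(R)))) > 1e-6)
    stop("NIfTI affine is not axis-aligned; resample to RAS first: ", path)
  if (any(diag(R) <= 0))
    stop("NIfTI affine has non-positive scales (flips unsupported): ", path)
  vol <- array(as.numeric(img), dim(img)[1:3])
  grid <- volume_grid(dim(vol), voxel_size = diag(R), origin = aff[1:3, 4])
  list(volume = vol, grid = grid)
}

#' Persist and reload an optical phantom
#'
#' A phantom is stored as one NIfTI volume per optical parameter per
#' wavelength plus the head mask, tied together by a JSON manifest naming
#' the files.
#'
#' @param phantom An `optical_phantom`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "optical_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(wavelengths = phantom$wavelengths,
                   classes = phantom$classes, volumes = list())
  for (wl in phantom$wavelengths) {
    key <- as.character(wl)
    for (param in c("mua", "mus", "g", "n")) {
      fn <- sprintf("%s_%s_%snm.nii.gz", prefix, param, key)
      write_volume(phantom[[param]][[key]], phantom$grid, file.path(dir, fn))
      manifest$volumes[[paste(param, key, sep = "@")]] <- fn
    }
  }
  fn_mask <- paste0(prefix, "_headmask.nii.gz")
  write_volume(phantom$head_mask * 1, phantom$grid, file.path(dir, fn_mask))
  manifest$head_mask <- fn_mask
  jsonlite::write_json(manifest, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_phantom
#' @param manifest_path Path to the phantom's JSON manifest.
#' @export
read_phantom <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  out <- list(wavelengths = as.numeric(man$wavelengths),
              mua = list(), mus = list(), g = list(), n = list(),
              classes = man$classes)
  grid <- NULL
  for (nm in names(man$volumes)) {
    parts <- strsplit(nm, "@", fixed = TRUE)[[1]]
    v <- read_volume(file.path(dir, man$volumes[[nm]]))
    if (is.null(grid)) grid <- v$grid
    out[[parts[1]]][[parts[2]]] <- v$volume
  }
  mask <- read_volume(file.path(dir, man$head_mask))
  out$head_mask <- mask$volume > 0.5
  out$grid <- grid
  structure(out, class = "optical_phantom")
}

#' Persist and reload a simulation result
#'
#' Stores the fluence and absorbed volumes (and time gates, if present) as
#' NIfTI files next to a JSON sidecar holding the scalar bookkeeping and the
#' configuration echo.
#'
#' @param result A `sim_result`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_sim_result <- function(result, dir, prefix = "sim") {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(result$fluence, result$grid, file.path(dir, paste0(prefix, "_fluence.nii.gz")))
  write_volume(result$absorbed, result$grid, file.path(dir, paste0(prefix, "_absorbed.nii.gz")))
  meta <- list(absorbed_fraction = result$absorbed_fraction,
               escaped_fraction = result$escaped_fraction,
               capped_fraction = result$capped_fraction,
               roulette_net = result$roulette_net,
               config = unclass(result$config),
               n_gates = if (is.null(result$gates)) 0L else ncol(result$gates))
  if (!is.null(result$gates)) {
    for (gi in seq_len(ncol(result$gates)))
      write_volume(array(result$gates[, gi], result$grid$shape), result$grid,
                   file.path(dir, sprintf("%s_gate%03d.nii.gz", prefix, gi)))
  }
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_sim_result
#' @param manifest_path Path to the result's JSON sidecar.
#' @export
read_sim_result <- function(manifest_path) {
  meta <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  prefix <- sub("\\.json$", "", basename(manifest_path))
  fl <- read_volume(file.path(dir, paste0(prefix, "_fluence.nii.gz")))
  ab <- read_volume(file.path(dir, paste0(prefix, "_absorbed.nii.gz")))
  gates <- NULL
  if (meta$n_gates > 0) {
    gates <- matrix(0, prod(fl$grid$shape), meta$n_gates)
    for (gi in seq_len(meta$n_gates))
      gates[, gi] <- as.vector(read_volume(
        file.path(dir, sprintf("%s_gate%03d.nii.gz", prefix, gi)))$volume)
  }
  cfg <- do.call(sim_config, meta$config[c("n_photons", "seed", "time_gate_ns",
                                           "n_gates", "weight_threshold",
                                           "roulette_survival", "ambient_n",
                                           "max_path_mm", "emission")])
  structure(list(grid = fl$grid, fluence = fl$volume, absorbed = ab$volume,
                 gates = gates,
                 absorbed_fraction = meta$absorbed_fraction,
                 escaped_fraction = meta$escaped_fraction,
                 capped_fraction = meta$capped_fraction,
                 roulette_net = meta$roulette_net,
                 per_source = NULL, source_summary = NULL,
                 sources = list(), config = cfg),
            class = "sim_result")
}

#' Read / write a region label lookup table as TSV
#'
#' Two tab-separated columns, `label` and `region`.
#'
#' @param path File path.
#' @export
read_label_lookup <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("label", "region") %in% names(df)))
    stop("label lookup must have columns 'label' and 'region': ", path)
  df$label <- as.integer(df$label)
  df
}

#' @rdname read_label_lookup
#' @param lookup Data frame with columns `label`, `region`.
#' @export
write_label_lookup <- function(lookup, path) {
  utils::write.table(lookup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a dose table as TSV
#'
#' Columns in fixed order: unit, name, pct_of_absorbed, pct_of_launched,
#' mean_fluence_mw_mm2, volume_mm3, empty.
#'
#' @param dose A data frame from [roi_dose()].
#' @param path File path.
#' @export
write_dose_table <- function(dose, path) {
  cols <- c("unit", "name", "pct_of_absorbed", "pct_of_launched",
            "mean_fluence_mw_mm2", "volume_mm3", "empty")
  utils::write.table(dose[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write source specifications as JSON
#'
#' A sources file is a JSON list of records mirroring [source_spec()]
#' fields (`kind`, `center`, `direction`, `wavelength`,
#' `power_density_mw_cm2`, plus the geometry fields for the kind).
#'
#' @param path File path.
#' @return `read_sources()`: list of `source_spec` objects.
#' @export
read_sources <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(r) {
    do.call(source_spec, r[intersect(names(r),
      c("kind", "center", "direction", "wavelength", "power_density_mw_cm2",
        "radius_mm", "width_mm", "height_mm", "u_axis", "power_mw"))])
  })
}

#' @rdname read_sources
#' @param sources List of `source_spec` objects.
#' @export
write_sources <- function(sources, path) {
  if (inherits(sources, "source_spec")) sources <- list(sources)
  recs <- lapply(sources, function(s)
    Filter(Negate(is.null),
           s[c("kind", "center", "direction", "wavelength",
               "power_density_mw_cm2", "radius_mm", "width_mm", "height_mm",
               "power_mw")]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
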