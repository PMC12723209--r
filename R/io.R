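#' Write parameter maps as NIfTI volumes with a JSON sidecar
#'
#' Writes `<prefix>_t1.nii`, `<prefix>_t1rho.nii`, `<prefix>_ssd.nii` with
#' the voxel spacing in the header, plus `<prefix>.json` recording the
#' dictionary grid extents, heart rate, acquisition window and package
#' version.
#'
#' @param maps `parameter_maps` object
#' @param prefix output path prefix
#' @param dict optional dictionary whose settings go into the sidecar
#' @return invisibly, the written file paths
#' @export
write_maps_nifti <- function(maps, prefix, dict = NULL) {
  paths <- character(0)
  for (p in c("t1", "t1rho", "ssd")) {
    img <- RNifti::asNifti(maps[[p]])
    RNifti::pixdim(img) <- maps$spacing
    f <- paste0(prefix, "_", p, ".nii")
    RNifti::writeNifti(img, f)
    paths <- c(paths, f)
  }
  side <- list(spacing_mm = maps$spacing, hr_bpm = maps$hr,
               software = paste0("jointmap ",
                                 as.character(utils::packageVersion("jointmap"))))
  if (!is.null(dict))
    side <- c(side, list(
      t1_grid_ms = range(dict$grid$t1_values),
      t1rho_grid_ms = range(dict$grid$t1rho_values),
      n_atoms = nrow(dict$atoms),
      acq_window_s = dict$acq_window))
  jf <- paste0(prefix, ".json")
  jsonlite::write_json(side, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jf))
}

#' Read a 3D volume from NIfTI
#' @param path file path
#' @return numeric array with a `spacing` attribute (mm)
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "spacing") <- RNifti::pixdim(img)
  arr
}

#' Load sequence and timing configuration from YAML/JSON
#'
#' Keys mirror the [sequence_params()] and [cardiac_timing()] argument
#' names, under top-level `sequence` and `timing` blocks (flat files are
#' also accepted).
#'
#' @param path YAML or JSON file
#' @return list with `seq` and `timing`
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  sq <- cfg$sequence %||% cfg
  tm <- cfg$timing %||% cfg
  take <- function(args, fn) args[intersect(names(args), names(formals(fn)))]
  seq <- do.call(sequence_params, take(sq, sequence_params))
  timing <- do.call(cardiac_timing, take(tm, cardiac_timing))
  list(seq = seq, timing = timing, raw = cfg)
}

#' Persist / load a k-space dataset
#' @param kspace `jointmap_kspace`
#' @param path file path
#' @return `path` (write) or the dataset (read)
#' @export
write_kspace <- function(kspace, path) { saveRDS(kspace, path); invisible(path) }

#' @rdname write_kspace
#' @export
read_kspace <- function(path) readRDS(path)
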