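#' NIfTI export of maps, region labels and DCE series
#'
#' Parameter maps and concentration frames are written as NIfTI volumes
#' with the lattice spacing as pixel dimension (um stored as mm * 1e-3
#' would lose the unit policy, so pixdim is recorded in um and noted in
#' the description field). Series are 4d volumes (x, y, z, t) with the
#' frame times in a sidecar CSV.
#'
#' @param map Numeric array over the lattice.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param lattice The [lattice_spec()] (for pixel dimensions).
#' @export
write_map_nifti <- function(map, path, lattice = NULL) {
  img <- RNifti::asNifti(map)
  if (!is.null(lattice)) RNifti::pixdim(img) <- rep(lattice$l, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(as.numeric(arr), dim(arr))
}

#' @rdname write_map_nifti
#' @param series A `dce_series`.
#' @export
write_series_nifti <- function(series, path) {
  d <- series$lattice$dims
  arr <- array(series$c, c(d, ncol(series$c)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(series$lattice$l, 3), diff(series$times[1:2]))
  RNifti::writeNifti(img, path)
  write.csv(data.frame(frame = seq_along(series$times),
                       t_s = series$times),
            sub("\\.nii(\\.gz)?$", "_times.csv", path), row.names = FALSE)
  invisible(path)
}

#' Write a region map as an 8-bit labelled NIfTI volume
#' @param regions A `region_map`.
#' @param path Output path.
#' @export
write_region_nifti <- function(regions, path) {
  lat <- attr(regions, "lattice")
  img <- RNifti::asNifti(array(as.integer(regions), dim(regions)),
                         datatype = "uint8")
  RNifti::pixdim(img) <- rep(lat$l, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write-then-read round trip for the supported objects
#'
#' Dispatches on object class and file extension: `vascular_graph` to
#' GraphML, arrays / parameter maps to NIfTI, `aif_model` to CSV,
#' `run_config` to YAML. Returns the re-read object, which must equal the
#' input (graph attribute-equality; arrays bitwise for the lossless
#' formats).
#'
#' @param object The object to round-trip.
#' @param path Target path with a supported extension.
#' @export
io_roundtrip <- function(object, path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (inherits(object, "vascular_graph")) {
    if (ext != "graphml")
      stop_invalid("vascular graphs support: graphml")
    write_graphml(object, path)
    return(read_graphml(path))
  }
  if (is.array(object) || is.numeric(object)) {
    if (ext != "nii") stop_invalid("arrays support: nii, nii.gz")
    write_map_nifti(object, path)
    arr <- as.array(RNifti::readNifti(path))
    return(array(as.numeric(arr), dim(arr)))
  }
  if (inherits(object, "aif_model")) {
    if (ext != "csv") stop_invalid("AIF models support: csv")
    write_aif_csv(object, path)
    return(read_aif_csv(path))
  }
  if (inherits(object, "run_config") || (is.list(object) && ext == "yaml")) {
    if (!ext %in% c("yaml", "yml")) stop_invalid("configs support: yaml")
    yaml::write_yaml(unclass(object), path)
    cfg <- yaml::read_yaml(path)
    class(cfg) <- "run_config"
    return(cfg)
  }
  stop_invalid("unsupported object/extension; supported: graphml, nii(.gz), csv, yaml")
}
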