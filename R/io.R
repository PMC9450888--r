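#' Volume and table I/O
#'
#' Volumes are written as multi-page 32-bit float TIFF (one page per z
#' slice) accompanied by a JSON sidecar (`<stem>.json`) that records the
#' voxel size in nm, the channel name and the intensity scale used to map
#' the data into the TIFF's unit range. Multi-channel scenes are written as
#' one TIFF per channel plus a shared manifest.
#'
#' @name volume-io
NULL

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a volume to TIFF (+ JSON metadata sidecar)
#'
#' @param vg a [voxel_grid()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vg, path) {
  stopifnot(inherits(vg, "exm_voxel_grid"))
  a <- vg$data
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  scale <- max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(z) t(a[, , z]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(voxel_size_nm = vg$voxel_size, channel = vg$channel,
               intensity_scale = scale, axis_order = "xyz",
               n_z = dim(a)[3])
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path `.tif` path (the `.json` sidecar must sit next to it).
#' @return a [voxel_grid()].
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) a[, , z] <- t(pages[[z]])
  a <- a * meta$intensity_scale
  voxel_grid(a, meta$voxel_size_nm,
             channel = if (is.null(meta$channel)) NA_character_ else meta$channel)
}

#' Write a multi-channel scene
#'
#' @param channels named list of [voxel_grid()]s sharing a geometry.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return the manifest path, invisibly.
#' @export
write_scene_tiff <- function(channels, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in names(channels)) {
    f <- file.path(dir, sprintf("%s_%s.tif", stem, ch))
    write_volume_tiff(channels[[ch]], f)
    files[ch] <- basename(f)
  }
  manifest <- file.path(dir, sprintf("%s_channels.json", stem))
  jsonlite::write_json(as.list(files), manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a multi-channel scene written by [write_scene_tiff()]
#'
#' @param manifest path to the `<stem>_channels.json` manifest.
#' @return named list of [voxel_grid()]s.
#' @export
read_scene_tiff <- function(manifest) {
  files <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  out <- lapply(files, function(f) read_volume_tiff(file.path(dir, f)))
  names(out) <- names(files)
  out
}

#' Read/write a control-point table
#'
#' CSV columns: `id, pre_x, pre_y, pre_z, post_x, post_y, post_z` (nm,
#' origin at the image corner) and optionally `role` (`train`/`validation`).
#'
#' @param points control-point data frame.
#' @param path CSV path.
#' @return for the reader, a validated data frame.
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "pre_x", "pre_y", "pre_z", "post_x", "post_y", "post_z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("control-point table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}
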