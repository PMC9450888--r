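#' Nucleus segmentation and mask-based expansion factors
#'
#' Two routes, mirroring how pre/post-expansion nuclei are measured: a 2D
#' area route (rolling-ball-style background subtraction, explicit
#' threshold, connected-component labelling, area filters, boundary
#' tracing) and a 3D volume route (global Otsu threshold, binary erosion
#' then dilation, hole filling, component volumes). The post/pre ratio of
#' mean nuclear area or volume converts to a linear expansion factor via
#' the square or cube root.
#'
#' @name segmentation
NULL

new_nucleus_mask <- function(labels, stats, voxel_size, boundaries = NULL) {
  structure(list(labels = labels, stats = stats, voxel_size = voxel_size,
                 boundaries = boundaries),
            class = "exm_nucleus_mask")
}

#' @export
print.exm_nucleus_mask <- function(x, ...) {
  nd <- length(dim(x$labels))
  cat(sprintf("nucleus mask: %d label(s), %dD\n", nrow(x$stats), nd))
  if (nrow(x$stats)) print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Segment nuclei in a 2D image by explicit threshold
#'
#' Background is estimated by grayscale opening with a disc structuring
#' element of the given radius (the morphological form of a rolling-ball
#' background) and subtracted; the image is thresholded at the explicitly
#' supplied value (the historical workflow used a manually determined
#' threshold; set `otsu_fallback = TRUE` to derive one automatically),
#' connected regions are labelled and regions outside `[min_area,
#' max_area]` are removed — dropping features too small to be nuclei and
#' merged features spanning more than one nucleus.
#'
#' @param vg a 2D [voxel_grid()].
#' @param threshold intensity threshold applied after background
#'   subtraction (required unless `otsu_fallback`).
#' @param min_area_um2,max_area_um2 retained area range in µm². Defaults
#'   derive from `expected_diameter_um` assuming circular nuclei:
#'   `[0.25, 4] x` the implied circle area.
#' @param rolling_ball_radius_px background disc radius in pixels (0
#'   disables background subtraction).
#' @param expected_diameter_um expected nuclear diameter for the default
#'   area bounds.
#' @param otsu_fallback derive the threshold by Otsu's method instead.
#' @return an `exm_nucleus_mask`: integer `labels` image (0 background,
#'   labels contiguous from 1), `stats` (label, centroid nm, area µm²,
#'   pixel count), traced `boundaries` (list of n x 2 pixel-index
#'   matrices), `voxel_size`.
#' @export
segment_nuclei_2d <- function(vg, threshold = NULL,
                              min_area_um2 = NULL, max_area_um2 = NULL,
                              rolling_ball_radius_px = 25,
                              expected_diameter_um = 12,
                              otsu_fallback = FALSE) {
  stopifnot(inherits(vg, "exm_voxel_grid"), length(dim(vg$data)) == 2L)
  a <- vg$data
  if (rolling_ball_radius_px > 0) {
    sz <- 2L * as.integer(rolling_ball_radius_px) + 1L
    brush <- EBImage::makeBrush(sz, shape = "disc")
    bg <- EBImage::dilate(EBImage::erode(a, brush), brush)
    a <- pmax(a - bg, 0)
  }
  if (is.null(threshold)) {
    if (!otsu_fallback)
      stop("threshold is required (or set otsu_fallback = TRUE)",
           call. = FALSE)
    rng <- range(a)
    if (diff(rng) < 1e-12)
      stop("constant image: Otsu threshold undefined", call. = FALSE)
    threshold <- EBImage::otsu(EBImage::Image((a - rng[1]) / diff(rng))) *
      diff(rng) + rng[1]
  }
  if (is.null(min_area_um2) || is.null(max_area_um2)) {
    circ <- pi * (expected_diameter_um / 2)^2
    if (is.null(min_area_um2)) min_area_um2 <- 0.25 * circ
    if (is.null(max_area_um2)) max_area_um2 <- 4 * circ
  }
  if (min_area_um2 >= max_area_um2)
    stop("min_area must be smaller than max_area", call. = FALSE)
  mask <- a >= threshold
  lab <- array(as.integer(EBImage::bwlabel(mask * 1)), dim(a))
  px_area_um2 <- prod(vg$voxel_size[1:2]) / 1e6
  n0 <- max(lab)
  keep <- integer(0)
  if (n0 > 0) {
    counts <- tabulate(lab[lab > 0L], n0)
    areas <- counts * px_area_um2
    keep <- which(areas >= min_area_um2 & areas <= max_area_um2)
  }
  if (!length(keep)) {
    if (n0 > 0 || !any(mask))
      warning("no nuclei retained after area filtering")
    return(new_nucleus_mask(
      array(0L, dim(a)),
      data.frame(label = integer(0), centroid_x_nm = numeric(0),
                 centroid_y_nm = numeric(0), area_um2 = numeric(0),
                 n_pixels = integer(0)),
      vg$voxel_size, boundaries = list()))
  }
  relab <- array(0L, dim(a))
  stats_rows <- vector("list", length(keep))
  boundaries <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    sel <- lab == keep[j]
    relab[sel] <- j
    idx <- which(sel, arr.ind = TRUE)
    ctr <- colMeans(idx)
    stats_rows[[j]] <- data.frame(
      label = j,
      centroid_x_nm = (ctr[1] - 0.5) * vg$voxel_size[1],
      centroid_y_nm = (ctr[2] - 0.5) * vg$voxel_size[2],
      area_um2 = nrow(idx) * px_area_um2,
      n_pixels = nrow(idx))
    interior <- erode_mask(sel, 1L)
    boundaries[[j]] <- which(sel & !interior, arr.ind = TRUE)
  }
  new_nucleus_mask(relab, do.call(rbind, stats_rows), vg$voxel_size,
                   boundaries = boundaries)
}

#' Segment nuclei in a 3D stack by Otsu threshold
#'
#' Global Otsu threshold over the whole stack, binary erosion then
#' dilation with a voxel ball (radius 1 by default, same element for
#' both), hole filling, and 3D connected-component labelling with
#' per-label volumes.
#'
#' @param vg a 3D [voxel_grid()] with at least 2 z planes.
#' @param morph_radius structuring-element radius in voxels.
#' @param min_volume_um3 optional minimum retained component volume.
#' @return an `exm_nucleus_mask` with `stats` columns label, centroid nm,
#'   volume µm³, voxel count.
#' @export
segment_nuclei_3d <- function(vg, morph_radius = 1L, min_volume_um3 = 0) {
  stopifnot(inherits(vg, "exm_voxel_grid"))
  d <- dim(vg$data)
  if (length(d) != 3L || d[3] < 2L)
    stop("need a 3D stack with at least 2 z planes", call. = FALSE)
  rng <- range(vg$data)
  if (diff(rng) < 1e-12)
    stop("constant image: Otsu threshold undefined", call. = FALSE)
  norm <- (vg$data - rng[1]) / diff(rng)
  # single global threshold: present the whole volume to Otsu as one frame
  thr <- EBImage::otsu(EBImage::Image(matrix(norm, d[1], d[2] * d[3])))
  mask <- norm >= thr
  mask <- dilate_mask(erode_mask(mask, morph_radius), morph_radius)
  mask <- fill_holes_3d(mask)
  lab <- label_components_3d(mask)
  vox_um3 <- prod(vg$voxel_size) / 1e9
  fg <- which(lab > 0L)
  empty <- data.frame(label = integer(0), centroid_x_nm = numeric(0),
                      centroid_y_nm = numeric(0), centroid_z_nm = numeric(0),
                      volume_um3 = numeric(0), n_voxels = integer(0))
  if (!length(fg)) return(new_nucleus_mask(lab, empty, vg$voxel_size))
  labs <- lab[fg]
  n0 <- max(labs)
  counts <- tabulate(labs, n0)
  keep <- which(counts * vox_um3 >= min_volume_um3 & counts > 0L)
  if (!length(keep))
    return(new_nucleus_mask(array(0L, d), empty, vg$voxel_size))
  ai <- arrayInd(fg, d)
  cent <- rowsum(ai, labs) / counts[sort(unique(labs))]
  relab <- array(0L, d)
  newid <- integer(n0)
  newid[keep] <- seq_along(keep)
  relab[fg] <- newid[labs]
  stats <- data.frame(
    label = seq_along(keep),
    centroid_x_nm = (cent[keep, 1] - 0.5) * vg$voxel_size[1],
    centroid_y_nm = (cent[keep, 2] - 0.5) * vg$voxel_size[2],
    centroid_z_nm = (cent[keep, 3] - 0.5) * vg$voxel_size[3],
    volume_um3 = counts[keep] * vox_um3,
    n_voxels = counts[keep])
  rownames(stats) <- NULL
  new_nucleus_mask(relab, stats, vg$voxel_size)
}

#' Expansion factor from pre/post nucleus masks
#'
#' Ratio of the mean per-nucleus area (2D masks) or volume (3D masks)
#' post/pre, converted to a linear factor by [linear_factor_from_area_ratio()]
#' or [linear_factor_from_volume_ratio()]; the raw ratio is stored on the
#' returned factor for audit.
#'
#' @param pre,post `exm_nucleus_mask`s of the pre- and post-expansion
#'   images.
#' @param mode `"area"` or `"volume"` (must match the mask dimensionality).
#' @return an [expansion_factor()].
#' @export
expansion_factor_from_masks <- function(pre, post,
                                        mode = c("area", "volume")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pre, "exm_nucleus_mask"),
            inherits(post, "exm_nucleus_mask"))
  col <- if (mode == "area") "area_um2" else "volume_um3"
  if (!col %in% names(pre$stats) || !col %in% names(post$stats))
    stop("masks do not carry ", col, " (wrong dimensionality for mode)",
         call. = FALSE)
  if (nrow(pre$stats) == 0L || nrow(post$stats) == 0L)
    stop("both masks must contain at least one nucleus", call. = FALSE)
  pre_mean <- mean(pre$stats[[col]])
  if (pre_mean <= 0)
    stop("zero pre-expansion measurement; cannot form a ratio", call. = FALSE)
  ratio <- mean(post$stats[[col]]) / pre_mean
  if (mode == "area") linear_factor_from_area_ratio(ratio)
  else linear_factor_from_volume_ratio(ratio)
}
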