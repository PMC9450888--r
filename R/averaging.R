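#' Average structures and radial intensity profiles
#'
#' Encapsulated (class 5) structures oriented parallel to the focal plane
#' are cropped, aligned by translation (core at the crop centre) and
#' averaged voxel-wise per channel. The averaged structure is summarised by
#' a radial intensity profile — mean intensity in fixed-width concentric
#' bands around the centre of the central z slice — from which
#' peak-to-peak distances, channel spans and the core–shell gap are read.
#'
#' @name averaging
NULL

#' Select structures oriented parallel to the focal plane
#'
#' Fits a plane through each structure's partner spots (principal-axes
#' fit) and keeps structures whose plane normal is within `max_tilt_deg`
#' of the optical (z) axis and whose core lies within half a band width of
#' the plane. Structures with fewer than 3 partner spots have no defined
#' plane and are skipped (with a message).
#'
#' @param structures list of `exm_structure`s.
#' @param max_tilt_deg maximum tilt in degrees (default 20).
#' @param band_width_nm radial band width, used for the core-to-plane
#'   tolerance (default 100 nm).
#' @param partner_channel shell channel (default first).
#' @return the selected subset (list).
#' @export
select_in_plane <- function(structures, max_tilt_deg = 20,
                            band_width_nm = 100, partner_channel = NULL) {
  keep <- logical(length(structures))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    chs <- names(s$members)
    pc <- if (is.null(partner_channel)) chs[1] else partner_channel
    m <- s$members[[pc]]
    if (nrow(m) < 3L) {
      message(sprintf("structure %d skipped: %d partner spot(s), plane undefined",
                      s$id, nrow(m)))
      next
    }
    pts <- as.matrix(m[, c("x", "y", "z")])
    ctr <- sweep(pts, 2, colMeans(pts))
    sv <- svd(ctr)
    normal <- sv$v[, 3]
    tilt <- acos(pmin(1, abs(normal[3]))) * 180 / pi
    core_off <- abs(sum((s$core - colMeans(pts)) * normal))
    keep[i] <- tilt <= max_tilt_deg && core_off <= band_width_nm / 2
  }
  structures[keep]
}

#' Average aligned structure crops
#'
#' Voxel-wise arithmetic mean per channel over crops of identical shape
#' and voxel size.
#'
#' @param crops list of contributions; each element is a named list of
#'   [voxel_grid()]s (one per channel) cropped with the core at the crop
#'   centre.
#' @param ids optional contributor identifiers.
#' @return object of class `exm_average_structure`: `channels` (named list
#'   of mean [voxel_grid()]s), `n`, `ids`.
#' @export
average_structures <- function(crops, ids = seq_along(crops)) {
  if (length(crops) < 1L) stop("need at least one crop", call. = FALSE)
  chs <- names(crops[[1]])
  ref_dim <- dim(crops[[1]][[1]]$data)
  ref_vox <- crops[[1]][[1]]$voxel_size
  for (cr in crops) {
    for (ch in chs) {
      if (!identical(dim(cr[[ch]]$data), ref_dim) ||
          any(abs(cr[[ch]]$voxel_size - ref_vox) > 1e-9))
        stop("all crops must share shape and voxel size", call. = FALSE)
    }
  }
  channels <- lapply(chs, function(ch) {
    acc <- array(0, ref_dim)
    for (cr in crops) acc <- acc + cr[[ch]]$data
    voxel_grid(acc / length(crops), ref_vox, channel = ch)
  })
  names(channels) <- chs
  structure(list(channels = channels, n = length(crops), ids = ids),
            class = "exm_average_structure")
}

#' Radial intensity profile of an averaged structure
#'
#' Pixels of the central z slice are binned into contiguous fixed-width
#' bands by their distance to the slice centre
#' (`band = floor(distance / band_width)`); the profile value of a band is
#' the mean intensity of its pixels.
#'
#' @param avg an `exm_average_structure` (or a single [voxel_grid()]).
#' @param channel channel name (ignored when a bare grid is given).
#' @param band_width_nm band width in nm (at least one voxel).
#' @return data frame of class `exm_radial_profile`: `band`, `r_mid_nm`
#'   (band-centre radius), `mean_intensity`, `n_pixels`; band width and
#'   channel stored as attributes.
#' @export
radial_profile <- function(avg, channel = NULL, band_width_nm = 100) {
  vg <- if (inherits(avg, "exm_average_structure")) avg$channels[[channel]]
        else avg
  stopifnot(inherits(vg, "exm_voxel_grid"))
  if (band_width_nm < min(vg$voxel_size[1:2]))
    stop("band width must be at least one voxel", call. = FALSE)
  d <- dim(vg$data)
  zc <- ceiling(d[3] / 2)
  slice <- vg$data[, , zc]
  centre <- d[1:2] * vg$voxel_size[1:2] / 2
  xs <- (seq_len(d[1]) - 0.5) * vg$voxel_size[1] - centre[1]
  ys <- (seq_len(d[2]) - 0.5) * vg$voxel_size[2] - centre[2]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  band <- floor(rr / band_width_nm)
  agg_mean <- tapply(as.vector(slice), as.vector(band), mean)
  agg_n <- tapply(as.vector(slice), as.vector(band), length)
  b <- as.integer(names(agg_mean))
  out <- data.frame(band = b,
                    r_mid_nm = (b + 0.5) * band_width_nm,
                    mean_intensity = as.numeric(agg_mean),
                    n_pixels = as.integer(agg_n))
  out <- out[order(out$band), ]
  rownames(out) <- NULL
  attr(out, "band_width_nm") <- band_width_nm
  attr(out, "channel") <- vg$channel
  class(out) <- c("exm_radial_profile", "data.frame")
  out
}

#' Peak-to-peak distance of a radial profile
#'
#' Twice the radius of the profile's global maximum band, refined by a
#' 3-point quadratic fit over the neighbouring bands — the distance between
#' the two opposite satellite-intensity peaks through the structure
#' centre. A profile whose maximum sits in the innermost band has no
#' annular peak (the contracted phenotype in which the central void is
#' lost); it returns 0 flagged `"no annular peak"`.
#'
#' @param profile an `exm_radial_profile` with at least 3 bands.
#' @return list with `length` (a post-expansion [physical_length()] in
#'   nm), `peak_radius_nm` and `flag` (`NA` or `"no annular peak"`).
#' @export
peak_to_peak <- function(profile) {
  stopifnot(inherits(profile, "exm_radial_profile"))
  if (nrow(profile) < 3L) stop("profile needs at least 3 bands",
                               call. = FALSE)
  i <- which.max(profile$mean_intensity)
  if (profile$band[i] == min(profile$band)) {
    return(list(length = physical_length(0, "nm", "post_expansion"),
                peak_radius_nm = 0, flag = "no annular peak"))
  }
  bw <- attr(profile, "band_width_nm")
  r <- profile$r_mid_nm[i]
  if (i > 1L && i < nrow(profile)) {
    fm <- profile$mean_intensity[i - 1L]
    f0 <- profile$mean_intensity[i]
    fp <- profile$mean_intensity[i + 1L]
    den <- fm - 2 * f0 + fp
    if (abs(den) > 1e-12) {
      off <- 0.5 * (fm - fp) / den
      r <- r + pmin(pmax(off, -0.5), 0.5) * bw
    }
  }
  list(length = physical_length(2 * r, "nm", "post_expansion"),
       peak_radius_nm = r, flag = NA_character_)
}

# outermost/innermost radius where the profile crosses thr, linearly
# interpolated between band centres
profile_crossing <- function(profile, thr, from = c("outside", "inside")) {
  from <- match.arg(from)
  v <- profile$mean_intensity
  r <- profile$r_mid_nm
  above <- v >= thr
  if (!any(above)) return(NA_real_)
  if (from == "outside") {
    i <- max(which(above))
    if (i == length(v)) return(r[i])
    # interpolate between band i (above) and i+1 (below)
    r[i] + (r[i + 1] - r[i]) * (v[i] - thr) / (v[i] - v[i + 1])
  } else {
    i <- min(which(above))
    if (i == 1L) return(r[1])
    r[i] - (r[i] - r[i - 1]) * (v[i] - thr) / (v[i] - v[i - 1])
  }
}

#' Channel spans and core–shell gap from radial profiles
#'
#' The span of a channel is twice the outermost radius at which its
#' profile is at least `fraction` of its maximum; the gap is the inner
#' edge radius of the shell (partner) channel minus the outer edge radius
#' of the core (site) channel at the same fraction, clamped at 0 (an
#' overlapping shell gives gap 0 — the contracted phenotype in which the
#' void between the proteins is lost).
#'
#' @param site_profile,partner_profile `exm_radial_profile`s of the core
#'   and shell channels.
#' @param fraction edge threshold as a fraction of each channel's maximum
#'   (default 0.5, i.e. full width at half maximum).
#' @param factor optional expansion factor for pre-expansion equivalents.
#' @return list of post-expansion [physical_length()]s: `core_span`,
#'   `partner_span`, `gap`; with `pre` sub-list when `factor` is given.
#' @export
span_and_gap <- function(site_profile, partner_profile, fraction = 0.5,
                         factor = NULL) {
  for (p in list(site_profile, partner_profile)) {
    if (diff(range(p$mean_intensity)) < 1e-12)
      stop("flat profile: span undefined", call. = FALSE)
  }
  thr_s <- fraction * max(site_profile$mean_intensity)
  thr_p <- fraction * max(partner_profile$mean_intensity)
  core_outer <- profile_crossing(site_profile, thr_s, "outside")
  partner_outer <- profile_crossing(partner_profile, thr_p, "outside")
  # inner edge of the shell: walk inwards from the shell peak to the
  # first band below threshold
  ip <- which.max(partner_profile$mean_intensity)
  inner <- 0
  if (ip > 1L) {
    v <- partner_profile$mean_intensity
    r <- partner_profile$r_mid_nm
    below <- which(v[seq_len(ip - 1L)] < thr_p)
    if (length(below)) {
      j <- max(below)
      inner <- r[j] + (r[j + 1] - r[j]) * (thr_p - v[j]) / (v[j + 1] - v[j])
    }
  }
  gap <- max(0, inner - core_outer)
  out <- list(
    core_span = physical_length(2 * core_outer, "nm", "post_expansion"),
    partner_span = physical_length(2 * partner_outer, "nm", "post_expansion"),
    gap = physical_length(gap, "nm", "post_expansion")
  )
  if (!is.null(factor)) {
    out$pre <- lapply(out[c("core_span", "partner_span", "gap")],
                      to_pre_expansion, factor = factor)
  }
  out
}
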