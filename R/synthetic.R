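#' Synthetic ExM scenes with planted ground truth
#'
#' The generator emulates the data the analysis was designed for: S-phase
#' nuclei containing DNA-damage focus structures built from
#' diffraction-limited puncta (a site channel such as BRCA1 plus partner
#' channels such as 53BP1), blurred by an anisotropic Gaussian PSF,
#' corrupted by Poisson and Gaussian noise, and physically expanded ~4x
#' with an optional smooth distortion field. Every scene carries a ground
#' truth table (planted spots, structure records, the true similarity
#' transform) so detection, clustering, classification, registration and
#' profiling can be scored exactly.
#'
#' @name synthetic
NULL

#' Default simulation configuration
#'
#' Geometry parameters are stated in post-expansion nanometres (the frame
#' the microscope sees); the scene is planted in the pre-expansion frame by
#' dividing by the expansion factor.
#'
#' @param seed integer seed; every random draw in the generator flows from
#'   it.
#' @param ... overrides for any default field.
#' @return a list of class `exm_sim_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # channels and roles
    channels = list(site = "BRCA1", partners = "53BP1", dna = "DNA"),
    taxonomy = "two_channel",
    # pre-expansion frame geometry
    pre_shape = c(96L, 96L, 48L),
    pre_voxel_nm = c(100, 100, 200),
    nucleus_semi_axes_nm = c(3200, 2600, 1700),
    s_phase = "mid",                        # early | mid | late
    # post-expansion frame geometry
    post_shape = c(192L, 192L, 96L),
    post_voxel_nm = c(200, 200, 400),
    # expansion
    expansion = list(factor = 4, distortion_amplitude_nm = 0,
                     distortion_scale_nm = 4000, rotation = "z"),
    # structure taxonomy geometry (post-expansion nm)
    n_structures_per_class = c(`1` = 2L, `2` = 2L, `3` = 2L, `4` = 2L,
                               `5` = 2L),
    class_geometry = list(
      satellite_radius_nm = 650,
      satellite_radius_jitter = 0.03,
      satellite_count = c(3L, 8L),
      satellite_arrangement = "shell",   # "shell" (3D) or "ring" (planar)
      ring_tilt_deg = NA,                # NA = random ring orientation
      pair_distance_nm = c(600, 1800),
      multi_site_polygon_radius_nm = 240,
      multi_site_count = c(2L, 3L),
      multi_partner_count = c(2L, 3L),
      multi_partner_distance_nm = c(700, 1600),
      brca1_offset_nm = 450,
      min_structure_separation_nm = 4200
    ),
    # optics and noise (post frame; pre frame uses psf_sigma_pre_nm)
    psf_sigma_nm = c(100, 100, 300),
    psf_sigma_pre_nm = c(60, 60, 180),
    intensity = 2000,
    intensity_jitter = 0.2,
    background = 20,
    nuclear_background = 200,
    noise = list(poisson = TRUE, gaussian_sd = 2)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "exm_sim_config")
}

## ---- geometric primitives -------------------------------------------------

# k approximately evenly spread unit directions (spherical Fibonacci
# lattice), randomly rotated so repeated draws differ
fibonacci_directions <- function(k, rotate = TRUE) {
  i <- seq_len(k) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / k
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (rotate) dirs <- dirs %*% t(quat_to_matrix(random_quaternion()))
  dirs
}

random_direction <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# regular polygon of k points, radius r, in a random plane through centre
polygon_points <- function(k, r, centre) {
  ang <- 2 * pi * seq_len(k) / k + stats::runif(1, 0, 2 * pi)
  pts <- cbind(r * cos(ang), r * sin(ang), 0)
  R <- quat_to_matrix(random_quaternion())
  sweep(pts %*% t(R), 2, centre, "+")
}

# satellite positions for an encapsulating class: either a 3D shell
# (spherical Fibonacci lattice) or a planar ring whose normal is tilted
# ring_tilt_deg away from the optical axis (NA = random orientation)
satellite_positions <- function(g, sc, centre) {
  k <- if (g$satellite_count[1] == g$satellite_count[2]) g$satellite_count[1]
       else sample(g$satellite_count[1]:g$satellite_count[2], 1L)
  rad <- g$satellite_radius_nm * sc *
    stats::runif(k, 1 - g$satellite_radius_jitter,
                 1 + g$satellite_radius_jitter)
  arr <- g$satellite_arrangement %||% "shell"
  if (arr == "shell") {
    dirs <- fibonacci_directions(k)
  } else {
    normal <- if (is.na(g$ring_tilt_deg %||% NA)) random_direction()
    else {
      tilt <- g$ring_tilt_deg * pi / 180
      az <- stats::runif(1, 0, 2 * pi)
      c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
    }
    u <- c(normal[2], -normal[1], 0)
    if (sqrt(sum(u^2)) < 1e-8) u <- c(1, 0, 0)
    u <- u / sqrt(sum(u^2))
    v <- c(normal[2] * u[3] - normal[3] * u[2],
           normal[3] * u[1] - normal[1] * u[3],
           normal[1] * u[2] - normal[2] * u[1])
    ang <- 2 * pi * seq_len(k) / k + stats::runif(1, 0, 2 * pi)
    dirs <- outer(cos(ang), u) + outer(sin(ang), v)
  }
  sweep(dirs * rad, 2, centre, "+")
}

# PSF-scaled minimum pairwise distance (in sigma units); used to keep
# planted same-channel spots resolvable
min_scaled_separation <- function(pts, sigma) {
  if (nrow(pts) < 2L) return(Inf)
  s <- sweep(pts, 2, sigma, "/")
  min(stats::dist(s))
}

spot_df <- function(channel, pts, intensity) {
  data.frame(channel = channel, x = pts[, 1], y = pts[, 2], z = pts[, 3],
             intensity = intensity, stringsAsFactors = FALSE)
}

draw_intensity <- function(n, cfg) {
  cfg$intensity * stats::runif(n, 1 - cfg$intensity_jitter,
                               1 + cfg$intensity_jitter)
}

## ---- structure planting ---------------------------------------------------

#' Plant one focus structure of a given class
#'
#' Places puncta around `centre` so that the resulting spot arrangement
#' satisfies the class definition it is planted as; this is verified at
#' generation time by re-classifying the planted coordinates with the
#' package's own classifier and refusing to return a mismatching draw.
#'
#' Two-channel taxonomy (site = BRCA1, partner = 53BP1): class 1 = core
#' site spot only; 2 = core + one partner; 3 = multiple site + one partner;
#' 4 = multiple site + multiple partner; 5 = single core encapsulated by a
#' shell of partner satellites. Three-channel taxonomy (site = RAD51,
#' partners = 53BP1 and BRCA1): see [three_channel_rules()].
#'
#' @param class_id planted class label (integer).
#' @param centre length-3 position in nm (the frame the geometry is stated
#'   in; divide geometry by the expansion factor to plant pre-expansion).
#' @param geometry `class_geometry` list from [simulation_config()].
#' @param cfg a [simulation_config()] (intensity and PSF parameters).
#' @param taxonomy `"two_channel"` or `"three_channel"`.
#' @param geometry_scale multiply all geometry distances by this factor
#'   (e.g. `1/4` to plant in the pre-expansion frame).
#' @return list with `spots` (data frame channel/x/y/z/intensity), `record`
#'   (class, centre, counts).
#' @export
plant_structure <- function(class_id, centre, geometry = NULL, cfg = NULL,
                            taxonomy = c("two_channel", "three_channel"),
                            geometry_scale = 1) {
  taxonomy <- match.arg(taxonomy)
  if (is.null(cfg)) cfg <- simulation_config()
  if (is.null(geometry)) geometry <- cfg$class_geometry
  g <- geometry
  sc <- geometry_scale
  if (g$satellite_radius_nm * sc <= 0 && g$satellite_count[1] >= 2)
    stop("unsatisfiable geometry: zero satellite radius with >= 2 satellites",
         call. = FALSE)
  sigma <- cfg$psf_sigma_nm * sc
  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(rng[1]:rng[2], 1L)
  centre <- as.numeric(centre)

  for (attempt in 1:50) {
    if (taxonomy == "two_channel")
      pl <- plant_two_channel(class_id, centre, g, sc, rint)
    else
      pl <- plant_three_channel(class_id, centre, g, sc, rint)
    # resolvable presets keep same-channel spots >= 4 PSF sigma apart;
    # set enforce_resolvable = FALSE to plant deliberately unresolvable
    # (e.g. contracted-shell) geometries
    if (isTRUE(g$enforce_resolvable %||% TRUE)) {
      ok <- TRUE
      for (ch in unique(pl$spots$channel)) {
        pts <- as.matrix(pl$spots[pl$spots$channel == ch, c("x", "y", "z")])
        if (min_scaled_separation(pts, sigma) < 4) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    lab <- classify_planted(pl$spots, cfg, taxonomy,
                            search_radius_nm = 2000 * sc,
                            link_radius_nm = 500 * sc)
    if (identical(as.integer(lab), as.integer(class_id))) {
      pl$spots$intensity <- draw_intensity(nrow(pl$spots), cfg)
      counts <- table(pl$spots$channel)
      pl$record <- list(class = as.integer(class_id), centre = centre,
                        counts = as.list(counts))
      return(pl)
    }
  }
  stop(sprintf("could not plant a class-%s structure satisfying its rule",
               class_id), call. = FALSE)
}

plant_two_channel <- function(class_id, centre, g, sc, rint) {
  site <- "site"; partner <- "partner"
  one <- matrix(centre, 1)
  ring <- function() satellite_positions(g, sc, centre)
  pair_pt <- function(n = 1L) {
    d <- stats::runif(n, g$pair_distance_nm[1] * sc, g$pair_distance_nm[2] * sc)
    t(vapply(seq_len(n), function(i) centre + random_direction() * d[i],
             numeric(3)))
  }
  multi_site <- function() {
    polygon_points(rint(g$multi_site_count),
                   g$multi_site_polygon_radius_nm * sc, centre)
  }
  multi_partner <- function() {
    n <- rint(g$multi_partner_count)
    d <- stats::runif(n, g$multi_partner_distance_nm[1] * sc,
                      g$multi_partner_distance_nm[2] * sc)
    t(vapply(seq_len(n), function(i) centre + random_direction() * d[i],
             numeric(3)))
  }
  spots <- switch(as.character(class_id),
    `1` = spot_df(site, one, 1),
    `2` = rbind(spot_df(site, one, 1), spot_df(partner, pair_pt(), 1)),
    `3` = rbind(spot_df(site, multi_site(), 1), spot_df(partner, pair_pt(), 1)),
    `4` = rbind(spot_df(site, multi_site(), 1),
                spot_df(partner, multi_partner(), 1)),
    `5` = rbind(spot_df(site, one, 1), spot_df(partner, ring(), 1)),
    stop("unknown two-channel class: ", class_id, call. = FALSE)
  )
  list(spots = spots)
}

plant_three_channel <- function(class_id, centre, g, sc, rint) {
  one <- matrix(centre, 1)
  ring <- function() satellite_positions(g, sc, centre)
  pair_pt <- function() matrix(centre + random_direction() *
    stats::runif(1, g$pair_distance_nm[1] * sc, g$pair_distance_nm[2] * sc), 1)
  multi <- function(role = c("site", "partner")) {
    role <- match.arg(role)
    if (role == "site")
      polygon_points(rint(g$multi_site_count),
                     g$multi_site_polygon_radius_nm * sc, centre)
    else {
      n <- rint(g$multi_partner_count)
      d <- stats::runif(n, g$multi_partner_distance_nm[1] * sc,
                        g$multi_partner_distance_nm[2] * sc)
      t(vapply(seq_len(n), function(i) centre + random_direction() * d[i],
               numeric(3)))
    }
  }
  brca1 <- function() matrix(centre + random_direction() *
                               g$brca1_offset_nm * sc, 1)
  S <- "site"; P <- "partner"; B <- "partner2"
  spots <- switch(as.character(class_id),
    `1` = spot_df(S, one, 1),
    `2` = rbind(spot_df(S, one, 1), spot_df(P, pair_pt(), 1)),
    `3` = rbind(spot_df(S, one, 1), spot_df(P, ring(), 1)),
    `4` = rbind(spot_df(S, multi("site"), 1), spot_df(P, multi("partner"), 1)),
    `5` = spot_df(S, multi("site"), 1),
    `6` = rbind(spot_df(S, one, 1), spot_df(B, brca1(), 1)),
    `7` = rbind(spot_df(S, one, 1), spot_df(P, pair_pt(), 1),
                spot_df(B, brca1(), 1)),
    `8` = rbind(spot_df(S, multi("site"), 1), spot_df(P, pair_pt(), 1),
                spot_df(B, brca1(), 1)),
    `9` = rbind(spot_df(S, multi("site"), 1), spot_df(P, ring(), 1),
                spot_df(B, brca1(), 1)),
    `10` = rbind(spot_df(S, multi("site"), 1), spot_df(P, pair_pt(), 1)),
    stop("unknown three-channel class: ", class_id, call. = FALSE)
  )
  list(spots = spots)
}

# classify planted coordinates directly (no imaging): used as the
# generation-time self-check and by the "ground-truth route" tests
classify_planted <- function(spots, cfg, taxonomy, search_radius_nm = 2000,
                             link_radius_nm = 500) {
  site <- spots[spots$channel == "site", c("x", "y", "z"), drop = FALSE]
  counts <- list(
    site = nrow(site),
    partner = sum(spots$channel == "partner"),
    partner2 = sum(spots$channel == "partner2")
  )
  core <- colMeans(as.matrix(site))
  sat <- as.matrix(spots[spots$channel == "partner", c("x", "y", "z"),
                         drop = FALSE])
  enc <- if (nrow(sat) >= 1)
    encapsulation_test(core, sat) else FALSE
  if (taxonomy == "two_channel")
    classify_counts_two_channel(counts$site, counts$partner, enc)
  else
    classify_counts_three_channel(counts$site, counts$partner,
                                  counts$partner2, enc)
}

## ---- rendering ------------------------------------------------------------

#' Render planted spots into a noisy volume
#'
#' Each spot becomes an anisotropic 3D Gaussian of the configured PSF sigma
#' (peak amplitude = spot intensity), summed onto a background; Poisson and
#' then Gaussian read noise are applied if enabled. Spots outside the image
#' are clipped with a warning.
#'
#' @param spots data frame with columns `x, y, z` (nm) and `intensity`.
#' @param shape integer length-3 volume dimensions (x, y, z).
#' @param voxel_size_nm per-axis voxel size in nm.
#' @param psf_sigma_nm per-axis Gaussian PSF sigma in nm.
#' @param background constant (or array) background level in photons.
#' @param poisson apply Poisson noise?
#' @param gaussian_sd Gaussian read-noise standard deviation (0 = off).
#' @param channel channel name attached to the output grid.
#' @return a [voxel_grid()]; all values non-negative.
#' @export
render_volume <- function(spots, shape, voxel_size_nm, psf_sigma_nm,
                          background = 0, poisson = FALSE, gaussian_sd = 0,
                          channel = NA_character_) {
  shape <- as.integer(shape)
  a <- array(0, shape)
  extent <- shape * voxel_size_nm
  if (nrow(spots)) {
    outside <- spots$x < 0 | spots$y < 0 | spots$z < 0 |
      spots$x > extent[1] | spots$y > extent[2] | spots$z > extent[3]
    if (any(outside))
      warning(sum(outside), " spot(s) outside image bounds; rendering clipped")
    sig_vox <- psf_sigma_nm / voxel_size_nm
    half <- ceiling(3.5 * sig_vox)
    for (s in seq_len(nrow(spots))) {
      ctr <- c(spots$x[s], spots$y[s], spots$z[s]) / voxel_size_nm + 0.5
      lo <- pmax(1L, floor(ctr - half))
      hi <- pmin(shape, ceiling(ctr + half))
      if (any(lo > hi)) next
      w <- lapply(1:3, function(ax) {
        i <- lo[ax]:hi[ax]
        exp(-(i - ctr[ax])^2 / (2 * sig_vox[ax]^2))
      })
      blob <- spots$intensity[s] *
        (w[[1]] %o% w[[2]] %o% w[[3]])
      a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
    }
  }
  a <- a + background
  if (poisson) a[] <- stats::rpois(length(a), pmax(a, 0))
  if (gaussian_sd > 0) a <- a + stats::rnorm(length(a), 0, gaussian_sd)
  a[a < 0] <- 0
  voxel_grid(a, voxel_size_nm, channel = channel)
}

## ---- expansion ------------------------------------------------------------

# band-limited random displacement field: per output component a sum of
# n_harmonics sinusoids with wavelength ~ scale; RMS magnitude ~= amplitude
make_distortion_field <- function(amplitude_nm, scale_nm, n_harmonics = 4L) {
  if (amplitude_nm <= 0) {
    return(list(amplitude = 0, fun = function(x) x * 0))
  }
  k <- t(vapply(seq_len(3L * n_harmonics), function(i) random_direction(),
                numeric(3))) / scale_nm
  phase <- stats::runif(3L * n_harmonics, 0, 2 * pi)
  amp <- amplitude_nm * sqrt(2 / (3 * n_harmonics))
  fun <- function(x) {
    # x: n x 3 matrix (nm); returns n x 3 displacement (nm)
    disp <- matrix(0, nrow(x), 3)
    for (cmp in 1:3) {
      for (j in seq_len(n_harmonics)) {
        row <- (cmp - 1L) * n_harmonics + j
        disp[, cmp] <- disp[, cmp] +
          amp * sin(2 * pi * (x %*% k[row, ]) + phase[row])
      }
    }
    disp
  }
  list(amplitude = amplitude_nm, scale = scale_nm, k = k, phase = phase,
       amp_per_harmonic = amp, fun = fun)
}

#' Simulate physical expansion of a point set
#'
#' Maps coordinates by `y = s * R x + t` plus an optional smooth random
#' displacement field of given RMS amplitude and correlation scale. With
#' zero amplitude the mapping is an exact similarity and the returned true
#' transform reproduces it to machine precision.
#'
#' @param coords n x 3 matrix of pre-expansion positions (nm).
#' @param factor linear expansion factor (> 0).
#' @param distortion_amplitude_nm RMS magnitude of the distortion field
#'   (0 = perfectly isotropic).
#' @param distortion_scale_nm correlation length of the field.
#' @param rotation `"z"` (random angle about z), `"random"` (uniform 3D
#'   rotation), `"none"`, or a unit quaternion.
#' @param translation length-3 nm, or `NULL` for zero.
#' @param seed optional integer; if given, the RNG is seeded locally.
#' @return list with `coords` (post-expansion n x 3), `transform`
#'   (an `exm_similarity`), and `distortion` (field parameters).
#' @export
simulate_expansion <- function(coords, factor = 4,
                               distortion_amplitude_nm = 0,
                               distortion_scale_nm = 4000,
                               rotation = "z", translation = NULL,
                               seed = NULL) {
  stopifnot(factor > 0, distortion_amplitude_nm >= 0)
  if (!is.null(seed)) set.seed(seed)
  coords <- as.matrix(coords)
  q <- if (is.numeric(rotation) && length(rotation) == 4L) {
    quat_normalize(rotation)
  } else switch(match.arg(rotation, c("z", "random", "none")),
    z = quat_from_axis_angle(c(0, 0, 1), stats::runif(1, 0, 2 * pi)),
    random = random_quaternion(),
    none = c(1, 0, 0, 0)
  )
  t_vec <- if (is.null(translation)) c(0, 0, 0) else as.numeric(translation)
  tr <- similarity_transform(scale = factor, quaternion = q,
                             translation = t_vec)
  field <- make_distortion_field(distortion_amplitude_nm, distortion_scale_nm)
  out <- apply_transform(tr, coords)
  out <- out + field$fun(coords)
  list(coords = out, transform = tr, distortion = field)
}

## ---- nucleus scenes -------------------------------------------------------

ellipsoid_mask <- function(shape, voxel_nm, centre_nm, semi_axes_nm,
                           transform = NULL) {
  idx <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                               z = seq_len(shape[3])))
  pos <- index_to_nm(idx, voxel_nm)
  if (!is.null(transform)) pos <- apply_transform(invert_transform(transform),
                                                  pos)
  u <- sweep(pos, 2, centre_nm, "-")
  u <- sweep(u, 2, semi_axes_nm, "/")
  array(rowSums(u^2) <= 1, shape)
}

# S-phase-style DNA texture spots (cosmetic; classification never reads
# the DNA channel): early = diffuse fine speckle, mid = patchy interior
# blobs, late = peripheral blobs
dna_texture_spots <- function(phase, centre, semi_axes, n = 120L) {
  u <- matrix(stats::rnorm(3L * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- switch(phase,
    early = stats::runif(n, 0, 0.95)^(1 / 3),
    mid = stats::runif(n, 0, 0.8)^(1 / 2),
    late = stats::runif(n, 0.8, 0.98),
    stop("unknown s_phase preset: ", phase, call. = FALSE)
  )
  pts <- sweep(u * rad, 2, semi_axes, "*")
  pts <- sweep(pts, 2, centre, "+")
  amp <- switch(phase, early = 0.4, mid = 1.0, late = 1.2)
  data.frame(channel = "dna", x = pts[, 1], y = pts[, 2], z = pts[, 3],
             intensity = amp)
}

sample_structure_centres <- function(n, centre, semi_axes, margin_nm,
                                     min_sep_nm, max_tries = 4000L) {
  axes <- pmax(semi_axes - margin_nm, 1)
  pts <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("structure count infeasible within the nucleus mask",
           call. = FALSE)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    r <- stats::runif(1)^(1 / 3)
    p <- centre + u * r * axes
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, p, "-")^2))) >= min_sep_nm)
      pts <- rbind(pts, p)
  }
  pts
}

#' Generate a matched pre/post-expansion nucleus scene
#'
#' Builds an ellipsoidal nucleus with an S-phase-style DNA texture, plants
#' the configured number of structures of each class inside it, simulates
#' expansion of all coordinates, and renders both the pre-expansion and the
#' post-expansion multi-channel volumes. Identical config + seed gives
#' bit-identical output.
#'
#' @param cfg a [simulation_config()].
#' @return list with `pre` and `post` (named lists of [voxel_grid()]s:
#'   `dna`, `site`, and partner channels), `truth` (ground-truth list:
#'   `spots` table with pre and post coordinates, `structures` records,
#'   `transform`, `distortion`, `nucleus`, `seed`).
#' @export
generate_nucleus_scene <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  f <- cfg$expansion$factor
  pre_extent <- cfg$pre_shape * cfg$pre_voxel_nm
  nuc_centre <- pre_extent / 2
  semi <- cfg$nucleus_semi_axes_nm

  # plant structures (geometry stated post-expansion; planted pre)
  counts <- cfg$n_structures_per_class
  classes <- rep(as.integer(names(counts)), counts)
  n_struct <- length(classes)
  g <- cfg$class_geometry
  margin <- (g$satellite_radius_nm * 1.3 + 3 * max(cfg$psf_sigma_nm)) / f
  centres <- if (n_struct)
    sample_structure_centres(n_struct, nuc_centre, semi, margin,
                             g$min_structure_separation_nm / f)
  else matrix(NA_real_, 0, 3)

  spots <- NULL
  records <- list()
  for (i in seq_along(classes)) {
    pl <- plant_structure(classes[i], centres[i, ], geometry = g, cfg = cfg,
                          taxonomy = cfg$taxonomy, geometry_scale = 1 / f)
    pl$spots$structure_id <- i
    spots <- rbind(spots, pl$spots)
    records[[i]] <- list(id = i, class = classes[i],
                         centre_pre = centres[i, ],
                         counts = pl$record$counts)
  }
  tex <- dna_texture_spots(cfg$s_phase, nuc_centre, semi)
  tex$intensity <- tex$intensity * cfg$intensity / 10
  tex$structure_id <- NA_integer_

  # expansion: centre the transformed nucleus in the post volume
  post_extent <- cfg$post_shape * cfg$post_voxel_nm
  rot <- cfg$expansion$rotation
  q <- if (is.numeric(rot)) quat_normalize(rot) else switch(rot,
    z = quat_from_axis_angle(c(0, 0, 1), stats::runif(1, 0, 2 * pi)),
    random = random_quaternion(),
    none = c(1, 0, 0, 0))
  t_vec <- post_extent / 2 - f * (quat_to_matrix(q) %*% nuc_centre)[, 1]
  all_pre <- as.matrix(rbind(spots[, c("x", "y", "z")],
                             tex[, c("x", "y", "z")]))
  ex <- simulate_expansion(all_pre, factor = f,
                           distortion_amplitude_nm =
                             cfg$expansion$distortion_amplitude_nm,
                           distortion_scale_nm =
                             cfg$expansion$distortion_scale_nm,
                           rotation = q, translation = t_vec)
  n_s <- nrow(spots)
  post_xyz <- ex$coords
  truth_spots <- rbind(
    cbind(spots, post_x = post_xyz[seq_len(n_s), 1],
          post_y = post_xyz[seq_len(n_s), 2],
          post_z = post_xyz[seq_len(n_s), 3]),
    cbind(tex, post_x = post_xyz[-seq_len(n_s), 1],
          post_y = post_xyz[-seq_len(n_s), 2],
          post_z = post_xyz[-seq_len(n_s), 3])
  )
  for (i in seq_along(records)) {
    m <- truth_spots$structure_id %in% i & truth_spots$channel == "site"
    records[[i]]$centre_post <-
      colMeans(truth_spots[m, c("post_x", "post_y", "post_z")])
  }

  # render both frames
  mask_pre <- ellipsoid_mask(cfg$pre_shape, cfg$pre_voxel_nm, nuc_centre, semi)
  mask_post <- ellipsoid_mask(cfg$post_shape, cfg$post_voxel_nm,
                              nuc_centre, semi, transform = ex$transform)
  render_frame <- function(frame) {
    post <- frame == "post"
    shape <- if (post) cfg$post_shape else cfg$pre_shape
    voxel <- if (post) cfg$post_voxel_nm else cfg$pre_voxel_nm
    psf <- if (post) cfg$psf_sigma_nm else cfg$psf_sigma_pre_nm
    mask <- if (post) mask_post else mask_pre
    cols <- if (post) c("post_x", "post_y", "post_z") else c("x", "y", "z")
    bg <- cfg$background + cfg$nuclear_background * mask
    take <- function(chs) {
      s <- truth_spots[truth_spots$channel %in% chs, ]
      data.frame(x = s[[cols[1]]], y = s[[cols[2]]], z = s[[cols[3]]],
                 intensity = s$intensity)
    }
    out <- list(
      # DNA texture blobs are chromatin domains, not puncta: render them
      # several times larger than the PSF
      dna = render_volume(take("dna"), shape, voxel, psf * 3,
                          background = bg,
                          poisson = cfg$noise$poisson,
                          gaussian_sd = cfg$noise$gaussian_sd,
                          channel = cfg$channels$dna),
      site = render_volume(take("site"), shape, voxel, psf, background = bg,
                           poisson = cfg$noise$poisson,
                           gaussian_sd = cfg$noise$gaussian_sd,
                           channel = cfg$channels$site)
    )
    for (pch in c("partner", "partner2")) {
      if (any(truth_spots$channel == pch)) {
        out[[pch]] <- render_volume(take(pch), shape, voxel, psf,
                                    background = bg,
                                    poisson = cfg$noise$poisson,
                                    gaussian_sd = cfg$noise$gaussian_sd,
                                    channel = pch)
      }
    }
    out
  }
  pre <- render_frame("pre")
  post <- render_frame("post")

  list(
    pre = pre, post = post,
    truth = list(
      spots = truth_spots,
      structures = records,
      transform = ex$transform,
      distortion = ex$distortion[c("amplitude", "scale")],
      nucleus = list(centre_pre = nuc_centre, semi_axes_nm = semi,
                     mask_pre = mask_pre, mask_post = mask_post),
      seed = cfg$seed
    )
  )
}
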