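ring_structure <- function(tilt_deg, r_nm = 650, k = 6, centre = c(0, 0, 0)) {
  tilt <- tilt_deg * pi / 180
  normal <- c(sin(tilt), 0, cos(tilt))
  u <- c(0, 1, 0)
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- 2 * pi * seq_len(k) / k
  pts <- sweep(r_nm * (outer(cos(ang), u) + outer(sin(ang), v)), 2,
               centre, "+")
  site <- data.frame(x = centre[1], y = centre[2], z = centre[3])
  cl <- cluster_site_spots(site, 500)
  st <- assemble_structures(site, cl,
                            list(partner = data.frame(x = pts[, 1],
                                                      y = pts[, 2],
                                                      z = pts[, 3])), 2000)
  classify_structure(st[[1]])
}

test_that("in-plane selection keeps flat rings and rejects tilted ones", {
  flat <- ring_structure(0)
  tilted <- ring_structure(45)
  sel <- select_in_plane(list(flat, tilted), max_tilt_deg = 20,
                         band_width_nm = 100)
  expect_equal(length(sel), 1L)
  expect_equal(sel[[1]]$core, flat$core)
  # < 3 partner spots: skipped with a message
  few <- ring_structure(0, k = 6)
  few$members$partner <- few$members$partner[1:2, ]
  expect_message(out <- select_in_plane(list(few), 20), "skipped")
  expect_equal(length(out), 0L)
})

test_that("selection matches brute-force tilt computation on planted rings", {
  set.seed(81)
  cfg <- simulation_config(
    seed = 7, class_geometry = list(satellite_arrangement = "ring",
                                    satellite_count = c(5L, 8L)))
  structures <- list(); truths <- numeric(0)
  for (i in 1:60) {
    pl <- plant_structure(5, c(3000, 3000, 3000), cfg = cfg)
    sat <- as.matrix(pl$spots[pl$spots$channel == "partner",
                              c("x", "y", "z")])
    sv <- svd(sweep(sat, 2, colMeans(sat)))
    truths <- c(truths, acos(pmin(1, abs(sv$v[3, 3]))) * 180 / pi)
    site <- pl$spots[pl$spots$channel == "site", c("x", "y", "z")]
    cl <- cluster_site_spots(site, 500)
    st <- assemble_structures(site, cl, list(partner = data.frame(
      x = sat[, 1], y = sat[, 2], z = sat[, 3])), 2000)
    structures[[i]] <- st[[1]]
  }
  sel <- select_in_plane(structures, max_tilt_deg = 20, band_width_nm = 100)
  sel_ids <- vapply(sel, function(s) s$core[1] + s$members$partner$x[1], 0)
  all_ids <- vapply(structures, function(s)
    s$core[1] + s$members$partner$x[1], 0)
  expect_equal(sort(sel_ids), sort(all_ids[truths <= 20]))
})

test_that("averaging is the voxel-wise mean and exact for identical crops", {
  vg <- voxel_grid(array(runif(10 * 10 * 6), c(10, 10, 6)), c(100, 100, 200),
                   channel = "partner")
  avg <- average_structures(list(list(partner = vg), list(partner = vg),
                                 list(partner = vg)))
  expect_equal(avg$channels$partner$data, vg$data)
  expect_equal(avg$n, 3L)
  a <- voxel_grid(array(2, c(4, 4, 2)), 100, "partner")
  b <- voxel_grid(array(6, c(4, 4, 2)), 100, "partner")
  avg2 <- average_structures(list(list(partner = a), list(partner = b)))
  expect_true(all(avg2$channels$partner$data == 4))
  bad <- voxel_grid(array(0, c(5, 4, 2)), 100, "partner")
  expect_error(average_structures(list(list(partner = a),
                                       list(partner = bad))), "shape")
})

test_that("averaging n noisy renders shrinks the voxel SD like 1/sqrt(n)", {
  set.seed(82)
  sp <- data.frame(x = 1550, y = 1550, z = 1500, intensity = 500)
  render1 <- function() list(partner = render_volume(
    sp, c(32, 32, 16), c(100, 100, 200), c(100, 100, 300),
    background = 100, poisson = TRUE, channel = "partner"))
  crops <- replicate(100, render1(), simplify = FALSE)
  avg <- average_structures(crops)
  # voxel-wise SD of the average vs a single crop, on background voxels
  bgv <- function(a) as.vector(a[1:8, 1:8, 1:4])
  sd_single <- sd(bgv(crops[[1]]$partner$data))
  sd_avg <- sd(bgv(avg$channels$partner$data))
  expect_lt(abs(sd_avg - sd_single / 10) / (sd_single / 10), 0.35)
})

test_that("radial profiles: constants, annuli and partition conservation", {
  # uniform slice -> constant profile
  u <- voxel_grid(array(4.2, c(41, 41, 5)), c(100, 100, 200), "site")
  pu <- radial_profile(u, band_width_nm = 100)
  expect_true(all(abs(pu$mean_intensity - 4.2) < 1e-12))
  # annulus between 1.2 and 1.4 um -> peak in the band containing 1.3 um
  d <- c(61, 61, 5)
  xs <- ((1:61) - 0.5) * 100 - 3050
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  slice <- (rr >= 1310 & rr <= 1390) * 10
  a <- array(0, d); a[, , 3] <- slice
  pa <- radial_profile(voxel_grid(a, c(100, 100, 200), "partner"),
                       band_width_nm = 100)
  expect_equal(pa$band[which.max(pa$mean_intensity)], 13L)  # 1.3 um band
  # conservation: sum over bands of n * mean equals total slice intensity
  expect_equal(sum(pa$mean_intensity * pa$n_pixels), sum(slice))
  expect_error(radial_profile(u, band_width_nm = 50), "band width")
})

test_that("peak-to-peak: annulus radius recovered; central peak flagged", {
  d <- c(61, 61, 5)
  xs <- ((1:61) - 0.5) * 100 - 3050
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  a <- array(0, d)
  a[, , 3] <- exp(-(rr - 650)^2 / (2 * 150^2))
  p <- radial_profile(voxel_grid(a, c(100, 100, 200), "partner"), band_width_nm = 100)
  pp <- peak_to_peak(p)
  expect_true(is.na(pp$flag))
  expect_lt(abs(pp$length$value - 1300), 100)   # within one band width
  # monotone centred disc -> no annular peak
  b <- array(0, d)
  b[, , 3] <- exp(-rr^2 / (2 * 400^2))
  pb <- radial_profile(voxel_grid(b, c(100, 100, 200), "partner"), band_width_nm = 100)
  ppb <- peak_to_peak(pb)
  expect_equal(ppb$length$value, 0)
  expect_equal(ppb$flag, "no annular peak")
})

test_that("span and gap: FWHM spans, clamped gap, flat-profile error", {
  d <- c(61, 61, 5)
  xs <- ((1:61) - 0.5) * 100 - 3050
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  core <- array(0, d)
  core[, , 3] <- exp(-rr^2 / (2 * (800 / 2.355)^2))   # FWHM 800 nm
  shell <- array(0, d)
  shell[, , 3] <- exp(-(rr - 1300)^2 / (2 * 200^2))
  pc <- radial_profile(voxel_grid(core, c(100, 100, 200), "site"), band_width_nm = 100)
  ps <- radial_profile(voxel_grid(shell, c(100, 100, 200), "partner"), band_width_nm = 100)
  sg <- span_and_gap(pc, ps, 0.5, factor = 4)
  expect_lt(abs(sg$core_span$value - 800), 100)
  # shell inner half-max edge at 1300 - 2.355/2*200 = 1064.5 nm,
  # core outer edge at 400 nm -> gap ~ 664.5 nm
  expect_lt(abs(sg$gap$value - 664.5), 150)
  expect_equal(sg$pre$core_span$value, sg$core_span$value / 4)
  # overlapping shell -> clamped zero gap
  overlap <- array(0, d)
  overlap[, , 3] <- exp(-(rr - 300)^2 / (2 * 400^2))
  po <- radial_profile(voxel_grid(overlap, c(100, 100, 200), "partner"), band_width_nm = 100)
  sg2 <- span_and_gap(pc, po, 0.5)
  expect_equal(sg2$gap$value, 0)
  flat <- radial_profile(voxel_grid(array(1, d), c(100, 100, 200), "site"), band_width_nm = 100)
  expect_error(span_and_gap(flat, ps), "flat")
})

test_that("profiles are linear: profile of average equals average of profiles", {
  set.seed(83)
  mk <- function() voxel_grid(array(runif(21 * 21 * 3), c(21, 21, 3)),
                              c(100, 100, 200), "partner")
  crops <- replicate(5, list(partner = mk()), simplify = FALSE)
  avg <- average_structures(crops)
  p_avg <- radial_profile(avg, "partner", 100)
  profs <- lapply(crops, function(cr) radial_profile(cr$partner, band_width_nm = 100))
  mean_prof <- Reduce(`+`, lapply(profs, `[[`, "mean_intensity")) / 5
  expect_equal(p_avg$mean_intensity, mean_prof, tolerance = 1e-12)
})

test_that("rotating contributing crops leaves the radial profile nearly unchanged", {
  # a ring rendered, then the same ring rotated 45 degrees about z
  render_ring <- function(phase) {
    ang <- 2 * pi * seq_len(8) / 8 + phase
    sp <- data.frame(x = 2050 + 650 * cos(ang), y = 2050 + 650 * sin(ang),
                     z = 1500, intensity = 100)
    list(partner = render_volume(sp, c(41, 41, 15), c(100, 100, 200),
                                 c(100, 100, 300), channel = "partner"))
  }
  p0 <- radial_profile(average_structures(list(render_ring(0)))$channels$partner,
                       band_width_nm = 100)
  p45 <- radial_profile(average_structures(list(render_ring(pi / 4)))$channels$partner,
                        band_width_nm = 100)
  rel <- sqrt(mean((p0$mean_intensity - p45$mean_intensity)^2)) /
    max(p0$mean_intensity)
  expect_lt(rel, 0.02)
})
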