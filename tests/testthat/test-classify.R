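make_structure <- function(site_pts, partner_pts = NULL, partner2_pts = NULL,
                           search_radius = 2000) {
  site <- data.frame(x = site_pts[, 1], y = site_pts[, 2], z = site_pts[, 3])
  partners <- list()
  if (!is.null(partner_pts))
    partners$partner <- data.frame(x = partner_pts[, 1], y = partner_pts[, 2],
                                   z = partner_pts[, 3])
  else partners$partner <- data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0))
  if (!is.null(partner2_pts))
    partners$partner2 <- data.frame(x = partner2_pts[, 1],
                                    y = partner2_pts[, 2],
                                    z = partner2_pts[, 3])
  cl <- cluster_site_spots(site, 500)
  assemble_structures(site, cl, partners, search_radius)[[1]]
}

origin3 <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)

test_that("two-channel classes follow the verbal definitions", {
  rules <- two_channel_rules()
  lab <- function(st) classify_structure(st, rules)$class_label
  expect_equal(lab(make_structure(origin3(0, 0, 0))), 1L)
  expect_equal(lab(make_structure(origin3(0, 0, 0),
                                  origin3(800, 0, 0))), 2L)
  expect_equal(lab(make_structure(origin3(0, 0, 0, 300, 0, 0),
                                  origin3(800, 0, 0))), 3L)
  expect_equal(lab(make_structure(origin3(0, 0, 0, 300, 0, 0),
                                  origin3(800, 0, 0, -900, 100, 0))), 4L)
  # one site + ring of 6 passing encapsulation -> class 5
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(650 * cos(ang), 650 * sin(ang), 0)
  expect_equal(lab(make_structure(origin3(0, 0, 0), ring)), 5L)
  # one site + multiple partners all on one side -> class 4
  expect_equal(lab(make_structure(origin3(0, 0, 0),
                                  origin3(700, 0, 0, 800, 100, 0,
                                          750, -60, 50))), 4L)
})

test_that("three-channel taxonomy matches its pinned definitions", {
  rules <- three_channel_rules()
  lab <- function(st) classify_three_channel(st, rules)$class_label
  multiR <- origin3(0, 0, 0, 300, 0, 0)
  multiP <- origin3(900, 0, 0, -800, 200, 0)
  b <- origin3(450, 0, 0)
  expect_equal(lab(make_structure(origin3(0, 0, 0))), 1L)
  expect_equal(lab(make_structure(multiR, multiP)), 4L)
  ang <- seq(0, 2 * pi, length.out = 6)[-6]
  ring <- cbind(150 + 650 * cos(ang), 650 * sin(ang), 0)
  expect_equal(lab(make_structure(multiR, ring, b)), 9L)
  expect_equal(lab(make_structure(multiR, multiP, b)), 8L)
  expect_equal(lab(make_structure(origin3(0, 0, 0), origin3(900, 0, 0), b)),
               7L)
  expect_equal(lab(make_structure(multiR, origin3(900, 0, 0))), 10L)
})

test_that("rule sets validate exhaustiveness and reject gaps/ambiguity", {
  expect_silent(validate_class_rules(two_channel_rules()))
  expect_silent(validate_class_rules(three_channel_rules()))
  gap <- data.frame(site_min = 1, site_max = 1, partner_min = 0,
                    partner_max = 0, class = 1L)
  expect_error(class_rule_set(gap), "rule gap")
  amb <- rbind(
    data.frame(site_min = 1, site_max = Inf, partner_min = 0,
               partner_max = Inf, encapsulated = NA, class = 1L),
    data.frame(site_min = 1, site_max = 1, partner_min = 0,
               partner_max = Inf, encapsulated = NA, class = 2L))
  expect_error(class_rule_set(amb), "ambiguous")
})

test_that("shipped YAML rule files equal the built-in rule sets", {
  y2 <- load_class_rules(system.file("extdata", "rules_two_channel.yaml",
                                     package = "exmfoci"))
  y3 <- load_class_rules(system.file("extdata", "rules_three_channel.yaml",
                                     package = "exmfoci"))
  grid <- expand.grid(site = 1:3, partner = 0:3, partner2 = 0:2,
                      enc = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (pair in list(list(y2, two_channel_rules()),
                      list(y3, three_channel_rules()))) {
      ma <- exmfoci:::match_rules(pair[[1]]$rules, g$site, g$partner,
                                  g$partner2, g$enc)
      mb <- exmfoci:::match_rules(pair[[2]]$rules, g$site, g$partner,
                                  g$partner2, g$enc)
      expect_equal(unique(pair[[1]]$rules$class[ma]),
                   unique(pair[[2]]$rules$class[mb]))
    }
  }
})

test_that("classification is invariant to spot order and rigid motion", {
  set.seed(71)
  cfg <- simulation_config(seed = 7)
  for (cl in c(2L, 4L, 5L)) {
    pl <- plant_structure(cl, c(3000, 3000, 3000), cfg = cfg)
    sp <- pl$spots
    # permuted order
    perm <- sp[sample.int(nrow(sp)), ]
    expect_equal(classify_truth_coords(perm), cl)
    # rigid motion
    R <- exmfoci:::quat_to_matrix(exmfoci:::random_quaternion())
    moved <- sp
    xyz <- as.matrix(sp[, c("x", "y", "z")]) %*% t(R)
    moved$x <- xyz[, 1] + 500; moved$y <- xyz[, 2] - 200
    moved$z <- xyz[, 3] + 100
    expect_equal(classify_truth_coords(moved), cl)
  }
})

test_that("distance subclassification uses the median shell distance and bins", {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  shell_at <- function(r_nm) {
    st <- make_structure(origin3(0, 0, 0),
                         cbind(r_nm * cos(ang), r_nm * sin(ang), 0),
                         search_radius = 3000)
    classify_structure(st)
  }
  expect_equal(subclassify_by_distance(shell_at(300))$label, "contracted")
  expect_equal(subclassify_by_distance(shell_at(1900))$label, "control_like")
  expect_equal(subclassify_by_distance(shell_at(2200))$label, "extended")
  expect_warning(out <- subclassify_by_distance(shell_at(2800)),
                 "overflow")
  expect_equal(out$label, "overflow")
  st1 <- make_structure(origin3(0, 0, 0))
  expect_error(subclassify_by_distance(st1), "no partner spots")
})

test_that("continuity: bridged spots continuous, separated spots not", {
  voxel <- c(100, 100, 200)
  shape <- c(50, 50, 26)
  # two spots joined by a ridge above half-max (positions at voxel centres)
  bridge <- data.frame(x = seq(1750, 3150, by = 100), y = 2450, z = 2500,
                       intensity = 800)
  vb <- render_volume(bridge, shape, voxel, c(100, 100, 300))
  members <- data.frame(x = c(1750, 3150), y = 2450, z = 2500)
  expect_equal(continuity_test(vb, members), "continuous")
  # far-separated gaussians
  iso <- data.frame(x = c(1250, 3750), y = 2450, z = 2500, intensity = 800)
  vi <- render_volume(iso, shape, voxel, c(100, 100, 300))
  expect_equal(continuity_test(vi, data.frame(x = c(1250, 3750), y = 2450,
                                              z = 2500)), "discontinuous")
  expect_error(continuity_test(vb, members[1, , drop = FALSE]),
               "at least 2")
})

test_that("structure crops have the stated geometry and zero padding", {
  vg <- voxel_grid(array(runif(100 * 100 * 50), c(100, 100, 50)),
                   c(100, 100, 100))
  cr <- crop_structure(vg, c(5000, 5000, 2500), box_edge_um = 5)
  expect_equal(dim(cr$data), c(51, 51, 51))   # 5 um edge at 100 nm voxels
  corner <- crop_structure(vg, c(200, 200, 200), box_edge_um = 5)
  expect_equal(dim(corner$data), c(51, 51, 51))
  expect_equal(corner$data[1, 1, 1], 0)
  again <- crop_structure(cr, c(2550, 2550, 2550), box_edge_um = 5)
  expect_equal(again$data, cr$data)
})

test_that("manual labels override and frequency tables sum to structure count", {
  site <- data.frame(x = c(0, 4000), y = 0, z = 0)
  cl <- cluster_site_spots(site, 500)
  st <- assemble_structures(site, cl,
                            list(partner = data.frame(x = numeric(0),
                                                      y = numeric(0),
                                                      z = numeric(0))), 2000)
  st <- lapply(st, classify_structure)
  tab <- class_frequency_table(st)
  expect_equal(sum(tab$n), 2L)
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(structure_id = 1, class = 5), path, row.names = FALSE)
  st2 <- ingest_manual_labels(st, path)
  expect_equal(st2[[1]]$class_label, 5)
})
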