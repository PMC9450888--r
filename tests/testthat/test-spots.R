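test_that("a single noiseless spot is detected within half a voxel", {
  sp <- data.frame(x = 3170, y = 3240, z = 2330, intensity = 1000)
  vg <- render_volume(sp, c(64, 64, 24), c(100, 100, 200), c(100, 100, 300))
  d <- detect_spots(vg, 250, 10)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x - sp$x), 50)
  expect_lt(abs(d$y - sp$y), 50)
  expect_lt(abs(d$z - sp$z), 100)
})

test_that("constant images yield no spots; invalid radius errors", {
  vg <- voxel_grid(array(20, c(32, 32, 16)), c(100, 100, 200))
  expect_equal(nrow(detect_spots(vg, 250, 10)), 0L)
  expect_error(detect_spots(vg, 150, 10), "voxel size")
  expect_error(detect_spots(vg, 250, 0), "positive")
})

test_that("50 well-separated spots are recovered with no false positives", {
  set.seed(61)
  shape <- c(128, 128, 48)
  voxel <- c(100, 100, 200)
  sigma <- c(100, 100, 300)
  # rejection-sample positions with pairwise separation >= 4 sigma (scaled)
  pts <- matrix(NA_real_, 0, 3)
  lo <- 3.5 * sigma; hi <- shape * voxel - 3.5 * sigma
  while (nrow(pts) < 50) {
    p <- runif(3, lo, hi)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(sweep(pts, 2, p), 2, sigma * 4, "/")^2))) >= 1)
      pts <- rbind(pts, p)
  }
  sp <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], intensity = 2000)
  vg <- render_volume(sp, shape, voxel, sigma, background = 220,
                      poisson = TRUE, gaussian_sd = 2)
  d <- detect_spots(vg, 250, 100)
  expect_equal(nrow(d), 50L)
  expect_equal(oracle_match(sp, d, tol_nm = 2 * max(voxel)), 50L)
})

test_that("raising the quality threshold never increases spot count", {
  set.seed(62)
  sp <- data.frame(x = runif(10, 1000, 5000), y = runif(10, 1000, 5000),
                   z = runif(10, 1000, 4000),
                   intensity = runif(10, 300, 2000))
  vg <- render_volume(sp, c(64, 64, 32), c(100, 100, 200), c(100, 100, 300),
                      background = 50, poisson = TRUE)
  thr <- c(5, 20, 50, 100, 200, 400)
  n <- vapply(thr, function(q) nrow(detect_spots(vg, 250, q)), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("fixed-radius clustering follows connected-component semantics", {
  # chain: spacings 0.9r -> one cluster despite ends 1.8r apart
  r <- 500
  chain <- data.frame(x = c(0, 450, 900), y = 0, z = 0)
  cl <- cluster_site_spots(chain, r)
  expect_equal(length(unique(cl$membership)), 1L)
  expect_equal(unname(cl$cores[1, ]), c(450, 0, 0))
  # two spots at 1.1r -> two clusters
  two <- data.frame(x = c(0, 550), y = 0, z = 0)
  expect_equal(length(unique(cluster_site_spots(two, r)$membership)), 2L)
  # boundary: exactly r links
  expect_equal(length(unique(cluster_site_spots(
    data.frame(x = c(0, 500), y = 0, z = 0), r)$membership)), 1L)
})

test_that("clustering matches brute-force union-find on random scenes", {
  set.seed(63)
  for (rep in 1:10) {
    n <- sample(50:200, 1)
    pts <- data.frame(x = runif(n, 0, 10000), y = runif(n, 0, 10000),
                      z = runif(n, 0, 5000))
    r <- runif(1, 300, 1500)
    got <- cluster_site_spots(pts, r)$membership
    expect_true(same_partition(got, oracle_cluster(as.matrix(pts), r)))
  }
  # larger scenes against the single-linkage oracle
  for (rep in 1:5) {
    n <- 500
    pts <- data.frame(x = runif(n, 0, 20000), y = runif(n, 0, 20000),
                      z = runif(n, 0, 8000))
    r <- runif(1, 400, 1200)
    got <- cluster_site_spots(pts, r)$membership
    expect_true(same_partition(got, oracle_cluster_hclust(as.matrix(pts), r)))
  }
})

test_that("partner attachment respects the search radius and flags sharing", {
  site <- data.frame(x = c(0, 5000), y = 0, z = 0)
  cl <- cluster_site_spots(site, 500)
  partners <- list(partner = data.frame(
    x = c(1500, 2500, 3200), y = 0, z = 0, quality = 1))
  st <- assemble_structures(site, cl, partners, search_radius_nm = 2000)
  expect_equal(length(st), 2L)
  first <- st[[which(vapply(st, function(s) s$core[1], 0) == 0)]]
  second <- st[[which(vapply(st, function(s) s$core[1], 0) == 5000)]]
  expect_equal(first$members$partner$x, 1500)     # 1.5 um attached
  expect_equal(second$members$partner$x, 3200)    # 2.5 um from 0: unattached
  # a spot within reach of both cores is flagged shared
  shared <- list(partner = data.frame(x = 2500, y = 0, z = 0, quality = 1))
  st2 <- assemble_structures(site, cl, shared, search_radius_nm = 2600)
  expect_true(all(vapply(st2, function(s) s$members$partner$shared[1],
                         logical(1))))
})

test_that("attachment equals a brute-force all-pairs distance test", {
  set.seed(64)
  site <- data.frame(x = runif(30, 0, 10000), y = runif(30, 0, 10000),
                     z = runif(30, 0, 5000))
  partner <- data.frame(x = runif(80, 0, 10000), y = runif(80, 0, 10000),
                        z = runif(80, 0, 5000), quality = 1)
  r_link <- 600; r_search <- 1500
  cl <- cluster_site_spots(site, r_link)
  st <- assemble_structures(site, cl, list(partner = partner), r_search)
  for (s in st) {
    dd <- sqrt((partner$x - s$core[1])^2 + (partner$y - s$core[2])^2 +
                 (partner$z - s$core[3])^2)
    expect_equal(sort(s$members$partner$x), sort(partner$x[dd <= r_search]))
  }
})

test_that("encapsulation: octahedron true, one-sided false, degenerate fallback", {
  r <- 650
  octa <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
                c(0, 0, r), c(0, 0, -r))
  expect_true(encapsulation_test(c(0, 0, 0), octa))
  oneside <- rbind(c(r, 0, 0), c(r, 100, 0), c(r, -80, 60))
  expect_false(encapsulation_test(c(0, 0, 0), oneside))
  expect_false(encapsulation_test(c(0, 0, 0), octa[1:2, ]))  # < min satellites
  # coplanar ring covers 360 degrees around the core -> fallback true
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(r * cos(ang), r * sin(ang), 0)
  expect_true(encapsulation_test(c(0, 0, 0), ring))
  # coplanar half-arc (120 degrees) fails the 180-degree default
  arc <- cbind(r * cos(ang[1:3] / 3), r * sin(ang[1:3] / 3), 0)
  expect_false(encapsulation_test(c(0, 0, 0), arc))
})

test_that("hull test agrees with Caratheodory enumeration on random configurations", {
  set.seed(65)
  agree <- 0L
  for (rep in 1:300) {
    k <- sample(4:8, 1)
    sat <- matrix(rnorm(3 * k, 0, 600), k)
    core <- rnorm(3, 0, 400)
    got <- exmfoci:::point_in_hull(core, sat)
    want <- oracle_in_hull(core, sat)
    expect_equal(got, want)
    agree <- agree + (got == want)
  }
  expect_equal(agree, 300L)
})
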