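random_points <- function(n, lo = 0, hi = 10000) {
  matrix(runif(3 * n, lo, hi), n)
}

test_that("control-point split counts and determinism", {
  pts <- data.frame(id = 1:21,
                    pre_x = 1:21, pre_y = 1:21, pre_z = 1:21,
                    post_x = 1:21, post_y = 1:21, post_z = 1:21)
  s <- split_control_points(pts, 0.8, seed = 3)
  expect_equal(sum(s$role == "train"), 17L)
  expect_equal(sum(s$role == "validation"), 4L)
  s2 <- split_control_points(pts, 0.8, seed = 3)
  expect_identical(s$role, s2$role)
  s10 <- split_control_points(pts[1:10, ], 0.8, seed = 1)
  expect_equal(sum(s10$role == "train"), 8L)
  expect_error(split_control_points(pts[1:4, ], 0.5, 1), "at least 4")
})

test_that("Horn fit exactly recovers noiseless similarity transforms", {
  set.seed(41)
  for (rep in 1:10) {
    x <- random_points(21)
    q <- exmfoci:::random_quaternion()
    s <- runif(1, 0.5, 5)
    t_vec <- runif(3, -2000, 2000)
    tr <- similarity_transform(s, q, t_vec)
    y <- apply_transform(tr, x)
    fit <- fit_similarity_horn(x, y)
    expect_lt(abs(fit$scale - s) / s, 1e-9)
    expect_lt(exmfoci:::quat_angle_between(fit$quaternion, q), 1e-9)
    expect_lt(registration_mse(fit, x, y)$mse, 1e-6)
  }
  # the specific configuration: scale 4, 90 degrees about z, +100 nm in x
  x <- random_points(10)
  tr <- similarity_transform(4, quat_from_axis_angle(c(0, 0, 1), pi / 2),
                             c(100, 0, 0))
  fit <- fit_similarity_horn(x, apply_transform(tr, x))
  expect_equal(fit$scale, 4, tolerance = 1e-9)
  expect_equal(fit$translation, c(100, 0, 0), tolerance = 1e-6)
  # identity on identical sets
  fid <- fit_similarity_horn(x, x)
  expect_equal(fid$scale, 1, tolerance = 1e-12)
  expect_lt(registration_mse(fid, x, x)$mse, 1e-9)
})

test_that("Horn fit agrees with brute-force optimisation over (s, Euler, t)", {
  set.seed(42)
  x <- random_points(8, 0, 1000)
  tr <- similarity_transform(2.5, exmfoci:::random_quaternion(),
                             c(300, -100, 50))
  y <- apply_transform(tr, x)
  # add mild noise so the optimum is non-trivial
  y <- y + matrix(rnorm(length(y), 0, 20), nrow(y))
  fit <- fit_similarity_horn(x, y)
  obj <- function(p) {
    R <- exmfoci:::quat_to_matrix(exmfoci:::quat_from_axis_angle(
      c(sin(p[2]) * cos(p[3]), sin(p[2]) * sin(p[3]), cos(p[2])), p[4]))
    yy <- sweep(exp(p[1]) * x %*% t(R), 2, p[5:7], "+")
    sum((yy - y)^2)
  }
  best <- Inf
  for (i in 1:100) {
    p0 <- c(log(runif(1, 0.5, 5)), acos(runif(1, -1, 1)), runif(1, 0, 2 * pi),
            runif(1, 0, pi), runif(3, -500, 500))
    o <- optim(p0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  horn_obj <- sum((apply_transform(fit, x) - y)^2)
  expect_lte(horn_obj, best * (1 + 1e-6))
})

test_that("degenerate collinear configurations are rejected", {
  x <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_similarity_horn(x, x * 2), "collinear|degenerate")
})

test_that("registration error is the mean Euclidean residual in nm", {
  tr <- similarity_transform()   # identity
  pre <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  post <- rbind(c(3, 0, 0), c(0, 4, 0), c(0, 0, 5))
  m <- registration_mse(tr, pre, post)
  expect_equal(m$mse, 4)
  expect_equal(sort(m$residuals), c(3, 4, 5))
  expect_equal(registration_mse(tr, pre, post, squared = TRUE)$mse,
               mean(c(9, 16, 25)))
})

test_that("noisy-landmark error matches a Monte-Carlo estimate of the 3D Gaussian norm", {
  set.seed(43)
  sigma <- 200
  # independent brute-force estimate of E||N(0, sigma^2 I_3)||
  mc <- mean(sqrt(rowSums(matrix(rnorm(3e5, 0, sigma), ncol = 3)^2)))
  x <- random_points(1000, 0, 50000)
  tr <- similarity_transform(4, exmfoci:::random_quaternion(), c(100, 2, 3))
  y <- apply_transform(tr, x) + matrix(rnorm(3000, 0, sigma), 1000)
  fit <- fit_similarity_horn(x, y)
  m <- registration_mse(fit, x, y)
  expect_lt(abs(m$mse - mc) / mc, 0.1)
})

test_that("transform composition with its inverse is the identity", {
  set.seed(44)
  tr <- similarity_transform(3.3, exmfoci:::random_quaternion(),
                             c(11, -22, 33))
  x <- random_points(50)
  back <- apply_transform(invert_transform(tr), apply_transform(tr, x))
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("isotropic resampling preserves constants, identity and ramps", {
  const <- voxel_grid(array(3.7, c(12, 12, 6)), c(100, 100, 200))
  rc <- resample_isotropic(const, 100)
  expect_equal(dim(rc$data), c(12, 12, 12))
  expect_true(all(abs(rc$data - 3.7) < 1e-9))

  a <- array(runif(12 * 12 * 12), c(12, 12, 12))
  iso <- voxel_grid(a, c(100, 100, 100))
  expect_equal(resample_isotropic(iso, 100)$data, a, tolerance = 1e-9)

  ramp <- voxel_grid(
    array(rep(seq_len(24), times = 12 * 6), c(24, 12, 6)),
    c(50, 100, 200))
  rr <- resample_isotropic(ramp, 100)
  # away from borders the linear ramp must be reproduced
  interior <- rr$data[3:10, 3:10, 3:4]
  expected <- array(rep(2 * (3:10) - 0.5, times = 8 * 2), c(8, 8, 2))
  expect_equal(interior, expected, tolerance = 1e-6)
  expect_error(resample_isotropic(const, 1), "upsampling")
})

test_that("pairwise distance table: counts, pure scaling, distortion monotonicity", {
  set.seed(45)
  x <- random_points(21)
  ex <- simulate_expansion(x, 4, 0, rotation = "random")
  pts <- data.frame(id = 1:21, pre_x = x[, 1], pre_y = x[, 2], pre_z = x[, 3],
                    post_x = ex$coords[, 1], post_y = ex$coords[, 2],
                    post_z = ex$coords[, 3])
  tab <- pairwise_distance_table(pts, 4)
  expect_equal(nrow(tab$pairs), 210L)
  expect_lt(tab$summary$max_abs_deviation_nm, 1e-6)

  dev_at <- function(amp) {
    m <- sapply(1:5, function(s) {
      exd <- simulate_expansion(x, 4, amp, 4000, rotation = "random",
                                seed = 1000 + s)
      p <- data.frame(id = 1:21, pre_x = x[, 1], pre_y = x[, 2],
                      pre_z = x[, 3], post_x = exd$coords[, 1],
                      post_y = exd$coords[, 2], post_z = exd$coords[, 3])
      pairwise_distance_table(p, 4)$summary$max_abs_deviation_nm
    })
    mean(m)
  }
  devs <- c(dev_at(0), dev_at(100), dev_at(400))
  expect_true(all(diff(devs) > 0))
})

test_that("validation error exceeds training error on average under noise", {
  set.seed(46)
  diffs <- replicate(40, {
    x <- random_points(21, 0, 30000)
    tr <- similarity_transform(4, exmfoci:::random_quaternion(), c(5, 5, 5))
    y <- apply_transform(tr, x) + matrix(rnorm(63, 0, 200), 21)
    pts <- data.frame(id = 1:21, pre_x = x[, 1], pre_y = x[, 2],
                      pre_z = x[, 3], post_x = y[, 1], post_y = y[, 2],
                      post_z = y[, 3])
    rep <- register_control_points(pts, 0.8, seed = sample.int(1e6, 1))
    rep$mse_validation - rep$mse_train
  })
  expect_gt(mean(diffs), 0)
})
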