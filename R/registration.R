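#' Pre/post-expansion registration and isotropy quantification
#'
#' Expansion isotropy is assessed by fitting a similarity transform
#' (scale + rotation + translation) to manually matched pre/post-expansion
#' control points with Horn's closed-form quaternion method, reporting the
#' registration error on a held-out validation split, and comparing
#' pairwise control-point distances between the two frames. Anisotropy
#' shows up as residual error that the best similarity cannot remove.
#'
#' @name registration
NULL

#' Construct a 3D similarity transform
#'
#' Maps `x -> scale * R x + translation` with `R` the rotation of the unit
#' quaternion.
#'
#' @param scale positive scale factor.
#' @param quaternion unit quaternion `(w, x, y, z)`.
#' @param translation length-3 translation in nm.
#' @return an object of class `exm_similarity`.
#' @export
similarity_transform <- function(scale = 1, quaternion = c(1, 0, 0, 0),
                                 translation = c(0, 0, 0)) {
  if (!is.numeric(scale) || scale <= 0)
    stop("scale must be positive", call. = FALSE)
  q <- quat_normalize(quaternion)
  if (abs(sqrt(sum(q^2)) - 1) > 1e-9)
    stop("quaternion could not be normalised", call. = FALSE)
  structure(list(scale = scale, quaternion = q,
                 translation = as.numeric(translation)),
            class = "exm_similarity")
}

#' @export
print.exm_similarity <- function(x, ...) {
  cat(sprintf("similarity: scale %.6g, quaternion (%s), translation (%s) nm\n",
              x$scale, paste(signif(x$quaternion, 6), collapse = ", "),
              paste(signif(x$translation, 6), collapse = ", ")))
  invisible(x)
}

#' Apply a similarity transform to points
#' @param transform an [similarity_transform()].
#' @param points n x 3 matrix of positions (nm).
#' @return n x 3 matrix of transformed positions.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "exm_similarity"))
  points <- as.matrix(points)
  R <- quat_to_matrix(transform$quaternion)
  sweep(transform$scale * points %*% t(R), 2, transform$translation, "+")
}

#' Invert a similarity transform
#' @param transform an [similarity_transform()].
#' @return the inverse `exm_similarity`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "exm_similarity"))
  q <- transform$quaternion
  q_inv <- c(q[1], -q[2:4])
  R_inv <- quat_to_matrix(q_inv)
  similarity_transform(
    scale = 1 / transform$scale,
    quaternion = q_inv,
    translation = -(R_inv %*% transform$translation)[, 1] / transform$scale
  )
}

#' Split control points into training and validation roles
#'
#' Deterministic seeded split: `round(fraction * n)` points are assigned
#' the `train` role, the remainder `validation` (21 points at 0.8 give
#' 17 train / 4 validation).
#'
#' @param points control-point data frame (see [read_control_points()]).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed for the split.
#' @return the data frame with a `role` column.
#' @export
split_control_points <- function(points, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  n <- nrow(points)
  n_train <- round(train_fraction * n)
  if (n_train < 4L)
    stop("at least 4 training points are required for a stable similarity ",
         "fit (3 non-collinear is the theoretical minimum); got ", n_train,
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n, n_train)
  points$role <- "validation"
  points$role[idx] <- "train"
  attr(points, "split_seed") <- seed
  points
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fit a similarity transform with Horn's quaternion method
#'
#' Closed-form least-squares estimate of scale, rotation and translation
#' minimising `sum ||s R x_i + t - y_i||^2`. The rotation is the
#' eigenvector for the largest eigenvalue of the 4x4 quaternion matrix
#' built from the cross-covariance of the centred point sets; the scale is
#' the symmetric estimate `sqrt(sum||y'||^2 / sum||x'||^2)` restricted to
#' the rotation-consistent form; translation aligns the centroids.
#' Noiseless similarity-related point sets are recovered exactly.
#'
#' @param pre n x 3 matrix of pre-expansion positions (nm).
#' @param post n x 3 matrix of matched post-expansion positions (nm).
#' @return an [similarity_transform()].
#' @export
fit_similarity_horn <- function(pre, post) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopifnot(ncol(pre) == 3, ncol(post) == 3, nrow(pre) == nrow(post))
  n <- nrow(pre)
  if (n < 3L)
    stop("at least 3 point pairs are required", call. = FALSE)
  mu_x <- colMeans(pre); mu_y <- colMeans(post)
  X <- sweep(pre, 2, mu_x); Y <- sweep(post, 2, mu_y)
  if (min(svd(X)$d) < 1e-9 * max(svd(X)$d, 1))
    stop("degenerate (collinear) control-point configuration", call. = FALSE)
  M <- t(X) %*% Y
  S <- function(i, j) M[i, j]
  N <- matrix(c(
    S(1,1)+S(2,2)+S(3,3), S(2,3)-S(3,2),       S(3,1)-S(1,3),       S(1,2)-S(2,1),
    S(2,3)-S(3,2),       S(1,1)-S(2,2)-S(3,3), S(1,2)+S(2,1),       S(3,1)+S(1,3),
    S(3,1)-S(1,3),       S(1,2)+S(2,1),       -S(1,1)+S(2,2)-S(3,3), S(2,3)+S(3,2),
    S(1,2)-S(2,1),       S(3,1)+S(1,3),       S(2,3)+S(3,2),       -S(1,1)-S(2,2)+S(3,3)
  ), 4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  if (q[1] < 0) q <- -q
  R <- quat_to_matrix(q)
  # scale: least squares given R (Horn's asymmetric estimate)
  num <- sum(Y * (X %*% t(R)))
  den <- sum(X^2)
  s <- num / den
  if (!is.finite(s) || s <= 0)
    stop("degenerate configuration: non-positive scale estimate",
         call. = FALSE)
  t_vec <- mu_y - s * (R %*% mu_x)[, 1]
  similarity_transform(scale = s, quaternion = q, translation = t_vec)
}

#' Registration error of a transform on matched points
#'
#' The aggregate error is the mean Euclidean distance in nm between the
#' transformed pre-expansion points and their matched post-expansion
#' points (`squared = TRUE` gives the mean squared distance in nm^2
#' instead).
#'
#' @param transform an [similarity_transform()].
#' @param pre,post matched n x 3 position matrices (nm).
#' @param squared report mean squared distance instead of mean distance.
#' @return list with `mse` (nm) and `residuals` (per-point distances, nm).
#' @export
registration_mse <- function(transform, pre, post, squared = FALSE) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (nrow(pre) == 0L) stop("empty point list", call. = FALSE)
  d <- sqrt(rowSums((apply_transform(transform, pre) - post)^2))
  list(mse = if (squared) mean(d^2) else mean(d), residuals = d)
}

#' Fit and evaluate a registration on split control points
#'
#' Convenience wrapper: splits the points (if no `role` column present),
#' fits Horn's transform on the training points and reports training and
#' validation errors.
#'
#' @param points control-point data frame with `pre_x..post_z` columns.
#' @param train_fraction,seed passed to [split_control_points()].
#' @param squared passed to [registration_mse()].
#' @return list of class `exm_registration_report`: `transform`,
#'   `mse_train`, `mse_validation`, `residuals_train`,
#'   `residuals_validation`, `n_train`, `n_validation`, `seed`.
#' @export
register_control_points <- function(points, train_fraction = 0.8, seed = 1L,
                                    squared = FALSE) {
  if (!"role" %in% names(points))
    points <- split_control_points(points, train_fraction, seed)
  tr_idx <- points$role == "train"
  pre <- as.matrix(points[, c("pre_x", "pre_y", "pre_z")])
  post <- as.matrix(points[, c("post_x", "post_y", "post_z")])
  fit <- fit_similarity_horn(pre[tr_idx, , drop = FALSE],
                             post[tr_idx, , drop = FALSE])
  m_tr <- registration_mse(fit, pre[tr_idx, , drop = FALSE],
                           post[tr_idx, , drop = FALSE], squared = squared)
  m_va <- if (any(!tr_idx))
    registration_mse(fit, pre[!tr_idx, , drop = FALSE],
                     post[!tr_idx, , drop = FALSE], squared = squared)
  else list(mse = NA_real_, residuals = numeric(0))
  structure(list(transform = fit, mse_train = m_tr$mse,
                 mse_validation = m_va$mse,
                 residuals_train = m_tr$residuals,
                 residuals_validation = m_va$residuals,
                 n_train = sum(tr_idx), n_validation = sum(!tr_idx),
                 seed = seed),
            class = "exm_registration_report")
}

#' @export
print.exm_registration_report <- function(x, ...) {
  cat(sprintf("registration: %d train / %d validation points\n",
              x$n_train, x$n_validation))
  cat(sprintf("  MSE train %.3g nm, validation %.3g nm\n",
              x$mse_train, x$mse_validation))
  print(x$transform)
  invisible(x)
}

#' Resample a volume onto an isotropic voxel grid
#'
#' Separable cubic-convolution (Keys) interpolation onto a grid of equal
#' voxel size along all axes; the physical extent is preserved to within
#' one voxel per axis.
#'
#' @param vg a [voxel_grid()].
#' @param target_voxel_nm isotropic target voxel size in nm.
#' @return a resampled [voxel_grid()].
#' @export
resample_isotropic <- function(vg, target_voxel_nm) {
  stopifnot(inherits(vg, "exm_voxel_grid"), target_voxel_nm > 0)
  if (any(vg$voxel_size / target_voxel_nm > 50))
    stop("refusing an upsampling factor > 50 per axis; choose a coarser ",
         "target voxel", call. = FALSE)
  a <- vg$data
  d <- dim(a)
  for (ax in seq_along(d)) {
    n_new <- max(1L, round(d[ax] * vg$voxel_size[ax] / target_voxel_nm))
    # output voxel centres, expressed as fractional input indices
    pos_nm <- (seq_len(n_new) - 0.5) * target_voxel_nm
    pos_idx <- pos_nm / vg$voxel_size[ax] + 0.5
    a <- resample_axis(a, pos_idx, ax)
  }
  voxel_grid(a, rep(target_voxel_nm, length(d)), channel = vg$channel)
}

#' Pairwise control-point distance table
#'
#' All `n(n-1)/2` pairs with their pre-expansion distance, post-expansion
#' distance, the post distance divided by the expansion factor, and the
#' deviation `post/factor - pre` (nm). On perfectly isotropic expansion the
#' deviation is zero for every pair.
#'
#' @param points control-point data frame with `pre_x..post_z` (nm).
#' @param factor an [expansion_factor()] or positive number.
#' @return list with `pairs` (data frame `id_a, id_b, pre_nm, post_nm,
#'   post_over_factor_nm, deviation_nm`) and `summary` (mean/max absolute
#'   deviation, RMS deviation, n pairs).
#' @export
pairwise_distance_table <- function(points, factor = 4) {
  if (nrow(points) < 2L) stop("need at least 2 points", call. = FALSE)
  s <- as_factor_value(factor)
  pre <- as.matrix(points[, c("pre_x", "pre_y", "pre_z")])
  post <- as.matrix(points[, c("post_x", "post_y", "post_z")])
  ij <- utils::combn(nrow(points), 2)
  d_pre <- sqrt(rowSums((pre[ij[1, ], ] - pre[ij[2, ], ])^2))
  d_post <- sqrt(rowSums((post[ij[1, ], ] - post[ij[2, ], ])^2))
  ids <- if ("id" %in% names(points)) points$id else seq_len(nrow(points))
  pairs <- data.frame(
    id_a = ids[ij[1, ]], id_b = ids[ij[2, ]],
    pre_nm = d_pre, post_nm = d_post,
    post_over_factor_nm = d_post / s,
    deviation_nm = d_post / s - d_pre
  )
  list(pairs = pairs,
       summary = list(n_pairs = nrow(pairs),
                      mean_abs_deviation_nm = mean(abs(pairs$deviation_nm)),
                      max_abs_deviation_nm = max(abs(pairs$deviation_nm)),
                      rms_deviation_nm = sqrt(mean(pairs$deviation_nm^2))))
}
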