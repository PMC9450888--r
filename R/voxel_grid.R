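#' 3D intensity volumes with physical voxel sizes
#'
#' A `voxel_grid` wraps a numeric 2D or 3D array together with the physical
#' size of its pixels/voxels in nanometres. It is the unit every image
#' operation in the package consumes and produces.
#'
#' Coordinate convention (fixed throughout the package): voxel indices are
#' 0-based externally; the voxel with 0-based index `i` along an axis spans
#' `[i, i+1) * voxel_size` so its centre is at `(i + 0.5) * voxel_size`.
#' In R's 1-based indexing the centre of element `j` is
#' `(j - 0.5) * voxel_size`. Array dimensions are ordered (x, y, z).
#'
#' @param data numeric 2D or 3D array, dimensions (x, y[, z]).
#' @param voxel_size numeric vector of per-axis physical sizes in nm
#'   (length matching the dimensionality; a scalar is recycled).
#' @param channel optional channel name carried as an attribute.
#' @return an object of class `exm_voxel_grid` with fields `data`,
#'   `voxel_size`, `channel`.
#' @export
voxel_grid <- function(data, voxel_size, channel = NA_character_) {
  if (!is.array(data) && !is.matrix(data))
    stop("data must be a matrix or array", call. = FALSE)
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L)
    stop("voxel_grid supports 2D or 3D data", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, nd)
  if (length(voxel_size) != nd)
    stop("voxel_size length must match dimensionality", call. = FALSE)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size entries must be positive", call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel = channel),
            class = "exm_voxel_grid")
}

#' @export
print.exm_voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_grid %s voxels, voxel size %s nm%s\n",
              paste(d, collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x "),
              if (is.na(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' Physical extent of a grid in nm
#' @param vg a [voxel_grid()].
#' @return numeric vector, per-axis extent in nm.
#' @export
grid_extent <- function(vg) {
  stopifnot(inherits(vg, "exm_voxel_grid"))
  dim(vg$data) * vg$voxel_size
}

# physical centre (nm) of 1-based indices; idx is a matrix with one column
# per axis
index_to_nm <- function(idx, voxel_size) {
  sweep(idx - 0.5, 2L, voxel_size, "*")
}

nm_to_index <- function(pos, voxel_size) {
  sweep(pos, 2L, voxel_size, "/") + 0.5
}

## ---- axis-wise array machinery -------------------------------------------

# subset array `a` along `axis` with (possibly repeated/clamped) indices
index_axis <- function(a, idx, axis) {
  nd <- length(dim(a))
  args <- rep(list(quote(expr = )), nd)
  args[[axis]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# shift array along axis by k voxels with replicate (edge) padding
shift_axis <- function(a, k, axis, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  n <- dim(a)[axis]
  idx <- seq_len(n) + k
  if (pad == "replicate") {
    idx <- pmin(pmax(idx, 1L), n)
    index_axis(a, idx, axis)
  } else {
    out <- array(0, dim(a))
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) return(out)
    nd <- length(dim(a))
    args_to <- rep(list(quote(expr = )), nd); args_to[[axis]] <- which(ok)
    src <- index_axis(a, idx[ok], axis)
    do.call(`[<-`, c(list(out), args_to, list(value = src)))
  }
}

# separable 1D convolution along `axis` (kernel centred, odd length),
# replicate padding
conv_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  for (k in seq_along(kernel)) {
    w <- kernel[k]
    if (w == 0) next
    out <- out + w * shift_axis(a, k - 1L - r, axis)
  }
  out
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing; sigma_vox per axis, in voxels
gauss_smooth <- function(a, sigma_vox) {
  for (ax in seq_along(dim(a))) {
    if (sigma_vox[ax] > 0) a <- conv_axis(a, gaussian_kernel(sigma_vox[ax]), ax)
  }
  a
}

# scale-normalised Laplacian of a (pre-smoothed) volume: sum over axes of
# sigma_nm^2 * d2/du2 with u in nm. Bright blobs give negative responses.
laplacian_scaled <- function(a, voxel_size, sigma_nm) {
  out <- array(0, dim(a))
  for (ax in seq_along(dim(a))) {
    d2 <- shift_axis(a, 1L, ax) - 2 * a + shift_axis(a, -1L, ax)
    out <- out + d2 * (sigma_nm[ax]^2 / voxel_size[ax]^2)
  }
  out
}

# running maximum along axis within +-r voxels (box), replicate padding
max_filter_axis <- function(a, r, axis) {
  out <- a
  for (k in seq_len(r)) {
    out <- pmax(out, shift_axis(a, k, axis), shift_axis(a, -k, axis))
  }
  out
}

## ---- binary 3D morphology -------------------------------------------------

ball_offsets <- function(radius, nd = 3L) {
  s <- (-radius):radius
  g <- as.matrix(expand.grid(rep(list(s), nd)))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

apply_offsets <- function(mask, offsets, op = c("or", "and")) {
  op <- match.arg(op)
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    sh <- mask
    for (ax in seq_along(dim(mask))) {
      k <- offsets[i, ax]
      if (k != 0) sh <- shift_axis(sh, k, ax, pad = "zero")
    }
    out <- if (is.null(out)) sh else if (op == "or") out | sh else out & sh
  }
  out
}

#' Binary erosion/dilation with a voxel ball
#'
#' 3D (or 2D) binary morphology with a digital ball structuring element;
#' voxels outside the image are treated as background.
#'
#' @param mask logical array.
#' @param radius ball radius in voxels (default 1: the 6-connected cross
#'   in 3D).
#' @return logical array of the same shape.
#' @keywords internal
erode_mask <- function(mask, radius = 1L) {
  apply_offsets(mask, ball_offsets(radius, length(dim(mask))), "and")
}

#' @rdname erode_mask
#' @keywords internal
dilate_mask <- function(mask, radius = 1L) {
  apply_offsets(mask, ball_offsets(radius, length(dim(mask))), "or")
}

## ---- connected components -------------------------------------------------

# weighted union-find over integer ids 1..n; edges is a 2-column matrix
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Label connected components of a 3D binary mask
#'
#' 6-connected 3D labelling built by 2D-labelling each z-slice (EBImage)
#' and merging slice labels that overlap between adjacent slices.
#'
#' @param mask logical 3D array (a 2D matrix is labelled directly).
#' @return integer array of the same shape; 0 = background, components
#'   numbered contiguously from 1.
#' @export
label_components_3d <- function(mask) {
  if (length(dim(mask)) == 2L)
    return(array(as.integer(EBImage::bwlabel(mask * 1)), dim(mask)))
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  offsets_per_slice <- integer(d[3])
  for (z in seq_len(d[3])) {
    sl <- EBImage::bwlabel(mask[, , z] * 1)
    sl <- as.integer(sl)
    nz <- sl > 0L
    sl[nz] <- sl[nz] + offset
    lab[, , z] <- sl
    offsets_per_slice[z] <- offset
    offset <- max(offset, if (any(nz)) max(sl) else offset)
  }
  n <- offset
  if (n == 0L) return(lab)
  edges <- NULL
  for (z in seq_len(d[3] - 1L)) {
    a <- lab[, , z]; b <- lab[, , z + 1L]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pr <- unique(cbind(a[both], b[both]))
      edges <- rbind(edges, pr)
    }
  }
  comp <- union_find(n, edges)
  nz <- lab > 0L
  lab[nz] <- comp[lab[nz]]
  lab
}

#' Fill interior holes of a 3D binary mask
#'
#' Background components not connected to the image border are converted
#' to foreground.
#'
#' @param mask logical 3D array.
#' @return logical array with holes filled.
#' @export
fill_holes_3d <- function(mask) {
  bg <- !mask
  lab <- label_components_3d(bg)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  mask | array(hole, d)
}

## ---- cropping -------------------------------------------------------------

#' Crop an axis-aligned box out of a volume
#'
#' The crop is centred on a physical position and zero-padded where the box
#' extends beyond the image, so the output always has the requested size.
#'
#' @param vg a [voxel_grid()].
#' @param centre_nm numeric length-3 (or 2) physical centre in nm.
#' @param edge_nm box edge length in nm (scalar or per axis).
#' @return a [voxel_grid()] crop with the same voxel size.
#' @export
crop_box <- function(vg, centre_nm, edge_nm) {
  stopifnot(inherits(vg, "exm_voxel_grid"))
  d <- dim(vg$data)
  nd <- length(d)
  if (length(edge_nm) == 1L) edge_nm <- rep(edge_nm, nd)
  half <- round(edge_nm / (2 * vg$voxel_size))
  ctr <- ceiling(centre_nm / vg$voxel_size)      # voxel containing the centre
  n_out <- 2L * half + 1L
  out <- array(0, n_out)
  from <- ctr - half
  to <- ctr + half
  if (any(to < 1L) || any(from > d))
    stop("crop box does not intersect the image", call. = FALSE)
  src_from <- pmax(from, 1L)
  src_to <- pmin(to, d)
  dst_from <- src_from - from + 1L
  dst_to <- dst_from + (src_to - src_from)
  idx_src <- lapply(seq_len(nd), function(ax) src_from[ax]:src_to[ax])
  idx_dst <- lapply(seq_len(nd), function(ax) dst_from[ax]:dst_to[ax])
  src <- do.call(`[`, c(list(vg$data), idx_src, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), idx_dst, list(value = src)))
  voxel_grid(out, vg$voxel_size, channel = vg$channel)
}

## ---- cubic resampling ------------------------------------------------------

# Keys cubic-convolution weights (a = -0.5) for fractional offset t in [0,1):
# taps at floor-1 .. floor+2
keys_weights <- function(t, a = -0.5) {
  w <- matrix(0, length(t), 4L)
  x <- cbind(1 + t, t, 1 - t, 2 - t)      # |distance| of the 4 taps
  near <- abs(x) <= 1
  w[] <- ifelse(near,
                (a + 2) * abs(x)^3 - (a + 3) * abs(x)^2 + 1,
                a * abs(x)^3 - 5 * a * abs(x)^2 + 8 * a * abs(x) - 4 * a)
  w
}

# resample axis `axis` of array a onto positions `pos` (1-based fractional
# indices), cubic convolution with replicate boundary
resample_axis <- function(a, pos, axis) {
  n <- dim(a)[axis]
  i0 <- floor(pos)
  t <- pos - i0
  w <- keys_weights(t)
  d_out <- dim(a); d_out[axis] <- length(pos)
  out <- array(0, d_out)
  for (k in 0:3) {
    idx <- pmin(pmax(i0 - 1L + k, 1L), n)
    piece <- index_axis(a, idx, axis)
    wk <- w[, k + 1L]
    if (axis == 1L) out <- out + piece * wk
    else {
      perm <- seq_along(d_out); perm[c(1L, axis)] <- perm[c(axis, 1L)]
      piece_p <- aperm(piece, perm)
      piece_p <- piece_p * wk
      out <- out + aperm(piece_p, perm)
    }
  }
  out
}
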