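#' 3D spot detection and structure assembly
#'
#' Repair-protein puncta are detected per channel as local maxima of a
#' scale-normalised Laplacian-of-Gaussian filtered volume, filtered on the
#' prominence (quality) of each maximum. Site-channel spots are then
#' clustered by fixed-radius connected components, and partner-channel
#' spots within a search radius of each cluster's centre of mass are
#' attached to form focus structures.
#'
#' @name spot-structures
NULL

#' Detect diffraction-limited spots in one channel
#'
#' The volume is smoothed with an anisotropy-aware Gaussian
#' (`sigma = expected_radius / sqrt(3)` in nm, converted per axis to
#' voxels) and the scale-normalised Laplacian is computed; bright blobs
#' give positive responses. Local maxima within a radius-sized box
#' neighbourhood are kept iff their response (the spot quality, i.e. the
#' prominence of the maximum over its local background in the band-passed
#' volume) reaches `quality_threshold`, then refined to sub-voxel accuracy
#' by a 3-point quadratic fit per axis. Ties are broken by lexicographic
#' voxel index.
#'
#' @param vg a single-channel [voxel_grid()].
#' @param expected_radius_nm expected blob radius in nm (must be at least
#'   one voxel on every axis).
#' @param quality_threshold minimum quality for a retained spot (> 0).
#' @return data frame of class `exm_spots`: `x, y, z` (nm), `quality`,
#'   `channel`, `radius_nm`, sorted by quality descending.
#' @export
detect_spots <- function(vg, expected_radius_nm, quality_threshold = 1) {
  stopifnot(inherits(vg, "exm_voxel_grid"))
  if (any(expected_radius_nm < vg$voxel_size))
    stop("expected radius is below the voxel size on at least one axis",
         call. = FALSE)
  if (quality_threshold <= 0)
    stop("quality_threshold must be positive", call. = FALSE)
  d <- dim(vg$data)
  sigma_nm <- rep(expected_radius_nm / sqrt(3), 3)
  sigma_vox <- sigma_nm / vg$voxel_size
  sm <- gauss_smooth(vg$data, sigma_vox)
  resp <- -laplacian_scaled(sm, vg$voxel_size, sigma_nm)
  r_vox <- pmax(1L, round(expected_radius_nm / vg$voxel_size))
  mx <- resp
  for (ax in 1:3) mx <- max_filter_axis(mx, r_vox[ax], ax)
  cand <- which(resp >= mx & resp >= quality_threshold & resp > 0)
  if (!length(cand)) {
    return(empty_spots(vg$channel, expected_radius_nm))
  }
  idx <- arrayInd(cand, d)
  q <- resp[cand]
  # order by quality desc, lexicographic index for ties; suppress any
  # candidate within the neighbourhood of an already accepted one
  ord <- order(-q, idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]; q <- q[ord]
  keep <- logical(length(q))
  acc <- matrix(0, 0, 3)
  for (i in seq_along(q)) {
    if (nrow(acc)) {
      rel <- abs(sweep(acc, 2, idx[i, ], "-"))
      if (any(rel[, 1] <= r_vox[1] & rel[, 2] <= r_vox[2] &
              rel[, 3] <= r_vox[3])) next
    }
    keep[i] <- TRUE
    acc <- rbind(acc, idx[i, ])
  }
  idx <- idx[keep, , drop = FALSE]; q <- q[keep]
  # sub-voxel refinement, one parabola per axis
  off <- matrix(0, nrow(idx), 3)
  for (ax in 1:3) {
    at <- function(sh) {
      j <- idx; j[, ax] <- pmin(pmax(j[, ax] + sh, 1L), d[ax])
      resp[j]
    }
    f0 <- at(0L); fm <- at(-1L); fp <- at(1L)
    den <- fm - 2 * f0 + fp
    o <- ifelse(abs(den) > 1e-12, 0.5 * (fm - fp) / den, 0)
    off[, ax] <- pmin(pmax(o, -0.5), 0.5)
  }
  pos <- sweep(idx - 0.5 + off, 2, vg$voxel_size, "*")
  out <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], quality = q,
                    channel = vg$channel, radius_nm = expected_radius_nm,
                    stringsAsFactors = FALSE)
  class(out) <- c("exm_spots", "data.frame")
  out
}

empty_spots <- function(channel = NA_character_, radius = NA_real_) {
  out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    quality = numeric(0), channel = character(0),
                    radius_nm = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("exm_spots", "data.frame")
  out
}

#' Cluster site-channel spots by fixed-radius connected components
#'
#' Two spots are linked if their distance is at most `link_radius_nm`;
#' clusters are the connected components of the resulting graph (so a
#' chain of close spots forms one cluster even if its ends are far apart).
#' The cluster core is the unweighted centre of mass of its members.
#' Implemented with a spatial grid hash plus union-find.
#'
#' @param spots data frame with `x, y, z` (nm).
#' @param link_radius_nm linking radius in nm (> 0).
#' @return list with `membership` (integer cluster id per spot, numbered
#'   from 1 in order of first appearance), `cores` (k x 3 matrix of
#'   centres of mass, nm), `sizes` (spots per cluster).
#' @export
cluster_site_spots <- function(spots, link_radius_nm) {
  if (link_radius_nm <= 0) stop("link_radius_nm must be positive",
                                call. = FALSE)
  n <- nrow(spots)
  if (n == 0L)
    return(list(membership = integer(0), cores = matrix(0, 0, 3),
                sizes = integer(0)))
  pts <- as.matrix(spots[, c("x", "y", "z")])
  cell <- floor(sweep(pts, 2, rep(link_radius_nm, 3), "/"))
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cell_map <- split(seq_len(n), key)
  cell_index <- lapply(strsplit(names(cell_map), " "), as.numeric)
  keys_env <- new.env(parent = emptyenv())
  for (i in seq_along(cell_map)) assign(names(cell_map)[i], i, envir = keys_env)
  edges <- NULL
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  r2 <- link_radius_nm^2
  for (ci in seq_along(cell_map)) {
    base <- cell_index[[ci]]
    ids_a <- cell_map[[ci]]
    for (k in seq_len(nrow(neigh))) {
      nb_key <- paste(base[1] + neigh[k, 1], base[2] + neigh[k, 2],
                      base[3] + neigh[k, 3])
      cj <- get0(nb_key, envir = keys_env, ifnotfound = NULL)
      if (is.null(cj) || cj < ci) next
      ids_b <- cell_map[[cj]]
      pr <- if (ci == cj) {
        if (length(ids_a) < 2L) next
        t(utils::combn(ids_a, 2))
      } else as.matrix(expand.grid(ids_a, ids_b))
      dd <- rowSums((pts[pr[, 1], , drop = FALSE] -
                       pts[pr[, 2], , drop = FALSE])^2)
      ok <- dd <= r2
      if (any(ok)) edges <- rbind(edges, pr[ok, , drop = FALSE])
    }
  }
  comp <- union_find(n, edges)
  comp <- match(comp, unique(comp))
  k <- max(comp)
  cores <- t(vapply(seq_len(k), function(cid)
    colMeans(pts[comp == cid, , drop = FALSE]), numeric(3)))
  list(membership = comp, cores = cores,
       sizes = as.integer(tabulate(comp, k)))
}

#' Assemble focus structures from site clusters and partner spots
#'
#' For each site-channel cluster, partner-channel spots within
#' `search_radius_nm` of the cluster's centre of mass are attached
#' (default 2 µm post-expansion). A partner spot lying within the radius
#' of several cores attaches to each of them and is flagged `shared`.
#'
#' @param site_spots site-channel spot data frame (`x, y, z`, nm).
#' @param clusters result of [cluster_site_spots()] on `site_spots`.
#' @param partner_spots named list of partner-channel spot data frames.
#' @param search_radius_nm attachment radius in nm.
#' @return list of `exm_structure` objects: `id`, `core` (nm), `site`
#'   (member site spots), `members` (per-partner-channel data frames with
#'   a `dist_nm` and `shared` column), `counts`.
#' @export
assemble_structures <- function(site_spots, clusters, partner_spots = list(),
                                search_radius_nm = 2000) {
  stopifnot(search_radius_nm > 0)
  k <- nrow(clusters$cores)
  # how many cores each partner spot is within reach of (for `shared`)
  reach <- lapply(partner_spots, function(ps) {
    if (nrow(ps) == 0L || k == 0L) return(integer(0))
    pm <- as.matrix(ps[, c("x", "y", "z")])
    within <- matrix(FALSE, nrow(ps), k)
    for (cid in seq_len(k)) {
      within[, cid] <- sqrt(rowSums(sweep(pm, 2, clusters$cores[cid, ],
                                          "-")^2)) <= search_radius_nm
    }
    rowSums(within)
  })
  out <- vector("list", k)
  for (cid in seq_len(k)) {
    core <- clusters$cores[cid, ]
    site_m <- site_spots[clusters$membership == cid, , drop = FALSE]
    members <- list()
    for (ch in names(partner_spots)) {
      ps <- partner_spots[[ch]]
      if (nrow(ps)) {
        dd <- sqrt(rowSums(sweep(as.matrix(ps[, c("x", "y", "z")]), 2,
                                 core, "-")^2))
        sel <- dd <= search_radius_nm
        m <- ps[sel, , drop = FALSE]
        m$dist_nm <- dd[sel]
        m$shared <- reach[[ch]][sel] > 1L
      } else {
        m <- ps
        m$dist_nm <- numeric(0)
        m$shared <- logical(0)
      }
      members[[ch]] <- m
    }
    out[[cid]] <- structure(
      list(id = cid, core = core, site = site_m, members = members,
           counts = c(site = nrow(site_m),
                      vapply(members, nrow, integer(1))),
           search_radius_nm = search_radius_nm),
      class = "exm_structure")
  }
  out
}

#' @export
print.exm_structure <- function(x, ...) {
  cat(sprintf("structure %d: core (%s) nm; counts: %s%s\n", x$id,
              paste(round(x$core), collapse = ", "),
              paste(names(x$counts), x$counts, collapse = ", ", sep = "="),
              if (!is.null(x$class_label))
                paste0("; class ", x$class_label) else ""))
  invisible(x)
}

#' Test whether satellites encapsulate a core position
#'
#' True iff there are at least `min_satellites` satellites and the core
#' lies inside the 3D convex hull of the satellite positions. The hull
#' test is an exact supporting-plane enumeration (satellite counts are
#' small). If the satellites are (near-)coplanar the hull is degenerate
#' and the test falls back to angular coverage: satellites are projected
#' onto their best-fit plane and the arc they cover around the projected
#' core must be at least `min_arc_deg`.
#'
#' @param core length-3 position (nm).
#' @param satellites n x 3 matrix of satellite positions (nm).
#' @param min_satellites minimum satellite count (default 3).
#' @param min_arc_deg angular-coverage threshold for the coplanar
#'   fallback, degrees (default 180).
#' @param use_hull set `FALSE` to force the angular-coverage test.
#' @return logical.
#' @export
encapsulation_test <- function(core, satellites, min_satellites = 3L,
                               min_arc_deg = 180, use_hull = TRUE) {
  satellites <- as.matrix(satellites)
  if (nrow(satellites) < 1L) stop("need at least 1 satellite", call. = FALSE)
  if (nrow(satellites) < min_satellites) return(FALSE)
  core <- as.numeric(core)
  ctr <- sweep(satellites, 2, colMeans(satellites))
  sv <- svd(ctr)
  scale0 <- max(sv$d[1], 1e-9)
  planar <- sv$d[3] < 1e-6 * scale0
  if (use_hull && !planar) {
    return(point_in_hull(core, satellites))
  }
  # coplanar fallback: angular coverage around the core in the best-fit
  # plane of the satellites
  basis <- sv$v[, 1:2, drop = FALSE]
  rel <- sweep(satellites, 2, core) %*% basis
  ang <- sort(atan2(rel[, 2], rel[, 1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  coverage <- 2 * pi - max(gaps)
  coverage >= min_arc_deg * pi / 180
}

# exact point-in-convex-hull test by supporting-plane enumeration:
# p is outside the hull iff some plane through three satellites has all
# satellites on one side and p strictly on the other
point_in_hull <- function(p, pts, tol_rel = 1e-9) {
  n <- nrow(pts)
  scale0 <- max(abs(sweep(pts, 2, colMeans(pts)))) + 1e-12
  tol <- tol_rel * scale0
  tri <- utils::combn(n, 3)
  for (t in seq_len(ncol(tri))) {
    a <- pts[tri[1, t], ]; b <- pts[tri[2, t], ]; c_ <- pts[tri[3, t], ]
    nrm <- c((b[2]-a[2])*(c_[3]-a[3]) - (b[3]-a[3])*(c_[2]-a[2]),
             (b[3]-a[3])*(c_[1]-a[1]) - (b[1]-a[1])*(c_[3]-a[3]),
             (b[1]-a[1])*(c_[2]-a[2]) - (b[2]-a[2])*(c_[1]-a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn < tol) next
    nrm <- nrm / nn
    d <- sweep(pts, 2, a) %*% nrm
    dp <- sum((p - a) * nrm)
    if (all(d <= tol) && dp > tol) return(FALSE)
    if (all(d >= -tol) && dp < -tol) return(FALSE)
  }
  TRUE
}
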