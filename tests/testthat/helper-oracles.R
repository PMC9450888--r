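# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: clustering via single-linkage hclust, hull
# membership via Caratheodory tetrahedron enumeration, matching via a
# quadratic nearest-neighbour sweep.

# fixed-radius connected components by brute force: union-find over every
# pair of the full distance matrix
oracle_cluster <- function(pts, r) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  lab <- seq_len(n)
  dm <- as.matrix(dist(pts))
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (dm[i, j] <= r && lab[i] != lab[j]) {
          old <- max(lab[i], lab[j]); new <- min(lab[i], lab[j])
          lab[lab == old] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# same partition via single-linkage dendrogram cut (second, faster oracle)
oracle_cluster_hclust <- function(pts, r) {
  n <- nrow(pts)
  if (n <= 1L) return(rep(1L, n))
  hc <- hclust(dist(pts), method = "single")
  unname(cutree(hc, h = r))
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# point-in-convex-hull by Caratheodory: p is in the hull iff it lies in
# some tetrahedron of 4 of the points (barycentric solve)
oracle_in_hull <- function(p, pts, tol = 1e-7) {
  n <- nrow(pts)
  if (n < 4L) return(FALSE)
  combs <- combn(n, 4)
  for (k in seq_len(ncol(combs))) {
    v <- pts[combs[, k], , drop = FALSE]
    A <- rbind(t(v), rep(1, 4))
    b <- c(p, 1)
    lam <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(lam) && all(lam >= -tol)) return(TRUE)
  }
  FALSE
}

# greedy nearest-neighbour matching of detections to ground truth within
# a tolerance; returns number matched
oracle_match <- function(truth, det, tol_nm) {
  if (nrow(det) == 0L || nrow(truth) == 0L) return(0L)
  used <- logical(nrow(det))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((det$x - truth$x[i])^2 + (det$y - truth$y[i])^2 +
                 (det$z - truth$z[i])^2)
    dd[used] <- Inf
    j <- which.min(dd)
    if (is.finite(dd[j]) && dd[j] <= tol_nm) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

# render a planted structure into site/partner channel grids under the
# generator's default imaging conditions
render_structure_scene <- function(pl, shape = c(56L, 56L, 28L),
                                   voxel = c(100, 100, 200),
                                   psf = c(100, 100, 300),
                                   background = 220, noise = TRUE) {
  out <- list()
  for (ch in c("site", "partner", "partner2")) {
    sp <- pl$spots[pl$spots$channel == ch, , drop = FALSE]
    if (ch != "site" && nrow(sp) == 0L) next
    out[[ch]] <- render_volume(sp, shape, voxel, psf,
                               background = background,
                               poisson = noise,
                               gaussian_sd = if (noise) 2 else 0,
                               channel = ch)
  }
  out
}

# classify planted ground-truth coordinates through the public API
# (cluster -> assemble -> classify), bypassing imaging
classify_truth_coords <- function(spots, link_radius_nm = 500,
                                  search_radius_nm = 2000,
                                  rules = two_channel_rules()) {
  site <- spots[spots$channel == "site", , drop = FALSE]
  partners <- list()
  for (ch in c("partner", "partner2")) {
    if (any(spots$channel == ch))
      partners[[ch]] <- spots[spots$channel == ch, , drop = FALSE]
  }
  cl <- cluster_site_spots(site, link_radius_nm)
  st <- assemble_structures(site, cl, partners, search_radius_nm)
  st <- lapply(st, classify_structure, rules = rules,
               partner_channel = if (length(partners)) "partner" else NULL)
  vapply(st, function(s) as.integer(s$class_label), integer(1))
}
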