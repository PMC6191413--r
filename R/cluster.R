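#' Gaussian-smooth an accuracy map
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`,
#' converted to voxel units through the grid's voxel size.  The volume is
#' zero-filled outside the mask before convolution and the mask reapplied
#' after (zero-padded boundary: interior values of a constant map are
#' preserved, boundary values attenuate).  `fwhm_mm = 0` is the identity.
#'
#' @param map an `accuracy_map`, or a bare 3D array (then `grid` must be
#'   supplied).
#' @param fwhm_mm kernel full width at half maximum in millimetres (>= 0).
#' @param grid grid for bare-array input.
#' @return object of the same kind as the input, smoothed.
#' @export
smooth_map <- function(map, fwhm_mm, grid = NULL) {
  stopifnot(fwhm_mm >= 0)
  is_map <- inherits(map, "accuracy_map")
  if (is_map) { grid <- map$grid; vol <- map$data } else vol <- map
  stopifnot(!is.null(grid))
  if (fwhm_mm == 0) return(map)

  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  h <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-h:h, sd = sigma)
  k <- k / sum(k)

  x <- vol
  x[is.na(x)] <- 0
  x[!grid$mask] <- 0
  for (axis in 1:3) {
    n <- dim(x)[1]  # convolve along the first axis, then rotate dims
    K <- matrix(0, n, n)
    for (d in -h:h) {
      ix <- seq_len(n)
      jx <- ix + d
      ok <- jx >= 1 & jx <= n
      K[cbind(ix[ok], jx[ok])] <- k[d + h + 1]
    }
    x <- array(K %*% matrix(x, n), dim = dim(x))
    x <- aperm(x, c(2, 3, 1))
  }
  x[!grid$mask] <- NA
  if (is_map) { map$data <- x; map } else x
}

#' Group one-sample t map over subjects
#'
#' Per voxel, the one-sample t statistic of the subjects' (accuracy - chance)
#' values against zero, with `n - 1` degrees of freedom; intended for the
#' one-sided test of above-chance decoding.  Voxels with zero across-subject
#' variance get `t = 0` and are flagged.
#'
#' @param maps list of smoothed `accuracy_map`s (or 3D arrays), one per
#'   subject, on a common grid.
#' @return a list of class `group_t`: `t` (3D array), `df`, `n`, and
#'   `zero_variance` (logical 3D array flag).
#' @export
group_t_map <- function(maps) {
  stopifnot(length(maps) >= 2)
  vols <- lapply(maps, function(m)
    if (inherits(m, "accuracy_map")) m$data else m)
  sh <- dim(vols[[1]])
  M <- vapply(vols, as.vector, numeric(prod(sh)))
  n <- ncol(M)
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  zv <- s == 0 & !is.na(s)
  t[zv] <- 0
  structure(list(t = array(t, sh), df = n - 1, n = n,
                 zero_variance = array(zv, sh)),
            class = "group_t")
}

# Neighbour offsets for a connectivity scheme (6 faces, 18 +edges, 26 +corners).
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array by breadth-first search.
# Returns an integer array (0 = background, 1..n = components).
label_components <- function(mask3d, connectivity = 26) {
  sh <- dim(mask3d)
  offs <- connectivity_offsets(connectivity)
  lab <- array(0L, sh)
  idx <- which(mask3d)
  if (length(idx) == 0) return(lab)
  in_set <- array(FALSE, sh)
  in_set[idx] <- TRUE
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      co <- index_to_coords(queue, sh)
      queue <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(co, 2, offs[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] &
          nb[, 2] >= 1 & nb[, 2] <= sh[2] &
          nb[, 3] >= 1 & nb[, 3] <= sh[3]
        if (!any(ok)) next
        ni <- coords_to_index(nb[ok, , drop = FALSE], sh)
        new <- ni[in_set[ni] & lab[ni] == 0L]
        if (length(new) > 0) {
          lab[new] <- cur
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# Max cluster size per sign-flip permutation, given the subject matrix
# M (nvox x n), the t threshold, and a +/-1 flip matrix (n x n_perm).
perm_max_cluster <- function(M, flips, t_thresh, sh, connectivity,
                             mask_vec) {
  n <- ncol(M)
  ss <- rowSums(M^2)
  S <- M %*% flips                     # nvox x n_perm sums
  mu <- S / n
  varr <- pmax(ss - n * mu^2, 0) / (n - 1)
  tmat <- mu / sqrt(varr / n)
  tmat[varr == 0] <- 0
  apply(tmat, 2, function(tv) {
    supra <- tv > t_thresh & mask_vec
    if (!any(supra, na.rm = TRUE)) return(0L)
    supra[is.na(supra)] <- FALSE
    lab <- label_components(array(supra, sh), connectivity)
    max(tabulate(lab[lab > 0L]))
  })
}

#' Define regions of interest by height + permutation extent thresholds
#'
#' Computes the group one-sample t map of the subjects' (smoothed, no-move)
#' accuracy maps, keeps voxels passing a one-sided height threshold
#' (`t > qt(1 - height_p, n - 1)`), labels connected components, and retains
#' components larger than a family-wise extent threshold calibrated by
#' sign-flip permutation: the maximum suprathreshold cluster size is recorded
#' for `n_perm` random sign flips of the subject maps, and the
#' `1 - extent_fwe_p` quantile of that null distribution is the cutoff.
#' Sign-flipping is exact under the symmetric null and replaces
#' random-field-theory cluster correction.
#'
#' @param maps list of per-subject `accuracy_map`s or 3D arrays (smoothed
#'   no-move maps), common grid.
#' @param height_p voxel-level height threshold (one-sided, uncorrected);
#'   must be in `(0, 0.5)`.
#' @param extent_fwe_p family-wise error level for cluster extent.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param grid grid when `maps` are bare arrays.
#' @param restrict_mask optional logical 3D array restricting the analysis
#'   (e.g. an anatomical mask); default is the grid mask.
#' @return a `cluster_set`: list of clusters (`label`, `voxels` coordinate
#'   matrix, `size`, `peak_t`, `peak` coordinate, `p_fwe`), possibly empty,
#'   with the t map, thresholds and extent cutoff as attributes.
#' @export
define_rois <- function(maps, height_p = 0.001, extent_fwe_p = 0.05,
                        n_perm = 1000, seed = 1, connectivity = 26,
                        grid = NULL, restrict_mask = NULL) {
  if (height_p <= 0 || height_p >= 0.5)
    stop("height_p must be in (0, 0.5): a height threshold must select ",
         "above-chance voxels")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (inherits(maps[[1]], "accuracy_map")) grid <- maps[[1]]$grid
  stopifnot(!is.null(grid))
  sh <- grid$shape
  mask_vec <- as.vector(if (is.null(restrict_mask)) grid$mask
                        else grid$mask & restrict_mask)

  gt <- group_t_map(maps)
  n <- gt$n
  t_thresh <- qt(1 - height_p, df = gt$df)

  tv <- as.vector(gt$t)
  supra <- !is.na(tv) & tv > t_thresh & mask_vec
  lab <- label_components(array(supra, sh), connectivity)

  vols <- lapply(maps, function(m)
    if (inherits(m, "accuracy_map")) m$data else m)
  M <- vapply(vols, as.vector, numeric(prod(sh)))
  M[is.na(M)] <- 0
  null_max <- with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    perm_max_cluster(M, flips, t_thresh, sh, connectivity, mask_vec)
  })
  cutoff <- as.numeric(quantile(null_max, 1 - extent_fwe_p, type = 1))

  clusters <- list()
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes > cutoff)
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    clusters <- lapply(seq_along(keep), function(i) {
      ix <- which(lab == keep[i])
      pk <- ix[which.max(tv[ix])]
      list(label = paste0("C", i),
           voxels = index_to_coords(ix, sh),
           size = length(ix),
           peak_t = max(tv[ix]),
           peak = index_to_coords(pk, sh)[1, ],
           p_fwe = mean(null_max >= length(ix)))
    })
  }
  structure(clusters, class = "cluster_set",
            t_map = gt$t, df = gt$df, t_threshold = t_thresh,
            extent_cutoff = cutoff, null_max = null_max,
            height_p = height_p, extent_fwe_p = extent_fwe_p,
            connectivity = connectivity, grid = grid)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d cluster(s); height t > %.3f (df %d), extent > %d voxels\n",
              length(x), attr(x, "t_threshold"), attr(x, "df"),
              attr(x, "extent_cutoff")))
  for (cl in x)
    cat(sprintf("  %s: %d voxels, peak t %.2f at (%d, %d, %d), FWE p %.3f\n",
                cl$label, cl$size, cl$peak_t,
                cl$peak[1], cl$peak[2], cl$peak[3], cl$p_fwe))
  invisible(x)
}

#' Cluster table as a data.frame
#'
#' @param rois a `cluster_set`.
#' @return data.frame with label, size, peak t and peak coordinates.
#' @export
cluster_table <- function(rois) {
  if (length(rois) == 0)
    return(data.frame(label = character(0), size = integer(0),
                      peak_t = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      p_fwe = numeric(0)))
  do.call(rbind, lapply(rois, function(cl)
    data.frame(label = cl$label, size = cl$size, peak_t = cl$peak_t,
               peak_i = cl$peak[1], peak_j = cl$peak[2],
               peak_k = cl$peak[3], p_fwe = cl$p_fwe)))
}
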