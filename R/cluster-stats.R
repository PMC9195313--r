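## Two-group cluster-based permutation statistics on subject-level
## time-frequency difference maps (faces minus mosaics), following the
## max/min cluster-sum algorithm: pixelwise two-sample t-map, voxel
## threshold at p = 0.05 (two-tailed), 4-neighbour clustering, and a
## permutation null of extreme cluster sums built by randomly reassigning
## subjects to groups.

#' Subject-level difference map
#'
#' Face-average minus mosaic-average dB map for one (patient, region)
#' analysis unit.
#'
#' @param tf_db an `fg_tfr` in dB for a single channel
#' @param channel channel index within the map
#' @return list(map = freqs x time matrix, freqs, t)
#' @export
subject_map <- function(tf_db, channel = 1L) {
  if (tf_db$units != "dB") stop("subject_map expects a dB map")
  face <- tfr_average(tf_db, intersect(FACE_CATEGORIES,
                                       unique(tf_db$category)))
  mos <- tfr_average(tf_db, "mosaic")
  list(map = face$power[1, channel, , ] - mos$power[1, channel, , ],
       freqs = tf_db$freqs, t = tf_db$t)
}

## Stack a list of maps (matrices with identical dims) into npix x nsubj.
stack_maps <- function(maps) {
  d <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d)) stop("subject maps must share axes")
  list(X = vapply(maps, as.vector, numeric(prod(d))), dims = d)
}

## Pooled-variance two-sample t per pixel for column index sets a, b.
pooled_t <- function(X, a, b) {
  na <- length(a); nb <- length(b)
  ma <- rowMeans(X[, a, drop = FALSE]); mb <- rowMeans(X[, b, drop = FALSE])
  va <- rowSums((X[, a, drop = FALSE] - ma)^2)
  vb <- rowSums((X[, b, drop = FALSE] - mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Pixelwise two-sample t-map
#'
#' Pooled-variance two-tailed two-sample t per pixel. Positive values mean
#' Group O exceeds Group M.
#'
#' @param maps_o,maps_m lists of freqs x time matrices (one per subject)
#' @return t matrix with the shared dimensions
#' @export
pixel_tmap <- function(maps_o, maps_m) {
  if (length(maps_o) < 2 || length(maps_m) < 2)
    stop("need at least 2 subject maps per group")
  st <- stack_maps(c(maps_o, maps_m))
  tv <- pooled_t(st$X, seq_along(maps_o),
                 length(maps_o) + seq_along(maps_m))
  matrix(tv, st$dims[1], st$dims[2])
}

#' Cluster-based permutation test
#'
#' Thresholds the observed t-map at the two-tailed voxel threshold for
#' `voxel_p`, labels 4-connected clusters, and compares each cluster's
#' t-sum against the permutation null: for each of `n_perm` random
#' reassignments of subjects into groups of the original sizes, the maximum
#' positive and minimum negative cluster sums are recorded (0 when no
#' cluster forms). Observed positive clusters survive at or above the 95th
#' percentile of the maxima; negative clusters at or below the 5th
#' percentile of the minima.
#'
#' @param maps_o,maps_m lists of subject maps (freqs x time matrices)
#' @param n_perm number of permutations (default 3000)
#' @param voxel_p voxel-level two-tailed p threshold
#' @param seed RNG seed for the permutation draws
#' @return object of class `fg_cluster_result`: tmap, voxel_threshold,
#'   clusters (data.frame id, sign, t_sum, n_pixels, survives), labels,
#'   surviving_mask, null_max, null_min, thr_hi, thr_lo, n_perm, seed
#' @export
cluster_permutation <- function(maps_o, maps_m, n_perm = 3000,
                                voxel_p = 0.05, seed = 1L) {
  no <- length(maps_o); nm <- length(maps_m)
  if (no < 2 || nm < 2) stop("need at least 2 subject maps per group")
  st <- stack_maps(c(maps_o, maps_m))
  X <- st$X
  nsub <- no + nm
  if (choose(nsub, no) < n_perm)
    warning("fewer than n_perm distinct group assignments; ",
            "permuting with replacement")
  tcrit <- stats::qt(1 - voxel_p / 2, df = nsub - 2)
  tmap <- matrix(pooled_t(X, 1:no, no + 1:nm), st$dims[1], st$dims[2])
  pos <- label_clusters_cpp(tmap, tcrit, 1L)
  neg <- label_clusters_cpp(tmap, tcrit, -1L)
  null_max <- numeric(n_perm); null_min <- numeric(n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      a <- sample.int(nsub, no)
      tp <- matrix(pooled_t(X, a, setdiff(seq_len(nsub), a)),
                   st$dims[1], st$dims[2])
      null_max[p] <- extreme_cluster_sum_cpp(tp, tcrit, 1L)
      null_min[p] <- extreme_cluster_sum_cpp(tp, tcrit, -1L)
    }
  })
  ## empirical (inverse-ECDF) percentiles: the permutation null is discrete
  thr_hi <- stats::quantile(null_max, 0.95, names = FALSE, type = 1)
  thr_lo <- stats::quantile(null_min, 0.05, names = FALSE, type = 1)
  cl <- rbind(
    if (length(pos$sums))
      data.frame(sign = "pos", t_sum = pos$sums,
                 n_pixels = tabulate(pos$labels[pos$labels > 0]),
                 survives = pos$sums >= thr_hi),
    if (length(neg$sums))
      data.frame(sign = "neg", t_sum = neg$sums,
                 n_pixels = tabulate(neg$labels[neg$labels > 0]),
                 survives = neg$sums <= thr_lo))
  if (is.null(cl))
    cl <- data.frame(sign = character(), t_sum = numeric(),
                     n_pixels = integer(), survives = logical())
  cl$id <- seq_len(nrow(cl))
  surv <- matrix(FALSE, st$dims[1], st$dims[2])
  if (nrow(cl)) {
    for (k in which(cl$survives[cl$sign == "pos"]))
      surv[pos$labels == k] <- TRUE
    for (k in which(cl$survives[cl$sign == "neg"]))
      surv[neg$labels == k] <- TRUE
  }
  structure(list(tmap = tmap, voxel_threshold = tcrit,
                 clusters = cl[, c("id", "sign", "t_sum", "n_pixels",
                                   "survives")],
                 labels_pos = pos$labels, labels_neg = neg$labels,
                 surviving_mask = surv, null_max = null_max,
                 null_min = null_min, thr_hi = thr_hi, thr_lo = thr_lo,
                 n_perm = n_perm, voxel_p = voxel_p, seed = seed),
            class = "fg_cluster_result")
}

#' @export
print.fg_cluster_result <- function(x, ...) {
  cat("<fg_cluster_result>", nrow(x$clusters), "cluster(s),",
      sum(x$clusters$survives), "surviving; voxel |t| >=",
      round(x$voxel_threshold, 3), "; cluster-sum thresholds [",
      round(x$thr_lo, 2), ",", round(x$thr_hi, 2), "] from", x$n_perm,
      "permutations\n")
  invisible(x)
}
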