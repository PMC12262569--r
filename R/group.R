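# Accept subject maps as: list of equal-shaped arrays, a matrix
# (subjects x voxels, needs `dims`), or a 4-D array (subject as 1st dim).
# Returns list(data = subjects x voxels matrix, dims = spatial dims).
as_subject_matrix <- function(maps, dims = NULL) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    if (is.null(dims)) dims <- length(maps[[1]])
    data <- t(vapply(maps, function(m) {
      if (!identical(dim(m), dim(maps[[1]]))) {
        stop("all subject maps must share the same shape", call. = FALSE)
      }
      as.numeric(m)
    }, numeric(prod(dims))))
  } else if (length(dim(maps)) == 4L) {
    dims <- dim(maps)[2:4]
    data <- matrix(maps, nrow = dim(maps)[1])
  } else if (is.matrix(maps)) {
    data <- maps
    if (is.null(dims)) dims <- ncol(maps)
  } else {
    stop("`maps` must be a list of arrays, a subjects x voxels matrix, or a 4-D array",
         call. = FALSE)
  }
  list(data = data, dims = as.integer(dims))
}

#' Precision-weighted fixed-effects combination across runs
#'
#' Inverse-variance weighted average of per-run contrast estimates, the
#' standard fixed-effects way to pool a subject's runs before group
#' analysis.  Equal variances reduce to the arithmetic mean; a single run is
#' returned unchanged.
#'
#' @param estimates Numeric vector/array per run (list), or runs x voxels
#'   matrix.
#' @param variances Matching per-run variances, all strictly positive.
#' @return A list with `estimate` (pooled estimate, same shape as one run's
#'   input) and `variance` (the pooled variance `1 / sum(1/v)`).
#' @export
fixed_effects_combine <- function(estimates, variances) {
  if (is.list(estimates)) {
    shape <- dim(estimates[[1]])
    E <- do.call(rbind, lapply(estimates, as.numeric))
    V <- do.call(rbind, lapply(variances, as.numeric))
  } else {
    shape <- NULL
    E <- rbind(estimates)
    V <- rbind(variances)
    if (is.matrix(estimates)) { E <- estimates; V <- variances }
  }
  if (!all(dim(E) == dim(V))) {
    stop("estimates and variances must have matching shapes", call. = FALSE)
  }
  if (any(V <= 0)) stop("variances must be strictly positive", call. = FALSE)
  w <- 1 / V
  est <- colSums(E * w) / colSums(w)
  var <- 1 / colSums(w)
  if (!is.null(shape)) { dim(est) <- shape; dim(var) <- shape }
  list(estimate = est, variance = var)
}

#' Voxelwise one-sample t map
#'
#' One-sample t of subject estimates against zero at every voxel.  Voxels
#' with zero variance but nonzero mean produce an unbounded t; these are set
#' to the largest representable value (with the mean's sign) and a warning.
#'
#' @param maps Subject maps (see [cluster_permutation_test()] for accepted
#'   shapes).
#' @param dims Spatial dims when `maps` is a plain matrix.
#' @return Array of t values with the maps' spatial shape.
#' @export
one_sample_tmap <- function(maps, dims = NULL) {
  sm <- as_subject_matrix(maps, dims)
  D <- sm$data
  n <- nrow(D)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  m <- colMeans(D)
  sd <- sqrt(pmax(colSums(D^2) - n * m^2, 0) / (n - 1))
  t <- m / (sd / sqrt(n))
  bad <- sd == 0 & m != 0
  if (any(bad)) {
    warning(sprintf("%d voxel(s) have zero variance; t set to +/- max double",
                    sum(bad)), call. = FALSE)
    t[bad] <- sign(m[bad]) * .Machine$double.xmax
  }
  t[sd == 0 & m == 0] <- 0
  if (length(sm$dims) > 1) dim(t) <- sm$dims
  t
}

#' Cohen's d from a one-sample t map
#'
#' `d = t / sqrt(n)` elementwise, the standardised effect size of a
#' one-sample test with `n` subjects.
#'
#' @param t_map Numeric array of t values.
#' @param n Number of subjects (>= 2).
#' @return Array of d values, same shape.
#' @export
cohens_d <- function(t_map, n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  t_map / sqrt(n)
}

# Connected components of a set of voxels under 6-connectivity (face
# adjacency). `idx` are linear indices into an array of shape `dims`.
# Returns an integer component label per element of idx.
connected_components_6 <- function(idx, dims) {
  nv <- length(idx)
  if (nv == 0) return(integer(0))
  dims <- as.integer(dims)
  if (length(dims) == 1L) dims <- c(dims, 1L, 1L)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  coord <- arrayInd(idx, dims)
  pos <- match(seq_len(prod(dims)), idx)  # reverse lookup, NA if not in set
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (ax in 1:3) {
    ok <- coord[, ax] < dims[ax]
    if (!any(ok)) next
    nb <- pos[idx[ok] + strides[ax]]
    here <- which(ok)[!is.na(nb)]
    there <- nb[!is.na(nb)]
    for (k in seq_along(here)) {
      ri <- find(here[k]); rj <- find(there[k])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  match(roots, unique(roots))
}

# max cluster size over positive and negative suprathreshold sets (pooled)
max_cluster_size <- function(t, thresh, dims) {
  mx <- 0L
  for (s in c(1, -1)) {
    idx <- which(s * t > thresh)
    if (length(idx) > 0) {
      lab <- connected_components_6(idx, dims)
      mx <- max(mx, max(tabulate(lab)))
    }
  }
  mx
}

#' Site-stratified sign-flip cluster-extent permutation test
#'
#' Group-level one-sample inference with family-wise error control that
#' respects multi-site structure: the null distribution is generated by
#' sign-flipping permutations in which all subjects of a scanner site flip
#' jointly (2^n_sites patterns; fully enumerated when that is at most
#' `max_perms`, otherwise uniformly sampled with the identity always
#' included).  For every permutation the t map is thresholded two-sided at
#' `t_thresh`, positive and negative suprathreshold voxels are labelled
#' separately with 6-connectivity (face adjacency), and the maximum cluster
#' size (pooled over signs) is recorded.  Observed clusters larger than the
#' `1 - alpha` quantile of that null distribution are significant.
#'
#' @param maps Subject contrast maps: a list of equal-shaped 3-D arrays, a
#'   subjects x voxels matrix (supply `dims`), or a 4-D array with subjects
#'   as the first dimension.
#' @param sites Site label per subject (any atomic vector; every site must
#'   have at least one subject and every subject a site).
#' @param t_thresh Cluster-forming threshold, applied two-sided (default
#'   3.1).
#' @param alpha FWER level (default 0.05).
#' @param max_perms Enumeration/sampling cap (default 10000).
#' @param dims Spatial dims when `maps` is a plain matrix.
#' @return A list of class `cluster_test` with fields `t_map`, `d_map`,
#'   `t_thresh`, `null_max_size` (one entry per permutation, identity
#'   included), `size_threshold` (the `1 - alpha` null quantile),
#'   `clusters` (data.frame: label, sign, size, peak t, peak coordinates,
#'   significant, p), `cluster_map` (integer array of significant cluster
#'   labels), `n_perms`, `enumerated`.
#' @export
cluster_permutation_test <- function(maps, sites, t_thresh = 3.1,
                                     alpha = 0.05, max_perms = 10000,
                                     dims = NULL) {
  sm <- as_subject_matrix(maps, dims)
  D <- sm$data
  n <- nrow(D)
  sites <- as.character(sites)
  if (length(sites) != n) {
    stop("need one site label per subject", call. = FALSE)
  }
  site_levels <- unique(sites)
  if (any(table(sites) == 0)) stop("a site has zero subjects", call. = FALSE)
  S <- length(site_levels)
  enumerated <- 2^S <= max_perms
  if (enumerated) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), S)))  # perms x sites
  } else {
    flips <- matrix(sample(c(1, -1), (max_perms - 1L) * S, replace = TRUE),
                    ncol = S)
    flips <- rbind(rep(1, S), flips)  # identity first
  }
  # subject-level sign matrix: perms x subjects
  Fsub <- flips[, match(sites, site_levels), drop = FALSE]
  # t statistics: means flip, sums of squares are flip-invariant
  ss <- colSums(D^2)
  M <- (Fsub %*% D) / n                      # perms x voxels, flipped means
  sd2 <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  Tm <- M / sqrt(pmax(sd2, 0) / n)
  Tm[!is.finite(Tm)] <- 0
  null_max <- vapply(seq_len(nrow(Tm)), function(p) {
    max_cluster_size(Tm[p, ], t_thresh, sm$dims)
  }, integer(1))
  # observed map = identity pattern (all +1)
  id <- which(rowSums(Fsub == 1) == n)[1]
  t_obs <- Tm[id, ]
  size_threshold <- sort(null_max)[ceiling((1 - alpha) * length(null_max))]
  # observed clusters, per sign
  cl_rows <- list()
  cluster_map <- integer(length(t_obs))
  lab_counter <- 0L
  for (s in c(1, -1)) {
    idx <- which(s * t_obs > t_thresh)
    if (length(idx) == 0) next
    lab <- connected_components_6(idx, sm$dims)
    for (k in seq_len(max(lab))) {
      vox <- idx[lab == k]
      size <- length(vox)
      lab_counter <- lab_counter + 1L
      peak <- vox[which.max(abs(t_obs[vox]))]
      pc <- arrayInd(peak, if (length(sm$dims) >= 3) sm$dims
                           else c(sm$dims, 1, 1))
      sig <- size > size_threshold
      cl_rows[[lab_counter]] <- data.frame(
        label = lab_counter, sign = if (s > 0) "pos" else "neg",
        size = size, peak_t = t_obs[peak],
        peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
        significant = sig,
        p = mean(null_max >= size), stringsAsFactors = FALSE)
      if (sig) cluster_map[vox] <- lab_counter
    }
  }
  clusters <- if (length(cl_rows) > 0) {
    do.call(rbind, cl_rows)
  } else {
    data.frame(label = integer(0), sign = character(0), size = integer(0),
               peak_t = numeric(0), peak_x = integer(0), peak_y = integer(0),
               peak_z = integer(0), significant = logical(0), p = numeric(0))
  }
  t_map <- t_obs
  d_map <- cohens_d(t_obs, n)
  if (length(sm$dims) > 1) {
    dim(t_map) <- sm$dims
    dim(d_map) <- sm$dims
    dim(cluster_map) <- sm$dims
  }
  structure(list(t_map = t_map, d_map = d_map, t_thresh = t_thresh,
                 alpha = alpha, null_max_size = null_max,
                 size_threshold = size_threshold, clusters = clusters,
                 cluster_map = cluster_map, n_perms = length(null_max),
                 enumerated = enumerated, n_subjects = n),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> %d subjects, |t| > %g, %d permutations (%s)\n",
    x$n_subjects, x$t_thresh, x$n_perms,
    if (x$enumerated) "enumerated" else "sampled"))
  cat(sprintf("  null 95th-pct max cluster size: %d; %d significant cluster(s)\n",
              x$size_threshold, sum(x$clusters$significant)))
  if (nrow(x$clusters) > 0) print(x$clusters, digits = 3)
  invisible(x)
}
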