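# Mask-constrained 3D radiomic feature extraction.
#
# Conventions used throughout this file:
#   * arrays are indexed (slice, row, col); angles live in the axial
#     (row, col) plane;
#   * discretized level grids store 0 outside the mask and 1..N inside;
#   * a feature that cannot be computed (degenerate matrix, zero
#     denominator) is returned as NA and later flagged `operable = FALSE`
#     by `extract_all()` -- it is never emitted as a bare NaN/Inf.

FIRST_ORDER_FEATURES <- c(
  "Energy", "Entropy", "Kurtosis", "Skewness", "Mean", "Median", "Minimum",
  "Maximum", "Range", "Variance", "Percentile10", "Percentile90",
  "InterquartileRange", "RootMeanSquared", "Uniformity")

GLCM_FEATURES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceEntropy", "DifferenceVariance",
  "JointEnergy", "JointEntropy", "Homogeneity", "InverseDifferenceMoment",
  "IMC1", "IMC2", "InverseVariance", "MaximumProbability", "SumAverage",
  "SumEntropy", "SumOfSquares", "Dissimilarity")

# Consensus run-length set trimmed to 15 names (LongRunHighGrayLevelEmphasis
# is the dropped 16th).
GLRLM_FEATURES <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis")

# Consensus size-zone set trimmed to 14 (SmallAreaHighGrayLevelEmphasis and
# LargeAreaLowGrayLevelEmphasis are the dropped cross terms).
GLSZM_FEATURES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

GLDM_FEATURES <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

NGTDM_FEATURES <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                    "Strength")

SHAPE_FEATURES <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Compactness1", "Compactness2", "SphericalDisproportion",
  "Maximum3DDiameter", "Maximum2DDiameterAxial", "Maximum2DDiameterCoronal",
  "Maximum2DDiameterSagittal", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "Elongation", "Flatness", "LargestSliceArea",
  "LargestSlicePerimeter", "PerimeterToAreaRatio")

FEATURE_FAMILIES <- c("first_order", "glcm", "glrlm", "glszm", "gldm",
                      "ngtdm", "shape")

#' Min-max normalize a volume to [0, 1]
#'
#' Scales all voxel intensities of an image affinely so that the minimum maps
#' to 0 and the maximum to 1; the intensity order is preserved. A constant
#' volume maps to all zeros by convention.
#'
#' @param volume An [image_volume()].
#' @return An [image_volume()] with intensities in `[0, 1]`.
#' @export
minmax_normalize <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  rng <- range(volume$data)
  d <- if (rng[2] > rng[1]) (volume$data - rng[1]) / (rng[2] - rng[1])
       else array(0, dim(volume$data))
  image_volume(d, volume$spacing, volume$case_id)
}

#' Discretize masked intensities to a fixed number of gray levels
#'
#' Maps intensities inside the mask onto `N = 2^bin_exponent` levels over the
#' masked min--max range: `level(v) = min(N, floor(N * (v - min) / (max -
#' min)) + 1)`. A constant region of interest maps to level 1 everywhere.
#' Voxels outside the mask carry level 0.
#'
#' @param volume An [image_volume()].
#' @param mask A [tumor_mask()] aligned with `volume`.
#' @param bin_exponent Integer in 1..8; number of gray levels is
#'   `2^bin_exponent`.
#' @return A list of class `discretized_volume` with elements `levels`
#'   (integer 3D array) and `n_levels`.
#' @export
discretize <- function(volume, mask, bin_exponent) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "tumor_mask"))
  check_aligned(volume, mask)
  bin_exponent <- as.integer(bin_exponent)
  if (bin_exponent < 1L || bin_exponent > 8L) {
    stop("bin_exponent must be in 1..8")
  }
  n <- 2L^bin_exponent
  v <- volume$data[mask$data]
  rng <- range(v)
  lev <- array(0L, dim(volume$data))
  if (rng[2] > rng[1]) {
    lv <- pmin(n, floor(n * (v - rng[1]) / (rng[2] - rng[1])) + 1L)
  } else {
    lv <- rep(1L, length(v))
  }
  lev[mask$data] <- as.integer(lv)
  structure(list(levels = lev, n_levels = n), class = "discretized_volume")
}

# B[i] = A[i + off] with `fill` where the source falls off the grid.
shift3 <- function(a, off, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, 1L - off[k]); hi <- min(d[k], d[k] - off[k])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) return(out)
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    a[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3]]
  out
}

# In-plane direction (slice, row, col) for an angle in degrees.
angle_offset <- function(angle) {
  switch(as.character(angle),
         "0"   = c(0L, 0L, 1L),
         "45"  = c(0L, -1L, 1L),
         "90"  = c(0L, -1L, 0L),
         "135" = c(0L, -1L, -1L),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Builds the symmetric, normalized co-occurrence matrix of level pairs at a
#' fixed voxel offset (`kernel_size` steps along `angle` within axial
#' slices). Both voxels of a pair must lie inside the mask.
#'
#' @param disc A `discretized_volume` from [discretize()].
#' @param kernel_size Offset distance in voxels (1..5).
#' @param angle One of 0, 45, 90, 135 degrees.
#' @return A normalized `n_levels x n_levels` matrix summing to 1, or `NULL`
#'   when the offset admits no valid voxel pair (inoperable).
#' @export
glcm_matrix <- function(disc, kernel_size, angle) {
  stopifnot(inherits(disc, "discretized_volume"))
  off <- angle_offset(angle) * as.integer(kernel_size)
  a <- disc$levels
  b <- shift3(a, off)
  keep <- a > 0L & b > 0L
  if (!any(keep)) return(NULL)
  n <- disc$n_levels
  idx <- (a[keep] - 1L) * n + b[keep]
  cnt <- tabulate(idx, nbins = n * n)
  m <- matrix(cnt, n, n, byrow = TRUE)
  m <- m + t(m)                       # symmetric: count both directions
  m / sum(m)
}

entropy2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

#' Co-occurrence matrix features
#'
#' Computes the 20 consensus co-occurrence statistics from a normalized
#' symmetric GLCM. `Correlation` and `IMC1` are flagged inoperable (NA) on
#' degenerate single-level matrices.
#'
#' @param glcm Normalized symmetric matrix from [glcm_matrix()], or `NULL`.
#' @return Named numeric vector of length 20 (NA marks inoperable values).
#' @export
glcm_features <- function(glcm) {
  out <- stats::setNames(rep(NA_real_, length(GLCM_FEATURES)), GLCM_FEATURES)
  if (is.null(glcm)) return(out)
  n <- nrow(glcm)
  px <- rowSums(glcm)                  # symmetric: px == py
  mu <- sum(seq_len(n) * px)
  sig2 <- sum((seq_len(n) - mu)^2 * px)
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  p <- glcm
  # difference |i-j| in 0..n-1 and sum i+j in 2..2n distributions
  pd <- vapply(0:(n - 1), function(k) sum(p[abs(ii - jj) == k]), 0)
  ps <- vapply(2:(2 * n), function(k) sum(p[ii + jj == k]), 0)
  da <- sum((0:(n - 1)) * pd)
  hx <- entropy2(px)
  hxy <- entropy2(p)
  pxy <- px[ii] * px[jj]
  sel <- p > 0 & pxy > 0
  hxy1 <- -sum(p[sel] * log2(pxy[sel]))
  hxy2 <- entropy2(pxy)
  out["Autocorrelation"] <- sum(ii * jj * p)
  out["ClusterProminence"] <- sum((ii + jj - 2 * mu)^4 * p)
  out["ClusterShade"] <- sum((ii + jj - 2 * mu)^3 * p)
  out["ClusterTendency"] <- sum((ii + jj - 2 * mu)^2 * p)
  out["Contrast"] <- sum((ii - jj)^2 * p)
  out["Correlation"] <- if (sig2 > 0) (sum(ii * jj * p) - mu^2) / sig2 else NA_real_
  out["DifferenceEntropy"] <- entropy2(pd)
  out["DifferenceVariance"] <- sum(((0:(n - 1)) - da)^2 * pd)
  out["JointEnergy"] <- sum(p^2)
  out["JointEntropy"] <- hxy
  out["Homogeneity"] <- sum(p / (1 + abs(ii - jj)))
  out["InverseDifferenceMoment"] <- sum(p / (1 + (ii - jj)^2))
  out["IMC1"] <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  out["IMC2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out["InverseVariance"] <- sum(p[ii != jj] / (ii - jj)[ii != jj]^2)
  out["MaximumProbability"] <- max(p)
  out["SumAverage"] <- sum((2:(2 * n)) * ps)
  out["SumEntropy"] <- entropy2(ps)
  out["SumOfSquares"] <- sig2
  out["Dissimilarity"] <- sum(abs(ii - jj) * p)
  out
}

# All mask-constrained lines of the level grid along an in-plane direction,
# each returned as a vector of levels (0 where outside the mask). Traversal
# order along each line is monotone in the direction parameter.
direction_lines <- function(levels, angle) {
  d <- dim(levels)
  lines <- list()
  for (s in seq_len(d[1])) {
    m <- levels[s, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, d[2], d[3])
    grp <- switch(as.character(angle),
                  "0"   = as.vector(row(m)),             # along +col
                  "90"  = as.vector(col(m)),             # along row
                  "45"  = as.vector(row(m) + col(m)),    # anti-diagonal
                  "135" = as.vector(col(m) - row(m)),    # diagonal
                  stop("angle must be one of 0, 45, 90, 135"))
    lines <- c(lines, split(as.vector(m), grp))
  }
  lines
}

#' Gray-level run-length matrix
#'
#' Runs of equal level along one in-plane direction; runs break at the mask
#' boundary. Returned as a `n_levels x max_run_length` count matrix.
#'
#' @param disc A `discretized_volume`.
#' @param angle One of 0, 45, 90, 135 degrees.
#' @return Integer count matrix `P[level, run_length]`.
#' @export
glrlm_matrix <- function(disc, angle) {
  lines <- direction_lines(disc$levels, angle)
  lev <- integer(0); len <- integer(0)
  for (v in lines) {
    r <- rle(v)
    keep <- r$values > 0L
    lev <- c(lev, r$values[keep])
    len <- c(len, r$lengths[keep])
  }
  if (!length(lev)) stop("mask has no foreground voxels")
  count_matrix(lev, len, disc$n_levels, max(len))
}

# P[i, s] = number of (level, size) observations; vectorized via tabulate.
count_matrix <- function(level, size, n_levels, max_size) {
  cnt <- tabulate((level - 1L) * max_size + size, nbins = n_levels * max_size)
  matrix(cnt, n_levels, max_size, byrow = TRUE)
}

# Shared emphasis-style statistics for matrices indexed (gray level, size):
# run-length, size-zone and dependence features all reduce to these.
level_size_stats <- function(P, n_voxels) {
  ns <- sum(P)
  pn <- P / ns
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  s <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  gl <- rowSums(P); sz <- colSums(P)
  mu_i <- sum(i * pn); mu_s <- sum(s * pn)
  list(
    small = sum(P / s^2) / ns,
    large = sum(P * s^2) / ns,
    gln = sum(gl^2) / ns,
    glnn = sum(gl^2) / ns^2,
    szn = sum(sz^2) / ns,
    sznn = sum(sz^2) / ns^2,
    pct = ns / n_voxels,
    glv = sum(pn * (i - mu_i)^2),
    szv = sum(pn * (s - mu_s)^2),
    ent = entropy2(pn),
    lgl = sum(P / i^2) / ns,
    hgl = sum(P * i^2) / ns,
    slgl = sum(P / (i^2 * s^2)) / ns,
    shgl = sum(P * i^2 / s^2) / ns,
    llgl = sum(P * s^2 / i^2) / ns,
    lhgl = sum(P * i^2 * s^2) / ns)
}

#' Run-length features
#'
#' The 15 run-length statistics along a single in-plane direction.
#'
#' @param disc A `discretized_volume`.
#' @param angle One of 0, 45, 90, 135 degrees.
#' @return Named numeric vector of length 15.
#' @export
glrlm_features <- function(disc, angle) {
  P <- glrlm_matrix(disc, angle)
  st <- level_size_stats(P, sum(disc$levels > 0L))
  c(ShortRunEmphasis = st$small, LongRunEmphasis = st$large,
    GrayLevelNonUniformity = st$gln, GrayLevelNonUniformityNormalized = st$glnn,
    RunLengthNonUniformity = st$szn, RunLengthNonUniformityNormalized = st$sznn,
    RunPercentage = st$pct, GrayLevelVariance = st$glv, RunVariance = st$szv,
    RunEntropy = st$ent, LowGrayLevelRunEmphasis = st$lgl,
    HighGrayLevelRunEmphasis = st$hgl, ShortRunLowGrayLevelEmphasis = st$slgl,
    ShortRunHighGrayLevelEmphasis = st$shgl,
    LongRunLowGrayLevelEmphasis = st$llgl)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal level inside the mask.
#'
#' @param disc A `discretized_volume`.
#' @return Integer count matrix `P[level, zone_size]`.
#' @export
glszm_matrix <- function(disc) {
  lev <- disc$levels
  d <- dim(lev)
  vox <- which(lev > 0L)
  if (!length(vox)) stop("mask has no foreground voxels")
  id <- array(0L, d)
  id[vox] <- seq_along(vox)
  offs <- as.matrix(expand.grid(ds = -1:1, dr = -1:1, dc = -1:1))
  offs <- offs[offs[, 1] != 0 | offs[, 2] != 0 | offs[, 3] != 0, ]
  # one of each opposite pair suffices for an undirected graph
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- shift3(lev, offs[k, ]); nbid <- shift3(id, offs[k, ])
    sel <- lev > 0L & nb == lev    # same level, both masked
    from <- c(from, id[sel]); to <- c(to, nbid[sel])
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  zl <- lev[vox][match(seq_len(comp$no), comp$membership)]
  zs <- comp$csize
  count_matrix(zl, zs, disc$n_levels, max(zs))
}

#' Size-zone features
#'
#' The 14 size-zone statistics over 26-connected equal-level zones.
#'
#' @param disc A `discretized_volume`.
#' @return Named numeric vector of length 14.
#' @export
glszm_features <- function(disc) {
  P <- glszm_matrix(disc)
  st <- level_size_stats(P, sum(disc$levels > 0L))
  c(SmallAreaEmphasis = st$small, LargeAreaEmphasis = st$large,
    GrayLevelNonUniformity = st$gln, GrayLevelNonUniformityNormalized = st$glnn,
    SizeZoneNonUniformity = st$szn, SizeZoneNonUniformityNormalized = st$sznn,
    ZonePercentage = st$pct, GrayLevelVariance = st$glv, ZoneVariance = st$szv,
    ZoneEntropy = st$ent, LowGrayLevelZoneEmphasis = st$lgl,
    HighGrayLevelZoneEmphasis = st$hgl,
    SmallAreaLowGrayLevelEmphasis = st$slgl,
    LargeAreaHighGrayLevelEmphasis = st$lhgl)
}

# Chebyshev-ball offsets of radius r, excluding the origin.
chebyshev_offsets <- function(r) {
  g <- as.matrix(expand.grid(ds = -r:r, dr = -r:r, dc = -r:r))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

# Per-voxel count of masked neighbors with identical level within Chebyshev
# distance `kernel_size`.
dependence_counts <- function(disc, kernel_size) {
  lev <- disc$levels
  dep <- array(0L, dim(lev))
  offs <- chebyshev_offsets(kernel_size)
  for (k in seq_len(nrow(offs))) {
    nb <- shift3(lev, offs[k, ])
    dep <- dep + (lev > 0L & nb == lev)
  }
  dep
}

#' Gray-level dependence matrix
#'
#' Dependence of a voxel is the number of masked neighbors within Chebyshev
#' distance `kernel_size` sharing its level. Column `j` of the returned
#' matrix corresponds to dependence `j - 1` (the center voxel itself counts
#' as the dependence group seed).
#'
#' @param disc A `discretized_volume`.
#' @param kernel_size Chebyshev neighborhood radius (1..5).
#' @return Integer count matrix `P[level, dependence + 1]`.
#' @export
gldm_matrix <- function(disc, kernel_size) {
  lev <- disc$levels
  dep <- dependence_counts(disc, kernel_size)
  sel <- lev > 0L
  count_matrix(lev[sel], dep[sel] + 1L, disc$n_levels, max(dep[sel]) + 1L)
}

#' Dependence features
#'
#' The 12 gray-level dependence statistics with neighborhood radius
#' `kernel_size`.
#'
#' @param disc A `discretized_volume`.
#' @param kernel_size Chebyshev neighborhood radius (1..5).
#' @return Named numeric vector of length 12.
#' @export
gldm_features <- function(disc, kernel_size) {
  P <- gldm_matrix(disc, kernel_size)
  st <- level_size_stats(P, sum(disc$levels > 0L))
  c(SmallDependenceEmphasis = st$small, LargeDependenceEmphasis = st$large,
    GrayLevelNonUniformity = st$gln, DependenceNonUniformity = st$szn,
    DependenceNonUniformityNormalized = st$sznn, GrayLevelVariance = st$glv,
    DependenceVariance = st$szv, DependenceEntropy = st$ent,
    LowGrayLevelEmphasis = st$lgl, HighGrayLevelEmphasis = st$hgl,
    SmallDependenceLowGrayLevelEmphasis = st$slgl,
    LargeDependenceHighGrayLevelEmphasis = st$lhgl)
}

# Neighborhood gray-tone difference table: for each level i present in the
# ROI, n_i voxels and s_i = sum over those voxels of |i - mean neighbor
# level|. Voxels with no masked neighbor are excluded.
ngtdm_table <- function(disc, kernel_size) {
  lev <- disc$levels
  nbsum <- array(0, dim(lev)); nbcnt <- array(0L, dim(lev))
  offs <- chebyshev_offsets(kernel_size)
  for (k in seq_len(nrow(offs))) {
    nb <- shift3(lev, offs[k, ])
    inm <- nb > 0L
    nbsum <- nbsum + nb * inm
    nbcnt <- nbcnt + inm
  }
  sel <- lev > 0L & nbcnt > 0L
  abar <- nbsum[sel] / nbcnt[sel]
  li <- lev[sel]
  n_i <- tabulate(li, nbins = disc$n_levels)
  s_i <- vapply(seq_len(disc$n_levels),
                function(i) sum(abs(i - abar)[li == i]), 0)
  list(n = n_i, s = s_i, total = sum(n_i))
}

#' Neighborhood gray-tone difference features
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength per the
#' neighborhood gray-tone difference formulation (neighborhood radius
#' `kernel_size`). Busyness is inoperable on single-level ROIs.
#'
#' @param disc A `discretized_volume`.
#' @param kernel_size Chebyshev neighborhood radius (1..5).
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(disc, kernel_size) {
  tb <- ngtdm_table(disc, kernel_size)
  out <- stats::setNames(rep(NA_real_, 5), NGTDM_FEATURES)
  nv <- tb$total
  if (nv == 0) return(out)
  p_i <- tb$n / nv
  pres <- which(p_i > 0)
  ngp <- length(pres)
  ps <- sum(p_i * tb$s)
  out["Coarseness"] <- if (ps > 0) 1 / ps else NA_real_
  if (ngp > 1) {
    pairs <- expand.grid(i = pres, j = pres)
    out["Contrast"] <- sum(p_i[pairs$i] * p_i[pairs$j] * (pairs$i - pairs$j)^2) /
      (ngp * (ngp - 1)) * sum(tb$s) / nv
    den <- sum(abs(outer(pres * p_i[pres], pres * p_i[pres], "-")))
    out["Busyness"] <- if (den > 0) ps / den else NA_real_
    out["Complexity"] <- sum(abs(pairs$i - pairs$j) *
      (p_i[pairs$i] * tb$s[pairs$i] + p_i[pairs$j] * tb$s[pairs$j]) /
      (p_i[pairs$i] + p_i[pairs$j])) / nv
    ssum <- sum(tb$s)
    out["Strength"] <- if (ssum > 0) {
      sum((p_i[pairs$i] + p_i[pairs$j]) * (pairs$i - pairs$j)^2) / ssum
    } else NA_real_
  } else {
    out["Contrast"] <- 0
    out["Complexity"] <- 0
    # Busyness and Strength have zero denominators on a single level
  }
  out
}

#' First-order intensity features
#'
#' The 15 first-order statistics of masked intensities. Entropy and
#' Uniformity are computed on the discretized histogram at `bin_exponent`;
#' everything else is computed on raw masked intensities with population
#' (n-denominator) moment conventions. Kurtosis is reported non-excess
#' (value 3 for a Gaussian). Percentiles use linear interpolation.
#'
#' @param volume An [image_volume()].
#' @param mask A [tumor_mask()] aligned with `volume`.
#' @param bin_exponent Integer in 1..8 for the histogram-based features.
#' @return Named numeric vector of length 15 (NA marks inoperable values,
#'   e.g. dispersion statistics on single-voxel ROIs).
#' @export
first_order_features <- function(volume, mask, bin_exponent) {
  check_aligned(volume, mask)
  v <- volume$data[mask$data]
  n <- length(v)
  disc <- discretize(volume, mask, bin_exponent)
  hist_p <- tabulate(disc$levels[mask$data], nbins = disc$n_levels) / n
  out <- stats::setNames(rep(NA_real_, 15), FIRST_ORDER_FEATURES)
  out["Energy"] <- sum(v^2)
  out["Entropy"] <- entropy2(hist_p)
  out["Uniformity"] <- sum(hist_p^2)
  out["Mean"] <- mean(v)
  out["Median"] <- stats::median(v)
  out["Minimum"] <- min(v)
  out["Maximum"] <- max(v)
  out["Range"] <- diff(range(v))
  q <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  out["Percentile10"] <- q[1]
  out["Percentile90"] <- q[4]
  out["InterquartileRange"] <- q[3] - q[2]
  out["RootMeanSquared"] <- sqrt(mean(v^2))
  if (n >= 2) {
    m2 <- mean((v - mean(v))^2)
    out["Variance"] <- m2
    if (m2 > 0) {
      out["Skewness"] <- mean((v - mean(v))^3) / m2^1.5
      out["Kurtosis"] <- mean((v - mean(v))^4) / m2^2
    }
  }
  out
}

# --- shape ------------------------------------------------------------------

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with zero padding.
smooth3d <- function(a, sigma) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  for (axis in 1:3) {
    out <- array(0, dim(a))
    for (t in -r:r) {
      off <- c(0L, 0L, 0L); off[axis] <- t
      out <- out + k[t + r + 1L] * shift3(a, off, fill = 0)
    }
    a <- out
  }
  a
}

# Surface area of the mask boundary. "face": plain voxel-face counting --
# exact for the voxelized solid but overestimating the underlying smooth
# surface of curved shapes by up to ~50%. "smoothed": co-area estimate
# A = sum |grad(G_sigma * chi)| dV with sigma = 0.6 voxels, which tracks
# the underlying smooth surface to ~1% on digitized balls (calibration in
# the methods vignette).
surface_area <- function(m, spacing, method = c("face", "smoothed")) {
  method <- match.arg(method)
  d <- dim(m)
  if (method == "face") {
    area <- 0
    for (axis in 1:3) {
      face_a <- prod(spacing[-axis])
      for (s in c(-1L, 1L)) {
        off <- c(0L, 0L, 0L); off[axis] <- s
        area <- area + sum(m & !shift3(m, off, fill = FALSE)) * face_a
      }
    }
    return(area)
  }
  g <- smooth3d(array(as.numeric(m), d), 0.6)
  grad2 <- 0
  for (axis in 1:3) {
    off <- c(0L, 0L, 0L); off[axis] <- 1L
    grad2 <- grad2 +
      ((shift3(g, off, fill = 0) - shift3(g, -off, fill = 0)) /
         (2 * spacing[axis]))^2
  }
  sum(sqrt(grad2)) * prod(spacing)
}

max_pairwise_dist <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(0)
  best <- 0
  step <- 256L
  for (a in seq(1L, n, by = step)) {
    idx <- a:min(n, a + step - 1L)
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    best <- max(best, max(d2))
  }
  sqrt(max(0, best))
}

#' Shape features of a tumor mask
#'
#' The 20 morphological features of the binary mask in physical units
#' (spacing in mm). Volumes are voxel volumes; `MeshVolume` is the volume
#' enclosed by the voxel boundary surface and therefore equals
#' `VoxelVolume`. Surface area uses voxel-face counting by default; the
#' `"smoothed"` co-area estimator corrects the staircase bias and is the
#' one to use when absolute areas of smooth shapes matter. Axis lengths
#' come from principal component analysis of voxel-center coordinates
#' (`4 * sqrt(eigenvalue)`), planar masks have `LeastAxisLength`/`Flatness`
#' flagged inoperable.
#'
#' @param mask A [tumor_mask()].
#' @param spacing Numeric length-3 voxel spacing in mm (slice, row, col).
#' @param surface Surface-area estimator, `"face"` (default) or
#'   `"smoothed"`.
#' @return Named numeric vector of length 20 (NA marks inoperable values).
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1),
                           surface = c("face", "smoothed")) {
  stopifnot(inherits(mask, "tumor_mask"))
  surface <- match.arg(surface)
  m <- mask$data
  sp <- as.numeric(spacing)
  out <- stats::setNames(rep(NA_real_, 20), SHAPE_FEATURES)
  nvox <- sum(m)
  vol <- nvox * prod(sp)
  area <- surface_area(m, sp, surface)
  out["VoxelVolume"] <- vol
  out["MeshVolume"] <- vol
  out["SurfaceArea"] <- area
  out["SurfaceVolumeRatio"] <- area / vol
  out["Sphericity"] <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  out["Compactness1"] <- vol / (sqrt(pi) * area^1.5)
  out["Compactness2"] <- 36 * pi * vol^2 / area^3
  out["SphericalDisproportion"] <- 1 / out["Sphericity"]

  idx <- which(m, arr.ind = TRUE)
  xyz <- sweep(idx, 2, sp, "*")
  # boundary voxels (6-neighborhood) are enough for diameters
  onb <- m
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    off <- c(0L, 0L, 0L); off[axis] <- s
    onb <- onb & shift3(m, off, fill = FALSE)
  }
  bidx <- which(m & !onb, arr.ind = TRUE)
  bxyz <- sweep(bidx, 2, sp, "*")
  out["Maximum3DDiameter"] <- max_pairwise_dist(bxyz)
  plane_max <- function(plane_axis, keep_axes) {
    mx <- 0
    for (s in unique(bidx[, plane_axis])) {
      pts <- bxyz[bidx[, plane_axis] == s, keep_axes, drop = FALSE]
      mx <- max(mx, max_pairwise_dist(pts))
    }
    mx
  }
  out["Maximum2DDiameterAxial"] <- plane_max(1, 2:3)
  out["Maximum2DDiameterCoronal"] <- plane_max(2, c(1, 3))
  out["Maximum2DDiameterSagittal"] <- plane_max(3, c(1, 2))

  if (nvox >= 2) {
    cv <- stats::cov(xyz) * (nvox - 1) / nvox   # population covariance
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    if (ev[1] > 0) {
      out["MajorAxisLength"] <- 4 * sqrt(ev[1])
      out["MinorAxisLength"] <- 4 * sqrt(ev[2])
      out["Elongation"] <- sqrt(ev[2] / ev[1])
      if (ev[3] > 0) {
        out["LeastAxisLength"] <- 4 * sqrt(ev[3])
        out["Flatness"] <- sqrt(ev[3] / ev[1])
      }
    }
  }

  slice_counts <- apply(m, 1, sum)
  s_big <- which.max(slice_counts)
  px_area <- sp[2] * sp[3]
  out["LargestSliceArea"] <- slice_counts[s_big] * px_area
  sl <- matrix(m[s_big, , ], dim(m)[2], dim(m)[3])
  per <- 0
  shifts2 <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (off in shifts2) {
    nb <- matrix(FALSE, nrow(sl), ncol(sl))
    r1 <- max(1, 1 - off[1]):min(nrow(sl), nrow(sl) - off[1])
    c1 <- max(1, 1 - off[2]):min(ncol(sl), ncol(sl) - off[2])
    nb[r1, c1] <- sl[r1 + off[1], c1 + off[2]]
    edge_len <- if (off[1] != 0) sp[3] else sp[2]
    per <- per + sum(sl & !nb) * edge_len
  }
  out["LargestSlicePerimeter"] <- per
  out["PerimeterToAreaRatio"] <- per / out["LargestSliceArea"]
  out
}

# --- the sweep --------------------------------------------------------------

#' Default radiomic parameter grid
#'
#' The full sweep: bin exponents 1..8 (2..256 gray levels), kernel sizes
#' 1..5, the four in-plane angles, all seven feature families.
#'
#' @param bin_exponents,kernels,angles,families Optional restrictions.
#' @return A list understood by [extract_all()].
#' @export
radiomic_grid <- function(bin_exponents = 1:8, kernels = 1:5,
                          angles = c(0, 45, 90, 135),
                          families = FEATURE_FAMILIES) {
  stopifnot(all(bin_exponents %in% 1:8), all(kernels %in% 1:5),
            all(angles %in% c(0, 45, 90, 135)),
            all(families %in% FEATURE_FAMILIES))
  list(bin_exponents = as.integer(bin_exponents),
       kernels = as.integer(kernels), angles = as.integer(angles),
       families = families)
}

# Closed-form record census of a sweep: how many rows extract_all() emits.
census_count <- function(grid) {
  nb <- length(grid$bin_exponents); nk <- length(grid$kernels)
  na_ <- length(grid$angles)
  per <- c(shape = 20L, first_order = 15L * nb, glcm = 20L * nb * nk * na_,
           glrlm = 15L * nb * na_, glszm = 14L * nb, gldm = 12L * nb * nk,
           ngtdm = 5L * nb * nk)
  sum(per[grid$families])
}

feature_row <- function(case_id, family, values, bin = NA_integer_,
                        kernel = NA_integer_, angle = NA_integer_) {
  data.frame(case_id = case_id, family = family, feature = names(values),
             bin_exponent = bin, kernel = kernel, angle = angle,
             value = ifelse(is.finite(values), unname(values), NA_real_),
             operable = is.finite(values), stringsAsFactors = FALSE)
}

#' Extract every radiomic feature over a parameter grid
#'
#' Runs the whole sweep on one case: shape once; first-order per bin
#' exponent; GLCM per (bin, kernel, angle); GLRLM per (bin, angle); GLSZM
#' per bin; GLDM and NGTDM per (bin, kernel). The volume is min-max
#' normalized before extraction. Non-finite values are flagged
#' `operable = FALSE` with `value = NA`.
#'
#' @param volume An [image_volume()].
#' @param mask A [tumor_mask()] aligned with `volume`.
#' @param grid A grid from [radiomic_grid()].
#' @return A long-format `data.frame` with columns `case_id`, `family`,
#'   `feature`, `bin_exponent`, `kernel`, `angle`, `value`, `operable`,
#'   in deterministic order.
#' @export
extract_all <- function(volume, mask, grid = radiomic_grid()) {
  check_aligned(volume, mask)
  volume <- minmax_normalize(volume)
  cid <- volume$case_id
  rows <- list()
  if ("shape" %in% grid$families) {
    rows[[length(rows) + 1L]] <-
      feature_row(cid, "shape", shape_features(mask, volume$spacing))
  }
  for (b in grid$bin_exponents) {
    disc <- discretize(volume, mask, b)
    if ("first_order" %in% grid$families) {
      rows[[length(rows) + 1L]] <-
        feature_row(cid, "first_order", first_order_features(volume, mask, b),
                    bin = b)
    }
    if ("glcm" %in% grid$families) {
      for (k in grid$kernels) for (a in grid$angles) {
        rows[[length(rows) + 1L]] <-
          feature_row(cid, "glcm", glcm_features(glcm_matrix(disc, k, a)),
                      bin = b, kernel = k, angle = a)
      }
    }
    if ("glrlm" %in% grid$families) {
      for (a in grid$angles) {
        rows[[length(rows) + 1L]] <-
          feature_row(cid, "glrlm", glrlm_features(disc, a), bin = b, angle = a)
      }
    }
    if ("glszm" %in% grid$families) {
      rows[[length(rows) + 1L]] <-
        feature_row(cid, "glszm", glszm_features(disc), bin = b)
    }
    if ("gldm" %in% grid$families) {
      for (k in grid$kernels) {
        rows[[length(rows) + 1L]] <-
          feature_row(cid, "gldm", gldm_features(disc, k), bin = b, kernel = k)
      }
    }
    if ("ngtdm" %in% grid$families) {
      for (k in grid$kernels) {
        rows[[length(rows) + 1L]] <-
          feature_row(cid, "ngtdm", ngtdm_features(disc, k), bin = b, kernel = k)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stable feature identifier
#'
#' Encodes family, feature name and parameter combination into one string,
#' e.g. `"glcm|Contrast|b3|k1|a0"`; shape features carry no parameters.
#'
#' @param table A long feature table from [extract_all()].
#' @return Character vector of ids, one per row.
#' @export
feature_id <- function(table) {
  paste0(table$family, "|", table$feature,
         ifelse(is.na(table$bin_exponent), "", paste0("|b", table$bin_exponent)),
         ifelse(is.na(table$kernel), "", paste0("|k", table$kernel)),
         ifelse(is.na(table$angle), "", paste0("|a", table$angle)))
}

#' Pivot a long feature table to a cases-by-features matrix
#'
#' @param table A long feature table (one or more cases).
#' @return Numeric matrix with case ids as rows and [feature_id()]s as
#'   columns; inoperable values are NA.
#' @export
features_wide <- function(table) {
  fid <- feature_id(table)
  cases <- unique(table$case_id)
  feats <- unique(fid)
  m <- matrix(NA_real_, length(cases), length(feats),
              dimnames = list(cases, feats))
  m[cbind(match(table$case_id, cases), match(fid, feats))] <- table$value
  m
}
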