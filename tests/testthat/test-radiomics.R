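# Radiomic engine: hand-computed oracles on tiny grids, degenerate
# conventions, and the invariances the features must respect.

test_that("min-max normalization maps to [0,1], is idempotent, and zeroes constants", {
  fx <- fixture_volume(c(2, 4, 6, 4), c(1, 2, 2))
  nv <- minmax_normalize(fx$volume)
  expect_equal(sort(unique(as.vector(nv$data))), c(0, 0.5, 1))
  expect_equal(minmax_normalize(nv)$data, nv$data)
  cv <- minmax_normalize(image_volume(array(5, c(1, 2, 2))))
  expect_true(all(cv$data == 0))
})

test_that("discretization follows the fixed-bin-count formula", {
  fx <- fixture_volume(c(0, 0.5, 1, 0.25), c(1, 2, 2))
  d1 <- discretize(fx$volume, fx$mask, 1)
  # min(N, floor(N*(v-min)/(max-min)) + 1) with N = 2: {0,.5,1,.25} -> {1,2,2,1}
  expect_equal(as.vector(d1$levels), c(1L, 2L, 2L, 1L))
  # distinct level count never exceeds 2^x
  set.seed(1)
  fx2 <- fixture_volume(runif(60), c(3, 4, 5))
  for (x in c(1, 3, 5)) {
    dx <- discretize(fx2$volume, fx2$mask, x)
    expect_lte(length(unique(dx$levels[fx2$mask$data])), 2^x)
  }
  # min-max invariance: affine rescale gives the identical level grid
  fx3 <- fixture_volume(fx2$volume$data * 7 - 3, c(3, 4, 5))
  expect_identical(discretize(fx3$volume, fx3$mask, 4)$levels,
                   discretize(fx2$volume, fx2$mask, 4)$levels)
  # constant ROI: all level 1
  cv <- fixture_volume(rep(2, 8), c(2, 2, 2))
  expect_true(all(discretize(cv$volume, cv$mask, 3)$levels == 1L))
})

test_that("first-order features match direct arithmetic and degenerate conventions", {
  fx <- fixture_volume(c(1, 2, 3, 4), c(1, 1, 4))
  fo <- first_order_features(fx$volume, fx$mask, 2)
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Range"]], 3)
  expect_equal(fo[["Variance"]], 1.25)   # population convention
  expect_equal(fo[["Median"]], 2.5)
  expect_equal(fo[["RootMeanSquared"]], sqrt(mean(c(1, 4, 9, 16))))
  expect_equal(fo[["Energy"]], 30)
  # constant ROI
  cv <- fixture_volume(rep(3, 8), c(2, 2, 2))
  fc <- first_order_features(cv$volume, cv$mask, 3)
  expect_equal(fc[["Entropy"]], 0)
  expect_equal(fc[["Uniformity"]], 1)
  expect_equal(fc[["Variance"]], 0)
  # uniform histogram over 2^x levels has entropy x bits
  x <- 3
  vals <- rep(seq_len(2^x), each = 2) - 0.5
  fu <- fixture_volume(vals, c(1, 4, 4))
  expect_equal(first_order_features(fu$volume, fu$mask, x)[["Entropy"]], x)
  # single voxel: dispersion statistics inoperable
  one <- fixture_volume(rep(1, 8), c(2, 2, 2), mask = c(TRUE, rep(FALSE, 7)))
  f1 <- first_order_features(one$volume, one$mask, 2)
  expect_true(is.na(f1[["Variance"]]))
  expect_equal(f1[["Mean"]], 1)
})

test_that("GLCM matches brute-force pair enumeration and hand values", {
  fx <- fixture_two_level_slice()
  disc <- discretize(fx$volume, fx$mask, 1)
  g <- glcm_matrix(disc, 1, 0)
  expect_equal(g, matrix(c(1/3, 1/6, 1/6, 1/3), 2, 2))
  f <- glcm_features(g)
  expect_equal(f[["Contrast"]], 1/3)
  # random small grids against the oracle, all angles and distances
  set.seed(42)
  for (rep in 1:5) {
    vals <- sample(1:4, 5 * 5 * 2, replace = TRUE)
    msk <- runif(50) > 0.2
    msk[1] <- TRUE
    fxr <- fixture_volume(vals, c(2, 5, 5), mask = msk)
    dr <- discretize(fxr$volume, fxr$mask, 2)
    for (a in c(0, 45, 90, 135)) for (k in 1:2) {
      got <- glcm_matrix(dr, k, a)
      ora <- oracle_glcm(dr$levels, k, a)
      if (is.null(got)) expect_true(all(is.nan(ora))) else expect_equal(got, ora)
    }
  }
})

test_that("GLCM features are symmetric in the matrix and angles are half-turn redundant", {
  set.seed(7)
  fx <- fixture_volume(runif(50), c(2, 5, 5))
  disc <- discretize(fx$volume, fx$mask, 3)
  for (a in c(0, 45, 90, 135)) {
    g <- glcm_matrix(disc, 1, a)
    expect_equal(g, t(g))
    expect_equal(sum(g), 1)
    expect_equal(glcm_features(g), glcm_features(t(g)))
  }
  # constant ROI: p(1,1) = 1, Contrast 0, MaximumProbability 1
  cv <- fixture_volume(rep(1, 27), c(3, 3, 3))
  dc <- discretize(cv$volume, cv$mask, 2)
  gc <- glcm_matrix(dc, 1, 0)
  expect_equal(gc[1, 1], 1)
  fc <- glcm_features(gc)
  expect_equal(fc[["Contrast"]], 0)
  expect_equal(fc[["MaximumProbability"]], 1)
  expect_true(is.na(fc[["Correlation"]]))
})

test_that("GLRLM runs match brute-force run enumeration", {
  fx <- fixture_volume(c(1, 1, 1, 2, 2), c(1, 1, 5))
  disc <- discretize(fx$volume, fx$mask, 1)
  p <- glrlm_matrix(disc, 0)
  expect_equal(p[1, 3], 1)   # run (level 1, length 3)
  expect_equal(p[2, 2], 1)   # run (level 2, length 2)
  expect_equal(sum(p), 2)
  f <- glrlm_features(disc, 0)
  expect_equal(f[["RunPercentage"]], 2 / 5)
  # constant 1x1xn ROI: single run, LongRunEmphasis = n^2
  n <- 7
  cn <- fixture_volume(rep(1, n), c(1, 1, n))
  dn <- discretize(cn$volume, cn$mask, 1)
  expect_equal(glrlm_features(dn, 0)[["LongRunEmphasis"]], n^2)
  # checkerboard: all runs length 1
  rr <- matrix(seq_len(4), 4, 4); vals <- (rr + t(rr)) %% 2 + 1
  cb <- fixture_volume(as.vector(vals), c(1, 4, 4))
  db <- discretize(cb$volume, cb$mask, 1)
  expect_equal(glrlm_features(db, 0)[["RunPercentage"]], 1)
  # runs truncate at the mask boundary
  gap <- fixture_volume(rep(1, 5), c(1, 1, 5), mask = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  dg <- discretize(gap$volume, gap$mask, 1)
  pg <- glrlm_matrix(dg, 0)
  expect_equal(pg[1, 2], 2)  # two runs of length 2
})

test_that("GLSZM zones are 26-connected equal-level components", {
  # two disjoint constant blobs (sizes 3 and 5) of the same level
  arr <- array(0, c(2, 3, 7))
  msk <- array(FALSE, c(2, 3, 7))
  msk[1, 1, 1:3] <- TRUE          # blob of 3
  msk[2, 3, 3:7] <- TRUE          # blob of 5, not 26-adjacent to the first
  arr[msk] <- 1
  fx <- fixture_volume(arr, c(2, 3, 7), mask = msk)
  disc <- discretize(fx$volume, fx$mask, 1)
  p <- glszm_matrix(disc)
  expect_equal(p[1, 3], 1)
  expect_equal(p[1, 5], 1)
  expect_equal(glszm_features(disc)[["ZonePercentage"]], 2 / 8)
  # constant ROI: one zone, zero entropy
  cv <- fixture_volume(rep(1, 27), c(3, 3, 3))
  dc <- discretize(cv$volume, cv$mask, 2)
  expect_equal(glszm_features(dc)[["ZoneEntropy"]], 0)
  # level permutation leaves size-only features unchanged
  set.seed(3)
  fx2 <- fixture_volume(sample(1:3, 45, replace = TRUE), c(3, 3, 5))
  d2 <- discretize(fx2$volume, fx2$mask, 2)
  perm <- array(5L - d2$levels, dim(d2$levels))  # reverse level order (1..4)
  perm[d2$levels == 0L] <- 0L
  d2p <- structure(list(levels = perm, n_levels = d2$n_levels),
                   class = "discretized_volume")
  f2 <- glszm_features(d2); f2p <- glszm_features(d2p)
  for (nm in c("SmallAreaEmphasis", "LargeAreaEmphasis", "ZonePercentage")) {
    expect_equal(f2[[nm]], f2p[[nm]])
  }
})

test_that("GLDM dependence counts match neighbor-counting oracle", {
  cv <- fixture_volume(rep(1, 9), c(1, 3, 3))
  dc <- discretize(cv$volume, cv$mask, 1)
  dep <- rgstage:::dependence_counts(dc, 1)
  expect_equal(dep[1, 2, 2], 8)   # center voxel of a constant 3x3x1 ROI
  set.seed(11)
  fx <- fixture_volume(sample(1:3, 50, replace = TRUE), c(2, 5, 5))
  d <- discretize(fx$volume, fx$mask, 2)
  for (k in 1:2) {
    got <- rgstage:::dependence_counts(d, k)
    ora <- oracle_dependence(d$levels, k)
    expect_equal(got[d$levels > 0], ora[d$levels > 0])
  }
  # four-level block pattern: every Chebyshev-1 neighbor differs, so all
  # dependences are 0 and SmallDependenceEmphasis is at its maximum 1
  rr <- matrix(seq_len(6), 6, 6); cc <- t(rr)
  vals <- 2 * (rr %% 2) + (cc %% 2) + 1
  cb <- fixture_volume(as.vector(vals), c(1, 6, 6))
  db <- discretize(cb$volume, cb$mask, 2)
  expect_true(all(rgstage:::dependence_counts(db, 1)[db$levels > 0] == 0))
  f <- gldm_features(db, 1)
  expect_equal(f[["SmallDependenceEmphasis"]], 1)
  # kernel monotonicity: mean dependence non-decreasing in kernel size
  md <- vapply(1:3, function(k) {
    mean(rgstage:::dependence_counts(d, k)[d$levels > 0])
  }, 0)
  expect_true(all(diff(md) >= 0))
})

test_that("NGTDM table matches brute-force neighborhood enumeration", {
  set.seed(5)
  fx <- fixture_volume(sample(1:2, 50, replace = TRUE), c(2, 5, 5))
  d <- discretize(fx$volume, fx$mask, 1)
  tb <- rgstage:::ngtdm_table(d, 1)
  ora <- oracle_ngtdm(d$levels, 1)
  expect_equal(tb$n, ora$n)
  expect_equal(tb$s, ora$s)
  # coarseness = 1 / sum(p_i s_i) against the oracle
  f <- ngtdm_features(d, 1)
  expect_equal(f[["Coarseness"]], 1 / sum(ora$n / sum(ora$n) * ora$s))
  # constant ROI: zero gray-tone differences, Busyness inoperable
  cv <- fixture_volume(rep(1, 27), c(3, 3, 3))
  dc <- discretize(cv$volume, cv$mask, 1)
  fc <- ngtdm_features(dc, 1)
  expect_equal(fc[["Contrast"]], 0)
  expect_true(is.na(fc[["Busyness"]]))
})

test_that("discretized-texture features are invariant to increasing affine intensity maps", {
  set.seed(9)
  fx <- fixture_volume(runif(60), c(3, 4, 5))
  fx2 <- fixture_volume(fx$volume$data * 11 + 5, c(3, 4, 5))
  d1 <- discretize(fx$volume, fx$mask, 3)
  d2 <- discretize(fx2$volume, fx2$mask, 3)
  expect_equal(glcm_features(glcm_matrix(d1, 1, 45)),
               glcm_features(glcm_matrix(d2, 1, 45)))
  expect_equal(glrlm_features(d1, 90), glrlm_features(d2, 90))
  expect_equal(glszm_features(d1), glszm_features(d2))
  expect_equal(gldm_features(d1, 1), gldm_features(d2, 1))
  expect_equal(ngtdm_features(d1, 1), ngtdm_features(d2, 1))
})

test_that("shape features: cube closed form, ball sphericity, scaling laws", {
  m <- array(FALSE, c(20, 20, 20)); m[5:16, 5:16, 5:16] <- TRUE
  cube <- tumor_mask(m)
  sf <- shape_features(cube)
  expect_equal(sf[["Sphericity"]], (pi / 6)^(1 / 3), tolerance = 1e-6)
  expect_equal(sf[["VoxelVolume"]], 12^3)
  expect_equal(sf[["SurfaceArea"]], 6 * 12^2)
  expect_equal(sf[["MeshVolume"]], sf[["VoxelVolume"]])
  expect_equal(sf[["SphericalDisproportion"]], 1 / sf[["Sphericity"]])
  # digitized ball: smoothed-surface sphericity close to (and not above) 1
  ball <- fixture_ball_mask(10)
  sb <- shape_features(ball, surface = "smoothed")
  expect_gte(sb[["Sphericity"]], 0.9)
  expect_lte(sb[["Sphericity"]], 1.0)
  expect_equal(sb[["Maximum3DDiameter"]], 20, tolerance = 0.05)
  # isotropic spacing doubled: volume x8, area x4
  s2 <- shape_features(cube, spacing = c(2, 2, 2))
  expect_equal(s2[["VoxelVolume"]] / sf[["VoxelVolume"]], 8)
  expect_equal(s2[["SurfaceArea"]] / sf[["SurfaceArea"]], 4)
  # planar mask: least-axis features inoperable
  pm <- array(FALSE, c(5, 8, 8)); pm[3, 2:7, 2:7] <- TRUE
  sp <- shape_features(tumor_mask(pm))
  expect_true(is.na(sp[["Flatness"]]))
  expect_true(is.na(sp[["LeastAxisLength"]]))
  expect_false(is.na(sp[["MajorAxisLength"]]))
})

test_that("extract_all emits the frozen census and is deterministic", {
  set.seed(21)
  fx <- fixture_volume(runif(16 * 8 * 8), c(8, 8, 16))
  # single parameter triple: the printed per-family counts, 101 records
  g1 <- radiomic_grid(bin_exponents = 3, kernels = 2, angles = 45)
  t1 <- extract_all(fx$volume, fx$mask, g1)
  counts <- table(t1$family)
  expect_equal(as.integer(counts[c("first_order", "glcm", "glrlm", "glszm",
                                   "gldm", "ngtdm", "shape")]),
               c(15L, 20L, 15L, 14L, 12L, 5L, 20L))
  expect_equal(nrow(t1), 101L)
  # full-grid census: 20 + 15*8 + 20*8*5*4 + 15*8*4 + 14*8 + 12*8*5 + 5*8*5
  expect_equal(rgstage:::census_count(radiomic_grid()), 4612L)
  # restricted two-triple grid matches its closed-form census
  g2 <- radiomic_grid(bin_exponents = c(2, 3), kernels = 1:2, angles = c(0, 90))
  t2 <- extract_all(fx$volume, fx$mask, g2)
  expect_equal(nrow(t2), rgstage:::census_count(g2))
  # permuting the grid order yields the identical table modulo ordering
  g3 <- radiomic_grid(bin_exponents = c(3, 2), kernels = 2:1, angles = c(90, 0))
  t3 <- extract_all(fx$volume, fx$mask, g3)
  key <- function(t) t[order(feature_id(t)), c("value", "operable")]
  expect_equal(key(t2), key(t3), ignore_attr = TRUE)
  # feature ids are unique
  expect_false(anyDuplicated(feature_id(t2)) > 0)
})
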