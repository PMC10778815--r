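# Small deterministic fixtures shared across test files.

# A volume/mask pair from explicit voxel values; values given slice by slice.
fixture_volume <- function(values, dim3, mask = NULL, spacing = c(1, 1, 1)) {
  arr <- array(values, dim3)
  v <- image_volume(arr, spacing = spacing, case_id = "FIX")
  m <- tumor_mask(if (is.null(mask)) array(TRUE, dim3) else array(mask, dim3),
                  case_id = "FIX")
  list(volume = v, mask = m)
}

# 4x4 axial slice whose rows are all (1,1,2,2); two gray levels.
fixture_two_level_slice <- function() {
  arr <- array(0, c(1, 4, 4))
  for (r in 1:4) arr[1, r, ] <- c(1, 1, 2, 2)
  fixture_volume(arr, c(1, 4, 4))
}

# Digitized ball of given radius (voxel units, isotropic spacing).
fixture_ball_mask <- function(radius, pad = 3) {
  d <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  g <- expand.grid(seq_len(d), seq_len(d), seq_len(d))
  tumor_mask(array((g[, 1] - ctr)^2 + (g[, 2] - ctr)^2 + (g[, 3] - ctr)^2 <=
                     radius^2, c(d, d, d)))
}

# Brute-force GLCM oracle: enumerate every masked voxel pair at the given
# in-plane offset, count both directions, normalize.
oracle_glcm <- function(levels, kernel, angle) {
  d <- dim(levels)
  off <- switch(as.character(angle),
                "0" = c(0, 0, 1), "45" = c(0, -1, 1),
                "90" = c(0, -1, 0), "135" = c(0, -1, -1)) * kernel
  n <- max(levels)
  cnt <- matrix(0, n, n)
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (levels[s, r, c] == 0) next
    p <- c(s, r, c) + off
    if (any(p < 1) || any(p > d)) next
    if (levels[p[1], p[2], p[3]] == 0) next
    a <- levels[s, r, c]; b <- levels[p[1], p[2], p[3]]
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  cnt / sum(cnt)
}

# Brute-force dependence oracle: per masked voxel, count equal-level masked
# neighbors within Chebyshev radius k.
oracle_dependence <- function(levels, k) {
  d <- dim(levels)
  dep <- array(NA_integer_, d)
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (levels[s, r, c] == 0) next
    cnt <- 0
    for (ds in -k:k) for (dr in -k:k) for (dc in -k:k) {
      if (ds == 0 && dr == 0 && dc == 0) next
      p <- c(s + ds, r + dr, c + dc)
      if (any(p < 1) || any(p > d)) next
      if (levels[p[1], p[2], p[3]] == levels[s, r, c]) cnt <- cnt + 1
    }
    dep[s, r, c] <- cnt
  }
  dep
}

# Brute-force NGTDM oracle: n_i and s_i by direct neighborhood enumeration.
oracle_ngtdm <- function(levels, k) {
  d <- dim(levels)
  nmax <- max(levels)
  n_i <- numeric(nmax); s_i <- numeric(nmax)
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    i <- levels[s, r, c]
    if (i == 0) next
    nb <- c()
    for (ds in -k:k) for (dr in -k:k) for (dc in -k:k) {
      if (ds == 0 && dr == 0 && dc == 0) next
      p <- c(s + ds, r + dr, c + dc)
      if (any(p < 1) || any(p > d)) next
      if (levels[p[1], p[2], p[3]] > 0) nb <- c(nb, levels[p[1], p[2], p[3]])
    }
    if (length(nb) == 0) next
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nb))
  }
  list(n = n_i, s = s_i)
}

# A small two-class feature table in long format: k_sig features with a
# class shift, k_noise pure-noise features, optionally some parameter
# variants of the same base name.
fixture_feature_table <- function(n_per_class = 8, k_sig = 4, k_noise = 4,
                                  shift = 2, seed = 99) {
  set.seed(seed)
  n <- 2 * n_per_class
  cases <- sprintf("C%02d", seq_len(n))
  labels <- stats::setNames(rep(c("intra", "extra"), each = n_per_class), cases)
  rows <- list()
  add <- function(fam, feat, vals, bin = NA, kern = NA, ang = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      case_id = cases, family = fam, feature = feat, bin_exponent = bin,
      kernel = kern, angle = ang, value = vals, operable = TRUE,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(k_sig)) {
    add("glcm", sprintf("Sig%02d", k),
        rnorm(n, ifelse(labels == "extra", shift, 0)), bin = 3, kern = 1, ang = 0)
  }
  for (k in seq_len(k_noise)) {
    add("glrlm", sprintf("Noise%02d", k), rnorm(n), bin = 3, ang = 0)
  }
  list(table = do.call(rbind, rows), labels = labels)
}
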