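# Cleaning, redundancy reduction and statistical screening of radiomic
# feature tables, down to the final capped feature set.

#' Clean a feature table
#'
#' Drops features with any inoperable / non-finite value across cases and
#' zero-variance features (constant across cases), recording a drop reason
#' per removed feature. A clean table is returned unchanged.
#'
#' @param table Long feature table from [extract_all()] (any number of
#'   cases).
#' @return The filtered table, with a `dropped` attribute (data.frame
#'   `feature_id`, `reason`).
#' @export
clean_features <- function(table) {
  fid <- feature_id(table)
  bad_op <- unique(fid[!table$operable | !is.finite(table$value)])
  wide <- features_wide(table[!(fid %in% bad_op), , drop = FALSE])
  vars <- apply(wide, 2, stats::var)
  bad_var <- colnames(wide)[is.na(vars) | vars == 0]
  dropped <- data.frame(
    feature_id = c(bad_op, bad_var),
    reason = rep(c("inoperable", "zero_variance"),
                 c(length(bad_op), length(bad_var))),
    stringsAsFactors = FALSE)
  out <- table[!(fid %in% dropped$feature_id), , drop = FALSE]
  if (nrow(out) == 0) stop("all features dropped during cleaning")
  attr(out, "dropped") <- dropped
  out
}

#' Greedy correlation-based redundancy reduction
#'
#' Features are ordered (by screening p-value when `order_p` is supplied,
#' otherwise by decreasing variance) and greedily retained; a candidate is
#' dropped when its absolute Pearson correlation with any already retained
#' feature exceeds `r_threshold`. At `r_threshold = 1` only exact
#' duplicates are dropped.
#'
#' @param table Cleaned long feature table.
#' @param r_threshold Correlation threshold in (0, 1] (default 0.95).
#' @param order_p Optional named numeric vector of screening p-values
#'   (names are feature ids) used to prioritize retention.
#' @return The reduced table.
#' @export
reduce_redundancy <- function(table, r_threshold = 0.95, order_p = NULL) {
  wide <- features_wide(table)
  feats <- colnames(wide)
  ord <- if (!is.null(order_p)) {
    order(order_p[feats], feats)
  } else {
    order(-apply(wide, 2, stats::var), feats)
  }
  keep <- character(0)
  for (f in feats[ord]) {
    if (length(keep) == 0) { keep <- f; next }
    r <- suppressWarnings(abs(stats::cor(wide[, f], wide[, keep, drop = FALSE])))
    ok <- if (r_threshold >= 1) all(r < 1 - 1e-12, na.rm = TRUE)
          else all(r <= r_threshold, na.rm = TRUE)
    if (ok) keep <- c(keep, f)
  }
  table[feature_id(table) %in% keep, , drop = FALSE]
}

#' Two-sample Student t screen
#'
#' Classical pooled-variance two-sided Student t test per feature between
#' the two stage groups (Welch available behind `welch`). Features with
#' zero pooled variance are flagged inoperable (NA).
#'
#' @param table Long feature table.
#' @param labels Named `"intra"`/`"extra"` labels (names = case ids), >= 2
#'   cases per class.
#' @param welch Use the Welch unequal-variance test instead.
#' @return Data.frame `feature_id`, `t_statistic`, `p_value`.
#' @export
ttest_screen <- function(table, labels, welch = FALSE) {
  wide <- features_wide(table)
  lab <- labels[rownames(wide)]
  stopifnot(all(lab %in% c("intra", "extra")))
  a <- wide[lab == "extra", , drop = FALSE]
  b <- wide[lab == "intra", , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 cases per class")
  res <- vapply(seq_len(ncol(wide)), function(k) {
    x <- a[, k]; y <- b[, k]
    if (stats::var(x) + stats::var(y) == 0) return(c(NA_real_, NA_real_))
    tt <- stats::t.test(x, y, var.equal = !welch)
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2))
  data.frame(feature_id = colnames(wide), t_statistic = res[1, ],
             p_value = res[2, ], stringsAsFactors = FALSE)
}

#' Bhattacharyya coefficient between two feature distributions
#'
#' Gaussian closed form: the Bhattacharyya distance is `D_B = (mu1 -
#' mu2)^2 / (4 (s1^2 + s2^2)) + log(((s1^2 + s2^2) / 2) / (s1 s2)) / 2` and
#' the coefficient is `BC = exp(-D_B)`, 1 for identical distributions and
#' decreasing towards 0 as they separate. A histogram form
#' (`method = "histogram"`, shared equal-width bins) is available; the
#' closed form agrees with numerical integration of `sqrt(p q)` for
#' Gaussian pairs to 1e-6.
#'
#' @param a,b Numeric vectors (>= 2 values each, positive variance for the
#'   Gaussian form).
#' @param method `"gaussian"` (default) or `"histogram"`.
#' @param bins Histogram bin count for the histogram form.
#' @return BC in `[0, 1]`, or NA (inoperable) on zero variance.
#' @export
bhattacharyya_coefficient <- function(a, b, method = c("gaussian", "histogram"),
                                      bins = 32) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (method == "gaussian") {
    v1 <- stats::var(a); v2 <- stats::var(b)
    if (v1 == 0 || v2 == 0) return(NA_real_)
    db <- (mean(a) - mean(b))^2 / (4 * (v1 + v2)) +
      0.5 * log(((v1 + v2) / 2) / sqrt(v1 * v2))
    exp(-db)
  } else {
    br <- seq(min(a, b), max(a, b), length.out = bins + 1)
    if (br[1] == br[length(br)]) return(1)
    pa <- tabulate(findInterval(a, br, rightmost.closed = TRUE), bins) / length(a)
    pb <- tabulate(findInterval(b, br, rightmost.closed = TRUE), bins) / length(b)
    sum(sqrt(pa * pb))
  }
}

#' Screen features by Student t and Bhattacharyya coefficient
#'
#' Runs [ttest_screen()] and [bhattacharyya_coefficient()] on every
#' feature; the significance flag uses strict `p < alpha`.
#'
#' @param table Long feature table.
#' @param labels Named stage labels.
#' @param alpha Screening significance level (default 0.05).
#' @param welch Use the Welch test.
#' @return Data.frame `feature_id`, `t_statistic`, `p_value`,
#'   `bhattacharyya`, `significant`.
#' @export
screen_features <- function(table, labels, alpha = 0.05, welch = FALSE) {
  tt <- ttest_screen(table, labels, welch = welch)
  wide <- features_wide(table)
  lab <- labels[rownames(wide)]
  bc <- vapply(tt$feature_id, function(f) {
    bhattacharyya_coefficient(wide[lab == "extra", f], wide[lab == "intra", f])
  }, 0)
  tt$bhattacharyya <- unname(bc)
  tt$significant <- !is.na(tt$p_value) & tt$p_value < alpha
  tt
}

#' Manhattan plot data
#'
#' Deterministically ordered per-feature `-log10 p` with the significance
#' flag at the threshold (strict `<`; a p-value exactly on the line is not
#' significant).
#'
#' @param screening Data.frame from [screen_features()] or
#'   [ttest_screen()].
#' @param alpha Threshold for the line (default 0.05).
#' @return Data.frame `index`, `feature_id`, `p_value`, `neg_log10_p`,
#'   `significant`, with the threshold in attribute `threshold`.
#' @export
manhattan_data <- function(screening, alpha = 0.05) {
  sc <- screening[order(screening$feature_id), , drop = FALSE]
  out <- data.frame(index = seq_len(nrow(sc)), feature_id = sc$feature_id,
                    p_value = sc$p_value,
                    neg_log10_p = -log10(sc$p_value),
                    significant = !is.na(sc$p_value) & sc$p_value < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- alpha
  out
}

#' Collapse parameter variants of the same base feature
#'
#' Among significant features differing only in the radiomic parameter
#' combination (same family and base name), one representative is chosen
#' uniformly at random under the seed; the choice is deterministic for a
#' fixed seed. Features without parameter variants pass through.
#'
#' @param screening Screening data.frame restricted to the rows to
#'   consider (typically the significant ones).
#' @param seed Integer seed for the random representative choice.
#' @return The reduced screening data.frame.
#' @export
dedup_parameter_variants <- function(screening, seed = 1) {
  base <- sub("^([^|]+\\|[^|]+).*$", "\\1", screening$feature_id)
  set.seed(derive_seed(seed, "dedup"))
  keep <- unlist(lapply(split(seq_len(nrow(screening)), base), function(idx) {
    if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
  }), use.names = FALSE)
  out <- screening[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the k features with smallest p-values
#'
#' Narrows the deduplicated set to the `k_target` features with smallest
#' screening p-values (ties broken by feature-id lexicographic order) so
#' the radiomic set size matches the genomic one, and reports the implied
#' p-value threshold. When fewer than `k_target` features are available the
#' whole list is returned with a warning.
#'
#' @param screening Deduplicated screening data.frame.
#' @param k_target Number of features to retain (>= 1).
#' @return The selected rows; attribute `implied_threshold` holds the
#'   largest selected p-value.
#' @export
match_count_by_pvalue <- function(screening, k_target) {
  stopifnot(k_target >= 1)
  sc <- screening[!is.na(screening$p_value), , drop = FALSE]
  sc <- sc[order(sc$p_value, sc$feature_id), , drop = FALSE]
  if (nrow(sc) < k_target) {
    warning(sprintf("only %d features available for k_target = %d",
                    nrow(sc), k_target))
    k_target <- nrow(sc)
  }
  out <- sc[seq_len(k_target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "implied_threshold") <- max(out$p_value)
  out
}

#' Full radiomic feature-selection pipeline
#'
#' Clean, screen, reduce redundancy among significant features, collapse
#' parameter variants, and cap the set at `k_target` by smallest p-value.
#'
#' @param table Long feature table.
#' @param labels Named stage labels.
#' @param k_target Final set size (matched to the genomic feature count).
#' @param alpha Screening significance level.
#' @param r_threshold Redundancy correlation threshold.
#' @param seed Seed for the dedup stage (the only seeded stage).
#' @return List with `screening`, `manhattan`, `selected` (final rows) and
#'   `dropped`.
#' @export
select_radiomic_features <- function(table, labels, k_target = 8,
                                     alpha = 0.05, r_threshold = 0.95,
                                     seed = 1) {
  cleaned <- clean_features(table)
  screening <- screen_features(cleaned, labels, alpha = alpha)
  pv <- stats::setNames(screening$p_value, screening$feature_id)
  sig <- screening[screening$significant, , drop = FALSE]
  sig_tab <- cleaned[feature_id(cleaned) %in% sig$feature_id, , drop = FALSE]
  if (nrow(sig_tab) > 0) {
    red <- reduce_redundancy(sig_tab, r_threshold, order_p = pv)
    sig <- sig[sig$feature_id %in% unique(feature_id(red)), , drop = FALSE]
  }
  dedup <- dedup_parameter_variants(sig, seed = seed)
  selected <- if (nrow(dedup) > 0) match_count_by_pvalue(dedup, k_target)
              else dedup
  list(screening = screening, manhattan = manhattan_data(screening, alpha),
       selected = selected, dropped = attr(cleaned, "dropped"))
}
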