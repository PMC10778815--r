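# Differential expression, DEG intersection, ssGSEA scoring and
# stage-trend testing for RNA-seq count matrices.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio of the sample's count to the gene's
#' geometric mean across samples. When no gene has all-positive counts the
#' median is taken over each sample's positive-ratio subset, with a
#' warning.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Positive numeric vector of length `ncol(counts)`.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  log_gm <- rowMeans(log(counts + 0L) * NA^(counts == 0), na.rm = TRUE)
  all_pos <- rowSums(counts == 0) == 0
  if (any(all_pos)) {
    lr <- log(counts[all_pos, , drop = FALSE]) -
      rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- exp(apply(lr, 2, stats::median))
  } else {
    warning("no gene with all-positive counts; using positive-subset medians")
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      pos <- counts[, j] > 0 & is.finite(log_gm)
      exp(stats::median(log(counts[pos, j]) - log_gm[pos]))
    }, 0)
  }
  stats::setNames(sf, colnames(counts))
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || any(counts < 0)) {
    stop("counts must be a non-negative matrix")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must have unique gene and sample identifiers")
  }
  invisible(TRUE)
}

#' Negative-binomial Wald differential expression
#'
#' A method-of-moments NB Wald test per gene: counts are normalized by
#' [size_factors()]; the per-gene dispersion is `alpha = max(0, (var -
#' mean) / mean^2)` estimated from within-group moments of normalized
#' counts; the log2 fold change contrasts extra- over intra-vesical group
#' means; the Wald statistic divides it by its delta-method standard error
#' `sqrt((1/m1 + a)/n1 + (1/m2 + a)/n2) / ln 2`; p-values are two-sided
#' against a t reference with `n1 + n2 - 2` degrees of freedom (a
#' small-sample correction that keeps the moment-estimated dispersion from
#' inflating the tail) and BH-adjusted across genes. Genes with zero
#' counts in both
#' groups are skipped (`skipped` flag). No dispersion shrinkage, outlier
#' replacement or independent filtering is applied.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param labels `"intra"`/`"extra"` per sample (>= 2 of each).
#' @param sf Optional precomputed size factors.
#' @return A data.frame with columns `gene`, `base_mean`, `log2fc`,
#'   `wald_stat`, `p_value`, `adj_p`, `direction`, `skipped`.
#' @export
nb_wald_de <- function(counts, labels, sf = NULL) {
  validate_counts(counts)
  stopifnot(length(labels) == ncol(counts))
  g1 <- labels == "intra"; g2 <- labels == "extra"
  if (sum(g1) < 2 || sum(g2) < 2) stop("need >= 2 samples per class")
  sf <- sf %||% size_factors(counts)
  z <- sweep(counts, 2, sf, "/")
  m1 <- rowMeans(z[, g1, drop = FALSE]); m2 <- rowMeans(z[, g2, drop = FALSE])
  v1 <- apply(z[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(z[, g2, drop = FALSE], 1, stats::var)
  n1 <- sum(g1); n2 <- sum(g2)
  # pooled within-group method-of-moments dispersion
  mbar <- (m1 + m2) / 2
  vbar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  alpha <- pmax(0, (vbar - mbar) / mbar^2)
  skipped <- m1 == 0 & m2 == 0
  # continuity floor so a zero group mean yields a finite fold change
  m1f <- pmax(m1, 0.5 / n1); m2f <- pmax(m2, 0.5 / n2)
  lfc <- log2(m2f / m1f)
  se <- sqrt((1 / m1f + alpha) / n1 + (1 / m2f + alpha) / n2) / log(2)
  w <- lfc / se
  p <- 2 * stats::pt(-abs(w), df = n1 + n2 - 2)
  p[skipped] <- NA
  res <- data.frame(
    gene = rownames(counts), base_mean = (m1 + m2) / 2, log2fc = lfc,
    wald_stat = w, p_value = p,
    adj_p = stats::p.adjust(p, method = "BH"),
    direction = ifelse(lfc >= 0, "up_in_high", "up_in_low"),
    skipped = skipped, stringsAsFactors = FALSE)
  res$log2fc[skipped] <- NA
  res$wald_stat[skipped] <- NA
  res$direction[skipped] <- NA
  rownames(res) <- NULL
  res
}

#' Intersect differentially expressed genes across datasets
#'
#' Genes significant (`adj_p < alpha`) in every dataset with the same
#' direction, partitioned by direction. Commutative and associative over
#' datasets; an empty overlap returns empty lists.
#'
#' @param results List of >= 2 data.frames from [nb_wald_de()].
#' @param alpha Significance threshold on BH-adjusted p (default 0.05).
#' @return List with character vectors `up_common` (up_in_high everywhere)
#'   and `down_common` (up_in_low everywhere).
#' @export
intersect_degs <- function(results, alpha = 0.05) {
  stopifnot(is.list(results), length(results) >= 2)
  pick <- function(r, dir) {
    r$gene[!is.na(r$adj_p) & r$adj_p < alpha & r$direction == dir & !r$skipped]
  }
  up <- Reduce(intersect, lapply(results, pick, dir = "up_in_high"))
  down <- Reduce(intersect, lapply(results, pick, dir = "up_in_low"))
  list(up_common = sort(up), down_common = sort(down))
}

#' Normalize counts for enrichment scoring
#'
#' Size-factor-normalized, log1p-transformed counts. ssGSEA is rank-based,
#' so the log is immaterial to the scores; it is applied for the benefit of
#' any downstream use of the matrix as expression values.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric matrix of the same shape.
#' @export
normalize_expression <- function(counts) {
  log1p(sweep(counts, 2, size_factors(counts), "/"))
}

#' Single-sample gene set enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; average
#' ranks on ties) and the score of a set S is the sum over positions of the
#' difference between the weighted in-set running distribution
#' `P_in(i) = sum_{k in S, rank <= i} r_k^alpha / sum_{k in S} r_k^alpha`
#' and the uniform out-of-set running distribution
#' `P_out(i) = sum_{k notin S, rank <= i} 1 / (N - |S|)`, where `r_k = N -
#' rank_k + 1` (largest for the most highly expressed gene). Sets with no
#' gene present in the matrix are flagged missing (NA column). Scores are
#' rank-based, hence invariant to monotone transforms of a sample's
#' expression. Optional min-max normalization of the score matrix is
#' available behind `normalize`.
#'
#' @param expr Numeric matrix genes x samples (normalized expression).
#' @param sets Named list of character vectors (gene sets).
#' @param alpha_weight Rank-weighting exponent (canonical default 0.25).
#' @param normalize If `TRUE`, scale all scores to `[0, 1]` by the global
#'   score range.
#' @return Numeric matrix sets x samples of enrichment scores.
#' @export
ssgsea_scores <- function(expr, sets, alpha_weight = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(expr), is.list(sets), length(sets) > 0)
  n <- nrow(expr)
  genes <- rownames(expr)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  memb <- lapply(sets, function(s) {
    idx <- match(unique(s), genes)
    idx[!is.na(idx)]
  })
  for (j in seq_len(ncol(expr))) {
    rk <- rank(-expr[, j], ties.method = "average")   # 1 = most expressed
    ord <- order(rk)                                   # positions top..bottom
    r <- n - rk + 1                                    # weight base, top = N
    for (k in seq_along(sets)) {
      s_idx <- memb[[k]]
      if (length(s_idx) == 0 || length(s_idx) >= n) next
      inset <- logical(n); inset[s_idx] <- TRUE
      inset_o <- inset[ord]
      w <- (r[ord] * inset_o)^alpha_weight * inset_o
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset_o) / (n - length(s_idx))
      out[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  }
  out
}

#' Kruskal-Wallis stage test per signature
#'
#' Tests each signature's enrichment scores for differences across >= 2
#' sample groups, with significance stars bucketed at 0.05 / 0.01 / 0.001 /
#' 0.0001.
#'
#' @param scores Matrix sets x samples from [ssgsea_scores()].
#' @param groups Factor or character vector of group labels per sample.
#' @return Data.frame with columns `signature`, `statistic`, `p_value`,
#'   `stars`.
#' @export
signature_stage_test <- function(scores, groups) {
  stopifnot(is.matrix(scores), length(groups) == ncol(scores))
  groups <- as.factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 1)) {
    stop("need >= 2 non-empty groups")
  }
  res <- lapply(rownames(scores), function(sig) {
    y <- scores[sig, ]
    if (all(is.na(y))) {
      return(data.frame(signature = sig, statistic = NA_real_,
                        p_value = NA_real_, stars = NA_character_,
                        stringsAsFactors = FALSE))
    }
    kw <- stats::kruskal.test(y ~ groups)
    data.frame(signature = sig, statistic = unname(kw$statistic),
               p_value = kw$p.value, stars = p_stars(kw$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.0001) "****" else if (p < 0.001) "***"
  else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}
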