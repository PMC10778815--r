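# Feature cleaning, redundancy pruning, screening statistics and the
# capped final selection.

test_that("cleaning drops inoperable and constant features with reasons", {
  fx <- fixture_feature_table()
  tab <- fx$table
  # make one feature inoperable for one case and one feature constant
  tab$operable[tab$feature == "Sig01"][3] <- FALSE
  tab$value[tab$feature == "Sig01"][3] <- NA
  tab$value[tab$feature == "Noise01"] <- 7
  out <- clean_features(tab)
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$reason[grepl("Sig01", dropped$feature_id)], "inoperable")
  expect_setequal(dropped$reason[grepl("Noise01", dropped$feature_id)], "zero_variance")
  expect_false(any(grepl("Sig01|Noise01", feature_id(out))))
  # a clean table passes through unchanged
  clean <- fx$table
  expect_equal(clean_features(clean)$value, clean$value)
  expect_equal(nrow(attr(clean_features(clean), "dropped")), 0)
  # everything dropped is an explicit error
  allbad <- fx$table
  allbad$operable <- FALSE
  expect_error(clean_features(allbad), "all features dropped")
})

test_that("redundancy pruning removes duplicates and near-duplicates", {
  fx <- fixture_feature_table(k_sig = 2, k_noise = 2)
  tab <- fx$table
  # append an exact duplicate of Sig01 under another name
  dup <- tab[tab$feature == "Sig01", ]
  dup$feature <- "Sig01Copy"
  tab2 <- rbind(tab, dup)
  red <- reduce_redundancy(tab2, r_threshold = 0.95)
  ids <- unique(feature_id(red))
  expect_equal(sum(grepl("Sig01", ids)), 1)
  # r_threshold = 1: only exact duplicates go
  red1 <- reduce_redundancy(tab2, r_threshold = 1)
  expect_equal(length(unique(feature_id(red1))), length(unique(feature_id(tab2))) - 1)
  # planted r = 0.99 pair: one dropped at threshold 0.95
  near <- tab[tab$feature == "Sig02", ]
  near$feature <- "Sig02Near"
  set.seed(1)
  near$value <- near$value + rnorm(nrow(near), sd = 0.02 * sd(near$value))
  tab3 <- rbind(tab, near)
  w <- features_wide(tab3)
  expect_gt(abs(cor(w[, grep("Sig02\\|", colnames(w))],
                    w[, grep("Sig02Near", colnames(w))])), 0.95)
  red3 <- reduce_redundancy(tab3, r_threshold = 0.95)
  expect_equal(sum(grepl("Sig02", unique(feature_id(red3)))), 1)
})

test_that("the t screen matches stats::t.test and handles degenerate features", {
  fx <- fixture_feature_table(n_per_class = 6)
  sc <- ttest_screen(fx$table, fx$labels)
  w <- features_wide(fx$table)
  lab <- fx$labels[rownames(w)]
  for (k in c(1, 5)) {
    tt <- stats::t.test(w[lab == "extra", k], w[lab == "intra", k],
                        var.equal = TRUE)
    expect_equal(sc$t_statistic[k], unname(tt$statistic))
    expect_equal(sc$p_value[k], tt$p.value)
  }
  # identical class samples: t = 0, p = 1
  cases <- sprintf("C%02d", 1:6)
  tab <- data.frame(case_id = cases, family = "glcm", feature = "Flat",
                    bin_exponent = 3, kernel = 1, angle = 0,
                    value = rep(c(1, 2, 3), 2), operable = TRUE)
  lab2 <- stats::setNames(rep(c("intra", "extra"), each = 3), cases)
  sc2 <- ttest_screen(tab, lab2)
  expect_equal(sc2$t_statistic, 0)
  expect_equal(sc2$p_value, 1)
  # zero pooled variance: flagged inoperable
  tab$value <- 5
  sc3 <- ttest_screen(tab, lab2)
  expect_true(is.na(sc3$p_value))
})

test_that("Bhattacharyya closed form matches numerical integration to 1e-6", {
  # mu1 = 0, mu2 = 2, sd = 1: BC = exp(-0.5)
  set.seed(4)
  a <- rnorm(500); b <- rnorm(500, 2)
  bc_sample <- bhattacharyya_coefficient(a, b)
  gauss_overlap <- function(m1, s1, m2, s2) {
    stats::integrate(function(x) sqrt(stats::dnorm(x, m1, s1) * stats::dnorm(x, m2, s2)),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }
  # exact parameter check through controlled vectors (variance fixed by construction)
  mk <- function(m, s) { v <- scale(rnorm(200))[, 1]; m + s * v }
  for (par in list(c(0, 1, 2, 1), c(1, 2, -1, 0.5), c(0, 1, 0, 1))) {
    x <- mk(par[1], par[2]); y <- mk(par[3], par[4])
    expect_equal(bhattacharyya_coefficient(x, y),
                 gauss_overlap(mean(x), stats::sd(x), mean(y), stats::sd(y)),
                 tolerance = 1e-6)
  }
  # identical distributions: BC = 1
  x <- mk(3, 2)
  expect_equal(bhattacharyya_coefficient(x, x), 1)
  # BC strictly decreases as the mean gap grows at fixed sd
  bcs <- vapply(c(0, 1, 2, 4), function(d) {
    bhattacharyya_coefficient(mk(0, 1), mk(d, 1))
  }, 0)
  expect_true(all(diff(bcs) < 0))
  # zero variance: inoperable
  expect_true(is.na(bhattacharyya_coefficient(rep(1, 5), rnorm(5))))
})

test_that("Manhattan data uses a strict significance boundary", {
  sc <- data.frame(feature_id = c("a", "b", "c"),
                   t_statistic = 1, p_value = c(0.05, 0.04, 1))
  md <- manhattan_data(sc, alpha = 0.05)
  expect_false(md$significant[md$feature_id == "a"])   # exactly on the line
  expect_true(md$significant[md$feature_id == "b"])
  md1 <- manhattan_data(data.frame(feature_id = letters[1:4], t_statistic = 0,
                                   p_value = rep(1, 4)))
  expect_equal(sum(md1$significant), 0)
})

test_that("parameter-variant dedup keeps one representative per base feature, deterministically", {
  # Contrast at 12 parameter combos, all significant
  combos <- expand.grid(bin = 1:3, kernel = 1:2, angle = c(0, 90))
  sc <- data.frame(
    feature_id = sprintf("glcm|Contrast|b%d|k%d|a%d", combos$bin, combos$kernel,
                         combos$angle),
    t_statistic = 3, p_value = 0.01, stringsAsFactors = FALSE)
  d1 <- dedup_parameter_variants(sc, seed = 17)
  expect_equal(nrow(d1), 1)
  expect_identical(d1, dedup_parameter_variants(sc, seed = 17))
  # no variants: identity
  sc2 <- data.frame(feature_id = c("glcm|Contrast|b1|k1|a0", "glrlm|RunEntropy|b1|a0"),
                    t_statistic = 1, p_value = 0.02, stringsAsFactors = FALSE)
  expect_equal(nrow(dedup_parameter_variants(sc2, seed = 1)), 2)
})

test_that("count matching takes the smallest p-values with lexicographic ties", {
  set.seed(8)
  sc <- data.frame(feature_id = sprintf("glcm|F%02d|b1|k1|a0", 1:30),
                   t_statistic = 1, p_value = runif(30), stringsAsFactors = FALSE)
  out <- match_count_by_pvalue(sc, 12)
  expect_equal(nrow(out), 12)
  expect_equal(sort(out$p_value), sort(sc$p_value)[1:12])
  expect_equal(attr(out, "implied_threshold"), max(out$p_value))
  # ties broken by feature id
  sct <- data.frame(feature_id = c("glcm|B|b1", "glcm|A|b1", "glcm|C|b1"),
                    t_statistic = 1, p_value = c(0.01, 0.01, 0.5))
  expect_equal(match_count_by_pvalue(sct, 2)$feature_id,
               c("glcm|A|b1", "glcm|B|b1"))
  # k_target larger than the list: whole list plus warning
  expect_warning(out2 <- match_count_by_pvalue(sc, 50), "only 30")
  expect_equal(nrow(out2), 30)
})

test_that("permuting stage labels destroys planted significance", {
  fx <- fixture_feature_table(n_per_class = 10, k_sig = 5, k_noise = 45,
                              shift = 2.5, seed = 42)
  sc <- screen_features(fx$table, fx$labels)
  expect_gte(sum(sc$significant[grepl("Sig", sc$feature_id)]), 4)
  set.seed(6)
  perm <- stats::setNames(sample(fx$labels), names(fx$labels))
  scp <- screen_features(fx$table, perm)
  expect_lt(mean(scp$significant), 0.2)
})

test_that("the full selection pipeline returns a capped, screened set", {
  fx <- fixture_feature_table(n_per_class = 8, k_sig = 10, k_noise = 10,
                              shift = 2, seed = 11)
  out <- select_radiomic_features(fx$table, fx$labels, k_target = 4, seed = 2)
  expect_lte(nrow(out$selected), 4)
  expect_true(all(out$selected$significant))
  expect_true(all(out$selected$p_value <= attr(out$selected, "implied_threshold")))
})
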