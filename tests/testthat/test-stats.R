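test_that("two-group sequential ANOVA matches the two-sample t-test identity", {
  set.seed(4)
  d <- data.frame(g = rep(c("a", "b"), each = 100),
                  y = c(rnorm(100, 0), rnorm(100, 1)))
  a <- sequential_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(a$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p[1], tt$p.value, tolerance = 1e-9)
})

test_that("sequential SS decomposition sums to the total SS", {
  co <- generate_cohort(cohort_design(seed = 3))
  wb <- co$wingbeats
  a <- sequential_anova(wb, "gamma_climb")
  total <- sum((wb$gamma_climb - mean(wb$gamma_climb))^2)
  expect_equal(sum(a$sum_sq), total, tolerance = 1e-9)
  # nested factor dfs: species contributes levels beyond microhabitat only
  expect_equal(a$df[a$term == "microhabitat"], 1)
  expect_equal(a$df[a$term == "species"], 5)
})

test_that("degenerate and confounded ANOVA inputs are handled", {
  d <- data.frame(g = rep(c("a", "b"), each = 10), y = 1)
  a <- sequential_anova(d, "y", "g")
  expect_equal(a$sum_sq, c(0, 0))
  expect_equal(a$F[1], 0)
  expect_equal(a$p[1], 1)
  d2 <- data.frame(g = letters[1:6], y = rnorm(6))
  expect_error(sequential_anova(d2, "y", "g"), "confounded")
})

test_that("Wilks' lambda matches brute-force determinant arithmetic on a small fixture", {
  d <- data.frame(g = rep(c("a", "b"), each = 3),
                  y1 = c(1, 2, 3, 5, 6, 7),
                  y2 = c(2, 1, 4, 3, 6, 5))
  m <- manova_wilks(d, c("y1", "y2"), "g")
  Y <- as.matrix(d[, 2:3])
  W <- crossprod(sweep(Y[1:3, ], 2, colMeans(Y[1:3, ]))) +
    crossprod(sweep(Y[4:6, ], 2, colMeans(Y[4:6, ])))
  Tm <- crossprod(sweep(Y, 2, colMeans(Y)))
  expect_equal(m$lambda, det(W) / det(Tm), tolerance = 1e-12)
  expect_true(m$lambda > 0 && m$lambda <= 1)
})

test_that("Wilks' lambda agrees with the MANOVA reference implementation", {
  set.seed(6)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 40),
                  y1 = rnorm(120), y2 = rnorm(120), y3 = rnorm(120))
  d$y1 <- d$y1 + as.numeric(factor(d$g)) * 0.5
  m <- manova_wilks(d, c("y1", "y2", "y3"), "g")
  sm <- summary(stats::manova(cbind(d$y1, d$y2, d$y3) ~ d$g),
                test = "Wilks")$stats
  expect_equal(m$lambda, unname(sm[1, "Wilks"]), tolerance = 1e-10)
  expect_equal(m$F, unname(sm[1, "approx F"]), tolerance = 1e-9)
  expect_equal(m$p, unname(sm[1, "Pr(>F)"]), tolerance = 1e-9)
})

test_that("single-response Wilks' lambda obeys the one-way ANOVA identity", {
  set.seed(5)
  d <- data.frame(g = rep(c("a", "b"), each = 50),
                  y = c(rnorm(50), rnorm(50, 0.8)))
  a <- sequential_anova(d, "y", "g")
  m <- manova_wilks(d, "y", "g")
  expect_equal(m$lambda, 1 / (1 + a$F[1] * 1 / 98), tolerance = 1e-12)
  expect_equal(m$F, a$F[1], tolerance = 1e-9)
})

test_that("lambda approaches 1 when responses are independent of the group", {
  set.seed(8)
  d <- data.frame(g = rep(c("a", "b"), each = 2000),
                  y1 = rnorm(4000), y2 = rnorm(4000))
  m <- manova_wilks(d, c("y1", "y2"), "g")
  expect_gt(m$lambda, 0.995)
})

test_that("phylogenetic ANOVA on a star tree reproduces standard ANOVA", {
  star <- star_tree7()
  g <- setNames(c("c", "c", "u", "u", "u", "u", "u"), star$tip.label)
  diffs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- setNames(rnorm(7) + (g == "c") * 1.0, star$tip.label)
    pa <- phylogenetic_anova(x, g, star, n_sim = 2000, seed = s + 100)
    p_std <- anova(stats::lm(x ~ g))$`Pr(>F)`[1]
    pa$p - p_std
  }, numeric(1))
  # agreement within Monte-Carlo error across seeds
  expect_lt(mean(abs(diffs)), 2 / sqrt(2000) + 0.02)
  expect_lt(max(abs(diffs)), 0.1)
})

test_that("deep phylogenetic structure absorbs group differences aligned with clades", {
  # two clades on long stems, groups perfectly segregated by clade, traits
  # evolving by pure Brownian motion (no group effect): the naive ANOVA is
  # fooled by the clade-level drift far more often than the phylogenetic
  # ANOVA, which stays calibrated
  tr <- ape::read.tree(
    text = "((A:0.1,B:0.1):3,(C:0.1,D:0.1,E:0.1,F:0.1,G:0.1):3);")
  g <- setNames(c("c", "c", "u", "u", "u", "u", "u"), tr$tip.label)
  Lc <- t(chol(ape::vcv(tr)[tr$tip.label, tr$tip.label]))
  set.seed(3)
  naive_sig <- phylo_sig <- logical(100)
  for (i in 1:100) {
    x <- setNames(as.numeric(Lc %*% rnorm(7)), tr$tip.label)
    naive_sig[i] <- anova(stats::lm(x ~ g))$`Pr(>F)`[1] < 0.05
    phylo_sig[i] <- phylogenetic_anova(x, g, tr, n_sim = 199,
                                       seed = 500 + i)$p < 0.05
  }
  expect_lt(mean(phylo_sig), 0.12)              # calibrated under the BM null
  expect_gt(mean(naive_sig), mean(phylo_sig) + 0.2)  # naive test misled
})

test_that("phylogenetic ANOVA agrees with the phytools reference on the same tree", {
  skip_if_not_installed("phytools")
  tr <- default_tree()
  g <- setNames(c("c", "c", "u", "u", "u", "u", "u"), tr$tip.label)
  set.seed(10)
  x <- setNames(rnorm(7) + (g == "c") * 1.5, tr$tip.label)
  ours <- phylogenetic_anova(x, g, tr, n_sim = 5000, seed = 2)
  ref <- phytools::phylANOVA(tr, factor(g), x, nsim = 5000, posthoc = FALSE)
  expect_equal(ours$F_obs, unname(ref$F), tolerance = 1e-9)
  expect_lt(abs(ours$p - ref$Pf), 0.05)
})

test_that("phylogenetic ANOVA validates its inputs and is seed-reproducible", {
  star <- star_tree7()
  g <- setNames(rep(c("c", "u"), c(2, 5)), star$tip.label)
  x <- setNames(rnorm(7), star$tip.label)
  expect_error(phylogenetic_anova(x, g, star, n_sim = 50), "at least 100")
  names(x)[1] <- "ZZZ"
  expect_error(phylogenetic_anova(x, g, star, n_sim = 200), "tips")
  names(x)[1] <- "A"
  a <- phylogenetic_anova(x, g, star, n_sim = 500, seed = 3)
  b <- phylogenetic_anova(x, g, star, n_sim = 500, seed = 3)
  expect_identical(a$p, b$p)
  expect_identical(a$F_sim, b$F_sim)
})

test_that("linear regression matches hand normal equations and exact lines", {
  ex <- linear_regression(1:5, 2 * (1:5) + 1)
  expect_equal(ex$slope, 2, tolerance = 1e-12)
  expect_equal(ex$intercept, 1, tolerance = 1e-12)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)
  x <- c(1, 2, 4, 5, 7); y <- c(2, 3, 5, 4, 8)
  f <- linear_regression(x, y)
  # brute-force normal equations
  sl <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  ic <- mean(y) - sl * mean(x)
  r2 <- 1 - sum((y - ic - sl * x)^2) / sum((y - mean(y))^2)
  expect_equal(f$slope, sl, tolerance = 1e-12)
  expect_equal(f$intercept, ic, tolerance = 1e-12)
  expect_equal(f$r_squared, r2, tolerance = 1e-12)
  # R^2 equals squared Pearson r in simple regression
  expect_equal(f$r_squared, pearson_correlation(x, y)$r^2, tolerance = 1e-12)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("Pearson correlation matches brute-force covariance arithmetic", {
  expect_equal(pearson_correlation(1:10, 1:10)$r, 1, tolerance = 1e-12)
  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  expect_equal(pearson_correlation(x, y)$r, 0, tolerance = 1e-12)
  x6 <- c(1, 3, 2, 5, 4, 6); y6 <- c(2, 1, 4, 3, 6, 5)
  r_hand <- sum((x6 - mean(x6)) * (y6 - mean(y6))) /
    sqrt(sum((x6 - mean(x6))^2) * sum((y6 - mean(y6))^2))
  expect_equal(pearson_correlation(x6, y6)$r, r_hand, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Wilcoxon rank-sum gives exact enumeration p-values for small samples", {
  # most extreme ranking of 3 vs 3: 2 of the 20 orderings are as extreme
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p, 0.1, tolerance = 1e-12)
  # identical groups: no evidence of a shift
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon power increases monotonically with the group shift", {
  pow <- vapply(c(0, 0.5, 1), function(shift) {
    rej <- vapply(1:200, function(s) {
      set.seed(s * 1000 + round(shift * 10))
      wilcoxon_rank_sum(rnorm(20), rnorm(20) + shift)$p < 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(pow) > 0))
})

test_that("percent differences reproduce the published contrasts from the published means", {
  expect_equal(percent_difference(46.7, 36.5, digits = 0), 28)
  expect_equal(percent_difference(1.56, 1.32, digits = 1), 18.2)
  expect_equal(percent_difference(1.07, 0.72, digits = 0), 49)
  expect_equal(percent_difference(1.55, 1.24, digits = 0), 25)
  expect_equal(percent_difference(3.3, 3.3), 0)
  expect_error(percent_difference(1, 0), "zero")
})
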