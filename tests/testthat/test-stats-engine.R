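# The permutation-statistics engine, checked against closed forms,
# exhaustive enumeration, and vegan as an independent oracle.

test_that("bray_curtis matches the formula and vegan", {
  x <- rbind(a = c(2, 1, 0), b = c(1, 1, 1), c = c(2, 1, 0), d = c(0, 0, 5))
  D <- bray_curtis(x)
  expect_equal(D["a", "b"], 1 / 3)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "d"], 1) # disjoint supports
  expect_error(bray_curtis(rbind(ok = c(1, 2), bad = c(0, 0))), "bad")

  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(rpois(60, 8), 6)
  expect_equal(unname(bray_curtis(m)),
               unname(as.matrix(vegan::vegdist(m, "bray"))),
               tolerance = 1e-12)
})

test_that("permanova reduces to classical ANOVA F in the univariate Euclidean limit", {
  set.seed(8)
  y <- rnorm(18)
  g <- rep(c("A", "B", "C"), each = 6)
  D <- as.matrix(dist(y))
  fit <- permanova(D, g, n_perm = 99, seed = 1)
  f_classical <- summary(aov(y ~ g))[[1]]["g", "F value"]
  expect_equal(fit$terms$pseudo_F[fit$terms$term == "group"], f_classical,
               tolerance = 1e-10)
  # SS additivity
  expect_equal(sum(fit$terms$SS) + fit$residual$SS, fit$total$SS,
               tolerance = 1e-9)
})

test_that("permanova p-value matches exhaustive enumeration for n = 6", {
  set.seed(21)
  m <- matrix(rpois(6 * 5, 12), 6) + 1
  D <- bray_curtis(m)
  g <- rep(c("A", "B"), each = 3)
  pseudo_f <- function(lab) {
    lab <- factor(lab)
    permanova(D, lab, n_perm = 1, seed = 1)$terms$pseudo_F[2 - 1]
  }
  # enumerate all 20 distinct assignments of 3 labels
  combos <- combn(6, 3)
  f_obs <- pseudo_f(g)
  f_all <- apply(combos, 2, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"; pseudo_f(lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  fit <- permanova(D, g, n_perm = 9999, seed = 4)
  expect_lt(abs(fit$terms$p_perm[1] - p_exact), 0.03)
})

test_that("permanova agrees with vegan::adonis2 on statistic and partition", {
  skip_if_not_installed("vegan")
  set.seed(13)
  m <- matrix(rpois(12 * 8, 20), 12)
  g <- rep(c("A", "B", "C"), each = 4)
  D <- bray_curtis(m)
  fit <- permanova(D, g, n_perm = 199, seed = 2)
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 199)
  expect_equal(fit$terms$pseudo_F[1], ref$F[1], tolerance = 1e-8)
  expect_equal(fit$terms$R2[1], ref$R2[1], tolerance = 1e-8)
  expect_equal(fit$residual$df, ref$Df[2])
})

test_that("blocked permanova fits year first and permutes within strata", {
  set.seed(30)
  n <- 24
  year <- rep(c("y1", "y2"), each = 12)
  id <- rep(c("a", "b", "c", "d"), each = 6) # a,b in y1; c,d in y2
  m <- matrix(rpois(n * 10, 15), n) +
    outer(as.integer(factor(id)), rep(1, 10)) * 3
  D <- bray_curtis(m)
  fit <- permanova(D, id, block = year, n_perm = 199, seed = 5)
  expect_identical(fit$terms$term, c("block", "group"))
  expect_identical(fit$terms$df, c(1L, 3L))
  expect_equal(fit$residual$df, n - 1 - 1 - 3)
  expect_equal(sum(fit$terms$SS) + fit$residual$SS, fit$total$SS,
               tolerance = 1e-9)
  # permutation p reproducible under the seed
  fit2 <- permanova(D, id, block = year, n_perm = 199, seed = 5)
  expect_identical(fit$terms$p_perm, fit2$terms$p_perm)
})

test_that("pairwise contrasts cover all level pairs with Holm adjustment", {
  set.seed(44)
  g <- rep(letters[1:4], each = 4)
  m <- matrix(rpois(16 * 6, 10), 16) + as.integer(factor(g)) * 2
  D <- bray_curtis(m)
  pw <- pairwise_permanova(D, g, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), choose(4, 2))
  expect_true(all(pw$p_holm >= pw$p_perm))
  # Holm adjusted p's are monotone in raw p's
  o <- order(pw$p_perm)
  expect_true(all(diff(pw$p_holm[o]) >= -1e-12))
  # two levels: adjusted = raw
  pw2 <- pairwise_permanova(D[1:8, 1:8], g[1:8], n_perm = 99, seed = 1)
  expect_equal(pw2$p_holm, pw2$p_perm)
})

test_that("holm_adjust matches hand computation and dominates Bonferroni", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(1)
  p <- runif(20)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"), tolerance = 1e-12)
  expect_true(all(holm_adjust(p) <= pmin(1, length(p) * p) + 1e-12))
})

test_that("mantel recovers exact correlations and matches vegan", {
  set.seed(3)
  pts <- matrix(rnorm(20), 10)
  D1 <- as.matrix(dist(pts))
  expect_equal(mantel(D1, D1, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel(D1, 2 * D1 + 0.3 * (1 - diag(10)), n_perm = 99, seed = 1)$r, 1)
  expect_error(mantel(D1, matrix(0, 10, 10)), "zero variance")

  skip_if_not_installed("vegan")
  D2 <- as.matrix(dist(matrix(rnorm(20), 10)))
  m <- mantel(D1, D2, n_perm = 999, seed = 2)
  ref <- vegan::mantel(D1, D2, permutations = 999)
  expect_equal(m$r, unname(ref$statistic), tolerance = 1e-12)
  expect_gt(m$p_perm, 0) # plus-one rule: never zero
})

test_that("nmds embeds Euclidean data with near-zero, nonincreasing stress", {
  set.seed(6)
  pts <- matrix(rnorm(24), 12)
  D <- as.matrix(dist(pts))
  fit <- nmds(D, k = 2, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_true(all(diff(fit$stress_trace) <= 1e-12))
  expect_identical(dim(fit$points), c(12L, 2L))
  expect_error(nmds(D, k = 12), "smaller")
})

test_that("ols_fit matches closed forms and lm", {
  x <- 1:20
  exact <- ols_fit(2 * x, data.frame(x = x))
  expect_equal(exact$coefficients["x", "estimate"], 2)
  expect_equal(exact$r_squared, 1)

  set.seed(10)
  xo <- rnorm(50)
  yo <- residuals(lm(rnorm(50) ~ xo)) # orthogonal to the fitted design
  expect_equal(ols_fit(yo, data.frame(x = xo))$coefficients["x", "estimate"], 0,
               tolerance = 1e-10)

  y <- 3 * x + rnorm(20)
  fit <- ols_fit(y, data.frame(x = x))
  ref <- lm(y ~ x)
  expect_equal(unname(fit$coefficients[, "estimate"]), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "p"]),
               unname(summary(ref)$coefficients[, 4]), tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, summary(ref)$adj.r.squared, tolerance = 1e-10)
  expect_error(ols_fit(y, data.frame(a = x, b = 2 * x)), "rank")
})

test_that("parameter recovery: large-n slope lands within 3 SE", {
  set.seed(77)
  x <- rnorm(1000)
  y <- 3 * x + rnorm(1000)
  fit <- ols_fit(y, data.frame(x = x))
  est <- fit$coefficients["x", ]
  expect_lt(abs(est$estimate - 3), 3 * est$se)
})

test_that("aicc_rank computes weights per the closed form", {
  set.seed(12)
  x1 <- rnorm(20); x2 <- rnorm(20)
  y <- x1 + rnorm(20)
  f1 <- ols_fit(y, data.frame(x1 = x1))
  f2 <- ols_fit(y, data.frame(x1 = x1, x2 = x2))
  rank <- aicc_rank(list(m1 = f1, m2 = f2))
  expect_equal(rank$delta_AICc[1], 0)
  expect_equal(sum(rank$weight), 1)
  # closed-form check of AICc for the simple model: k = 3 (2 coefs + sigma)
  aicc1 <- 20 * log(f1$rss / 20) + 2 * 3 + 2 * 3 * 4 / (20 - 3 - 1)
  expect_equal(rank$AICc[rank$model == "m1"], aicc1, tolerance = 1e-10)

  solo <- aicc_rank(list(only = f1))
  expect_equal(solo$weight, 1)

  # delta = (0, 2) -> weights (0.731, 0.269)
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 3), c(0.731, 0.269))

  tiny <- ols_fit(y[1:4], data.frame(x1 = x1[1:4]))
  expect_error(aicc_rank(list(a = tiny)), "AICc")
})

test_that("welch_t matches t.test and its pooled special case", {
  set.seed(2)
  x1 <- rnorm(12); x2 <- rnorm(15, 1)
  w <- welch_t(x1, x2)
  ref <- t.test(x1, x2)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)

  expect_equal(welch_t(x1, x1)$t, 0)
  # equal n: Welch t equals the pooled t statistic algebraically
  x3 <- rnorm(12)
  pooled <- t.test(x1, x3, var.equal = TRUE)
  expect_equal(welch_t(x1, x3)$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "zero")
})

test_that("condition index is an oriented first principal component", {
  set.seed(31)
  base <- rnorm(30)
  m <- data.frame(rump_fat = 2 * base + 1, girth = -3 * base + 5)
  ci <- condition_index(m)
  # two perfectly correlated variables: scores proportional to either z-score
  expect_equal(abs(cor(ci$scores, scale(m$rump_fat)[, 1])), 1, tolerance = 1e-10)
  expect_gt(ci$loadings["rump_fat"], 0)
  expect_gt(cor(ci$scores, m$rump_fat), 0) # higher score = better condition

  # the orientation rule neutralizes PCA's arbitrary component sign:
  # column order must not matter, and the anchor loading is always positive
  ci_perm <- condition_index(m[, c("girth", "rump_fat")])
  expect_equal(unname(ci$scores), unname(ci_perm$scores), tolerance = 1e-10)
  expect_gt(ci_perm$loadings["rump_fat"], 0)

  m$const <- 1
  expect_warning(ci2 <- condition_index(m), "constant")
  expect_identical(ci2$dropped, "const")

  # isotropic data: PC1 explains ~1/p of the variance
  big <- as.data.frame(matrix(rnorm(4000), 1000, 4))
  ci3 <- condition_index(big, anchor = "V1")
  expect_lt(ci3$var_explained, 0.35)
})

test_that("permutation p-values are reproducible and never zero", {
  set.seed(55)
  m <- matrix(rpois(40, 10), 8) + rep(c(0, 20), each = 4)
  D <- bray_curtis(m)
  g <- rep(c("A", "B"), each = 4)
  p1 <- permanova(D, g, n_perm = 999, seed = 9)$terms$p_perm
  p2 <- permanova(D, g, n_perm = 999, seed = 9)$terms$p_perm
  expect_identical(p1, p2)
  expect_gte(p1[1], 1 / 1000)
})
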