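# Community statistics against closed forms, brute-force enumeration and
# independent implementations (vegan, lme4, base aov).

test_that("Shannon diversity matches the closed form", {
  expect_equal(shannon_diversity(rep(5, 4)), log(4))
  expect_equal(shannon_diversity(c(0, 7, 0)), 0)
  p <- (1:4) / 10
  expect_equal(shannon_diversity(1:4), -sum(p * log(p)))
  expect_equal(round(shannon_diversity(1:4), 4), 1.2799)
  expect_warning(h <- shannon_diversity(c(0, 0)), "all-zero")
  expect_true(is.na(h))
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  x <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  expect_equal(bray_curtis(x, transform = "none")["s1", "s2"], 1)
  y <- rbind(s1 = c(4, 1), s2 = c(1, 4))
  expect_equal(bray_curtis(y, transform = "sqrt")["s1", "s2"], 1 / 3)
  expect_equal(bray_curtis(rbind(a = 1:3, b = 1:3))["a", "b"], 0)

  set.seed(5)
  m <- matrix(rpois(60, 8), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  d <- bray_curtis(m, transform = "sqrt")
  expect_equal(max(abs(d - as.matrix(vegan::vegdist(sqrt(m))))), 0,
               tolerance = 1e-12)
  # metric axioms on the tested domain
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(a = -1, b = 1)), "non-negative")
  expect_warning(bray_curtis(rbind(a = c(0, 0), b = c(0, 0))), "all-zero")
})

test_that("NMDS recovers exact embeddings and tracks vegan's stress", {
  set.seed(6)
  P <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(P)); dimnames(D) <- list(paste0("s", 1:8),
                                               paste0("s", 1:8))
  o <- nmds(D, n_starts = 5, seed = 3)
  expect_lt(o$stress, 0.001)
  expect_true(all(diff(o$stress_trajectory) <= 1e-12))

  set.seed(8)
  m <- matrix(rpois(6 * 12, 10), 6, 12, dimnames = list(paste0("s", 1:6), NULL))
  d6 <- bray_curtis(m)
  ours <- nmds(d6, n_starts = 20, seed = 1)
  ref <- vegan::metaMDS(stats::as.dist(d6), k = 2, trace = 0,
                        try = 20, trymax = 20)
  expect_lt(abs(ours$stress - ref$stress), 0.01)
})

test_that("PERMANOVA matches vegan and exhaustive enumeration", {
  set.seed(9)
  m <- matrix(rpois(12 * 18, 9), 12, 18,
              dimnames = list(paste0("s", 1:12), NULL))
  des <- data.frame(compartment = rep(c("bulk", "rhizosphere"), each = 6),
                    rotation = rep(c("continuous", "virgin"), 6))
  d <- bray_curtis(m)
  ours <- permanova(d, des, n_permutations = 999, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(d) ~ compartment + rotation,
                        data = des, permutations = 999, by = "terms")
  expect_equal(ours$f[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(ours$r2, ref$R2[1:3], tolerance = 1e-10)
  expect_equal(sum(ours$r2), 1, tolerance = 1e-9)
  expect_true(all(ours$p[1:2] > 0))

  # n = 6: permutation p identical to complete enumeration via vegan
  set.seed(10)
  m6 <- matrix(rpois(6 * 10, 8), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  des6 <- data.frame(compartment = rep(c("bulk", "rhizosphere"), 3))
  d6 <- bray_curtis(m6)
  ours6 <- permanova(d6, des6, terms = "compartment",
                     n_permutations = "exhaustive")
  ref6 <- vegan::adonis2(stats::as.dist(d6) ~ compartment, data = des6,
                         permutations = rhizovir:::all_perms(6)[-1, ])
  expect_equal(ours6$p[1], ref6$`Pr(>F)`[1], tolerance = 1e-12)

  # extreme separation: R^2 near 1, p at the add-one floor
  sep <- rbind(matrix(rpois(9, 200), 3, 3), matrix(rpois(9, 2), 3, 3))
  rownames(sep) <- paste0("s", 1:6)
  dsep <- bray_curtis(sep)
  psep <- permanova(dsep, data.frame(compartment = rep(c("a", "b"), each = 3)),
                    terms = "compartment", n_permutations = "exhaustive")
  expect_gt(psep$r2[1], 0.8)
  # only the 3!3!2 = 72 partition-preserving relabelings tie the max F
  expect_equal(psep$p[1], 72 / 720)
  expect_error(permanova(dsep, data.frame(compartment = rep("a", 6)),
                         terms = "compartment"), "single level")
})

test_that("Mantel matches brute-force enumeration and vegan", {
  set.seed(12)
  d1 <- bray_curtis(matrix(rpois(25, 9), 5, 5,
                           dimnames = list(paste0("s", 1:5), NULL)))
  d2 <- bray_curtis(matrix(rpois(25, 9), 5, 5,
                           dimnames = list(paste0("s", 1:5), NULL)))
  got <- mantel(d1, d2, n_permutations = "exhaustive")
  # independent oracle: direct enumeration of all 120 relabelings
  perms <- rhizovir:::all_perms(5)
  v1 <- d1[upper.tri(d1)]
  rs <- apply(perms, 1, function(p) cor(v1, d2[p, p][upper.tri(d2)]))
  expect_equal(got$r, rs[1], tolerance = 1e-12)
  expect_equal(got$p, mean(rs >= rs[1] - 1e-12), tolerance = 1e-12)

  expect_equal(mantel(d1, d1, n_permutations = 99, seed = 1)$r, 1)
  set.seed(13)
  da <- bray_curtis(matrix(rpois(80, 9), 8, 10,
                           dimnames = list(paste0("s", 1:8), NULL)))
  db <- bray_curtis(matrix(rpois(80, 9), 8, 10,
                           dimnames = list(paste0("s", 1:8), NULL)))
  expect_equal(mantel(da, db, n_permutations = 99, seed = 1)$r,
               unname(vegan::mantel(stats::as.dist(da), stats::as.dist(db),
                                    permutations = 0)$statistic),
               tolerance = 1e-12)
  cd <- matrix(0.5, 4, 4); diag(cd) <- 0
  expect_warning(mantel(cd, cd, 9), "constant")
})

test_that("two-way ANOVA and Tukey HSD match base R", {
  set.seed(14)
  fA <- gl(3, 8); fB <- gl(2, 4, 24)
  y <- rnorm(24) + as.numeric(fA) + 0.5 * as.numeric(fB)
  ours <- two_way_anova(y, fA, fB)
  ref <- summary(stats::aov(y ~ fA + fB))[[1]]
  expect_equal(ours$anova$f[1:2], ref$`F value`[1:2], tolerance = 1e-10)
  expect_equal(ours$anova$p[1:2], ref$`Pr(>F)`[1:2], tolerance = 1e-10)
  tk <- stats::TukeyHSD(stats::aov(y ~ fA + fB))$fA
  expect_equal(ours$tukey$A$p_adj, unname(tk[, "p adj"]), tolerance = 1e-8)
  expect_equal(ours$tukey$A$diff, unname(tk[, "diff"]), tolerance = 1e-10)

  # interaction term agrees too
  oi <- two_way_anova(y, fA, fB, interaction = TRUE)
  ri <- summary(stats::aov(y ~ fA * fB))[[1]]
  expect_equal(oi$anova$f[1:3], ri$`F value`[1:3], tolerance = 1e-10)

  # constant response: F = 0, p = 1
  oc <- two_way_anova(rep(2, 24), fA, fB)
  expect_equal(oc$anova$f[1:2], c(0, 0))
  expect_equal(oc$anova$p[1:2], c(1, 1))

  # single-level factorB collapses to one-way ANOVA
  o1 <- two_way_anova(y, fA, factor(rep("x", 24)))
  r1 <- summary(stats::aov(y ~ fA))[[1]]
  expect_equal(o1$anova$f[1], r1$`F value`[1], tolerance = 1e-10)
  expect_error(two_way_anova(y[1:8], gl(2, 4), gl(2, 4),
                             interaction = TRUE), "empty design cell")
})

test_that("REML mixed model matches lme4, closed forms and OLS limits", {
  dd <- simulate_ktw(54, slope = -0.039, seed = 8)
  fit <- fit_random_intercept_lmm(dd$y, dd$x, dd$compartment)
  lf <- lme4::lmer(y ~ x + (1 | compartment), data = dd, REML = TRUE)
  expect_equal(fit$slope, unname(lme4::fixef(lf)[2]), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(c(fit$sigma2_group, fit$sigma2_resid), vc, tolerance = 1e-4)
  expect_equal(fit$slope_se, sqrt(stats::vcov(lf)[2, 2]), tolerance = 1e-6)
  expect_true(fit$slope_df > 1 && fit$slope_df <= 52)

  # balanced intercept-only fit equals the closed-form ANOVA estimators
  set.seed(15)
  g <- gl(4, 6)
  yb <- rnorm(24) + rep(rnorm(4, 0, 1.5), each = 6)
  f2 <- fit_random_intercept_lmm(yb, NULL, g)
  av <- stats::anova(stats::aov(yb ~ g))
  msb <- av["g", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
  expect_equal(f2$sigma2_resid, msw, tolerance = 1e-6)
  expect_equal(f2$sigma2_group, max((msb - msw) / 6, 0), tolerance = 1e-6)

  # zero group variance: slope within 2 SE of OLS, variance component ~ 0
  set.seed(16)
  xd <- rnorm(80); yd <- 1 + 0.5 * xd + rnorm(80, 0, 0.3)
  gd <- gl(10, 8)
  f3 <- fit_random_intercept_lmm(yd, xd, gd)
  ols <- stats::coef(stats::lm(yd ~ xd))[2]
  expect_lt(abs(f3$slope - ols), 2 * f3$slope_se)
  expect_lt(f3$sigma2_group, 0.05)
  expect_error(fit_random_intercept_lmm(yd, rep(1, 80), gd), "singular")
})
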