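test_that("square-root transform applies to root traits only and rejects negatives", {
  expect_equal(transform_trait(c(0, 1, 4, 9), "No_Lat_1st"), c(0, 1, 2, 3))
  expect_equal(transform_trait(c(0, 1, 4, 9), "ER_Cr"), c(0, 1, 2, 3))
  expect_equal(transform_trait(c(-3, 7), "ER_S"), c(-3, 7))  # shoot: identity
  expect_equal(transform_trait(c(5, 2), "SPAD"), c(5, 2))
  expect_error(transform_trait(c(1, -0.1), "Med_Lat_2nd"), "negative")
})

test_that("zero-noise data identify the generating fixed effects exactly", {
  tt <- trial_truth(n_genotypes = 4, n_reps = 2, mu = 10,
                    genotype_effects = c(-1, 0, 0.5, 0.5),
                    gn_effects = cbind(high = c(0.2, -0.2, 0, 0),
                                       low = c(-0.2, 0.2, 0, 0)),
                    n_effect = 2, rep_effects = c(0.3, -0.3),
                    side_effects = c(0.1, -0.1),
                    sigma2_GR = 0, sigma2_e = c(high = 0, low = 0))
  tab <- simulate_trial(tt, trait = "ER_Cr", seed = 1)
  fit <- fit_mixed(tab, model_spec("ER_Cr", transform = "none"))
  expect_equal(unname(fit$beta["(Intercept)"]), 10, tolerance = 1e-10)
  expect_equal(unname(fit$varcomp$sigma2_GR), 0)
  expect_equal(unname(fit$varcomp$sigma2_e), c(0, 0))
  # sum-to-zero coding: first genotype coefficient equals its effect
  expect_equal(unname(fit$beta["G1"]), -1, tolerance = 1e-10)
  expect_equal(unname(fit$beta["N1"]), 1, tolerance = 1e-10)  # high = +n_effect/2
})

test_that("REML matches ANOVA expected-mean-square estimators on balanced one-way data", {
  set.seed(61)
  for (i in 1:5) {
    g <- gl(10, 4)
    y <- rnorm(40, mean = rep(rnorm(10, 0, 2), each = 4), sd = 1)
    fit <- reml_fit(y, matrix(1, 40, 1), group = g)
    mom <- oracle_oneway_components(y, g)
    if (mom["sigma2_g"] > 0) {
      expect_equal(fit$sigma2_u, unname(mom["sigma2_g"]), tolerance = 1e-5)
      expect_equal(unname(fit$sigma2_e), unname(mom["sigma2_e"]), tolerance = 1e-5)
    } else {
      expect_equal(fit$sigma2_u, 0)
    }
  }
})

test_that("per-slide model F statistics equal two-way ANOVA on balanced data", {
  set.seed(62)
  tab <- trait_table(genotype = rep(sprintf("G%d", 1:8), each = 4),
                     n_level = "none", replicate = rep(1:4, 8), side = "none",
                     trait = "DW_S", value = rnorm(32, 5), units = "g")
  fit <- fit_mixed(tab, model_spec("DW_S", type = "per_slide"))
  ref <- anova(aov(value ~ factor(genotype) + factor(replicate),
                   data = as.data.frame(tab)))
  expect_lt(max(abs(fit$anova$F - ref$`F value`[1:2])), 1e-8)
  expect_equal(fit$anova$df, ref$Df[1:2])
  expect_equal(fit$anova$ddf, rep(ref$Df[3], 2))
})

test_that("heterogeneous-variance REML recovers the generating components", {
  res <- vapply(1:60, function(i) {
    tt <- trial_truth(n_genotypes = 24, n_reps = 4, mu = 10, sd_g = 0.5,
                      sigma2_GR = 1, sigma2_e = c(high = 2, low = 4), seed = i)
    tab <- simulate_trial(tt, trait = "X", seed = 5000 + i)
    fit <- fit_mixed(tab, model_spec("X", transform = "none"))
    c(fit$varcomp$sigma2_GR, fit$varcomp$sigma2_e)
  }, numeric(3))
  means <- rowMeans(res)
  expect_lt(abs(means[1] - 1) / 1, 0.08)
  expect_lt(abs(means[2] - 2) / 2, 0.08)
  expect_lt(abs(means[3] - 4) / 4, 0.08)
})

test_that("mixed fit agrees with nlme::lme on unbalanced heterogeneous data", {
  skip_if_not_installed("nlme")
  tt <- trial_truth(n_genotypes = 8, n_reps = 4, mu = 10, sd_g = 1, sd_gn = 0.4,
                    n_effect = 1.5, sigma2_GR = 0.5,
                    sigma2_e = c(high = 1, low = 2.5),
                    missing_rate = 0.1, seed = 9)
  tab <- simulate_trial(tt, trait = "X", seed = 10)
  fit <- fit_mixed(tab, model_spec("X", transform = "none"))
  d <- as.data.frame(tab)
  d$G <- factor(d$genotype); d$N <- factor(d$n_level, c("high", "low"))
  d$R <- factor(d$replicate); d$S <- factor(d$side)
  d$slide <- interaction(d$G, d$R, drop = TRUE)
  old <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(old))
  lfit <- nlme::lme(value ~ G + N + G:N + R + S, random = ~ 1 | slide,
                    weights = nlme::varIdent(form = ~ 1 | N), data = d,
                    control = nlme::lmeControl(opt = "optim"))
  s2_slide <- as.numeric(nlme::VarCorr(lfit)["(Intercept)", "Variance"])
  s2_resid <- lfit$sigma^2
  ratio <- coef(lfit$modelStruct$varStruct, unconstrained = FALSE, allCoef = TRUE)
  s2_by_n <- s2_resid * ratio[c("high", "low")]^2
  expect_equal(fit$varcomp$sigma2_GR, s2_slide, tolerance = 1e-4)
  expect_equal(unname(fit$varcomp$sigma2_e),
               unname(s2_by_n), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(nlme::fixef(lfit)[names(fit$beta)]),
               tolerance = 1e-5)
})

test_that("heritability formula clamps, bounds and responds monotonically", {
  expect_equal(heritability(3, 4, 4), 0.75)
  expect_equal(heritability(2, 4, 4), 2 / 3)
  expect_equal(heritability(0, 7, 4), 0)
  expect_equal(heritability(-0.3, 7, 4), 0)  # clamped
  expect_error(heritability(1, 1, 0), "positive")
  # monotone in sigma2_g and in r, always within [0, 1]
  h_prev <- -1
  for (s2g in seq(0, 5, by = 0.5)) {
    h <- heritability(s2g, 2, 4)
    expect_gte(h, h_prev); expect_gte(h, 0); expect_lte(h, 1)
    h_prev <- h
  }
  expect_gt(heritability(1, 2, 8), heritability(1, 2, 2))
})

test_that("Tukey HSD and the avsed-to-MSE inversion follow their closed forms", {
  expect_equal(tukey_hsd(4, 1, 4), 2)
  expect_equal(tukey_hsd(3.5, 0, 6), 0)
  expect_equal(mse_from_avsed(1, 2), 1)   # sed = sqrt(2 MSE / n) inverted
  expect_equal(tukey_hsd(2, mse_from_avsed(1, 2), 2), 2 * sqrt(0.5))
  expect_error(tukey_hsd(4, 1, 0), "n must be")
  expect_error(tukey_hsd(-1, 1, 4), "q must be")
})

test_that("BLUP summaries: correlations, PCA sign convention and degenerate traits", {
  set.seed(71)
  g <- sprintf("G%02d", 1:24)
  x <- rnorm(24)
  # two perfectly correlated traits: r = 1 and PC1 carries all shared variance
  b <- cbind(t1 = x, t2 = 2 * x + 3)
  rownames(b) <- g
  s <- blup_summaries(b)
  expect_equal(s$correlations["t1", "t2"], 1)
  expect_equal(s$var_explained[1], 1)
  expect_true(all(s$loadings[, 1] >= 0))  # largest loading made positive
  # hand-computed 3 x 2 Pearson
  b3 <- cbind(a = c(1, 2, 4), b = c(2, 1, 5)); rownames(b3) <- g[1:3]
  s3 <- blup_summaries(b3)
  manual <- sum((b3[, 1] - mean(b3[, 1])) * (b3[, 2] - mean(b3[, 2]))) /
    sqrt(sum((b3[, 1] - mean(b3[, 1]))^2) * sum((b3[, 2] - mean(b3[, 2]))^2))
  expect_equal(s3$correlations["a", "b"], manual)
  # independent traits: correlations stay small (sampling bound at n = 24)
  set.seed(72)
  bi <- matrix(rnorm(24 * 4), 24, 4,
               dimnames = list(g, paste0("u", 1:4)))
  si <- blup_summaries(bi)
  off <- si$correlations[upper.tri(si$correlations)]
  expect_true(all(abs(off) < 0.45))
  # zero-variance trait dropped with warning
  bz <- cbind(b, flat = rep(1, 24))
  expect_warning(sz <- blup_summaries(bz), "zero-variance")
  expect_false("flat" %in% colnames(sz$correlations))
})

test_that("genotype BLUPs shrink toward zero and sum to approximately zero", {
  tt <- trial_truth(n_genotypes = 12, n_reps = 4, mu = 10, sd_g = 1,
                    sigma2_GR = 0.2, sigma2_e = c(high = 1, low = 1), seed = 5)
  tab <- simulate_trial(tt, trait = "IC_Cr", seed = 6)
  tab$value <- abs(tab$value)  # keep sqrt transform applicable
  b <- genotype_blups(tab)
  expect_equal(dim(b), c(12L, 1L))
  expect_lt(abs(sum(b[, 1])), 1e-6 * max(abs(b[, 1])) * 12 + 1e-8)
})
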