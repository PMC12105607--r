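test_that("midrank averages ties and conserves the rank sum", {
  expect_equal(midrank(c(1.2, 3.4, 3.4, 5.0)), c(1, 2.5, 2.5, 4))
  x <- c(9, 2, 7, 1, 5)
  expect_setequal(midrank(x), 1:5)
  expect_equal(midrank(rep(3, 5)), rep(3, 5))
  for (n in c(3, 10, 27)) {
    set.seed(n)
    expect_equal(sum(midrank(sample(round(rnorm(n), 1)))),
                 n * (n + 1) / 2)
  }
})

test_that("Lilliefors D is location-scale invariant and matches nortest", {
  skip_if_not_installed("nortest")
  set.seed(101)
  x <- rnorm(40, 5, 3)
  D1 <- focalsna:::lilliefors_D(x)
  D2 <- focalsna:::lilliefors_D(2.7 * x - 13)
  expect_equal(D1, D2)
  expect_equal(D1, unname(nortest::lillie.test(x)$statistic))
})

test_that("normality screen calibrates on normal and bimodal samples", {
  # normal data exceeds the 0.15 reporting cap at the calibrated frequency:
  # the Monte Carlo p is uniform under the null, so P(p > 0.15) = 0.85
  set.seed(7)
  res_norm <- vapply(1:100, function(i) {
    ks_normality(rnorm(50), n_mc = 1500, seed = 1000 + i)$bound == ">0.15"
  }, logical(1))
  expect_gte(mean(res_norm), 0.75)
  # ... and a strong bimodal mixture should land below 0.01
  res_bi <- vapply(1:60, function(i) {
    x <- c(rnorm(25, -3, 0.5), rnorm(25, 3, 0.5))
    ks_normality(x, n_mc = 1500, seed = 2000 + i)$bound == "<0.01"
  }, logical(1))
  expect_gte(mean(res_bi), 0.9)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("planned contrasts are orthogonal and partition the between-SS", {
  cm <- context_contrasts()
  expect_equal(rowSums(cm), setNames(rep(0, 3), rownames(cm)))
  expect_equal(unname(cm %*% t(cm))[lower.tri(diag(3))], rep(0, 3))

  # balanced design: contrast SS must sum to the between-groups SS
  set.seed(55)
  y <- rnorm(24, rep(c(10, 12, 9, 11), each = 6))
  ctx <- factor(rep(context_levels(), each = 6), levels = context_levels())
  res <- anova_oneway_contrasts(y, ctx, rank_response = FALSE)
  yb <- tapply(y, ctx, mean)
  ss_between <- 6 * sum((yb - mean(y))^2)
  expect_equal(sum(res$contrasts$ss), ss_between, tolerance = 1e-9)
})

test_that("omnibus F matches a direct sums-of-squares oracle", {
  y <- c(4.1, 5.2, 3.9, 7.7, 8.0, 6.9, 2.2, 2.8, 3.0, 5.5, 6.1, 5.0)
  ctx <- factor(rep(context_levels(), each = 3), levels = context_levels())
  res <- anova_oneway_contrasts(y, ctx, rank_response = FALSE)
  # brute-force decomposition
  gm <- mean(y)
  ssb <- sum(tapply(y, ctx, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, ctx, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ssb / 3) / (ssw / 8)
  expect_equal(res$omnibus$F, F_oracle, tolerance = 1e-12)
  expect_equal(res$omnibus$df1, 3)
  expect_equal(res$omnibus$df2, 8)

  # rank invariance: any strictly monotone transform leaves results alone
  res_rank <- anova_oneway_contrasts(y, ctx)
  res_exp <- anova_oneway_contrasts(exp(2 * y), ctx)
  expect_equal(res_rank$omnibus$F, res_exp$omnibus$F)
  expect_equal(res_rank$contrasts$F, res_exp$contrasts$F)
})

test_that("degenerate all-equal input yields zero F throughout", {
  y <- rep(5, 16)
  ctx <- factor(rep(context_levels(), each = 4), levels = context_levels())
  res <- anova_oneway_contrasts(y, ctx)
  expect_equal(res$omnibus$F, 0)
  expect_equal(res$contrasts$F, rep(0, 3))
  tw <- anova_twoway_ranks(y, rep(c("DF", "other"), 8), ctx)
  expect_true(all(tw$F == 0))
})

test_that("a contrast naming an absent context errors by name", {
  y <- rnorm(12)
  ctx <- factor(rep(c("neutral", "post_outburst", "post_intragroup"),
                    each = 4))
  expect_error(anova_oneway_contrasts(y, ctx),
               "nonconflict_vs_conflict.*post_intergroup")
})

test_that("two-way rank ANOVA: Type III equals Type I under balance", {
  set.seed(77)
  dat <- expand.grid(dominance = c("DF", "other"),
                     context = context_levels(),
                     rep = 1:5)
  dat$y <- rnorm(nrow(dat), ifelse(dat$dominance == "DF", 1, 0) +
                   as.numeric(factor(dat$context)))
  res3 <- anova_twoway_ranks(dat$y, dat$dominance, dat$context, ss_type = 3)
  # Type I on the same ranked response
  r <- midrank(dat$y)
  fit <- lm(r ~ dominance * context, data = dat)
  a1 <- anova(fit)
  expect_equal(res3$F[res3$effect == "dominance"], a1["dominance", "F value"],
               tolerance = 1e-9)
  expect_equal(res3$F[res3$effect == "context"], a1["context", "F value"],
               tolerance = 1e-9)
  expect_equal(res3$F[res3$effect == "dominance:context"],
               a1["dominance:context", "F value"], tolerance = 1e-9)
})

test_that("two-way model F matches a full-vs-null residual-SS oracle", {
  set.seed(78)
  # unbalanced: unequal cell sizes
  dat <- data.frame(
    dominance = sample(c("DF", "other"), 60, TRUE, prob = c(.25, .75)),
    context = sample(context_levels(), 60, TRUE))
  dat$y <- rnorm(60)
  res <- anova_twoway_ranks(dat$y, dat$dominance, dat$context)
  r <- midrank(dat$y)
  fit_full <- lm(r ~ interaction(dat$dominance, dat$context))
  rss_full <- sum(residuals(fit_full)^2)
  rss_null <- sum((r - mean(r))^2)
  k <- length(unique(interaction(dat$dominance, dat$context)))
  F_oracle <- ((rss_null - rss_full) / (k - 1)) /
    (rss_full / (60 - k))
  expect_equal(res$F[res$effect == "model"], F_oracle, tolerance = 1e-9)
  expect_equal(res$df1[res$effect == "model"], k - 1)
})

test_that("contexts observed for only one dominance class are dropped", {
  set.seed(79)
  dat <- expand.grid(dominance = c("DF", "other"),
                     context = c("neutral", "post_outburst"), rep = 1:4)
  extra <- data.frame(dominance = "other", context = "post_intergroup",
                      rep = 1:4)
  dat <- rbind(dat[, 1:2], extra[, 1:2])
  y <- rnorm(nrow(dat))
  expect_warning(
    res <- anova_twoway_ranks(y, dat$dominance, dat$context),
    "empty dominance cell")
  expect_equal(res$df1[res$effect == "context"], 1)
})

test_that("Spearman validation behaves at its edge cases and oracle", {
  a <- c(3, 9, 1, 7, 5, 6, 2, 8, 4, 10)
  expect_equal(spearman_affiliation(a, a)$rho, 1)
  expect_equal(spearman_affiliation(a, -a)$rho, -1)
  set.seed(91)
  b <- rnorm(10)
  res <- spearman_affiliation(a, b)
  # definition equivalence: Spearman rho is Pearson on midranks
  expect_equal(res$rho, cor(midrank(a), midrank(b)))
  expect_error(spearman_affiliation(rep(1, 10), b), "zero variance")
  expect_error(spearman_affiliation(a[1:4], b[1:4]), "at least 5")
})
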