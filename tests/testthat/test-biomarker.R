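cohort_fixture <- function(seed = 1, n_healthy = 10, n_gdm = 6,
                           sigma = 0.3,
                           effects = c(sFLT1 = 3.1, MIF = 1,
                                       ANGPT2 = 1.97, IGF2 = 1)) {
  cfg <- sim_config(n_healthy = n_healthy, n_gdm = n_gdm,
                    biomarker_sigma = sigma, gdm_effects = effects,
                    seed = seed)
  set.seed(seed)
  generate_biomarker_cohort(cfg)
}

test_that("healthy-group MoM median is exactly 1 in every stratum", {
  tab <- cohort_fixture(2)
  moms <- compute_mom(tab, "healthy")
  agg <- aggregate(mom ~ week + analyte,
                   moms[moms$group == "healthy", ], median)
  expect_equal(agg$mom, rep(1, nrow(agg)))
})

test_that("MoM values are invariant to per-analyte unit rescaling", {
  tab <- cohort_fixture(3)
  scaled <- tab
  scale_of <- c(sFLT1 = 1000, MIF = 0.01, ANGPT2 = 7, IGF2 = 1)
  scaled$concentration <- scaled$concentration * scale_of[scaled$analyte]
  expect_equal(compute_mom(tab)$mom, compute_mom(scaled)$mom)
})

test_that("MoM rejects an empty reference stratum by name", {
  tab <- cohort_fixture(4)
  tab <- tab[!(tab$group == "healthy" & tab$analyte == "MIF" &
                 tab$week == 28), ]
  expect_error(compute_mom(tab), "28.MIF")
})

test_that("MoM ratios divide per subject and exclude incomplete subjects", {
  tab <- cohort_fixture(5)
  moms <- compute_mom(tab)
  r <- mom_ratio(moms, "sFLT1", "MIF")
  one <- moms[moms$subject == "H001" & moms$week == 12, ]
  expect_equal(r$ratio[r$subject == "H001" & r$week == 12],
               one$mom[one$analyte == "sFLT1"] / one$mom[one$analyte == "MIF"])
  same <- mom_ratio(moms, "MIF", "MIF")
  expect_true(all(same$ratio == 1))
  # drop one subject's MIF measurements: excluded from the ratio
  moms2 <- moms[!(moms$subject == "H002" & moms$analyte == "MIF"), ]
  r2 <- mom_ratio(moms2, "sFLT1", "MIF")
  expect_false("H002" %in% r2$subject)
  expect_equal(attr(r2, "n_excluded"), 2L)
})

test_that("percent increase matches its defining formula", {
  expect_equal(percent_increase(c(3.1, 3.1), c(1, 1)), 210)
  expect_equal(percent_increase(1:5, 1:5), 0)
  set.seed(9)
  a <- runif(20, 1, 5); b <- runif(15, 1, 5)
  expect_equal(percent_increase(a, b),
               100 * (mean(a) - mean(b)) / mean(b))
})

test_that("t-test reproduces the closed-form pooled computation", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- two_sample_ttest(a, b, "student")
  # pooled: sp2 = 1, se = sqrt(2/3), t = -3/se
  t_exact <- -3 / sqrt(2 / 3)
  expect_equal(res$t, t_exact, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(t_exact, 4), tolerance = 1e-10)
  same <- suppressWarnings(two_sample_ttest(c(2, 2), c(2, 2)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("two-way ANOVA on a null balanced design gives zero F", {
  # identical cell patterns: every mean equals the grand mean exactly
  vals <- rep(c(-1, 1), 8)
  g <- rep(c("healthy", "GDM"), each = 8)
  w <- rep(rep(c(12, 28), each = 4), 2)
  res <- two_way_anova(vals, g, w)
  expect_equal(res$F, rep(0, 3), tolerance = 1e-12)
  expect_equal(res$p, rep(1, 3), tolerance = 1e-12)
})

test_that("one-week ANOVA reduces to the squared pooled t statistic", {
  set.seed(12)
  vals <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  res <- two_way_anova(vals, g, rep(12, 20))
  tt <- two_sample_ttest(vals[g == "a"], vals[g == "b"], "student")
  expect_equal(res$F, tt$t^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p, tolerance = 1e-10)
})

test_that("balanced two-way ANOVA matches the closed-form decomposition", {
  # 2x2 balanced toy, 3 replicates per cell
  cells <- expand.grid(g = c("A", "B"), w = c("w1", "w2"))
  mu <- c(10, 12, 14, 13)
  vals <- unlist(lapply(seq_len(4), function(i) mu[i] + c(-1, 0, 1)))
  g <- rep(cells$g, each = 3)
  w <- rep(cells$w, each = 3)
  res <- two_way_anova(vals, g, w)
  # hand decomposition (balanced: type II == type I)
  n <- 3; gm <- mean(mu)
  ss_g <- 2 * n * sum((tapply(mu, cells$g, mean) - gm)^2)
  ss_w <- 2 * n * sum((tapply(mu, cells$w, mean) - gm)^2)
  ss_int <- n * sum((mu - rep(tapply(mu, cells$g, mean), 2) -
                       rep(tapply(mu, cells$w, mean), each = 2) + gm)^2)
  mse <- sum(rep(c(-1, 0, 1), 4)^2) / (12 - 4)
  expect_equal(res$F, c(ss_g, ss_w, ss_int) / mse, tolerance = 1e-10)
  expect_error(two_way_anova(vals[-(1:3)], g[-(1:3)], w[-(1:3)]),
               "empty cell")
})

test_that("summary t-test agrees with a moment-matched sample test", {
  set.seed(22)
  for (variant in c("student", "welch")) {
    n1 <- 8; n2 <- 11
    m1 <- runif(1, 0, 10); m2 <- runif(1, 0, 10)
    s1 <- runif(1, 0.5, 2); s2 <- runif(1, 0.5, 2)
    # construct samples with exactly these means and SDs
    z1 <- scale(rnorm(n1)); z2 <- scale(rnorm(n2))
    a <- m1 + s1 * z1 * sqrt((n1 - 1) / (n1 - 1))
    b <- m2 + s2 * z2
    full <- two_sample_ttest(as.numeric(a), as.numeric(b), variant)
    summ <- summary_ttest(m1, s1 / sqrt(n1), n1, m2, s2 / sqrt(n2), n2,
                          variant)
    expect_equal(summ$t, full$t, tolerance = 1e-8)
    expect_equal(summ$df, full$df, tolerance = 1e-8)
    expect_equal(summ$p, full$p, tolerance = 1e-8)
  }
  expect_equal(summary_ttest(10, 1, 5, 10, 1, 5)$t, 0)
})

test_that("a planted 3.1x effect yields a ~210 percent MoM-ratio increase at n=200", {
  tab <- cohort_fixture(7, n_healthy = 200, n_gdm = 200)
  moms <- compute_mom(tab)
  r <- mom_ratio(moms, "sFLT1", "MIF")
  r12 <- r[r$week == 12, ]
  inc <- percent_increase(r12$ratio[r12$group == "GDM"],
                          r12$ratio[r12$group == "healthy"])
  expect_lt(abs(inc - 210), 0.15 * 210)
})
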