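test_that("one-way ANOVA matches the hand-computed table", {
  a <- one_way_anova(c(2, 4, 6, 8), c("g1", "g1", "g2", "g2"))
  expect_equal(a$F, 8)
  expect_equal(c(a$df1, a$df2), c(1, 2))
  expect_equal(a$ms_effect, 16)
  expect_equal(a$ms_error, 2)

  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  deg <- one_way_anova(c(0, 0, 1, 1), rep(c("a", "b"), each = 2))
  expect_true(deg$degenerate)
  expect_equal(deg$F, Inf)
})

test_that("one-way F equals t squared for two groups", {
  set.seed(51)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = 0.5)
    av <- one_way_anova(c(a, b), rep(c("x", "y"), c(length(a), length(b))))
    tt <- unpaired_t(a, b)
    expect_equal(av$F, tt$t^2, tolerance = 1e-10)
    expect_equal(av$p, tt$p, tolerance = 1e-10)
  }
})

test_that("pooled t-test matches hand arithmetic and flags degeneracy", {
  tt <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-10)  # -3.674
  expect_equal(tt$df, 4)

  eq <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  deg <- unpaired_t(c(0, 0), c(1, 1))
  expect_true(deg$degenerate)

  w <- unpaired_t(c(1, 2, 3), c(4, 5, 6, 7, 20), welch = TRUE)
  expect_lt(w$df, 6)  # Welch df shrink under variance heterogeneity
})

test_that("Fisher's LSD reuses the pooled MSE with no adjustment", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("g1", "g2", "g3"), each = 2)
  lsd <- fisher_lsd(v, g)
  expect_equal(nrow(lsd), 3)
  r <- lsd[lsd$group1 == "g1" & lsd$group2 == "g3", ]
  expect_equal(r$t, -4 / sqrt(0.5 * 1), tolerance = 1e-10)  # |t| = 5.657
  expect_equal(r$df, 3)

  # two groups: LSD p identical to the pooled two-sample t-test p
  set.seed(52)
  a <- rnorm(5); b <- rnorm(6, 1)
  lsd2 <- fisher_lsd(c(a, b), rep(c("a", "b"), c(5, 6)))
  expect_equal(lsd2$p, unpaired_t(a, b)$p, tolerance = 1e-10)

  ident <- fisher_lsd(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("mixed ANOVA agrees with the textbook split-plot oracle", {
  set.seed(53)
  for (i in 1:10) {
    k <- sample(3:4, 1)
    d <- balanced_rm_data(n_per_group = sample(4:6, 1), k = k)
    res <- mixed_anova_gg(d, gg = "never")
    or <- oracle_split_plot(d)
    expect_equal(res$group$F, or$F_group, tolerance = 1e-8)
    expect_equal(res$phase$F, or$F_phase, tolerance = 1e-8)
    expect_equal(res$group_by_phase$F, or$F_inter, tolerance = 1e-8)
    expect_equal(c(res$group$df1, res$group$df2), or$df$group)
    expect_equal(c(res$phase$df1, res$phase$df2), or$df$phase)
    expect_equal(c(res$group_by_phase$df1, res$group_by_phase$df2),
                 or$df$inter)
  }
})

test_that("with two phases the interaction F is the squared two-sample t on differences", {
  set.seed(54)
  d <- balanced_rm_data(n_per_group = 6, k = 2)
  res <- mixed_anova_gg(d)
  wide <- reshape(d, idvar = c("animal", "group"), timevar = "phase",
                  direction = "wide")
  diffs <- wide$value.p2 - wide$value.p1
  tt <- unpaired_t(diffs[wide$group == "A"], diffs[wide$group == "B"])
  expect_equal(res$group_by_phase$F, tt$t^2, tolerance = 1e-8)
  expect_equal(res$group_by_phase$eps, 1)  # k = 2: sphericity trivially holds
})

test_that("GG epsilon is 1 under an exactly compound-symmetric covariance", {
  set.seed(55)
  k <- 4
  S <- diag(k) + 0.5
  gen <- function(n, k) exact_cov_matrix(n, S) +
    matrix(rnorm(n), n, k)  # per-subject shifts leave within-cov structure
  d <- balanced_rm_data(n_per_group = 8, k = k,
                        gen = function(n, k) exact_cov_matrix(n, S))
  res <- mixed_anova_gg(d)
  expect_equal(res$phase$eps, 1, tolerance = 1e-6)
})

test_that("GG epsilon stays in its bounds and the correction is conservative", {
  set.seed(56)
  seen_rejection <- 0
  for (i in 1:10) {
    k <- sample(3:5, 1)
    # inject a phase effect so small p-values occur
    d <- balanced_rm_data(n_per_group = 6, k = k,
      gen = function(n, k) matrix(rnorm(n * k), n, k) +
        matrix(seq(0, 2, length.out = k), n, k, byrow = TRUE))
    res <- mixed_anova_gg(d, gg = "always")
    for (eff in list(res$phase, res$group_by_phase)) {
      expect_gte(eff$eps, 1 / (k - 1) - 1e-12)
      expect_lte(eff$eps, 1 + 1e-12)
      # in the rejection region the correction can only raise the p-value
      if (eff$p <= 0.1) {
        seen_rejection <- seen_rejection + 1
        expect_gte(eff$p_gg, eff$p - 1e-12)
      }
    }
  }
  expect_gt(seen_rejection, 0)
})

test_that("tests are invariant to group relabeling", {
  set.seed(57)
  v <- rnorm(12); g <- rep(c("a", "b", "c"), each = 4)
  relab <- c(a = "z3", b = "z1", c = "z2")[g]
  a1 <- one_way_anova(v, g); a2 <- one_way_anova(v, relab)
  expect_equal(a1$F, a2$F)
  expect_equal(a1$p, a2$p)
  tt1 <- unpaired_t(v[g == "a"], v[g == "b"])
  tt2 <- unpaired_t(v[g == "b"], v[g == "a"])
  expect_equal(tt1$t, -tt2$t)
  expect_equal(tt1$p, tt2$p)
})

test_that("mean +/- 2 SD exclusion is single-pass and hand-checkable", {
  ex <- exclude_outliers(c(0, 0, 0, 0, 0, 100))
  expect_equal(ex$excluded, 100)
  expect_equal(ex$mean, 100 / 6, tolerance = 1e-10)
  expect_equal(ex$sd, sqrt(5000 / 3), tolerance = 1e-10)  # 40.82
  expect_equal(length(ex$retained), 5)

  expect_equal(exclude_outliers(c(1, 2, 3))$excluded, numeric(0))
  expect_equal(exclude_outliers(rep(4, 5))$excluded, numeric(0))
  expect_error(exclude_outliers(c(1, 2)), "three")
})

test_that("listwise deletion drops incomplete animals with a warning", {
  d <- balanced_rm_data(n_per_group = 4, k = 3)
  d$value[d$animal == "A1" & d$phase == "p2"] <- NA
  expect_warning(res <- mixed_anova_gg(d), "listwise")
  expect_equal(res$group$df2, 5)  # 7 animals - 2 groups
})
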