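test_that("pearson_corr reproduces closed-form values and base R", {
  expect_equal(pearson_corr(1:10, 1:10)$statistic, 1)
  expect_equal(pearson_corr(1:10, -(1:10))$statistic, -1)

  r <- pearson_corr(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$statistic, 3 / sqrt(2 * 14 / 3), tolerance = 1e-10)
  expect_equal(r$statistic, 0.98198, tolerance = 1e-5)

  set.seed(3)
  x <- stats::rnorm(25); y <- 0.4 * x + stats::rnorm(25)
  got <- pearson_corr(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  expect_error(pearson_corr(rep(1, 5), 1:5), "zero variance")
})

test_that("paired_t matches hand computation and base R", {
  same <- c(0.4, 0.7, 1.1)
  z <- paired_t(same, same)
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)

  # differences (1, 2, 3): t = 2 / (1/sqrt(3))
  t1 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(t1$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(t1$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(t1$df, 2L)

  set.seed(4)
  a <- stats::rnorm(15, 1); b <- stats::rnorm(15)
  ref <- stats::t.test(a, b, paired = TRUE)
  got <- paired_t(a, b)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("unpaired_t matches base R in pooled and Welch forms", {
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(unpaired_t(c(0, 0), c(1, 1)), "zero variance")

  set.seed(5)
  a <- stats::rnorm(12, 0.5, 1); b <- stats::rnorm(20, 0, 2)
  for (ev in c(TRUE, FALSE)) {
    got <- unpaired_t(a, b, equal_var = ev)
    ref <- stats::t.test(a, b, var.equal = ev)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mood's median test builds the 2x2 table and its chi-square", {
  m <- moods_median(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(m$statistic, 8)
  expect_equal(m$p, 0.00468, tolerance = 1e-3)
  expect_equal(m$p, stats::pchisq(8, 1, lower.tail = FALSE))

  same <- moods_median(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)

  expect_error(moods_median(rep(1, 4), rep(1, 6)), "degenerate")

  # random instances: equal to brute-force table construction fed to the
  # generic Pearson chi-square (continuity correction off)
  set.seed(6)
  for (i in 1:50) {
    a <- stats::rnorm(sample(5:40, 1))
    b <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1))
    gm <- stats::median(c(a, b))
    tab <- rbind(c(sum(a > gm), sum(a <= gm)), c(sum(b > gm), sum(b <= gm)))
    if (any(colSums(tab) == 0)) next
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    got <- moods_median(a, b)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("split-plot ANOVA equals the explicit-loop SS oracle", {
  # balanced 2-group x 3-level toy data
  set.seed(7)
  vals <- matrix(stats::rnorm(8 * 3), nrow = 8)
  vals[5:8, ] <- vals[5:8, ] + 1
  vals[, 2] <- vals[, 2] + 0.5
  grp <- rep(c("ctl", "dec"), each = 4)
  got <- mixed_anova(vals, grp)
  want <- oracle_split_plot_ss(vals, grp)
  tab <- got$table
  expect_equal(tab$SS[tab$term == "group"], want$group, tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "subjects_within_groups"], want$subj_within,
               tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "within"], want$time, tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "group_x_within"], want$interaction,
               tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "within_x_subjects"], want$resid,
               tolerance = 1e-10)
  # SS add up and df are additive
  expect_equal(sum(tab$SS[1:5]), tab$SS[6], tolerance = 1e-9)
  expect_equal(sum(tab$df[1:5]), tab$df[6])
})

test_that("split-plot ANOVA agrees with aov error strata, balanced and not", {
  for (ns in list(c(4, 4), c(7, 3))) {
    set.seed(sum(ns))
    n <- sum(ns); Tn <- 4
    vals <- matrix(stats::rnorm(n * Tn), nrow = n) +
      stats::rnorm(n, sd = 0.7)                   # subject random effect
    grp <- rep(c("ctl", "dec"), times = ns)
    vals[grp == "dec", ] <- vals[grp == "dec", ] + 0.8
    got <- mixed_anova(vals, grp)

    df <- data.frame(y = as.vector(vals),
                     subj = factor(rep(seq_len(n), Tn)),
                     grp = factor(rep(grp, Tn)),
                     time = factor(rep(seq_len(Tn), each = n)))
    ref <- stats::aov(y ~ grp * time + Error(subj / time), data = df)
    s <- summary(ref)
    between <- s[["Error: subj"]][[1]]
    within <- s[["Error: subj:time"]][[1]]
    pick <- function(tab, term, col) tab[trimws(rownames(tab)) == term, col]
    expect_equal(got$F_between, pick(between, "grp", "F value"), tolerance = 1e-8)
    expect_equal(got$p_between, pick(between, "grp", "Pr(>F)"), tolerance = 1e-8)
    expect_equal(got$F_within, pick(within, "time", "F value"), tolerance = 1e-8)
    expect_equal(got$F_interaction, pick(within, "grp:time", "F value"),
                 tolerance = 1e-8)
    expect_equal(got$p_interaction, pick(within, "grp:time", "Pr(>F)"),
                 tolerance = 1e-8)
  }
})

test_that("parallel group profiles give a near-zero interaction F", {
  base <- matrix(rep(c(1, 2, 3), each = 6), nrow = 6)
  vals <- rbind(base[1:3, ], base[4:6, ] + 5)     # same pattern, shifted
  # subject deviations whose per-cell means vanish (residual variance but no
  # interaction), plus zero-mean subject offsets (between-subjects variance)
  D <- rbind(c(0.1, -0.2, 0.1), c(-0.1, 0.1, 0.0), c(0.0, 0.1, -0.1))
  vals <- vals + rbind(D, D) + c(0.3, 0, -0.3, 0.3, 0, -0.3)
  got <- mixed_anova(vals, rep(c("a", "b"), each = 3))
  expect_lt(got$F_interaction, 1e-6)
})

test_that("tests are invariant under the required affine transforms", {
  set.seed(9)
  a <- stats::rnorm(10, 1); b <- stats::rnorm(10)
  expect_equal(paired_t(a + 5, b + 5)$statistic, paired_t(a, b)$statistic,
               tolerance = 1e-9)
  expect_equal(unpaired_t(a * 2, b * 2)$statistic, unpaired_t(a, b)$statistic,
               tolerance = 1e-9)
  expect_equal(pearson_corr(3 * a + 1, b)$statistic,
               pearson_corr(a, b)$statistic, tolerance = 1e-12)

  vals <- matrix(stats::rnorm(24), nrow = 6)
  grp <- rep(c("x", "y"), each = 3)
  f1 <- mixed_anova(vals, grp)
  f2 <- mixed_anova(vals + 100, grp)
  expect_equal(f1$F_between, f2$F_between, tolerance = 1e-6)
  expect_equal(f1$F_within, f2$F_within, tolerance = 1e-6)
})

test_that("p values are uniform under the null for the continuous tests", {
  set.seed(10)
  reps <- 600
  p_pear <- replicate(reps, pearson_corr(stats::rnorm(10), stats::rnorm(10))$p)
  p_pair <- replicate(reps, paired_t(stats::rnorm(8), stats::rnorm(8))$p)
  p_unp <- replicate(reps, unpaired_t(stats::rnorm(8), stats::rnorm(10))$p)
  p_anova <- replicate(reps, {
    vals <- matrix(stats::rnorm(8 * 3), nrow = 8) + stats::rnorm(8, sd = 0.5)
    mixed_anova(vals, rep(c("a", "b"), each = 4))$p_between
  })
  for (p in list(p_pear, p_pair, p_unp, p_anova))
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("degenerate ANOVA inputs are rejected or dropped with notice", {
  vals <- matrix(stats::rnorm(12), nrow = 4)
  expect_error(mixed_anova(vals, c("a", "a", "a", "b")), "at least 2")
  vals2 <- rbind(vals, c(NA, 1, 2))
  expect_message(mixed_anova(vals2, c("a", "a", "b", "b", "b")), "dropping")
})
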