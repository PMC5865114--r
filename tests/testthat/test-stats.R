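test_that("between-only ANOVA reduces to the pooled t-test (F = t^2)", {
  set.seed(81)
  df <- data.frame(subject_id = sprintf("s%02d", 1:20),
                   group = rep(c("1d", "28d"), each = 10),
                   value = rnorm(20, rep(c(0, 0.8), each = 10)))
  res <- mixed_anova(df, "value", "group", character(), "subject_id")
  tt <- stats::t.test(value ~ group, df, var.equal = TRUE)
  expect_equal(res$F[res$effect == "group"], unname(tt$statistic)^2)
  expect_equal(res$p[res$effect == "group"], tt$p.value)
  # ges equals classical eta squared in the purely between design
  ss_b <- res$ss[res$effect == "group"]
  expect_equal(res$ges[res$effect == "group"],
               ss_b / (ss_b + res$ss_error[res$effect == "group"]))
})

test_that("mixed ANOVA agrees with the multivariate-lm oracle", {
  skip_if_not_installed("car")
  set.seed(82)
  n <- 10
  df <- expand.grid(subject_id = sprintf("s%02d", 1:(2 * n)),
                    pt = c("old", "related", "novel"),
                    em = c("neg", "neu"))
  df$group <- ifelse(as.integer(sub("s", "", df$subject_id)) <= n,
                     "1d", "28d")
  df$value <- rnorm(nrow(df)) + (df$pt == "old") * 0.6 +
    (df$group == "28d") * 0.4 + (df$pt == "old") * (df$group == "28d") * 0.3
  res <- mixed_anova(df, "value", "group", c("pt", "em"), "subject_id")

  df2 <- df[order(df$subject_id, df$pt, df$em), ]
  Y <- matrix(df2$value, nrow = 2 * n, byrow = TRUE)
  grp <- factor(tapply(as.character(df2$group), df2$subject_id, `[`, 1))
  contrasts(grp) <- stats::contr.sum(2)
  idata <- data.frame(pt = factor(rep(c("old", "related", "novel"),
                                      each = 2)),
                      em = factor(rep(c("neg", "neu"), 3)))
  aa <- suppressWarnings(summary(
    car::Anova(stats::lm(Y ~ grp), idata = idata, idesign = ~ pt * em,
               type = 3), multivariate = FALSE))
  ut <- aa$univariate.tests
  map <- c(group = "grp", pt = "pt", "group:pt" = "grp:pt", em = "em",
           "group:em" = "grp:em", "pt:em" = "pt:em",
           "group:pt:em" = "grp:pt:em")
  for (eff in names(map)) {
    i <- which(res$effect == eff)
    expect_equal(res$F[i], ut[map[[eff]], "F value"], tolerance = 1e-8,
                 info = eff)
    expect_equal(res$p[i], ut[map[[eff]], "Pr(>F)"], tolerance = 1e-8,
                 info = eff)
  }
  # sphericity: Mauchly W and Greenhouse-Geisser epsilon / corrected p
  sph <- aa$sphericity.tests
  adj <- aa$pval.adjustments
  i_pt <- which(res$effect == "pt")
  expect_equal(res$mauchly_w[i_pt], sph["pt", "Test statistic"],
               tolerance = 1e-6)
  expect_equal(res$mauchly_p[i_pt], sph["pt", "p-value"], tolerance = 1e-6)
  expect_equal(res$gg_epsilon[i_pt], adj["pt", "GG eps"], tolerance = 1e-6)
  expect_equal(res$p_gg[i_pt], adj["pt", "Pr(>F[GG])"], tolerance = 1e-6)
})

test_that("mixed ANOVA validates design completeness", {
  df <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                   group = "1d", w = c("x", "y", "x", "x"),
                   value = rnorm(4))
  expect_error(mixed_anova(df, "value", "group", "w", "subject_id"),
               "not balanced")
})

test_that("interaction type-I error is nominal under the null", {
  set.seed(83)
  n_rep <- 500
  rej <- replicate(n_rep, {
    df <- expand.grid(sid = sprintf("s%02d", 1:16), w = c("a", "b", "c"))
    df$group <- ifelse(as.integer(sub("s", "", df$sid)) <= 8, "g1", "g2")
    df$value <- rnorm(nrow(df))
    res <- mixed_anova(df, "value", "group", "w", "sid")
    res$p[res$effect == "group:w"] < 0.05
  })
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("Welch and paired t-tests match closed forms", {
  # equal variance, equal n: Welch statistic equals Student statistic
  set.seed(84)
  x <- rnorm(12); y <- rnorm(12, 0.5)
  expect_equal(welch_t(x, y)$t,
               unname(stats::t.test(x, y, var.equal = TRUE)$statistic))
  # textbook paired fixture
  a <- c(12, 14, 11, 16, 13, 15, 10, 14)
  b <- c(10, 13, 12, 14, 12, 13, 9, 13)
  d <- a - b
  got <- paired_t(a, b)
  expect_equal(got$t, mean(d) / (stats::sd(d) / sqrt(8)))
  expect_equal(got$df, 7)
  expect_equal(got$cohens_d, mean(d) / stats::sd(d))
  # degenerate cases
  expect_equal(paired_t(a, a)$t, 0)
  expect_equal(paired_t(a, a)$p, 1)
  expect_error(paired_t(a, a - 2), "zero variance")
})

test_that("Pearson test follows t = r sqrt(n-2)/sqrt(1-r^2)", {
  # construct data with r exactly 0.5 at n = 48 via Gram-Schmidt
  set.seed(85)
  n <- 48
  x <- rnorm(n)
  e <- rnorm(n)
  zx <- scale(x)[, 1] / sqrt(n - 1)          # unit vector, centred
  ez <- e - mean(e); ez <- ez - sum(ez * zx) / sum(zx * zx) * zx
  ez <- ez / sqrt(sum(ez^2))
  y <- 0.5 * zx + sqrt(0.75) * ez
  got <- pearson_test(x, y)
  expect_equal(got$r, 0.5, tolerance = 1e-10)
  expect_equal(got$df, 46)
  expect_equal(got$t, 0.5 * sqrt(46) / sqrt(0.75), tolerance = 1e-8)
  expect_equal(got$t, 3.91578, tolerance = 1e-4)
  # exact zero correlation fixture
  x0 <- c(1, -1, 1, -1); y0 <- c(1, 1, -1, -1)
  z <- pearson_test(x0, y0)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Pearson-Filon z has its symmetry and antisymmetry fixed points", {
  expect_equal(pearson_filon_z(0.4, 0.4, 0.2, 48)$z, 0)
  expect_equal(pearson_filon_z(0.4, 0.4, 0.2, 48)$p, 1)
  a <- pearson_filon_z(0.6, 0.2, 0.3, 48)
  b <- pearson_filon_z(0.2, 0.6, 0.3, 48)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(pearson_filon_z(0.9, -0.9, 0.9, 48), "positive semidefinite")
  expect_error(pearson_filon_z(0.5, 0.2, 0.1, 3), "at least 4")
})

test_that("Pearson-Filon agrees with a bootstrap difference test in sign", {
  set.seed(86)
  for (rep in 1:5) {
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- runif(1, -0.5, 0.8)
    R[1, 3] <- R[3, 1] <- runif(1, -0.5, 0.8)
    R[2, 3] <- R[3, 2] <- runif(1, -0.3, 0.6)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 0.05)
      next
    X <- rmvnorm3(100, R)
    rr <- stats::cor(X)
    pf <- pearson_filon_z(rr[1, 2], rr[1, 3], rr[2, 3], 100)
    boot <- replicate(400, {
      idx <- sample.int(100, replace = TRUE)
      rb <- stats::cor(X[idx, ])
      rb[1, 2] - rb[1, 3]
    })
    # same sign of effect; significance agreement when both are decisive
    expect_equal(sign(pf$z), sign(mean(boot)))
  }
})

test_that("Shapiro-Wilk wrapper flags skew and rejects constants", {
  set.seed(87)
  skewed <- exp(rnorm(100))
  expect_lt(shapiro_wilk(skewed)$p, 0.05)
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  # null rejection rate near nominal
  rej <- replicate(300, shapiro_wilk(rnorm(50))$p < 0.05)
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})
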