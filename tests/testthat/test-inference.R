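.fixture_2x3 <- function() {
  set.seed(123)
  n <- 12
  g <- factor(rep(c("s", "m"), c(5, 7)))
  Y <- matrix(rnorm(n * 6, mean = rep(c(0, 1, 2, 0, 1, 3), each = n)), n, 6)
  d <- data.frame(
    id = rep(sprintf("p%02d", 1:n), 6),
    A = factor(rep(rep(c("a1", "a2"), each = n), 3)),
    B = factor(rep(c("b1", "b2", "b3"), each = 2 * n)),
    grp = rep(g, 6),
    y = as.vector(Y)
  )
  list(d = d, Y = Y, g = g)
}

test_that("the mixed ANOVA matches an independent Type III engine to 1e-6", {
  fx <- .fixture_2x3()
  tab <- mixed_anova(fx$d, dv = "y", id = "id", within = c("A", "B"),
                     between = "grp")
  idata <- expand.grid(A = factor(c("a1", "a2")),
                       B = factor(c("b1", "b2", "b3")))
  mlm <- stats::lm(fx$Y ~ g, data = data.frame(g = fx$g),
                   contrasts = list(g = "contr.sum"))
  s <- suppressWarnings(
    summary(car::Anova(mlm, idata = idata, idesign = ~ A * B, type = 3),
            multivariate = FALSE))
  uni <- s$univariate.tests
  ref_names <- c(grp = "g", A = "A", `grp:A` = "g:A", B = "B",
                 `grp:B` = "g:B", `A:B` = "A:B", `grp:A:B` = "g:A:B")
  for (i in seq_len(nrow(tab))) {
    ref <- ref_names[[tab$effect[i]]]
    expect_equal(tab$F[i], uni[ref, "F value"], tolerance = 1e-6)
    expect_equal(tab$ss[i], uni[ref, "Sum Sq"], tolerance = 1e-6)
    expect_equal(tab$df[i], uni[ref, "num Df"])  # no correction active here
    expect_equal(tab$ss_error[i], uni[ref, "Error SS"], tolerance = 1e-6)
  }
  adj <- s$pval.adjustments
  expect_equal(tab$gg_epsilon[tab$effect == "B"], adj["B", "GG eps"],
               tolerance = 1e-6)
  expect_equal(tab$gg_epsilon[tab$effect == "A:B"], adj["A:B", "GG eps"],
               tolerance = 1e-6)
  sph <- s$sphericity.tests
  expect_equal(tab$mauchly_p[tab$effect == "B"], sph["B", "p-value"],
               tolerance = 1e-6)
  expect_equal(tab$mauchly_p[tab$effect == "A:B"], sph["A:B", "p-value"],
               tolerance = 1e-6)
})

test_that("the Greenhouse-Geisser correction rescales df when sphericity fails", {
  # strongly non-spherical within covariance: one noisy level
  set.seed(42)
  n <- 16
  Y <- cbind(rnorm(n, 0, 0.2), rnorm(n, 0.3, 0.2), rnorm(n, 0.6, 3))
  d <- data.frame(id = rep(seq_len(n), 3),
                  w = factor(rep(1:3, each = n)), y = as.vector(Y))
  tab <- mixed_anova(d, dv = "y", id = "id", within = "w")
  expect_true(tab$corrected[tab$effect == "w"])
  eps <- tab$gg_epsilon[tab$effect == "w"]
  expect_equal(tab$df[tab$effect == "w"], 2 * eps)
  expect_equal(tab$df_error[tab$effect == "w"], 2 * (n - 1) * eps)
  expect_gte(eps, 0.5)  # lower bound 1/(k-1)
  expect_lte(eps, 1)
})

test_that("with two within levels the F statistic is the squared paired t", {
  set.seed(31)
  n <- 10
  y1 <- rnorm(n); y2 <- rnorm(n, 0.8)
  d <- data.frame(id = rep(seq_len(n), 2),
                  w = factor(rep(c("a", "b"), each = n)),
                  y = c(y1, y2))
  tab <- mixed_anova(d, dv = "y", id = "id", within = "w")
  tt <- t.test(y1, y2, paired = TRUE)
  expect_equal(tab$F[tab$effect == "w"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(tab$p[tab$effect == "w"], tt$p.value, tolerance = 1e-10)
  expect_true(is.na(tab$gg_epsilon[tab$effect == "w"]))  # Mauchly n/a at 2 levels
})

test_that("a pure between design reduces to one-way ANOVA", {
  set.seed(7)
  d <- data.frame(id = sprintf("p%02d", 1:18),
                  g = factor(rep(c("x", "y", "z"), each = 6)),
                  y = rnorm(18, rep(c(0, 0.5, 2), each = 6)))
  tab <- mixed_anova(d, dv = "y", id = "id", between = "g")
  ref <- anova(lm(y ~ g, data = d))
  expect_equal(tab$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(tab$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Type III tests are invariant to factor-level ordering", {
  fx <- .fixture_2x3()
  tab <- mixed_anova(fx$d, dv = "y", id = "id", within = c("A", "B"),
                     between = "grp")
  d2 <- fx$d
  d2$grp <- factor(d2$grp, levels = c("s", "m"))
  d2$B <- factor(d2$B, levels = c("b3", "b1", "b2"))
  tab2 <- mixed_anova(d2, dv = "y", id = "id", within = c("A", "B"),
                      between = "grp")
  expect_equal(tab2$F, tab$F, tolerance = 1e-8)
  expect_equal(tab2$ges, tab$ges, tolerance = 1e-8)
})

test_that("epsilon stays in its theoretical range and participants drop case-wise", {
  set.seed(91)
  for (i in 1:10) {
    n <- 9
    d <- data.frame(id = rep(seq_len(n), 4),
                    w = factor(rep(1:4, each = n)),
                    y = rnorm(4 * n))
    tab <- mixed_anova(d, dv = "y", id = "id", within = "w")
    eps <- tab$gg_epsilon[1]
    expect_gte(eps, 1 / 3)
    expect_lte(eps, 1)
  }
  d <- data.frame(id = rep(1:8, 3), w = factor(rep(1:3, each = 8)),
                  y = rnorm(24))
  d$y[1] <- NA
  expect_warning(tab <- mixed_anova(d, dv = "y", id = "id", within = "w"),
                 "case-wise")
  expect_equal(attr(tab, "n"), 7)
})

test_that("Tukey's HSD matches the stats reference and degenerates sensibly", {
  set.seed(14)
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 8)),
                  y = rnorm(24, rep(c(0, 1, 3), each = 8)))
  fit <- aov(y ~ g, data = d)
  ref <- TukeyHSD(fit)$g
  means <- tapply(d$y, d$g, mean)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  mine <- tukey_hsd(means, mse, df_error = 21, ns = 8)
  key <- paste(mine$cell_2, mine$cell_1, sep = "-")
  expect_equal(mine$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(mine$diff, unname(-ref[key, "diff"]), tolerance = 1e-10)

  same <- tukey_hsd(c(a = 1, b = 1, c = 1), mse = 2, df_error = 20, ns = 5)
  expect_true(all(abs(same$p_adj - 1) < 1e-10))

  # two cells: adjusted p equals the plain two-sided t-test p
  x <- d$y[d$g == "a"]; y <- d$y[d$g == "b"]
  pooled_t <- t.test(x, y, var.equal = TRUE)
  two <- tukey_hsd(c(a = mean(x), b = mean(y)),
                   mse = ((7 * var(x) + 7 * var(y)) / 14),
                   df_error = 14, ns = 8)
  expect_equal(two$p_adj, pooled_t$p.value, tolerance = 1e-8)
  expect_error(tukey_hsd(c(a = 1), 1, 10, 5), "at least 2")
})

test_that("correlation and chi-square utilities handle canonical cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(2, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")

  even <- matrix(c(10, 10, 10, 10), 2)
  r <- contingency_chi2(even)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(contingency_chi2(matrix(c(20, 0, 0, 20), 2))$chi2, 40)
  expect_error(contingency_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(contingency_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})
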