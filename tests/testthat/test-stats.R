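test_that("spearman matches the rank-formula oracle and handles edges", {
  expect_equal(spearman(1:10, (1:10)^2)$statistic, 1)
  expect_equal(spearman(1:10, -(1:10))$statistic, -1)
  expect_equal(spearman(1:10, (1:10)^2)$p_raw, 0)

  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  # no ties: rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))
  d <- rank(x) - rank(y)
  oracle <- 1 - 6 * sum(d^2) / (5 * 24)
  res <- spearman(x, y)
  expect_equal(res$statistic, oracle)
  expect_equal(res$p_raw,
               2 * pt(-abs(oracle * sqrt(3 / (1 - oracle^2))), df = 3))

  # exact permutation p agrees with cor.test's exact null distribution
  ex <- spearman(x, y, p_method = "exact")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = TRUE))
  expect_equal(ex$p_raw, ct$p.value, tolerance = 1e-12)

  short <- spearman(c(1, 2, NA), c(NA, 1, 2))
  expect_true(is.na(short$statistic))
  expect_identical(short$n, 1L)
})

test_that("BH adjustment equals the literal step-up", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))
    expect_equal(fdr_adjust(p), bh_stepup(p))
  }
  # missing entries pass through and shrink the family
  p <- c(0.01, NA, 0.04)
  adj <- fdr_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_stepup(p[c(1, 3)]))
})

test_that("pooled t-test matches the closed form and guards degeneracy", {
  same <- t_test_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)

  res <- t_test_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, pooled_t(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)

  flat <- t_test_unpaired(c(2, 2, 2), c(2, 2))
  expect_equal(flat$p_raw, 1)
  expect_warning(sep <- t_test_unpaired(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(sep$p_raw, 0)
})

test_that("levene matches car's mean-centred test and detects spread", {
  g <- list(c(1, 4, 2, 7), c(2, 2, 3, 9), c(1, 1, 8, 3))
  ours <- levene(g)
  y <- unlist(g)
  f <- factor(rep(seq_along(g), lengths(g)))
  ref <- car::leveneTest(y, f, center = mean)
  expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$p_raw, ref[1, "Pr(>F)"], tolerance = 1e-10)

  expect_equal(levene(list(c(1, 1, 1), c(1, 1, 1)))$p_raw, 1)

  set.seed(81)
  hits <- mean(replicate(100, {
    a <- rnorm(20)
    b <- rnorm(20, sd = 10)
    c <- rnorm(20)
    levene(list(a, b, c))$p_raw < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("one-way ANOVA matches the SS oracle and the t^2 identity", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- anova_oneway(g)
  # hand decomposition: SSB = 3((2-3)^2+(3-3)^2+(4-3)^2) = 6, SSW = 6
  expect_equal(res$statistic, (6 / 2) / (6 / 6))
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  ref <- oneway.test(unlist(g) ~ factor(rep(1:3, each = 3)),
                     var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)

  set.seed(82)
  a <- rnorm(12)
  b <- rnorm(15, 1)
  f <- anova_oneway(list(a, b))
  t2 <- t_test_unpaired(a, b)$statistic^2
  expect_equal(f$statistic, t2, tolerance = 1e-10)
})

test_that("post hoc gate selects LSD or Games-Howell appropriately", {
  # unequal variances at k = 2: Games-Howell must equal the Welch t-test
  set.seed(91)
  a <- rnorm(15, 0, 1)
  b <- rnorm(25, 1, 6)
  gate <- data.frame(p_raw = 0.001)
  gh <- posthoc(list(a = a, b = b), levene_result = gate)
  expect_identical(gh$method, "games_howell")
  welch <- t.test(a, b)
  expect_equal(gh$p_raw, welch$p.value, tolerance = 1e-6)
  expect_equal(gh$df, unname(welch$parameter), tolerance = 1e-9)

  # equal variances at k = 3: LSD equals the pooled-MSE formula
  g <- list(x = rnorm(10), y = rnorm(10, 0.5), z = rnorm(10, 1))
  aov_row <- anova_oneway(g)
  lsd <- posthoc(g, levene_result = data.frame(p_raw = 0.8))
  expect_true(all(lsd$method == "lsd"))
  t_xy <- (mean(g$x) - mean(g$y)) /
    sqrt(aov_row$mse * (1 / 10 + 1 / 10))
  expect_equal(lsd$statistic[lsd$comparison_id == "x-y"], t_xy)
  expect_equal(lsd$p_raw[lsd$comparison_id == "x-y"],
               2 * pt(-abs(t_xy), 27))

  ident <- posthoc(list(c(1, 1, 1), c(1, 1, 1)),
                   levene_result = data.frame(p_raw = 0.001))
  expect_true(all(ident$p_raw == 1))
})

test_that("correlation grids vary n per cell and adjust as one family", {
  set.seed(92)
  sections <- sprintf("S%02d", 1:20)
  params <- do.call(rbind, lapply(seq_along(sections), function(i) {
    data.frame(section_id = sections[i],
               region = c("FPS", "PPS", "CPS"),
               count = c(i + rnorm(1), i + rnorm(1), rnorm(1)),
               area_fraction_pct = c(i, i, 0) + rnorm(3, 0, 0.5),
               mean_diameter_um = c(9 + rnorm(1),
                                    ifelse(i <= 10, 9 + rnorm(1), NA),
                                    NA),
               min_diameter_um = NA_real_,
               max_diameter_um = NA_real_,
               stringsAsFactors = FALSE)
  }))
  covs <- data.frame(section_id = sections, rank = seq_along(sections))
  grid <- build_grid(params, covs, "rank",
                     regions = c("FPS", "PPS", "CPS"))
  expect_identical(nrow(grid), 15L)
  n_fps <- grid$n[grid$region == "FPS" & grid$parameter == "count"]
  n_pps_d <- grid$n[grid$region == "PPS" &
                      grid$parameter == "mean_diameter_um"]
  expect_identical(n_fps, 20L)
  expect_identical(n_pps_d, 10L)
  # all-missing cells stay missing and shrink the family
  miss <- is.na(grid$p_raw)
  expect_true(any(miss))
  expect_true(all(is.na(grid$p_adjusted[miss])))
  expect_equal(grid$p_adjusted[!miss], bh_stepup(grid$p_raw[!miss]))
  # the gradient cells come out positive and significant
  expect_true(all(grid$significant[grid$region == "FPS" &
                                     grid$parameter == "count"]))
})

test_that("type-I error is controlled at the nominal level", {
  set.seed(93)
  reps <- 500
  t_rej <- mean(replicate(reps, {
    t_test_unpaired(rnorm(10), rnorm(10))$p_raw < 0.05
  }))
  a_rej <- mean(replicate(reps, {
    anova_oneway(list(rnorm(8), rnorm(8), rnorm(8)))$p_raw < 0.05
  }))
  expect_lt(abs(t_rej - 0.05), 0.03)
  expect_lt(abs(a_rej - 0.05), 0.03)
})
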