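stat_result <- function(comparison_id, method, statistic, p_raw,
                        n, df = NA_real_, p_adjusted = NA_real_,
                        extra = NULL) {
  out <- data.frame(comparison_id = comparison_id, method = method,
                    statistic = statistic, p_raw = p_raw,
                    p_adjusted = p_adjusted, n = n, df = df,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

## All permutations of 1..n (n small), one per row.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- sub + (sub >= i)
  }
  out
}

#' Spearman rank correlation with a two-sided p value
#'
#' Computes Spearman's rho on average ranks (ties shared) after pairwise
#' deletion of missing values. The two-sided p value uses the t
#' approximation \code{t = r * sqrt((n - 2) / (1 - r^2))} on \code{n - 2}
#' degrees of freedom; for very small samples an exact permutation p value
#' is available (\code{p_method = "exact"}, n <= 8, full enumeration).
#' Fewer than 3 complete pairs, or a constant margin, yields a missing
#' result -- this is what makes the per-cell n of correlation grids vary.
#'
#' @param x,y Paired numeric vectors; \code{NA}s removed pairwise.
#' @param comparison_id Label carried into the result.
#' @param p_method \code{"t_approx"} (default) or \code{"exact"}.
#' @return One-row data frame: \code{comparison_id}, \code{method},
#'   \code{statistic} (rho), \code{p_raw}, \code{p_adjusted} (NA here),
#'   \code{n}, \code{df}.
#' @export
spearman <- function(x, y, comparison_id = "spearman",
                     p_method = c("t_approx", "exact")) {
  p_method <- match.arg(p_method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(stat_result(comparison_id, "spearman", NA_real_, NA_real_,
                       n = n))
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 8) stop("exact permutation p only for n <= 8", call. = FALSE)
    perms <- permutations_of(n)
    rs <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_result(comparison_id, "spearman", r, p, n = n, df = n - 2)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a family of p values: sorted ascending, the i-th
#' adjusted value is \code{min over j >= i of m * p_(j) / j}, capped at 1,
#' then restored to input order. Missing entries pass through unchanged
#' and do not count towards the family size m.
#'
#' @param p Numeric vector of raw p values in (0, 1], possibly with
#'   \code{NA}s.
#' @return Vector of adjusted p values, same length and order.
#' @export
fdr_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Unpaired two-tailed t-test (pooled variance)
#'
#' Classical two-sample Student t-test with pooled variance and
#' \code{n1 + n2 - 2} degrees of freedom. Degenerate samples with zero
#' pooled variance are guarded: equal means give t = 0, p = 1; unequal
#' means give p = 0 with a warning.
#'
#' @param a,b Numeric vectors, each of length >= 2; \code{NA}s dropped.
#' @param comparison_id Label carried into the result.
#' @return One-row data frame (see [spearman()]) with method
#'   \code{"t_test"}; \code{n} is \code{n1 + n2}.
#' @export
t_test_unpaired <- function(a, b, comparison_id = "t_test") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      return(stat_result(comparison_id, "t_test", 0, 1, n = n1 + n2,
                         df = df))
    }
    warning("zero pooled variance with unequal means: p = 0",
            call. = FALSE)
    return(stat_result(comparison_id, "t_test",
                       sign(mean(a) - mean(b)) * Inf, 0, n = n1 + n2,
                       df = df))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  stat_result(comparison_id, "t_test", unname(tt$statistic),
              tt$p.value, n = n1 + n2, df = unname(tt$parameter))
}

as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  stopifnot(all(vapply(groups, length, integer(1)) >= 2))
  groups
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA F test on the absolute deviations of each observation
#' from its group centre. The default centre is the group mean (the SPSS
#' default); \code{centre = "median"} gives the Brown-Forsythe variant.
#' Identical degenerate groups (all deviations zero) return p = 1 by
#' convention.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @param centre \code{"mean"} or \code{"median"}.
#' @param comparison_id Label carried into the result.
#' @return One-row data frame with method \code{"levene"}, the F statistic
#'   and numerator/denominator df in \code{df1}/\code{df2}.
#' @export
levene <- function(groups, centre = c("mean", "median"),
                   comparison_id = "levene") {
  centre <- match.arg(centre)
  groups <- as_group_list(groups)
  cfun <- if (centre == "mean") mean else stats::median
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  anova_oneway(z, comparison_id = comparison_id, method_tag = "levene")
}

#' One-way analysis of variance
#'
#' Standard between/within F decomposition across k groups. With two
#' groups the F statistic equals the square of the pooled t statistic.
#' Zero within-group variance is guarded: equal group means give F = 0,
#' p = 1; unequal means give p = 0 with a warning.
#'
#' @inheritParams levene
#' @param method_tag Method label recorded in the result (used internally
#'   by [levene()]).
#' @return One-row data frame with the F statistic, \code{df1},
#'   \code{df2}, and the pooled within-group mean square \code{mse} (used
#'   by the LSD post hoc test).
#' @export
anova_oneway <- function(groups, comparison_id = "anova",
                         method_tag = "anova") {
  groups <- as_group_list(groups)
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  n <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / n
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  mse <- ss_within / df2
  extra <- data.frame(df1 = df1, df2 = df2, mse = mse)
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(stat_result(comparison_id, method_tag, 0, 1, n = n,
                         df = df1, extra = extra))
    }
    warning("zero within-group variance with unequal means: p = 0",
            call. = FALSE)
    return(stat_result(comparison_id, method_tag, Inf, 0, n = n,
                       df = df1, extra = extra))
  }
  f <- (ss_between / df1) / mse
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  stat_result(comparison_id, method_tag, f, p, n = n, df = df1,
              extra = extra)
}

#' Variance-gated post hoc pairwise comparisons
#'
#' Selects the post hoc procedure by Levene's test, the gate used
#' throughout the analysis: when variances are judged equal (Levene p >
#' \code{alpha}) Fisher's LSD is used -- pairwise t-tests on the pooled
#' within-group mean square with its error df; otherwise Games-Howell --
#' pairwise Welch t statistics with Welch-Satterthwaite df, referred to
#' the studentized-range distribution with k groups via \code{q = |t| *
#' sqrt(2)}. At k = 2 Games-Howell reduces exactly to the Welch two-sample
#' test.
#'
#' @param groups Named or unnamed list of >= 2 numeric vectors.
#' @param levene_result Optional precomputed [levene()] row; computed here
#'   when \code{NULL}.
#' @param alpha Gate level for Levene's test.
#' @return Data frame with one row per pair: \code{comparison_id}
#'   (\code{"i-j"} or group names), method (\code{"lsd"} or
#'   \code{"games_howell"}), t statistic, df, raw p.
#' @export
posthoc <- function(groups, levene_result = NULL, alpha = 0.05) {
  groups <- as_group_list(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  if (is.null(levene_result)) levene_result <- levene(groups)
  equal_var <- levene_result$p_raw > alpha
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  aov_row <- anova_oneway(groups)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      cid <- paste(nm[i], nm[j], sep = "-")
      diff <- means[i] - means[j]
      if (equal_var) {
        se <- sqrt(aov_row$mse * (1 / ns[i] + 1 / ns[j]))
        df <- aov_row$df2
        method <- "lsd"
      } else {
        se <- sqrt(vars[i] / ns[i] + vars[j] / ns[j])
        df <- se^4 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                        (vars[j] / ns[j])^2 / (ns[j] - 1))
        method <- "games_howell"
      }
      if (se == 0) {
        tstat <- if (diff == 0) 0 else sign(diff) * Inf
        p <- if (diff == 0) 1 else 0
        if (method == "games_howell") df <- NA_real_
      } else {
        tstat <- diff / se
        p <- if (method == "lsd") {
          2 * stats::pt(-abs(tstat), df)
        } else {
          stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                        lower.tail = FALSE)
        }
      }
      if (method == "games_howell" && (is.nan(p) || is.na(p)) &&
          !is.na(tstat)) {
        stop("studentized-range evaluation failed (k = ", k, ", df = ",
             signif(df, 4), ")", call. = FALSE)
      }
      out[[cid]] <- stat_result(cid, method, tstat, p,
                                n = ns[i] + ns[j], df = df)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
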