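#' Monte Carlo permutation test for a difference in mean or median
#'
#' Tests the difference in a group statistic (mean or median) between two
#' groups by shuffling group labels. The empirical p-value is the proportion
#' of permuted statistics greater than or equal to the observed one; by
#' default differences are compared in absolute value (two-sided). With
#' `exhaustive = TRUE` all label assignments are enumerated instead of
#' sampled, giving the exact permutation p-value for small samples.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param statistic `"mean"` or `"median"`.
#' @param n_perm number of random permutations (default 10000).
#' @param seed integer seed making the Monte Carlo draw reproducible.
#' @param exhaustive enumerate all `choose(na + nb, na)` assignments.
#' @param alternative `"two.sided"` compares absolute differences;
#'   `"greater"` compares signed differences (statistic(a) - statistic(b)).
#' @param plus_one use the (k + 1)/(n + 1) estimator, which cannot return 0.
#' @return object of class `perm_result`: list with `statistic`,
#'   `observed_diff`, `p`, `n_perm` (number of permutations actually used),
#'   `exhaustive`, `seed`.
#' @export
perm_test <- function(a, b, statistic = c("mean", "median"), n_perm = 10000,
                      seed = NULL, exhaustive = FALSE,
                      alternative = c("two.sided", "greater"),
                      plus_one = FALSE) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2, n_perm >= 1)
  stat_fun <- if (statistic == "mean") mean else stats::median
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  obs <- stat_fun(a) - stat_fun(b)
  side <- function(d) if (alternative == "two.sided") abs(d) else d

  if (exhaustive) {
    if (choose(n, na) > 2e5)
      stop("exhaustive enumeration infeasible for choose(", n, ", ", na, ")")
    idx <- utils::combn(n, na)
    perm <- apply(idx, 2, function(i) stat_fun(pool[i]) - stat_fun(pool[-i]))
    n_used <- ncol(idx)
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    perm <- vapply(seq_len(n_perm), function(k) {
      i <- sample.int(n, na)
      stat_fun(pool[i]) - stat_fun(pool[-i])
    }, 0)
    n_used <- n_perm
  }
  k <- sum(side(perm) >= side(obs))
  p <- if (plus_one) (k + 1) / (n_used + 1) else k / n_used
  structure(list(statistic = statistic, observed_diff = obs, p = p,
                 n_perm = n_used, exhaustive = exhaustive, seed = seed,
                 alternative = alternative),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s diff = %.6g, p = %.4g (%s, %d permutations%s)\n",
              x$statistic, x$observed_diff, x$p, x$alternative, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests, capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param m number of tests in the family (defaults to `length(pvals)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmin(1, m * pvals)
}

#' Welch's two-sample t-test (unequal variances)
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE`, returning
#' the statistic, Welch–Satterthwaite degrees of freedom and two-sided p.
#' Degenerate zero-variance inputs with equal means return `t = 0, p = 1`.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p`.
#' @export
welch_pairwise <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Welch's ANOVA across k groups
#'
#' Omnibus heteroscedasticity-robust one-way test ([stats::oneway.test()]
#' with `var.equal = FALSE`).
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups) {
  ht <- stats::oneway.test(values ~ factor(groups), var.equal = FALSE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = unname(ht$p.value))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the sample mean: a
#' scale-free measure of dispersion.
#'
#' @param values numeric vector of length >= 2 with non-zero mean.
#' @return the coefficient of variation.
#' @export
cv <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined: mean is 0")
  stats::sd(values) / m
}

#' Ratio of coefficients of variation between two variables
#'
#' `cv(x) / cv(y)` compares the relative variability of two traits across
#' the same set of species; a ratio above 1 means x varies more (relative
#' to its mean) than y.
#'
#' @param x,y numeric vectors (not necessarily the same length).
#' @return the CV ratio.
#' @export
cv_ratio <- function(x, y) {
  cvy <- cv(y)
  if (cvy == 0) stop("cv(y) = 0: CV ratio undefined")
  cv(x) / cvy
}

#' Per-group summary of variables: mean, 5-95 percentile range, sd
#'
#' For each group and each variable reports the mean, the 5th and 95th
#' percentiles (linear interpolation between order statistics), and the
#' sample standard deviation. Groups of a single species report sd = 0 with
#' `single_species = TRUE`.
#'
#' @param table data.frame with a group column and numeric variable columns.
#' @param variables character vector of columns to summarize (default: all
#'   numeric columns).
#' @param group name of the group-label column (default `"group"`).
#' @return long-format data.frame: `group`, `variable`, `n`, `mean`, `q05`,
#'   `q95`, `sd`, `single_species`.
#' @export
summary_table <- function(table, variables = NULL, group = "group") {
  stopifnot(group %in% names(table))
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, TRUE) &
                                names(table) != group]
  out <- expand.grid(group = unique(as.character(table[[group]])),
                     variable = variables, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(out)), function(i) {
    v <- table[table[[group]] == out$group[i], out$variable[i]]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
    data.frame(n = length(v), mean = mean(v), q05 = q[1], q95 = q[2],
               sd = if (length(v) > 1) stats::sd(v) else 0,
               single_species = length(v) == 1)
  })
  cbind(out, do.call(rbind, rows))
}

#' All pairwise group comparisons by permutation test
#'
#' Runs [perm_test()] for every pair of groups, every requested variable and
#' every requested statistic, then Bonferroni-adjusts across the whole
#' family of tests.
#'
#' @param table data.frame of species rows with a group column and numeric
#'   variables.
#' @param variables columns to compare (default: all numeric).
#' @param group name of the group column.
#' @param statistics subset of `c("mean", "median")`.
#' @param n_perm,seed passed to [perm_test()]; each test uses a distinct
#'   seed derived from `seed`.
#' @return long-format data.frame: `group1`, `group2`, `variable`,
#'   `statistic`, `observed_diff`, `p`, `p_bonferroni`.
#' @export
compare_groups <- function(table, variables = NULL, group = "group",
                           statistics = c("mean", "median"),
                           n_perm = 10000, seed = 42) {
  stopifnot(group %in% names(table))
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, TRUE) &
                                names(table) != group]
  labs <- unique(as.character(table[[group]]))
  if (length(labs) < 2) stop("need at least two groups to compare")
  pairs <- utils::combn(labs, 2)
  grid <- expand.grid(pair = seq_len(ncol(pairs)), variable = variables,
                      statistic = statistics, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g1 <- pairs[1, grid$pair[i]]; g2 <- pairs[2, grid$pair[i]]
    va <- table[table[[group]] == g1, grid$variable[i]]
    vb <- table[table[[group]] == g2, grid$variable[i]]
    pr <- perm_test(va[!is.na(va)], vb[!is.na(vb)],
                    statistic = grid$statistic[i], n_perm = n_perm,
                    seed = seed + i)
    data.frame(group1 = g1, group2 = g2, variable = grid$variable[i],
               statistic = grid$statistic[i],
               observed_diff = pr$observed_diff, p = pr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p)
  out
}
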