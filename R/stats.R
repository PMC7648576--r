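# The nonparametric statistics used for screen-scale comparisons. The
# tests themselves are the standard ones (delegated to stats::); the
# wrappers fix the conventions used throughout this package: two-sided
# probability-mass Fisher p-values, tie-corrected Kruskal-Wallis,
# exact-or-corrected-normal Wilcoxon, Wilson proportion intervals, and
# linearly interpolated quartiles. No multiple-testing correction is
# applied anywhere.

as_2x2 <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (is.numeric(table) && length(table) == 4L && is.null(dim(table)))
    table <- matrix(table, 2, 2, byrow = TRUE)
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L)))
    stopf("expected a 2x2 table")
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(table != round(table))) stopf("counts must be integers")
  if (sum(table) < 1) stopf("table total must be >= 1")
  table
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass convention: the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more likely than the observed one (with a 1e-7 relative
#' tolerance for floating-point ties). The reported odds ratio is the
#' sample cross-product `a*d / (b*c)` (`NA` when 0/0).
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of counts;
#'   rows = condition, columns = category vs rest.
#' @return list of class `asympart_test`: `method`, `statistic` (odds
#'   ratio), `p_value`, `n_per_group` (row totals), `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as_2x2(table)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (num == 0 && den == 0) NA_real_ else num / den
  structure(list(method = "Fisher's exact test (two-sided)",
                 statistic = or, p_value = min(p, 1),
                 n_per_group = rowSums(tab), odds_ratio = or),
            class = "asympart_test")
}

#' @export
print.asympart_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test across k groups
#'
#' Midranks for ties, tie-corrected H, p-value from the chi-square
#' distribution with k-1 degrees of freedom. When every pooled value is
#' identical the statistic is 0 and p is 1.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return `asympart_test` list (statistic = H) plus `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("groups must be a list of >= 2 numeric vectors")
  n <- vapply(groups, length, integer(1))
  if (any(n < 1L) || sum(n) < 3L)
    stopf("each group needs n >= 1 and total n >= 3")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  if (length(unique(x)) == 1L) {
    res <- list(statistic = 0, parameter = length(groups) - 1L, p.value = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic),
                parameter = unname(kt$parameter), p.value = kt$p.value)
  }
  structure(list(method = "Kruskal-Wallis rank sum test",
                 statistic = res$statistic, p_value = res$p.value,
                 n_per_group = n, df = res$parameter),
            class = "asympart_test")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by enumeration of the rank-sum distribution when
#' there are no ties and the smaller sample has fewer than 50
#' observations (the mainstream convention); otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#' The method used is recorded in the result.
#'
#' @param x,y numeric samples.
#' @return `asympart_test` list (statistic = Mann-Whitney W for `x`).
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) < 50L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(list(
    method = if (exact) "Wilcoxon rank sum test (exact)"
             else "Wilcoxon rank sum test (normal approximation)",
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_per_group = c(length(x), length(y))),
    class = "asympart_test")
}

#' Confidence interval for a proportion
#'
#' Wilson score interval by default (well behaved at 0% and 100%, both of
#' which occur in small telophase tallies); Clopper-Pearson exact interval
#' as an alternative.
#'
#' @param successes,n counts, `0 <= successes <= n`.
#' @param level confidence level.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return list with `estimate`, `lower`, `upper`, `level`, `method`.
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (n < 1 || successes < 0 || successes > n)
    stopf("need 0 <= successes <= n and n >= 1")
  p <- successes / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  } else {
    ci <- stats::binom.test(successes, n, conf.level = level)$conf.int
    lo <- ci[1]; hi <- ci[2]
  }
  list(estimate = p, lower = lo, upper = hi, level = level, method = method)
}

#' Median and quartiles
#'
#' Linearly interpolated (type-7) 25th/50th/75th percentiles, the summary
#' plotted for cumulative pair intensities.
#'
#' @param values numeric vector, n >= 1.
#' @return list with `median`, `q25`, `q75`, `n`.
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stopf("need at least one finite value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' Compare classified pair tables across groups
#'
#' The screen-style comparison bundle for two or more groups of classified
#' pairs: per-group category tallies with Wilson intervals, pairwise
#' Fisher tests on each category versus the rest, a Kruskal-Wallis test on
#' cumulative intensity across groups, and per-group median/quartile
#' summaries.
#'
#' @param pair_tables named list of [classify_pairs()] outputs, one per
#'   group (e.g. strain or temperature).
#' @return list with `tallies`, `fisher`, `kruskal_cumulative`,
#'   `summaries`.
#' @export
compare_groups <- function(pair_tables) {
  if (is.null(names(pair_tables)) || length(pair_tables) < 1L)
    stopf("pair_tables must be a named list")
  tallies <- lapply(pair_tables, function(p) {
    t <- tally_categories(p$category)
    t$ci_lower <- NA_real_; t$ci_upper <- NA_real_
    tot <- sum(t$n)
    if (tot > 0) for (i in seq_len(nrow(t))) {
      ci <- proportion_ci(t$n[i], tot)
      t$ci_lower[i] <- ci$lower; t$ci_upper[i] <- ci$upper
    }
    t
  })
  fisher <- list()
  grp <- names(pair_tables)
  if (length(grp) >= 2) {
    combos <- utils::combn(grp, 2, simplify = FALSE)
    for (cb in combos) {
      for (cat in tallies[[cb[1]]]$category) {
        t1 <- tallies[[cb[1]]]; t2 <- tallies[[cb[2]]]
        a <- t1$n[t1$category == cat]; na <- sum(t1$n) - a
        b <- t2$n[t2$category == cat]; nb <- sum(t2$n) - b
        if (a + na == 0 || b + nb == 0) next
        ft <- fisher_exact_2x2(matrix(c(a, na, b, nb), 2, byrow = TRUE))
        fisher[[length(fisher) + 1L]] <- data.frame(
          group1 = cb[1], group2 = cb[2], category = cat,
          odds_ratio = ft$odds_ratio, p_value = ft$p_value)
      }
    }
  }
  fisher <- if (length(fisher)) do.call(rbind, fisher) else NULL
  cum <- lapply(pair_tables, function(p)
    p$cumulative[is.finite(p$cumulative)])
  cum <- cum[vapply(cum, length, integer(1)) > 0]
  kw <- if (length(cum) >= 2 && sum(lengths(cum)) >= 3)
    kruskal_wallis(cum) else NULL
  summaries <- lapply(cum, summarize_values)
  list(tallies = tallies, fisher = fisher, kruskal_cumulative = kw,
       summaries = summaries)
}
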