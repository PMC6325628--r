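# Per-feature statistical layer: IQR outlier rule, Mann-Whitney /
# Kruskal-Wallis with Dunn's post hoc, Benjamini-Hochberg adjustment over a
# declared family size, and the bootstrap rescue-size estimate.

#' Remove outliers by the 1 x IQR rule
#'
#' A value is an outlier when it is strictly greater than Q3 + IQR or
#' strictly smaller than Q1 - IQR (boundary values are kept). Quartiles use
#' linear interpolation (R type 7) by default; `quartile_type = 5` gives the
#' Matlab-like convention.
#'
#' @param values Numeric vector (>= 4 values for the rule to engage).
#' @param quartile_type Passed to [stats::quantile()].
#' @return List with numeric vectors `kept` and `removed`.
#' @export
remove_outliers_iqr <- function(values, quartile_type = 7) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values; outlier rule not applied")
    return(list(kept = values, removed = numeric(0)))
  }
  q <- quantile(values, c(0.25, 0.75), type = quartile_type, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values > q[2] + iqr | values < q[1] - iqr
  list(kept = values[!out], removed = values[out])
}

# Dunn's rank-based post hoc z tests with tie correction, two-sided.
dunn_pairs <- function(values, groups, pairs) {
  groups <- as.character(groups)
  r <- rank(values)
  n_tot <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  res <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(mean_rank)))
      stop(sprintf("post hoc pair references missing group: %s",
                   paste(pr, collapse = " vs ")))
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
                 (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    z <- (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
    data.frame(comparison = paste(pr, collapse = " vs "),
               method = "dunn", statistic = z,
               p_value = 2 * pnorm(-abs(z)),
               n1 = n_g[[pr[1]]], n2 = n_g[[pr[2]]])
  })
  do.call(rbind, res)
}

#' Compare groups of a feature with nonparametric tests
#'
#' Outliers are removed per group by [remove_outliers_iqr()] first. Two
#' groups are compared with a two-sided Mann-Whitney test; more than two
#' with Kruskal-Wallis, followed by Dunn's rank-based z tests on the listed
#' pairs. Benjamini-Hochberg adjustment is applied across the declared
#' family size `m_adjust` (features x comparisons, as configured by the
#' caller), never inferred.
#'
#' @param table `data.frame` of bioreactor rows.
#' @param feature Name of the feature column.
#' @param groups Name of the metadata column defining the groups.
#' @param post_hoc_pairs List of length-2 character vectors of group levels
#'   (required when more than two groups are present and post hoc tests are
#'   wanted).
#' @param m_adjust Family size for the BH adjustment; defaults to the number
#'   of tests returned by this call.
#' @param remove_outliers Apply the IQR rule per group first?
#' @param quartile_type Quartile convention for the IQR rule.
#' @return `data.frame` with one row per test: `feature`, `comparison`,
#'   `method`, `statistic`, `p_value`, `p_adjusted`, `n1`, `n2`.
#' @export
compare_groups <- function(table, feature, groups, post_hoc_pairs = NULL,
                           m_adjust = NULL, remove_outliers = TRUE,
                           quartile_type = 7) {
  if (!feature %in% names(table)) stop(sprintf("feature '%s' not in table", feature))
  if (!groups %in% names(table)) stop(sprintf("grouping column '%s' not in table", groups))
  g <- as.character(table[[groups]])
  v <- table[[feature]]
  keep <- !is.na(v)
  g <- g[keep]; v <- v[keep]
  lv <- unique(g)
  vals <- list(); grp <- character(0)
  for (l in lv) {
    x <- v[g == l]
    if (remove_outliers && length(x) >= 4L) x <- remove_outliers_iqr(x, quartile_type)$kept
    if (length(x) == 0L) stop(sprintf("group '%s' is empty after outlier removal", l))
    vals[[l]] <- x
    grp <- c(grp, rep(l, length(x)))
  }
  pooled <- unlist(vals, use.names = FALSE)

  if (length(lv) < 2L) stop("need at least two groups")
  if (length(lv) == 2L) {
    wt <- suppressWarnings(wilcox.test(vals[[1]], vals[[2]], alternative = "two.sided"))
    res <- data.frame(comparison = paste(lv, collapse = " vs "),
                      method = "mann-whitney", statistic = unname(wt$statistic),
                      p_value = wt$p.value,
                      n1 = length(vals[[1]]), n2 = length(vals[[2]]))
  } else {
    kw <- kruskal.test(pooled, factor(grp))
    res <- data.frame(comparison = paste(lv, collapse = " vs "),
                      method = "kruskal-wallis", statistic = unname(kw$statistic),
                      p_value = kw$p.value,
                      n1 = length(pooled), n2 = NA_real_)
    if (!is.null(post_hoc_pairs) && length(post_hoc_pairs) > 0L)
      res <- rbind(res, dunn_pairs(pooled, grp, post_hoc_pairs))
  }
  m <- if (is.null(m_adjust)) nrow(res) else m_adjust
  if (m < nrow(res)) stop("m_adjust must be at least the number of tests")
  res$p_adjusted <- p.adjust(res$p_value, method = "BH", n = m)
  cbind(data.frame(feature = feature), res)
}

#' Bootstrap estimate of the rescue size effect
#'
#' Expresses the treated-group mean on a scale where the mutant mean is 0%
#' and the wild-type mean is 100%. Per iteration, `k` values are drawn with
#' replacement from each of the three groups and the rescue computed as
#' `100 * (mean(treated) - mean(mutant)) / (mean(wt) - mean(mutant))`; the
#' estimate is the bootstrap mean with a percentile confidence interval.
#'
#' @param wt,mut,treated Numeric vectors (wild-type, mutant, treated mutant).
#' @param iterations Number of bootstrap iterations.
#' @param k Samples drawn per group per iteration.
#' @param seed Integer seed; required for reproducibility.
#' @param conf Confidence level of the percentile interval.
#' @return An object of class `rescue_estimate`: list with `rescue_percent`,
#'   `ci`, `sd`, `iterations`, `k`, `seed`, `n_degenerate`.
#' @export
bootstrap_rescue <- function(wt, mut, treated, iterations = 1e5, k = 10,
                             seed = 1L, conf = 0.95) {
  if (length(wt) == 0L || length(mut) == 0L || length(treated) == 0L)
    stop("all three groups must be non-empty")
  if (mean(wt) == mean(mut))
    stop("rescue undefined: wild-type and mutant means are equal")
  set.seed(seed)
  draw_means <- function(x) {
    m <- matrix(sample(x, iterations * k, replace = TRUE), nrow = k)
    colMeans(m)
  }
  mw <- draw_means(wt); mm <- draw_means(mut); mt <- draw_means(treated)
  den <- mw - mm
  degenerate <- den == 0
  if (mean(degenerate) > 0.01)
    stop(sprintf("degenerate denominator in %.1f%% of iterations", 100 * mean(degenerate)))
  rescue <- 100 * (mt[!degenerate] - mm[!degenerate]) / den[!degenerate]
  alpha <- (1 - conf) / 2
  structure(list(rescue_percent = mean(rescue),
                 ci = unname(quantile(rescue, c(alpha, 1 - alpha), type = 7)),
                 sd = sd(rescue),
                 iterations = iterations, k = k, seed = seed,
                 n_degenerate = sum(degenerate)),
            class = "rescue_estimate")
}

#' @export
print.rescue_estimate <- function(x, ...) {
  cat(sprintf("<rescue_estimate: %.1f%% [%.1f, %.1f] (%d iterations, k = %d, seed = %d)>\n",
              x$rescue_percent, x$ci[1], x$ci[2], x$iterations, x$k, x$seed))
  invisible(x)
}
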