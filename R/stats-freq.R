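#' Benjamini-Hochberg FDR adjustment
#'
#' In-package implementation of the step-up BH procedure: with p-values
#' sorted ascending, \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j}, capped at 1
#' and returned in the original order. Rows flagged at `q < 0.10` are treated
#' as significant throughout the frequency reports.
#'
#' @param p Numeric vector of p-values in `[0,1]`.
#' @return Numeric vector of q-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0,1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Compare a category's frequency between two groups
#'
#' Builds the 2x2 table of category presence vs group and tests it
#' two-sidedly. `method = "auto"` uses Fisher's exact test when any expected
#' cell count is below 5 and the chi-square test (without continuity
#' correction) otherwise. Degenerate tables with an empty margin return
#' p = 1.
#'
#' @param k_a,n_a Category count and group total for group A (`k_a <= n_a`).
#' @param k_b,n_b Same for group B.
#' @param method `"auto"`, `"chi_square"` or `"fisher_exact"`.
#' @return list with `p_value` and `method` (the test actually used).
#' @export
frequency_compare <- function(k_a, n_a, k_b, n_b,
                              method = c("auto", "chi_square",
                                         "fisher_exact")) {
  method <- match.arg(method)
  if (n_a == 0 || n_b == 0) stop("group totals must be positive")
  if (k_a > n_a || k_b > n_b || k_a < 0 || k_b < 0)
    stop("category counts must satisfy 0 <= k <= n")
  tab <- rbind(c(k_a, n_a - k_a), c(k_b, n_b - k_b))
  if (any(colSums(tab) == 0))
    return(list(p_value = 1, method = "degenerate"))
  if (method == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (any(expected < 5)) "fisher_exact" else "chi_square"
  }
  p <- if (method == "fisher_exact")
    stats::fisher.test(tab)$p.value
  else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  list(p_value = min(1, p), method = method)
}

#' Frequency table with BH-adjusted q-values
#'
#' One row per category: per-group counts and percentages, the two-sided
#' p-value of [frequency_compare()] against the reference group, and
#' q-values BH-adjusted within the declared test family (by default all rows
#' together; pass `family` to correct within, e.g., each taxonomic level
#' separately, as in super-haplogroup / haplogroup / sub-haplogroup
#' reports). Rows with `q < q_threshold` are flagged significant.
#'
#' @param category Character vector of row labels.
#' @param k_a,k_b Per-row counts in the test and reference group.
#' @param n_a,n_b Group totals (scalars or per-row vectors).
#' @param family Optional factor declaring the multiple-testing family of
#'   each row; q-values are adjusted within each family level.
#' @param method Test selection, see [frequency_compare()].
#' @param q_threshold Significance threshold on q (default 0.10).
#' @return data.frame with columns `category`, `n_a`, `pct_a`, `n_b`,
#'   `pct_b`, `test`, `p_value`, `q_value`, `significant`.
#' @export
frequency_table <- function(category, k_a, n_a, k_b, n_b, family = NULL,
                            method = "auto", q_threshold = 0.10) {
  m <- length(category)
  n_a <- rep_len(n_a, m); n_b <- rep_len(n_b, m)
  res <- mapply(function(ka, na, kb, nb)
    frequency_compare(ka, na, kb, nb, method = method),
    k_a, n_a, k_b, n_b, SIMPLIFY = FALSE)
  p <- vapply(res, `[[`, numeric(1), "p_value")
  used <- vapply(res, `[[`, character(1), "method")
  if (is.null(family)) family <- rep("all", m)
  q <- numeric(m)
  for (f in unique(family)) {
    idx <- family == f
    q[idx] <- bh_adjust(p[idx])
  }
  data.frame(category = category,
             n_a = k_a, pct_a = round(100 * k_a / n_a, 1),
             n_b = k_b, pct_b = round(100 * k_b / n_b, 1),
             test = used, p_value = p, q_value = q,
             significant = q < q_threshold,
             stringsAsFactors = FALSE)
}

# Dunn's pairwise post-hoc test after Kruskal-Wallis (rank-sum z statistics
# with tie correction); no pre-installed package provides it.
dunn_test <- function(values, groups, p_adjust = "BH") {
  groups <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sigma <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
    z[j] <- (mean_rank[a] - mean_rank[b]) / sigma
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

# D'Agostino-Pearson omnibus K^2 normality test (skewness + kurtosis
# z-transforms); advisory only, requires n >= 20.
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20) return(list(statistic = NA_real_, p_value = NA_real_))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  eg2 <- -6 / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  zk <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- zs^2 + zk^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Rank-based comparison of mtDNA content (or any measure) across groups
#'
#' Two groups are compared by the two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test; more than two by Kruskal-Wallis followed by Dunn's pairwise
#' post-hoc test. A normality screen (D'Agostino-Pearson omnibus,
#' Shapiro-Wilk, Lilliefors/Kolmogorov-Smirnov) is reported per group as
#' advisory information only; the rank tests are used regardless.
#'
#' @param groups Named list of numeric vectors, each with at least 2 values.
#' @return list with `test` ("mann_whitney" or "kruskal_wallis"),
#'   `p_value`, `dunn` (pairwise table or `NULL`), and `normality`
#'   (per-group data.frame of advisory p-values).
#' @export
content_compare <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a named list of at least two numeric vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("each group needs at least 2 values; offending group(s): ",
         paste(names(groups)[sizes < 2], collapse = ", "))
  normality <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    sw <- if (length(x) >= 3 && length(x) <= 5000 && stats::sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
    lf <- if (length(x) >= 5 && stats::sd(x) > 0)
      tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
    else NA_real_
    dp <- dagostino_pearson(x)$p_value
    data.frame(group = g, n = length(x), dagostino_pearson = dp,
               shapiro_wilk = sw, lilliefors_ks = lf,
               stringsAsFactors = FALSE)
  }))
  if (length(groups) == 2) {
    p <- suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]],
                         alternative = "two.sided")$p.value)
    if (is.nan(p)) p <- 1
    list(test = "mann_whitney", p_value = p, dunn = NULL,
         normality = normality)
  } else {
    values <- unlist(groups, use.names = FALSE)
    glab <- rep(names(groups), sizes)
    kw <- stats::kruskal.test(values, as.factor(glab))
    list(test = "kruskal_wallis", p_value = kw$p.value,
         dunn = dunn_test(values, glab), normality = normality)
  }
}
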