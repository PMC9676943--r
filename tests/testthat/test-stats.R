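test_that("BH adjustment matches hand-applied and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(51)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # q is monotone non-decreasing after sorting by p
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("Fisher path equals exhaustive hypergeometric enumeration", {
  res <- frequency_compare(8, 77, 4, 242, method = "fisher_exact")
  expect_equal(res$p_value, oracle_fisher(8, 77 - 8, 4, 242 - 4),
               tolerance = 1e-9)
  expect_equal(frequency_compare(10, 100, 10, 100)$p_value, 1)
  set.seed(52)
  for (i in 1:80) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(
      frequency_compare(k1, n1, k2, n2, method = "fisher_exact")$p_value,
      oracle_fisher(k1, n1 - k1, k2, n2 - k2), tolerance = 1e-9)
  }
  expect_error(frequency_compare(1, 0, 1, 10), "positive")
  expect_error(frequency_compare(5, 4, 1, 10))
})

test_that("auto method switches on expected cell counts", {
  # Table-1-sized UK comparison: all expected counts >= 5 -> chi-square
  expect_equal(frequency_compare(30, 77, 42, 242)$method, "chi_square")
  expect_equal(frequency_compare(2, 20, 1, 25)$method, "fisher_exact")
})

test_that("frequency table flags enrichment after within-family BH", {
  tab <- frequency_table(
    category = c("H", "JT", "UK", "Others"),
    k_a = c(27, 10, 30, 10), n_a = 77,
    k_b = c(101, 51, 42, 48), n_b = 242)
  expect_true(tab$significant[tab$category == "UK"])
  expect_false(any(tab$significant[tab$category %in% c("H", "JT")]))
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  # q monotone non-decreasing in p within the family
  o <- order(tab$p_value)
  expect_true(all(diff(tab$q_value[o]) >= -1e-15))
})

test_that("rank tests: exact Mann-Whitney, ties, Kruskal-Wallis + Dunn", {
  res <- content_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$test, "mann_whitney")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_mann_whitney(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(content_compare(list(a = c(1, 2, 3),
                                    b = c(1, 2, 3)))$p_value, 1)
  set.seed(53)
  g4 <- split(rnorm(80), rep(letters[1:4], each = 20))
  res4 <- content_compare(g4)
  expect_equal(res4$test, "kruskal_wallis")
  expect_equal(nrow(res4$dunn), 6)
  expect_true(all(c("dagostino_pearson", "shapiro_wilk", "lilliefors_ks")
                  %in% names(res4$normality)))
  expect_error(content_compare(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("conditional logistic matches survival::clogit exactly", {
  library(survival)
  set.seed(54)
  rows <- lapply(1:40, function(s) {
    n_s <- sample(2:4, 1); d <- sample(1:min(2, n_s - 1), 1)
    x1 <- rnorm(n_s); x2 <- rbinom(n_s, 1, 0.5)
    y <- rep(0, n_s); y[sample(n_s, d, prob = exp(0.7 * x1))] <- 1
    data.frame(stratum = s, y = y, x1 = x1, x2 = x2)
  })
  d <- do.call(rbind, rows)
  fit <- fit_conditional_logistic(d, "y", "stratum", c("x1", "x2"))
  ref <- survival::clogit(y ~ x1 + x2 + survival::strata(stratum), data = d,
                          method = "exact")
  expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("stratum-constant covariates are dropped with a warning", {
  d <- data.frame(stratum = rep(1:30, each = 2),
                  y = rep(c(1, 0), 30),
                  x = rnorm(60),
                  shared = rep(rnorm(30), each = 2))
  expect_warning(fit <- fit_conditional_logistic(d, "y", "stratum",
                                                 c("x", "shared")),
                 "shared")
  expect_false("shared" %in% fit$coefficients$covariate)
})

test_that("mixed logistic collapses to plain logistic without clustering", {
  set.seed(55)
  n <- 300
  d <- data.frame(family_id = rep(1:150, each = 2), x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.2 + 0.8 * d$x))
  m <- suppressMessages(fit_mixed_logistic(d, "y", "family_id", "x"))
  p <- fit_plain_logistic(d, "y", "x")
  expect_equal(m$coefficients$beta, p$coefficients$beta, tolerance = 1e-3)
  expect_true(all(m$coefficients$ci_low < m$coefficients$or))
  expect_true(all(m$coefficients$ci_high > m$coefficients$or))
})

test_that("strong family clustering is detected by the LR comparison", {
  set.seed(56)
  n_fam <- 120
  d <- data.frame(family_id = rep(seq_len(n_fam), each = 3),
                  x = rnorm(3 * n_fam))
  fam_eff <- rep(rnorm(n_fam, sd = 2.5), each = 3)
  d$y <- rbinom(3 * n_fam, 1, plogis(fam_eff + 0.3 * d$x))
  m <- suppressMessages(fit_mixed_logistic(d, "y", "family_id", "x"))
  expect_gt(m$random_intercept_sd, 0.5)
  expect_lt(m$lr_vs_plain$p_value, 0.05)
})

test_that("stepwise selection orders by univariable p and applies p<0.2", {
  set.seed(57)
  n <- 400
  d <- data.frame(strong = rnorm(n), null1 = rnorm(n), null2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(1.2 * d$strong))
  fit_fn <- function(data, outcome, covariates)
    fit_plain_logistic(data, outcome, covariates)
  sel <- stepwise_select(d, "y", c("null1", "strong", "null2"), fit_fn)
  expect_equal(sel$trace$covariate[1], "strong")
  expect_equal(sel$trace$order[1], 1L)
  expect_true("strong" %in% sel$selected)
  # same data -> identical trace (deterministic)
  sel2 <- stepwise_select(d, "y", c("null1", "strong", "null2"), fit_fn)
  expect_identical(sel$trace, sel2$trace)
  # all-null candidates with high p -> empty model
  d2 <- data.frame(y = rbinom(60, 1, 0.5), a = rnorm(60))
  d2$a <- d2$a - mean(d2$a)
  suppressWarnings({
    uni <- fit_plain_logistic(d2, "y", "a")$coefficients$p_value
  })
  if (uni >= 0.2) {
    sel3 <- stepwise_select(d2, "y", "a", fit_fn)
    expect_length(sel3$selected, 0)
    expect_null(sel3$final_model)
  }
})
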