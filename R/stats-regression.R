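# --- stratum-conditional logistic likelihood (exact, subset enumeration) ---
#
# For stratum s with members X_s (n_s x p) and d_s cases, the conditional
# likelihood contribution is exp(sum_cases x'b) / sum_{|S|=d_s} exp(sum_S x'b).
# Strata are small (families), so the subset sums are enumerated exactly;
# this matches the "exact" partial likelihood of survival::clogit, which
# serves as the independent cross-check in the test suite.

build_clogit_strata <- function(X, y, stratum) {
  strata <- split(seq_len(nrow(X)), stratum)
  out <- list()
  for (idx in strata) {
    d <- sum(y[idx])
    n_s <- length(idx)
    if (d == 0 || d == n_s) next  # uninformative stratum
    if (choose(n_s, d) > 5000)
      stop("stratum too large for exact conditional likelihood (",
           n_s, " members, ", d, " cases)")
    subs <- utils::combn(idx, d)
    S <- t(apply(subs, 2, function(ix)
      colSums(X[ix, , drop = FALSE])))
    if (ncol(X) == 1) S <- matrix(S, ncol = 1)
    obs <- colSums(X[idx[y[idx] == 1], , drop = FALSE])
    out[[length(out) + 1L]] <- list(S = S, obs = obs)
  }
  out
}

clogit_loglik <- function(beta, strata) {
  ll <- 0
  for (st in strata) {
    eta <- drop(st$S %*% beta)
    mx <- max(eta)
    ll <- ll + sum(st$obs * beta) - (mx + log(sum(exp(eta - mx))))
  }
  ll
}

clogit_gradient <- function(beta, strata) {
  g <- numeric(length(beta))
  for (st in strata) {
    eta <- drop(st$S %*% beta)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    g <- g + st$obs - drop(t(st$S) %*% w)
  }
  g
}

clogit_hessian <- function(beta, strata) {
  p <- length(beta)
  H <- matrix(0, p, p)
  for (st in strata) {
    eta <- drop(st$S %*% beta)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    m <- drop(t(st$S) %*% w)
    ES2 <- t(st$S) %*% (st$S * w)
    H <- H - (ES2 - tcrossprod(m))
  }
  H
}

#' Family-matched conditional logistic regression
#'
#' Matched case-control (case vs unaffected sibling) logistic regression
#' conditioning on the family stratum, which eliminates all stratum-constant
#' confounding (the shared intra-familial genetic background, including the
#' maternal haplogroup). The exact stratum-conditional likelihood is
#' maximised with BFGS using analytic gradients; standard errors come from
#' the analytic observed information at the optimum. Covariates that do not
#' vary within any stratum carry no conditional information and are dropped
#' with a warning; strata without both a case and a control are
#' uninformative and skipped. Complete separation is flagged and the
#' affected covariate reported non-estimable. A likelihood-ratio-style
#' statistic versus the unconditioned (plain) logistic model with the same
#' covariates is reported as an advisory diagnostic of family clustering.
#'
#' @param data data.frame of per-individual rows.
#' @param outcome Name of the binary outcome column (0/1 or logical;
#'   case = 1).
#' @param stratum Name of the family/stratum column.
#' @param covariates Character vector of covariate column names (numeric or
#'   two-level factors/logicals).
#' @return Object of class `regression_result`: list with `model`
#'   ("conditional_logistic"), `coefficients` (data.frame: covariate, beta,
#'   se, or, ci_low, ci_high, p_value, estimable), `loglik`, `loglik_null`,
#'   `r2_mcfadden`, `lr_vs_plain` (stat, df, p_value), `n_strata`,
#'   `dropped_covariates`.
#' @export
fit_conditional_logistic <- function(data, outcome, stratum, covariates) {
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  strat <- as.character(data[[stratum]])
  X <- covariate_matrix(data, covariates)

  varying <- vapply(colnames(X), function(cv) {
    any(tapply(X[, cv], strat, function(v) length(unique(v)) > 1))
  }, logical(1))
  dropped <- colnames(X)[!varying]
  if (length(dropped)) {
    warning("covariate(s) constant within every stratum dropped: ",
            paste(dropped, collapse = ", "))
    X <- X[, varying, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no informative covariates remain")

  strata <- build_clogit_strata(X, y, strat)
  if (!length(strata))
    stop("no informative strata (each needs >= 1 case and >= 1 control)")

  p <- ncol(X)
  fit <- stats::optim(rep(0, p), fn = function(b) -clogit_loglik(b, strata),
                      gr = function(b) -clogit_gradient(b, strata),
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  beta <- fit$par
  H <- clogit_hessian(beta, strata)
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(V))
  estimable <- is.finite(se) & abs(beta) < 15 & se < 50
  if (any(!estimable))
    warning("possible complete separation; covariate(s) non-estimable: ",
            paste(colnames(X)[!estimable], collapse = ", "))
  zcrit <- stats::qnorm(0.975)
  coefs <- data.frame(
    covariate = colnames(X), beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - zcrit * se), ci_high = exp(beta + zcrit * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    estimable = estimable, stringsAsFactors = FALSE)
  coefs[!estimable, c("or", "ci_low", "ci_high", "p_value")] <- NA_real_

  ll <- clogit_loglik(beta, strata)
  ll0 <- clogit_loglik(rep(0, p), strata)
  plain <- stats::glm(y ~ X, family = stats::binomial())
  lr_stat <- 2 * (ll - as.numeric(stats::logLik(plain)))
  structure(list(
    model = "conditional_logistic",
    coefficients = coefs,
    loglik = ll, loglik_null = ll0,
    r2_mcfadden = 1 - ll / ll0,
    lr_vs_plain = list(stat = lr_stat, df = 1,
                       p_value = stats::pchisq(abs(lr_stat), 1,
                                               lower.tail = FALSE)),
    n_strata = length(strata),
    dropped_covariates = dropped
  ), class = "regression_result")
}

covariate_matrix <- function(data, covariates) {
  cols <- lapply(covariates, function(cv) {
    v <- data[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (is.logical(v)) as.numeric(v)
    else if (is.factor(v) || is.character(v)) {
      f <- as.factor(v)
      if (nlevels(f) != 2)
        stop("categorical covariate ", cv, " must have exactly 2 levels")
      as.numeric(f) - 1
    } else as.numeric(v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

#' Family-clustered mixed logistic regression (GLMM)
#'
#' Logistic fixed effects with a family-level random intercept, fitted with
#' `lme4::glmer`, for binary outcomes such as severe vs mild/moderate ASD
#' phenotype. Reports odds ratios with Wald 95% CIs, McFadden pseudo-R2
#' against the random-intercept-only null, and a likelihood-ratio test
#' against the plain (non-clustered) logistic model with the same fixed
#' effects (the random-intercept variance is on the boundary under the null,
#' so the reported p-value halves the chi-square(1) tail). Non-convergence
#' is reported in the `convergence` field, never silently replaced.
#'
#' @param data data.frame of per-individual rows.
#' @param outcome Binary outcome column name.
#' @param family_col Cluster (family id) column name.
#' @param covariates Covariate column names.
#' @return `regression_result` with `model = "mixed_logistic"`, plus
#'   `random_intercept_sd` and `convergence`.
#' @export
fit_mixed_logistic <- function(data, outcome, family_col, covariates) {
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(data[[family_col]])) < 2)
    stop("need at least 2 families")
  X <- covariate_matrix(data, covariates)
  df <- data.frame(.y = y, .fam = as.factor(data[[family_col]]), X,
                   check.names = FALSE)
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    "+ (1 | .fam)"))
  fit <- lme4::glmer(fml, data = df, family = stats::binomial(), nAGQ = 1)
  msgs <- fit@optinfo$conv$lme4$messages
  convergence <- if (is.null(msgs)) "converged" else
    paste(unlist(msgs), collapse = "; ")
  co <- summary(fit)$coefficients
  keep <- rownames(co) != "(Intercept)"
  beta <- co[keep, "Estimate"]; se <- co[keep, "Std. Error"]
  zcrit <- stats::qnorm(0.975)
  coefs <- data.frame(
    covariate = gsub("`", "", rownames(co)[keep]),
    beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - zcrit * se), ci_high = exp(beta + zcrit * se),
    p_value = co[keep, "Pr(>|z|)"],
    estimable = is.finite(se) & se < 50,
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL

  ll <- as.numeric(stats::logLik(fit))
  null_fit <- lme4::glmer(.y ~ 1 + (1 | .fam), data = df,
                          family = stats::binomial(), nAGQ = 1)
  ll0 <- as.numeric(stats::logLik(null_fit))
  plain <- stats::glm(.y ~ . - .fam, data = df, family = stats::binomial())
  lr_stat <- 2 * (ll - as.numeric(stats::logLik(plain)))
  structure(list(
    model = "mixed_logistic",
    coefficients = coefs,
    loglik = ll, loglik_null = ll0,
    r2_mcfadden = 1 - ll / ll0,
    lr_vs_plain = list(stat = lr_stat, df = 1,
                       p_value = 0.5 * stats::pchisq(max(lr_stat, 0), 1,
                                                     lower.tail = FALSE)),
    random_intercept_sd = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
    convergence = convergence
  ), class = "regression_result")
}

#' Plain logistic regression (no clustering)
#'
#' Ordinary logistic fit via `glm`, used as the unconditioned comparator of
#' the matched and mixed models and as a univariable engine for stepwise
#' selection.
#'
#' @inheritParams fit_mixed_logistic
#' @return `regression_result` with `model = "plain_logistic"`.
#' @export
fit_plain_logistic <- function(data, outcome, covariates) {
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  X <- covariate_matrix(data, covariates)
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  co <- summary(fit)$coefficients
  keep <- rownames(co) != "(Intercept)"
  beta <- co[keep, "Estimate"]; se <- co[keep, "Std. Error"]
  zcrit <- stats::qnorm(0.975)
  coefs <- data.frame(
    covariate = gsub("`", "", rownames(co)[keep]),
    beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - zcrit * se), ci_high = exp(beta + zcrit * se),
    p_value = co[keep, "Pr(>|z|)"],
    estimable = is.finite(se) & se < 50,
    stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  ll <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(.y ~ 1, data = df, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(null_fit))
  structure(list(model = "plain_logistic", coefficients = coefs,
                 loglik = ll, loglik_null = ll0,
                 r2_mcfadden = 1 - ll / ll0, lr_vs_plain = NULL),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(x$model, "fit (McFadden R2 =", sprintf("%.3f", x$r2_mcfadden), ")\n")
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-22s OR %6.2f  95%% CI %6.2f-%-6.2f  p=%.4g%s\n",
                co$covariate[i], co$or[i], co$ci_low[i], co$ci_high[i],
                co$p_value[i],
                if (!co$estimable[i]) "  [non-estimable]" else ""))
  if (!is.null(x$lr_vs_plain))
    cat(sprintf("  LR vs plain logistic: stat=%.2f p=%.3g\n",
                x$lr_vs_plain$stat, x$lr_vs_plain$p_value))
  invisible(x)
}

#' Stepwise covariate selection by ascending univariable p-value
#'
#' Fits each candidate covariate univariably, ranks candidates by ascending
#' univariable p-value, and enters those with p < `enter_p` one by one into
#' a growing multivariable model; after each entry the new covariate is
#' retained only if its multivariable p-value is still below `enter_p`.
#' The full decision trace is returned. Candidates whose univariable fit
#' fails are recorded as non-estimable and skipped.
#'
#' @param data data.frame of per-individual rows.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate covariate names.
#' @param fit_fn Fitting function with signature
#'   `(data, outcome, covariates)` returning a `regression_result`
#'   (e.g. [fit_plain_logistic()], or a wrapper closing over the stratum /
#'   family argument of the matched and mixed fitters).
#' @param enter_p Selection threshold on the p-value, default 0.2.
#' @return list with `final_model` (a `regression_result`, or `NULL` when
#'   nothing is selected), `selected` (character vector) and `trace`
#'   (data.frame: covariate, univariable_p, entered, order, multivariable_p,
#'   retained).
#' @export
stepwise_select <- function(data, outcome, candidates, fit_fn,
                            enter_p = 0.2) {
  uni <- vapply(candidates, function(cv) {
    res <- tryCatch(fit_fn(data, outcome, cv), error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    pv <- res$coefficients$p_value[1]
    if (is.na(pv)) NA_real_ else pv
  }, numeric(1))
  ord <- order(uni, na.last = TRUE)
  trace <- data.frame(covariate = candidates[ord],
                      univariable_p = uni[ord],
                      entered = FALSE, order = NA_integer_,
                      multivariable_p = NA_real_, retained = FALSE,
                      stringsAsFactors = FALSE)
  selected <- character(0)
  final <- NULL
  step <- 0L
  for (i in seq_len(nrow(trace))) {
    cv <- trace$covariate[i]
    pu <- trace$univariable_p[i]
    if (is.na(pu) || pu >= enter_p) next
    step <- step + 1L
    trace$entered[i] <- TRUE
    trace$order[i] <- step
    fit <- tryCatch(fit_fn(data, outcome, c(selected, cv)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pm <- fit$coefficients$p_value[match(cv, fit$coefficients$covariate)]
    trace$multivariable_p[i] <- pm
    if (!is.na(pm) && pm < enter_p) {
      selected <- c(selected, cv)
      trace$retained[i] <- TRUE
      final <- fit
    }
  }
  if (length(selected) && !identical(final$coefficients$covariate, selected))
    final <- fit_fn(data, outcome, selected)
  list(final_model = final, selected = selected, trace = trace)
}
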