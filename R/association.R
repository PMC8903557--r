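#' Weighted cross-tabulation of a factor against covert use
#'
#' Weighted per-category Ns and percent covert, with a Pearson chi-square
#' test of independence computed on the weighted count table via
#' sum (O - E)^2 / E, E from the row/column margins. Weights are
#' renormalized to mean 1 inside the function so the effective total equals
#' the sample size and the statistic is invariant to rescaling all weights
#' by a constant.
#'
#' @param factor_values Categorical vector (factor or character).
#' @param covert Binary covert indicator.
#' @param weights Analysis weights; default unit weights.
#' @param factor_name Label used in the output.
#' @return A tibble of class `crosstab_result` with one row per category:
#'   `factor`, `level`, `n_weighted`, `pct_covert` (0-100), and the
#'   table-level `chisq`, `df`, `p_value` repeated per row (`NA` when the
#'   factor has a single level, for which the test is undefined).
#' @export
weighted_crosstab <- function(factor_values, covert,
                              weights = rep(1, length(covert)),
                              factor_name = deparse(substitute(factor_values))) {
  stopifnot(length(factor_values) == length(covert),
            length(weights) == length(covert))
  f <- if (is.factor(factor_values)) droplevels(factor_values)
       else factor(factor_values)
  w <- weights / mean(weights)
  O <- vapply(c(0, 1), function(y) {
    as.numeric(tapply(w * (covert == y), f, sum, default = 0))
  }, numeric(nlevels(f)))
  O <- matrix(O, nrow = nlevels(f))
  n_lvl <- rowSums(O)
  pct <- 100 * O[, 2] / n_lvl
  if (nlevels(f) < 2) {
    chisq <- df <- p <- NA_real_
  } else {
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    chisq <- sum((O - E)^2 / E)
    df <- (nlevels(f) - 1) * 1
    p <- pchisq(chisq, df, lower.tail = FALSE)
  }
  out <- tibble::tibble(
    factor = factor_name, level = levels(f),
    n_weighted = n_lvl, pct_covert = pct,
    chisq = chisq, df = df, p_value = p
  )
  class(out) <- c("crosstab_result", class(out))
  out
}

## Weighted Bernoulli log-likelihood at fitted probabilities.
weighted_binom_loglik <- function(y, mu, w) {
  sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Weighted logistic regression with odds ratios
#'
#' Fits a binary logistic regression by iteratively reweighted least
#' squares with observation weights (via [stats::glm()]), and reports
#' tidy coefficients, Wald standard errors, odds ratios with 95% Wald
#' confidence intervals (exp(b +/- 1.959964 SE)), p-values, and McFadden's
#' pseudo-R-squared 1 - l_model / l_null computed on the weighted
#' Bernoulli log-likelihood. Model 1 of the analysis uses the husband's
#' attitude class alone; model 2 adds the couple-level and socioeconomic
#' covariates.
#'
#' @param data Data frame containing the outcome and predictors.
#' @param formula Model formula with a binary (0/1) outcome.
#' @param weights Observation weights; default unit weights. Rescaling all
#'   weights by a constant leaves coefficients unchanged (standard errors
#'   scale with the implied information).
#' @param model_id Identifier (e.g. 1 or 2) carried into the output.
#' @param robust Use cluster-robust standard errors (requires the
#'   `sandwich` package and `cluster`).
#' @param cluster Cluster identifiers for `robust = TRUE`.
#' @return A list of class `logit_result`: `model_id`, `terms` (tibble:
#'   term, estimate, se, or, ci_low, ci_high, p_value), `loglik_model`,
#'   `loglik_null`, `mcfadden`, `n`, `separation` (character vector of
#'   terms with divergent estimates, if any), and the underlying `glm`
#'   object as `fit`.
#' @export
fit_weighted_logit <- function(data, formula, weights = NULL, model_id = 1,
                               robust = FALSE, cluster = NULL) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  mf <- droplevels(mf)
  keep <- as.integer(rownames(mf))
  y <- stats::model.response(mf)
  if (any(!y %in% c(0, 1))) abort("Outcome must be binary 0/1.")
  w <- if (is.null(weights)) rep(1, nrow(mf)) else weights[keep]
  if (any(w <= 0)) abort("Weights must be strictly positive.")

  X <- model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Singular design; collinear term(s): ",
                 paste(drop_cols, collapse = ", ")))
  }

  dat <- mf
  dat$.w <- w
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  fit <- suppressWarnings(
    glm(formula, family = binomial(), data = dat, weights = .w,
        control = ctrl))
  null_fit <- suppressWarnings(
    glm(y ~ 1, family = binomial(), weights = w, control = ctrl))

  est <- coef(fit)
  V <- if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      abort("`sandwich` is required for robust standard errors.")
    }
    if (is.null(cluster)) abort("`cluster` is required for robust = TRUE.")
    sandwich::vcovCL(fit, cluster = cluster[keep])
  } else {
    vcov(fit)
  }
  se <- sqrt(diag(V))
  z975 <- 1.959963984540054
  zval <- est / se
  terms_tbl <- tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - z975 * unname(se)),
    ci_high = exp(unname(est) + z975 * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(zval)))
  )

  mu <- fitted(fit)
  ll_model <- weighted_binom_loglik(y, mu, w)
  ll_null <- weighted_binom_loglik(y, fitted(null_fit), w)
  mcfadden <- if (abs(ll_null) < 1e-12) 0 else 1 - ll_model / ll_null

  separation <- names(est)[abs(est) > 10 & se > 100]
  if (length(separation) > 0) {
    warn(paste0("Possible separation in term(s): ",
                paste(separation, collapse = ", ")))
  }

  structure(list(
    model_id = model_id, terms = terms_tbl,
    loglik_model = ll_model, loglik_null = ll_null,
    mcfadden = max(0, mcfadden), n = nrow(mf),
    separation = separation, fit = fit
  ), class = "logit_result")
}

#' @export
print.logit_result <- function(x, ...) {
  cat(sprintf("Weighted logistic regression (model %s), N = %d\n",
              x$model_id, x$n))
  cat(sprintf("McFadden pseudo-R2 = %.3f\n", x$mcfadden))
  print(x$terms, n = nrow(x$terms))
  invisible(x)
}

## Formula for the adjusted (model 2) specification; reference levels are
## the first level of each factor, set upstream by recode/attitude merge.
MODEL2_TERMS <- c(
  "attitude_class", "concordance", "religion", "caste", "residence",
  "wife_education", "age_diff_cat", "edu_diff_cat", "working",
  "wealth_group", "living_children_cat", "region",
  "mobility_market", "mobility_health", "money_own"
)

#' Model formulas for the unadjusted and adjusted specifications
#'
#' Model 1 regresses covert use on the husband's attitude class alone;
#' model 2 adds concordance of the desire for more children, religion,
#' caste, residence, wife's education, spousal age and education
#' differences, working status, wealth group, living children (0/1/2/3+),
#' region, mobility (market, health facility), and independent money use.
#'
#' @param model_id 1 or 2.
#' @return A formula.
#' @export
model_formula <- function(model_id) {
  if (model_id == 1) {
    covert ~ attitude_class
  } else if (model_id == 2) {
    as.formula(paste("covert ~", paste(MODEL2_TERMS, collapse = " + ")))
  } else {
    abort("`model_id` must be 1 or 2.")
  }
}

#' Variance inflation factors of a design matrix
#'
#' For each non-intercept column j of the expanded (reference-coded)
#' design matrix, VIF_j = 1 / (1 - R^2_j), with R^2_j from the ordinary
#' least-squares regression of column j on all other columns (plus an
#' intercept). Exactly collinear columns are reported as infinite.
#'
#' @param X Numeric design matrix; an `(Intercept)` column, if present, is
#'   excluded from the targets but retained as a regressor.
#' @return A list of class `vif_report` with `vif` (named per-column) and
#'   `mean_vif`.
#' @export
vif_report <- function(X) {
  X <- as.matrix(X)
  has_int <- "(Intercept)" %in% colnames(X)
  targets <- if (has_int) setdiff(colnames(X), "(Intercept)")
             else colnames(X)
  if (length(targets) < 2) abort("Need at least two predictor columns.")
  vifs <- vapply(targets, function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, setdiff(targets, j), drop = FALSE])
    fit <- lm.fit(Z, yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    if (sst < 1e-12) return(NA_real_)  # constant column
    r2 <- 1 - ssr / sst
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(list(vif = vifs, mean_vif = mean(vifs[is.finite(vifs)])),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("Variance inflation factors (mean of finite values:",
      sprintf("%.2f", x$mean_vif), ")\n")
  print(round(x$vif, 3))
  invisible(x)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p Numeric p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Assemble and write the report tables
#'
#' Produces the machine-readable report: the bivariate cross-tabulations
#' (per-level weighted N, percent covert, chi-square with stars), the
#' model 1 / model 2 odds-ratio table, the VIF table, and the covert
#' method-mix shares. When `out_dir` is given the four CSVs
#' (`table1_bivariate.csv`, `table2_models.csv`, `vif.csv`,
#' `method_mix.csv`) are written there.
#'
#' @param crosstabs List of `crosstab_result` tibbles.
#' @param logit_results List of `logit_result` objects.
#' @param vif A `vif_report` (or `NULL`).
#' @param mix A [method_mix()] result (or `NULL`).
#' @param out_dir Optional output directory.
#' @return A list of tibbles `table1`, `table2`, `vif`, `method_mix`.
#' @export
results_report <- function(crosstabs, logit_results, vif = NULL, mix = NULL,
                           out_dir = NULL) {
  if (length(crosstabs) == 0 && length(logit_results) == 0) {
    abort("Empty cohort: nothing to report.")
  }
  t1 <- dplyr::bind_rows(crosstabs)
  if (nrow(t1) > 0) t1$stars <- significance_stars(t1$p_value)
  t2 <- dplyr::bind_rows(lapply(logit_results, function(r) {
    tb <- r$terms
    tb$model_id <- r$model_id
    tb$stars <- significance_stars(tb$p_value)
    tb$mcfadden <- r$mcfadden
    tb$n <- r$n
    tb
  }))
  if (is.null(vif)) {
    vt <- tibble::tibble()
  } else {
    vif_names <- names(vif$vif)
    vif_values <- unname(vif$vif)
    vif_mean <- vif$mean_vif
    vt <- tibble::tibble(predictor = vif_names, vif = vif_values,
                         mean_vif = vif_mean)
  }
  if (is.null(mix)) {
    mt <- tibble::tibble()
  } else {
    mix_methods <- names(mix$shares)
    mix_shares <- unname(mix$shares)
    mix_prev <- mix$prevalence
    mix_n <- mix$n_covert
    mt <- tibble::tibble(method = mix_methods, share = mix_shares,
                         covert_prevalence = mix_prev, n_covert = mix_n)
  }
  out <- list(table1 = t1, table2 = t2, vif = vt, method_mix = mt)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(t1, file.path(out_dir, "table1_bivariate.csv"))
    readr::write_csv(t2, file.path(out_dir, "table2_models.csv"))
    readr::write_csv(vt, file.path(out_dir, "vif.csv"))
    readr::write_csv(mt, file.path(out_dir, "method_mix.csv"))
  }
  out
}
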