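make_counts_data <- function(O, levels_f = LETTERS[seq_len(nrow(O))]) {
  # expand a counts matrix (levels x outcome) to row data
  f <- rep(rep(levels_f, 2), times = as.vector(O))
  y <- rep(rep(c(0, 1), each = nrow(O)), times = as.vector(O))
  list(f = f, y = y)
}

test_that("weighted chi-square matches the brute-force oracle", {
  O <- matrix(c(10, 30, 20, 40), 2, 2, byrow = TRUE)
  d <- make_counts_data(matrix(c(10, 20, 30, 40), 2, 2))
  ct <- weighted_crosstab(d$f, d$y)
  expect_equal(ct$chisq[1], brute_chisq(matrix(c(10, 30, 20, 40), 2, 2,
                                               byrow = TRUE)))
  # cross-check against the classical test without continuity correction
  ref <- suppressWarnings(stats::chisq.test(table(d$f, d$y),
                                            correct = FALSE))
  expect_equal(ct$chisq[1], unname(ref$statistic))
  expect_equal(ct$p_value[1], unname(ref$p.value))
  expect_equal(ct$df[1], 1)
})

test_that("chi-square matches the oracle on larger random tables", {
  set.seed(99)
  for (L in c(3, 4, 6)) {
    O <- matrix(rpois(L * 2, 25) + 1, L, 2)
    d <- make_counts_data(O)
    ct <- weighted_crosstab(d$f, d$y)
    expect_equal(ct$chisq[1], brute_chisq(O), tolerance = 1e-12)
    expect_equal(ct$df[1], L - 1)
    ref <- suppressWarnings(stats::chisq.test(table(d$f, d$y),
                                              correct = FALSE))
    expect_equal(ct$chisq[1], unname(ref$statistic))
  }
})

test_that("a proportional table gives a zero statistic", {
  d <- make_counts_data(matrix(c(10, 20, 30, 60), 2, 2))
  ct <- weighted_crosstab(d$f, d$y)
  expect_equal(ct$chisq[1], 0, tolerance = 1e-12)
  expect_equal(ct$pct_covert, c(75, 75))
})

test_that("rescaling all weights leaves the crosstab unchanged", {
  set.seed(10)
  f <- sample(c("a", "b", "c"), 120, replace = TRUE)
  y <- rbinom(120, 1, 0.3)
  c1 <- weighted_crosstab(f, y, weights = rep(1, 120))
  c2 <- weighted_crosstab(f, y, weights = rep(2, 120))
  expect_equal(c1$pct_covert, c2$pct_covert)
  expect_equal(c1$chisq, c2$chisq)
  expect_equal(c1$n_weighted, c2$n_weighted)
})

test_that("a single-level factor yields an undefined test", {
  ct <- weighted_crosstab(rep("only", 10), rbinom(10, 1, 0.5))
  expect_true(is.na(ct$chisq[1]) && is.na(ct$p_value[1]))
})

test_that("the logit reproduces the closed-form cross-product OR", {
  # 2x2: exposed covert a=10, exposed open b=20, unexposed covert c=30,
  # unexposed open d=40 -> OR = (10*40)/(20*30)
  dat <- tibble::tibble(
    covert = c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40)),
    exposed = c(rep(1, 30), rep(0, 70)))
  res <- fit_weighted_logit(dat, covert ~ exposed, model_id = 1)
  or <- res$terms$or[res$terms$term == "exposed"]
  expect_equal(or, (10 * 40) / (20 * 30), tolerance = 1e-8)
  expect_equal(res$terms$ci_low, exp(res$terms$estimate -
                                       1.959963984540054 * res$terms$se))
})

test_that("unit weights equal unweighted estimation exactly", {
  set.seed(21)
  dat <- tibble::tibble(x = rnorm(150), covert = rbinom(150, 1, 0.4))
  r1 <- fit_weighted_logit(dat, covert ~ x, model_id = 1)
  ref <- glm(covert ~ x, family = binomial(), data = dat)
  expect_equal(r1$terms$estimate, unname(coef(ref)), tolerance = 1e-12)
  expect_equal(r1$terms$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-12)
})

test_that("doubling weights keeps coefficients, shrinks standard errors", {
  set.seed(31)
  dat <- tibble::tibble(x = rnorm(200), covert = rbinom(200, 1, 0.35))
  r1 <- fit_weighted_logit(dat, covert ~ x, weights = rep(1, 200))
  r2 <- fit_weighted_logit(dat, covert ~ x, weights = rep(2, 200))
  expect_equal(r1$terms$estimate, r2$terms$estimate, tolerance = 1e-8)
  # sqrt(2) shrinkage holds at the optimum; IRLS stops within ~1e-5 of it
  expect_equal(r2$terms$se, r1$terms$se / sqrt(2), tolerance = 1e-4)
})

test_that("an intercept-only model has zero pseudo-R-squared", {
  dat <- tibble::tibble(covert = rbinom(80, 1, 0.3))
  res <- fit_weighted_logit(dat, covert ~ 1)
  expect_equal(res$mcfadden, 0, tolerance = 1e-12)
})

test_that("pseudo-R-squared lies in [0, 1) and grows with signal", {
  set.seed(77)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(-1 + 2 * x))
  dat <- tibble::tibble(covert = y, x = x, noise = rnorm(500))
  r_sig <- fit_weighted_logit(dat, covert ~ x)
  r_noise <- fit_weighted_logit(dat, covert ~ noise)
  expect_gt(r_sig$mcfadden, r_noise$mcfadden)
  expect_lt(r_sig$mcfadden, 1)
  expect_gte(r_noise$mcfadden, 0)
})

test_that("singular designs and separation are surfaced", {
  set.seed(3)
  dat <- tibble::tibble(x = rnorm(50), covert = rbinom(50, 1, 0.5))
  dat$x2 <- 2 * dat$x
  expect_error(fit_weighted_logit(dat, covert ~ x + x2), "collinear")
  sep <- tibble::tibble(
    covert = c(rep(1, 20), rep(0, 20)),
    g = factor(c(rep("a", 20), rep("b", 20))))
  expect_warning(fit_weighted_logit(sep, covert ~ g), "separation")
})

test_that("VIF matches the auxiliary-regression oracle", {
  # orthogonal columns -> every VIF = 1
  X <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  v <- vif_report(X)
  expect_equal(unname(v$vif), c(1, 1), tolerance = 1e-12)

  # exact half-shared variance -> VIF = 2
  x1 <- c(1, -1, 1, -1); x2 <- c(1, 1, -1, -1); u <- c(1, -1, -1, 1)
  X2 <- cbind(x1 = x1, x2 = x2, x3 = x1 + u)
  v2 <- vif_report(X2)
  expect_equal(unname(v2$vif[["x3"]]), 2, tolerance = 1e-12)

  # duplicated column -> infinite VIF
  X3 <- cbind(x1 = x1, x2 = x2, dup = x1)
  v3 <- vif_report(X3)
  expect_true(is.infinite(v3$vif[["dup"]]))

  # random design: agree with a direct lm-based R^2 computation
  set.seed(8)
  Z <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(NULL, paste0("z", 1:4)))
  Z[, 4] <- Z[, 1] * 0.7 + rnorm(60, sd = 0.5)
  vz <- vif_report(Z)
  for (j in colnames(Z)) {
    r2 <- summary(stats::lm(Z[, j] ~ Z[, setdiff(colnames(Z), j)]))$r.squared
    expect_equal(unname(vz$vif[[j]]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("significance stars follow the footnote thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.004, 0.03, 0.2, NA)),
               c("***", "**", "*", "", ""))
})

test_that("report tables round-trip through CSV", {
  set.seed(12)
  dat <- tibble::tibble(x = rnorm(100), covert = rbinom(100, 1, 0.4),
                        g = sample(c("u", "v"), 100, replace = TRUE))
  ct <- weighted_crosstab(dat$g, dat$covert, factor_name = "g")
  m <- fit_weighted_logit(dat, covert ~ x, model_id = 1)
  v <- vif_report(cbind(x = dat$x, g = as.numeric(factor(dat$g))))
  mx <- method_mix(sample(c("pill", "iud"), 100, replace = TRUE),
                   dat$covert)
  dir <- withr::local_tempdir()
  rep <- results_report(list(ct), list(m), v, mx, out_dir = dir)
  back <- readr::read_csv(file.path(dir, "table2_models.csv"),
                          show_col_types = FALSE)
  expect_equal(back$estimate, rep$table2$estimate, tolerance = 1e-12)
  back1 <- readr::read_csv(file.path(dir, "table1_bivariate.csv"),
                           show_col_types = FALSE)
  expect_equal(back1$pct_covert, rep$table1$pct_covert, tolerance = 1e-12)
  expect_error(results_report(list(), list()), "Empty cohort")
})
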