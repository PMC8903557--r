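test_that("a single-class fit reduces to item means in closed form", {
  set.seed(7)
  Y <- matrix(rbinom(20 * 3, 1, c(0.2, 0.5, 0.8)), 20, 3, byrow = TRUE)
  fit <- fit_em(Y, C = 1, n_restarts = 1, seed = 1)
  expect_equal(unname(fit$delta), 1)
  phat <- colMeans(Y)
  expect_equal(unname(fit$tau[1, ]), phat, tolerance = 1e-6)
  k1 <- colSums(Y)
  ll <- sum(k1 * log(phat) + (nrow(Y) - k1) * log(1 - phat))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("returned log-likelihood equals brute-force mixture evaluation", {
  # toy matrices across sizes, items and class counts
  set.seed(123)
  for (rep in 1:6) {
    N <- sample(3:8, 1)
    m <- sample(2:4, 1)
    C <- sample(1:3, 1)
    if (N < C) next
    Y <- matrix(rbinom(N * m, 1, runif(m)), N, m, byrow = TRUE)
    fit <- fit_em(Y, C, n_restarts = 5, seed = rep)
    expect_equal(fit$loglik, brute_mixture_loglik(Y, fit$delta, fit$tau),
                 tolerance = 1e-9)
    # per-iteration log-likelihood trace is non-decreasing
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_equal(fit$loglik, max(fit$restart_logliks))
  }
})

test_that("row weights act as frequency weights in the likelihood", {
  set.seed(5)
  Y <- matrix(rbinom(12 * 3, 1, 0.4), 12, 3)
  Ydup <- rbind(Y, Y[1:4, ])
  w <- c(rep(1, 12)); w[1:4] <- 2
  f_dup <- fit_em(Ydup, C = 2, n_restarts = 8, seed = 3)
  f_w <- fit_em(Y, C = 2, n_restarts = 8, seed = 3, weights = w)
  expect_equal(f_w$loglik, f_dup$loglik, tolerance = 1e-5)
})

test_that("information criteria follow their definitions", {
  fit <- list(loglik = -100, n_params = 10L, N = 100L, C = 2L, m = 4L)
  class(fit) <- "lca_fit"
  ic <- information_criteria(fit)
  expect_equal(ic[["AIC"]], 220)
  expect_equal(ic[["BIC"]], 200 + 10 * log(100))
  expect_error(information_criteria(fit, N = 0), "positive")
  # parameter count for the 3-class, 12-item attitude model
  Y <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12)
  f3 <- fit_em(Y, 3, n_restarts = 2, seed = 1, max_iter = 50)
  expect_equal(f3$n_params, 2 + 36)
})

test_that("BIC selection recovers the class count of separated data", {
  cfg <- default_profiles()
  sim <- simulate_attitudes(5000, cfg$delta, cfg$tau, seed = 77)
  sel <- select_num_classes(sim$Y, candidates = 2:4, n_restarts = 4,
                            seed = 42)
  expect_equal(sel$chosen_C, 3)
  b <- sel$table$BIC
  expect_true(b[2] < b[1] && b[2] < b[3])
  # degenerate single candidate
  expect_equal(select_num_classes(sim$Y[1:200, ], candidates = 3,
                                  n_restarts = 2, seed = 1)$chosen_C, 3)
})

test_that("labeling orders classes by egalitarian score", {
  tau <- rbind(rep(0.5, 4), rep(0.95, 4), rep(0.10, 4))
  fit <- structure(list(delta = c(0.3, 0.5, 0.2), tau = tau, C = 3L,
                        m = 4L, n_params = 14L, loglik = -10),
                   class = "lca_fit")
  lab <- label_classes(fit)
  expect_equal(lab$labels, c("high", "moderate", "low"))
  expect_equal(unname(lab$delta), c(0.5, 0.3, 0.2))
  expect_equal(unname(lab$tau[1, 1]), 0.95)
  expect_equal(unname(lab$tau[3, 1]), 0.10)
  expect_equal(lab$perm, c(2L, 1L, 3L))
})

test_that("labeled output is invariant to input class permutation", {
  cfg <- default_profiles()
  sim <- simulate_attitudes(1500, cfg$delta, cfg$tau, seed = 11)
  fit <- fit_em(sim$Y, 3, n_restarts = 6, seed = 2)
  lab <- label_classes(fit)
  perm <- c(3L, 1L, 2L)
  fit_p <- fit
  fit_p$delta <- fit$delta[perm]
  fit_p$tau <- fit$tau[perm, ]
  lab_p <- label_classes(fit_p)
  expect_equal(lab_p$delta, lab$delta)
  expect_equal(lab_p$tau, lab$tau)
  # permuting classes leaves likelihood and criteria unchanged
  expect_equal(brute_mixture_loglik(sim$Y[1:8, ], fit_p$delta, fit_p$tau),
               brute_mixture_loglik(sim$Y[1:8, ], fit$delta, fit$tau),
               tolerance = 1e-12)
  expect_equal(information_criteria(lab_p, N = 1500),
               information_criteria(lab, N = 1500))
})

test_that("posterior assignment follows the Bayes rule", {
  # two classes, two items, hand-computed posterior for row (1, 0)
  delta <- c(0.6, 0.4)
  tau <- rbind(c(0.9, 0.2), c(0.3, 0.7))
  fit <- structure(list(delta = delta, tau = tau, C = 2L, m = 2L),
                   class = "lca_fit")
  pa <- posterior_assign(fit, matrix(c(1, 0), 1, 2))
  p1 <- 0.6 * 0.9 * 0.8
  p2 <- 0.4 * 0.3 * 0.3
  expect_equal(pa$posterior[1, ], c(p1, p2) / (p1 + p2), tolerance = 1e-12)
  expect_equal(pa$modal, 1L)
  expect_equal(rowSums(pa$posterior), 1, tolerance = 1e-10)

  # degenerate prior forces every posterior onto class 1
  fit1 <- structure(list(delta = c(1, 0), tau = tau, C = 2L, m = 2L),
                    class = "lca_fit")
  Y <- matrix(rbinom(20, 1, 0.5), 10, 2)
  pa1 <- posterior_assign(fit1, Y)
  expect_true(all(pa1$posterior[, 1] == 1))
  expect_true(all(pa1$modal == 1L))
  expect_error(posterior_assign(fit1, matrix(0, 2, 3)), "items")
})

test_that("modal assignment is accurate on well-separated classes", {
  cfg <- default_profiles()
  sim <- simulate_attitudes(4000, cfg$delta, cfg$tau, seed = 19)
  fit <- label_classes(fit_em(sim$Y, 3, n_restarts = 8, seed = 4))
  pa <- posterior_assign(fit, sim$Y)
  truth <- c("high", "moderate", "low")[sim$class]
  expect_gte(mean(as.character(pa$modal) == truth), 0.90)
})

test_that("the likelihood-ratio statistic matches enumeration", {
  # independence model that reproduces pattern frequencies exactly
  Y0 <- as.matrix(expand.grid(0:1, 0:1))
  colnames(Y0) <- NULL
  f0 <- fit_em(Y0, C = 1, n_restarts = 1, seed = 1)
  g0 <- likelihood_ratio_statistic(f0, Y0)
  expect_equal(g0$G2, 0, tolerance = 1e-9)
  expect_equal(g0$n_patterns, 4L)

  # 3-item toy: G2 by brute-force 2 * sum O log(O / E)
  set.seed(33)
  Y <- matrix(rbinom(60 * 3, 1, c(0.3, 0.6, 0.5)), 60, 3, byrow = TRUE)
  fit <- fit_em(Y, C = 2, n_restarts = 6, seed = 2)
  g <- likelihood_ratio_statistic(fit, Y)
  pats <- apply(Y, 1, paste, collapse = "")
  O <- table(pats)
  g2_brute <- 0
  for (p in names(O)) {
    y <- as.numeric(strsplit(p, "")[[1]])
    prob <- sum(fit$delta * apply(fit$tau, 1, function(tc) {
      prod(tc^y * (1 - tc)^(1 - y))
    }))
    g2_brute <- g2_brute + 2 * O[[p]] * log(O[[p]] / (nrow(Y) * prob))
  }
  expect_equal(g$G2, g2_brute, tolerance = 1e-8)
  expect_equal(g$df, (2^3 - 1) - fit$n_params)

  # df for the 12-item, 3-class attitude model
  f12 <- structure(list(m = 12L, n_params = 38L, delta = 1,
                        tau = matrix(0.5, 1, 12)), class = "lca_fit")
  g12 <- likelihood_ratio_statistic(
    f12, matrix(rbinom(24, 1, 0.5), 2, 12))
  expect_equal(g12$df, 4095 - 38)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_em(matrix(0, 0, 3), 2), "at least one row")
  expect_error(fit_em(matrix(0, 5, 3), 0), "positive")
  expect_error(fit_em(matrix(1, 2, 3), 3), "at least C rows")
  expect_error(fit_em(matrix(2, 4, 3), 2), "0 or 1")
  expect_error(select_num_classes(matrix(0:1, 10, 2),
                                  candidates = integer(0)), "non-empty")
})
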