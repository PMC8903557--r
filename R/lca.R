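## Latent class model for binary attitude items.
##
## Model: P(Y = y) = sum_c delta_c prod_i tau_ci^{y_i} (1 - tau_ci)^{1 - y_i},
## with delta the class shares and tau the class-conditional probabilities
## of the positive (code-1) response. Items are conditionally independent
## given class. Fitting is plain EM on response patterns: rows are
## collapsed to distinct 0/1 patterns with (weighted) counts, which makes
## each iteration O(P x C x m) for P observed patterns instead of O(N).

## Collapse a binary matrix to unique response patterns with counts.
## Returns list(Y = P x m pattern matrix, w = total weight per pattern).
collapse_patterns <- function(Y, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(Y))
  key <- apply(Y, 1, paste, collapse = "")
  first <- !duplicated(key)
  w <- tapply(weights, key, sum)
  Yp <- Y[first, , drop = FALSE]
  list(Y = Yp, w = as.numeric(w[key[first]]))
}

## Per-pattern, per-class complete-data log density log(delta_c) +
## sum_i [y log tau + (1-y) log(1-tau)].
pattern_logdens <- function(Yp, delta, tau) {
  lt <- log(tau); lt1 <- log1p(-tau)
  ## P x C: Yp %*% t(lt) + (1 - Yp) %*% t(lt1)
  sweep(Yp %*% t(lt) + (1 - Yp) %*% t(lt1), 2, log(delta), `+`)
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

## Observed-data log-likelihood at (delta, tau), via pattern collapsing.
mixture_loglik <- function(Y, delta, tau, weights = NULL) {
  pc <- collapse_patterns(as.matrix(Y), weights)
  sum(pc$w * logsumexp_rows(pattern_logdens(pc$Y, delta, tau)))
}

#' Fit a binary latent class model by EM
#'
#' Maximum-likelihood estimation of class shares `delta` and
#' class-conditional positive-response probabilities `tau` for C latent
#' classes over m binary items, by expectation-maximization. The E-step
#' computes per-row class responsibilities proportional to
#' `delta_c * prod_i tau_ci^y (1-tau_ci)^(1-y)`; the M-step sets `delta` to
#' the mean responsibility and `tau` to the responsibility-weighted item
#' means. Iteration stops when the absolute change in log-likelihood falls
#' below `tol` or after `max_iter` iterations. Multiple random restarts
#' (initial responsibilities drawn row-wise from a flat Dirichlet) guard
#' against local maxima; the best restart by final log-likelihood is
#' returned.
#'
#' @param Y N x m binary (0/1) matrix or data frame of item responses; no
#'   missing entries.
#' @param C Number of latent classes (>= 1).
#' @param max_iter Maximum EM iterations per restart. Default 300.
#' @param tol Absolute log-likelihood convergence tolerance. Default 1e-7.
#' @param n_restarts Number of random restarts. Default 20.
#' @param seed Optional integer seed for the restart initializations.
#' @param weights Optional positive row weights; when supplied they
#'   multiply each row's log-likelihood contribution (a weighted
#'   pseudo-likelihood).
#' @return An object of class `lca_fit`: a list with `delta` (length C,
#'   floored at 1e-8 and renormalized), `tau` (C x m, clamped to
#'   `[1e-6, 1 - 1e-6]`), `C`, `m`, `n_params` = (C-1) + C*m, `loglik`,
#'   `loglik_trace` (non-decreasing within the winning restart), `n_iter`,
#'   `converged`, `restart_logliks`, `N`, `sum_weights`, and `seed`.
#' @export
#' @examples
#' Y <- matrix(rbinom(200 * 4, 1, 0.5), 200, 4)
#' fit <- fit_em(Y, C = 2, n_restarts = 3, seed = 1)
#' fit$loglik
fit_em <- function(Y, C, max_iter = 300L, tol = 1e-7, n_restarts = 20L,
                   seed = NULL, weights = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (nrow(Y) == 0) abort("`Y` must have at least one row.")
  if (C < 1) abort("`C` must be a positive integer.")
  if (nrow(Y) < C) abort("Need at least C rows to fit C classes.")
  if (any(!(Y %in% c(0, 1)))) abort("`Y` entries must be 0 or 1.")
  m <- ncol(Y)
  pc <- collapse_patterns(Y, weights)
  Yp <- pc$Y; wp <- pc$w
  W <- sum(wp)
  if (!is.null(seed)) set.seed(seed)

  run_one <- function() {
    ## flat-Dirichlet initial responsibilities per pattern
    R <- matrix(-log(runif(nrow(Yp) * C)), ncol = C)
    R <- R / rowSums(R)
    delta <- tau <- NULL
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      ## M-step from current responsibilities
      wc <- colSums(wp * R)
      delta <- pmax(wc / W, 1e-8); delta <- delta / sum(delta)
      tau <- t(crossprod(wp * R, Yp) / wc)
      tau <- t(pmin(pmax(tau, 1e-6), 1 - 1e-6))
      if (iter >= max_iter) break
      ## E-step at the new parameters; log-likelihood as a by-product
      ld <- pattern_logdens(Yp, delta, tau)
      ll_row <- logsumexp_rows(ld)
      ll <- sum(wp * ll_row)
      R <- exp(ld - ll_row)
      iter <- iter + 1L
      trace <- c(trace, ll)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    ## final log-likelihood at the returned (post-M-step) parameters
    ll_final <- sum(wp * logsumexp_rows(pattern_logdens(Yp, delta, tau)))
    list(delta = delta, tau = tau, loglik = ll_final,
         trace = c(trace, ll_final), n_iter = iter, converged = converged)
  }

  runs <- lapply(seq_len(max(1L, n_restarts)), function(r) run_one())
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]
  tau <- best$tau
  colnames(tau) <- colnames(Y)
  structure(list(
    delta = best$delta, tau = tau, C = as.integer(C), m = as.integer(m),
    n_params = (C - 1L) + C * m,
    loglik = best$loglik, loglik_trace = best$trace,
    n_iter = best$n_iter, converged = best$converged,
    restart_logliks = lls, N = nrow(Y), sum_weights = W, seed = seed
  ), class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf(
    "Binary latent class model: C = %d classes, m = %d items, N = %d\n",
    x$C, x$m, x$N))
  cat(sprintf("log-likelihood %.4f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "max iterations reached"))
  cat("class shares:", paste(sprintf("%.3f", x$delta), collapse = " "), "\n")
  invisible(x)
}

#' Information criteria for a latent class fit
#'
#' AIC = -2l + 2k and BIC = -2l + k log(N), with k = (C - 1) + C*m free
#' parameters (class shares plus class-conditional item probabilities).
#'
#' @param fit An `lca_fit`.
#' @param N Sample size; defaults to the fit's row count.
#' @return Named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit, N = fit$N) {
  if (N <= 0) abort("`N` must be positive.")
  k <- fit$n_params
  c(AIC = -2 * fit$loglik + 2 * k,
    BIC = -2 * fit$loglik + k * log(N))
}

#' Select the number of latent classes by BIC
#'
#' Fits each candidate class count with shared EM settings and selects the
#' candidate minimizing BIC (AIC is reported alongside). A candidate whose
#' fit fails is recorded and selection proceeds over the remainder.
#'
#' @param Y Binary response matrix.
#' @param candidates Candidate class counts. Default `2:4`.
#' @param max_iter,tol,n_restarts,seed,weights Passed to [fit_em()]; each
#'   candidate uses a seed offset derived from `seed` so fits are
#'   independently reproducible.
#' @return A list with `table` (tibble of C, loglik, k, AIC, BIC,
#'   converged, error), `chosen_C`, and `fits` (named list of `lca_fit`
#'   objects for the successful candidates).
#' @export
select_num_classes <- function(Y, candidates = 2:4, max_iter = 300L,
                               tol = 1e-7, n_restarts = 20L, seed = NULL,
                               weights = NULL) {
  if (length(candidates) == 0) abort("`candidates` must be non-empty.")
  fits <- list(); rows <- list()
  for (C in candidates) {
    cseed <- if (is.null(seed)) NULL else stage_seed(seed, paste0("lca", C))
    res <- tryCatch(
      fit_em(Y, C, max_iter = max_iter, tol = tol,
             n_restarts = n_restarts, seed = cseed, weights = weights),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[as.character(C)]] <- tibble::tibble(
        C = C, loglik = NA_real_, k = NA_integer_, AIC = NA_real_,
        BIC = NA_real_, converged = NA, error = conditionMessage(res))
    } else {
      ic <- information_criteria(res)
      fits[[as.character(C)]] <- res
      rows[[as.character(C)]] <- tibble::tibble(
        C = C, loglik = res$loglik, k = res$n_params,
        AIC = ic[["AIC"]], BIC = ic[["BIC"]],
        converged = res$converged, error = NA_character_)
    }
  }
  tab <- dplyr::bind_rows(rows)
  ok <- !is.na(tab$BIC)
  if (!any(ok)) abort("Every candidate fit failed.")
  chosen <- tab$C[ok][which.min(tab$BIC[ok])]
  list(table = tab, chosen_C = chosen, fits = fits)
}

#' Order and label latent classes by egalitarian score
#'
#' Resolves label switching by ranking classes on their egalitarian score —
#' the mean over items of the probability of the positive response. For a
#' three-class fit the classes are labeled `high`, `moderate`, `low`
#' egalitarian in descending score order (ties broken by class share,
#' descending); for other C the labels are `class_1..class_C` in score
#' order. The permutation is applied to `delta`, `tau`, and the restart
#' metadata-free copies; it is also returned for relabeling assignments.
#'
#' @param fit An `lca_fit`.
#' @return The fit with classes permuted, plus `labels` (character) and
#'   `perm` (the permutation applied: new position k holds old class
#'   `perm[k]`).
#' @export
label_classes <- function(fit) {
  score <- rowMeans(fit$tau)
  perm <- order(-score, -fit$delta)
  fit$delta <- fit$delta[perm]
  fit$tau <- fit$tau[perm, , drop = FALSE]
  fit$labels <- if (fit$C == 3) ATTITUDE_CLASS_LEVELS
                else paste0("class_", seq_len(fit$C))
  names(fit$delta) <- fit$labels
  rownames(fit$tau) <- fit$labels
  fit$perm <- perm
  fit
}

#' Posterior class membership and modal assignment
#'
#' Bayes-rule posterior probabilities of class membership for each row of
#' `Y` under a fitted model, and the modal (highest-posterior) class, ties
#' going to the lower class index.
#'
#' @param fit An `lca_fit` (labeled or not).
#' @param Y Binary response matrix with the fit's m columns.
#' @return A list with `posterior` (N x C matrix, rows summing to 1) and
#'   `modal` (integer class index; if the fit is labeled, a factor with the
#'   class labels).
#' @export
posterior_assign <- function(fit, Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) != fit$m) abort("`Y` has a different number of items.")
  ld <- pattern_logdens(Y, fit$delta, fit$tau)
  post <- exp(ld - logsumexp_rows(ld))
  modal <- max.col(post, ties.method = "first")
  if (!is.null(fit$labels)) {
    colnames(post) <- fit$labels
    modal <- factor(fit$labels[modal], levels = fit$labels)
  }
  list(posterior = post, modal = modal)
}

#' Likelihood-ratio statistic against the saturated pattern model
#'
#' G-squared = 2 (l_sat - l_fit), where the saturated log-likelihood comes
#' from the observed response-pattern frequencies
#' (sum_p n_p log(n_p / N)), with degrees of freedom
#' (2^m - 1) - k for k model parameters.
#'
#' @param fit An `lca_fit`.
#' @param Y The binary response matrix the model was fitted to.
#' @param weights Optional row weights matching the fit.
#' @return A list with `G2`, `df`, `loglik_sat`, `loglik_fit`, and
#'   `n_patterns` (count of observed distinct patterns).
#' @export
likelihood_ratio_statistic <- function(fit, Y, weights = NULL) {
  Y <- as.matrix(Y)
  pc <- collapse_patterns(Y, weights)
  W <- sum(pc$w)
  ll_sat <- sum(pc$w * log(pc$w / W))
  ll_fit <- mixture_loglik(Y, fit$delta, fit$tau, weights)
  list(G2 = 2 * (ll_sat - ll_fit),
       df = (2^fit$m - 1) - fit$n_params,
       loglik_sat = ll_sat, loglik_fit = ll_fit,
       n_patterns = nrow(pc$Y))
}
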