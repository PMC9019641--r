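#' Proportional-odds ordinal logistic regression
#'
#' Maximum-likelihood fit of the cumulative-logit proportional-odds model
#' `P(Y <= k | x) = logit^-1(alpha_k - x'beta)` for an ordered outcome with
#' K >= 2 categories (with K = 2 the model is exactly binary logistic
#' regression on the upper category). The log-likelihood is maximised by
#' Newton iteration with an analytic gradient and a central-difference
#' Hessian of that gradient; standard errors come from the observed
#' information at the optimum. Odds ratios are `exp(beta)` with Wald 95%
#' confidence intervals.
#'
#' Covariates with zero variance are not estimable: their coefficient is
#' reported as 0 with `NA` standard error and the model is fitted on the
#' remaining columns (an empty design gives the intercept-only model, whose
#' thresholds are the empirical cumulative logits). Complete or
#' quasi-complete separation (coefficients diverging during iteration) is
#' reported as an error; non-convergence within `max_iter` is flagged and
#' the estimates are withheld (`NA`).
#'
#' @param outcome ordered factor (or coercible integer codes) with the
#'   ordinal response; unused levels are dropped.
#' @param x numeric design matrix (n rows; no intercept column -- the
#'   thresholds play that role).
#' @param tol convergence tolerance on the max-norm of the score (1e-8).
#' @param max_iter Newton iteration cap.
#' @return an object of class `ordinal_fit`: `thresholds`, `coefficients`,
#'   `se_thresholds`, `se_coefficients`, `t_values`, `odds_ratio`,
#'   `ci_lower`, `ci_upper`, `log_lik`, `converged`, `n`, `levels`,
#'   `vcov`, `dropped` (names of zero-variance covariates).
#' @examples
#' set.seed(1)
#' x <- cbind(grp = rbinom(500, 1, 0.5))
#' y <- simulate_proportional_odds(x, thresholds = c(-0.5, 1.5), beta = 0.8)
#' fit_proportional_odds(y, x)
#' @export
fit_proportional_odds <- function(outcome, x, tol = 1e-8, max_iter = 100L) {
  if (is.null(dim(x))) x <- cbind(x = x)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.factor(outcome)) outcome <- factor(outcome)
  outcome <- droplevels(outcome)
  if (any(is.na(outcome)) || any(is.na(x))) stop("missing values not allowed")
  if (nrow(x) != length(outcome)) stop("outcome and design matrix sizes differ")
  K <- nlevels(outcome)
  if (K < 2L) stop("outcome needs at least 2 observed categories")
  y <- as.integer(outcome)
  n <- length(y)

  const_cols <- apply(x, 2L, function(v) max(v) == min(v))
  dropped <- colnames(x)[const_cols]
  xf <- x[, !const_cols, drop = FALSE]
  p <- ncol(xf)

  # log-likelihood and analytic score in theta = (alpha_1..alpha_{K-1}, beta)
  loglik <- function(theta) {
    a <- theta[seq_len(K - 1L)]
    if (is.unsorted(a, strictly = TRUE)) return(-Inf)
    eta <- if (p) drop(xf %*% theta[K:(K - 1L + p)]) else rep(0, n)
    up <- ifelse(y == K, 1, stats::plogis(a[pmin(y, K - 1L)] - eta))
    lo <- ifelse(y == 1L, 0, stats::plogis(a[pmax(y - 1L, 1L)] - eta))
    pr <- up - lo
    if (any(pr <= 0)) return(-Inf)
    sum(log(pr))
  }
  score <- function(theta) {
    a <- theta[seq_len(K - 1L)]
    eta <- if (p) drop(xf %*% theta[K:(K - 1L + p)]) else rep(0, n)
    up_f <- ifelse(y == K, 0, stats::dlogis(a[pmin(y, K - 1L)] - eta))
    lo_f <- ifelse(y == 1L, 0, stats::dlogis(a[pmax(y - 1L, 1L)] - eta))
    up_F <- ifelse(y == K, 1, stats::plogis(a[pmin(y, K - 1L)] - eta))
    lo_F <- ifelse(y == 1L, 0, stats::plogis(a[pmax(y - 1L, 1L)] - eta))
    pr <- up_F - lo_F
    g_a <- numeric(K - 1L)
    for (k in seq_len(K - 1L)) {
      g_a[k] <- sum(up_f[y == k] / pr[y == k]) -
                sum(lo_f[y == k + 1L] / pr[y == k + 1L])
    }
    g_b <- if (p) drop(crossprod(xf, -(up_f - lo_f) / pr)) else numeric(0)
    c(g_a, g_b)
  }
  num_hessian <- function(theta) {
    m <- length(theta)
    H <- matrix(0, m, m)
    h <- pmax(1e-5, 1e-5 * abs(theta))
    for (j in seq_len(m)) {
      tp <- theta; tp[j] <- tp[j] + h[j]
      tm <- theta; tm[j] <- tm[j] - h[j]
      H[, j] <- (score(tp) - score(tm)) / (2 * h[j])
    }
    (H + t(H)) / 2
  }

  cum <- cumsum(tabulate(y, K) / n)
  theta <- c(stats::qlogis(cum[seq_len(K - 1L)]), rep(0, p))
  ll <- loglik(theta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- score(theta)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- num_hessian(theta)
    step <- tryCatch(-solve(H, g), error = function(e) g)  # fall back to ascent
    # step-halving: keep thresholds ordered and the log-likelihood rising
    lam <- 1
    repeat {
      cand <- theta + lam * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- theta; llc <- ll; break }
    }
    theta <- cand; ll <- llc
    if (p && max(abs(theta[K:(K - 1L + p)])) > 30)
      stop("complete (or quasi-complete) separation detected: ",
           "a coefficient diverged during fitting")
  }
  if (!converged) {
    warning("proportional-odds fit did not converge in ", max_iter,
            " iterations; estimates withheld")
    theta[] <- NA_real_
  }

  vc <- matrix(NA_real_, length(theta), length(theta))
  if (converged) {
    info <- -num_hessian(theta)
    vc <- tryCatch(solve(info), error = function(e) vc)
  }
  se <- sqrt(pmax(diag(vc), 0))

  a_idx <- seq_len(K - 1L)
  beta <- se_beta <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  beta[dropped] <- 0
  if (p) {
    beta[colnames(xf)] <- theta[-a_idx]
    se_beta[colnames(xf)] <- se[-a_idx]
  }
  z <- stats::qnorm(0.975)
  structure(list(
    thresholds = stats::setNames(theta[a_idx],
      paste(levels(outcome)[-K], levels(outcome)[-1L], sep = "|")),
    se_thresholds = se[a_idx],
    coefficients = beta,
    se_coefficients = se_beta,
    t_values = beta / se_beta,
    odds_ratio = exp(beta),
    ci_lower = exp(beta - z * se_beta),
    ci_upper = exp(beta + z * se_beta),
    log_lik = if (converged) ll else NA_real_,
    converged = converged,
    n = n, levels = levels(outcome), vcov = vc, dropped = dropped
  ), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds ordinal logistic regression (n = %d, %s)\n",
              x$n, if (x$converged) "converged" else "NOT converged"))
  cat("Outcome levels:", paste(x$levels, collapse = " < "), "\n\nThresholds:\n")
  print(round(cbind(estimate = x$thresholds, se = x$se_thresholds), 4))
  if (length(x$coefficients)) {
    cat("\nCoefficients:\n")
    print(round(cbind(B = x$coefficients, se = x$se_coefficients,
                      t = x$t_values, OR = x$odds_ratio,
                      ci_low = x$ci_lower, ci_high = x$ci_upper), 4))
  }
  cat(sprintf("\nlog-likelihood: %.4f\n", x$log_lik))
  invisible(x)
}

#' Simulate from a proportional-odds model
#'
#' Draws ordinal outcomes with `P(Y <= k | x) = logit^-1(alpha_k - x'beta)`
#' by thresholding a logistic latent variable `x'beta + e`,
#' `e ~ Logistic(0, 1)`, at the `alpha_k`. Used for parameter-recovery tests
#' and power exploration.
#'
#' @param x design matrix (n rows).
#' @param thresholds strictly increasing numeric vector `alpha` (length K-1).
#' @param beta coefficient vector matching `ncol(x)`.
#' @return integer vector of outcomes in 1..K.
#' @export
simulate_proportional_odds <- function(x, thresholds, beta) {
  x <- as.matrix(x)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (length(beta) != ncol(x)) stop("beta length must match ncol(x)")
  latent <- drop(x %*% beta) + stats::rlogis(nrow(x))
  1L + rowSums(outer(latent, thresholds, `>`))
}
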