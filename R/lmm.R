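#' Maximum-likelihood random-intercept linear mixed model
#'
#' Fits `y ~ fixed effects + (1 | subject)` by maximum likelihood (not
#' REML). The likelihood is profiled over the variance ratio
#' `psi = sigma^2_subject / sigma^2_resid`: for each `psi` the generalized
#' least-squares estimates of the fixed effects and of the residual variance
#' have closed forms (per-subject covariance `I + psi * J` is inverted
#' analytically), leaving a one-dimensional optimization of the profile
#' log-likelihood over `log(psi)`. The boundary `psi = 0` (no subject
#' effect, ordinary regression) is compared explicitly and reported.
#'
#' ML rather than REML is used throughout so that likelihood-ratio tests on
#' fixed effects between nested fits are valid.
#'
#' @param formula fixed-effects formula, e.g. `z_rt ~ position`.
#' @param data data frame / tibble containing the model variables.
#' @param subject name of the grouping column (default `"subject"`).
#' @param tol convergence tolerance on the profile log-likelihood
#'   (default 1e-8).
#' @return object of class `"lmm_fit"`: list with `coefficients`, `se`,
#'   `vcov`, `sigma2_resid`, `sigma2_subject`, `psi`, `logLik`, `n`,
#'   `n_subjects`, `df_fixed`, `boundary` (TRUE when psi = 0), `converged`,
#'   `formula`.
#' @export
fit_lmm_ml <- function(formula, data, subject = "subject", tol = 1e-8) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  used <- rownames(mf)
  g <- factor(data[[subject]][as.integer(used)])
  if (nlevels(g) < 2L) stop("need at least 2 subjects")
  p <- ncol(X)
  if (p > 0L && qr(X)$rank < p) stop("singular fixed-effect design")
  N <- length(y)

  # Per-subject sufficient statistics: likelihood evaluation is O(S * p^2).
  idx <- split(seq_len(N), g)
  S <- length(idx)
  XtX <- vector("list", S); Xty <- vector("list", S)
  sX <- vector("list", S); sy <- numeric(S); yty <- numeric(S)
  ni <- integer(S)
  for (i in seq_len(S)) {
    ii <- idx[[i]]
    Xi <- X[ii, , drop = FALSE]; yi <- y[ii]
    XtX[[i]] <- crossprod(Xi); Xty[[i]] <- crossprod(Xi, yi)
    sX[[i]] <- colSums(Xi); sy[i] <- sum(yi); yty[i] <- sum(yi^2)
    ni[i] <- length(ii)
  }

  profile_fit <- function(psi) {
    A <- matrix(0, p, p); b <- numeric(p); q <- 0; ldet <- 0
    for (i in seq_len(S)) {
      ci <- psi / (1 + ni[i] * psi)
      A <- A + XtX[[i]] - ci * tcrossprod(sX[[i]])
      b <- b + Xty[[i]] - ci * sX[[i]] * sy[i]
      q <- q + yty[i] - ci * sy[i]^2
      ldet <- ldet + log1p(ni[i] * psi)
    }
    if (p > 0L) {
      beta <- drop(solve(A, b))
      rss <- q - 2 * sum(beta * b) + sum(beta * (A %*% beta))
      # guard tiny negative round-off
      rss <- max(rss, 0)
    } else {
      beta <- numeric(0); rss <- q
    }
    sigma2 <- rss / N
    ll <- -0.5 * (N * log(2 * pi * sigma2) + ldet + N)
    list(beta = beta, sigma2 = sigma2, logLik = ll, A = A, ldet = ldet)
  }

  obj <- function(lpsi) -profile_fit(exp(lpsi))$logLik
  opt <- optimize(obj, interval = c(-14, 8), tol = 1e-10)
  ll_int <- -opt$objective
  ll_zero <- profile_fit(0)$logLik
  if (ll_zero >= ll_int - tol) {
    psi <- 0; boundary <- TRUE
  } else {
    psi <- exp(opt$minimum); boundary <- FALSE
  }
  fit <- profile_fit(psi)
  vc <- if (p > 0L) fit$sigma2 * solve(fit$A) else matrix(0, 0, 0)
  se <- if (p > 0L) sqrt(diag(vc)) else numeric(0)
  names(fit$beta) <- colnames(X)
  if (p > 0L) names(se) <- colnames(X)
  structure(list(
    coefficients = fit$beta, se = se, vcov = vc,
    sigma2_resid = fit$sigma2, sigma2_subject = psi * fit$sigma2,
    psi = psi, logLik = fit$logLik, n = N, n_subjects = S, df_fixed = p,
    boundary = boundary, converged = TRUE, formula = formula),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat("  fixed:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d trials, %d subjects; logLik = %.3f\n",
              x$n, x$n_subjects, x$logLik))
  cat(sprintf("  sigma2_subject = %.4g%s, sigma2_resid = %.4g\n",
              x$sigma2_subject, if (x$boundary) " (boundary)" else "",
              x$sigma2_resid))
  if (x$df_fixed > 0) {
    print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested maximum-likelihood fits
#'
#' Computes `chi^2 = 2 * (logLik_full - logLik_reduced)` with degrees of
#' freedom equal to the difference in fixed-effect counts, referred to the
#' chi-squared distribution. Both fits must be maximum-likelihood fits on
#' the same observations with nested fixed-effect designs; nesting is
#' checked via parameter counts, sample size and the log-likelihood
#' ordering (a "reduced" model fitting better than the full one beyond
#' numerical tolerance is rejected as non-nested).
#'
#' @param full,reduced `"lmm_fit"` or `"glmm_fit"` objects.
#' @param tol tolerance for a negative chi-squared statistic due to
#'   round-off (default 1e-6); values in `(-tol, 0)` are clipped to 0.
#' @return object of class `"lrt_result"`: list with `chisq`, `df`,
#'   `p_value`, `logLik_full`, `logLik_reduced`.
#' @export
lrt <- function(full, reduced, tol = 1e-6) {
  if (full$n != reduced$n) {
    stop("fits are on different numbers of observations; not nested")
  }
  df <- full$df_fixed - reduced$df_fixed
  if (df <= 0L) stop("`full` must have more fixed-effect parameters than `reduced`")
  chisq <- 2 * (full$logLik - reduced$logLik)
  if (chisq < -tol) {
    stop("reduced model has higher likelihood than full model; models are not nested")
  }
  chisq <- max(chisq, 0)
  structure(list(chisq = chisq, df = df,
                 p_value = pchisq(chisq, df, lower.tail = FALSE),
                 logLik_full = full$logLik, logLik_reduced = reduced$logLik),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi^2(%d) = %.3f, p = %.4g\n", x$df, x$chisq, x$p_value))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$coefficients
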