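# Independent oracles used across test files. These deliberately re-derive
# results from first principles (brute force, closed forms) and never call
# the implementation paths they check.

# Brute-force peri-error classifier: for every trial, examine all error
# distances explicitly. O(n^2) per sequence.
oracle_classify <- function(correct, block, miss = rep(FALSE, length(correct))) {
  n <- length(correct)
  iso <- logical(n)
  for (i in seq_len(n)) {
    if (correct[i] || miss[i]) next
    nbr <- c(i - 3:1, i + 1:3)
    ok <- all(nbr >= 1 & nbr <= n) && all(block[nbr] == block[i]) &&
      all(correct[nbr])
    iso[i] <- isTRUE(ok)
  }
  lab <- character(n)
  for (i in seq_len(n)) {
    if (iso[i]) { lab[i] <- "ERROR_ISOLATED"; next }
    if (!correct[i]) { lab[i] <- "EXCLUDED"; next }
    d <- i - which(iso & block == block[i])
    near <- d[abs(d) <= 3]
    if (length(near) == 1) {
      lab[i] <- if (near > 0) paste0("ER_P", near) else paste0("ER_M", -near)
    } else if (length(near) >= 2) {
      lab[i] <- "EXCLUDED"
    } else {
      bad <- which(!correct & block == block[i])
      lab[i] <- if (length(bad) && any(abs(bad - i) <= 3)) "EXCLUDED"
                else "ERROR_FREE"
    }
  }
  factor(lab, levels = levels(classify_trials(c(TRUE), c(1L))))
}

# Closed-form Hann-windowed DFT coefficient of a sinusoid
# A*cos(2*pi*f0*t + phi) sampled at fs, window of nwin samples, evaluated at
# bin k (frequency k*fs/nwin). t = 0 at the first window sample.
oracle_hann_sin_power <- function(A, f0, phi, fs, nwin, k) {
  nidx <- 0:(nwin - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * nidx / nwin)
  x <- A * cos(2 * pi * f0 * nidx / fs + phi)
  co <- sum(w * x * exp(-2i * pi * k * nidx / nwin))
  Mod(co)^2 * 2 / sum(w)^2
}

# Analytic magnitude response of a digital Butterworth cascade at frequency
# f (Hz) for the package's zero-phase two-pass filters, evaluated directly
# from the filter polynomials.
oracle_filter_gain <- function(filt, f, fs, passes = 2) {
  z <- exp(-2i * pi * f / fs)
  H <- sum(filt$b * z^(seq_along(filt$b) - 1)) /
    sum(filt$a * z^(seq_along(filt$a) - 1))
  Mod(H)^passes
}

# Direct multivariate-normal log-likelihood of the random-intercept linear
# mixed model, evaluated by explicit covariance construction (no profiling,
# no closed-form inverses): oracle for the LMM optimizer.
oracle_lmm_loglik <- function(beta, sigma2_subj, sigma2_resid, y, X, g) {
  mu <- if (ncol(X)) drop(X %*% beta) else rep(0, length(y))
  ll <- 0
  for (s in unique(g)) {
    i <- which(g == s)
    V <- diag(sigma2_resid, length(i)) + sigma2_subj
    ll <- ll + mvn_logdens(y[i] - mu[i], V)
  }
  ll
}

mvn_logdens <- function(r, V) {
  L <- chol(V)
  -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(L))) +
            sum(backsolve(L, r, transpose = TRUE)^2))
}

# Unbiased column variances without extra dependencies.
matrixStats_colVars <- function(m) {
  (colMeans(m^2) - colMeans(m)^2) * nrow(m) / (nrow(m) - 1)
}

# Random correctness/block layouts for property tests.
random_layout <- function(n_trials, n_blocks = 2, p_err = 0.15,
                          p_miss = 0.05) {
  block <- sort(sample(seq_len(n_blocks), n_trials, replace = TRUE))
  u <- runif(n_trials)
  miss <- u < p_miss
  correct <- u >= p_miss + p_err
  list(correct = correct, block = block, miss = miss)
}
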