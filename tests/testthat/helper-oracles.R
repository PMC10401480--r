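# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# Wald z from a generic optimizer maximizing the joint two-group NB
# log-likelihood, with the covariance taken from the numerical Hessian.
oracle_wald_z <- function(y, sf, grp, alpha, groups = sort(unique(grp))) {
  nll <- function(beta) {
    mu <- sf * exp(beta[match(grp, groups)])
    -sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  q0 <- log(pmax(tapply(y / sf, grp, mean)[groups], 1e-6))
  fit <- stats::optim(unname(q0), nll, method = "BFGS", hessian = TRUE)
  v <- solve(fit$hessian)
  lfc <- (fit$par[2] - fit$par[1]) / log(2)
  se <- sqrt(v[1, 1] + v[2, 2] - 2 * v[1, 2]) / log(2)
  lfc / se
}

# Literal Benjamini-Hochberg step-up enumeration.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  q
}

# Median-of-ratios by explicit enumeration.
oracle_size_factors <- function(counts) {
  ref <- apply(counts, 1, function(r) all(r > 0))
  g <- apply(counts[ref, , drop = FALSE], 1,
             function(r) prod(r)^(1 / length(r)))
  sapply(seq_len(ncol(counts)), function(j)
    stats::median(counts[ref, j] / g))
}
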