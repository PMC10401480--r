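## Negative-binomial differential-expression engine.
##
## Two-group Wald test on a log-link NB model with fixed per-feature
## dispersion (variance = mu + alpha * mu^2) and per-sample size factors
## entering as offsets.  Group means are fitted by Newton iteration on
## the log scale (the per-group log-likelihood is strictly concave in
## the log-mean), vectorized across features.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors correcting for sequencing depth and
#' composition.  Reference features are those with a nonzero count in
#' every sample; each sample's factor is the median of its counts
#' divided by the per-feature geometric means.
#'
#' @param counts integer matrix, features x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) stop("size factors need at least two samples")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no feature has nonzero counts in every sample; ",
         "cannot form the median-of-ratios reference ",
         "(pseudo-reference fallback is disabled)")
  sub <- counts[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion estimates
#'
#' Per-feature NB dispersion `alpha` (variance = mu + alpha * mu^2)
#' estimated from size-factor-normalized counts: the within-group
#' variance pooled across the design's groups, combined with the pooled
#' mean as `alpha = max(floor, (V - m) / m^2)`.  No shrinkage is
#' applied.
#'
#' @param counts integer matrix, features x samples.
#' @param size_factors named positive numeric vector per sample.
#' @param design named character vector, sample_id -> group.
#' @param floor lower bound for alpha (default 1e-8), also used for
#'   features whose pooled mean is zero (these are flagged).
#' @return named numeric vector of dispersions with attribute
#'   `"zero_mean"` listing features that had no counts.
#' @export
estimate_dispersions <- function(counts, size_factors, design,
                                 floor = 1e-8) {
  assert_count_matrix(counts)
  assert_design(design, counts)
  samples <- intersect(colnames(counts), names(design))
  q <- sweep(counts[, samples, drop = FALSE], 2,
             size_factors[samples], "/")
  groups <- unique(design[samples])
  n <- length(samples)
  if (n - length(groups) < 1)
    stop("need at least one residual degree of freedom per design")
  m <- rowMeans(q)
  ss <- 0
  for (g in groups) {
    gs <- samples[design[samples] == g]
    if (length(gs) < 2)
      stop("group '", g, "' has fewer than 2 samples")
    sub <- q[, gs, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / (n - length(groups))
  zero <- m == 0
  alpha <- rep(floor, nrow(q))
  alpha[!zero] <- pmax(floor, (v[!zero] - m[!zero]) / m[!zero]^2)
  names(alpha) <- rownames(counts)
  if (any(zero))
    attr(alpha, "zero_mean") <- rownames(counts)[zero]
  alpha
}

## Vectorized Newton fit of per-group NB log-means.
## y: features x samples counts; sf: size factors; alpha: per-feature
## dispersion.  Returns list(beta = log fitted mean at size factor 1,
## info = observed information of the log-likelihood in beta).
fit_nb_group <- function(y, sf, alpha, max_iter = 100L, tol = 1e-12) {
  n <- ncol(y)
  zero <- rowSums(y) == 0
  qbar <- rowSums(sweep(y, 2, sf, "/")) / n
  beta <- log(pmax(qbar, 1e-8))
  active <- which(!zero)
  sfm <- matrix(sf, nrow(y), n, byrow = TRUE)
  for (iter in seq_len(max_iter)) {
    if (!length(active)) break
    mu <- sfm[active, , drop = FALSE] * exp(beta[active])
    a <- alpha[active]
    denom <- 1 + a * mu
    score <- rowSums((y[active, , drop = FALSE] - mu) / denom)
    info <- rowSums(mu * (1 + a * y[active, , drop = FALSE]) / denom^2)
    step <- score / info
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 3), -3)   # damp far-from-optimum jumps
    beta[active] <- beta[active] + step
    active <- active[abs(step) > tol]
  }
  mu <- sfm * exp(beta)
  info <- rowSums(mu * (1 + alpha * y) / (1 + alpha * mu)^2)
  beta[zero] <- -Inf
  info[zero] <- 0
  list(beta = beta, info = info, zero = zero)
}

## Observed information for an all-zero group evaluated at a fixed
## (capped) log-mean.
info_at_beta <- function(beta, sf, alpha) {
  mu <- outer(exp(beta), sf)
  rowSums(mu / (1 + alpha * mu)^2)
}

#' Two-group negative-binomial Wald test
#'
#' Fits per-group NB means by maximum likelihood (log link, size-factor
#' offsets, fixed per-feature dispersion) and tests the log2 fold change
#' between the numerator and denominator groups with a Wald z statistic.
#' The standard error comes from the observed information of the two
#' group fits.  Positive `log2fc` means higher expression in the
#' numerator group.
#'
#' Features with zero counts in both groups get `log2fc = 0`, `wald_p =
#' 1`.  If exactly one group is all-zero the log2 fold change is capped
#' at `+/- lfc_cap`, the p-value computed from the capped fit, and the
#' feature flagged `"lfc_capped"`.
#'
#' @param counts integer matrix, features x samples.
#' @param size_factors named numeric vector per sample.
#' @param dispersions named numeric vector per feature.
#' @param design named character vector, sample_id -> group.
#' @param numerator_group,denominator_group group labels contrasted.
#' @param lfc_cap absolute cap on log2 fold change for one-sided zero
#'   groups (default 10).
#' @return data.frame with columns `feature_id`, `base_mean`, `log2fc`,
#'   `se`, `wald_p`, `padj`, `flag`, plus attributes `numerator` and
#'   `denominator`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, design,
                         numerator_group, denominator_group,
                         lfc_cap = 10) {
  assert_count_matrix(counts)
  assert_design(design, NULL)
  for (g in c(numerator_group, denominator_group)) {
    if (!g %in% design) stop("group not present in design: ", g)
  }
  s_num <- intersect(colnames(counts),
                     names(design)[design == numerator_group])
  s_den <- intersect(colnames(counts),
                     names(design)[design == denominator_group])
  if (length(s_num) < 2 || length(s_den) < 2)
    stop("both groups need at least 2 samples in the matrix")
  alpha <- dispersions[rownames(counts)]
  if (any(is.na(alpha))) stop("dispersions missing for some features")

  y_num <- counts[, s_num, drop = FALSE]
  y_den <- counts[, s_den, drop = FALSE]
  sf_num <- size_factors[s_num]
  sf_den <- size_factors[s_den]
  fit_num <- fit_nb_group(y_num, sf_num, alpha)
  fit_den <- fit_nb_group(y_den, sf_den, alpha)

  ln2 <- log(2)
  log2fc <- (fit_num$beta - fit_den$beta) / ln2
  se <- sqrt(1 / fit_num$info + 1 / fit_den$info) / ln2
  flag <- rep("", nrow(counts))

  both0 <- fit_num$zero & fit_den$zero
  num0 <- fit_num$zero & !fit_den$zero
  den0 <- !fit_num$zero & fit_den$zero

  if (any(num0)) {
    beta_cap <- fit_den$beta[num0] - lfc_cap * ln2
    info_cap <- info_at_beta(beta_cap, sf_num, alpha[num0])
    log2fc[num0] <- -lfc_cap
    se[num0] <- sqrt(1 / info_cap + 1 / fit_den$info[num0]) / ln2
    flag[num0] <- "lfc_capped"
  }
  if (any(den0)) {
    beta_cap <- fit_num$beta[den0] - lfc_cap * ln2
    info_cap <- info_at_beta(beta_cap, sf_den, alpha[den0])
    log2fc[den0] <- lfc_cap
    se[den0] <- sqrt(1 / fit_num$info[den0] + 1 / info_cap) / ln2
    flag[den0] <- "lfc_capped"
  }
  if (any(both0)) {
    log2fc[both0] <- 0
    se[both0] <- NA_real_
    flag[both0] <- "zero_both"
  }

  z <- ifelse(is.na(se) | se == 0, 0, log2fc / se)
  wald_p <- 2 * stats::pnorm(-abs(z))
  wald_p[both0] <- 1

  base_mean <- rowMeans(cbind(sweep(y_num, 2, sf_num, "/"),
                              sweep(y_den, 2, sf_den, "/")))
  res <- data.frame(
    feature_id = rownames(counts),
    base_mean = base_mean,
    log2fc = log2fc,
    se = se,
    wald_p = wald_p,
    padj = bh_adjust(wald_p),
    flag = flag,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "numerator") <- numerator_group
  attr(res, "denominator") <- denominator_group
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (via [stats::p.adjust]); input order is preserved and values are
#' clipped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
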