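# Small in-code fixtures shared across the suite.

make_counts <- function(values, n_feat, n_samp,
                        feat = sprintf("F%02d", seq_len(n_feat)),
                        samp = sprintf("S%02d", seq_len(n_samp))) {
  matrix(values, n_feat, n_samp, dimnames = list(feat, samp))
}

# Two-group NB fixture with a few planted effects.
make_two_group <- function(n_feat = 50, n1 = 8, n2 = 6, alpha = 0.2,
                           n_effect = 10, effect = 4, seed = 7) {
  set.seed(seed)
  mu <- exp(stats::runif(n_feat, log(20), log(500)))
  eff <- rep(1, n_feat)
  eff[seq_len(n_effect)] <- effect
  counts <- cbind(
    matrix(stats::rnbinom(n_feat * n1, mu = mu, size = 1 / alpha),
           n_feat, n1),
    matrix(stats::rnbinom(n_feat * n2, mu = mu * eff, size = 1 / alpha),
           n_feat, n2)
  )
  dimnames(counts) <- list(sprintf("F%02d", seq_len(n_feat)),
                           sprintf("S%02d", seq_len(n1 + n2)))
  design <- stats::setNames(rep(c("a", "b"), c(n1, n2)), colnames(counts))
  list(counts = counts, design = design, alpha = alpha)
}

# DE result table built directly, for gate tests.
make_de <- function(feature_id, log2fc, padj) {
  n <- length(feature_id)
  data.frame(feature_id = feature_id, base_mean = rep(10, n),
             log2fc = log2fc, se = rep(1, n), wald_p = padj,
             padj = padj, flag = rep("", n), stringsAsFactors = FALSE)
}

quiet_gene_cascade <- function(co, config = cascade_config()) {
  suppressWarnings(run_gene_cascade(co$counts, co$lengths, co$design,
                                    co$catalog, co$tissue_medians, config))
}

quiet_isoform_cascade <- function(co, iso, gene_candidates = NULL,
                                  config = cascade_config()) {
  suppressWarnings(run_isoform_cascade(iso$counts, iso$lengths, co$design,
                                       iso$tx2gene, co$catalog, iso$medians,
                                       config, gene_candidates))
}
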