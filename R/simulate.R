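## Synthetic-cohort generator.
##
## Emulates the statistical structure the cascade assumes: NB counts
## with group-specific means and per-sample size factors, a GTEx-style
## feature x tissue median matrix, surface-annotation files spread over
## five source types, and transcript-isoform switches.  Planted feature
## classes are constructed so that each one exercises exactly one
## cascade stage:
##
##   true_target     NEPC-only surface gene        -> nominated
##   benign_leaky    NEPC-high, benign TPM > 1     -> dropped stage 1 (presence)
##   nonsurface      NEPC-only, not in catalog     -> dropped stage 3
##   broad_tissue    NEPC-only, broad GTEx         -> dropped stage 4
##   crpc_shared     high in NEPC and CRPC         -> dropped stage 5 (DE)
##   isoform_switch  flat gene total, NEPC-biased  -> gene dropped stage 1;
##                   isoform usage 0.1 -> 0.9         switch isoform nominated
##                                                    by the isoform branch

#' Simulation configuration
#'
#' Defaults are a scaled-down echo of the study cohort (benign 20,
#' PCa 20, CRPC 20, NEPC 12 samples; 2,000 genes; 30 normal tissues),
#' NB dispersion 0.2, background baseline means log-normal(log 50, 1),
#' and ten planted features per class at fold change 8.  Planted
#' features use an off-state mean of 1.5 counts and a 20-kb length,
#' chosen from the exact NB tail probabilities so that the 1-TPM
#' presence threshold (about four counts at this length and depth)
#' sits several-fold above the off state and several-fold below the
#' NEPC state — the count regime the threshold occupies in a
#' full-depth, full-transcriptome dataset.
#'
#' @param n_genes total number of genes.
#' @param group_sizes named integer vector of samples per group.
#' @param n_tissues number of GTEx-style tissues.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   background baseline means.
#' @param n_true_targets,n_crpc_shared,n_nonsurface,n_broad_tissue,n_benign_leaky
#'   planted class sizes.
#' @param n_isoform_switch number of isoform-switch genes.
#' @param target_fc planted fold change of NEPC-overexpressed classes.
#' @param off_mean off-state mean count of planted features.
#' @param leaky_benign_mean benign-group mean count of the
#'   benign-leaky class (chosen to put benign TPM well above 1).
#' @param planted_length transcript length (bp) of planted features.
#' @param switch_major_prop major-isoform usage proportion outside NEPC
#'   (reversed inside NEPC).
#' @param background_surface_frac fraction of background genes also
#'   placed in the surface catalog, so the catalog is not a pure
#'   truth oracle.
#' @param seed master seed; all random streams derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(benign = 20, pca = 20,
                                       crpc = 20, nepc = 12),
                       n_tissues = 30,
                       dispersion = 0.2,
                       baseline_meanlog = log(50),
                       baseline_sdlog = 1,
                       n_true_targets = 10,
                       n_crpc_shared = 10,
                       n_nonsurface = 10,
                       n_broad_tissue = 10,
                       n_benign_leaky = 10,
                       n_isoform_switch = 5,
                       target_fc = 8,
                       off_mean = 1.5,
                       leaky_benign_mean = 12,
                       planted_length = 20000,
                       switch_major_prop = 0.9,
                       background_surface_frac = 0.25,
                       seed = 1) {
  cfg <- as.list(environment())
  n_planted <- n_true_targets + n_crpc_shared + n_nonsurface +
    n_broad_tissue + n_benign_leaky + n_isoform_switch
  if (n_planted > n_genes)
    stop("planted class counts (", n_planted, ") exceed n_genes")
  if (is.null(names(group_sizes)) || length(group_sizes) < 2 ||
      any(group_sizes < 2))
    stop("group_sizes must be a named vector of >= 2 groups, ",
         "each with >= 2 samples")
  if (n_planted > 0 &&
      !all(c("benign", "pca", "crpc", "nepc") %in% names(group_sizes)))
    stop("planted classes require the four cohort groups ",
         "benign, pca, crpc, nepc")
  if (target_fc <= 1) stop("target_fc must exceed 1")
  structure(cfg, class = "sim_config")
}

rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Draws NB gene counts with group-specific means and log-uniform
#' per-sample size factors in \[0.5, 2\], builds the tissue-median
#' matrix, annotation sources and surface catalog, and the per-feature
#' truth table stating each feature's class, its expected cascade
#' outcome and — for decoys with a designed failure — the expected
#' drop reason.  Isoform-level counts for switch genes are drawn here
#' too (the gene row is their exact sum) and assembled by
#' [simulate_isoforms()].
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `counts`,
#'   `lengths`, `design`, `tissue_medians`, `sources` (annotation
#'   sources), `go_table`, `catalog`, `truth`, `isoforms` (transcript
#'   bundle for [simulate_isoforms()]) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  n_samp <- sum(gs)
  sample_ids <- sprintf("S%03d_%s", seq_len(n_samp), groups)
  design <- stats::setNames(groups, sample_ids)

  ng <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(ng))

  classes <- rep("background", ng)
  planted <- c(
    rep("true_target", config$n_true_targets),
    rep("crpc_shared", config$n_crpc_shared),
    rep("nonsurface", config$n_nonsurface),
    rep("broad_tissue", config$n_broad_tissue),
    rep("benign_leaky", config$n_benign_leaky),
    rep("isoform_switch", config$n_isoform_switch)
  )
  classes[sample.int(ng, length(planted))] <- sample(planted)

  ## group-specific means
  base <- stats::rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
  off <- config$off_mean
  fc <- config$target_fc
  switch_total <- 10 * off  # minor isoform sits at off_mean outside NEPC
  mu <- matrix(base, ng, length(gs), dimnames = list(gene_ids, names(gs)))
  if (length(planted)) {
    nepc_like <- classes %in% c("true_target", "nonsurface", "broad_tissue")
    mu[nepc_like, ] <- off
    mu[nepc_like, "nepc"] <- off * fc
    mu[classes == "crpc_shared", ] <- off
    mu[classes == "crpc_shared", c("crpc", "nepc")] <- off * fc
    mu[classes == "benign_leaky", ] <- off
    mu[classes == "benign_leaky", "benign"] <- config$leaky_benign_mean
    mu[classes == "benign_leaky", "nepc"] <- config$leaky_benign_mean * fc
    mu[classes == "isoform_switch", ] <- switch_total
  }

  lengths <- round(stats::rlnorm(ng, log(1000), 0.5))
  lengths <- pmax(lengths, 200)
  lengths[classes != "background"] <- config$planted_length
  names(lengths) <- gene_ids

  sf <- exp(stats::runif(n_samp, log(0.5), log(2)))
  names(sf) <- sample_ids

  alpha <- config$dispersion
  counts <- matrix(0L, ng, n_samp, dimnames = list(gene_ids, sample_ids))
  switch_genes <- gene_ids[classes == "isoform_switch"]
  plain <- classes != "isoform_switch"
  mu_samp <- mu[, groups, drop = FALSE] *
    matrix(sf, ng, n_samp, byrow = TRUE)
  counts[plain, ] <- rnb(sum(plain) * n_samp, mu_samp[plain, ], alpha)

  ## isoform-switch genes: draw the two isoforms, gene row is the sum
  p_major <- config$switch_major_prop
  iso_counts <- NULL
  iso_ids <- character()
  if (length(switch_genes)) {
    iso_ids <- c(paste0(switch_genes, ".iso1"),
                 paste0(switch_genes, ".iso2"))
    iso_counts <- matrix(0L, length(iso_ids), n_samp,
                         dimnames = list(iso_ids, sample_ids))
    is_nepc <- groups == "nepc"
    for (g in switch_genes) {
      tot <- switch_total
      mu1 <- ifelse(is_nepc, (1 - p_major) * tot, p_major * tot) * sf
      mu2 <- ifelse(is_nepc, p_major * tot, (1 - p_major) * tot) * sf
      iso_counts[paste0(g, ".iso1"), ] <- rnb(n_samp, mu1, alpha)
      iso_counts[paste0(g, ".iso2"), ] <- rnb(n_samp, mu2, alpha)
      counts[g, ] <- iso_counts[paste0(g, ".iso1"), ] +
        iso_counts[paste0(g, ".iso2"), ]
    }
  }

  tissue_ids <- sprintf("tissue%02d", seq_len(config$n_tissues))
  medians <- gene_tissue_medians(gene_ids, classes, tissue_ids)

  ann <- build_annotations(gene_ids, classes, config)
  truth <- truth_table(gene_ids, classes)

  iso <- assemble_isoform_bundle(counts, lengths, classes, gene_ids,
                                 switch_genes, iso_counts, medians,
                                 tissue_ids, config)

  structure(list(counts = counts, lengths = lengths, design = design,
                 size_factors = sf, tissue_medians = medians,
                 sources = ann$sources, go_table = ann$go_table,
                 catalog = ann$catalog, truth = truth,
                 classes = stats::setNames(classes, gene_ids),
                 isoforms = iso, config = config),
            class = "sim_cohort")
}

## GTEx-style per-tissue medians constructed directly (the cascade
## consumes only medians).  Planted classes that must pass the breadth
## gate get at most 3 elevated tissues; broad_tissue decoys get 5-12.
gene_tissue_medians <- function(gene_ids, classes, tissue_ids) {
  ng <- length(gene_ids)
  nt <- length(tissue_ids)
  med <- matrix(stats::rlnorm(ng * nt, log(3), 1.5), ng, nt,
                dimnames = list(gene_ids, tissue_ids))
  narrow <- classes %in% c("true_target", "crpc_shared", "nonsurface",
                           "benign_leaky", "isoform_switch")
  for (i in which(narrow)) {
    med[i, ] <- stats::runif(nt, 0, 2)
    n_hi <- sample(0:3, 1)
    if (n_hi) med[i, sample.int(nt, n_hi)] <- stats::runif(n_hi, 4, 8)
  }
  for (i in which(classes == "broad_tissue")) {
    med[i, ] <- stats::runif(nt, 0, 2)
    n_hi <- sample(5:12, 1)
    med[i, sample.int(nt, n_hi)] <- stats::runif(n_hi, 4, 8)
  }
  med
}

## Surface annotation sources: every surface-class gene plus a random
## slice of the background, spread over the five source types.
build_annotations <- function(gene_ids, classes, config) {
  surface_classes <- c("true_target", "crpc_shared", "broad_tissue",
                       "benign_leaky", "isoform_switch")
  surface <- gene_ids[classes %in% surface_classes]
  bg <- gene_ids[classes == "background"]
  extra <- sample(bg, round(length(bg) * config$background_surface_frac))
  members <- c(surface, extra)
  source_ids <- c("CD", "CSPA", "GO:0034220", "GO:0055085", "GO:0016020")
  assign <- lapply(members, function(g)
    sample(source_ids, sample(1:3, 1)))
  names(assign) <- members
  sources <- lapply(source_ids, function(s)
    annotation_source(s, members[vapply(assign, function(a) s %in% a,
                                        logical(1))]))
  names(sources) <- source_ids
  go_ids <- grep("^GO:", source_ids, value = TRUE)
  go_rows <- do.call(rbind, lapply(go_ids, function(s)
    if (length(sources[[s]]$genes))
      data.frame(gene_id = sources[[s]]$genes, go_id = s,
                 stringsAsFactors = FALSE)))
  list(sources = sources,
       go_table = go_rows,
       catalog = build_catalog(sources))
}

truth_table <- function(gene_ids, classes) {
  expected <- c(background = "dropped_benign",
                true_target = "nominated",
                benign_leaky = "dropped_benign",
                nonsurface = "dropped_surface",
                broad_tissue = "dropped_gtex",
                crpc_shared = "dropped_crpc",
                isoform_switch = "dropped_benign")
  reason <- c(background = NA_character_,
              true_target = NA_character_,
              benign_leaky = "presence_benign",
              nonsurface = "not_surface",
              broad_tissue = "broad_tissue",
              crpc_shared = "de_crpc",
              isoform_switch = NA_character_)
  data.frame(feature_id = gene_ids,
             class = classes,
             expected_outcome = unname(expected[classes]),
             expected_reason = unname(reason[classes]),
             stringsAsFactors = FALSE)
}

assemble_isoform_bundle <- function(counts, lengths, classes, gene_ids,
                                    switch_genes, iso_counts, medians,
                                    tissue_ids, config) {
  singles <- gene_ids[classes != "isoform_switch"]
  tx_single <- paste0(singles, ".iso1")
  tx_counts <- counts[singles, , drop = FALSE]
  rownames(tx_counts) <- tx_single
  tx2gene <- stats::setNames(singles, tx_single)
  tx_lengths <- stats::setNames(lengths[singles], tx_single)
  tx_medians <- medians[singles, , drop = FALSE]
  rownames(tx_medians) <- tx_single
  tx_truth <- data.frame(feature_id = tx_single,
                         class = classes[match(singles, gene_ids)],
                         expected_outcome = NA_character_,
                         stringsAsFactors = FALSE)
  tx_truth$expected_outcome <-
    ifelse(tx_truth$class == "true_target", "nominated", "dropped")

  if (length(switch_genes)) {
    iso1 <- paste0(switch_genes, ".iso1")  # major outside NEPC
    iso2 <- paste0(switch_genes, ".iso2")  # the NEPC switch isoform
    tx_counts <- rbind(tx_counts, iso_counts)
    tx2gene <- c(tx2gene,
                 stats::setNames(rep(switch_genes, 2), c(iso1, iso2)))
    tx_lengths <- c(tx_lengths,
                    stats::setNames(rep(config$planted_length,
                                        2 * length(switch_genes)),
                                    c(iso1, iso2)))
    nt <- length(tissue_ids)
    sw_med <- matrix(stats::runif(2 * length(switch_genes) * nt, 0, 2),
                     2 * length(switch_genes), nt,
                     dimnames = list(c(iso1, iso2), tissue_ids))
    tx_medians <- rbind(tx_medians, sw_med)
    tx_truth <- rbind(
      tx_truth,
      data.frame(feature_id = iso1, class = "isoform_switch_major",
                 expected_outcome = "dropped", stringsAsFactors = FALSE),
      data.frame(feature_id = iso2, class = "isoform_switch_minor",
                 expected_outcome = "nominated_isoform_specific",
                 stringsAsFactors = FALSE)
    )
  }
  list(counts = tx_counts, lengths = tx_lengths, tx2gene = tx2gene,
       medians = tx_medians, truth = tx_truth)
}

#' Assemble the transcript-level matrices of a simulated cohort
#'
#' Returns the transcript bundle drawn by [simulate_cohort()]: every
#' non-switch gene contributes one isoform identical to its gene row;
#' each isoform-switch gene contributes two isoforms whose counts sum
#' exactly to the gene row, with usage proportions reversed in NEPC
#' (major/minor 0.9/0.1 outside NEPC, 0.1/0.9 inside).  Taking the
#' bundle from the realized cohort guarantees exact count conservation
#' between the two levels.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @return list with `counts`, `lengths`, `tx2gene`, `medians`,
#'   `truth`.
#' @export
simulate_isoforms <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!nrow(cohort$isoforms$counts))
    stop("cohort has no transcript bundle")
  cohort$isoforms
}
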