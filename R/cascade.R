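## The five-stage nomination cascade.
##
## Stage 1  DE gate NEPC vs benign (padj < 0.05, FC >= 2) together with
##          the presence gate (drop if benign TPM > 1 or NEPC TPM < 1).
## Stage 2  DE gate NEPC vs PCa (padj < 0.1, FC >= 1.5) + presence gate
##          with PCa in the benign role.
## Stage 3  restriction to the surface-protein catalog.
## Stage 4  tissue-breadth gate over GTEx-style per-tissue medians
##          (drop if median TPM > 3 in >= 5 tissues).
## Stage 5  DE gate NEPC vs CRPC (padj < 0.1, FC >= 1.5).
##
## Boundary conventions follow the filtering rules exactly: strict "<"
## on adjusted p, inclusive ">=" on fold change, strict ">" on the
## presence and tissue thresholds, ">=" on tissue breadth.

#' Cascade configuration
#'
#' Thresholds of the nomination cascade.  Defaults are the published
#' filtering criteria: NEPC vs benign at adjusted p < 0.05 and fold
#' change >= 2; NEPC vs PCa and NEPC vs CRPC at adjusted p < 0.1 and
#' fold change >= 1.5; presence at 1.0 TPM (candidates must exceed it
#' in NEPC and stay at or below it in the comparison tissue); the
#' tissue-breadth rule drops features whose median TPM exceeds 3.0 in
#' five or more tissues.
#'
#' @param benign_padj,benign_fc gates for the NEPC-vs-benign comparison.
#' @param pca_padj,pca_fc gates for NEPC vs localized prostate cancer.
#' @param crpc_padj,crpc_fc gates for NEPC vs CRPC.
#' @param presence_tpm presence threshold in abundance units.
#' @param gtex_median_tpm,gtex_max_tissues tissue-breadth rule: drop a
#'   feature whose median exceeds `gtex_median_tpm` in at least
#'   `gtex_max_tissues` tissues.
#' @param presence_statistic per-group aggregate for the presence gate
#'   (`"median"` or `"mean"`).
#' @param abundance_unit `"TPM"` or `"FPKM"`.
#' @param gtex_exclude_tissues optional tissue labels dropped from the
#'   breadth count (off by default).
#' @param lfc_cap,dispersion_floor numeric stability settings passed to
#'   the DE engine.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(benign_padj = 0.05, benign_fc = 2.0,
                           pca_padj = 0.1, pca_fc = 1.5,
                           crpc_padj = 0.1, crpc_fc = 1.5,
                           presence_tpm = 1.0,
                           gtex_median_tpm = 3.0,
                           gtex_max_tissues = 5L,
                           presence_statistic = c("median", "mean"),
                           abundance_unit = c("TPM", "FPKM"),
                           gtex_exclude_tissues = character(),
                           lfc_cap = 10, dispersion_floor = 1e-8) {
  cfg <- list(
    benign_padj = benign_padj, benign_fc = benign_fc,
    pca_padj = pca_padj, pca_fc = pca_fc,
    crpc_padj = crpc_padj, crpc_fc = crpc_fc,
    presence_tpm = presence_tpm,
    gtex_median_tpm = gtex_median_tpm,
    gtex_max_tissues = as.integer(gtex_max_tissues),
    presence_statistic = match.arg(presence_statistic),
    abundance_unit = match.arg(abundance_unit),
    gtex_exclude_tissues = gtex_exclude_tissues,
    lfc_cap = lfc_cap, dispersion_floor = dispersion_floor
  )
  num <- c("benign_padj", "benign_fc", "pca_padj", "pca_fc",
           "crpc_padj", "crpc_fc", "presence_tpm", "gtex_median_tpm")
  for (f in num) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    stop("config field must be a positive number: ", f)
  if (cfg$gtex_max_tissues < 1)
    stop("gtex_max_tissues must be a positive integer")
  structure(cfg, class = "cascade_config")
}

#' Differential-expression gate
#'
#' Keeps features significantly overexpressed in the numerator group:
#' adjusted p strictly below `padj_max` and signed log2 fold change at
#' or above `log2(fc_min)`.  The gate is one-sided by design — the
#' cascade nominates overexpressed features only.
#'
#' @param results DE result data.frame from [nb_wald_test()].
#' @param padj_max adjusted-p threshold (strict `<`).
#' @param fc_min fold-change threshold (inclusive `>=`, on the linear
#'   fold-change scale).
#' @return character vector of surviving feature IDs.
#' @export
de_gate <- function(results, padj_max, fc_min) {
  keep <- !is.na(results$padj) & results$padj < padj_max &
    results$log2fc >= log2(fc_min)
  results$feature_id[keep]
}

#' Presence gate on group-level abundance
#'
#' Drops a feature if its summary abundance in the reference group
#' exceeds `presence_tpm`, or its summary abundance in the target group
#' falls below `presence_tpm`.
#'
#' @param abund abundance matrix (features x samples).
#' @param design named character vector, sample_id -> group.
#' @param features feature IDs to gate.
#' @param ref_group group that must be at or below the threshold
#'   (e.g. `"benign"` or `"pca"`).
#' @param target_group group that must be at or above the threshold
#'   (default `"nepc"`).
#' @param presence_tpm threshold (default 1.0).
#' @param statistic per-group aggregate (default `"median"`).
#' @return character vector of surviving feature IDs.
#' @export
presence_gate <- function(abund, design, features,
                          ref_group, target_group = "nepc",
                          presence_tpm = 1.0,
                          statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (!length(features)) return(character())
  ref <- group_summary(abund[features, , drop = FALSE], design,
                       ref_group, statistic)
  tgt <- group_summary(abund[features, , drop = FALSE], design,
                       target_group, statistic)
  features[!(ref > presence_tpm | tgt < presence_tpm)]
}

#' Tissue-breadth gate over per-tissue median expression
#'
#' Drops a feature whose median abundance exceeds `gtex_median_tpm` in
#' at least `gtex_max_tissues` tissues.  Features missing from the
#' median matrix are treated as absent from every tissue (breadth 0)
#' with a warning.
#'
#' @param medians numeric matrix, features x tissues, of median TPM.
#' @param features feature IDs to gate.
#' @param config a [cascade_config()].
#' @return character vector of surviving feature IDs.
#' @export
gtex_breadth_gate <- function(medians, features, config = cascade_config()) {
  if (!length(features)) return(character())
  breadth <- tissue_breadth(medians, features, config)
  features[breadth < config$gtex_max_tissues]
}

tissue_breadth <- function(medians, features, config) {
  keep_tissues <- setdiff(colnames(medians), config$gtex_exclude_tissues)
  med <- medians[, keep_tissues, drop = FALSE]
  present <- features %in% rownames(med)
  if (any(!present))
    warning(sum(!present), " feature(s) missing from the tissue-median ",
            "matrix; treated as absent from all tissues")
  breadth <- integer(length(features))
  if (any(present))
    breadth[present] <-
      rowSums(med[features[present], , drop = FALSE] > config$gtex_median_tpm)
  stats::setNames(breadth, features)
}

## ---- filter trace -----------------------------------------------------------

new_trace <- function(universe) {
  structure(list(stages = list(), universe = universe),
            class = "filter_trace")
}

add_stage <- function(trace, name, params, input, survivors, reasons) {
  dropped <- setdiff(input, survivors)
  stage <- list(
    name = name, params = params,
    n_in = length(input), n_out = length(survivors),
    survivors = survivors,
    drops = data.frame(feature_id = dropped,
                       reason = unname(reasons[dropped]),
                       stringsAsFactors = FALSE)
  )
  trace$stages <- c(trace$stages, stats::setNames(list(stage), name))
  trace
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("<filter_trace>", length(x$stages), "stages\n")
  for (st in x$stages)
    cat(sprintf("  %-8s %5d -> %5d\n", st$name, st$n_in, st$n_out))
  invisible(x)
}

#' Flatten a filter trace to one row per dropped feature per stage
#' @param x a `filter_trace`.
#' @param ... unused.
#' @return data.frame with columns `stage`, `feature_id`, `reason`.
#' @export
as.data.frame.filter_trace <- function(x, ...) {
  rows <- lapply(x$stages, function(st) {
    if (!nrow(st$drops)) return(NULL)
    cbind(stage = st$name, st$drops)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(stage = character(), feature_id = character(),
                      reason = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Survivors of the final cascade stage
#' @param trace a `filter_trace`.
#' @return character vector of feature IDs.
#' @export
trace_survivors <- function(trace) {
  st <- trace$stages
  if (!length(st)) return(trace$universe)
  st[[length(st)]]$survivors
}

## ---- cascade core -----------------------------------------------------------

## Shared engine behind the gene and isoform branches.  `member` is a
## logical vector (named by feature) giving surfaceome membership,
## already resolved through the parent gene for isoforms.
run_cascade_core <- function(counts, lengths, design, member, medians,
                             config) {
  assert_count_matrix(counts)
  assert_design(design, counts)
  for (g in c("benign", "pca", "crpc", "nepc"))
    if (!g %in% design) stop("required group missing from design: ", g)

  abund <- if (config$abundance_unit == "TPM")
    compute_tpm(counts, lengths) else compute_fpkm(counts, lengths)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, design,
                               floor = config$dispersion_floor)
  de <- lapply(c(benign = "benign", pca = "pca", crpc = "crpc"),
               function(g) nb_wald_test(counts, sf, disp, design,
                                        "nepc", g, lfc_cap = config$lfc_cap))

  stat <- config$presence_statistic
  grp <- c("benign", "pca", "crpc", "nepc")
  summ <- matrix(0, nrow(counts), length(grp),
                 dimnames = list(rownames(counts), grp))
  for (g in grp) summ[, g] <- group_summary(abund, design, g, stat)

  universe <- rownames(counts)
  trace <- new_trace(universe)
  current <- universe

  ## stages 1-2: DE + presence against benign, then PCa
  for (stage in c("benign", "pca")) {
    padj_max <- config[[paste0(stage, "_padj")]]
    fc_min <- config[[paste0(stage, "_fc")]]
    de_keep <- de_gate(de[[stage]], padj_max, fc_min)
    pres_keep <- presence_gate(abund, design, current, ref_group = stage,
                               target_group = "nepc",
                               presence_tpm = config$presence_tpm,
                               statistic = stat)
    survivors <- intersect(current, intersect(de_keep, pres_keep))
    reasons <- vapply(setdiff(current, survivors), function(f) {
      r <- character()
      if (!f %in% de_keep) r <- c(r, paste0("de_", stage))
      if (!f %in% pres_keep) r <- c(r, paste0("presence_", stage))
      paste(r, collapse = "+")
    }, character(1))
    trace <- add_stage(trace, stage,
                       list(padj_max = padj_max, fc_min = fc_min,
                            presence_tpm = config$presence_tpm),
                       current, survivors, reasons)
    current <- survivors
  }

  ## stage 3: surfaceome restriction
  survivors <- current[member[current]]
  reasons <- stats::setNames(rep("not_surface",
                                 length(setdiff(current, survivors))),
                             setdiff(current, survivors))
  trace <- add_stage(trace, "surface", list(), current, survivors, reasons)
  current <- survivors

  ## stage 4: tissue breadth
  survivors <- gtex_breadth_gate(medians, current, config)
  reasons <- stats::setNames(rep("broad_tissue",
                                 length(setdiff(current, survivors))),
                             setdiff(current, survivors))
  trace <- add_stage(trace, "gtex",
                     list(median_tpm = config$gtex_median_tpm,
                          max_tissues = config$gtex_max_tissues),
                     current, survivors, reasons)
  current <- survivors

  ## stage 5: DE against CRPC
  de_keep <- de_gate(de$crpc, config$crpc_padj, config$crpc_fc)
  survivors <- intersect(current, de_keep)
  reasons <- stats::setNames(rep("de_crpc",
                                 length(setdiff(current, survivors))),
                             setdiff(current, survivors))
  trace <- add_stage(trace, "crpc",
                     list(padj_max = config$crpc_padj,
                          fc_min = config$crpc_fc),
                     current, survivors, reasons)
  current <- survivors

  breadth <- tissue_breadth(medians, current, config)
  list(candidates = current, trace = trace, de = de, summ = summ,
       breadth = breadth, abund = abund)
}

rank_candidates <- function(ids, de) {
  lfc_crpc <- de$crpc$log2fc[match(ids, de$crpc$feature_id)]
  padj_ben <- de$benign$padj[match(ids, de$benign$feature_id)]
  ids[order(-lfc_crpc, padj_ben, ids, method = "radix")]
}

candidate_frame <- function(ids, core, provenance) {
  de <- core$de
  idx <- function(res) match(ids, res$feature_id)
  data.frame(
    feature_id = ids,
    log2fc_benign = de$benign$log2fc[idx(de$benign)],
    padj_benign = de$benign$padj[idx(de$benign)],
    log2fc_pca = de$pca$log2fc[idx(de$pca)],
    padj_pca = de$pca$padj[idx(de$pca)],
    log2fc_crpc = de$crpc$log2fc[idx(de$crpc)],
    padj_crpc = de$crpc$padj[idx(de$crpc)],
    tpm_benign = core$summ[ids, "benign"],
    tpm_pca = core$summ[ids, "pca"],
    tpm_crpc = core$summ[ids, "crpc"],
    tpm_nepc = core$summ[ids, "nepc"],
    surface_sources = provenance,
    gtex_breadth = unname(core$breadth[ids]),
    rank = seq_along(ids),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Run the gene-level nomination cascade
#'
#' Executes the five-stage filtering procedure on a gene-level count
#' matrix: differential overexpression in NEPC versus benign prostate
#' and versus localized prostate cancer with presence filters, surface
#' catalog restriction, normal-tissue breadth elimination, and
#' NEPC-versus-CRPC enrichment.  Candidates are ranked by
#' NEPC-vs-CRPC log2 fold change (descending), ties broken by
#' NEPC-vs-benign adjusted p (ascending), then lexically by feature ID.
#'
#' @param counts gene-level count matrix (features x samples).
#' @param lengths named vector of gene lengths in bp.
#' @param design named character vector mapping each sample to one of
#'   `benign`, `pca`, `crpc`, `nepc`.
#' @param catalog a [build_catalog()] surface catalog.
#' @param medians tissue-median abundance matrix (features x tissues).
#' @param config a [cascade_config()].
#' @return list with `candidates` (data.frame, one row per nominated
#'   gene) and `trace` (a `filter_trace` of all five stages).
#' @export
run_gene_cascade <- function(counts, lengths, design, catalog, medians,
                             config = cascade_config()) {
  member <- stats::setNames(in_catalog(catalog, rownames(counts)),
                            rownames(counts))
  core <- run_cascade_core(counts, lengths, design, member, medians, config)
  ids <- rank_candidates(core$candidates, core$de)
  cand <- candidate_frame(ids, core, catalog_provenance(catalog, ids))
  list(candidates = cand, trace = core$trace, de = core$de)
}

#' Run the transcript-isoform nomination cascade
#'
#' Applies the identical five-stage logic to a transcript-level count
#' matrix.  Surfaceome membership of an isoform is decided through its
#' parent gene (`tx2gene`).  If the gene-level candidate set is
#' supplied, each nominated isoform is flagged `isoform_specific` when
#' its parent gene was *not* nominated by the gene cascade — the
#' isoform-switch pattern in which a gene with flat total output swaps
#' to an NEPC-exclusive isoform.
#'
#' @param tx_counts transcript-level count matrix.
#' @param tx_lengths named vector of transcript lengths in bp.
#' @param design cohort design as in [run_gene_cascade()].
#' @param tx2gene named character vector, transcript_id -> gene_id;
#'   every transcript in the matrix must be mapped.
#' @param catalog surface catalog (gene identifiers).
#' @param tx_medians tissue-median matrix over transcripts.
#' @param config a [cascade_config()].
#' @param gene_candidates optional character vector of genes nominated
#'   by the gene cascade, used to set the `isoform_specific` flag
#'   (NA if omitted).
#' @return list with `candidates` (data.frame including `gene_id` and
#'   `isoform_specific`) and `trace`.
#' @export
run_isoform_cascade <- function(tx_counts, tx_lengths, design, tx2gene,
                                catalog, tx_medians,
                                config = cascade_config(),
                                gene_candidates = NULL) {
  txs <- rownames(tx_counts)
  unmapped <- setdiff(txs, names(tx2gene))
  if (length(unmapped))
    stop("transcript(s) without gene mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  parent <- tx2gene[txs]
  member <- stats::setNames(in_catalog(catalog, parent), txs)
  core <- run_cascade_core(tx_counts, tx_lengths, design, member,
                           tx_medians, config)
  ids <- rank_candidates(core$candidates, core$de)
  cand <- candidate_frame(ids, core,
                          catalog_provenance(catalog, unname(parent[ids])))
  cand$gene_id <- unname(parent[ids])
  cand$isoform_specific <- if (is.null(gene_candidates)) NA else
    !(cand$gene_id %in% gene_candidates)
  cand <- cand[, c("feature_id", "gene_id", setdiff(names(cand),
                   c("feature_id", "gene_id")))]
  list(candidates = cand, trace = core$trace, de = core$de)
}
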