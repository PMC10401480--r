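test_that("gate boundaries follow the filtering rules exactly", {
  # adjusted p: strict "less than"; fold change: inclusive ">="
  de <- make_de(c("A", "B", "C", "D"),
                log2fc = c(5, 1.0, 0.99, 5),
                padj = c(0.05, 0.001, 0.001, 0.049))
  kept <- de_gate(de, padj_max = 0.05, fc_min = 2.0)
  expect_false("A" %in% kept)   # padj exactly at threshold -> dropped
  expect_true("B" %in% kept)    # log2fc exactly log2(2) -> kept
  expect_false("C" %in% kept)   # just below the fold-change bar
  expect_true("D" %in% kept)
  expect_length(de_gate(make_de(character(), numeric(), numeric()),
                        0.05, 2), 0)

  # presence rule: drop if reference > 1.0 or NEPC < 1.0 (both strict)
  abund <- make_counts(c(1.5, 0.2, 0.2, 1.0, 0.2,
                         50, 0.5, 8, 5, 1.0),
                       5, 2, feat = c("hi_ben", "lo_nepc", "ok",
                                      "ben_at_1", "nepc_at_1"),
                       samp = c("b1", "n1"))
  abund <- cbind(abund, abund)  # two samples per group
  colnames(abund) <- c("b1", "n1", "b2", "n2")
  design <- c(b1 = "benign", n1 = "nepc", b2 = "benign", n2 = "nepc")
  kept <- presence_gate(abund, design, rownames(abund), "benign")
  expect_setequal(kept, c("ok", "ben_at_1", "nepc_at_1"))

  # tissue breadth: "five or more" tissues above 3.0 eliminates
  med <- matrix(0, 3, 30,
                dimnames = list(c("five", "four", "silent"),
                                sprintf("t%02d", 1:30)))
  med["five", 1:5] <- 3.5
  med["four", 1:4] <- 100
  cfg <- cascade_config()
  expect_setequal(gtex_breadth_gate(med, rownames(med), cfg),
                  c("four", "silent"))
  # exactly 3.0 is not "greater than 3.0"
  med["four", 5:30] <- 3.0
  expect_true("four" %in% gtex_breadth_gate(med, rownames(med), cfg))
  # features missing from the matrix are treated as absent, with warning
  expect_warning(kept <- gtex_breadth_gate(med, c("five", "ghost"), cfg),
                 "missing")
  expect_identical(kept, "ghost")
})

test_that("gene cascade recovers exactly the planted targets with a consistent trace", {
  co <- simulate_cohort(sim_config(seed = 42))
  res <- quiet_gene_cascade(co)
  targets <- co$truth$feature_id[co$truth$class == "true_target"]
  expect_setequal(res$candidates$feature_id, targets)

  # trace chain: monotone counts, stage k input = stage k-1 output
  tr <- res$trace
  expect_identical(names(tr$stages),
                   c("benign", "pca", "surface", "gtex", "crpc"))
  prev <- tr$universe
  for (st in tr$stages) {
    expect_equal(st$n_in, length(prev))
    expect_true(all(st$survivors %in% prev))
    expect_lte(st$n_out, st$n_in)
    expect_setequal(c(st$survivors, st$drops$feature_id), prev)
    prev <- st$survivors
  }
  expect_setequal(trace_survivors(tr), res$candidates$feature_id)

  # ranking: descending NEPC-vs-CRPC log2fc with deterministic ties
  expect_true(all(diff(res$candidates$log2fc_crpc) <= 1e-12))
  expect_identical(res$candidates$rank, seq_len(nrow(res$candidates)))

  # every decoy class dropped at its designed stage with its reason
  tc <- truth_comparison(res$trace, co$truth)
  dec <- tc[tc$class %in% c("benign_leaky", "nonsurface",
                            "broad_tissue", "crpc_shared"), ]
  expect_true(all(dec$matches_expected))
})

test_that("threshold monotonicity: relaxing gates never shrinks the candidate set", {
  co <- simulate_cohort(sim_config(seed = 9))
  strict <- quiet_gene_cascade(co)
  relaxed <- quiet_gene_cascade(co, cascade_config(
    benign_padj = 0.2, benign_fc = 1.2, pca_padj = 0.4, pca_fc = 1.1,
    crpc_padj = 0.4, crpc_fc = 1.1, gtex_max_tissues = 12))
  expect_true(all(strict$candidates$feature_id %in%
                    relaxed$candidates$feature_id))
})

test_that("cascade is deterministic and an empty catalog annihilates at stage 3", {
  co <- simulate_cohort(sim_config(n_genes = 400, seed = 5))
  r1 <- quiet_gene_cascade(co)
  r2 <- quiet_gene_cascade(co)
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(as.data.frame(r1$trace), as.data.frame(r2$trace))

  empty_cat <- structure(list(), class = "surface_catalog")
  r0 <- suppressWarnings(run_gene_cascade(co$counts, co$lengths, co$design,
                                          empty_cat, co$tissue_medians))
  expect_equal(nrow(r0$candidates), 0)
  st3 <- r0$trace$stages$surface
  expect_equal(st3$n_out, 0)
  expect_true(all(st3$drops$reason == "not_surface"))

  # a missing cohort group is a hard error naming it
  sub <- co$design[co$design != "crpc"]
  expect_error(
    suppressWarnings(run_gene_cascade(co$counts[, names(sub)], co$lengths,
                                      sub, co$catalog, co$tissue_medians)),
    "crpc")
})

test_that("isoform cascade finds the switch isoform and flags isoform-specific hits", {
  co <- simulate_cohort(sim_config(seed = 17))
  gene <- quiet_gene_cascade(co)
  iso <- simulate_isoforms(co)
  res <- quiet_isoform_cascade(co, iso, gene$candidates$feature_id)

  sw <- iso$truth$feature_id[iso$truth$class == "isoform_switch_minor"]
  expect_true(all(sw %in% res$candidates$feature_id))
  idx <- match(sw, res$candidates$feature_id)
  expect_true(all(res$candidates$isoform_specific[idx]))
  # the parent genes (flat total output) are absent from the gene branch
  expect_false(any(iso$tx2gene[sw] %in% gene$candidates$feature_id))
  # the NEPC-depleted major isoforms are not nominated
  major <- iso$truth$feature_id[iso$truth$class == "isoform_switch_major"]
  expect_false(any(major %in% res$candidates$feature_id))

  # transcripts without a gene mapping are a hard error
  iso2 <- iso
  iso2$tx2gene <- iso$tx2gene[-1]
  expect_error(quiet_isoform_cascade(co, iso2), "without gene mapping")
})

test_that("one-isoform-per-gene identity mapping reduces to the gene cascade", {
  cfg <- sim_config(n_genes = 500, n_isoform_switch = 0, seed = 8)
  co <- simulate_cohort(cfg)
  gene <- quiet_gene_cascade(co)
  iso <- simulate_isoforms(co)
  res <- quiet_isoform_cascade(co, iso, gene$candidates$feature_id)
  expect_setequal(res$candidates$gene_id, gene$candidates$feature_id)
  expect_false(any(res$candidates$isoform_specific))
})
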