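test_that("simulation is reproducible from its seed", {
  c1 <- simulate_cohort(sim_config(n_genes = 300, seed = 77))
  c2 <- simulate_cohort(sim_config(n_genes = 300, seed = 77))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$tissue_medians, c2$tissue_medians)
  expect_identical(c1$truth, c2$truth)
  expect_identical(simulate_isoforms(c1)$counts,
                   simulate_isoforms(c2)$counts)
  c3 <- simulate_cohort(sim_config(n_genes = 300, seed = 78))
  expect_false(identical(c1$counts, c3$counts))

  # written outputs are byte-identical across reruns of the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("counts.tsv", "tx_counts.tsv", "gtex_medians.tsv",
              "truth.tsv", "go_associations.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  # inconsistent class counts are rejected up front
  expect_error(sim_config(n_genes = 30, n_true_targets = 40),
               "exceed")
})

test_that("planted classes realize their designed expression structure", {
  cfg <- sim_config(seed = 123)
  co <- simulate_cohort(cfg)
  nepc <- names(co$design)[co$design == "nepc"]
  benign <- names(co$design)[co$design == "benign"]
  # undo the per-sample depth factors before comparing group means
  q <- sweep(co$counts, 2, co$size_factors, "/")

  targets <- co$truth$feature_id[co$truth$class == "true_target"]
  ratio <- rowMeans(q[targets, nepc]) / rowMeans(q[targets, benign])
  # empirical NEPC/benign mean ratio near the planted fold change
  expect_equal(mean(ratio), cfg$target_fc, tolerance = 0.2)

  # background features carry no group effect
  bg <- sample(co$truth$feature_id[co$truth$class == "background"], 200)
  bg_ratio <- rowMeans(q[bg, nepc]) / rowMeans(q[bg, benign])
  expect_equal(stats::median(bg_ratio), 1, tolerance = 0.1)

  # tissue medians realize the breadth design
  cfg_casc <- cascade_config()
  breadth <- rowSums(co$tissue_medians > cfg_casc$gtex_median_tpm)
  broad <- co$truth$feature_id[co$truth$class == "broad_tissue"]
  expect_true(all(breadth[broad] >= cfg_casc$gtex_max_tissues))
  expect_true(all(breadth[targets] < cfg_casc$gtex_max_tissues))

  # surface classes are in the catalog, the nonsurface decoys are not
  nonsurf <- co$truth$feature_id[co$truth$class == "nonsurface"]
  expect_true(all(in_catalog(co$catalog, targets)))
  expect_false(any(in_catalog(co$catalog, nonsurf)))
})

test_that("isoform counts conserve gene totals and encode the switch", {
  cfg <- sim_config(seed = 55)
  co <- simulate_cohort(cfg)
  iso <- simulate_isoforms(co)
  gene_from_tx <- rowsum(iso$counts, iso$tx2gene[rownames(iso$counts)])
  expect_equal(gene_from_tx[rownames(co$counts), ], co$counts)

  # usage proportions ~0.9/0.1 reversed in NEPC: minor-isoform FC = 9
  sw_genes <- co$truth$feature_id[co$truth$class == "isoform_switch"]
  minor <- paste0(sw_genes, ".iso2")
  nepc <- names(co$design)[co$design == "nepc"]
  benign <- names(co$design)[co$design == "benign"]
  q <- sweep(iso$counts, 2, co$size_factors, "/")
  fc_minor <- rowMeans(q[minor, nepc]) / rowMeans(q[minor, benign])
  expect_equal(mean(fc_minor),
               cfg$switch_major_prop / (1 - cfg$switch_major_prop),
               tolerance = 0.25)
  # the major isoform is depleted in NEPC
  major <- paste0(sw_genes, ".iso1")
  fc_major <- rowMeans(q[major, nepc]) / rowMeans(q[major, benign])
  expect_true(all(fc_major < 1))
})

test_that("with no planted targets the cascade nominates nothing", {
  null_cfg <- function(seed)
    sim_config(n_true_targets = 0, n_crpc_shared = 0, n_nonsurface = 0,
               n_broad_tissue = 0, n_benign_leaky = 0,
               n_isoform_switch = 0, seed = seed)
  hits <- vapply(1:40, function(s) {
    co <- simulate_cohort(null_cfg(s))
    nrow(quiet_gene_cascade(co)$candidates)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})
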