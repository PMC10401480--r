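test_that("size factors reproduce median-of-ratios on hand cases", {
  # identical columns -> all 1
  m <- make_counts(rep(c(4, 9, 2), 2), 3, 2)
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  # doubling a column doubles its factor
  a <- c(5, 10, 20)
  m2 <- make_counts(c(a, 2 * a), 3, 2)
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # explicit enumeration oracle on the 3x2 case and random matrices
  m3 <- make_counts(c(2, 4, 6, 8, 4, 6), 3, 2)
  expect_equal(unname(estimate_size_factors(m3)), oracle_size_factors(m3))
  set.seed(31)
  for (rep in 1:5) {
    r <- make_counts(rpois(8 * 4, 40) + 1, 8, 4)
    expect_equal(unname(estimate_size_factors(r)), oracle_size_factors(r))
  }

  # no all-nonzero feature: hard error
  bad <- make_counts(c(0, 5, 5, 0), 2, 2)
  expect_error(estimate_size_factors(bad), "reference")
})

test_that("dispersion method-of-moments matches hand computation", {
  # two groups with equal means and known within-group variances:
  # alpha = (pooled var - pooled mean) / pooled mean^2
  x1 <- c(2, 6, 10, 14, 18)       # mean 10, var 40
  x2 <- c(0, 1, 10, 19, 20)       # mean 10, var 90.5
  counts <- make_counts(c(x1, x2), 1, 10)
  design <- stats::setNames(rep(c("a", "b"), each = 5), colnames(counts))
  sf <- stats::setNames(rep(1, 10), colnames(counts))
  v_pooled <- (sum((x1 - 10)^2) + sum((x2 - 10)^2)) / 8
  expect_equal(unname(estimate_dispersions(counts, sf, design)),
               (v_pooled - 10) / 100)

  # Poisson-like and constant features collapse to the floor
  set.seed(13)
  pois <- make_counts(rpois(2000, 40), 200, 10)
  dpois <- stats::setNames(rep(c("a", "b"), each = 5), colnames(pois))
  sfp <- stats::setNames(rep(1, 10), colnames(pois))
  disp <- estimate_dispersions(pois, sfp, dpois)
  expect_lt(stats::median(disp), 0.01)
  const <- make_counts(rep(7, 10), 1, 10)
  expect_equal(unname(estimate_dispersions(const, sfp, dpois)), 1e-8)

  # all-zero feature: floored and flagged
  zed <- rbind(const, F99 = rep(0, 10))
  dz <- estimate_dispersions(zed, sfp, dpois)
  expect_equal(unname(dz["F99"]), 1e-8)
  expect_identical(attr(dz, "zero_mean"), "F99")
})

test_that("Wald test symmetries: identical groups, contrast swap, zero features", {
  fx <- make_two_group(n_feat = 30, n1 = 6, n2 = 6, n_effect = 0, seed = 21)
  counts <- fx$counts
  # mirror group a onto group b: label permutation symmetric data
  counts[, 7:12] <- counts[, 1:6]
  sf <- stats::setNames(rep(1, 12), colnames(counts))
  disp <- estimate_dispersions(counts, sf, fx$design)
  de <- nb_wald_test(counts, sf, disp, fx$design, "b", "a")
  expect_equal(de$log2fc, rep(0, 30), tolerance = 1e-8)
  expect_equal(de$wald_p, rep(1, 30), tolerance = 1e-6)

  # swapping numerator and denominator negates log2fc, keeps p
  fx2 <- make_two_group(seed = 22)
  sf2 <- estimate_size_factors(fx2$counts)
  disp2 <- estimate_dispersions(fx2$counts, sf2, fx2$design)
  ab <- nb_wald_test(fx2$counts, sf2, disp2, fx2$design, "b", "a")
  ba <- nb_wald_test(fx2$counts, sf2, disp2, fx2$design, "a", "b")
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-9)
  expect_equal(ab$wald_p, ba$wald_p, tolerance = 1e-9)

  # zero-in-both-groups and one-sided-zero features
  z <- fx2$counts
  z["F01", ] <- 0
  z["F02", names(fx2$design)[fx2$design == "a"]] <- 0
  z["F02", names(fx2$design)[fx2$design == "b"]] <-
    pmax(z["F02", names(fx2$design)[fx2$design == "b"]], 5)
  dz <- estimate_dispersions(z, sf2, fx2$design)
  de <- nb_wald_test(z, sf2, dz, fx2$design, "b", "a")
  expect_equal(de$log2fc[de$feature_id == "F01"], 0)
  expect_equal(de$wald_p[de$feature_id == "F01"], 1)
  expect_identical(de$flag[de$feature_id == "F01"], "zero_both")
  expect_equal(de$log2fc[de$feature_id == "F02"], 10)
  expect_identical(de$flag[de$feature_id == "F02"], "lfc_capped")
})

test_that("Wald z agrees with the numeric-MLE oracle", {
  fx <- make_two_group(n_feat = 50, n1 = 8, n2 = 6, seed = 7)
  sf <- estimate_size_factors(fx$counts)
  disp <- estimate_dispersions(fx$counts, sf, fx$design)
  de <- nb_wald_test(fx$counts, sf, disp, fx$design, "b", "a")
  z_engine <- de$log2fc / de$se
  grp <- fx$design[colnames(fx$counts)]
  z_oracle <- vapply(seq_len(50), function(i)
    oracle_wald_z(fx$counts[i, ], sf, grp, disp[i]), numeric(1))
  expect_lt(max(abs(z_engine - z_oracle)), 0.05)
})

test_that("scale invariance: rescaling one sample's depth barely moves results", {
  fx <- make_two_group(n_feat = 40, n1 = 8, n2 = 8, seed = 33)
  sf1 <- estimate_size_factors(fx$counts)
  d1 <- estimate_dispersions(fx$counts, sf1, fx$design)
  de1 <- nb_wald_test(fx$counts, sf1, d1, fx$design, "b", "a")
  scaled <- fx$counts
  scaled[, 3] <- scaled[, 3] * 2
  sf2 <- estimate_size_factors(scaled)
  # relative depth between samples doubles exactly (the geometric-mean
  # reference absorbs a common 2^(1/n) factor)
  expect_equal(unname(sf2[3] / sf2[1]), unname(2 * sf1[3] / sf1[1]))
  d2 <- estimate_dispersions(scaled, sf2, fx$design)
  de2 <- nb_wald_test(scaled, sf2, d2, fx$design, "b", "a")
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 0.05)
  expect_lt(max(abs(de2$log2fc / de2$se - de1$log2fc / de1$se)), 0.1)
})

test_that("BH adjustment equals brute-force step-up and keeps p-order", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_equal(order(q[order(p)]), seq_along(p))  # order preserved
  }
})

test_that("p-values rank-agree with an established NB DE implementation", {
  set.seed(11)
  n <- 10
  mu <- exp(runif(400, log(5), log(500)))
  eff <- c(rep(2, 40), rep(1, 360))
  counts <- cbind(matrix(rnbinom(400 * n, mu = mu, size = 5), 400, n),
                  matrix(rnbinom(400 * n, mu = mu * eff, size = 5), 400, n))
  dimnames(counts) <- list(sprintf("F%03d", 1:400),
                           sprintf("S%02d", 1:(2 * n)))
  design <- stats::setNames(rep(c("a", "b"), each = n), colnames(counts))
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, design)
  de <- nb_wald_test(counts, sf, disp, design, "b", "a")

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, S4Vectors::DataFrame(cond = factor(rep(c("a", "b"), each = n))),
      ~cond)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
  })
  ref <- DESeq2::results(dds, contrast = c("cond", "b", "a"))
  expect_equal(unname(sf), unname(DESeq2::sizeFactors(dds)),
               tolerance = 1e-10)
  rho <- stats::cor(de$wald_p, ref$pvalue, method = "spearman",
                    use = "complete.obs")
  expect_gt(rho, 0.95)
})
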