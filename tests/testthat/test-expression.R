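test_that("Nalimov statistic matches hand evaluation and removes only extreme values", {
  nf <- suppressMessages(nalimov_filter(c(1, 1, 1, 1, 10), alpha = 0.001))
  expect_equal(nf$q, 2, tolerance = 1e-9) # |10 - 2.8| / 4.0249 * sqrt(5/4)
  expect_identical(nf$excluded, 5L)
  expect_identical(nf$kept, c(1, 1, 1, 1))
  # constant values: degenerate, nothing removed
  expect_message(nfc <- nalimov_filter(rep(2, 5)), "degenerate")
  expect_identical(nfc$excluded, integer())
  # n < 3: no test performed
  expect_message(nf2 <- nalimov_filter(c(1, 100)), "skipped")
  expect_identical(nf2$kept, c(1, 100))
  # unremarkable replicates are all kept
  set.seed(12)
  nf3 <- nalimov_filter(rnorm(5), alpha = 0.001)
  expect_identical(nf3$excluded, integer())
})

test_that("Nalimov critical values are monotone and the table covers the documented grid", {
  tab <- nucpos:::.nalimov_table
  expect_identical(tab$n, 3:10)
  # stricter level -> larger critical value; more replicates -> larger value
  expect_true(all(tab$q001 >= tab$q01 & tab$q01 >= tab$q05))
  expect_true(all(diff(tab$q05) > 0))
  expect_true(all(diff(tab$q001) > 0))
  expect_identical(nucpos:::nalimov_critical(5, 0.001), 1.982)
  # n > 10 falls back to the t-based bound, continuous-ish with the table
  expect_gt(nucpos:::nalimov_critical(11, 0.001),
            nucpos:::nalimov_critical(10, 0.001) - 0.2)
})

test_that("fold changes are antilog-mean ratios with reciprocal symmetry and exact noise-free recovery", {
  cfg <- synthetic_config(rng_seed = 41, n_genes = 10, n_probes_per_gene = 1,
                          noise_sd = 0, planted_log2fc = c(g0002 = 1.5,
                                                           g0005 = -2))
  ex <- generate_expression(cfg)
  fc <- suppressMessages(fold_change(ex$matrix, ex$samples, "MB", "MT"))
  g <- collapse_to_gene(fc, ex$probe_map)
  expect_equal(g$log2fc[g$gene_id == "g0002"], 1.5, tolerance = 1e-6)
  expect_equal(g$log2fc[g$gene_id == "g0005"], -2, tolerance = 1e-6)
  expect_equal(g$fold_change[g$gene_id == "g0001"], 1, tolerance = 1e-9)
  # reciprocity on the same kept replicates
  fc_ba <- suppressMessages(fold_change(ex$matrix, ex$samples, "MT", "MB"))
  expect_equal(fc$fold_change * fc_ba$fold_change, rep(1, nrow(fc)),
               tolerance = 1e-9)
  expect_error(fold_change(ex$matrix, ex$samples, "MB", "nope"), "absent")
})

test_that("a planted 11-fold change is recovered within [9, 13] at 0.1 SD replicate noise", {
  cfg <- synthetic_config(rng_seed = 42, n_genes = 20, noise_sd = 0.1,
                          replicates_per_condition = 5,
                          planted_log2fc = c(g0001 = log2(11)))
  ex <- generate_expression(cfg)
  fc <- fold_change(ex$matrix, ex$samples, "MB", "MT")
  g <- collapse_to_gene(fc, ex$probe_map)
  est <- g$fold_change[g$gene_id == "g0001"]
  expect_gt(est, 9); expect_lt(est, 13)
  # selection at p <= 4e-6 keeps large planted effects, not null genes
  expect_true(g$selected[g$gene_id == "g0001"])
  expect_false(any(g$selected[g$gene_id != "g0001"]))
  # selection count is monotone nonincreasing as the threshold tightens
  n_sel <- vapply(c(0.05, 1e-3, 4e-6, 1e-9), function(thr)
    sum(fold_change(ex$matrix, ex$samples, "MB", "MT",
                    select_p = thr)$selected), numeric(1))
  expect_true(all(diff(n_sel) <= 0))
})

test_that("generator-planted aberrant replicates are flagged by the Nalimov stage", {
  cfg <- synthetic_config(rng_seed = 43, n_genes = 60, outlier_rate = 0.04)
  ex <- generate_expression(cfg)
  expect_gt(nrow(ex$truth$outliers), 5)
  fc <- fold_change(ex$matrix, ex$samples, "MB", "MT")
  expect_gte(sum(fc$n_outliers), 0.9 * nrow(ex$truth$outliers))
  # with outlier_rate = 0 and noise-free replicates, nothing is removed
  cfg0 <- synthetic_config(rng_seed = 44, n_genes = 40, outlier_rate = 0,
                           noise_sd = 0)
  ex0 <- generate_expression(cfg0)
  fc0 <- suppressMessages(fold_change(ex0$matrix, ex0$samples, "MB", "MT"))
  expect_identical(sum(fc0$n_outliers), 0L)
  # with Gaussian noise, the false-flag rate stays near the nominal 0.1%
  cfg1 <- synthetic_config(rng_seed = 45, n_genes = 40, outlier_rate = 0)
  ex1 <- generate_expression(cfg1)
  fc1 <- fold_change(ex1$matrix, ex1$samples, "MB", "MT")
  n_groups <- nrow(ex1$matrix) * length(unique(ex1$samples$condition))
  expect_lte(sum(fc1$n_outliers), ceiling(0.02 * n_groups))
})

test_that("probe records collapse to the maximally regulated probe with documented tie-breaks", {
  pr <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                   fold_change = c(2^0.5, 2^-2, 1, 2, 0.5),
                   log2fc = c(0.5, -2, 0, 1, -1),
                   p_t = c(0.1, 0.2, 0.5, 0.04, 0.01),
                   p_anova = NA_real_, n_outliers = 0L, selected = FALSE)
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                    gene_id = c("gA", "gA", "gB", "gC", "gC"))
  out <- collapse_to_gene(pr, map)
  expect_identical(out$log2fc[out$gene_id == "gA"], -2) # max |log2fc|
  expect_identical(out$probe_id[out$gene_id == "gB"], "p3") # single probe
  # |1| ties |-1|: smaller p wins
  expect_identical(out$probe_id[out$gene_id == "gC"], "p5")
  # full tie: lexicographic probe id
  pr2 <- pr[4:5, ]; pr2$p_t <- 0.05
  out2 <- collapse_to_gene(pr2, map[4:5, ])
  expect_identical(out2$probe_id, "p4")
})

test_that("BAC expression is the overlap-weighted mean over contained genes", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(1000, 6000, 30000),
                      end = c(3000, 16000, 40000),
                      fold_change = c(2, 4, 8))
  bacs <- data.frame(bac_id = "b1", chrom = "chr1", start = 0, end = 10000)
  res <- suppressMessages(bac_expression(genes, bacs))
  # g1 fully inside (weight 1 -> 2); g2 10 kb long with 4 kb inside
  # (weight 0.4 -> 1.6); g3 outside. mean(2, 1.6) = 1.8
  expect_equal(res$bac_values$value, 1.8, tolerance = 1e-12)
  ov <- res$overlaps
  expect_equal(ov$gene_fraction[ov$gene_id == "g1"], 1, tolerance = 1e-12)
  expect_equal(ov$gene_fraction[ov$gene_id == "g2"], 0.4, tolerance = 1e-12)
  expect_true(all(c("pct_overlap_of_bac") %in% names(ov)))
  # two fully contained genes with values 2 and 4 average to 3
  bacs2 <- data.frame(bac_id = "b2", chrom = "chr1", start = 0, end = 20000)
  res2 <- suppressMessages(bac_expression(genes[1:2, ], bacs2))
  expect_equal(res2$bac_values$value, 3, tolerance = 1e-12)
  # a BAC with no genes is missing, with a logged reason
  bacs3 <- data.frame(bac_id = "b3", chrom = "chr1", start = 5e5, end = 6e5)
  expect_message(res3 <- bac_expression(genes, bacs3), "zero genes")
  expect_true(is.na(res3$bac_values$value))
  # malformed intervals are named
  expect_error(bac_expression(genes, data.frame(bac_id = "x", chrom = "chr1",
                                                start = 10, end = 10)),
               "malformed interval")
})

test_that("neighborhood means use half-open windows anchored at the gene centre", {
  recs <- data.frame(gene_id = c("c", "u", "d", "far"), chrom = "chr1",
                     start = c(4999000, 4100000, 5900000, 6000000),
                     end = c(5001000, 4150000, 5950000, 6050000),
                     fold_change = c(1, 3, 5, 100))
  nb <- neighborhood_expression(recs, "c", half_width = 1e6)
  expect_identical(nb$window$start, 4e6)
  expect_identical(nb$window$end, 6e6)
  # "far" starts exactly at the half-open end -> excluded
  expect_equal(nb$mean, mean(c(1, 3, 5)), tolerance = 1e-12)
  only <- neighborhood_expression(recs[1, , drop = FALSE], "c", 1e6)
  expect_identical(only$mean, 1)
  expect_message(neighborhood_expression(recs, "c", 1e7), "truncated")
  expect_error(neighborhood_expression(recs, "nope", 1e6), "absent")
})

test_that("volcano tables pair fold changes with -log10 p and clamp zero p-values", {
  recs <- data.frame(probe_id = c("a", "b", "c"), fold_change = c(2, 1, 11),
                     p_t = c(0.01, 1, 0))
  expect_message(v <- volcano_table(recs), "clamped")
  expect_equal(v$neg_log10_p[1], 2, tolerance = 1e-12)
  expect_identical(v$neg_log10_p[2], 0)
  gamma <- -log10(4e-6)
  expect_gt(v$neg_log10_p[3], gamma)
})
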