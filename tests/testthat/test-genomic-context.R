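test_that("CpG island caller handles the canonical extreme sequences", {
  expect_identical(nrow(call_cpg_islands(strrep("AT", 250))), 0L)
  r <- call_cpg_islands(strrep("CG", 250))
  expect_identical(nrow(r), 1L)
  expect_identical(c(r$start, r$end), c(0L, 500L))
  expect_identical(r$gc_fraction, 1)
  # 250 CpG dinucleotides, N_C = N_G = 250: 250 * 500 / 250^2 = 2
  expect_identical(r$obs_exp, 2)
  # below the minimum length: empty result, not an error
  expect_identical(nrow(call_cpg_islands(strrep("CG", 249))), 0L)
  # windows containing N never qualify
  with_n <- paste0(strrep("CG", 200), "N", strrep("CG", 200))
  expect_identical(nrow(call_cpg_islands(with_n)), 0L)
})

test_that("CpG island caller agrees exactly with the exhaustive oracle", {
  cases <- list(
    fixture_cpg_sequence(1500, core_len = 600, core_at = 450, seed = 1),
    fixture_cpg_sequence(2000, core_len = 700, core_at = 0, seed = 2),
    fixture_cpg_sequence(2500, core_len = 550, core_at = 1900, seed = 3),
    # two cores close enough for their qualifying windows to merge
    {
      s <- fixture_cpg_sequence(3000, core_len = 600, core_at = 600, seed = 4)
      core2 <- fixture_cpg_sequence(600, core_len = 600, core_at = 0, seed = 5)
      paste0(substr(s, 1, 1400), core2, substr(s, 2001, 3000))
    },
    fixture_cpg_sequence(1200, seed = 6)) # no core: typically no island
  for (s in cases) {
    called <- call_cpg_islands(s)
    oracle <- brute_force_cpg(s)
    expect_identical(nrow(called), nrow(oracle %||% data.frame()))
    if (nrow(called)) {
      expect_identical(called$start, oracle$start)
      expect_identical(called$end, oracle$end)
    }
  }
})

test_that("GC content excludes N from the denominator", {
  expect_identical(gc_content("GCGC"), 1)
  expect_identical(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ANGC"), 2 / 3, tolerance = 1e-12)
  expect_message(na <- gc_content("NNNN"), "missing")
  expect_true(is.na(na))
})

test_that("interval coverage merges unions and is invariant to interval splitting", {
  win <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_identical(interval_coverage(win, data.frame(chrom = character(),
                                                     start = integer(),
                                                     end = integer())), 0)
  iv <- data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150))
  expect_equal(interval_coverage(win, iv), 0.15, tolerance = 1e-12)
  full <- data.frame(chrom = "chr1", start = -50, end = 2000)
  full$start <- pmax(full$start, 0)
  expect_identical(interval_coverage(win, full), 1)
  # splitting an interval into abutting pieces changes nothing
  split3 <- data.frame(chrom = "chr1", start = c(0, 30, 50, 90),
                       end = c(30, 50, 90, 150))
  expect_equal(interval_coverage(win, split3), 0.15, tolerance = 1e-12)
  expect_error(interval_coverage(win, data.frame(chrom = "chr1", start = 10,
                                                 end = 5)),
               "line 1")
})

test_that("gene counting uses >= 1 bp overlap in half-open coordinates", {
  win <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  expect_identical(count_genes(win, data.frame(chrom = character(),
                                               start = integer(),
                                               end = integer())), 0L)
  genes <- data.frame(chrom = "chr1",
                      start = c(1100, 1300, 1500, 1900, 2000, 500),
                      end = c(1200, 1400, 1600, 2100, 2500, 1000))
  # three inside, one straddling the right edge; the gene starting exactly
  # at the half-open boundary (2000) and the one ending at 1000 do not count
  expect_identical(count_genes(win, genes), 4L)
})

test_that("window features separate RIDGE from anti-RIDGE construction", {
  cfg <- synthetic_config(rng_seed = 61, n_genes = 12, genome_length = 4e6)
  g <- generate_genome_annotation(cfg)
  gr <- g$genes[g$genes$block_type == "RIDGE", ][2, ]
  ga <- g$genes[g$genes$block_type == "antiRIDGE", ][2, ]
  hw <- 5e5 # window inside one 2-Mbp block
  fr <- suppressMessages(window_features(gr$gene_id, hw, g$genome, g$genes,
                                         g$repeats,
                                         cpg_islands = g$cpg_islands))
  fa <- suppressMessages(window_features(ga$gene_id, hw, g$genome, g$genes,
                                         g$repeats,
                                         cpg_islands = g$cpg_islands))
  expect_gt(fr$n_cpg_islands, fa$n_cpg_islands)
  expect_gt(fr$gc_fraction, fa$gc_fraction)
  expect_gt(fr$n_genes, fa$n_genes)
  expect_gt(fr$sine_coverage, fa$sine_coverage)
  expect_lt(fr$line_coverage, fa$line_coverage)
  # calling islands from sequence in an island-free block reports zero
  anti_block <- g$blocks[g$blocks$type == "antiRIDGE", ][1, ]
  sub <- substr(as.character(g$genome[[1]]), anti_block$start + 1,
                anti_block$start + 3e5)
  expect_identical(nrow(call_cpg_islands(sub)), 0L)
  # 2-Mbp window is contained in the 5-Mbp window around the same gene
  f2 <- suppressMessages(window_features(gr$gene_id, 1e6, g$genome, g$genes,
                                         g$repeats, cpg_islands = g$cpg_islands))
  f5 <- suppressMessages(window_features(gr$gene_id, 2.5e6, g$genome,
                                         g$genes, g$repeats,
                                         cpg_islands = g$cpg_islands))
  expect_lte(f5$start, f2$start)
  expect_gte(f5$end, f2$end)
  expect_error(window_features("nope", 1e6, g$genome, g$genes, g$repeats),
               "absent")
})

test_that("window features are pure functions of their inputs", {
  cfg <- synthetic_config(rng_seed = 62, n_genes = 6, genome_length = 4e6)
  g1 <- generate_genome_annotation(cfg)
  g2 <- generate_genome_annotation(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  f1 <- suppressMessages(window_features(g1$genes$gene_id[1], 1e6, g1$genome,
                                         g1$genes, g1$repeats,
                                         cpg_islands = g1$cpg_islands))
  f2 <- suppressMessages(window_features(g2$genes$gene_id[1], 1e6, g2$genome,
                                         g2$genes, g2$repeats,
                                         cpg_islands = g2$cpg_islands))
  expect_identical(f1, f2)
})
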