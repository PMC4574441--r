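# Nalimov critical values, q = |x* - mean| / s * sqrt(n / (n - 1)), for the
# most extreme of n replicates. Published small-n table (Kaiser & Gottschalk
# 1972, as reprinted e.g. in Lohninger, Teach/Me Data Analysis) for
# significance levels 95% / 99% / 99.9%; beyond n = 10 a t-distribution
# (extreme studentized deviate with Bonferroni) approximation is used.
.nalimov_table <- data.frame(
  n = 3:10,
  q05  = c(1.409, 1.645, 1.757, 1.814, 1.848, 1.870, 1.885, 1.895),
  q01  = c(1.414, 1.715, 1.918, 2.051, 2.142, 2.208, 2.256, 2.294),
  q001 = c(1.414, 1.730, 1.982, 2.183, 2.331, 2.447, 2.509, 2.557))

nalimov_critical <- function(n, alpha = 0.001) {
  if (n < 3L) stopf("Nalimov test needs n >= 3")
  if (n > 10L) { # extreme studentized deviate bound mapped to the q scale
    t <- qt(1 - alpha / (2 * n), df = n - 2)
    return(sqrt(n - 1) * sqrt(t^2 / (n - 2 + t^2)))
  }
  row <- .nalimov_table[.nalimov_table$n == n, ]
  alphas <- c(0.05, 0.01, 0.001)
  qs <- c(row$q05, row$q01, row$q001)
  if (alpha %in% alphas) return(qs[match(alpha, alphas)])
  # linear interpolation on log10(alpha) for nonstandard levels
  la <- log10(alphas)
  stats::approx(la, qs, xout = log10(alpha), rule = 2)$y
}

#' Nalimov outlier test on replicate values
#'
#' Computes `q = |x* - mean| / s * sqrt(n / (n - 1))` for the most extreme
#' replicate and removes it when `q` exceeds the tabulated critical value at
#' the chosen level (default p = 0.001). The test runs in a single pass: at
#' typical replicate counts (n = 5), iterative removal risks emptying
#' groups. With fewer than 3 values no test is performed and everything is
#' kept (logged); a zero standard deviation is a logged degenerate case with
#' no exclusion.
#'
#' @param x numeric replicate values.
#' @param alpha significance level (default 0.001).
#' @return list with `kept` (values), `excluded` (integer indices into `x`),
#'   `q` (statistic of the most extreme value, `NA` when not testable) and
#'   `q_crit`.
#' @export
nalimov_filter <- function(x, alpha = 0.001) {
  n <- length(x)
  if (n < 3L) {
    msgf("Nalimov test skipped: n = %d < 3, all values kept", n)
    return(list(kept = x, excluded = integer(), q = NA_real_,
                q_crit = NA_real_))
  }
  s <- sd(x)
  if (s == 0) {
    msgf("Nalimov test degenerate: zero standard deviation, all values kept")
    return(list(kept = x, excluded = integer(), q = NA_real_,
                q_crit = nalimov_critical(n, alpha)))
  }
  dev <- abs(x - mean(x))
  worst <- which.max(dev)
  q <- dev[worst] / s * sqrt(n / (n - 1))
  q_crit <- nalimov_critical(n, alpha)
  if (q > q_crit)
    list(kept = x[-worst], excluded = worst, q = q, q_crit = q_crit)
  else
    list(kept = x, excluded = integer(), q = q, q_crit = q_crit)
}

#' Per-probe fold changes with outlier filtering and significance
#'
#' For every probe, replicate values of each condition are passed through
#' the Nalimov filter, fold changes are computed as the ratio of antilog
#' means (`mean(2^b) / mean(2^a)`, values being log2-scale normalized
#' intensities), an unpaired two-sided Student's t test compares the two
#' conditions on the log scale (variance-stabilized; the fold change itself
#' is computed on the antilog scale -- a documented asymmetry), and a
#' one-way ANOVA spans all conditions. Probes whose t-test p-value is at or
#' below `select_p` (default 4e-6) are flagged as selected.
#'
#' @param mat numeric matrix, probes x samples, log2 scale; rownames are
#'   probe ids, colnames are sample names.
#' @param samples data.frame with `sample` and `condition` mapping every
#'   column of `mat` to exactly one condition (>= 2 replicates each).
#' @param condition_a,condition_b the comparison pair (fold change is b/a).
#' @param nalimov_alpha outlier-filter level (default 0.001).
#' @param select_p selection threshold on the t-test p-value.
#' @return data.frame `probe_id`, `fold_change`, `log2fc`, `p_t`, `p_anova`,
#'   `n_outliers`, `selected`.
#' @export
fold_change <- function(mat, samples, condition_a, condition_b,
                        nalimov_alpha = 0.001, select_p = 4e-6) {
  if (!all(c("sample", "condition") %in% names(samples)))
    stopf("`samples` needs columns sample, condition")
  if (!all(colnames(mat) %in% samples$sample))
    stopf("every matrix column must be mapped to a condition")
  cond <- samples$condition[match(colnames(mat), samples$sample)]
  for (cc in c(condition_a, condition_b))
    if (!cc %in% cond) stopf("condition '%s' absent from the matrix", cc)
  tab <- table(cond)
  if (any(tab < 2L)) stopf("every condition needs >= 2 replicates")
  conds <- unique(cond)
  probes <- rownames(mat) %||% sprintf("probe_%05d", seq_len(nrow(mat)))
  res <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    kept <- list(); n_out <- 0L
    for (cc in conds) {
      nf <- suppressMessages(nalimov_filter(mat[i, cond == cc],
                                            alpha = nalimov_alpha))
      kept[[cc]] <- nf$kept
      n_out <- n_out + length(nf$excluded)
    }
    a <- kept[[condition_a]]; b <- kept[[condition_b]]
    fc <- mean(2^b) / mean(2^a)
    p_t <- if (sd(a) == 0 && sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else t.test(b, a, var.equal = TRUE)$p.value
    grp <- rep(conds, lengths(kept[conds]))
    val <- unlist(kept[conds], use.names = FALSE)
    p_an <- if (sd(val) == 0) 1 else
      tryCatch(oneway.test(val ~ factor(grp), var.equal = TRUE)$p.value,
               error = function(e) NA_real_)
    res[[i]] <- data.frame(probe_id = probes[i], fold_change = fc,
                           log2fc = log2(fc), p_t = p_t, p_anova = p_an,
                           n_outliers = n_out, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$selected <- out$p_t <= select_p
  rownames(out) <- NULL
  out
}

#' Collapse per-probe records to one record per gene
#'
#' When multiple probe sets map to the same transcript/gene, the maximally
#' regulated one (largest `|log2fc|`) is kept. Ties are broken by smaller
#' p-value, then lexicographic probe id.
#'
#' @param probe_records output of [fold_change()].
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @return data.frame with one row per gene (plus a `gene_id` column);
#'   genes with zero probes are absent.
#' @export
collapse_to_gene <- function(probe_records, probe_map) {
  merged <- merge(probe_records, probe_map, by = "probe_id")
  ord <- order(merged$gene_id, -abs(merged$log2fc), merged$p_t,
               merged$probe_id)
  merged <- merged[ord, ]
  out <- merged[!duplicated(merged$gene_id), ]
  rownames(out) <- NULL
  out[, c("gene_id", setdiff(names(out), "gene_id"))]
}

#' Overlap-weighted cumulative expression per BAC
#'
#' The cumulative expression change of a BAC probe is the average, over the
#' genes it overlaps, of the gene's value weighted by the overlapping
#' fraction of the gene (`overlap length / total gene length`). The
#' per-transcript percentage of overlap with the BAC is reported alongside.
#'
#' @param gene_records data.frame with `gene_id`, a value column
#'   (`value_col`, default `fold_change`) and 0-based half-open coordinates
#'   `chrom`, `start`, `end`.
#' @param bacs data.frame of BAC intervals with `chrom`, `start`, `end` and
#'   `bac_id`.
#' @param value_col which column of `gene_records` to aggregate.
#' @return list with `bac_values` (`bac_id`, `value`, `n_genes`; `value` is
#'   `NA` with a logged reason for BACs overlapping no gene) and `overlaps`
#'   (`bac_id`, `gene_id`, `overlap_bp`, `gene_fraction`,
#'   `pct_overlap_of_bac`).
#' @export
bac_expression <- function(gene_records, bacs, value_col = "fold_change") {
  gr_genes <- df_to_gr(gene_records)
  gr_bacs <- df_to_gr(bacs)
  hits <- GenomicRanges::findOverlaps(gr_bacs, gr_genes)
  ov <- GenomicRanges::pintersect(gr_bacs[S4Vectors::queryHits(hits)],
                                  gr_genes[S4Vectors::subjectHits(hits)])
  overlaps <- data.frame(
    bac_id = bacs$bac_id[S4Vectors::queryHits(hits)],
    gene_id = gene_records$gene_id[S4Vectors::subjectHits(hits)],
    overlap_bp = GenomicRanges::width(ov),
    gene_fraction = GenomicRanges::width(ov) /
      GenomicRanges::width(gr_genes[S4Vectors::subjectHits(hits)]),
    pct_overlap_of_bac = 100 * GenomicRanges::width(ov) /
      GenomicRanges::width(gr_bacs[S4Vectors::queryHits(hits)]),
    stringsAsFactors = FALSE)
  vals <- gene_records[[value_col]][S4Vectors::subjectHits(hits)]
  weighted <- overlaps$gene_fraction * vals
  bac_values <- data.frame(bac_id = bacs$bac_id, value = NA_real_,
                           n_genes = 0L, stringsAsFactors = FALSE)
  if (nrow(overlaps)) {
    agg <- tapply(weighted, overlaps$bac_id, mean)
    cnt <- tapply(weighted, overlaps$bac_id, length)
    idx <- match(names(agg), bac_values$bac_id)
    bac_values$value[idx] <- as.numeric(agg)
    bac_values$n_genes[idx] <- as.integer(cnt)
  }
  empty <- bac_values$bac_id[bac_values$n_genes == 0L]
  if (length(empty))
    msgf("BAC(s) overlapping zero genes reported missing: %s",
         paste(empty, collapse = ", "))
  list(bac_values = bac_values, overlaps = overlaps)
}

#' Mean expression over a genomic neighborhood window
#'
#' Averages the values of all entries overlapping the window
#' `[center - half_width, center + half_width)` anchored at the midpoint of
#' the center gene's span. Windows extending beyond the chromosome are
#' truncated with a logged note.
#'
#' @param records data.frame with `gene_id` (or probe id), a `value` column
#'   named by `value_col`, and 0-based half-open `chrom`, `start`, `end`.
#' @param center_gene gene id present in `records` anchoring the window.
#' @param half_width half-window in bp (1e6 for the 2-Mbp scale, 2.5e6 for
#'   the 5-Mbp scale).
#' @param chrom_length optional chromosome length for right truncation.
#' @param value_col value column name.
#' @return list `window` (`chrom`, `start`, `end`), `mean` and `n`.
#' @export
neighborhood_expression <- function(records, center_gene, half_width = 1e6,
                                    chrom_length = NULL,
                                    value_col = "fold_change") {
  row <- records[records$gene_id == center_gene, , drop = FALSE]
  if (!nrow(row)) stopf("center gene '%s' absent from records", center_gene)
  row <- row[1, ]
  center <- floor((row$start + row$end) / 2)
  w0 <- center - half_width; w1 <- center + half_width
  if (w0 < 0 || (!is.null(chrom_length) && w1 > chrom_length)) {
    w0 <- max(w0, 0)
    if (!is.null(chrom_length)) w1 <- min(w1, chrom_length)
    msgf("window around '%s' truncated at chromosome edge", center_gene)
  }
  sel <- records$chrom == row$chrom & records$start < w1 & records$end > w0
  list(window = data.frame(chrom = row$chrom, start = w0, end = w1),
       mean = if (any(sel)) mean(records[[value_col]][sel]) else NA_real_,
       n = sum(sel))
}

#' Volcano-plot table
#'
#' Pairs each record's fold change with `-log10(p)`. Zero p-values are
#' clamped to the smallest positive double with a logged note. No plotting
#' happens here; the table feeds any graphics layer.
#'
#' @param records data.frame with `fold_change` and a p-value column
#'   (`p_col`, default `p_t`).
#' @param p_col p-value column name.
#' @return data.frame `fold_change`, `neg_log10_p` plus any id columns
#'   present in `records`.
#' @export
volcano_table <- function(records, p_col = "p_t") {
  p <- records[[p_col]]
  if (any(p == 0, na.rm = TRUE)) {
    msgf("%d zero p-value(s) clamped to machine minimum", sum(p == 0))
    p[p == 0] <- .Machine$double.xmin
  }
  ids <- intersect(c("probe_id", "gene_id"), names(records))
  out <- cbind(records[, ids, drop = FALSE],
               data.frame(fold_change = records$fold_change,
                          neg_log10_p = -log10(p)))
  rownames(out) <- NULL
  out
}
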