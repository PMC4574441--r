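#' Chi-square test of positional randomness
#'
#' Normalized distances are binned in 0.25 steps over `[0, 1]` (four bins,
#' last bin right-closed). Under random positioning each bin holds 25% of
#' loci; divergence is tested with the chi-square statistic
#' `sum((O - E)^2 / E)` with `E = n / 4` and 3 degrees of freedom.
#'
#' @param values normalized distances in `[0, 1]` (one gene/condition/
#'   compartment set).
#' @param alpha significance level for the verdict (default 0.05).
#' @param gene_id,condition,compartment annotation carried into the result.
#' @param min_n warning threshold for expected-count validity (default 8).
#' @return one-row data.frame: observed counts `o1..o4`, `chi2`, `df`,
#'   `p_value` and `verdict` (`"random"` or `"nonrandom"`).
#' @export
randomness_test <- function(values, alpha = 0.05, gene_id = NA_character_,
                            condition = NA_character_,
                            compartment = NA_character_, min_n = 8L) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("no normalized values supplied")
  if (any(values < 0 | values > 1))
    stopf("normalized values must lie in [0, 1]")
  if (length(values) < min_n)
    warnf("only %d values; expected counts below chi-square validity",
          length(values))
  bin <- findInterval(values, c(0, 0.25, 0.5, 0.75), rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = 4L)
  n <- sum(counts)
  expected <- n / 4
  chi2 <- sum((counts - expected)^2 / expected)
  p <- pchisq(chi2, df = 3, lower.tail = FALSE)
  data.frame(gene_id = gene_id, condition = condition,
             compartment = compartment,
             o1 = counts[1], o2 = counts[2], o3 = counts[3], o4 = counts[4],
             n = n, chi2 = chi2, df = 3L, p_value = p,
             verdict = if (p < alpha) "nonrandom" else "random",
             stringsAsFactors = FALSE)
}

#' Pearson correlation with Fisher confidence interval
#'
#' Product-moment correlation with a two-sided p-value from the t
#' distribution on `n - 2` degrees of freedom and a confidence interval from
#' the Fisher z-transform at the requested level (default 0.95). With
#' `one_sided = TRUE` the interval and p-value are one-sided in the
#' direction of the observed coefficient, which reproduces reports whose
#' printed intervals are bounded by -1 or +1 on one side.
#'
#' @param x,y numeric vectors of equal length `>= 3` with finite values and
#'   nonzero variance (a constant input is an error, not `R = 0`).
#' @param confidence confidence level.
#' @param one_sided use a one-sided alternative in the sign of `R`.
#' @return one-row data.frame `r`, `ci_lower`, `ci_upper`, `p_value`, `n`.
#'   The Fisher interval requires `n >= 4`; at `n = 3` the bounds are `NA`.
#' @export
pearson_ci <- function(x, y, confidence = 0.95, one_sided = FALSE) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stopf("`x` and `y` must be finite")
  if (length(x) < 3L) stopf("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("undefined correlation: zero variance in input")
  r0 <- cor(x, y)
  alt <- if (!one_sided) "two.sided" else if (r0 >= 0) "greater" else "less"
  ct <- suppressWarnings(cor.test(x, y, method = "pearson",
                                  conf.level = confidence,
                                  alternative = alt))
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  data.frame(r = unname(ct$estimate), ci_lower = ci[1], ci_upper = ci[2],
             p_value = ct$p.value, n = length(x))
}

#' Correlate repositioning with expression change
#'
#' Pairs per-gene changes in normalized position (`delta`, from
#' [delta_position()]) with per-gene expression changes (signed log2 fold
#' change by default) and computes the Pearson correlation for each
#' compartment present. Under the sign conventions used throughout the
#' package, a positive correlation means up-regulated genes move away from
#' the compartment (equivalently, down-regulated genes move toward it --
#' the "silencing compartment" direction).
#'
#' @param delta_pos data.frame with `gene_id`, `compartment`, `delta`.
#' @param delta_expr data.frame with `gene_id` and an expression-change
#'   column named by `expr_col` (default `log2fc`).
#' @param scale label for the aggregation scale (`"gene"`, `"BAC"`,
#'   `"2Mbp"`, `"5Mbp"`).
#' @param system label for the cellular system (e.g. `"differentiation"`).
#' @param expr_col expression column to correlate.
#' @param confidence,one_sided passed to [pearson_ci()].
#' @return data.frame with one row per compartment: `scale`, `system`,
#'   `compartment`, `feature`, `r`, `ci_lower`, `ci_upper`, `p_value`, `n`.
#'   Compartments with fewer than 3 paired genes are skipped with a logged
#'   reason; a zero-variance expression change surfaces as an error.
#' @export
correlate_repositioning <- function(delta_pos, delta_expr, scale = "gene",
                                    system = "differentiation",
                                    expr_col = "log2fc", confidence = 0.95,
                                    one_sided = FALSE) {
  if (!all(c("gene_id", "compartment", "delta") %in% names(delta_pos)))
    stopf("`delta_pos` needs gene_id, compartment, delta")
  if (!all(c("gene_id", expr_col) %in% names(delta_expr)))
    stopf("`delta_expr` needs gene_id and '%s'", expr_col)
  out <- list()
  for (comp in unique(delta_pos$compartment)) {
    sub <- delta_pos[delta_pos$compartment == comp, ]
    merged <- merge(sub, delta_expr[, c("gene_id", expr_col)], by = "gene_id")
    merged <- merged[complete.cases(merged[, c("delta", expr_col)]), ]
    if (nrow(merged) < 3L) {
      msgf("skipping %s/%s/%s: %d paired genes (< 3)", scale, system, comp,
           nrow(merged))
      next
    }
    pc <- tryCatch(
      pearson_ci(merged$delta, merged[[expr_col]], confidence, one_sided),
      error = function(e) stopf("cell %s/%s/%s: %s", scale, system, comp,
                                conditionMessage(e)))
    out[[comp]] <- cbind(data.frame(scale = scale, system = system,
                                    compartment = comp,
                                    feature = paste0("delta_", expr_col),
                                    stringsAsFactors = FALSE), pc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate gene position with RIDGE/anti-RIDGE genomic features
#'
#' For one condition and compartment, correlates each gene's mean normalized
#' distance with each genomic-context feature of its surrounding window
#' (CpG-island count, %GC, gene count and %SINE as RIDGE markers; %LINE as
#' the anti-RIDGE marker). Positive correlations mean high-feature regions
#' lie farther from the heterochromatin compartment.
#'
#' @param mean_pos data.frame with `gene_id`, `compartment`, `condition`,
#'   `mean_norm` (mean normalized distance per gene).
#' @param features data.frame with `gene_id` plus feature columns (default
#'   set: `n_cpg_islands`, `gc_fraction`, `n_genes`, `sine_coverage`,
#'   `line_coverage`).
#' @param feature_cols feature columns to correlate.
#' @param confidence,one_sided passed to [pearson_ci()].
#' @param bh_column append a Benjamini-Hochberg adjusted p-value column
#'   (`p_bh_supplementary`) across the emitted rows; this adjustment is a
#'   supplementary output, not part of the per-cell reporting convention.
#' @return data.frame with one row per condition x compartment x feature.
#' @export
correlate_position_features <- function(mean_pos, features,
                                        feature_cols = c("n_cpg_islands",
                                                         "gc_fraction",
                                                         "n_genes",
                                                         "sine_coverage",
                                                         "line_coverage"),
                                        confidence = 0.95, one_sided = FALSE,
                                        bh_column = TRUE) {
  if (!all(c("gene_id", "compartment", "condition", "mean_norm") %in%
           names(mean_pos)))
    stopf("`mean_pos` needs gene_id, compartment, condition, mean_norm")
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols))
    stopf("feature column(s) absent: %s", paste(missing_cols, collapse = ", "))
  out <- list()
  for (cond in unique(mean_pos$condition))
    for (comp in unique(mean_pos$compartment)) {
      sub <- mean_pos[mean_pos$condition == cond &
                        mean_pos$compartment == comp, ]
      merged <- merge(sub, features, by = "gene_id")
      for (feat in feature_cols) {
        keep <- complete.cases(merged[, c("mean_norm", feat)])
        if (sum(keep) < 3L) {
          msgf("skipping %s/%s/%s: %d paired genes (< 3)", cond, comp, feat,
               sum(keep))
          next
        }
        pc <- tryCatch(
          pearson_ci(merged$mean_norm[keep], merged[[feat]][keep],
                     confidence, one_sided),
          error = function(e) stopf("cell %s/%s/%s: %s", cond, comp, feat,
                                    conditionMessage(e)))
        out[[length(out) + 1L]] <-
          cbind(data.frame(condition = cond, compartment = comp,
                           feature = feat,
                           feature_class = if (feat == "line_coverage")
                             "anti-RIDGE" else "RIDGE",
                           stringsAsFactors = FALSE), pc)
      }
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(res) && bh_column)
    res$p_bh_supplementary <- p.adjust(res$p_value, method = "BH")
  res
}
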