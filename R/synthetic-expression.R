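#' Generate a synthetic probe-level expression matrix
#'
#' Emulates an RMA-normalized microarray experiment on the log2 scale:
#' per-gene baselines, per-probe offsets, Gaussian replicate noise, planted
#' log2 fold changes between condition pairs, and optional aberrant
#' replicates (a single replicate of a probe x condition cell shifted by
#' `outlier_sd_mult` noise SDs -- at least 5, so the Nalimov stage at its
#' p = 0.001 threshold must flag them).
#'
#' Planted effects: `config$planted_log2fc` (named by gene id, recycled from
#' a scalar) is added to the second condition of `conditions`;
#' `planted_log2fc_2`, when supplied, is added to the fourth condition
#' (the ectopic high-expressor), letting both comparison pairs carry
#' independent effects.
#'
#' @param config a [synthetic_config()].
#' @param planted_log2fc_2 optional named vector for the second pair.
#' @param rng_seed seed (default `config$rng_seed`).
#' @return list with `matrix` (probes x samples, log2), `samples`
#'   (`sample`, `condition`, `replicate`), `probe_map` (`probe_id`,
#'   `gene_id`), and `truth` (`planted` per-gene effects and `outliers`
#'   table of injected aberrant replicates).
#' @export
generate_expression <- function(config, planted_log2fc_2 = NULL,
                                rng_seed = config$rng_seed) {
  if (config$replicates_per_condition < 2L)
    stopf("replicates_per_condition must be >= 2 (variance undefined)")
  n_genes <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n_genes))
  expand_fc <- function(v) {
    out <- setNames(rep(0, n_genes), genes)
    if (is.null(v)) return(out)
    if (is.null(names(v)) && length(v) == 1L) v <- setNames(rep(v, n_genes), genes)
    keep <- intersect(names(v), genes)
    out[keep] <- v[keep]
    out
  }
  fc1 <- expand_fc(config$planted_log2fc)
  fc2 <- expand_fc(planted_log2fc_2)
  conds <- config$conditions
  reps <- config$replicates_per_condition
  with_seed(rng_seed, {
    base_gene <- rnorm(n_genes, mean = 8, sd = 1.5)
    probe_map <- data.frame(
      probe_id = sprintf("%s_p%d", rep(genes, each = config$n_probes_per_gene),
                         seq_len(config$n_probes_per_gene)),
      gene_id = rep(genes, each = config$n_probes_per_gene),
      stringsAsFactors = FALSE)
    n_probes <- nrow(probe_map)
    probe_offset <- rnorm(n_probes, 0, 0.3)
    samples <- data.frame(
      sample = paste0(rep(conds, each = reps), "_", seq_len(reps)),
      condition = rep(conds, each = reps),
      replicate = rep(seq_len(reps), length(conds)),
      stringsAsFactors = FALSE)
    eff <- matrix(0, n_genes, length(conds), dimnames = list(genes, conds))
    if (length(conds) >= 2L) eff[, 2L] <- fc1
    if (length(conds) >= 4L) eff[, 4L] <- fc2
    gidx <- match(probe_map$gene_id, genes)
    mat <- matrix(NA_real_, n_probes, nrow(samples),
                  dimnames = list(probe_map$probe_id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- base_gene[gidx] + probe_offset + eff[gidx, samples$condition[j]]
      mat[, j] <- mu + rnorm(n_probes, 0, config$noise_sd)
    }
    outliers <- NULL
    if (config$outlier_rate > 0 && config$noise_sd > 0) {
      cells <- expand.grid(probe = seq_len(n_probes),
                           condition = conds, stringsAsFactors = FALSE)
      hit <- runif(nrow(cells)) < config$outlier_rate
      recs <- vector("list", sum(hit))
      ki <- 0L
      for (ci in which(hit)) {
        cols <- which(samples$condition == cells$condition[ci])
        col <- cols[sample.int(length(cols), 1L)]
        shift <- sample(c(-1, 1), 1L) * config$outlier_sd_mult * config$noise_sd
        mat[cells$probe[ci], col] <- mat[cells$probe[ci], col] + shift
        ki <- ki + 1L
        recs[[ki]] <- data.frame(probe_id = probe_map$probe_id[cells$probe[ci]],
                                 sample = samples$sample[col], shift = shift,
                                 stringsAsFactors = FALSE)
      }
      outliers <- if (ki) do.call(rbind, recs) else NULL
    }
    list(matrix = mat, samples = samples, probe_map = probe_map,
         truth = list(planted = data.frame(gene_id = genes,
                                           log2fc_pair1 = unname(fc1),
                                           log2fc_pair2 = unname(fc2),
                                           stringsAsFactors = FALSE),
                      outliers = outliers))
  })
}
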