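#' Simulate a null positioning study (uniform loci)
#'
#' Generates `config$n_nuclei` synthetic nuclei, samples a
#' `config$n_background`-point background per nucleus, places
#' `config$loci_per_nucleus` loci uniformly over each nucleus's in-mask
#' volume (independently per replicate) and normalizes every locus distance
#' against its own nucleus's background. Because loci and background points
#' are drawn from the same distribution and measured identically, the
#' normalized distances are uniform on `[0, 1]`: this is the null the
#' chi-square randomness test is built on. Nuclei are processed one at a
#' time so only distance summaries are retained.
#'
#' @param config a [synthetic_config()].
#' @param n_replicates independent locus placements per nucleus set;
#'   backgrounds and nuclei are shared across replicates.
#' @param rng_seed root seed (default `config$rng_seed`).
#' @return data.frame with `replicate`, `locus_id`, `nucleus_id`,
#'   `d_periphery_um`, `d_chromocenter_um`, `norm_periphery`,
#'   `norm_chromocenter`.
#' @export
simulate_null_positioning <- function(config, n_replicates = 1L,
                                      rng_seed = config$rng_seed) {
  gen <- generate_nuclei(config, n = config$n_nuclei, render = FALSE,
                         rng_seed = derive_seed(rng_seed, 1L))
  out <- vector("list", config$n_nuclei)
  for (i in seq_along(gen$nuclei)) {
    nuc <- gen$nuclei[[i]]
    fields <- distance_fields(nuc)
    bg <- sample_background(nuc, config$n_background,
                            rng_seed = derive_seed(rng_seed, 100L + i),
                            fields = fields)
    n_loci <- config$loci_per_nucleus * n_replicates
    loci <- place_loci(nuc, n_loci, bias = config$locus_bias,
                       rng_seed = derive_seed(rng_seed, 5000L + i))
    d <- measure_distances(as.matrix(loci[, c("x_um", "y_um", "z_um")]),
                           nuc, fields)
    out[[i]] <- data.frame(
      replicate = rep(seq_len(n_replicates), each = config$loci_per_nucleus),
      locus_id = loci$locus_id, nucleus_id = nuc$nucleus_id,
      d_periphery_um = d$d_periphery_um,
      d_chromocenter_um = d$d_chromocenter_um,
      norm_periphery = normalize_distance(d$d_periphery_um, bg$d_periphery),
      norm_chromocenter = if (is.null(bg$d_chromocenter)) NA_real_ else
        normalize_distance(d$d_chromocenter_um, bg$d_chromocenter),
      stringsAsFactors = FALSE)
    gen$nuclei[i] <- list(NULL) # release the mask
  }
  do.call(rbind, out)
}

#' Simulate a two-condition repositioning study with planted effects
#'
#' The parameter-recovery workhorse: for each gene a latent effect couples a
#' planted log2 fold change with a planted change in normalized position at
#' correlation `config$planted_rho`. Condition A nuclei use the
#' myoblast-like chromocenter preset, condition B the myotube-like preset
#' (heterochromatin remodelling accompanies the condition change). Each gene
#' receives one locus per nucleus, placed at its target background quantile
#' of the chosen compartment via inverse-ECDF lookup (plus per-locus
#' quantile jitter), so the measured per-gene position change recovers the
#' planted one up to sampling noise.
#'
#' Sign convention: positive planted/measured position change means the
#' locus is farther from the compartment in condition B; with positive
#' `planted_rho`, up-regulated genes move away from the compartment.
#'
#' @param config a [synthetic_config()] with non-`NA` `planted_rho`.
#' @param compartment compartment carrying the planted shift.
#' @param conditions length-2 character vector (A, B).
#' @param rng_seed root seed.
#' @param log2fc optional named per-gene log2 fold changes; drawn
#'   `N(0, 1.5)` when `NULL`.
#' @param delta_scale SD of planted position changes (normalized units).
#' @param locus_jitter SD of per-locus quantile noise.
#' @return list: `norm_table` (`gene_id`, `nucleus_id`, `condition`,
#'   `compartment`, `value`), `loci` (per-locus table with raw and
#'   normalized distances: `locus_id`, `gene_id`, `nucleus_id`,
#'   `condition`, `d_per_um`, `d_cc_um`, `norm_per`, `norm_cc`), `delta`
#'   (per-gene measured change per compartment, from [delta_position()]),
#'   `planted` (`gene_id`, `log2fc`, `delta_target`), and `conditions`.
#' @export
simulate_repositioning_study <- function(config,
                                         compartment = c("periphery",
                                                         "chromocenter"),
                                         conditions = config$conditions[1:2],
                                         rng_seed = config$rng_seed,
                                         log2fc = NULL, delta_scale = 0.3,
                                         locus_jitter = 0.05) {
  compartment <- match.arg(compartment)
  rho <- config$planted_rho
  if (is.na(rho)) stopf("config$planted_rho must be set for this study")
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  planted <- with_seed(derive_seed(rng_seed, 11L), {
    z <- rnorm(config$n_genes)
    e <- rnorm(config$n_genes)
    fc <- if (is.null(log2fc)) 1.5 * z else {
      v <- setNames(rep(0, config$n_genes), genes)
      v[intersect(names(log2fc), genes)] <-
        log2fc[intersect(names(log2fc), genes)]
      unname(v)
    }
    zf <- as.numeric(scale(fc))
    delta <- delta_scale * (rho * zf + sqrt(1 - rho^2) * e)
    delta <- pmin(pmax(delta, -0.7), 0.7)
    data.frame(gene_id = genes, log2fc = fc, delta_target = delta,
               stringsAsFactors = FALSE)
  })
  q_target <- cbind(0.5 - planted$delta_target / 2,
                    0.5 + planted$delta_target / 2)
  presets <- c("MB", "MT")
  rows <- list()
  for (ci in 1:2) {
    cond_cfg <- synthetic_config(
      rng_seed = config$rng_seed, n_nuclei = config$n_nuclei,
      nucleus_semiaxes = config$nucleus_semiaxes,
      voxel_size = config$voxel_size, preset = presets[ci],
      n_background = config$n_background)
    gen <- generate_nuclei(cond_cfg, n = config$n_nuclei, render = FALSE,
                           rng_seed = derive_seed(rng_seed, 20L + ci),
                           id_prefix = paste0("nuc_", conditions[ci]))
    for (i in seq_along(gen$nuclei)) {
      nuc <- gen$nuclei[[i]]
      fields <- distance_fields(nuc)
      bg <- sample_background(nuc, config$n_background,
                              rng_seed = derive_seed(rng_seed,
                                                     1000L * ci + i),
                              fields = fields, keep_points = TRUE)
      q_loc <- with_seed(derive_seed(rng_seed, 7000L * ci + i),
                         pmin(pmax(q_target[, ci] +
                                     rnorm(config$n_genes, 0, locus_jitter),
                                   0.001), 0.999))
      loci <- place_loci(nuc, config$n_genes,
                         bias = list(type = "quantile", q = q_loc,
                                     compartment = compartment),
                         background = bg)
      d <- measure_distances(as.matrix(loci[, c("x_um", "y_um", "z_um")]),
                             nuc, fields)
      np <- normalize_distance(d$d_periphery_um, bg$d_periphery)
      ncc <- if (is.null(bg$d_chromocenter)) rep(NA_real_, nrow(d)) else
        normalize_distance(d$d_chromocenter_um, bg$d_chromocenter)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loci$locus_id, gene_id = genes,
        nucleus_id = nuc$nucleus_id, condition = conditions[ci],
        d_per_um = d$d_periphery_um, d_cc_um = d$d_chromocenter_um,
        periphery = np, chromocenter = ncc, stringsAsFactors = FALSE)
      gen$nuclei[i] <- list(NULL)
    }
  }
  wide <- do.call(rbind, rows)
  loci_table <- data.frame(wide[, c("locus_id", "gene_id", "nucleus_id",
                                    "condition", "d_per_um", "d_cc_um")],
                           norm_per = wide$periphery,
                           norm_cc = wide$chromocenter,
                           stringsAsFactors = FALSE)
  norm_table <- rbind(
    data.frame(gene_id = wide$gene_id, nucleus_id = wide$nucleus_id,
               condition = wide$condition, compartment = "periphery",
               value = wide$periphery, stringsAsFactors = FALSE),
    data.frame(gene_id = wide$gene_id, nucleus_id = wide$nucleus_id,
               condition = wide$condition, compartment = "chromocenter",
               value = wide$chromocenter, stringsAsFactors = FALSE))
  norm_table <- norm_table[!is.na(norm_table$value), ]
  delta <- do.call(rbind, lapply(unique(norm_table$compartment), function(cp) {
    sub <- norm_table[norm_table$compartment == cp, ]
    dd <- suppressWarnings(delta_position(sub, conditions[1], conditions[2]))
    cbind(compartment = cp, dd, stringsAsFactors = FALSE)
  }))
  rownames(delta) <- NULL
  list(norm_table = norm_table, loci = loci_table, delta = delta,
       planted = planted, conditions = conditions, compartment = compartment)
}
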