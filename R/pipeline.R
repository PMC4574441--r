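#' Default pipeline run configuration
#'
#' All analysis defaults are the study parameters: 10,000 background points
#' per nucleus, 0.25 bin width, chi-square verdict at alpha 0.05, Nalimov
#' threshold p = 0.001, selection threshold p <= 4e-6, window half-widths
#' 1 and 2.5 Mbp, chromocenter threshold multiplier k = 2, and a
#' 47-nuclei-per-condition warning benchmark. The `synthetic` block holds
#' [synthetic_config()] arguments for simulated runs.
#'
#' @param rng_seed root seed; every stage derives its own stream from it.
#' @return a nested configuration list (round-trips losslessly through
#'   [write_run_config()] / [read_run_config()]).
#' @export
default_run_config <- function(rng_seed = 1L) {
  list(
    rng_seed = as.integer(rng_seed),
    n_background = 10000L,
    bin_width = 0.25,
    alpha_random = 0.05,
    alpha_nalimov = 0.001,
    select_p = 4e-6,
    window_half_widths = list("2Mbp" = 1e6, "5Mbp" = 2.5e6),
    chromocenter_k = 2,
    min_nuclei = 47L,
    condition_pairs = list(differentiation = c("MB", "MT"),
                           ectopic = c("low", "high")),
    cpg_mode = "bed",
    synthetic = list(n_nuclei = 50L, n_genes = 14L, n_probes_per_gene = 2L,
                     replicates_per_condition = 5L, noise_sd = 0.1,
                     outlier_rate = 0.01, planted_rho = 0.8,
                     genome_length = 8e6,
                     nucleus_semiaxes = c(5, 5, 2.5),
                     voxel_size = c(0.08, 0.08, 0.2)))
}

#' Read/write a pipeline configuration
#'
#' Plain-text YAML; reading then writing reproduces the same configuration.
#' @param path YAML file path.
#' @return `read_run_config()` returns the configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  base[names(cfg)] <- cfg
  base
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

syn_config_from_run <- function(config) {
  args <- config$synthetic
  args$rng_seed <- config$rng_seed
  args$n_background <- config$n_background
  do.call(synthetic_config, args)
}

#' Run the positioning-analysis pipeline end to end
#'
#' Orchestrates the synthetic study: simulates two condition pairs
#' (differentiation-like and ectopic-remodelling-like) with planted
#' coupling between repositioning and expression, generates the matching
#' expression matrix and annotated genome, and emits every report:
#' normalized-distance table, expression records and volcano table,
#' per-gene randomness verdicts, genomic-context features, the
#' repositioning-vs-expression correlation report (4 scales x 2
#' compartments x 2 systems) and the position-vs-RIDGE-feature correlation
#' report. Each stage writes CSV artifacts into `outdir` and registers them
#' in a JSON run manifest with seeds and md5 hashes; a rerun with the same
#' seed reproduces every artifact byte for byte.
#'
#' @param config configuration list from [default_run_config()] /
#'   [read_run_config()].
#' @param outdir output directory (created if missing).
#' @param stages subset of
#'   `c("simulate", "expression", "test-random", "context", "correlate",
#'   "report")` or `"all"`.
#' @return (invisibly) a list with every in-memory artifact plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         outdir = "nucpos_run", stages = "all") {
  all_stages <- c("simulate", "expression", "test-random", "context",
                  "correlate", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(outdir, "pipeline_state.rds")
  art <- if (file.exists(state_path)) readRDS(state_path) else list()
  manifest <- art$manifest %||% list(
    package_version = as.character(utils::packageVersion("nucpos")),
    rng_seed = config$rng_seed, config = config, stages = list(),
    warnings = list())
  scfg <- syn_config_from_run(config)
  pairs <- config$condition_pairs
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  register <- function(stage, paths) {
    manifest$stages[[stage]] <<- list(
      seed = derive_seed(config$rng_seed, match(stage, all_stages)),
      outputs = as.list(setNames(unname(tools::md5sum(paths)),
                                 basename(paths))))
    manifest
  }

  if ("simulate" %in% stages) {
    studies <- list()
    for (k in seq_along(pairs)) {
      studies[[names(pairs)[k]]] <- simulate_repositioning_study(
        scfg, conditions = pairs[[k]],
        rng_seed = derive_seed(config$rng_seed, 40L + k))
    }
    genome <- generate_genome_annotation(scfg,
                                         rng_seed = derive_seed(config$rng_seed, 60L))
    art$studies <- studies
    art$genome <- genome
    norm_all <- do.call(rbind, lapply(names(studies), function(nm)
      cbind(system = nm, studies[[nm]]$norm_table)))
    loci_all <- do.call(rbind, lapply(names(studies), function(nm)
      cbind(system = nm, studies[[nm]]$loci)))
    paths <- c(emit(loci_all, "loci_distances.csv"),
               emit(norm_all, "normalized_distances.csv"),
               emit(do.call(rbind, lapply(names(studies), function(nm)
                 cbind(system = nm, studies[[nm]]$delta))), "delta_position.csv"),
               emit(genome$genes, "genes.csv"),
               emit(genome$cpg_islands, "cpg_islands.csv"),
               emit(genome$bacs, "bacs.csv"))
    register("simulate", paths)
  }

  if ("expression" %in% stages) {
    studies <- art$studies %||% stopf("run the simulate stage first")
    fc1 <- setNames(studies[[1]]$planted$log2fc, studies[[1]]$planted$gene_id)
    fc2 <- setNames(studies[[2]]$planted$log2fc, studies[[2]]$planted$gene_id)
    scfg1 <- scfg
    scfg1$planted_log2fc <- fc1
    expr <- generate_expression(scfg1, planted_log2fc_2 = fc2,
                                rng_seed = derive_seed(config$rng_seed, 70L))
    art$expression <- expr
    est <- list()
    for (k in seq_along(pairs)) {
      pr <- suppressMessages(
        fold_change(expr$matrix, expr$samples, pairs[[k]][1], pairs[[k]][2],
                    nalimov_alpha = config$alpha_nalimov,
                    select_p = config$select_p))
      est[[names(pairs)[k]]] <- collapse_to_gene(pr, expr$probe_map)
    }
    art$expression_records <- est
    paths <- c(
      emit(do.call(rbind, lapply(names(est), function(nm)
        cbind(system = nm, est[[nm]]))), "expression_records.csv"),
      emit(do.call(rbind, lapply(names(est), function(nm)
        cbind(system = nm, suppressMessages(volcano_table(est[[nm]]))))),
        "volcano.csv"))
    register("expression", paths)
  }

  if ("test-random" %in% stages) {
    studies <- art$studies %||% stopf("run the simulate stage first")
    rows <- list()
    for (nm in names(studies)) {
      nt <- studies[[nm]]$norm_table
      for (cond in unique(nt$condition))
        for (cp in unique(nt$compartment))
          for (g in unique(nt$gene_id)) {
            v <- nt$value[nt$condition == cond & nt$compartment == cp &
                            nt$gene_id == g]
            if (!length(v)) next
            rows[[length(rows) + 1L]] <- cbind(
              system = nm,
              suppressWarnings(randomness_test(v, config$alpha_random,
                                               gene_id = g, condition = cond,
                                               compartment = cp)))
          }
    }
    art$randomness <- do.call(rbind, rows)
    register("test-random", emit(art$randomness, "randomness_summary.csv"))
  }

  if ("context" %in% stages) {
    genome <- art$genome %||% stopf("run the simulate stage first")
    feats <- list()
    for (wn in names(config$window_half_widths)) {
      hw <- config$window_half_widths[[wn]]
      f <- do.call(rbind, lapply(genome$genes$gene_id, function(g)
        suppressMessages(window_features(
          g, hw, genome$genome, genome$genes, genome$repeats,
          cpg_islands = if (config$cpg_mode == "bed") genome$cpg_islands
                        else NULL))))
      feats[[wn]] <- cbind(window = wn, f)
    }
    art$features <- feats
    register("context", emit(do.call(rbind, feats), "window_features.csv"))
  }

  if ("correlate" %in% stages) {
    studies <- art$studies %||% stopf("run the simulate stage first")
    est <- art$expression_records %||% stopf("run the expression stage first")
    genome <- art$genome
    feats <- art$features %||% stopf("run the context stage first")
    gene_coords <- genome$genes[, c("gene_id", "chrom", "start", "end")]
    t1 <- list()
    for (nm in names(studies)) {
      study <- studies[[nm]]
      erec <- merge(est[[nm]], gene_coords, by = "gene_id")
      dpos <- study$delta
      # expression change per scale
      scale_expr <- list(gene = erec[, c("gene_id", "log2fc")])
      bv <- suppressMessages(bac_expression(erec, genome$bacs,
                                            value_col = "log2fc"))
      scale_expr$BAC <- merge(bv$bac_values, genome$bacs[, c("bac_id", "gene_id")],
                              by = "bac_id")[, c("gene_id", "value")]
      names(scale_expr$BAC)[2] <- "log2fc"
      for (wn in names(config$window_half_widths)) {
        hw <- config$window_half_widths[[wn]]
        vals <- vapply(erec$gene_id, function(g)
          suppressMessages(neighborhood_expression(
            erec, g, hw, chrom_length = genome$params$genome_length,
            value_col = "log2fc"))$mean, numeric(1))
        scale_expr[[wn]] <- data.frame(gene_id = erec$gene_id, log2fc = vals)
      }
      for (sc in names(scale_expr))
        t1[[length(t1) + 1L]] <- correlate_repositioning(
          dpos, scale_expr[[sc]], scale = sc, system = nm)
    }
    art$table1 <- do.call(rbind, t1)
    # position vs genomic context at the 2-Mbp scale per condition
    mp <- list()
    for (nm in names(studies)) {
      nt <- studies[[nm]]$norm_table
      agg <- stats::aggregate(value ~ gene_id + compartment + condition,
                              data = nt, FUN = mean)
      names(agg)[names(agg) == "value"] <- "mean_norm"
      mp[[nm]] <- agg
    }
    mean_pos <- do.call(rbind, mp)
    art$table2 <- correlate_position_features(
      mean_pos, feats[["2Mbp"]][, c("gene_id", "n_cpg_islands", "gc_fraction",
                                    "n_genes", "sine_coverage",
                                    "line_coverage")])
    paths <- c(emit(art$table1, "correlation_expression.csv"),
               emit(art$table2, "correlation_features.csv"))
    register("correlate", paths)
  }

  if ("report" %in% stages) {
    manifest_path <- file.path(outdir, "run_manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  art$manifest <- manifest
  saveRDS(art, state_path)
  invisible(art)
}
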