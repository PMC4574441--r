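#' Write a complete synthetic dataset to disk
#'
#' Emits every artifact class the pipeline can consume, in its external
#' format: DAPI-like image stacks and label masks (multi-page TIFF, one
#' file per nucleus, z pages), a FISH spot table (CSV), the expression
#' matrix with sample sheet and probe map (CSV), the genome (FASTA) with
#' gene/repeat/CpG-island/BAC annotations (BED, 0-based half-open), ground
#' truth tables (true distances and normalized positions of every spot,
#' planted expression effects), and a JSON manifest listing all files.
#' With a fixed `config$rng_seed` every artifact is byte-identical across
#' runs.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory.
#' @param render write intensity stacks in addition to label masks.
#' @return (invisibly) the manifest list; written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
write_synthetic_dataset <- function(config, outdir, render = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  gen <- generate_nuclei(config, render = render,
                         rng_seed = derive_seed(config$rng_seed, 1L))
  files <- list(images = character(), masks = character(),
                chromocenter_masks = character())
  spot_rows <- truth_rows <- list()
  for (i in seq_along(gen$nuclei)) {
    nuc <- gen$nuclei[[i]]
    id <- nuc$nucleus_id
    mpath <- p(sprintf("%s_mask.tif", id))
    write_stack(nuc$mask * 1, mpath)
    cpath <- p(sprintf("%s_chromocenters.tif", id))
    write_stack(nuc$chromocenters / 255, cpath)
    files$masks <- c(files$masks, mpath)
    files$chromocenter_masks <- c(files$chromocenter_masks, cpath)
    if (render) {
      ipath <- p(sprintf("%s_dapi.tif", id))
      write_stack(gen$stacks[[i]], ipath)
      files$images <- c(files$images, ipath)
    }
    fields <- distance_fields(nuc)
    bg <- sample_background(nuc, config$n_background,
                            rng_seed = derive_seed(config$rng_seed, 100L + i),
                            fields = fields)
    loci <- place_loci(nuc, config$loci_per_nucleus,
                       bias = config$locus_bias,
                       rng_seed = derive_seed(config$rng_seed, 5000L + i))
    d <- measure_distances(as.matrix(loci[, c("x_um", "y_um", "z_um")]),
                           nuc, fields)
    spot_rows[[i]] <- loci
    truth_rows[[i]] <- cbind(
      loci["locus_id"], d,
      norm_periphery = normalize_distance(d$d_periphery_um, bg$d_periphery),
      norm_chromocenter = if (is.null(bg$d_chromocenter)) NA_real_ else
        normalize_distance(d$d_chromocenter_um, bg$d_chromocenter))
  }
  spots <- do.call(rbind, spot_rows)
  write.csv(spots, p("spots.csv"), row.names = FALSE)
  truth <- do.call(rbind, truth_rows)
  write.csv(truth, p("ground_truth_spots.csv"), row.names = FALSE)
  write.csv(gen$truth$nuclei, p("ground_truth_nuclei.csv"), row.names = FALSE)
  if (!is.null(gen$truth$chromocenters))
    write.csv(gen$truth$chromocenters, p("ground_truth_chromocenters.csv"),
              row.names = FALSE)

  expr <- generate_expression(config,
                              rng_seed = derive_seed(config$rng_seed, 7L))
  write.csv(data.frame(probe_id = rownames(expr$matrix), expr$matrix,
                       check.names = FALSE),
            p("expression_matrix.csv"), row.names = FALSE)
  write.csv(expr$samples, p("samples.csv"), row.names = FALSE)
  write.csv(expr$probe_map, p("probe_map.csv"), row.names = FALSE)
  write.csv(expr$truth$planted, p("ground_truth_expression.csv"),
            row.names = FALSE)

  genome <- generate_genome_annotation(config,
                                       rng_seed = derive_seed(config$rng_seed, 9L))
  Biostrings::writeXStringSet(genome$genome, p("genome.fasta"))
  write_bed <- function(df, name_col, path) {
    gr <- df_to_gr(df)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = df[[name_col]])
    rtracklayer::export(gr, path, format = "BED")
    path
  }
  write_bed(genome$genes, "gene_id", p("genes.bed"))
  write_bed(genome$repeats, "class", p("repeats.bed"))
  if (nrow(genome$cpg_islands)) {
    ci <- genome$cpg_islands
    ci$name <- sprintf("cpg_%03d", seq_len(nrow(ci)))
    write_bed(ci, "name", p("cpg_islands.bed"))
  }
  write_bed(genome$bacs, "bac_id", p("bacs.bed"))

  manifest <- list(
    rng_seed = config$rng_seed,
    images = lapply(files$images, basename),
    masks = lapply(files$masks, basename),
    chromocenter_masks = lapply(files$chromocenter_masks, basename),
    spot_table = "spots.csv",
    expression = c("expression_matrix.csv", "samples.csv", "probe_map.csv"),
    genome = "genome.fasta",
    annotations = c("genes.bed", "repeats.bed",
                    if (nrow(genome$cpg_islands)) "cpg_islands.bed",
                    "bacs.bed"),
    ground_truth = c("ground_truth_spots.csv", "ground_truth_nuclei.csv",
                     "ground_truth_expression.csv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
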