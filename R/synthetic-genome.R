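# CpG-suppressed random sequence: bases drawn independently, then the G of
# a fraction of CpG dinucleotides is rewritten to A/T. Real vertebrate
# genomes are CpG-depleted (obs/exp around 0.2); without suppression an iid
# sequence at GC >= 0.5 would satisfy the island criteria everywhere. The
# initial C/G probabilities are inflated so the post-edit GC content hits
# the requested target.
random_sequence <- function(n, gc_target, cpg_keep = 0.15) {
  # solve 2x - (1 - keep) x^2 = gc_target for the initial C=G probability x
  a <- (1 - cpg_keep); b <- -2; cc <- gc_target
  x <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - 2 * x) / 2, x, x, (1 - 2 * x) / 2))
  is_cpg <- which(base[-n] == "C" & base[-1] == "G")
  if (length(is_cpg)) {
    kill <- is_cpg[runif(length(is_cpg)) >= cpg_keep]
    if (length(kill))
      base[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
  }
  base
}

# CpG-island-like sequence: emit "CG" tokens with probability p_cg, single
# GC-rich bases otherwise; GC ~ 0.78, obs/exp ~ 1.5
island_sequence <- function(n, p_cg = 0.3) {
  out <- character(0)
  while (sum(nchar(out)) < n) {
    k <- n # draw a generous batch
    tok <- ifelse(runif(k) < p_cg, "CG",
                  sample(c("A", "C", "G", "T"), k, replace = TRUE,
                         prob = c(0.2, 0.3, 0.3, 0.2)))
    out <- c(out, tok)
    if (sum(nchar(out)) >= n) break
  }
  substr(paste(out, collapse = ""), 1, n)
}

# sample k non-overlapping intervals of given lengths inside [0, span)
place_disjoint <- function(span, lengths, max_tries = 500L) {
  placed <- matrix(numeric(0), ncol = 2)
  for (len in lengths) {
    ok <- FALSE
    for (i in seq_len(max_tries)) {
      s <- floor(runif(1, 0, span - len))
      if (!nrow(placed) ||
          all(s + len <= placed[, 1] | s >= placed[, 2])) {
        placed <- rbind(placed, c(s, s + len))
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place %d disjoint intervals in %g bp",
                   length(lengths), span)
  }
  placed[order(placed[, 1]), , drop = FALSE]
}

#' Generate a synthetic genome with RIDGE and anti-RIDGE blocks
#'
#' Builds one chromosome of alternating 2-Mbp blocks. RIDGE-like blocks
#' (regions of increased gene expression) are GC-rich, CpG-island-bearing,
#' gene-dense and SINE-dense with few LINEs; anti-RIDGE blocks carry the
#' opposite profile (AT-rich, island-poor, gene-poor, LINE-dense). BAC-like
#' probe intervals of about 180 kbp (uniform in 150-250 kbp) are centred on
#' every gene. Background sequence outside planted islands is CpG-depleted
#' so that only planted islands satisfy the CpG-island criteria.
#'
#' @param config a [synthetic_config()]; uses `genome_length`, `n_genes`
#'   and `rng_seed`.
#' @param block_size block width in bp (default 2e6). `genome_length` must
#'   host at least one RIDGE and one anti-RIDGE block.
#' @param rng_seed seed (default `config$rng_seed`).
#' @return list with `genome` (a `DNAStringSet` with one `chr1` record),
#'   `blocks`, `genes`, `repeats`, `cpg_islands`, `bacs` -- all 0-based
#'   half-open data.frames -- and generation parameters in `params`.
#' @export
generate_genome_annotation <- function(config, block_size = 2e6,
                                       rng_seed = config$rng_seed) {
  glen <- config$genome_length
  n_blocks <- floor(glen / block_size)
  if (n_blocks < 2L)
    stopf("genome_length %g too small: needs at least two %g-bp blocks",
          glen, block_size)
  glen <- n_blocks * block_size
  types <- rep(c("RIDGE", "antiRIDGE"), length.out = n_blocks)
  p <- list(
    RIDGE = list(gc = 0.55, islands_per_mb = 8, island_len = 800,
                 gene_weight = 10, gene_len = c(2e4, 6e4),
                 sine_cov = 0.25, line_cov = 0.05),
    antiRIDGE = list(gc = 0.42, islands_per_mb = 0, island_len = 800,
                     gene_weight = 3, gene_len = c(2e4, 6e4),
                     sine_cov = 0.05, line_cov = 0.25))
  with_seed(rng_seed, {
    weights <- vapply(types, function(tt) p[[tt]]$gene_weight, numeric(1))
    n_gene_blk <- floor(config$n_genes * weights / sum(weights))
    rem <- config$n_genes - sum(n_gene_blk)
    if (rem > 0) { # distribute the remainder over the densest blocks
      ord <- order(weights, decreasing = TRUE)
      n_gene_blk[ord[seq_len(rem)]] <- n_gene_blk[ord[seq_len(rem)]] + 1L
    }
    seq_parts <- vector("list", n_blocks)
    blocks <- genes <- repeats <- islands <- list()
    gene_i <- 0L
    for (b in seq_len(n_blocks)) {
      off <- (b - 1) * block_size
      bp <- p[[types[b]]]
      s <- random_sequence(block_size, bp$gc)
      # plant islands, then genes and repeats (annotations may overlap
      # sequence features; only islands alter the sequence)
      n_isl <- round(bp$islands_per_mb * block_size / 1e6)
      if (n_isl > 0) {
        pos <- place_disjoint(block_size - 2 * bp$island_len,
                              rep(bp$island_len, n_isl)) + bp$island_len
        for (i in seq_len(nrow(pos))) {
          isl <- strsplit(island_sequence(bp$island_len), "")[[1]]
          s[(pos[i, 1] + 1):(pos[i, 1] + bp$island_len)] <- isl
          islands[[length(islands) + 1L]] <- data.frame(
            chrom = "chr1", start = off + pos[i, 1],
            end = off + pos[i, 1] + bp$island_len, block = b)
        }
      }
      n_gene <- n_gene_blk[b]
      if (n_gene > 0) {
        glens <- round(runif(n_gene, bp$gene_len[1], bp$gene_len[2]))
        if (sum(glens) > 0.6 * block_size)
          stopf("genome_length too small to host %d genes in block %d",
                n_gene, b)
        gp <- place_disjoint(block_size, glens)
        for (i in seq_len(nrow(gp))) {
          gene_i <- gene_i + 1L
          genes[[length(genes) + 1L]] <- data.frame(
            chrom = "chr1", start = off + gp[i, 1], end = off + gp[i, 2],
            gene_id = sprintf("g%04d", gene_i), strand = "+", block = b,
            block_type = types[b], stringsAsFactors = FALSE)
        }
      }
      for (cls in c("SINE", "LINE")) {
        cov <- if (cls == "SINE") bp$sine_cov else bp$line_cov
        lr <- if (cls == "SINE") c(150, 300) else c(1000, 6000)
        total <- cov * block_size
        lens <- numeric(0)
        while (sum(lens) < total) lens <- c(lens, round(runif(50, lr[1], lr[2])))
        lens <- lens[cumsum(lens) <= total]
        if (length(lens)) {
          rp <- place_disjoint(block_size, lens)
          repeats[[length(repeats) + 1L]] <- data.frame(
            chrom = "chr1", start = off + rp[, 1], end = off + rp[, 2],
            class = cls, stringsAsFactors = FALSE)
        }
      }
      blocks[[b]] <- data.frame(chrom = "chr1", start = off,
                                end = off + block_size, type = types[b],
                                stringsAsFactors = FALSE)
      seq_parts[[b]] <- paste(s, collapse = "")
    }
    genes <- do.call(rbind, genes)
    bacs <- NULL
    if (!is.null(genes) && nrow(genes)) {
      blen <- round(runif(nrow(genes), 150e3, 250e3))
      ctr <- floor((genes$start + genes$end) / 2)
      # shift (rather than clip) BACs at genome edges so lengths stay in range
      bstart <- pmax(0, pmin(ctr - floor(blen / 2), glen - blen))
      bacs <- data.frame(chrom = "chr1",
                         start = bstart,
                         end = bstart + blen,
                         bac_id = paste0("bac_", genes$gene_id),
                         gene_id = genes$gene_id, stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(paste(unlist(seq_parts), collapse = ""))
    names(genome) <- "chr1"
    list(genome = genome,
         blocks = do.call(rbind, blocks),
         genes = genes,
         repeats = do.call(rbind, repeats),
         cpg_islands = if (length(islands)) do.call(rbind, islands) else
           data.frame(chrom = character(), start = integer(),
                      end = integer(), block = integer()),
         bacs = bacs,
         params = list(block_size = block_size, profiles = p,
                       genome_length = glen))
  })
}
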