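# uniform sampling over the in-mask physical volume: uniform voxel choice
# plus uniform in-voxel jitter (all voxels share one volume on the regular
# grid; the jitter avoids lattice artifacts)
sample_in_mask <- function(nucleus, n) {
  lin <- which(nucleus$mask)
  if (!length(lin)) stopf("nuclear mask is empty")
  pick <- lin[sample.int(length(lin), n, replace = TRUE)]
  dims <- dim(nucleus$mask)
  vox <- cbind((pick - 1) %% dims[1],
               ((pick - 1) %/% dims[1]) %% dims[2],
               (pick - 1) %/% (as.numeric(dims[1]) * dims[2])) + 1L
  jitter <- matrix(runif(3 * n) - 0.5, ncol = 3)
  sweep((vox - 0.5) + jitter, 2, nucleus$voxel_size, "*")
}

#' Sample a per-nucleus random-point background distribution
#'
#' Simulates `n` points uniformly over the in-mask physical volume of one
#' nucleus and measures, for every point, the shortest 3D distance to the
#' nuclear periphery and to the nearest chromocenter surface. These
#' distributions are the morphological background against which actual locus
#' distances are normalized; 10,000 points per nucleus is the default.
#'
#' @param nucleus a [nucleus_model()].
#' @param n number of random points (default 10000).
#' @param rng_seed integer seed making the background reproducible.
#' @param fields optional precomputed [distance_fields()].
#' @param keep_points retain the sampled coordinates and unsorted distances
#'   (needed for rank-targeted synthetic locus placement).
#' @return object of class `background_distribution`: `nucleus_id`,
#'   `n_points`, sorted ascending `d_periphery` and `d_chromocenter`
#'   (the latter `NULL` when the nucleus has no chromocenters), `rng_seed`,
#'   and optionally `points` with aligned raw distances.
#' @export
sample_background <- function(nucleus, n = 10000L, rng_seed = NULL,
                              fields = NULL, keep_points = FALSE) {
  if (!is.numeric(n) || n < 1) stopf("`n` must be a positive count")
  n <- as.integer(n)
  if (is.null(fields)) fields <- distance_fields(nucleus)
  pts <- with_seed(rng_seed, sample_in_mask(nucleus, n))
  d <- measure_distances(pts, nucleus, fields)
  out <- list(nucleus_id = nucleus$nucleus_id, n_points = n,
              d_periphery = sort(d$d_periphery_um),
              d_chromocenter = if (all(is.na(d$d_chromocenter_um))) NULL
                               else sort(d$d_chromocenter_um),
              rng_seed = rng_seed)
  if (keep_points) {
    out$points <- pts
    out$d_periphery_raw <- d$d_periphery_um
    out$d_chromocenter_raw <- d$d_chromocenter_um
  }
  structure(out, class = "background_distribution")
}

#' @export
print.background_distribution <- function(x, ...) {
  cat(sprintf("<background_distribution '%s'> %d points%s\n", x$nucleus_id,
              x$n_points,
              if (is.null(x$d_chromocenter)) " (no chromocenters)" else ""))
  invisible(x)
}

#' Normalize a raw distance against a background distribution
#'
#' Mid-rank empirical CDF: `(#\{b < d\} + 0.5 #\{b = d\}) / n`. The result
#' lies in `[0, 1]`, is monotone in the raw distance, is invariant to any
#' monotone rescaling of the distances (e.g. a unit change), and averages
#' exactly 0.5 over the background's own points. For loci positioned
#' uniformly at random the normalized value is uniform on `[0, 1]`, which is
#' what makes "25% per 0.25-wide bin" the exact null of the downstream
#' chi-square randomness test.
#'
#' @param d numeric vector of raw distances (micrometres).
#' @param background numeric vector of background distances (any order), or
#'   a `background_distribution` (its periphery set is used unless
#'   `compartment = "chromocenter"`).
#' @param compartment which compartment set to use when `background` is a
#'   `background_distribution`.
#' @return numeric vector of normalized distances in `[0, 1]`.
#' @export
normalize_distance <- function(d, background,
                               compartment = c("periphery", "chromocenter")) {
  if (inherits(background, "background_distribution")) {
    compartment <- match.arg(compartment)
    background <- if (compartment == "periphery") background$d_periphery
                  else background$d_chromocenter
  }
  if (is.null(background) || !length(background))
    stopf("background distribution is empty")
  bg <- sort(background)
  n_le <- findInterval(d, bg)
  n_lt <- findInterval(d, bg, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / length(bg)
}

#' Per-gene change in normalized position between conditions
#'
#' For each gene, the mean normalized distance over nuclei in `condition_b`
#' minus the mean over nuclei in `condition_a`. Positive values mean the
#' locus is farther from the compartment in `condition_b`. Genes missing
#' from either condition are excluded with a logged reason. Conditions with
#' fewer nuclei than `min_nuclei` (default 47, the study's per-condition
#' benchmark) trigger a warning but are still analyzed.
#'
#' @param norm_table data.frame with columns `gene_id`, `nucleus_id`,
#'   `condition` and `value` (a normalized distance in `[0, 1]`).
#' @param condition_a,condition_b condition labels (change is b minus a).
#' @param min_nuclei warning threshold on nuclei per condition.
#' @return data.frame `gene_id`, `delta` (in `[-1, 1]`), `n_a`, `n_b`.
#' @export
delta_position <- function(norm_table, condition_a, condition_b,
                           min_nuclei = 47L) {
  need <- c("gene_id", "nucleus_id", "condition", "value")
  if (!all(need %in% names(norm_table)))
    stopf("`norm_table` needs columns %s", paste(need, collapse = ", "))
  for (cond in c(condition_a, condition_b)) {
    sub <- norm_table[norm_table$condition == cond, ]
    if (!nrow(sub)) stopf("condition '%s' absent from `norm_table`", cond)
    n_nuc <- length(unique(sub$nucleus_id))
    if (n_nuc < min_nuclei)
      warnf("condition '%s' has %d nuclei (below the %d-nuclei benchmark)",
            cond, n_nuc, min_nuclei)
  }
  # per-nucleus mean first, then mean over nuclei within a condition
  agg <- stats::aggregate(value ~ gene_id + nucleus_id + condition,
                          data = norm_table, FUN = mean)
  mean_of <- function(cond) {
    sub <- agg[agg$condition == cond, ]
    stats::aggregate(value ~ gene_id, data = sub,
                     FUN = mean) -> m
    stats::setNames(m$value, m$gene_id)
  }
  counts_of <- function(cond) {
    sub <- agg[agg$condition == cond, ]
    table(sub$gene_id)
  }
  ma <- mean_of(condition_a); mb <- mean_of(condition_b)
  genes <- sort(union(names(ma), names(mb)))
  common <- intersect(names(ma), names(mb))
  dropped <- setdiff(genes, common)
  if (length(dropped))
    msgf("excluding %d gene(s) missing from one condition: %s",
         length(dropped), paste(head(dropped, 5), collapse = ", "))
  ca <- counts_of(condition_a); cb <- counts_of(condition_b)
  data.frame(gene_id = common,
             delta = unname(mb[common] - ma[common]),
             n_a = as.integer(ca[common]), n_b = as.integer(cb[common]),
             stringsAsFactors = FALSE)
}
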