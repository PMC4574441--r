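#' Configuration for the synthetic-data generator
#'
#' One validated container for every tunable of the in-silico study. The
#' defaults are the study conditions the analysis assumes: a confocal voxel
#' grid of 0.08 x 0.08 x 0.2 um, 10,000 background points per nucleus, four
#' conditions (myoblast MB, myotube MT, low and high ectopic MeCP2) with
#' five replicate arrays each, and flat-ellipsoid adherent-cell nuclei
#' (default semi-axes 5 x 5 x 2.5 um).
#'
#' Chromocenter morphology presets mirror the two cell states: `"MB"`
#' (myoblast-like, many small chromocenters) and `"MT"` (myotube-like, few
#' large ones, as after differentiation or high ectopic MeCP2).
#'
#' @param rng_seed integer root seed; every artifact is byte-identical for a
#'   fixed seed.
#' @param n_nuclei nuclei per condition.
#' @param nucleus_semiaxes ellipsoid semi-axes in um (x, y, z).
#' @param voxel_size physical voxel size in um.
#' @param chromocenter_count_range integer pair, inclusive range of
#'   chromocenter counts per nucleus (overridden by `preset`).
#' @param chromocenter_radius_range um pair of chromocenter radii.
#' @param preset `"MB"`, `"MT"` or `NULL` (use the explicit ranges).
#' @param locus_bias distribution of target normalized periphery distance for
#'   placed loci: `list(type = "uniform")` or `list(type = "beta", a=, b=)`.
#' @param loci_per_nucleus loci placed per nucleus in null simulations.
#' @param n_genes,n_probes_per_gene expression layout.
#' @param conditions condition labels; the first two form the differentiation
#'   pair, the last two the ectopic-MeCP2 pair.
#' @param replicates_per_condition replicate arrays per condition (>= 2).
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param planted_log2fc named numeric vector (gene -> log2 fold change)
#'   applied to the second condition versus the first; `NULL` for none.
#' @param outlier_rate fraction of probe x condition cells receiving one
#'   aberrant replicate.
#' @param outlier_sd_mult magnitude of planted outliers in noise-SD units
#'   (>= 5 by contract). The default of 40 emulates gross scanner or
#'   hybridization artifacts: with five replicates the Nalimov statistic is
#'   bounded by `sqrt(n - 1) = 2` while its p = 0.001 critical value is
#'   1.982, so only gross aberrations are reliably detectable.
#' @param genome_length synthetic genome length in bp.
#' @param planted_rho correlation in `[-1, 1]` between planted position
#'   change and log2 fold change (`NA` to disable).
#' @param n_background background points per nucleus (default 10000).
#' @param noise_sd_image additive Gaussian image noise (intensity units).
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(rng_seed = 1L,
                             n_nuclei = 50L,
                             nucleus_semiaxes = c(5, 5, 2.5),
                             voxel_size = c(0.08, 0.08, 0.2),
                             chromocenter_count_range = c(12L, 18L),
                             chromocenter_radius_range = c(0.4, 0.6),
                             preset = NULL,
                             locus_bias = list(type = "uniform"),
                             loci_per_nucleus = 80L,
                             n_genes = 200L,
                             n_probes_per_gene = 2L,
                             conditions = c("MB", "MT", "low", "high"),
                             replicates_per_condition = 5L,
                             noise_sd = 0.1,
                             planted_log2fc = NULL,
                             outlier_rate = 0,
                             outlier_sd_mult = 40,
                             genome_length = 8e6,
                             planted_rho = NA_real_,
                             n_background = 10000L,
                             noise_sd_image = 0.05) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("MB", "MT"))
    # chromocenter radii scale with the smallest semi-axis so presets stay
    # feasible for any nucleus size (defaults: MB 0.4-0.6 um, MT 0.8-1.2 um)
    smin <- min(nucleus_semiaxes)
    if (preset == "MB") {
      chromocenter_count_range <- c(10L, 15L)
      chromocenter_radius_range <- c(0.13, 0.19) * smin
    } else {
      chromocenter_count_range <- c(4L, 8L)
      chromocenter_radius_range <- c(0.26, 0.38) * smin
    }
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("voxel sizes must be three strictly positive numbers")
  if (length(nucleus_semiaxes) != 3L || any(nucleus_semiaxes <= 0))
    stopf("nucleus semi-axes must be three strictly positive numbers")
  if (replicates_per_condition < 2L)
    stopf("replicates_per_condition must be >= 2 (variance undefined below)")
  if (!is.na(planted_rho) && abs(planted_rho) > 1)
    stopf("planted_rho must lie in [-1, 1]")
  if (chromocenter_count_range[1] > chromocenter_count_range[2] ||
      chromocenter_count_range[1] < 0)
    stopf("invalid chromocenter count range")
  if (outlier_rate < 0 || outlier_rate > 1)
    stopf("outlier_rate must be a fraction in [0, 1]")
  if (!locus_bias$type %in% c("uniform", "beta"))
    stopf("locus_bias$type must be 'uniform' or 'beta'")
  structure(list(
    rng_seed = as.integer(rng_seed), n_nuclei = as.integer(n_nuclei),
    nucleus_semiaxes = as.numeric(nucleus_semiaxes),
    voxel_size = voxel_size,
    chromocenter_count_range = as.integer(chromocenter_count_range),
    chromocenter_radius_range = as.numeric(chromocenter_radius_range),
    locus_bias = locus_bias, loci_per_nucleus = as.integer(loci_per_nucleus),
    n_genes = as.integer(n_genes),
    n_probes_per_gene = as.integer(n_probes_per_gene),
    conditions = conditions,
    replicates_per_condition = as.integer(replicates_per_condition),
    noise_sd = noise_sd, planted_log2fc = planted_log2fc,
    outlier_rate = outlier_rate, outlier_sd_mult = outlier_sd_mult,
    genome_length = as.numeric(genome_length), planted_rho = planted_rho,
    n_background = as.integer(n_background),
    noise_sd_image = noise_sd_image), class = "synthetic_config")
}

# rasterize one synthetic nucleus: ellipsoid mask + chromocenter spheres
build_nucleus <- function(semiaxes, voxel_size, cc_count_range,
                          cc_radius_range, nucleus_id, pad_vox = 2L,
                          max_tries = 500L) {
  dims <- ceiling(2 * semiaxes / voxel_size) + 2L * pad_vox
  ctr <- dims / 2 * voxel_size
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 0.5) * voxel_size[a] -
                                   ctr[a]) / semiaxes[a])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  mask <- array(q <= 1, dims)

  n_cc <- if (cc_count_range[2] == 0L) 0L else
    sample(seq(cc_count_range[1], cc_count_range[2]), 1L)
  cc_tab <- NULL
  cc_lab <- array(0L, dims)
  if (n_cc > 0L) {
    # spheres keep a voxel-scale gap so rasterized chromocenters stay
    # separable after smoothing-based segmentation
    gap <- 1.5 * max(voxel_size)
    placed <- FALSE
    for (attempt in 1:3) { # re-draw radii if a packing dead-ends
      centers <- matrix(NA_real_, n_cc, 3)
      radii <- runif(n_cc, cc_radius_range[1], cc_radius_range[2])
      if (max(radii) >= min(semiaxes))
        stopf("chromocenter radius exceeds the smallest nuclear semi-axis")
      all_ok <- TRUE
      for (i in seq_len(n_cc)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          u <- runif(3, -1, 1) * (semiaxes - radii[i])
          if (sum((u / (semiaxes - radii[i]))^2) > 1) next
          if (i > 1L) {
            dd <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                  matrix(u, i - 1L, 3, byrow = TRUE))^2))
            if (any(dd <= radii[seq_len(i - 1L)] + radii[i] + gap)) next
          }
          centers[i, ] <- u
          ok <- TRUE
          break
        }
        if (!ok) { all_ok <- FALSE; break }
      }
      if (all_ok) { placed <- TRUE; break }
    }
    if (!placed)
      stopf("chromocenter placement infeasible for nucleus '%s' after %d tries",
            nucleus_id, max_tries)
    xs <- (seq_len(dims[1]) - 0.5) * voxel_size[1] - ctr[1]
    ys <- (seq_len(dims[2]) - 0.5) * voxel_size[2] - ctr[2]
    zs <- (seq_len(dims[3]) - 0.5) * voxel_size[3] - ctr[3]
    for (i in seq_len(n_cc)) {
      ix <- which(abs(xs - centers[i, 1]) <= radii[i])
      iy <- which(abs(ys - centers[i, 2]) <= radii[i])
      iz <- which(abs(zs - centers[i, 3]) <= radii[i])
      if (!length(ix) || !length(iy) || !length(iz)) next
      sub <- outer(outer((xs[ix] - centers[i, 1])^2,
                         (ys[iy] - centers[i, 2])^2, "+"),
                   (zs[iz] - centers[i, 3])^2, "+") <= radii[i]^2
      block <- cc_lab[ix, iy, iz]
      block[sub] <- i
      cc_lab[ix, iy, iz] <- block
    }
    cc_lab[!mask] <- 0L
    cc_tab <- data.frame(nucleus_id = nucleus_id, cc = seq_len(n_cc),
                         x_um = centers[, 1] + ctr[1],
                         y_um = centers[, 2] + ctr[2],
                         z_um = centers[, 3] + ctr[3], radius_um = radii)
  }
  list(nucleus = nucleus_model(mask, voxel_size, cc_lab, nucleus_id,
                               validate = FALSE),
       center_um = ctr, semiaxes = semiaxes, chromocenters = cc_tab)
}

#' Generate synthetic nuclei with chromocenters
#'
#' Builds ellipsoidal nuclear masks on the anisotropic voxel grid with
#' spherical chromocenters placed fully inside the nucleus and pairwise
#' disjoint (bounded retries; an error names the offending nucleus).
#' Optionally renders DAPI-like intensity stacks (bright chromocenters on a
#' dimmer nucleoplasm, additive Gaussian noise) for exercising segmentation.
#' Per-nucleus semi-axes are jittered by +/-10% to emulate morphological
#' variability between cells -- the variability the background normalization
#' is designed to absorb.
#'
#' @param config a [synthetic_config()].
#' @param n number of nuclei (default `config$n_nuclei`).
#' @param render also return intensity stacks.
#' @param rng_seed seed (default `config$rng_seed`).
#' @param id_prefix prefix for nucleus ids.
#' @return list with `nuclei` (list of [nucleus_model()]), `stacks` (list of
#'   arrays or `NULL`), and ground truth `truth` (`nuclei` and
#'   `chromocenters` data.frames).
#' @export
generate_nuclei <- function(config, n = config$n_nuclei, render = FALSE,
                            rng_seed = config$rng_seed,
                            id_prefix = "nuc") {
  with_seed(rng_seed, {
    nuclei <- vector("list", n)
    stacks <- if (render) vector("list", n) else NULL
    truth_n <- vector("list", n)
    truth_cc <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", id_prefix, i)
      semi <- config$nucleus_semiaxes * runif(3, 0.9, 1.1)
      built <- build_nucleus(semi, config$voxel_size,
                             config$chromocenter_count_range,
                             config$chromocenter_radius_range, id)
      nuclei[[i]] <- built$nucleus
      truth_n[[i]] <- data.frame(nucleus_id = id, semi_x = semi[1],
                                 semi_y = semi[2], semi_z = semi[3],
                                 n_chromocenters =
                                   if (is.null(built$chromocenters)) 0L
                                   else nrow(built$chromocenters))
      truth_cc[[i]] <- built$chromocenters
      if (render) {
        img <- 0.12 + 0.38 * built$nucleus$mask +
          0.40 * (built$nucleus$chromocenters > 0L)
        if (config$noise_sd_image > 0)
          img <- img + array(rnorm(length(img), 0, config$noise_sd_image),
                             dim(img))
        stacks[[i]] <- array(pmin(pmax(img, 0), 1), dim(built$nucleus$mask))
      }
    }
    list(nuclei = nuclei, stacks = stacks,
         truth = list(nuclei = do.call(rbind, truth_n),
                      chromocenters = if (all(vapply(truth_cc, is.null,
                                                     logical(1)))) NULL
                                      else do.call(rbind, truth_cc)))
  })
}

#' Place synthetic FISH loci inside a nucleus
#'
#' Under `bias = list(type = "uniform")`, loci are uniform over the in-mask
#' physical volume (uniform voxel choice plus in-voxel jitter), the same
#' scheme used for background points, so normalized distances of such loci
#' are uniform on `[0, 1]` by the probability integral transform. Under a
#' beta bias, each locus targets the background quantile drawn from
#' `Beta(a, b)` of the periphery-distance distribution via inverse-ECDF
#' lookup against the nucleus's own background sample (self-consistent with
#' the normalization stage). `type = "quantile"` targets explicit quantiles
#' in `q` and is the hook used to plant positional shifts.
#'
#' @param nucleus a [nucleus_model()].
#' @param n number of loci (must be positive).
#' @param bias `list(type = "uniform")`, `list(type = "beta", a=, b=)` or
#'   `list(type = "quantile", q = <numeric>, compartment = "periphery")`.
#' @param rng_seed seed.
#' @param background a `background_distribution` sampled with
#'   `keep_points = TRUE` (required for beta/quantile bias).
#' @param gene_id,condition optional annotation columns.
#' @return data.frame `locus_id`, `gene_id`, `nucleus_id`, `condition`,
#'   `x_um`, `y_um`, `z_um`.
#' @export
place_loci <- function(nucleus, n, bias = list(type = "uniform"),
                       rng_seed = NULL, background = NULL,
                       gene_id = NA_character_, condition = NA_character_) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stopf("`n` must be a positive count")
  n <- as.integer(n)
  pts <- with_seed(rng_seed, {
    if (bias$type == "uniform") {
      sample_in_mask(nucleus, n)
    } else {
      if (is.null(background) || is.null(background$points))
        stopf("beta/quantile bias needs a background sampled with keep_points = TRUE")
      q <- if (bias$type == "beta") rbeta(n, bias$a, bias$b) else {
        if (length(bias$q) == 1L) rep(bias$q, n) else bias$q
      }
      if (length(q) != n) stopf("quantile vector length must equal `n`")
      comp <- bias$compartment %||% "periphery"
      draw <- if (comp == "periphery") background$d_periphery_raw
              else background$d_chromocenter_raw
      if (is.null(draw)) stopf("background has no %s distances", comp)
      ord <- order(draw)
      j <- pmin(pmax(ceiling(q * length(ord)), 1L), length(ord))
      background$points[ord[j], , drop = FALSE]
    }
  })
  data.frame(locus_id = sprintf("%s_locus_%04d", nucleus$nucleus_id,
                                seq_len(n)),
             gene_id = gene_id, nucleus_id = nucleus$nucleus_id,
             condition = condition,
             x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
             stringsAsFactors = FALSE)
}
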