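# In-code fixtures and independent oracles shared across test files.

# rasterize an ellipsoid nucleus without RNG (deterministic geometry)
fixture_ellipsoid <- function(semiaxes, voxel_size, pad_vox = 2L,
                              id = "fix") {
  dims <- as.integer(ceiling(2 * semiaxes / voxel_size) + 2L * pad_vox)
  ctr <- dims / 2 * voxel_size
  ax <- lapply(1:3, function(a)
    ((seq_len(dims[a]) - 0.5) * voxel_size[a] - ctr[a]) / semiaxes[a])
  mask <- array(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+") <= 1,
                dims)
  list(nucleus = nucleus_model(mask, voxel_size, nucleus_id = id,
                               validate = FALSE),
       center_um = ctr, dims = dims)
}

# add a spherical chromocenter (center in um relative to nucleus center)
fixture_add_chromocenter <- function(fix, center, radius, label = 1L) {
  nuc <- fix$nucleus
  d <- dim(nuc$mask)
  vs <- nuc$voxel_size
  xs <- (seq_len(d[1]) - 0.5) * vs[1] - fix$center_um[1]
  ys <- (seq_len(d[2]) - 0.5) * vs[2] - fix$center_um[2]
  zs <- (seq_len(d[3]) - 0.5) * vs[3] - fix$center_um[3]
  sph <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
               (zs - center[3])^2, "+") <= radius^2
  cc <- nuc$chromocenters
  cc[sph & nuc$mask] <- label
  nuc$chromocenters <- cc
  fix$nucleus <- nuc
  fix
}

# exhaustive centre-to-centre nearest-site oracle for the distance transform
brute_force_edt <- function(sites, voxel_size) {
  dims <- dim(sites)
  lin <- which(sites)
  stopifnot(length(lin) > 0)
  co <- cbind((lin - 1) %% dims[1],
              ((lin - 1) %/% dims[1]) %% dims[2],
              (lin - 1) %/% (dims[1] * dims[2])) + 0.5
  co <- sweep(co, 2, voxel_size, "*")
  out <- array(NA_real_, dims)
  for (i in seq_len(prod(dims))) {
    p <- c((i - 1) %% dims[1], ((i - 1) %/% dims[1]) %% dims[2],
           (i - 1) %/% (dims[1] * dims[2])) + 0.5
    p <- p * voxel_size
    out[i] <- sqrt(min(colSums((t(co) - p)^2)))
  }
  out
}

# double-loop product-moment correlation oracle
brute_force_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# naive character-by-character CpG-island oracle: every 500-bp window is
# re-evaluated from scratch, qualifying windows merged, merged regions
# re-tested and symmetrically trimmed -- no shared code with the caller
brute_force_cpg <- function(seq_str, min_length = 500L, min_gc = 0.5,
                            min_obs_exp = 0.6) {
  chars <- strsplit(toupper(seq_str), "")[[1]]
  L <- length(chars)
  qualifies <- function(s0, s1) { # 0-based half-open
    sub <- chars[(s0 + 1):s1]
    if (any(!sub %in% c("A", "C", "G", "T"))) return(FALSE)
    nc <- sum(sub == "C"); ng <- sum(sub == "G")
    len <- s1 - s0
    if ((nc + ng) / len < min_gc) return(FALSE)
    if (nc == 0 || ng == 0) return(FALSE)
    ncpg <- sum(sub[-len] == "C" & sub[-1] == "G")
    ncpg * len / (nc * ng) >= min_obs_exp
  }
  if (L < min_length) return(data.frame(start = integer(), end = integer()))
  ok <- vapply(0:(L - min_length), function(s)
    qualifies(s, s + min_length), logical(1))
  if (!any(ok)) return(data.frame(start = integer(), end = integer()))
  qs <- (0:(L - min_length))[ok]
  grp <- cumsum(c(1L, diff(qs) > min_length))
  out <- list()
  for (g in unique(grp)) {
    s0 <- min(qs[grp == g]); s1 <- max(qs[grp == g]) + min_length
    while (s1 - s0 >= min_length && !qualifies(s0, s1)) {
      s0 <- s0 + 1L; s1 <- s1 - 1L
    }
    if (s1 - s0 >= min_length)
      out[[length(out) + 1L]] <- data.frame(start = s0, end = s1)
  }
  do.call(rbind, out)
}

# CpG-suppressed background + optional planted CpG-rich core, for caller
# vs oracle comparisons (no dependence on the package generator)
fixture_cpg_sequence <- function(n_bg, core_len = 0L, core_at = NULL,
                                 seed = 1L) {
  set.seed(seed)
  bg <- sample(c("A", "T", "G", "C"), n_bg, replace = TRUE,
               prob = c(0.35, 0.35, 0.15, 0.15))
  cpg <- which(bg[-n_bg] == "C" & bg[-1] == "G")
  if (length(cpg)) bg[cpg + 1L] <- "T"
  if (core_len > 0L) {
    core <- unlist(lapply(seq_len(core_len), function(i)
      if (runif(1) < 0.35) "CG" else
        sample(c("A", "C", "G", "T"), 1, prob = c(0.2, 0.3, 0.3, 0.2))))
    core <- substr(paste(core, collapse = ""), 1, core_len)
    bg[(core_at + 1):(core_at + core_len)] <- strsplit(core, "")[[1]]
  }
  paste(bg, collapse = "")
}

small_null_config <- function(seed = 1L, ...) {
  synthetic_config(rng_seed = seed, n_nuclei = 6L, loci_per_nucleus = 30L,
                   nucleus_semiaxes = c(3, 3, 1.8),
                   voxel_size = c(0.12, 0.12, 0.3), n_background = 2000L,
                   chromocenter_count_range = c(4L, 7L),
                   chromocenter_radius_range = c(0.25, 0.4), ...)
}
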