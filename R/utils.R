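`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-stage seed expansion from one root seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 99991 * as.numeric(k)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf <- function(fmt, ...) message(sprintf(fmt, ...))

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# 0-based half-open data.frame (chrom, start, end) -> GRanges (1-based closed)
df_to_gr <- function(df, seq_lengths = NULL) {
  bad <- which(df$start >= df$end)
  if (length(bad))
    stopf("malformed interval on line %d: start (%d) >= end (%d)",
          bad[1], df$start[bad[1]], df$end[bad[1]])
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  if (!is.null(seq_lengths))
    GenomicRanges::seqlengths(gr) <- seq_lengths[GenomicRanges::seqlevels(gr)]
  gr
}

gr_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}
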