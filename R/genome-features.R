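# sequence helpers ----------------------------------------------------------

# normalize a DNAString/DNAStringSet/character to one uppercase character
# string for windowed counting
as_seq_string <- function(x, chrom = NULL) {
  if (inherits(x, "DNAStringSet")) {
    if (is.null(chrom)) {
      if (length(x) != 1L) stopf("`chrom` required for a multi-record genome")
      chrom <- names(x)[1] %||% 1L
    }
    x <- x[[chrom]]
  }
  toupper(as.character(x))
}

seq_indicators <- function(s) {
  r <- charToRaw(s)
  list(C = r == charToRaw("C"), G = r == charToRaw("G"),
       A = r == charToRaw("A"), T = r == charToRaw("T"),
       N = !(r %in% charToRaw("ACGT")))
}

#' GC content of a sequence
#'
#' Fraction `(G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator. A window with zero non-N bases yields `NA` (missing) with a
#' logged note.
#'
#' @param x DNAString, DNAStringSet (with `chrom`) or character sequence.
#' @param chrom record name when `x` is a multi-record genome.
#' @return fraction in `[0, 1]` or `NA`.
#' @export
gc_content <- function(x, chrom = NULL) {
  ind <- seq_indicators(as_seq_string(x, chrom))
  denom <- sum(!ind$N)
  if (denom == 0L) {
    msgf("gc_content: no non-N bases in window; reporting missing")
    return(NA_real_)
  }
  (sum(ind$C) + sum(ind$G)) / denom
}

#' Call CpG islands with a sliding-window scan
#'
#' A CpG island is a region of at least 500 bp with GC content >= 50% and an
#' observed/expected CpG ratio >= 0.60, the observed/expected ratio being
#' the Gardiner-Garden & Frommer form `N_CpG * L / (N_C * N_G)`. The caller
#' slides a 500-bp window one base at a time, marks qualifying windows
#' (windows containing `N` never qualify), merges overlapping or adjacent
#' qualifying windows, then re-tests each merged region, trimming one base
#' from both ends until the whole region qualifies or its length drops
#' below 500 bp (then it is discarded).
#'
#' @param x DNAString/DNAStringSet/character sequence.
#' @param chrom record name for multi-record input; also used to label
#'   output rows.
#' @param min_length,min_gc,min_obs_exp the three thresholds (defaults 500,
#'   0.5, 0.6).
#' @return data.frame with 0-based half-open `start`, `end`, plus `length`,
#'   `gc_fraction`, `obs_exp` (empty for sequences shorter than
#'   `min_length`).
#' @export
call_cpg_islands <- function(x, chrom = NULL, min_length = 500L,
                             min_gc = 0.5, min_obs_exp = 0.6) {
  s <- as_seq_string(x, chrom)
  L <- nchar(s)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      gc_fraction = numeric(), obs_exp = numeric())
  if (L < min_length) return(empty)
  ind <- seq_indicators(s)
  cC <- c(0, cumsum(ind$C)); cG <- c(0, cumsum(ind$G))
  cN <- c(0, cumsum(ind$N))
  cpg <- ind$C[-L] & ind$G[-1]
  # cCpG[k + 1] = number of CpG dinucleotides starting at 1-based pos <= k
  cCpG <- c(0, cumsum(cpg))
  w <- min_length
  region_stats <- function(s0, s1) { # 0-based half-open [s0, s1)
    len <- s1 - s0
    nc <- cC[s1 + 1L] - cC[s0 + 1L]
    ng <- cG[s1 + 1L] - cG[s0 + 1L]
    nn <- cN[s1 + 1L] - cN[s0 + 1L]
    ncpg <- if (s1 - 1L >= s0) cCpG[s1] - cCpG[s0 + 1L] + 0 else 0
    gc <- (nc + ng) / max(len - nn, 1L)
    oe <- if (nc > 0 && ng > 0) ncpg * len / (nc * ng) else 0
    list(len = len, gc = gc, oe = oe, nn = nn)
  }
  starts <- 0:(L - w)
  nc <- cC[starts + w + 1L] - cC[starts + 1L]
  ng <- cG[starts + w + 1L] - cG[starts + 1L]
  nn <- cN[starts + w + 1L] - cN[starts + 1L]
  ncpg <- cCpG[starts + w] - cCpG[starts + 1L]
  gc <- (nc + ng) / w
  oe <- ifelse(nc > 0 & ng > 0, ncpg * w / (nc * ng), 0)
  ok <- nn == 0L & gc >= min_gc & oe >= min_obs_exp
  if (!any(ok)) return(empty)
  qs <- starts[ok]
  grp <- cumsum(c(1L, diff(qs) > w))
  out <- list()
  for (g in unique(grp)) {
    s0 <- min(qs[grp == g]); s1 <- max(qs[grp == g]) + w
    repeat {
      st <- region_stats(s0, s1)
      if (st$len < min_length) { s0 <- NA; break }
      if (st$nn == 0L && st$gc >= min_gc && st$oe >= min_obs_exp) break
      s0 <- s0 + 1L; s1 <- s1 - 1L
    }
    if (is.na(s0)) next
    st <- region_stats(s0, s1)
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom %||% NA_character_, start = s0, end = s1,
      length = st$len, gc_fraction = st$gc, obs_exp = st$oe,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# interval operations --------------------------------------------------------

#' Fraction of a window covered by intervals
#'
#' Computes the merged-union overlap length of the supplied intervals with
#' the window, divided by the window length. Splitting any interval into
#' abutting pieces does not change the result. Malformed intervals
#' (`start >= end`) raise a parse error naming the offending line.
#'
#' @param window list/data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param intervals data.frame of intervals in the same convention.
#' @return fraction in `[0, 1]`.
#' @export
interval_coverage <- function(window, intervals) {
  wlen <- window$end - window$start
  if (wlen <= 0) stopf("window has nonpositive length")
  if (!nrow(intervals)) return(0)
  gr <- GenomicRanges::reduce(df_to_gr(intervals))
  win <- df_to_gr(data.frame(chrom = window$chrom, start = window$start,
                             end = window$end))
  ov <- GenomicRanges::intersect(gr, win)
  sum(GenomicRanges::width(ov)) / wlen
}

#' Count genes overlapping a window
#'
#' A gene counts when it overlaps the window by at least 1 bp in half-open
#' coordinates; a gene touching the window edge exactly at the boundary
#' does not count.
#'
#' @param window as in [interval_coverage()].
#' @param genes data.frame of gene spans (`chrom`, `start`, `end`).
#' @return integer count.
#' @export
count_genes <- function(window, genes) {
  if (!nrow(genes)) return(0L)
  win <- df_to_gr(data.frame(chrom = window$chrom, start = window$start,
                             end = window$end))
  sum(GenomicRanges::countOverlaps(df_to_gr(genes), win) > 0L)
}

#' Assemble RIDGE/anti-RIDGE features for a gene-centred window
#'
#' Windows of total width `2 * half_width` are anchored at the midpoint of
#' the center gene's span (rounded down) and truncated at chromosome edges
#' with a logged note. Features: gene count, CpG-island count (either called
#' from the window sequence or counted from a supplied island table --
#' mirroring workflows that take islands from a browser track), GC fraction,
#' and SINE/LINE coverage fractions.
#'
#' @param center_gene gene id present in `genes`.
#' @param half_width half-window in bp (1e6 or 2.5e6 for the 2-/5-Mbp
#'   scales).
#' @param genome DNAStringSet (or DNAString/character for a single
#'   chromosome).
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param repeats data.frame `chrom`, `start`, `end`, `class` with classes
#'   `"SINE"`/`"LINE"`.
#' @param cpg_islands optional island table (`chrom`, `start`, `end`); when
#'   supplied, islands are counted by overlap instead of being called from
#'   sequence.
#' @return one-row data.frame: window coordinates plus `n_genes`,
#'   `n_cpg_islands`, `gc_fraction`, `sine_coverage`, `line_coverage`.
#' @export
window_features <- function(center_gene, half_width, genome, genes, repeats,
                            cpg_islands = NULL) {
  row <- genes[genes$gene_id == center_gene, , drop = FALSE]
  if (!nrow(row)) stopf("center gene '%s' absent from the gene annotation",
                        center_gene)
  row <- row[1, ]
  seq_str <- as_seq_string(genome, row$chrom)
  chrom_len <- nchar(seq_str)
  center <- floor((row$start + row$end) / 2)
  w0 <- center - half_width; w1 <- center + half_width
  if (w0 < 0 || w1 > chrom_len) {
    w0 <- max(w0, 0); w1 <- min(w1, chrom_len)
    msgf("window around '%s' truncated at chromosome edge", center_gene)
  }
  win <- data.frame(chrom = row$chrom, start = w0, end = w1)
  win_seq <- substr(seq_str, w0 + 1L, w1)
  n_cpg <- if (is.null(cpg_islands)) {
    nrow(call_cpg_islands(win_seq))
  } else {
    count_genes(win, cpg_islands) # >=1 bp overlap count, same rule as genes
  }
  sine <- repeats[repeats$class == "SINE", , drop = FALSE]
  line <- repeats[repeats$class == "LINE", , drop = FALSE]
  data.frame(gene_id = center_gene, chrom = row$chrom, start = w0, end = w1,
             width = w1 - w0,
             n_genes = count_genes(win, genes),
             n_cpg_islands = n_cpg,
             gc_fraction = suppressMessages(gc_content(win_seq)),
             sine_coverage = interval_coverage(win, sine),
             line_coverage = interval_coverage(win, line),
             stringsAsFactors = FALSE)
}
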