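# Anchor-centered meta-profiles and window statistics.  The meta-profile is
# the average normalized count at each offset relative to a set of anchors
# (TSSs, TTSs, CpG-island centers), with minus-strand anchors flipped so
# that negative offsets are always 5' of the anchor.

#' Anchor sets from gene models and CpG islands
#'
#' Build width-1 anchor `GRanges` for profile aggregation.  TSS/TTS anchors
#' carry the gene strand (profiles are strand-oriented); CpG-center anchors
#' are unstranded.
#'
#' @param gm A `GeneModels` object.
#' @return Stranded width-1 `GRanges` named by gene id.
#' @export
tss_anchors <- function(gm) {
  g <- gm$genes
  GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                         IRanges::IRanges(S4Vectors::mcols(g)$tss, width = 1L),
                         strand = GenomicRanges::strand(g),
                         seqinfo = GenomeInfoDb::seqinfo(g))
}

#' @rdname tss_anchors
#' @export
tts_anchors <- function(gm) {
  g <- gm$genes
  GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                         IRanges::IRanges(S4Vectors::mcols(g)$tts, width = 1L),
                         strand = GenomicRanges::strand(g),
                         seqinfo = GenomeInfoDb::seqinfo(g))
}

#' @rdname tss_anchors
#' @param cpg CpG-island `GRanges` as returned by [read_cpg_islands()].
#' @export
cpg_anchors <- function(cpg) {
  centers <- S4Vectors::mcols(cpg)$center
  if (is.null(centers)) centers <- cpg_centers(cpg)
  GenomicRanges::GRanges(GenomicRanges::seqnames(cpg),
                         IRanges::IRanges(centers, width = 1L),
                         strand = "*",
                         seqinfo = GenomeInfoDb::seqinfo(cpg))
}

#' Average profile around a set of anchors
#'
#' For offsets `d` in `-half_window .. half_window - 1`, the profile value is
#' the mean over anchors of `track[anchor + d]`, with `d` sign-flipped for
#' minus-strand anchors so negative offsets always lie 5' of the anchor.
#' Windows truncated at chromosome edges contribute zeros for the
#' out-of-range offsets (the divisor stays the anchor count at every
#' offset); the number of truncated anchors is recorded.
#'
#' @param track A `CoverageTrack` (normally normalized).
#' @param anchors Width-1 `GRanges`; strand `*` is treated as `+`.
#' @param half_window Half window size W in bp (default 3000); the profile
#'   has `2 * W` offsets.
#' @return `data.frame(offset, value)` with attributes `n_anchors` and
#'   `n_truncated`.
#' @export
meta_profile <- function(track, anchors, half_window = 3000L) {
  stopifnot(is_coverage_track(track))
  if (length(anchors) == 0L) stop("empty anchor set")
  if (half_window < 1L) stop("half_window must be >= 1")
  W <- as.integer(half_window)
  n <- 2L * W
  total <- numeric(n)
  truncated <- 0L
  chr <- as.character(GenomicRanges::seqnames(anchors))
  pos <- GenomicRanges::start(anchors)
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  for (i in seq_along(anchors)) {
    v <- track$cov[[chr[i]]]
    if (is.null(v)) stop("anchor on chromosome absent from track: ", chr[i])
    # plus: positions p-W .. p+W-1; minus: p-W+1 .. p+W reversed, so that
    # value[offset d] = track[p - d] on the minus strand
    s <- if (minus[i]) pos[i] - W + 1L else pos[i] - W
    if (s < 1L || s + n - 1L > length(v)) truncated <- truncated + 1L
    vals <- rle_window_padded(v, s, n)
    if (minus[i]) vals <- rev(vals)
    total <- total + vals
  }
  out <- data.frame(offset = seq.int(-W, W - 1L), value = total / length(anchors))
  attr(out, "n_anchors") <- length(anchors)
  attr(out, "n_truncated") <- truncated
  out
}

#' Two-sample t-test over CpG-island windows
#'
#' Per island, the mean normalized count over a window of `window` bp
#' centered on the island midpoint is computed in each track; the two
#' per-island vectors are compared with a two-sample t-test (Welch by
#' default, pooled-variance with `pooled = TRUE`).
#'
#' @param track_a,track_b `CoverageTrack`s on the same genome.
#' @param islands CpG-island `GRanges` (>= 2 islands).
#' @param window Window length in bp centered on the island midpoint
#'   (default 500).
#' @param pooled Use Student's pooled-variance test instead of Welch.
#' @return List of class `cpg_ttest`: `mean_a`, `mean_b`, `t_statistic`,
#'   `p_value`, `n_a`, `n_b`, `method`, and the per-island means.
#' @export
cpg_window_ttest <- function(track_a, track_b, islands, window = 500L,
                             pooled = FALSE) {
  stopifnot(is_coverage_track(track_a), is_coverage_track(track_b))
  if (length(islands) < 2L) stop("need >= 2 CpG islands for the t-test")
  centers <- S4Vectors::mcols(islands)$center
  if (is.null(centers)) centers <- cpg_centers(islands)
  half <- as.integer(window) %/% 2L
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(islands),
                                IRanges::IRanges(centers - half,
                                                 centers + (as.integer(window) - half) - 1L))
  a <- region_count(track_a, win) / as.integer(window)
  b <- region_count(track_b, win) / as.integer(window)
  tt <- stats::t.test(a, b, var.equal = pooled)
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_a = length(a), n_b = length(b),
                 method = if (pooled) "pooled" else "welch",
                 island_means_a = a, island_means_b = b),
            class = "cpg_ttest")
}

#' @export
print.cpg_ttest <- function(x, ...) {
  cat(sprintf("CpG-window t-test (%s): mean_a = %.4g, mean_b = %.4g, t = %.3f, p = %.3g (n = %d islands)\n",
              x$method, x$mean_a, x$mean_b, x$t_statistic, x$p_value, x$n_a))
  invisible(x)
}

#' Per-gene normalized counts in the TSS-vicinity window
#'
#' Sums track values over the strand-oriented window
#' `[TSS - upstream, TSS + downstream)` (mirrored on the minus strand),
#' the promoter-proximal region where H3K4me3 concentrates.
#'
#' @param track A `CoverageTrack`.
#' @param gm A `GeneModels` object.
#' @param upstream,downstream Window extent in bp (defaults 500 and 1000,
#'   i.e. the -0.5 kb to +1 kb TSS vicinity).
#' @return `data.frame(gene_id, count)`.
#' @export
tss_vicinity_counts <- function(track, gm, upstream = 500L, downstream = 1000L) {
  stopifnot(is_coverage_track(track))
  if (length(gm$genes) == 0L) stop("no genes")
  win <- suppressWarnings(
    GenomicRanges::promoters(gm$genes, upstream = as.integer(upstream),
                             downstream = as.integer(downstream)))
  data.frame(gene_id = names(gm$genes),
             count = region_count(track, win),
             row.names = NULL, stringsAsFactors = FALSE)
}
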