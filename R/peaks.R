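# Differential peak analysis: read peak calls, assign them to per-gene
# promoter/exon/gene-body categories, classify genes as gained/lost between
# the two samples, summarize peak overlap and widths, and a deterministic
# stand-in threshold caller so the pipeline is testable without an external
# peak caller.

#' Promoter/exon/gene-body region scheme
#'
#' The two promoter windows reported for peak distributions: the distal
#' window (-5 kb / +1 kb around the TSS) and the proximal window
#' (-250 / +250 bp).  The gain/loss classifier uses the distal window by
#' default (the more inclusive definition).
#'
#' @param promoter_upstream,promoter_downstream Distal promoter extent (bp).
#' @param proximal_upstream,proximal_downstream Proximal promoter extent (bp).
#' @return A list of class `RegionScheme`.
#' @export
region_scheme <- function(promoter_upstream = 5000L, promoter_downstream = 1000L,
                          proximal_upstream = 250L, proximal_downstream = 250L) {
  vals <- c(promoter_upstream, promoter_downstream,
            proximal_upstream, proximal_downstream)
  if (any(vals < 0)) stop("region scheme extents must be >= 0")
  structure(list(promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream),
                 proximal_upstream = as.integer(proximal_upstream),
                 proximal_downstream = as.integer(proximal_downstream)),
            class = "RegionScheme")
}

#' Read peak calls (broadPeak or BED)
#'
#' Nine-column files are parsed as ENCODE broadPeak (score taken from the
#' signalValue column 7); anything else as BED3+.  Peaks are validated
#' (width >= 1), clipped to chromosome bounds, sorted by position and
#' labelled with the sample of origin.
#'
#' @param path broadPeak or BED file.
#' @param sample_label Label stored in `mcols()$sample` (e.g. "control").
#' @param sizes Named vector of chromosome lengths.
#' @return Sorted unstranded `GRanges` with `sample` and optional `score`.
#' @export
read_peaks <- function(path, sample_label, sizes) {
  assert_chrom_sizes(sizes)
  con <- file(path, "r"); on.exit(close(con))
  first <- readLines(con, n = 50L)
  first <- first[!grepl("^(track|browser|#)", first) & nzchar(first)]
  if (length(first) == 0L) stop("no peaks in ", path)
  nfield <- length(strsplit(first[1], "\t")[[1]])
  gr <- if (nfield == 9L) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric", qValue = "numeric"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  if (length(gr) == 0L) stop("no peaks in ", path)
  if (any(GenomicRanges::width(gr) < 1L))
    stop("peak with end <= start in ", path)
  GenomicRanges::strand(gr) <- "*"
  score <- if (nfield == 9L) S4Vectors::mcols(gr)$signalValue
           else S4Vectors::mcols(gr)$score
  gr2 <- set_genome(GenomicRanges::granges(gr), sizes)
  gr2 <- IRanges::trim(gr2)
  S4Vectors::mcols(gr2)$score <- if (is.null(score)) NA_real_ else as.numeric(score)
  S4Vectors::mcols(gr2)$sample <- sample_label
  order_granges(gr2)
}

# Strand-oriented promoter windows for a gene set under a scheme.
promoter_windows <- function(gm, scheme, which = c("distal", "proximal")) {
  which <- match.arg(which)
  up <- if (which == "distal") scheme$promoter_upstream else scheme$proximal_upstream
  dn <- if (which == "distal") scheme$promoter_downstream else scheme$proximal_downstream
  suppressWarnings(GenomicRanges::promoters(gm$genes, upstream = up, downstream = dn))
}

#' Count peaks per gene in promoter, exon and gene-body categories
#'
#' A peak is counted for a category when it overlaps the category's interval
#' by at least 1 bp; one peak may count in several categories and for
#' several genes.  The promoter is the strand-oriented window of the scheme
#' (distal by default); the exon category counts peaks overlapping any exon;
#' the gene body is the full transcript interval.
#'
#' @param peaks Peak `GRanges`.
#' @param gm A `GeneModels` object.
#' @param scheme A [region_scheme()].
#' @param promoter Which promoter window to use, `"distal"` or `"proximal"`.
#' @return `data.frame(gene_id, promoter, exon, gene_body)` of peak counts.
#' @export
assign_peaks <- function(peaks, gm, scheme = region_scheme(),
                         promoter = c("distal", "proximal")) {
  promoter <- match.arg(promoter)
  prom <- promoter_windows(gm, scheme, promoter)
  data.frame(
    gene_id = names(gm$genes),
    promoter = GenomicRanges::countOverlaps(prom, peaks, ignore.strand = TRUE),
    exon = GenomicRanges::countOverlaps(gm$exons, peaks, ignore.strand = TRUE),
    gene_body = GenomicRanges::countOverlaps(gm$genes, peaks, ignore.strand = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes as gained / lost / unchanged between two samples
#'
#' A gene with no peak in any of promoter, exon or gene body in the control
#' but at least one peak in at least one category in the case sample is
#' "gained"; the reverse is "lost"; peaks in both samples (any category) is
#' "unchanged_present"; peaks in neither is "unchanged_absent".
#'
#' @param counts_control,counts_case Count tables from [assign_peaks()] over
#'   the same gene universe.
#' @return `data.frame(gene_id, status, ...)` with per-category evidence
#'   counts from both samples (`*_control`, `*_case` columns).
#' @export
classify_gain_loss <- function(counts_control, counts_case) {
  if (!setequal(counts_control$gene_id, counts_case$gene_id) ||
      nrow(counts_control) != nrow(counts_case))
    stop("gene universes of the two count tables differ")
  counts_case <- counts_case[match(counts_control$gene_id, counts_case$gene_id), ]
  cats <- c("promoter", "exon", "gene_body")
  any_control <- rowSums(counts_control[cats]) > 0
  any_case <- rowSums(counts_case[cats]) > 0
  status <- ifelse(!any_control & any_case, "gained",
            ifelse(any_control & !any_case, "lost",
            ifelse(any_control & any_case, "unchanged_present",
                   "unchanged_absent")))
  out <- data.frame(gene_id = counts_control$gene_id, status = status,
                    stringsAsFactors = FALSE)
  for (cat in cats) {
    out[[paste0(cat, "_control")]] <- counts_control[[cat]]
    out[[paste0(cat, "_case")]] <- counts_case[[cat]]
  }
  out
}

#' Overlap (Venn) and width summary for two peak sets
#'
#' A peak is "shared" when it overlaps at least one peak of the other sample
#' by >= 1 bp.  Sharing is counted per peak and per side, so the two shared
#' counts may differ (a control peak overlapping two case peaks is one
#' shared control peak).  Width statistics (mean, median) are reported for
#' shared and exclusive peaks of each side.
#'
#' @param peaks_control,peaks_case Non-empty peak `GRanges`.
#' @return List of class `PeakOverlapSummary`.
#' @export
overlap_summary <- function(peaks_control, peaks_case) {
  if (length(peaks_control) == 0L || length(peaks_case) == 0L)
    stop("both peak sets must be non-empty")
  shared_c <- GenomicRanges::countOverlaps(peaks_control, peaks_case,
                                           ignore.strand = TRUE) > 0
  shared_t <- GenomicRanges::countOverlaps(peaks_case, peaks_control,
                                           ignore.strand = TRUE) > 0
  wstats <- function(w) if (length(w)) c(mean = mean(w), median = stats::median(w))
                        else c(mean = NA_real_, median = NA_real_)
  structure(list(
    n_control = length(peaks_control),
    n_case = length(peaks_case),
    n_control_shared = sum(shared_c),
    n_case_shared = sum(shared_t),
    n_control_only = sum(!shared_c),
    n_case_only = sum(!shared_t),
    width_control_shared = wstats(GenomicRanges::width(peaks_control)[shared_c]),
    width_control_only = wstats(GenomicRanges::width(peaks_control)[!shared_c]),
    width_case_shared = wstats(GenomicRanges::width(peaks_case)[shared_t]),
    width_case_only = wstats(GenomicRanges::width(peaks_case)[!shared_t])),
    class = "PeakOverlapSummary")
}

#' @export
print.PeakOverlapSummary <- function(x, ...) {
  cat(sprintf("Peaks: control %d (%d shared, %d only), case %d (%d shared, %d only)\n",
              x$n_control, x$n_control_shared, x$n_control_only,
              x$n_case, x$n_case_shared, x$n_case_only))
  invisible(x)
}

#' Deterministic stand-in peak caller
#'
#' Calls maximal runs of positions whose normalized value is at least
#' `min_value`, merges runs separated by gaps of at most `merge_gap` bp, and
#' keeps merged runs at least `min_width` bp wide.  This is a simple
#' threshold caller for self-contained testing of the downstream
#' classification; it is not a re-implementation of a model-based broad-peak
#' caller, and real analyses should supply externally called peaks.
#'
#' @param track A normalized `CoverageTrack`.
#' @param min_value Minimum normalized value (fold over the genome mean of 1).
#' @param min_width Minimum merged peak width in bp.
#' @param merge_gap Maximum gap in bp across which runs are merged.
#' @param sample_label Label stored in `mcols()$sample`.
#' @return Sorted peak `GRanges`.
#' @export
standin_call_peaks <- function(track, min_value = 5, min_width = 100L,
                               merge_gap = 50L, sample_label = "sample") {
  stopifnot(is_coverage_track(track))
  if (!track$normalized) stop("stand-in caller needs a normalized track")
  res <- list()
  for (chrom in names(track$cov)) {
    ir <- IRanges::slice(track$cov[[chrom]], lower = min_value,
                         rangesOnly = TRUE)
    ir <- IRanges::reduce(ir, min.gapwidth = as.integer(merge_gap) + 1L)
    ir <- ir[IRanges::width(ir) >= min_width]
    if (length(ir))
      res[[chrom]] <- GenomicRanges::GRanges(chrom, ir)
  }
  if (length(res) == 0L) {
    out <- GenomicRanges::GRanges()
  } else {
    out <- suppressWarnings(do.call(c, unname(res)))
  }
  out <- set_genome(out, track$seqlengths)
  if (length(out)) S4Vectors::mcols(out)$sample <- sample_label
  order_granges(out)
}
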