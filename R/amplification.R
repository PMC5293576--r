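# Copy-number amplification from ChIP-seq read counts: duplicate-read
# removal, a five-criteria sliding-window scan, and an upper-tail Poisson
# significance score with the control count as lambda and the case count
# as k.

#' Remove duplicate reads
#'
#' At most one read is retained per (chrom, start, end, strand, sequence)
#' key.  When reads carry a sequence tag (the BED name column as written by
#' [simulate_chipseq()]), reads at identical coordinates with different
#' sequences are distinct molecules and are all kept; without sequence
#' information the key falls back to coordinates plus strand.
#'
#' @param reads Stranded `GRanges`, optionally with `mcols()$name` sequence
#'   tags.
#' @param use_sequence Include the sequence tag in the key when present.
#' @return Deduplicated `GRanges` with attribute `n_removed`.
#' @export
dedup_reads <- function(reads, use_sequence = TRUE) {
  if (length(reads) == 0L) {
    attr(reads, "n_removed") <- 0L
    return(reads)
  }
  key <- paste(as.character(GenomicRanges::seqnames(reads)),
               GenomicRanges::start(reads), GenomicRanges::end(reads),
               as.character(GenomicRanges::strand(reads)), sep = ":")
  seqs <- S4Vectors::mcols(reads)$name
  if (use_sequence && !is.null(seqs)) key <- paste(key, seqs, sep = ":")
  keep <- !duplicated(key)
  out <- reads[keep]
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message(sprintf("dedup_reads: removed %d duplicate read(s)", n_removed))
  attr(out, "n_removed") <- n_removed
  out
}

#' Upper-tail Poisson probability
#'
#' `P(X >= ceiling(k))` for `X ~ Poisson(lambda)` (inclusive tail, the
#' standard enrichment convention), computed with [stats::ppois()] in log
#' space internally for numerical stability.  For `lambda = 0` the tail is 1
#' when `k = 0` and 0 otherwise.
#'
#' @param lambda Non-negative expectation(s).
#' @param k Non-negative observed count(s); non-integers are ceiled.
#' @return Probability vector.
#' @export
poisson_upper_tail <- function(lambda, k) {
  if (any(lambda < 0) || any(k < 0)) stop("lambda and k must be >= 0")
  k2 <- ceiling(k)
  ifelse(k2 <= 0, 1, stats::ppois(k2 - 1, lambda, lower.tail = FALSE))
}

#' Parameters for the amplification scan
#'
#' The five reported criteria for an amplified region: (1) width strictly
#' greater than `min_width`; (2) region count at least
#' `fold_over_case_mean`-fold the case genome average; (3) at least
#' `fold_case_over_control`-fold the control count in the region; (4) at
#' least `fold_over_control_mean`-fold the control genome average; (5)
#' duplicate reads excluded upstream by sequence.  Candidates are delimited
#' by a sliding-window scan (`window`/`step`) with a two-threshold
#' (hysteresis) rule: windows enter candidacy when the fold criteria hold at
#' `candidate_frac` of their thresholds, candidate windows are merged across
#' gaps of at most `merge_gap` bp, and every criterion is then re-tested at
#' full strength on the merged region's aggregate counts.  The lower entry
#' bar keeps Poisson counting noise in single windows from truncating or
#' fragmenting a true region; the aggregate re-test guarantees that every
#' emitted region satisfies all five criteria.
#'
#' @param min_width Minimum region width, exclusive (default 1000 bp).
#' @param fold_over_case_mean,fold_case_over_control,fold_over_control_mean
#'   Fold thresholds (defaults 5, 5 and 2).
#' @param window,step Sliding-window size and step in bp (defaults 200/100).
#' @param merge_gap Maximum gap bridged when merging candidate windows
#'   (default 200 bp).
#' @param candidate_frac Fraction of the fold thresholds at which a window
#'   enters candidacy (default 0.8); the merged region is always re-tested
#'   at the full thresholds.
#' @param depth_scaling Scale lambda by the case/control library-size ratio
#'   (default TRUE); `FALSE` reproduces the unadjusted reading.
#' @param dedup Whether duplicate removal is expected upstream; recorded as
#'   criterion 5.
#' @return A list of class `AmplificationParams`.
#' @export
amplification_params <- function(min_width = 1000L, fold_over_case_mean = 5,
                                 fold_case_over_control = 5,
                                 fold_over_control_mean = 2,
                                 window = 200L, step = 100L, merge_gap = 200L,
                                 candidate_frac = 0.8,
                                 depth_scaling = TRUE, dedup = TRUE) {
  if (min_width < 1) stop("min_width must be >= 1")
  if (any(c(fold_over_case_mean, fold_case_over_control,
            fold_over_control_mean) <= 0))
    stop("fold thresholds must be > 0")
  if (candidate_frac <= 0 || candidate_frac > 1)
    stop("candidate_frac must be in (0, 1]")
  structure(list(min_width = as.integer(min_width),
                 fold_over_case_mean = fold_over_case_mean,
                 fold_case_over_control = fold_case_over_control,
                 fold_over_control_mean = fold_over_control_mean,
                 window = as.integer(window), step = as.integer(step),
                 merge_gap = as.integer(merge_gap),
                 candidate_frac = candidate_frac,
                 depth_scaling = isTRUE(depth_scaling),
                 dedup = isTRUE(dedup)),
            class = "AmplificationParams")
}

#' Scan for copy-number-amplified regions
#'
#' Slides `window`-bp windows at `step`-bp steps over each chromosome of the
#' normalized tracks, keeps windows where the fold criteria (2)-(4) hold
#' pointwise, merges passing windows across gaps of at most `merge_gap` bp,
#' and re-tests every criterion (including the strict width criterion) on
#' each merged region's aggregate counts.  Criteria are evaluated on the
#' normalized scale; criterion (4) relates the case region density to the
#' control genome average on the raw scale (ratio of genome means).  The
#' Poisson p-value is computed on read-count scale: coverage sums are
#' converted back to raw counts via each track's genome mean and divided by
#' its mean read width; lambda is the control region count, library-size
#' scaled by default, and k the case region count.
#'
#' @param track_case,track_control Normalized `CoverageTrack`s on the same
#'   chromosome set.
#' @param params An [amplification_params()] object.
#' @param dedup_applied Whether duplicate reads were removed upstream
#'   (criterion 5); defaults to `params$dedup`.
#' @return `data.frame` of amplified regions sorted by ascending `p_value`:
#'   coordinates, normalized counts, fold ratios, estimated read counts,
#'   `p_value`, and the five criterion flags (`crit_width`,
#'   `crit_case_mean`, `crit_vs_control`, `crit_control_mean`,
#'   `crit_dedup`), all `TRUE` for emitted regions.
#' @export
scan_amplified <- function(track_case, track_control,
                           params = amplification_params(),
                           dedup_applied = params$dedup) {
  stopifnot(is_coverage_track(track_case), is_coverage_track(track_control))
  if (!track_case$normalized || !track_control$normalized)
    stop("both tracks must be normalized")
  if (!identical(track_case$seqlengths, track_control$seqlengths))
    stop("tracks are on different chromosome sets")
  gm_ratio <- track_case$genome_mean / track_control$genome_mean
  f2 <- params$fold_over_case_mean
  f3 <- params$fold_case_over_control
  f4 <- params$fold_over_control_mean
  cand <- list()
  for (chrom in names(track_case$seqlengths)) {
    len <- track_case$seqlengths[[chrom]]
    starts <- seq.int(1L, max(1L, len - params$window + 1L), by = params$step)
    ends <- pmin(starts + params$window - 1L, len)
    w <- ends - starts + 1L
    cs <- rle_interval_sums(track_case$cov[[chrom]], starts, ends)
    ct <- rle_interval_sums(track_control$cov[[chrom]], starts, ends)
    cf <- params$candidate_frac
    pass <- (cs >= cf * f2 * w) &
            (cs >= cf * f3 * ct) &
            (cs * gm_ratio >= cf * f4 * w)
    if (any(pass)) {
      ir <- IRanges::reduce(IRanges::IRanges(starts[pass], ends[pass]),
                            min.gapwidth = params$merge_gap + 1L)
      cand[[chrom]] <- GenomicRanges::GRanges(chrom, ir)
    }
  }
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      width = integer(0), count_case = numeric(0),
                      count_control = numeric(0), fold_vs_case_mean = numeric(0),
                      fold_vs_control = numeric(0), fold_vs_control_mean = numeric(0),
                      reads_case = numeric(0), reads_control = numeric(0),
                      p_value = numeric(0), crit_width = logical(0),
                      crit_case_mean = logical(0), crit_vs_control = logical(0),
                      crit_control_mean = logical(0), crit_dedup = logical(0),
                      stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(empty)
  regions <- suppressWarnings(do.call(c, unname(cand)))
  # aggregate re-test on merged regions
  cs <- region_count(track_case, regions)
  ct <- region_count(track_control, regions)
  w <- GenomicRanges::width(regions)
  fold_case_mean <- cs / w
  fold_vs_control <- ifelse(ct > 0, cs / ct, ifelse(cs > 0, Inf, NaN))
  fold_control_mean <- cs * gm_ratio / w
  crit1 <- w > params$min_width
  crit2 <- fold_case_mean >= f2
  crit3 <- fold_vs_control >= f3
  crit4 <- fold_control_mean >= f4
  crit5 <- rep(isTRUE(dedup_applied), length(regions))
  reads_case <- cs * track_case$genome_mean / track_case$read_width_mean
  reads_control <- ct * track_control$genome_mean / track_control$read_width_mean
  scale <- if (params$depth_scaling)
    track_case$total_reads / track_control$total_reads else 1
  p <- poisson_upper_tail(reads_control * scale, reads_case)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    width = w, count_case = cs, count_control = ct,
    fold_vs_case_mean = fold_case_mean,
    fold_vs_control = fold_vs_control,
    fold_vs_control_mean = fold_control_mean,
    reads_case = reads_case, reads_control = reads_control,
    p_value = p,
    crit_width = crit1, crit_case_mean = crit2, crit_vs_control = crit3,
    crit_control_mean = crit4, crit_dedup = crit5,
    stringsAsFactors = FALSE)
  out <- out[crit1 & crit2 & crit3 & crit4 & crit5, , drop = FALSE]
  out <- out[order(out$p_value, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes overlapping amplified regions
#'
#' A gene overlapping any amplified region by >= 1 bp is an amplified gene;
#' it is reported with the minimum p-value among its overlapping regions.
#'
#' @param regions `data.frame` from [scan_amplified()].
#' @param gm A `GeneModels` object.
#' @return `data.frame(gene_id, p_value, n_regions)`.
#' @export
annotate_amplified <- function(regions, gm) {
  if (nrow(regions) == 0L)
    return(data.frame(gene_id = character(0), p_value = numeric(0),
                      n_regions = integer(0), stringsAsFactors = FALSE))
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(gm$genes, rgr, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(0), p_value = numeric(0),
                      n_regions = integer(0), stringsAsFactors = FALSE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ids <- names(gm$genes)[qh]
  agg_p <- tapply(regions$p_value[sh], ids, min)
  agg_n <- tapply(sh, ids, function(x) length(unique(x)))
  out <- data.frame(gene_id = names(agg_p),
                    p_value = unname(as.numeric(agg_p)),
                    n_regions = unname(as.integer(agg_n)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker-gene evidence report for subgroup assessment
#'
#' Collects, per marker gene, the TSS-vicinity normalized counts in both
#' samples and their case/control ratio with a qualitative flag, whether
#' the marker overlaps an amplified region, plus the amplified-gene table
#' and the CpG-window t-test.  The report states evidence; any subgroup
#' label is a rule outcome over the user-supplied ratio thresholds, not a
#' diagnosis.
#'
#' @param track_case,track_control Normalized `CoverageTrack`s.
#' @param gm A `GeneModels` object.
#' @param marker_ids Character vector of marker gene ids (e.g. IDH1, EGFR,
#'   OLIG2 when present in the annotation); ids absent from the annotation
#'   are listed as not evaluable.
#' @param amplified Amplified-gene table from [annotate_amplified()].
#' @param cpg_test A `cpg_ttest` result, or `NULL`.
#' @param thresholds List with `reduced_below` and `elevated_above`
#'   case/control ratio cutoffs for the qualitative flags.
#' @return List of class `subgroup_report` with elements `markers`
#'   (data.frame), `amplified_genes` and `cpg_ttest`.
#' @export
subgroup_evidence_report <- function(track_case, track_control, gm,
                                     marker_ids = character(0),
                                     amplified = NULL, cpg_test = NULL,
                                     thresholds = list(reduced_below = 2/3,
                                                       elevated_above = 1.5)) {
  stopifnot(is_coverage_track(track_case), is_coverage_track(track_control))
  markers <- data.frame(gene_id = character(0), evaluable = logical(0),
                        count_control = numeric(0), count_case = numeric(0),
                        ratio = numeric(0), flag = character(0),
                        amplified = logical(0), stringsAsFactors = FALSE)
  if (length(marker_ids)) {
    present <- marker_ids %in% names(gm$genes)
    rows <- list()
    cc_case <- tss_vicinity_counts(track_case, gm)
    cc_ctrl <- tss_vicinity_counts(track_control, gm)
    amp_ids <- if (is.null(amplified)) character(0) else amplified$gene_id
    for (i in seq_along(marker_ids)) {
      id <- marker_ids[i]
      if (!present[i]) {
        rows[[i]] <- data.frame(gene_id = id, evaluable = FALSE,
                                count_control = NA_real_, count_case = NA_real_,
                                ratio = NA_real_, flag = "not evaluable",
                                amplified = NA, stringsAsFactors = FALSE)
        next
      }
      ctl <- cc_ctrl$count[cc_ctrl$gene_id == id]
      cas <- cc_case$count[cc_case$gene_id == id]
      ratio <- if (ctl > 0) cas / ctl else ifelse(cas > 0, Inf, NaN)
      flag <- if (is.nan(ratio)) "no signal"
              else if (ratio < thresholds$reduced_below) "reduced in case"
              else if (ratio > thresholds$elevated_above) "elevated in case"
              else "comparable"
      rows[[i]] <- data.frame(gene_id = id, evaluable = TRUE,
                              count_control = ctl, count_case = cas,
                              ratio = ratio, flag = flag,
                              amplified = id %in% amp_ids,
                              stringsAsFactors = FALSE)
    }
    markers <- do.call(rbind, rows)
  }
  structure(list(markers = markers,
                 amplified_genes = amplified %||%
                   data.frame(gene_id = character(0), p_value = numeric(0),
                              n_regions = integer(0)),
                 cpg_ttest = cpg_test,
                 thresholds = thresholds),
            class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Subgroup evidence report\n")
  if (nrow(x$markers)) {
    cat("Marker genes:\n")
    print(x$markers)
  } else cat("No marker genes evaluated.\n")
  cat(sprintf("Amplified genes: %d\n", nrow(x$amplified_genes)))
  if (!is.null(x$cpg_ttest)) print(x$cpg_ttest)
  invisible(x)
}
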