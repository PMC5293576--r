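# Normalized coverage tracks: 50-bp center-ward read shift, per-base pileup,
# genome-average normalization, region counting, bedGraph round-trip.

#' Shift parameters for read correction
#'
#' ChIP-seq reads are sequenced from fragment ends; shifting each read toward
#' the fragment midpoint (`+` reads downstream, `-` reads upstream) centers
#' the signal on the protein-bound site.  The default 50 bp matches a
#' ~100-200 bp fragment.  `literal_5prime = TRUE` instead shifts every read
#' toward its own 5' direction (`+` reads upstream), the alternative reading
#' of "shifted in the 5' direction"; it moves the two strands apart and is
#' provided for fidelity, not recommended.
#'
#' @param shift_bp Non-negative shift in bp (default 50).
#' @param extend_to Optional fixed fragment length; reads are resized to this
#'   width anchored at their 5' end before shifting.  Default `NULL` keeps
#'   mapped length.
#' @param literal_5prime Reverse the shift direction (see above).
#' @return A list of class `ShiftParams`.
#' @export
shift_params <- function(shift_bp = 50L, extend_to = NULL, literal_5prime = FALSE) {
  if (shift_bp < 0) stop("shift_bp must be >= 0")
  if (!is.null(extend_to) && extend_to < 1) stop("extend_to must be >= 1")
  structure(list(shift_bp = as.integer(shift_bp), extend_to = extend_to,
                 literal_5prime = isTRUE(literal_5prime)),
            class = "ShiftParams")
}

#' Shift reads toward the fragment midpoint
#'
#' `+`-strand reads are translated by `+shift_bp`, `-`-strand reads by
#' `-shift_bp` (reversed under `literal_5prime`); results are clipped to
#' chromosome bounds and reads left with zero width are dropped and counted.
#'
#' @param reads Stranded `GRanges` of mapped reads.
#' @param params A [shift_params()] object.
#' @param sizes Named vector of chromosome lengths.
#' @return `GRanges` of shifted intervals with attribute `n_dropped`.
#' @export
shift_reads <- function(reads, params = shift_params(), sizes) {
  assert_chrom_sizes(sizes)
  st <- as.character(GenomicRanges::strand(reads))
  if (any(!st %in% c("+", "-"))) stop("reads must be stranded (+ or -)")
  gr <- set_genome(reads, sizes)
  if (!is.null(params$extend_to))
    gr <- GenomicRanges::resize(gr, width = as.integer(params$extend_to),
                                fix = "start")  # strand-aware 5' anchor
  delta <- ifelse(st == "+", params$shift_bp, -params$shift_bp)
  if (params$literal_5prime) delta <- -delta
  gr <- suppressWarnings(GenomicRanges::shift(gr, as.integer(delta)))
  gr <- IRanges::trim(gr)
  n0 <- length(gr)
  gr <- gr[GenomicRanges::width(gr) >= 1L]
  attr(gr, "n_dropped") <- n0 - length(gr)
  gr
}

new_coverage_track <- function(cov, sizes, total_reads, genome_mean,
                               normalized, read_width_mean) {
  structure(list(cov = cov,
                 seqlengths = stats::setNames(as.integer(sizes), names(sizes)),
                 total_reads = total_reads,
                 genome_mean = genome_mean,
                 normalized = normalized,
                 read_width_mean = read_width_mean),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: %d chromosome(s), %s bp, %d reads, %s (genome mean %.4g)\n",
              length(x$cov),
              format(sum(as.numeric(x$seqlengths)), big.mark = ",",
                     scientific = FALSE),
              x$total_reads, if (x$normalized) "normalized" else "raw",
              x$genome_mean))
  invisible(x)
}

is_coverage_track <- function(x) inherits(x, "CoverageTrack")

#' Pile mapped reads into a raw coverage track
#'
#' Each position's value is the number of shifted read intervals covering it.
#' The genome-average per-base count (over every position of every
#' chromosome in `sizes`, zero-coverage bases included) is recorded for
#' [normalize_track()], together with the library size and the mean retained
#' read width (used to convert coverage sums back to read-count scale for
#' the Poisson test in [scan_amplified()]).
#'
#' @param reads Stranded `GRanges` of mapped reads.
#' @param params A [shift_params()] object.
#' @param sizes Named vector of chromosome lengths.
#' @return A raw `CoverageTrack`.
#' @export
pileup <- function(reads, params = shift_params(), sizes) {
  shifted <- shift_reads(reads, params, sizes)
  if (length(shifted) == 0L) stop("no reads retained for pileup (empty library)")
  cov <- GenomicRanges::coverage(shifted)
  cov <- cov[names(sizes)]
  genome_len <- sum(as.numeric(sizes))
  total_cov <- sum(vapply(cov, function(v) sum(as.numeric(S4Vectors::runValue(v)) *
                                                 S4Vectors::runLength(v)), numeric(1)))
  new_coverage_track(cov, sizes,
                     total_reads = length(shifted),
                     genome_mean = total_cov / genome_len,
                     normalized = FALSE,
                     read_width_mean = mean(GenomicRanges::width(shifted)))
}

#' Normalize a coverage track by its genome-average count
#'
#' Divides every per-base value by the genome mean so that the global mean of
#' the normalized track is exactly 1.  Applying it to an already-normalized
#' track is an error (not a silent re-application).
#'
#' @param track A raw `CoverageTrack`.
#' @return A normalized `CoverageTrack` (the genome mean is retained so raw
#'   counts can be recovered).
#' @export
normalize_track <- function(track) {
  stopifnot(is_coverage_track(track))
  if (track$normalized) stop("track is already normalized")
  if (track$genome_mean <= 0) stop("cannot normalize: genome mean is 0")
  track$cov <- track$cov / track$genome_mean
  track$normalized <- TRUE
  track
}

#' Sum of track values over regions
#'
#' Per-region sum of per-base values; regions are clipped to chromosome
#' bounds and regions empty after clipping contribute 0.
#'
#' @param track A `CoverageTrack`.
#' @param regions A `GRanges` (strand ignored).
#' @return Numeric vector parallel to `regions`.
#' @export
region_count <- function(track, regions) {
  stopifnot(is_coverage_track(track))
  out <- numeric(length(regions))
  chr <- as.character(GenomicRanges::seqnames(regions))
  for (c in unique(chr)) {
    i <- which(chr == c)
    if (!c %in% names(track$cov)) next
    out[i] <- rle_interval_sums(track$cov[[c]],
                                GenomicRanges::start(regions)[i],
                                GenomicRanges::end(regions)[i])
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted and values written with 6 decimal places.  Track
#' metadata (library size, genome mean, normalization flag, read width,
#' chromosome sizes) goes to a JSON sidecar `<path>.json` so the track
#' round-trips through [read_bedgraph()].
#'
#' @param track A `CoverageTrack`.
#' @param path Output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is_coverage_track(track))
  gr <- methods::as(track$cov, "GRanges")
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  S4Vectors::mcols(gr)$score <- round(S4Vectors::mcols(gr)$score, 6)
  rtracklayer::export(gr, path, format = "bedGraph")
  meta <- list(total_reads = track$total_reads,
               genome_mean = track$genome_mean,
               normalized = track$normalized,
               read_width_mean = track$read_width_mean,
               seqlengths = as.list(track$seqlengths))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a coverage track from bedGraph
#'
#' Overlapping bedGraph intervals are a format error.  If the JSON sidecar
#' written by [write_bedgraph()] is present its metadata is restored;
#' otherwise `sizes` must be given and the track is treated as raw with
#' unknown library size.
#'
#' @param path bedGraph path.
#' @param sizes Named vector of chromosome lengths (optional when the
#'   sidecar exists).
#' @return A `CoverageTrack`.
#' @export
read_bedgraph <- function(path, sizes = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else NULL
  if (is.null(sizes)) {
    if (is.null(meta)) stop("need `sizes` (no metadata sidecar found for ", path, ")")
    sizes <- unlist(meta$seqlengths)
  }
  assert_chrom_sizes(sizes)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 0 && !IRanges::isDisjoint(gr))
    stop("overlapping bedGraph intervals in ", path)
  gr <- set_genome(gr, sizes)
  cov <- if (length(gr) == 0L)
    GenomicRanges::coverage(gr)[names(sizes)] * 0
  else GenomicRanges::coverage(gr, weight = "score")[names(sizes)]
  new_coverage_track(cov, sizes,
                     total_reads = meta$total_reads %||% NA_integer_,
                     genome_mean = meta$genome_mean %||% NA_real_,
                     normalized = meta$normalized %||% FALSE,
                     read_width_mean = meta$read_width_mean %||% NA_real_)
}
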