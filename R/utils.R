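# Internal helpers shared across modules.

# Validate a chromosome-sizes vector: named, unique names, positive lengths.
assert_chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be a named vector")
  if (anyDuplicated(names(sizes)))
    stop("duplicate chromosome names: ",
         paste(unique(names(sizes)[duplicated(names(sizes))]), collapse = ", "))
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all chromosome lengths must be positive")
  invisible(sizes)
}

as_seqinfo <- function(sizes) {
  assert_chrom_sizes(sizes)
  GenomeInfoDb::Seqinfo(seqnames = names(sizes), seqlengths = as.integer(sizes))
}

# Deterministic ordering by (chrom, start, end) without relying on S4 sort
# dispatch from an Imports-only namespace.
order_granges <- function(gr) {
  gr[base::order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr))]
}

# Sum of per-base Rle values over [s, e] (1-based closed), clipped to [1, len];
# empty-after-clipping intervals contribute 0.  Vectorized over s/e.
rle_interval_sums <- function(v, s, e) {
  len <- length(v)
  s2 <- pmax(as.integer(s), 1L)
  e2 <- pmin(as.integer(e), len)
  out <- numeric(length(s2))
  ok <- e2 >= s2 & s2 <= len & e2 >= 1L
  if (any(ok))
    out[ok] <- IRanges::viewSums(IRanges::Views(v, start = s2[ok], end = e2[ok]))
  out
}

# Extract a window of length n starting at position s (1-based) from an Rle,
# padding positions outside [1, length] with zeros.
rle_window_padded <- function(v, s, n) {
  out <- numeric(n)
  lo <- max(s, 1L)
  hi <- min(s + n - 1L, length(v))
  if (hi >= lo)
    out[(lo - s + 1L):(hi - s + 1L)] <- as.numeric(v[lo:hi])
  out
}

# Attach the governing genome to a GRanges: keep only chromosomes present in
# `sizes`, then expand seqlevels to all of them with lengths set.
set_genome <- function(gr, sizes) {
  assert_chrom_sizes(sizes)
  keep <- intersect(GenomeInfoDb::seqlevels(gr), names(sizes))
  gr <- GenomeInfoDb::keepSeqlevels(gr, keep, pruning.mode = "coarse")
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- as.integer(unname(sizes)))
  gr
}

# Evaluate an expression under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
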