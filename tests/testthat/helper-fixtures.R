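suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

quiet <- function(expr) suppressMessages(expr)

# Build a CoverageTrack directly from per-chromosome numeric vectors.
make_track <- function(values, normalized = TRUE, genome_mean = 1,
                       total_reads = 1000L, read_width_mean = 36) {
  cov <- IRanges::RleList(lapply(values, S4Vectors::Rle))
  sizes <- vapply(values, length, integer(1))
  histodiff:::new_coverage_track(cov, sizes, total_reads = total_reads,
                                 genome_mean = genome_mean,
                                 normalized = normalized,
                                 read_width_mean = read_width_mean)
}

# Independent per-base pileup oracle: count shifted-read cover per position.
# reads: GRanges (1-based closed); returns list of numeric vectors.
brute_pileup <- function(reads, shift_bp, sizes) {
  out <- lapply(sizes, function(len) numeric(len))
  chr <- as.character(seqnames(reads))
  st <- as.character(strand(reads))
  s <- start(reads); e <- end(reads)
  for (i in seq_along(reads)) {
    d <- if (st[i] == "+") shift_bp else -shift_bp
    a <- s[i] + d; b <- e[i] + d
    len <- sizes[[chr[i]]]
    a <- max(a, 1L); b <- min(b, len)
    if (b >= a) out[[chr[i]]][a:b] <- out[[chr[i]]][a:b] + 1
  }
  out
}

random_reads <- function(n, sizes, read_len_range = c(20L, 50L)) {
  chr <- sample(names(sizes), n, replace = TRUE)
  len <- sizes[chr]
  w <- sample(seq(read_len_range[1], read_len_range[2]), n, replace = TRUE)
  s <- floor(runif(n) * (len - w)) + 1L
  GRanges(chr, IRanges(as.integer(s), width = w),
          strand = sample(c("+", "-"), n, replace = TRUE))
}

jaccard_interval <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  inter / ((e1 - s1 + 1) + (e2 - s2 + 1) - inter)
}

# Uniform-background fixture with one multiplied case region: the
# adequate-count conditions for amplification parameter-recovery tests.
amp_fixture_config <- function(seed, width = 2000L, fold = 6) {
  sim_config(seed = seed, genome = c(chrA = 300000L), n_genes = 0L,
             background_depth = 0.5,
             amplified_region = list(chrom = "chrA", start = 150001L,
                                     end = 150000L + width, fold = fold),
             n_intergenic_cpg = 0L)
}

# Reduced default-structure study for fast pipeline tests.
small_study_config <- function(seed) {
  sim_config(seed = seed, genome = c(chr1 = 200000L, chr2 = 200000L),
             n_genes = 16L,
             amplified_region = list(chrom = "chr2", start = 100001L,
                                     end = 102000L, fold = 6))
}

# Write a GRanges of reads as BED6 and return the path.
write_reads_tmp <- function(reads) {
  f <- tempfile(fileext = ".bed")
  write_reads_bed(reads, f)
  f
}
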