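# Strand-shifted pileup, normalization, region counting and the bedGraph
# round trip.

test_that("reads shift center-ward by strand and clip at bounds", {
  sizes <- c(chr1 = 1000L)
  # BED [100,136) on + shifted 50 -> BED [150,186); 1-based [151,186]
  plus <- GRanges("chr1", IRanges(101, 136), strand = "+")
  s <- shift_reads(plus, shift_params(50), sizes)
  expect_identical(c(start(s), end(s)), c(151L, 186L))

  minus <- GRanges("chr1", IRanges(101, 136), strand = "-")
  s <- shift_reads(minus, shift_params(50), sizes)
  expect_identical(c(start(s), end(s)), c(51L, 86L))

  # zero shift is the identity
  s <- shift_reads(plus, shift_params(0), sizes)
  expect_identical(ranges(s), ranges(plus))

  # literal 5' mode reverses the direction
  s <- shift_reads(plus, shift_params(50, literal_5prime = TRUE), sizes)
  expect_identical(start(s), 51L)

  # unstranded reads are an error
  expect_error(shift_reads(GRanges("chr1", IRanges(1, 10)), shift_params(), sizes),
               "strand")

  # reads shifted fully off the chromosome are dropped and counted
  far <- GRanges("chr1", IRanges(980, 999), strand = "+")
  s <- shift_reads(far, shift_params(50), sizes)
  expect_length(s, 0)
  expect_identical(attr(s, "n_dropped"), 1L)
})

test_that("shift is invertible when nothing is clipped", {
  sizes <- c(chr1 = 5000L, chr2 = 3000L)
  set.seed(1)
  reads <- random_reads(100, c(chr1 = 4000L, chr2 = 2000L))
  reads <- GenomicRanges::shift(reads, 500L)  # keep away from both edges
  fwd <- shift_reads(reads, shift_params(60), sizes)
  st <- as.character(strand(fwd))
  back <- GenomicRanges::shift(fwd, ifelse(st == "+", -60L, 60L))
  expect_identical(ranges(back), ranges(histodiff:::set_genome(reads, sizes)))
})

test_that("pileup counts per-base read cover and records library stats", {
  sizes <- c(chr1 = 20L)
  reads <- GRanges("chr1", IRanges(c(1, 6), width = 10), strand = "+")
  tr <- pileup(reads, shift_params(0), sizes)
  expect_identical(as.numeric(tr$cov$chr1),
                   c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_identical(tr$total_reads, 2L)
  expect_false(tr$normalized)

  # conservation: track sum equals total shifted-read length
  expect_equal(sum(as.numeric(tr$cov$chr1)), 20)

  # single read: max 1, sum = read length
  tr1 <- pileup(reads[1], shift_params(0), sizes)
  expect_identical(max(as.numeric(tr1$cov$chr1)), 1)
  expect_equal(sum(as.numeric(tr1$cov$chr1)), width(reads)[1])

  # all reads clipped off -> empty library error
  off <- GRanges("chr1", IRanges(15, 19), strand = "+")
  expect_error(pileup(off, shift_params(50), sizes), "empty library")
})

test_that("pileup equals brute-force membership counting on random instances", {
  set.seed(99)
  for (i in 1:10) {
    sizes <- c(a = sample(500:3000, 1), b = sample(500:3000, 1))
    reads <- random_reads(sample(50:300, 1), sizes)
    shift <- sample(0:100, 1)
    tr <- pileup(reads, shift_params(shift), sizes)
    oracle <- brute_pileup(reads, shift, sizes)
    for (chrom in names(sizes))
      expect_identical(as.numeric(tr$cov[[chrom]]), oracle[[chrom]])
  }
})

test_that("normalization divides by the genome mean exactly once", {
  # constant raw track -> constant 1.0
  tr <- make_track(list(chr1 = rep(4, 10)), normalized = FALSE, genome_mean = 4)
  n <- normalize_track(tr)
  expect_identical(as.numeric(n$cov$chr1), rep(1, 10))

  # {0,0,8,8} -> {0,0,2,2}
  tr <- make_track(list(chr1 = c(0, 0, 8, 8)), normalized = FALSE, genome_mean = 4)
  expect_identical(as.numeric(normalize_track(tr)$cov$chr1), c(0, 0, 2, 2))

  # any raw track: global mean exactly 1
  set.seed(5)
  sizes <- c(a = 2000L, b = 1500L)
  tr <- pileup(random_reads(300, sizes), shift_params(30), sizes)
  n <- normalize_track(tr)
  total <- sum(vapply(n$cov, function(v) sum(as.numeric(v)), numeric(1)))
  expect_equal(total / sum(sizes), 1, tolerance = 1e-12)

  # double normalization is rejected
  expect_error(normalize_track(n), "already normalized")
  # zero-coverage track cannot be normalized
  z <- make_track(list(chr1 = rep(0, 5)), normalized = FALSE, genome_mean = 0)
  expect_error(normalize_track(z), "genome mean")
})

test_that("region_count sums per-base values over clipped intervals", {
  tr <- make_track(list(chr1 = rep(1, 200)))
  expect_identical(region_count(tr, GRanges("chr1", IRanges(51, 150))), 100)
  # zero-width interval -> 0
  expect_identical(region_count(tr, GRanges("chr1", IRanges(10, 9))), 0)
  # {0,0,2,2} over BED [1,4) = 1-based [2,4]
  tr2 <- make_track(list(chr1 = c(0, 0, 2, 2)))
  expect_identical(region_count(tr2, GRanges("chr1", IRanges(2, 4))), 4)
  # clipping beyond the chromosome end
  expect_identical(region_count(tr, GRanges("chr1", IRanges(150, 500))), 51)
})

test_that("bedGraph round-trips tracks with metadata", {
  tr <- make_track(list(chr1 = c(1, 1, 0, 2), chr2 = c(0, 0, 0)),
                   normalized = TRUE, genome_mean = 2.5,
                   total_reads = 7L, read_width_mean = 36)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  tr2 <- read_bedgraph(f)
  expect_identical(as.numeric(tr2$cov$chr1), c(1, 1, 0, 2))
  expect_identical(as.numeric(tr2$cov$chr2), c(0, 0, 0))
  expect_identical(tr2$total_reads, 7L)
  expect_identical(tr2$genome_mean, 2.5)
  expect_true(tr2$normalized)

  # empty (all-zero) track writes a data-free file and reads back as zeros
  z <- make_track(list(chr1 = rep(0, 4)))
  fz <- tempfile(fileext = ".bedgraph")
  write_bedgraph(z, fz)
  expect_identical(as.numeric(read_bedgraph(fz)$cov$chr1), rep(0, 4))

  # overlapping bedGraph lines are a format error
  fo <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t10\t1.0", "chr1\t5\t15\t2.0"), fo)
  expect_error(read_bedgraph(fo, c(chr1 = 20L)), "overlapping")
})
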