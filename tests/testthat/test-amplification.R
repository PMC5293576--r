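# Duplicate removal, the Poisson upper tail, and the five-criteria
# amplification scan.

test_that("dedup keys on coordinates plus sequence tag", {
  r <- GRanges("chr1", IRanges(c(100, 100), width = 36), strand = "+")
  mcols(r)$name <- c("ACGT", "ACGT")
  expect_length(quiet(dedup_reads(r)), 1)
  expect_identical(attr(quiet(dedup_reads(r)), "n_removed"), 1L)

  # same coordinates, different sequences: both retained
  mcols(r)$name <- c("ACGT", "TTTT")
  expect_length(dedup_reads(r), 2)

  # without sequences the key is coordinates + strand
  mcols(r)$name <- NULL
  expect_length(quiet(dedup_reads(r)), 1)

  # empty stream passes through
  expect_length(dedup_reads(GRanges()), 0)
})

test_that("poisson_upper_tail matches direct pmf summation", {
  # (lambda = 2, k = 5): 1 - sum_{i<5} e^-2 2^i / i!
  ref <- 1 - sum(exp(-2) * 2^(0:4) / factorial(0:4))
  expect_equal(poisson_upper_tail(2, 5), ref, tolerance = 1e-12)
  expect_equal(ref, 5.265302e-2, tolerance = 1e-6)

  # k = 0 covers the whole support
  expect_identical(poisson_upper_tail(3.7, 0), 1)
  expect_identical(poisson_upper_tail(0, 0), 1)
  expect_identical(poisson_upper_tail(0, 2), 0)

  # non-increasing in k
  p <- poisson_upper_tail(rep(4, 51), 0:50)
  expect_true(all(diff(p) <= 0))

  expect_error(poisson_upper_tail(-1, 2), ">= 0")
})

# Construct normalized case/control tracks with a given per-base fold in
# [from, to] over unit background.
fold_tracks <- function(len, from, to, fold, gm_case = 1, gm_control = 1) {
  vc <- rep(1, len)
  vt <- rep(1, len); vt[from:to] <- fold
  list(case = make_track(list(chr1 = vt), genome_mean = gm_case,
                         total_reads = 10000L),
       control = make_track(list(chr1 = vc), genome_mean = gm_control,
                            total_reads = 10000L))
}

test_that("scan_amplified applies all five criteria", {
  # flat equal tracks: criterion 3 fails everywhere
  tr <- fold_tracks(20000, 1, 1, 1)
  expect_identical(nrow(scan_amplified(tr$case, tr$control)), 0L)

  # 2-kb 10x region over 1x control: exactly one region, all criteria true
  tr <- fold_tracks(20000, 8001, 10000, 10)
  amp <- scan_amplified(tr$case, tr$control)
  expect_identical(nrow(amp), 1L)
  expect_true(all(unlist(amp[1, c("crit_width", "crit_case_mean",
                                  "crit_vs_control", "crit_control_mean",
                                  "crit_dedup")])))
  expect_true(amp$start <= 8001 && amp$end >= 10000)  # covers the core
  expect_true(amp$p_value < 1e-10)

  # 800-bp region meeting every fold is excluded by the width criterion
  tr <- fold_tracks(20000, 8001, 8800, 10)
  expect_identical(nrow(scan_amplified(tr$case, tr$control)), 0L)

  # width strictly greater than min_width: an exactly-1000-bp fold-6
  # region aligned to the window grid (boundary windows fail the entry
  # criteria, so the candidate is exactly the region) is not reported
  tr <- fold_tracks(20000, 8001, 9000, 6)
  amp <- scan_amplified(tr$case, tr$control,
                        amplification_params(candidate_frac = 1))
  expect_identical(nrow(amp), 0L)

  # dedup flag is carried into criterion 5
  tr <- fold_tracks(20000, 8001, 10000, 10)
  amp <- scan_amplified(tr$case, tr$control, dedup_applied = FALSE)
  expect_identical(nrow(amp), 0L)
})

test_that("emitted regions satisfy recomputed aggregate folds", {
  sim <- simulate_chipseq(amp_fixture_config(101))
  tc <- normalize_track(pileup(sim$reads_control, shift_params(), sim$sizes))
  tt <- normalize_track(pileup(sim$reads_case, shift_params(), sim$sizes))
  amp <- scan_amplified(tt, tc)
  expect_gt(nrow(amp), 0)
  for (i in seq_len(nrow(amp))) {
    reg <- GRanges(amp$chrom[i], IRanges(amp$start[i], amp$end[i]))
    cs <- region_count(tt, reg); ct <- region_count(tc, reg)
    w <- amp$end[i] - amp$start[i] + 1
    expect_gte(cs / w, 5)
    expect_gte(cs / ct, 5)
    expect_gte(cs * tt$genome_mean / tc$genome_mean / w, 2)
    expect_gt(w, 1000)
  }
})

test_that("emitted region count is monotone in the amplification factor", {
  counts <- vapply(c(1, 2, 4, 5.5, 7, 10), function(f) {
    tr <- fold_tracks(20000, 8001, 10000, f)
    nrow(scan_amplified(tr$case, tr$control))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 0)   # no amplification
  expect_identical(counts[6], 1)   # strong amplification
})

test_that("annotate_amplified maps regions to overlapping genes", {
  sizes <- c(chr1 = 100000L)
  g <- GRanges("chr1", IRanges(c(10001, 30001), c(20000, 40000)),
               strand = c("+", "+"))
  names(g) <- c("gA", "gB")
  g <- histodiff:::set_genome(g, sizes)
  ex <- GRangesList(gA = g[1], gB = g[2])
  gm <- gene_models(g, ex)

  none <- scan_amplified(make_track(list(chr1 = rep(1, 1000))),
                         make_track(list(chr1 = rep(1, 1000))))
  expect_identical(nrow(annotate_amplified(none, gm)), 0L)

  regions <- data.frame(chrom = "chr1", start = 12000L, end = 14000L,
                        p_value = 1e-8, stringsAsFactors = FALSE)
  ann <- annotate_amplified(regions, gm)
  expect_identical(ann$gene_id, "gA")

  # a region spanning two adjacent genes lists both at the same p-value
  regions <- data.frame(chrom = "chr1", start = 19000L, end = 31000L,
                        p_value = 1e-8, stringsAsFactors = FALSE)
  ann <- annotate_amplified(regions, gm)
  expect_setequal(ann$gene_id, c("gA", "gB"))
  expect_identical(unique(ann$p_value), 1e-8)
})

test_that("the evidence report flags marker ratios and amplification", {
  sizes <- c(chr1 = 100000L)
  g <- GRanges("chr1", IRanges(c(10001, 30001), c(14000, 34000)),
               strand = c("+", "+"))
  names(g) <- c("IDH1", "EGFR")
  g <- histodiff:::set_genome(g, sizes)
  gm <- gene_models(g, GRangesList(IDH1 = g[1], EGFR = g[2]))

  vt <- rep(1, 100000); vt[29501:31000] <- 8   # EGFR promoter high in case
  vc <- rep(1, 100000); vc[9501:11000] <- 3    # IDH1 promoter high in control
  tt <- make_track(list(chr1 = vt))
  tc <- make_track(list(chr1 = vc))
  amp_genes <- data.frame(gene_id = "EGFR", p_value = 1e-20, n_regions = 1L,
                          stringsAsFactors = FALSE)
  rep_ <- subgroup_evidence_report(tt, tc, gm,
                                   marker_ids = c("IDH1", "EGFR", "OLIG2"),
                                   amplified = amp_genes)
  m <- rep_$markers
  expect_identical(m$flag[m$gene_id == "IDH1"], "reduced in case")
  expect_identical(m$flag[m$gene_id == "EGFR"], "elevated in case")
  expect_true(m$amplified[m$gene_id == "EGFR"])
  expect_false(m$amplified[m$gene_id == "IDH1"])
  expect_identical(m$flag[m$gene_id == "OLIG2"], "not evaluable")

  # empty marker list: report still carries amplification section
  rep0 <- subgroup_evidence_report(tt, tc, gm, marker_ids = character(0),
                                   amplified = amp_genes)
  expect_identical(nrow(rep0$markers), 0L)
  expect_identical(rep0$amplified_genes$gene_id, "EGFR")
})
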