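# Peak input, category assignment, gain/loss classification, overlap
# summary and the stand-in caller.

test_that("read_peaks handles broadPeak and BED3 with validation", {
  sizes <- c(chr1 = 10000L)
  f <- tempfile(fileext = ".broadPeak")
  writeLines("chr1\t100\t900\tpk1\t50\t.\t7.5\t3.2\t2.1", f)
  p <- read_peaks(f, "case", sizes)
  expect_identical(mcols(p)$score, 7.5)  # signalValue column 7
  expect_identical(mcols(p)$sample, "case")

  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t900", f)
  p <- read_peaks(f, "control", sizes)
  expect_true(is.na(mcols(p)$score))

  writeLines("chr1\t100\t100", f)  # end <= start
  expect_error(read_peaks(f, "x", sizes), "peak")
})

make_gm_toy <- function() {
  sizes <- c(chr1 = 100000L)
  g <- GRanges("chr1", IRanges(c(20001, 50001, 80001), c(24000, 53000, 82000)),
               strand = c("+", "-", "+"))
  names(g) <- c("g1", "g2", "g3")
  g <- histodiff:::set_genome(g, sizes)
  ex <- GRangesList(
    g1 = GRanges("chr1", IRanges(c(20001, 23001), c(20500, 24000)), strand = "+"),
    g2 = GRanges("chr1", IRanges(c(50001, 52001), c(50800, 53000)), strand = "-"),
    g3 = GRanges("chr1", IRanges(80001, 82000), strand = "+"))
  gene_models(g, ex)
}

test_that("peaks are assigned to promoter/exon/gene-body by >= 1 bp overlap", {
  gm <- make_gm_toy()
  # peak wholly inside an exon counts for exon AND gene body
  pk <- GRanges("chr1", IRanges(20100, 20200))
  cnt <- assign_peaks(pk, gm)
  expect_identical(cnt$exon[cnt$gene_id == "g1"], 1L)
  expect_identical(cnt$gene_body[cnt$gene_id == "g1"], 1L)

  # promoter overlap by exactly 1 bp still counts (g1 distal promoter
  # = [15001, 21000]; peak ending at 15001)
  pk <- GRanges("chr1", IRanges(14500, 15001))
  cnt <- assign_peaks(pk, gm)
  expect_identical(cnt$promoter[cnt$gene_id == "g1"], 1L)
  expect_identical(cnt$gene_body[cnt$gene_id == "g1"], 0L)
  # one bp less and it no longer counts
  cnt <- assign_peaks(GRanges("chr1", IRanges(14500, 15000)), gm)
  expect_identical(cnt$promoter[cnt$gene_id == "g1"], 0L)

  # proximal window option: [tss-250, tss+250) around g1's tss 20001
  cnt <- assign_peaks(GRanges("chr1", IRanges(19800, 19800)), gm,
                      promoter = "proximal")
  expect_identical(cnt$promoter[cnt$gene_id == "g1"], 1L)
})

test_that("assign_peaks matches exhaustive pairwise enumeration", {
  gm <- make_gm_toy()
  set.seed(21)
  for (rep in 1:5) {
    starts <- sample(10000:90000, 6)
    pk <- GRanges("chr1", IRanges(starts, starts + sample(200:4000, 6)))
    cnt <- assign_peaks(pk, gm)
    # brute force over every (gene, peak) pair
    scheme <- region_scheme()
    for (i in seq_along(gm$genes)) {
      id <- names(gm$genes)[i]
      st <- as.character(strand(gm$genes))[i]
      tss <- mcols(gm$genes)$tss[i]
      prom <- if (st == "+") c(tss - 5000, tss + 999) else c(tss - 999, tss + 5000)
      ov <- function(a1, a2) sum(pmin(end(pk), a2) >= pmax(start(pk), a1))
      expect_identical(cnt$promoter[cnt$gene_id == id], as.integer(ov(prom[1], prom[2])))
      expect_identical(cnt$gene_body[cnt$gene_id == id],
                       as.integer(ov(start(gm$genes)[i], end(gm$genes)[i])))
      n_ex <- sum(vapply(seq_along(pk), function(j) {
        any(start(pk)[j] <= end(gm$exons[[i]]) & end(pk)[j] >= start(gm$exons[[i]]))
      }, logical(1)))
      expect_identical(cnt$exon[cnt$gene_id == id], as.integer(n_ex))
    }
  }
})

test_that("gain/loss classification follows the presence/absence rule", {
  tab <- function(p, e, b) data.frame(gene_id = "g", promoter = p, exon = e,
                                      gene_body = b, stringsAsFactors = FALSE)
  expect_identical(classify_gain_loss(tab(0, 0, 0), tab(1, 0, 0))$status, "gained")
  expect_identical(classify_gain_loss(tab(0, 2, 1), tab(0, 0, 0))$status, "lost")
  # presence in both, category shift irrelevant
  expect_identical(classify_gain_loss(tab(1, 0, 0), tab(0, 1, 0))$status,
                   "unchanged_present")
  expect_identical(classify_gain_loss(tab(0, 0, 0), tab(0, 0, 0))$status,
                   "unchanged_absent")
  # universe mismatch
  t2 <- tab(1, 0, 0); t2$gene_id <- "other"
  expect_error(classify_gain_loss(tab(0, 0, 0), t2), "universe")
})

test_that("classification is a pure function of the count tables", {
  set.seed(3)
  n <- 30
  mk <- function() data.frame(gene_id = sprintf("g%02d", 1:n),
                              promoter = rpois(n, 0.5), exon = rpois(n, 0.5),
                              gene_body = rpois(n, 0.5), stringsAsFactors = FALSE)
  a <- mk(); b <- mk()
  res <- classify_gain_loss(a, b)
  perm <- sample(n)
  res_p <- classify_gain_loss(a[perm, ], b[perm, ])
  expect_identical(res_p$status, res$status[perm])
  expect_identical(res_p$gene_id, res$gene_id[perm])
})

test_that("overlap summary counts shared peaks per side", {
  pk <- GRanges("chr1", IRanges(c(100, 500, 900), width = 100))
  s <- overlap_summary(pk, pk)
  expect_identical(s$n_control_shared, 3L)
  expect_identical(s$n_case_shared, 3L)
  expect_identical(s$n_control_only, 0L)

  far <- GenomicRanges::shift(pk, 5000L)
  s <- overlap_summary(pk, far)
  expect_identical(s$n_control_shared, 0L)
  expect_identical(s$n_case_only, 3L)

  # 5 control / 4 case peaks with 2 overlapping pairs; checked by brute force
  pc <- GRanges("chr1", IRanges(c(100, 300, 600, 1000, 2000), width = 50))
  pt <- GRanges("chr1", IRanges(c(120, 620, 3000, 4000), width = 50))
  s <- overlap_summary(pc, pt)
  brute_c <- vapply(seq_along(pc), function(i)
    any(start(pc)[i] <= end(pt) & end(pc)[i] >= start(pt)), logical(1))
  brute_t <- vapply(seq_along(pt), function(i)
    any(start(pt)[i] <= end(pc) & end(pt)[i] >= start(pc)), logical(1))
  expect_identical(s$n_control_shared, sum(brute_c))
  expect_identical(s$n_case_shared, sum(brute_t))
  expect_identical(s$n_control, s$n_control_shared + s$n_control_only)
  expect_identical(s$n_case, s$n_case_shared + s$n_case_only)
  expect_equal(s$width_control_only[["mean"]], 50)
})

test_that("stand-in caller thresholds, merges and filters runs", {
  # constant 1.0 track, min_value 2 -> no peaks
  tr <- make_track(list(chr1 = rep(1, 1000)))
  expect_length(standin_call_peaks(tr, min_value = 2), 0)

  # one 300-bp block of 5 on zero background -> exactly that interval
  v <- rep(0, 1000); v[201:500] <- 5
  tr <- make_track(list(chr1 = v))
  pk <- standin_call_peaks(tr, min_value = 2, min_width = 100)
  expect_identical(c(start(pk), end(pk)), c(201L, 500L))

  # two blocks 40 bp apart merge across a 50-bp gap
  v <- rep(0, 1000); v[101:200] <- 5; v[241:340] <- 5
  tr <- make_track(list(chr1 = v))
  pk <- standin_call_peaks(tr, min_value = 2, min_width = 100, merge_gap = 50)
  expect_length(pk, 1)
  expect_identical(c(start(pk), end(pk)), c(101L, 340L))
  # but not across a 30-bp merge limit
  pk <- standin_call_peaks(tr, min_value = 2, min_width = 100, merge_gap = 30)
  expect_length(pk, 2)

  # unnormalized track is refused
  raw <- make_track(list(chr1 = v), normalized = FALSE, genome_mean = 1)
  expect_error(standin_call_peaks(raw), "normalized")
})
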