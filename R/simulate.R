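# Synthetic ChIP-seq study generator.  Produces a small two-chromosome
# genome with non-overlapping gene models, paired control/case read sets
# (uniform background plus promoter-localized enrichment), a set of genes
# enriched only in the case (gained) or only in the control (lost), one
# copy-number-amplified region simulated as genuine extra molecules, CpG
# islands, and an expression table linearly coupled to the true promoter
# enrichment -- with full ground truth for every downstream stage.

#' Simulation configuration
#'
#' Defines the synthetic study.  Background reads are uniform with
#' Poisson-distributed counts per strand; enriched promoters receive extra
#' reads whose 5' ends are placed ~`fragment_offset` bp outside the TSS on
#' each strand (Gaussian jitter `positional_sd`), so the 50-bp center-ward
#' shift stacks them on the TSS.  Per-gene true enrichment intensities are
#' log-normally dispersed around the `enriched_fold` level (floored at
#' `enrichment_floor` of it) so that signal spans a realistic dynamic
#' range.  The amplified region multiplies every case read whose 5' end
#' falls inside it by the integer fold (extra copies carry distinct
#' sequence tags: genuine molecules, not PCR duplicates).  Expression is
#' `expression_slope * true case-sample promoter intensity + N(0,
#' expression_sigma)`, floored at 0.
#'
#' @param seed Integer seed; one seed drives the whole simulation.
#' @param genome Named vector of chromosome lengths (default two 500-kb
#'   chromosomes).
#' @param n_genes Number of genes (default 60).
#' @param read_length Read length in bp (default 36).
#' @param background_depth Mean background reads per bp per sample
#'   (default 0.02).
#' @param enriched_fold Promoter enrichment multiplier over background
#'   (default 8).
#' @param enrichment_span Effective promoter span in bp used to convert the
#'   fold into an expected extra-read count (default 500).
#' @param enrichment_sdlog,enrichment_floor,enrichment_cap Log-normal
#'   dispersion of per-gene enrichment, with lower floor and upper cap as
#'   fractions of the central level (defaults 1.3, 1 and 12): signal spans
#'   about two orders of magnitude without single extreme promoters
#'   dominating the genome-wide mean.
#' @param positional_sd Gaussian jitter of enrichment read placement (bp).
#' @param fragment_offset 5'-end offset of enrichment reads from the TSS
#'   (default 50, matching the pileup shift).
#' @param gained_frac,lost_frac Fractions of genes enriched only in the
#'   case / only in the control (defaults 0.1 each).
#' @param amplified_region List `(chrom, start, end, fold)` in 1-based
#'   closed coordinates, or `NULL`; default one 2-kb region at fold 6.
#' @param pcr_duplicate_rate Fraction of reads duplicated with the *same*
#'   sequence tag (PCR artefacts for exercising dedup; default 0).
#' @param expression_slope,expression_sigma Linear coupling of expression
#'   to true case promoter intensity and its Gaussian noise sd.
#' @param n_intergenic_cpg Extra CpG islands placed away from promoters.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 500000L, chr2 = 500000L),
                       n_genes = 60L,
                       read_length = 36L,
                       background_depth = 0.02,
                       enriched_fold = 8,
                       enrichment_span = 750L,
                       enrichment_sdlog = 1.3,
                       enrichment_floor = 1,
                       enrichment_cap = 12,
                       positional_sd = 30,
                       fragment_offset = 50L,
                       gained_frac = 0.1,
                       lost_frac = 0.1,
                       amplified_region = list(chrom = "chr2", start = 300001L,
                                               end = 302000L, fold = 6),
                       pcr_duplicate_rate = 0,
                       expression_slope = 0.1,
                       expression_sigma = 2,
                       n_intergenic_cpg = 10L) {
  assert_chrom_sizes(genome)
  if (gained_frac + lost_frac > 1) stop("gained_frac + lost_frac must be <= 1")
  if (enriched_fold <= 1) stop("enriched_fold must be > 1")
  if (!is.null(amplified_region)) {
    ar <- amplified_region
    if (!ar$chrom %in% names(genome) || ar$start < 1 ||
        ar$end > genome[[ar$chrom]] || ar$end <= ar$start)
      stop("amplified_region outside the genome")
    if (ar$fold <= 1) stop("amplified_region fold must be > 1")
  }
  structure(list(seed = as.integer(seed), genome = genome,
                 n_genes = as.integer(n_genes),
                 read_length = as.integer(read_length),
                 background_depth = background_depth,
                 enriched_fold = enriched_fold,
                 enrichment_span = as.integer(enrichment_span),
                 enrichment_sdlog = enrichment_sdlog,
                 enrichment_floor = enrichment_floor,
                 enrichment_cap = enrichment_cap,
                 positional_sd = positional_sd,
                 fragment_offset = as.integer(fragment_offset),
                 gained_frac = gained_frac, lost_frac = lost_frac,
                 amplified_region = amplified_region,
                 pcr_duplicate_rate = pcr_duplicate_rate,
                 expression_slope = expression_slope,
                 expression_sigma = expression_sigma,
                 n_intergenic_cpg = as.integer(n_intergenic_cpg)),
            class = "sim_config")
}

# Slot-based non-overlapping gene placement with >= 10 kb spacing.  Each
# chromosome is divided into fixed slots; a gene is placed at a jittered
# offset inside its slot with a 5-kb margin on both sides, which bounds the
# gap between adjacent gene bodies below by 10 kb.  Slots intersecting the
# amplified region (plus the distal promoter reach) are reserved.
place_genes <- function(config) {
  pitch <- 15500L
  margin <- 5000L
  glen_range <- c(2000L, 5000L)
  slots <- list()
  for (chrom in names(config$genome)) {
    len <- config$genome[[chrom]]
    ns <- floor(len / pitch)
    if (ns < 1L) next
    starts <- (seq_len(ns) - 1L) * pitch + 1L
    slots[[chrom]] <- data.frame(chrom = chrom, slot_start = starts,
                                 slot_end = starts + pitch - 1L,
                                 stringsAsFactors = FALSE)
  }
  slots <- do.call(rbind, slots)
  if (!is.null(config$amplified_region)) {
    ar <- config$amplified_region
    reach <- 6000L  # distal promoter (5 kb) + margin
    excl <- slots$chrom == ar$chrom &
      slots$slot_start <= ar$end + reach &
      slots$slot_end >= ar$start - reach
    slots <- slots[!excl, , drop = FALSE]
  }
  if (nrow(slots) < config$n_genes)
    stop("infeasible gene placement: need ", config$n_genes, " slots, have ",
         nrow(slots), "; use a larger genome or fewer genes")
  pick <- sort(sample(nrow(slots), config$n_genes))
  slots <- slots[pick, , drop = FALSE]
  glen <- sample(seq(glen_range[1], glen_range[2], by = 100L),
                 config$n_genes, replace = TRUE)
  max_off <- pitch - glen - 2L * margin
  off <- margin + floor(runif(config$n_genes) * (max_off + 1L))
  start <- slots$slot_start + off
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  data.frame(gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
             chrom = slots$chrom, start = start, end = start + glen - 1L,
             strand = strand, stringsAsFactors = FALSE)
}

# Random exon structure: 1-4 exons partitioning the body, first exon
# starting at the body start and last ending at the body end (BED12 block
# convention), alternating exon/intron widths drawn from a Dirichlet-like
# gamma scheme with a 50-bp minimum.
make_exons <- function(chrom, start, end, strand) {
  glen <- end - start + 1L
  k <- sample(1:4, 1L)
  nseg <- 2L * k - 1L
  repeat {
    props <- stats::rgamma(nseg, shape = 2)
    widths <- pmax(50L, as.integer(floor(props / sum(props) * glen)))
    widths[nseg] <- glen - sum(widths[-nseg])
    if (widths[nseg] >= 50L) break
  }
  bounds <- cumsum(c(0L, widths))
  exon_idx <- seq(1L, nseg, by = 2L)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start + bounds[exon_idx],
                                          start + bounds[exon_idx + 1L] - 1L),
                         strand = strand)
}

# Uniform background reads for one sample: per-strand Poisson counts with
# uniform 5' positions.
background_reads <- function(config, prefix) {
  rl <- config$read_length
  out <- list()
  for (chrom in names(config$genome)) {
    len <- config$genome[[chrom]]
    for (st in c("+", "-")) {
      n <- stats::rpois(1L, len * config$background_depth / 2)
      if (n == 0L) next
      p5 <- 1L + floor(runif(n) * len)  # 5' position
      s <- if (st == "+") p5 else p5 - rl + 1L
      out[[paste(chrom, st)]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(as.integer(s), width = rl), strand = st)
    }
  }
  gr <- suppressWarnings(do.call(c, unname(out)))
  S4Vectors::mcols(gr)$name <- sprintf("%s%07d", prefix, seq_along(gr))
  gr
}

# Promoter enrichment reads for one gene in one sample: n ~ Poisson(level);
# read 5' ends offset so the center-ward shift stacks coverage on the TSS.
enrichment_reads <- function(config, chrom, tss, level, prefix) {
  n <- stats::rpois(1L, level)
  if (n == 0L) return(NULL)
  rl <- config$read_length
  plus <- as.logical(stats::rbinom(n, 1L, 0.5))
  jitter <- round(stats::rnorm(n, 0, config$positional_sd))
  half_read <- (rl - 1L) %/% 2L
  s <- integer(n)
  # + reads: start so that the +shift window centers on the TSS
  s[plus] <- tss - config$fragment_offset - half_read + jitter[plus]
  # - reads: 5' end (interval end) at tss + offset + half_read
  e_minus <- tss + config$fragment_offset + half_read + jitter[!plus]
  s[!plus] <- e_minus - rl + 1L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(s), width = rl),
                               strand = ifelse(plus, "+", "-"))
  S4Vectors::mcols(gr)$name <- sprintf("%s%05d", prefix, seq_len(n))
  gr
}

#' Generate a synthetic paired ChIP-seq study
#'
#' Runs the whole generator under one seed (the global RNG state is left
#' untouched) and optionally writes the standard file set.  Identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `chrom.sizes`,
#'   `genes.bed`, `cpg.bed`, `reads_control.bed.gz`, `reads_case.bed.gz`,
#'   `expression.tsv` and `truth.json` into it.
#' @return A list with `config`, `sizes`, `genes` (`GeneModels`), `cpg`
#'   (`GRanges`), `reads_control`/`reads_case` (`GRanges` with sequence
#'   tags in `name`), `expression` (named vector), `truth` (gained/lost
#'   ids, amplified region, per-gene true intensities), and `files` (paths,
#'   when `dir` was given).
#' @export
simulate_chipseq <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes_df <- place_genes(config)
    exons <- GenomicRanges::GRangesList(lapply(seq_len(nrow(genes_df)), function(i)
      make_exons(genes_df$chrom[i], genes_df$start[i], genes_df$end[i],
                 genes_df$strand[i])))
    body <- GenomicRanges::GRanges(genes_df$chrom,
                                   IRanges::IRanges(genes_df$start, genes_df$end),
                                   strand = genes_df$strand)
    names(body) <- genes_df$gene_id
    body <- set_genome(body, config$genome)
    gm <- gene_models(body, exons)

    # roles
    n <- config$n_genes
    n_gain <- round(config$gained_frac * n)
    n_lost <- round(config$lost_frac * n)
    roles <- rep("both", n)
    pick <- sample(n, n_gain + n_lost)
    roles[pick[seq_len(n_gain)]] <- "gained"
    roles[pick[seq_len(n_lost) + n_gain]] <- "lost"

    # per-gene true enrichment intensity (expected extra reads per sample)
    base_level <- (config$enriched_fold - 1) * config$background_depth *
      config$enrichment_span
    disp <- pmin(config$enrichment_cap,
                 pmax(config$enrichment_floor,
                      stats::rlnorm(n, meanlog = 0,
                                    sdlog = config$enrichment_sdlog)))
    level <- base_level * disp
    level_control <- ifelse(roles %in% c("lost", "both"), level, 0)
    level_case <- ifelse(roles %in% c("gained", "both"), level, 0)

    tss <- S4Vectors::mcols(gm$genes)$tss
    build_sample <- function(levels, tag) {
      parts <- list(background_reads(config, paste0(tag, "bg")))
      for (i in seq_len(n)) {
        if (levels[i] <= 0) next
        er <- enrichment_reads(config, genes_df$chrom[i], tss[i], levels[i],
                               sprintf("%sprom%03d_", tag, i))
        if (!is.null(er)) parts[[length(parts) + 1L]] <- er
      }
      gr <- suppressWarnings(do.call(c, parts))
      gr <- set_genome(gr, config$genome)
      gr <- IRanges::trim(gr)
      gr[GenomicRanges::width(gr) >= 1L]
    }
    reads_control <- build_sample(level_control, "c")
    reads_case <- build_sample(level_case, "t")

    # amplification: multiply case reads whose 5' end falls in the region
    if (!is.null(config$amplified_region)) {
      ar <- config$amplified_region
      p5 <- ifelse(as.character(GenomicRanges::strand(reads_case)) == "+",
                   GenomicRanges::start(reads_case),
                   GenomicRanges::end(reads_case))
      inside <- as.character(GenomicRanges::seqnames(reads_case)) == ar$chrom &
        p5 >= ar$start & p5 <= ar$end
      n_extra <- floor(ar$fold) - 1L
      if (any(inside) && n_extra > 0L) {
        dup <- rep(which(inside), each = n_extra)
        extra <- reads_case[dup]
        S4Vectors::mcols(extra)$name <- sprintf(
          "%s_amp%d", S4Vectors::mcols(extra)$name,
          rep(seq_len(n_extra), times = sum(inside)))
        reads_case <- suppressWarnings(c(reads_case, extra))
      }
    }

    # optional PCR duplicates (same sequence tag)
    add_pcr <- function(gr) {
      if (config$pcr_duplicate_rate <= 0) return(gr)
      n_dup <- stats::rpois(1L, config$pcr_duplicate_rate * length(gr))
      if (n_dup == 0L) return(gr)
      suppressWarnings(c(gr, gr[sample(length(gr), n_dup, replace = TRUE)]))
    }
    reads_control <- add_pcr(reads_control)
    reads_case <- add_pcr(reads_case)

    # CpG islands: one per promoter, centered on the TSS, plus intergenic
    cpg_w <- sample(seq(300L, 1500L, by = 50L), n, replace = TRUE)
    cpg_start <- pmax(1L, tss - cpg_w %/% 2L)
    cpg <- GenomicRanges::GRanges(genes_df$chrom,
                                  IRanges::IRanges(cpg_start, width = cpg_w))
    if (config$n_intergenic_cpg > 0L) {
      ic_chrom <- sample(names(config$genome), config$n_intergenic_cpg,
                         replace = TRUE)
      ic_w <- sample(seq(300L, 1500L, by = 50L), config$n_intergenic_cpg,
                     replace = TRUE)
      ic_start <- vapply(seq_len(config$n_intergenic_cpg), function(i)
        1L + floor(runif(1) * (config$genome[[ic_chrom[i]]] - ic_w[i])),
        numeric(1))
      cpg <- suppressWarnings(c(cpg, GenomicRanges::GRanges(
        ic_chrom, IRanges::IRanges(as.integer(ic_start), width = ic_w))))
    }
    cpg <- set_genome(cpg, config$genome)
    cpg <- IRanges::trim(cpg)
    S4Vectors::mcols(cpg)$name <- sprintf("cpg%03d", seq_along(cpg))
    S4Vectors::mcols(cpg)$center <- cpg_centers(cpg)
    cpg <- order_granges(cpg)

    # expression coupled to the true case-sample promoter intensity
    expr <- pmax(0, config$expression_slope * level_case +
                   stats::rnorm(n, 0, config$expression_sigma))
    names(expr) <- genes_df$gene_id

    truth <- list(
      gained = genes_df$gene_id[roles == "gained"],
      lost = genes_df$gene_id[roles == "lost"],
      unchanged = genes_df$gene_id[roles == "both"],
      amplified_region = config$amplified_region,
      levels = data.frame(gene_id = genes_df$gene_id, role = roles,
                          level_control = level_control,
                          level_case = level_case,
                          stringsAsFactors = FALSE))

    out <- list(config = config, sizes = config$genome, genes = gm, cpg = cpg,
                reads_control = reads_control, reads_case = reads_case,
                expression = expr, truth = truth)
    if (!is.null(dir)) out$files <- write_simulation(out, dir)
    out
  })
}

# Write the standard file set for a simulated study.
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    genes = file.path(dir, "genes.bed"),
    cpg = file.path(dir, "cpg.bed"),
    reads_control = file.path(dir, "reads_control.bed.gz"),
    reads_case = file.path(dir, "reads_case.bed.gz"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"))
  write_chrom_sizes(sim$sizes, files$chrom_sizes)
  write_gene_models(sim$genes, files$genes)
  cpg_out <- GenomicRanges::granges(sim$cpg)
  S4Vectors::mcols(cpg_out)$name <- S4Vectors::mcols(sim$cpg)$name
  rtracklayer::export(cpg_out, files$cpg, format = "BED")
  write_reads_bed(sim$reads_control, files$reads_control)
  write_reads_bed(sim$reads_case, files$reads_case)
  write_expression_table(sim$expression, files$expression)
  jsonlite::write_json(sim$truth, files$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files
}
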