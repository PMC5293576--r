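# Annotation and read I/O: chromosome sizes, BED6 reads, BED12 gene models,
# BED4 CpG islands, two-column expression tables.  File parsing is delegated
# to rtracklayer wherever a standard format is involved; the domain
# validation (strand conventions, exon containment, duplicate ids) is done
# here on the imported objects.

#' Read a chromosome-sizes file
#'
#' Parses a two-column TSV (chromosome name, length in bp) into a named
#' integer vector, the object every coordinate-bearing function in the
#' package validates against.
#'
#' @param path Path to a `chrom.sizes`-style file (optionally gzipped).
#' @return Named integer vector of chromosome lengths.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chromosome sizes file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  sizes <- integer(0)
  nms <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 2L)
      stop(sprintf("malformed chrom.sizes row at line %d: expected 2 fields, got %d",
                   i, length(f)))
    len <- suppressWarnings(as.numeric(f[2]))
    if (is.na(len))
      stop(sprintf("malformed chrom.sizes row at line %d: length '%s' is not numeric",
                   i, f[2]))
    if (len <= 0)
      stop(sprintf("invalid chromosome length at line %d: %s must be > 0", i, f[2]))
    nms <- c(nms, f[1])
    sizes <- c(sizes, as.integer(len))
  }
  names(sizes) <- nms
  assert_chrom_sizes(sizes)
  sizes
}

#' Write a chromosome-sizes file
#'
#' @param sizes Named vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  assert_chrom_sizes(sizes)
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

#' Read mapped reads from a BED6 file
#'
#' Reads must carry a strand (`+` or `-`); reads on chromosomes absent from
#' `sizes` are dropped (with a message and a recorded count), and coordinates
#' are clipped to chromosome bounds.  The BED name column is retained in
#' `mcols(reads)$name`; the synthetic-data generator stores a per-molecule
#' sequence tag there, which [dedup_reads()] uses as the sequence key.
#'
#' @param path BED6 file (optionally gzipped).
#' @param sizes Named vector of chromosome lengths.
#' @return A stranded `GRanges` with attribute `n_dropped` (reads removed for
#'   unknown chromosome or being fully off-chromosome).
#' @export
read_reads_bed <- function(path, sizes) {
  assert_chrom_sizes(sizes)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("no reads in ", path)
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("reads BED must have a strand column with '+' or '-' entries: ", path)
  n0 <- length(gr)
  gr <- set_genome(gr, sizes)
  gr <- IRanges::trim(gr)
  gr <- gr[GenomicRanges::width(gr) >= 1L]
  n_dropped <- n0 - length(gr)
  if (length(gr) == 0L) stop("all reads dropped while reading ", path)
  if (n_dropped > 0)
    message(sprintf("read_reads_bed: dropped %d read(s) (unknown chromosome or off-end)",
                    n_dropped))
  attr(gr, "n_dropped") <- n_dropped
  gr
}

#' Write mapped reads to BED6
#'
#' @param reads Stranded `GRanges` of reads.
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  if (is.null(S4Vectors::mcols(reads)$name))
    S4Vectors::mcols(reads)$name <- paste0("r", seq_along(reads))
  if (is.null(S4Vectors::mcols(reads)$score))
    S4Vectors::mcols(reads)$score <- 0L
  rtracklayer::export(reads, path, format = "BED")
  invisible(path)
}

#' Construct a gene-model set
#'
#' The container used throughout the package for gene annotation: a stranded
#' body `GRanges` named by gene id with `tss`/`tts` metadata columns, plus a
#' parallel `GRangesList` of exons.  TSS conventions follow UCSC: on `+` the
#' TSS is the first base of the body, on `-` the last base.
#'
#' @param genes Stranded `GRanges`, one range per gene body, with unique
#'   `names()` (gene ids).
#' @param exons `GRangesList` parallel to `genes`: per-gene exon intervals,
#'   sorted, non-overlapping, contained in the body, first starting at the
#'   body start and last ending at the body end (BED12 block convention).
#' @return An object of class `GeneModels`.
#' @export
gene_models <- function(genes, exons) {
  ids <- names(genes)
  if (is.null(ids) || any(!nzchar(ids))) stop("gene bodies must be named by gene id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  st <- as.character(GenomicRanges::strand(genes))
  if (any(!st %in% c("+", "-")))
    stop("gene models must be stranded (+ or -)")
  if (length(exons) != length(genes)) stop("exons must parallel genes")
  for (i in seq_along(genes)) {
    ex <- exons[[i]]
    if (length(ex) == 0L) stop("gene ", ids[i], " has no exons")
    if (as.character(GenomicRanges::seqnames(ex))[1] !=
        as.character(GenomicRanges::seqnames(genes))[i])
      stop("exon chromosome mismatch for gene ", ids[i])
    s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
    if (is.unsorted(s) || any(s[-1] <= e[-length(e)]))
      stop("exons of gene ", ids[i], " overlap or are unsorted")
    if (min(s) < GenomicRanges::start(genes)[i] ||
        max(e) > GenomicRanges::end(genes)[i])
      stop("exon outside gene body for gene ", ids[i])
  }
  tss <- ifelse(st == "+", GenomicRanges::start(genes), GenomicRanges::end(genes))
  tts <- ifelse(st == "+", GenomicRanges::end(genes), GenomicRanges::start(genes))
  S4Vectors::mcols(genes)$tss <- as.integer(tss)
  S4Vectors::mcols(genes)$tts <- as.integer(tts)
  names(exons) <- ids
  structure(list(genes = genes, exons = exons), class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d genes on %d chromosome(s)\n",
              length(x$genes),
              length(unique(as.character(GenomicRanges::seqnames(x$genes))))))
  invisible(x)
}

#' Number of genes in a GeneModels object
#' @param x A `GeneModels` object.
#' @export
length.GeneModels <- function(x) length(x$genes)

#' Gene ids of a GeneModels object
#' @param x A `GeneModels` object.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) names(x$genes)

#' Read gene models from BED12
#'
#' BED12 blocks define exons.  Genes must be stranded; duplicate gene ids,
#' overlapping blocks or blocks outside the gene body are rejected with the
#' offending gene named.
#'
#' @param path BED12 file (optionally gzipped).
#' @param sizes Named vector of chromosome lengths.
#' @return A `GeneModels` object.
#' @export
read_gene_models <- function(path, sizes) {
  assert_chrom_sizes(sizes)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("no genes in ", path)
  if (is.null(S4Vectors::mcols(gr)$blocks))
    stop("gene file must be BED12 (blocks define exons): ", path)
  bad <- !as.character(GenomicRanges::seqnames(gr)) %in% names(sizes)
  if (any(bad))
    stop("gene(s) on chromosome absent from sizes: ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]), collapse = ", "))
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids) || any(is.na(ids) | !nzchar(ids)))
    stop("every gene needs a name (column 4): ", path)
  blocks <- S4Vectors::mcols(gr)$blocks  # 1-based, relative to range start
  exons <- GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(gr))[i],
      IRanges::shift(b, GenomicRanges::start(gr)[i] - 1L),
      strand = as.character(GenomicRanges::strand(gr))[i])
  }))
  body <- GenomicRanges::granges(gr)
  names(body) <- ids
  body <- set_genome(body, sizes)
  gene_models(body, exons)
}

#' Write gene models to BED12
#'
#' @param gm A `GeneModels` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes
  out <- GenomicRanges::granges(g)
  S4Vectors::mcols(out)$name <- names(g)
  S4Vectors::mcols(out)$score <- 0L
  S4Vectors::mcols(out)$thick <- IRanges::ranges(out)
  rel <- IRanges::IRangesList(lapply(seq_along(g), function(i) {
    IRanges::shift(IRanges::ranges(gm$exons[[i]]), -(GenomicRanges::start(g)[i] - 1L))
  }))
  S4Vectors::mcols(out)$blocks <- rel
  names(out) <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read CpG islands from BED
#'
#' @param path BED (>= 3 columns) file of CpG islands.
#' @param sizes Named vector of chromosome lengths.
#' @return Unstranded `GRanges`; `mcols()$center` holds the 1-based midpoint
#'   position `floor((start0 + end0) / 2) + 1` used as the profile anchor.
#' @export
read_cpg_islands <- function(path, sizes) {
  assert_chrom_sizes(sizes)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("no CpG islands in ", path)
  bad <- !as.character(GenomicRanges::seqnames(gr)) %in% names(sizes)
  if (any(bad)) stop("CpG island(s) on unknown chromosome in ", path)
  GenomicRanges::strand(gr) <- "*"
  gr <- set_genome(gr, sizes)
  S4Vectors::mcols(gr)$center <- cpg_centers(gr)
  gr
}

#' Midpoint positions of intervals
#'
#' 1-based position of `floor((start0 + end0) / 2)` in BED (0-based)
#' coordinates, i.e. the integer midpoint of the island.
#'
#' @param gr A `GRanges`.
#' @return Integer vector of 1-based center positions.
#' @export
cpg_centers <- function(gr) {
  as.integer(floor(((GenomicRanges::start(gr) - 1L) + GenomicRanges::end(gr)) / 2) + 1L)
}

#' Read a two-column expression table
#'
#' @param path TSV with columns `gene_id` and a numeric mean expression
#'   (header optional; detected).
#' @return Named numeric vector of mean expression values.
#' @export
read_expression_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs 2 columns: ", path)
  vals <- as.numeric(tab[[2]])
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene_id in expression table: ", path)
  if (any(!is.finite(vals))) stop("non-finite expression value in ", path)
  stats::setNames(vals, ids)
}

#' Write a two-column expression table
#'
#' @param expr Named numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(
    data.frame(gene_id = names(expr), mean_expression = unname(expr)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
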