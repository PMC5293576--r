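# Single-process pipeline orchestration: simulate -> pileup -> profiles ->
# diff-peaks -> amplify -> link-expression -> report, under one
# configuration with a deterministic JSON manifest (input/output md5 hashes
# per stage) and hash-based stage caching.

#' Pipeline configuration
#'
#' Assembles the per-stage parameter objects and input paths.  When
#' `simulate` is a [sim_config()], stage inputs are generated; otherwise
#' the `inputs` list must point at existing files (`chrom_sizes`,
#' `reads_control`, `reads_case`, optionally `genes`, `cpg`, `expression`,
#' and externally called `peaks_control`/`peaks_case`).
#'
#' @param simulate A [sim_config()] or `NULL`.
#' @param inputs Named list of input paths (ignored where simulate provides
#'   them).
#' @param shift A [shift_params()].
#' @param scheme A [region_scheme()].
#' @param amplification An [amplification_params()].
#' @param caller List of stand-in caller settings (`min_value`,
#'   `min_width`, `merge_gap`), used only when no peak files are given.
#' @param profile_half_window Half window for meta-profiles (bp).
#' @param cpg_window CpG t-test window (bp).
#' @param marker_genes Character vector of marker gene ids for the report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            inputs = list(),
                            shift = shift_params(),
                            scheme = region_scheme(),
                            amplification = amplification_params(),
                            caller = list(min_value = 5, min_width = 100L,
                                          merge_gap = 50L),
                            profile_half_window = 3000L,
                            cpg_window = 500L,
                            marker_genes = character(0)) {
  structure(list(simulate = simulate, inputs = inputs, shift = shift,
                 scheme = scheme, amplification = amplification,
                 caller = caller,
                 profile_half_window = as.integer(profile_half_window),
                 cpg_window = as.integer(cpg_window),
                 marker_genes = marker_genes),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] (`simulate`, `inputs`, `shift`, `scheme`,
#' `amplification`, `caller`, `profile_half_window`, `cpg_window`,
#' `marker_genes`); nested keys mirror the corresponding constructor
#' arguments.  Omitted keys take the package defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$genome)) y$simulate$genome <- unlist(y$simulate$genome)
    do.call(sim_config, y$simulate)
  } else NULL
  pipeline_config(
    simulate = sim,
    inputs = y$inputs %||% list(),
    shift = do.call(shift_params, y$shift %||% list()),
    scheme = do.call(region_scheme, y$scheme %||% list()),
    amplification = do.call(amplification_params, y$amplification %||% list()),
    caller = utils::modifyList(list(min_value = 5, min_width = 100L,
                                    merge_gap = 50L), y$caller %||% list()),
    profile_half_window = y$profile_half_window %||% 3000L,
    cpg_window = y$cpg_window %||% 500L,
    marker_genes = unlist(y$marker_genes) %||% character(0))
}

# Strip non-serializable attributes for stable JSON parameter snapshots.
param_snapshot <- function(x) {
  if (inherits(x, "sim_config")) x$genome <- as.list(x$genome)
  lapply(unclass(x), function(v) if (is.null(v)) "none" else v)
}

file_hashes <- function(paths) {
  if (length(paths) == 0L) return(stats::setNames(list(), character(0)))
  h <- as.list(unname(tools::md5sum(unlist(paths))))
  names(h) <- names(paths)
  h
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order, writing each stage's artifacts
#' under `outdir` and recording a manifest entry (parameters, input md5
#' hashes, output md5 hashes) per stage.  A stage whose parameters and
#' input hashes match the existing manifest and whose outputs are intact is
#' skipped ("cached").  With a fixed simulation seed the run is fully
#' deterministic: manifests of two runs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (as written), `status`
#'   (per-stage `"done"`/`"cached"`) and `results` (in-memory objects of
#'   the main stages).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  manifest <- list()
  status <- list()
  results <- list()

  rel <- function(p) sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", outdir), "/?"),
                         "", p)
  hash_rel <- function(paths) {
    h <- file_hashes(paths)
    names(h) <- rel(unlist(paths)) %||% character(0)
    h
  }
  cached_ok <- function(name, params_json, in_paths) {
    old <- old_manifest[[name]]
    if (is.null(old)) return(FALSE)
    if (!identical(jsonlite::toJSON(old$params, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(params_json, auto_unbox = TRUE, digits = NA)))
      return(FALSE)
    if (!all(vapply(unlist(in_paths), file.exists, logical(1)) %||% logical(0)))
      return(FALSE)
    if (!identical(unlist(old$inputs), unlist(hash_rel(in_paths))))
      return(FALSE)
    outs <- unlist(old$outputs)
    paths <- file.path(outdir, names(outs))
    if (!all(file.exists(paths))) return(FALSE)
    identical(unname(tools::md5sum(paths)), unname(outs))
  }
  record <- function(name, params_json, in_paths, out_paths) {
    manifest[[name]] <<- list(params = params_json,
                              inputs = hash_rel(in_paths),
                              outputs = hash_rel(out_paths))
  }

  # --- stage: simulate -------------------------------------------------
  inputs <- config$inputs
  if (!is.null(config$simulate)) {
    fixdir <- file.path(outdir, "fixtures")
    params_json <- param_snapshot(config$simulate)
    expected <- list(chrom_sizes = file.path(fixdir, "chrom.sizes"),
                     genes = file.path(fixdir, "genes.bed"),
                     cpg = file.path(fixdir, "cpg.bed"),
                     reads_control = file.path(fixdir, "reads_control.bed.gz"),
                     reads_case = file.path(fixdir, "reads_case.bed.gz"),
                     expression = file.path(fixdir, "expression.tsv"),
                     truth = file.path(fixdir, "truth.json"))
    if (cached_ok("simulate", params_json, list())) {
      status$simulate <- "cached"
      manifest$simulate <- old_manifest$simulate
    } else {
      sim <- simulate_chipseq(config$simulate, dir = fixdir)
      status$simulate <- "done"
      record("simulate", params_json, list(), expected)
    }
    inputs <- utils::modifyList(expected, inputs)
  } else if (is.null(inputs$chrom_sizes) || is.null(inputs$reads_control) ||
             is.null(inputs$reads_case)) {
    stop("without a simulate block, inputs must provide chrom_sizes, reads_control and reads_case")
  }
  for (key in c("chrom_sizes", "reads_control", "reads_case")) {
    if (!file.exists(inputs[[key]]))
      stop("pipeline prerequisite missing for stage pileup: ", key, " (",
           inputs[[key]], ")")
  }

  sizes <- read_chrom_sizes(inputs$chrom_sizes)
  gm <- if (!is.null(inputs$genes)) {
    if (!file.exists(inputs$genes))
      stop("pipeline prerequisite missing for stage diff_peaks: genes (",
           inputs$genes, ")")
    read_gene_models(inputs$genes, sizes)
  } else NULL
  cpg <- if (!is.null(inputs$cpg)) read_cpg_islands(inputs$cpg, sizes) else NULL

  # --- stage: pileup ---------------------------------------------------
  pu_params <- list(shift = param_snapshot(config$shift),
                    dedup = config$amplification$dedup)
  pu_out <- list(control = file.path(outdir, "control.bedgraph"),
                 control_meta = file.path(outdir, "control.bedgraph.json"),
                 case = file.path(outdir, "case.bedgraph"),
                 case_meta = file.path(outdir, "case.bedgraph.json"))
  pu_in <- inputs[c("chrom_sizes", "reads_control", "reads_case")]
  run_pileup <- function() {
    reads_c <- read_reads_bed(inputs$reads_control, sizes)
    reads_t <- read_reads_bed(inputs$reads_case, sizes)
    if (config$amplification$dedup) {
      reads_c <- dedup_reads(reads_c)
      reads_t <- dedup_reads(reads_t)
    }
    tc <- normalize_track(pileup(reads_c, config$shift, sizes))
    tt <- normalize_track(pileup(reads_t, config$shift, sizes))
    write_bedgraph(tc, pu_out$control)
    write_bedgraph(tt, pu_out$case)
    list(control = tc, case = tt)
  }
  if (cached_ok("pileup", pu_params, pu_in)) {
    status$pileup <- "cached"
    manifest$pileup <- old_manifest$pileup
    tracks <- list(control = read_bedgraph(pu_out$control),
                   case = read_bedgraph(pu_out$case))
  } else {
    tracks <- run_pileup()
    status$pileup <- "done"
    record("pileup", pu_params, pu_in, pu_out)
  }
  results$tracks <- tracks

  # --- stage: profiles -------------------------------------------------
  if (!is.null(gm)) {
    pr_params <- list(half_window = config$profile_half_window,
                      cpg_window = config$cpg_window)
    pr_out <- list(tss = file.path(outdir, "profile_tss.tsv"),
                   tts = file.path(outdir, "profile_tts.tsv"),
                   counts_control = file.path(outdir, "tss_counts_control.tsv"),
                   counts_case = file.path(outdir, "tss_counts_case.tsv"))
    if (!is.null(cpg)) {
      pr_out$cpg <- file.path(outdir, "profile_cpg.tsv")
      pr_out$cpg_ttest <- file.path(outdir, "cpg_ttest.json")
    }
    pr_in <- inputs[c("chrom_sizes", "reads_control", "reads_case", "genes")]
    if (!is.null(cpg)) pr_in$cpg <- inputs$cpg
    if (cached_ok("profiles", pr_params, pr_in)) {
      status$profiles <- "cached"
      manifest$profiles <- old_manifest$profiles
      counts <- list(
        control = utils::read.table(pr_out$counts_control, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE),
        case = utils::read.table(pr_out$counts_case, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE))
      cpg_test <- if (!is.null(cpg)) {
        j <- jsonlite::read_json(pr_out$cpg_ttest, simplifyVector = TRUE)
        structure(j, class = "cpg_ttest")
      } else NULL
    } else {
      wtsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                                 quote = FALSE, row.names = FALSE)
      wtsv(meta_profile(tracks$case, tss_anchors(gm), config$profile_half_window),
           pr_out$tss)
      wtsv(meta_profile(tracks$case, tts_anchors(gm), config$profile_half_window),
           pr_out$tts)
      counts <- list(control = tss_vicinity_counts(tracks$control, gm),
                     case = tss_vicinity_counts(tracks$case, gm))
      wtsv(counts$control, pr_out$counts_control)
      wtsv(counts$case, pr_out$counts_case)
      cpg_test <- NULL
      if (!is.null(cpg)) {
        wtsv(meta_profile(tracks$case, cpg_anchors(cpg),
                          config$profile_half_window), pr_out$cpg)
        cpg_test <- cpg_window_ttest(tracks$control, tracks$case, cpg,
                                     window = config$cpg_window)
        jsonlite::write_json(unclass(cpg_test), pr_out$cpg_ttest,
                             auto_unbox = TRUE, digits = NA)
      }
      status$profiles <- "done"
      record("profiles", pr_params, pr_in, pr_out)
    }
    results$tss_counts <- counts
    results$cpg_ttest <- cpg_test
  }

  # --- stage: diff_peaks -----------------------------------------------
  if (!is.null(gm)) {
    dp_params <- list(scheme = param_snapshot(config$scheme),
                      caller = config$caller,
                      external_peaks = !is.null(inputs$peaks_control))
    dp_out <- list(gain_loss = file.path(outdir, "gain_loss.tsv"),
                   overlap = file.path(outdir, "peak_overlap.json"),
                   peaks_control = file.path(outdir, "peaks_control.bed"),
                   peaks_case = file.path(outdir, "peaks_case.bed"))
    dp_in <- inputs[c("chrom_sizes", "reads_control", "reads_case", "genes")]
    if (!is.null(inputs$peaks_control)) {
      dp_in$peaks_control <- inputs$peaks_control
      dp_in$peaks_case <- inputs$peaks_case
    }
    if (cached_ok("diff_peaks", dp_params, dp_in)) {
      status$diff_peaks <- "cached"
      manifest$diff_peaks <- old_manifest$diff_peaks
      gain_loss <- utils::read.table(dp_out$gain_loss, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
    } else {
      if (!is.null(inputs$peaks_control)) {
        pk_c <- read_peaks(inputs$peaks_control, "control", sizes)
        pk_t <- read_peaks(inputs$peaks_case, "case", sizes)
      } else {
        pk_c <- standin_call_peaks(tracks$control,
                                   min_value = config$caller$min_value,
                                   min_width = config$caller$min_width,
                                   merge_gap = config$caller$merge_gap,
                                   sample_label = "control")
        pk_t <- standin_call_peaks(tracks$case,
                                   min_value = config$caller$min_value,
                                   min_width = config$caller$min_width,
                                   merge_gap = config$caller$merge_gap,
                                   sample_label = "case")
      }
      gain_loss <- classify_gain_loss(assign_peaks(pk_c, gm, config$scheme),
                                      assign_peaks(pk_t, gm, config$scheme))
      utils::write.table(gain_loss, dp_out$gain_loss, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ov <- if (length(pk_c) && length(pk_t)) overlap_summary(pk_c, pk_t)
            else NULL
      jsonlite::write_json(if (is.null(ov)) list() else unclass(ov),
                           dp_out$overlap, auto_unbox = TRUE, digits = NA)
      rtracklayer::export(pk_c, dp_out$peaks_control, format = "BED")
      rtracklayer::export(pk_t, dp_out$peaks_case, format = "BED")
      status$diff_peaks <- "done"
      record("diff_peaks", dp_params, dp_in, dp_out)
      results$peaks <- list(control = pk_c, case = pk_t)
      results$overlap <- ov
    }
    results$gain_loss <- gain_loss
  }

  # --- stage: amplify --------------------------------------------------
  amp_params <- param_snapshot(config$amplification)
  amp_out <- list(regions = file.path(outdir, "amplified_regions.tsv"),
                  bed = file.path(outdir, "amplified_regions.bed"))
  if (!is.null(gm)) amp_out$genes <- file.path(outdir, "amplified_genes.tsv")
  amp_in <- inputs[c("chrom_sizes", "reads_control", "reads_case")]
  if (cached_ok("amplify", amp_params, amp_in)) {
    status$amplify <- "cached"
    manifest$amplify <- old_manifest$amplify
    amp <- utils::read.table(amp_out$regions, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    amp_genes <- if (!is.null(gm))
      utils::read.table(amp_out$genes, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
  } else {
    amp <- scan_amplified(tracks$case, tracks$control, config$amplification)
    utils::write.table(amp, amp_out$regions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    bed <- if (nrow(amp))
      sprintf("%s\t%d\t%d\tamp%d\t%.4f", amp$chrom, amp$start - 1L, amp$end,
              seq_len(nrow(amp)), -log10(pmax(amp$p_value, 1e-300)))
    else character(0)
    writeLines(bed, amp_out$bed)
    amp_genes <- NULL
    if (!is.null(gm)) {
      amp_genes <- annotate_amplified(amp, gm)
      utils::write.table(amp_genes, amp_out$genes, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    status$amplify <- "done"
    record("amplify", amp_params, amp_in, amp_out)
  }
  results$amplified <- amp
  results$amplified_genes <- amp_genes

  # --- stage: link_expression ------------------------------------------
  if (!is.null(gm) && !is.null(inputs$expression) &&
      file.exists(inputs$expression)) {
    le_params <- list(log_transform = TRUE)
    le_out <- list(json = file.path(outdir, "expression_link.json"))
    le_in <- inputs[c("chrom_sizes", "reads_case", "genes", "expression")]
    if (cached_ok("link_expression", le_params, le_in)) {
      status$link_expression <- "cached"
      manifest$link_expression <- old_manifest$link_expression
      expr_link <- jsonlite::read_json(le_out$json, simplifyVector = TRUE)
    } else {
      expr <- read_expression_table(inputs$expression)
      expr_link <- signal_expression_correlation(results$tss_counts$case, expr)
      jsonlite::write_json(expr_link, le_out$json, auto_unbox = TRUE,
                           digits = NA)
      status$link_expression <- "done"
      record("link_expression", le_params, le_in, le_out)
    }
    results$expression_link <- expr_link
  }

  # --- stage: report ---------------------------------------------------
  if (!is.null(gm)) {
    rp_params <- list(marker_genes = as.list(config$marker_genes))
    rp_out <- list(json = file.path(outdir, "report.json"))
    rp_in <- inputs[c("chrom_sizes", "reads_control", "reads_case", "genes")]
    if (cached_ok("report", rp_params, rp_in)) {
      status$report <- "cached"
      manifest$report <- old_manifest$report
      report <- jsonlite::read_json(rp_out$json, simplifyVector = TRUE)
    } else {
      report <- subgroup_evidence_report(
        tracks$case, tracks$control, gm,
        marker_ids = config$marker_genes,
        amplified = results$amplified_genes,
        cpg_test = results$cpg_ttest)
      jsonlite::write_json(unclass(report), rp_out$json, auto_unbox = TRUE,
                           digits = NA, dataframe = "columns", force = TRUE)
      status$report <- "done"
      record("report", rp_params, rp_in, rp_out)
    }
    results$report <- report
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, status = status, results = results))
}
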