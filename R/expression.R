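# Linking promoter H3K4me3 signal to expression: signal-expression
# correlation over the shared gene universe, and a two-gene-set expression
# comparison (e.g. homeobox vs cadherin families).

#' Correlation between promoter signal and expression
#'
#' Pearson correlation over the intersection of gene ids, optionally on
#' `log(1 + x)`-transformed values (the default, since both ChIP signal and
#' expression are heavy-tailed).
#'
#' @param counts Per-gene signal: `data.frame(gene_id, count)` as returned
#'   by [tss_vicinity_counts()], or a named numeric vector.
#' @param expr Named numeric vector of mean expression (see
#'   [read_expression_table()]).
#' @param log_transform Apply `log1p` to both variables (default TRUE).
#' @return List with `r`, `n`, and `log_transform`.  `r` is `NA` with a
#'   warning when either variable has zero variance.
#' @export
signal_expression_correlation <- function(counts, expr, log_transform = TRUE) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$count, counts$gene_id)
  ids <- intersect(names(counts), names(expr))
  if (length(ids) < 3L)
    stop("need >= 3 genes shared between counts and expression (got ",
         length(ids), ")")
  x <- as.numeric(counts[ids])
  y <- as.numeric(expr[ids])
  if (log_transform) { x <- log1p(x); y <- log1p(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(x, y)
  }
  list(r = r, n = length(ids), log_transform = log_transform)
}

#' Compare expression between two gene sets
#'
#' Summarizes each set's expression and tests the difference with a
#' two-sided Wilcoxon rank-sum test by default (expression distributions
#' are typically heavy-tailed); `test = "t"` gives a Welch t-test instead.
#'
#' @param expr Named numeric vector of mean expression.
#' @param set_a,set_b Character vectors of gene ids (each must intersect
#'   `expr` in >= 2 genes).
#' @param name_a,name_b Labels used in messages and output.
#' @param test `"ranksum"` (default) or `"t"`.
#' @return List with per-set `n`, `mean`, `median`, the test `statistic`,
#'   `p_value`, a `direction` flag (`"a < b"`, `"a > b"` or `"tie"`, by
#'   median), and the test used.
#' @export
gene_set_comparison <- function(expr, set_a, set_b, name_a = "set_a",
                                name_b = "set_b",
                                test = c("ranksum", "t")) {
  test <- match.arg(test)
  va <- expr[intersect(set_a, names(expr))]
  vb <- expr[intersect(set_b, names(expr))]
  if (length(va) < 2L)
    stop("gene set '", name_a, "' shares fewer than 2 genes with the expression table")
  if (length(vb) < 2L)
    stop("gene set '", name_b, "' shares fewer than 2 genes with the expression table")
  res <- if (test == "ranksum")
    suppressWarnings(stats::wilcox.test(va, vb, alternative = "two.sided"))
  else stats::t.test(va, vb)
  ma <- stats::median(va); mb <- stats::median(vb)
  direction <- if (ma < mb) "a < b" else if (ma > mb) "a > b" else "tie"
  list(name_a = name_a, name_b = name_b,
       n_a = length(va), n_b = length(vb),
       mean_a = mean(va), mean_b = mean(vb),
       median_a = ma, median_b = mb,
       statistic = unname(res$statistic), p_value = res$p.value,
       direction = direction, test = test)
}
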