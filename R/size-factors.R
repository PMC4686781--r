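#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample correcting for sequencing
#' depth and library composition. For each gene positive in every sample, a
#' per-sample ratio to the gene's geometric mean across samples is formed;
#' the size factor of a sample is the median of these ratios. When no gene
#' is positive in all samples the estimator falls back to ratios of column
#' totals (rescaled to geometric mean one), with a warning.
#'
#' @param counts A counts tibble (`gene_id` column plus one numeric column
#'   per sample).
#' @return A tibble with columns `sample_id`, `size_factor`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"),
#'                          s1 = c(10, 30), s2 = c(20, 60))
#' estimate_size_factors(counts)
estimate_size_factors <- function(counts) {
  validate_count_matrix(counts, allow_fractional = TRUE)
  m <- counts_matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (any(ref)) {
    logm <- log(m[ref, , drop = FALSE])
    loggeo <- rowMeans(logm)
    s <- apply(exp(logm - loggeo), 2, stats::median)
  } else {
    warn("no gene is positive in all samples; falling back to total-count ratios")
    tot <- colSums(m)
    if (any(tot == 0)) abort("a sample has zero total counts; size factors undefined")
    s <- tot / exp(mean(log(tot)))
  }
  tibble(sample_id = colnames(m), size_factor = unname(s))
}
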