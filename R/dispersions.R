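#' Per-gene method-of-moments dispersion estimates
#'
#' Estimates the negative-binomial overdispersion `alpha` in the variance
#' model `Var = mu + alpha * mu^2` for every gene. Counts are first divided
#' by their sample's size factor; the within-line (replicate-group) sample
#' variance is pooled across lines so that real biological differences
#' between lines do not inflate the estimate, and the method-of-moments
#' estimator
#' `alpha_hat = (s2 - mu_bar) / mu_bar^2`
#' is clamped to `[alpha_min, alpha_max]`. `mu_bar` is the grand mean of
#' normalized counts. Genes with zero mean receive `alpha_min`. No
#' empirical-Bayes shrinkage is applied; the estimator is deliberately
#' transparent.
#'
#' @param counts A counts tibble.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param sheet Sample sheet defining the replicate groups (lines); every
#'   line needs at least two replicates.
#' @param alpha_min,alpha_max Clamp bounds (defaults `1e-8`, `10`).
#' @return A tibble with columns `gene_id`, `dispersion`.
#' @export
estimate_dispersions <- function(counts, size_factors, sheet,
                                 alpha_min = 1e-8, alpha_max = 10) {
  validate_count_matrix(counts, allow_fractional = TRUE)
  validate_sample_sheet(sheet, counts = counts)
  m <- counts_matrix(counts)[, sheet$sample_id, drop = FALSE]
  s <- size_factors$size_factor[match(sheet$sample_id, size_factors$sample_id)]
  if (anyNA(s)) abort("size factors missing for some samples in the sheet")
  y <- sweep(m, 2, s, "/")

  grand_mean <- rowMeans(y)
  groups <- split(seq_len(ncol(y)), sheet$line_id)
  ss <- 0
  df <- 0
  for (idx in groups) {
    yg <- y[, idx, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
    df <- df + length(idx) - 1
  }
  pooled_var <- ss / df
  alpha <- (pooled_var - grand_mean) / grand_mean^2
  alpha[!is.finite(alpha)] <- alpha_min
  alpha <- pmin(pmax(alpha, alpha_min), alpha_max)
  tibble(gene_id = rownames(m), dispersion = unname(alpha))
}
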