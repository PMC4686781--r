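# Vectorized Newton fit of the per-gene NB group mean on the log scale.
# For gene g with counts K_gj, offsets s_j and fixed dispersion alpha_g the
# log-link score in eta = log q is
#   U(eta) = sum_j (K_gj - mu_gj) / (1 + alpha_g * mu_gj),  mu_gj = s_j e^eta
# and the Fisher information is I(eta) = sum_j mu_gj / (1 + alpha_g * mu_gj).
# Rows that are all zero are pinned at the pseudo-mean floor.
fit_nb_group <- function(K, s, alpha, mu_floor = 1e-8) {
  n_gene <- nrow(K)
  eta <- log(pmax(rowSums(K) / sum(s), mu_floor))
  zero <- rowSums(K) == 0
  active <- which(!zero)
  for (it in seq_len(100)) {
    if (length(active) == 0) break
    mu <- exp(eta[active]) %o% s
    denom <- 1 + alpha[active] * mu
    U <- rowSums((K[active, , drop = FALSE] - mu) / denom)
    I <- rowSums(mu / denom)
    step <- pmin(pmax(U / I, -2), 2)
    eta[active] <- eta[active] + step
    active <- active[abs(step) > 1e-12]
  }
  mu <- exp(eta) %o% s
  info <- rowSums(mu / (1 + alpha * mu))
  list(q = unname(exp(eta)), info = unname(info), all_zero = unname(zero))
}

#' Negative-binomial Wald test between two sample groups
#'
#' Fits, per gene, a two-group negative-binomial model with log link and
#' size-factor offsets at a fixed per-gene dispersion, and tests the log2
#' fold change of group `b` versus group `a` with a Wald statistic. The
#' group means are maximum-likelihood estimates; the standard error of the
#' log fold change comes from the Fisher information of each group fit.
#' P-values are two-sided normal tails and are Benjamini-Hochberg adjusted
#' within the contrast. Genes with zero counts in both groups are reported
#' with `log2fc = 0`, `pvalue = 1` and flag `"untestable"`, and are excluded
#' from the adjustment denominator; genes with one all-zero group have that
#' group's mean floored at a pseudo-mean `mu_floor` and are flagged
#' `"extreme"` rather than reported as infinite.
#'
#' @param counts A counts tibble.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @param dispersions Tibble from [estimate_dispersions()].
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   length >= 2. `group_a` is the reference: positive `log2fc` means
#'   higher expression in `group_b`.
#' @param label Contrast label stored on the result (default
#'   `"b_vs_a"`-style from the group arguments).
#' @param mu_floor Pseudo-mean floor used when a group is all zero.
#' @return A tibble of class `reprog_de` with one row per gene: `gene_id`,
#'   `base_mean_a`, `base_mean_b` (normalized group means), `log2fc`, `se`,
#'   `wald_z`, `pvalue`, `qvalue`, `flag`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, group_a, group_b,
                         label = NULL, mu_floor = 1e-8) {
  validate_count_matrix(counts, allow_fractional = TRUE)
  if (length(intersect(group_a, group_b)) > 0) abort("contrast groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each contrast group needs at least 2 samples")
  }
  absent <- setdiff(c(group_a, group_b), count_sample_ids(counts))
  if (length(absent) > 0) {
    abort(sprintf("contrast sample '%s' not found in count matrix", absent[1]))
  }
  m <- counts_matrix(counts)
  alpha <- dispersions$dispersion[match(counts$gene_id, dispersions$gene_id)]
  if (anyNA(alpha)) abort("dispersions missing for some genes")
  sf <- function(ids) size_factors$size_factor[match(ids, size_factors$sample_id)]
  sa <- sf(group_a); sb <- sf(group_b)
  if (anyNA(sa) || anyNA(sb)) abort("size factors missing for contrast samples")

  fa <- fit_nb_group(m[, group_a, drop = FALSE], sa, alpha, mu_floor)
  fb <- fit_nb_group(m[, group_b, drop = FALSE], sb, alpha, mu_floor)

  untestable <- fa$all_zero & fb$all_zero
  extreme <- xor(fa$all_zero, fb$all_zero)

  log2fc <- log2(fb$q) - log2(fa$q)
  se <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))

  log2fc[untestable] <- 0
  z[untestable] <- 0
  p[untestable] <- 1
  se[untestable] <- NA_real_

  q <- rep(1, length(p))
  q[!untestable] <- bh_adjust(p[!untestable])

  out <- tibble(
    gene_id = counts$gene_id,
    base_mean_a = fa$q, base_mean_b = fb$q,
    log2fc = log2fc, se = se, wald_z = z,
    pvalue = p, qvalue = q,
    flag = dplyr::case_when(untestable ~ "untestable",
                            extreme ~ "extreme",
                            TRUE ~ "ok")
  )
  attr(out, "contrast") <- label %||% "b_vs_a"
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  class(out) <- c("reprog_de", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; returned q-values satisfy
#' `q >= p`, are capped at 1 and are monotone in `p`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @exportS3Method generics::tidy
tidy.reprog_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "reprog_de")
  out
}

#' @exportS3Method generics::glance
glance.reprog_de <- function(x, alpha_sig = 0.05, ...) {
  tibble(
    contrast = attr(x, "contrast"),
    n_genes = nrow(x),
    n_testable = sum(x$flag != "untestable"),
    n_significant = sum(x$qvalue < alpha_sig & x$flag != "untestable"),
    alpha_sig = alpha_sig
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.reprog_de <- function(object, alpha_sig = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$flag != "untestable") |>
    dplyr::mutate(significant = .data$qvalue < alpha_sig)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$pvalue, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}
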