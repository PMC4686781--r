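# In-code fixtures shared across test files.

# Counts tibble from a plain matrix (adds ids when absent).
make_counts <- function(m, gene_ids = NULL, sample_ids = NULL) {
  if (!is.null(gene_ids)) rownames(m) <- gene_ids
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  if (!is.null(sample_ids)) colnames(m) <- sample_ids
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

# The five-line, three-replicate study sheet over given sample ids.
study_sheet <- function(sample_ids = sprintf("%s_r%d",
                                             rep(c("EF", "ES1", "ES2", "iPS1", "iPS2"), each = 3),
                                             rep(1:3, 5))) {
  tibble::tibble(
    sample_id = sample_ids,
    line_id = sub("_r[0-9]+$", "", sample_ids),
    cell_class = dplyr::case_when(
      grepl("^EF", sample_ids) ~ "fibroblast",
      grepl("^ES", sample_ids) ~ "es",
      TRUE ~ "ips"),
    replicate = as.integer(sub("^.*_r", "", sample_ids)))
}

# Full five-line null experiment: every line shares one mean. Dispersions
# are then estimated exactly as the pipeline does, from all 15 samples.
null_experiment <- function(n_genes, mu = 100, alpha = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * 15, mu = mu, size = 1 / alpha),
              nrow = n_genes)
  counts <- make_counts(m, gene_ids = sprintf("g%05d", seq_len(n_genes)),
                        sample_ids = study_sheet()$sample_id)
  list(counts = counts, sheet = study_sheet())
}

unit_size_factors <- function(sample_ids) {
  tibble::tibble(sample_id = sample_ids, size_factor = 1)
}

# A synthetic DE-result tibble with the columns the classifier consumes.
fake_de <- function(gene_id, qvalue, base_mean_a = 100, base_mean_b = 100,
                    flag = "ok") {
  tibble::tibble(gene_id = gene_id, base_mean_a = base_mean_a,
                 base_mean_b = base_mean_b,
                 log2fc = log2(base_mean_b / base_mean_a),
                 se = 1, wald_z = 0, pvalue = qvalue, qvalue = qvalue,
                 flag = flag)
}

# Independent step-up BH oracle, straight from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in seq(n - 1, 1, length.out = max(n - 1, 0))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Independent median-of-ratios oracle using explicit loops.
size_factor_oracle <- function(m) {
  ref <- which(apply(m, 1, function(r) all(r > 0)))
  s <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(length(ref))
    for (i in seq_along(ref)) {
      g <- m[ref[i], ]
      ratios[i] <- m[ref[i], j] / exp(mean(log(g)))
    }
    s[j] <- stats::median(ratios)
  }
  s
}
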