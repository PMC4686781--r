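#' Simulation configuration
#'
#' Builds the configuration for [generate_experiment()]. The default is the
#' documented strong-signal design mirroring a five-line study (one
#' fibroblast line, two ES lines, two iPS lines, three replicates each):
#' 6000 genes of which 1500 carry a fibroblast-versus-ES signature with
#' |log2 fold change| 4, planted iPS categories in proportions
#' 0.80 / 0.07 / 0.07 / 0.06 (correct / intermediate / not reprogrammed /
#' novel), NB dispersion 0.05, log-normal baseline means centred on 200,
#' and per-sample library-size factors drawn uniformly from `[0.7, 1.4]`.
#'
#' @param n_genes Total genes.
#' @param n_signature Signature genes (`<= n_genes`).
#' @param proportions Named or ordered numeric of length 4 (correct,
#'   intermediate, not_reprogrammed, novel), non-negative, summing to 1.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   fibroblast baseline mean.
#' @param log2fc Absolute planted log2 fold change between fibroblast and
#'   ES means for signature genes (direction random per gene).
#' @param dispersion NB dispersion `alpha` (`Var = mu + alpha mu^2`); 0
#'   gives Poisson counts.
#' @param libsize_range Range of per-sample library-size factors.
#' @param n_replicates Replicates per line (>= 2).
#' @param n_ips_lines Number of iPS lines.
#' @param es_line_effect Multiplicative factor applied to the second ES
#'   line's means (1 = the two ES lines are exact replicates in
#'   expectation).
#' @param novel_factor How far outside the fibroblast-ES interval a novel
#'   gene is planted (default 4-fold).
#' @param category_cor Correlation of planted categories across iPS lines:
#'   each gene draws a base category, kept per line with this probability
#'   and redrawn otherwise (marginals preserved). The default 0.6 matches
#'   the degree of category sharing reported between sibling iPS lines.
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 6000, n_signature = 1500,
                       proportions = c(correct = 0.80, intermediate = 0.07,
                                       not_reprogrammed = 0.07, novel = 0.06),
                       baseline_meanlog = log(200), baseline_sdlog = 1,
                       log2fc = 4, dispersion = 0.05,
                       libsize_range = c(0.7, 1.4),
                       n_replicates = 3, n_ips_lines = 2,
                       es_line_effect = 1, novel_factor = 4,
                       category_cor = 0.6, seed = 76543) {
  cfg <- list(n_genes = n_genes, n_signature = n_signature,
              proportions = stats::setNames(unname(proportions), gene_categories),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              log2fc = log2fc, dispersion = dispersion,
              libsize_range = libsize_range,
              n_replicates = n_replicates, n_ips_lines = n_ips_lines,
              es_line_effect = es_line_effect, novel_factor = novel_factor,
              category_cor = category_cor, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1 || n_signature > n_genes) {
      abort("need 1 <= n_signature <= n_genes")
    }
    if (length(proportions) != 4 || any(proportions < 0) ||
        abs(sum(proportions) - 1) > 1e-8) {
      abort("proportions must be 4 non-negative numbers summing to 1")
    }
    if (dispersion < 0) abort("dispersion must be >= 0")
    if (n_replicates < 2) abort("n_replicates must be >= 2")
    if (n_ips_lines < 1) abort("need at least one iPS line")
    if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
        libsize_range[1] > libsize_range[2]) {
      abort("libsize_range must be a positive (lo, hi) pair")
    }
    if (novel_factor <= 1) abort("novel_factor must exceed 1")
    if (category_cor < 0 || category_cor > 1) {
      abort("category_cor must lie in [0, 1]")
    }
  })
  invisible(cfg)
}

rnbinom_disp <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Generate a synthetic reprogramming experiment
#'
#' Draws a gene-by-sample NB count matrix with the study design of
#' [sim_config()] and a planted ground truth for every signature gene:
#' *correct* genes share the ES mean in the iPS line, *not reprogrammed*
#' genes keep the fibroblast mean, *intermediate* genes sit at the
#' geometric midpoint of the fibroblast and ES means, and *novel* genes
#' are planted `novel_factor`-fold outside the fibroblast-ES interval (side
#' chosen at random). Non-signature genes share one mean across all lines.
#' Counts are `NB(mean = s_j * mu, Var = mu + alpha mu^2)` with per-sample
#' library factors `s_j`. Output is deterministic given `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return A list with elements `counts` (counts tibble), `sample_sheet`
#'   (tibble) and `truth`: one row per (gene, iPS line) with `gene_id`,
#'   `is_signature`, planted means `mu_ef`, `mu_es1`, `mu_es2`, `ips_line`,
#'   `category` (`NA` for non-signature genes) and `mu_ips`.
#' @export
generate_experiment <- function(cfg) {
  validate_sim_config(cfg)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
  ips_lines <- sprintf("iPS%d", seq_len(cfg$n_ips_lines))
  lines <- c("EF", "ES1", "ES2", ips_lines)

  # planted means
  set.seed(derive_seed(cfg$seed, "means"))
  mu_ef <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  is_signature <- seq_len(cfg$n_genes) %in%
    sample.int(cfg$n_genes, cfg$n_signature)
  direction <- sample(c(-1, 1), cfg$n_genes, replace = TRUE)
  mu_es1 <- ifelse(is_signature, mu_ef * 2^(direction * cfg$log2fc), mu_ef)
  mu_es2 <- ifelse(is_signature, mu_es1 * cfg$es_line_effect, mu_ef)
  mu_es_planted <- sqrt(mu_es1 * mu_es2)

  # Categories are correlated across iPS lines: a base category per gene is
  # kept with probability category_cor and redrawn otherwise (marginal
  # proportions preserved), mirroring how reprogramming failures are shared
  # between sibling iPS lines. The novel side is drawn once per gene.
  set.seed(derive_seed(cfg$seed, "categories"))
  base_category <- rep(NA_character_, cfg$n_genes)
  base_category[is_signature] <- sample(gene_categories, sum(is_signature),
                                        replace = TRUE, prob = cfg$proportions)
  side <- sample(c(TRUE, FALSE), cfg$n_genes, replace = TRUE)
  truth <- purrr::map(ips_lines, function(line) {
    category <- base_category
    redraw <- is_signature &
      stats::runif(cfg$n_genes) > cfg$category_cor
    category[redraw] <- sample(gene_categories, sum(redraw),
                               replace = TRUE, prob = cfg$proportions)
    lo <- pmin(mu_ef, mu_es_planted)
    hi <- pmax(mu_ef, mu_es_planted)
    mu_ips <- dplyr::case_when(
      !is_signature ~ mu_ef,
      category == "correct" ~ mu_es_planted,
      category == "not_reprogrammed" ~ mu_ef,
      category == "intermediate" ~ sqrt(mu_ef * mu_es_planted),
      side ~ hi * cfg$novel_factor,
      TRUE ~ lo / cfg$novel_factor
    )
    tibble(gene_id = gene_id, is_signature = is_signature,
           mu_ef = mu_ef, mu_es1 = mu_es1, mu_es2 = mu_es2,
           ips_line = line, category = category, mu_ips = mu_ips)
  }) |> purrr::list_rbind()

  # samples
  sheet <- tidyr::expand_grid(line_id = lines,
                              replicate = seq_len(cfg$n_replicates)) |>
    dplyr::mutate(
      sample_id = sprintf("%s_r%d", .data$line_id, .data$replicate),
      cell_class = dplyr::case_when(
        .data$line_id == "EF" ~ "fibroblast",
        .data$line_id %in% c("ES1", "ES2") ~ "es",
        TRUE ~ "ips")) |>
    dplyr::select("sample_id", "line_id", "cell_class", "replicate")

  set.seed(derive_seed(cfg$seed, "libsize"))
  libsize <- stats::runif(nrow(sheet), cfg$libsize_range[1], cfg$libsize_range[2])

  line_means <- cbind(EF = mu_ef, ES1 = mu_es1, ES2 = mu_es2)
  for (line in ips_lines) {
    line_means <- cbind(line_means,
                        truth$mu_ips[truth$ips_line == line])
    colnames(line_means)[ncol(line_means)] <- line
  }

  set.seed(derive_seed(cfg$seed, "counts"))
  m <- vapply(seq_len(nrow(sheet)), function(j) {
    rnbinom_disp(cfg$n_genes, libsize[j] * line_means[, sheet$line_id[j]],
                 cfg$dispersion)
  }, numeric(cfg$n_genes))
  colnames(m) <- sheet$sample_id
  rownames(m) <- gene_id

  list(counts = counts_tibble(m), sample_sheet = sheet, truth = truth)
}
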