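#' Log-transform normalized counts
#'
#' `x = log2(count / size_factor + 1)`: a simple monotone transform putting
#' counts on a roughly variance-comparable scale for clustering, PCA and
#' heat maps. A zero count under a unit size factor maps to exactly 0.
#'
#' @param counts A counts tibble.
#' @param size_factors Tibble from [estimate_size_factors()].
#' @return A tibble of the same shape with transformed values.
#' @export
transform_counts <- function(counts, size_factors) {
  validate_count_matrix(counts, allow_fractional = TRUE)
  m <- counts_matrix(counts)
  s <- size_factors$size_factor[match(colnames(m), size_factors$sample_id)]
  if (anyNA(s) || any(s <= 0)) abort("positive size factors required for every sample")
  counts_tibble(log2(sweep(m, 2, s, "/") + 1))
}

#' Genes with the highest across-sample variance
#'
#' @param transformed A transformed tibble from [transform_counts()].
#' @param k Number of genes to keep. Ties are broken by lexicographic
#'   `gene_id`; `k` larger than the gene count returns all genes with a
#'   warning.
#' @return Character vector of `k` gene ids, most variable first.
#' @export
top_variance_genes <- function(transformed, k = 100) {
  if (k < 1) abort("k must be >= 1")
  m <- counts_matrix(transformed)
  if (k > nrow(m)) {
    warn(sprintf("k = %d exceeds the %d genes available; returning all", k, nrow(m)))
    k <- nrow(m)
  }
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m))
  rownames(m)[ord[seq_len(k)]]
}

#' Hierarchical clustering of samples
#'
#' Agglomerative average-linkage clustering of sample expression profiles
#' under the correlation distance `1 - Pearson r`. A zero-variance profile
#' has undefined correlations; these are set to 0 (distance 1) with a
#' warning. Average linkage is monotone, so merge heights never decrease.
#'
#' @param transformed A transformed tibble, typically restricted to the
#'   top-variance genes.
#' @return An object of class `sample_clust` wrapping the
#'   [stats::hclust()] tree; see [cluster_newick()], `autoplot()`.
#' @export
cluster_samples <- function(transformed) {
  m <- counts_matrix(transformed)
  if (ncol(m) < 2) abort("clustering requires at least 2 samples")
  cc <- suppressWarnings(stats::cor(m))
  if (anyNA(cc)) {
    warn("zero-variance sample profile(s); their correlations set to 0")
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  }
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  structure(list(hclust = hc, n_genes = nrow(m)), class = "sample_clust")
}

#' Serialize a sample dendrogram as Newick
#'
#' Branch lengths are differences of merge heights.
#'
#' @param clust A `sample_clust` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
cluster_newick <- function(clust, path = NULL) {
  phy <- ape::as.phylo(clust$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Test whether a set of samples forms one clade
#'
#' @param clust A `sample_clust` object.
#' @param samples Character vector of sample ids.
#' @return `TRUE` if the smallest clade containing all `samples` contains
#'   no other sample (monophyly).
#' @export
is_monophyletic_clade <- function(clust, samples) {
  phy <- ape::as.phylo(clust$hclust)
  ape::is.monophyletic(phy, tips = samples)
}

#' @export
print.sample_clust <- function(x, ...) {
  cat(sprintf("sample_clust: %d samples, %d genes, average linkage on 1 - Pearson r\n",
              length(x$hclust$labels), x$n_genes))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.sample_clust <- function(object, ...) {
  hc <- object$hclust
  # segment representation of the dendrogram, built from the merge table
  pos <- stats::order.dendrogram(stats::as.dendrogram(hc))
  xpos <- numeric(length(hc$labels)); xpos[pos] <- seq_along(pos)
  node_x <- numeric(nrow(hc$merge)); node_y <- hc$height
  seg <- purrr::map(seq_len(nrow(hc$merge)), function(i) {
    ch <- hc$merge[i, ]
    cx <- ifelse(ch < 0, xpos[-ch], node_x[pmax(ch, 1)])
    cy <- ifelse(ch < 0, 0, node_y[pmax(ch, 1)])
    node_x[i] <<- mean(cx)
    tibble(x = c(cx[1], cx[1], cx[2]), xend = c(cx[1], cx[2], cx[2]),
           y = c(cy[1], hc$height[i], hc$height[i]),
           yend = c(hc$height[i], hc$height[i], cy[2]))
  }) |> purrr::list_rbind()
  labs <- tibble(x = xpos, y = 0, label = hc$labels)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs, ggplot2::aes(x = .data$x, y = .data$y,
                                                 label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.3, 0.05))) +
    ggplot2::labs(x = NULL, y = "1 - Pearson r (average linkage)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Principal component analysis of samples
#'
#' Gene-centered PCA of sample expression profiles: each gene's transformed
#' values are centred, and samples are projected onto the principal axes.
#' Variance fractions are eigenvalue shares of the total variance.
#'
#' @param transformed A transformed tibble, typically restricted to the
#'   top-variance genes.
#' @param n_components Number of components to report (truncated, with a
#'   warning, when fewer non-degenerate dimensions exist).
#' @return An object of class `sample_pca` with elements `scores` (tibble:
#'   `sample_id`, `PC1`, ...) and `variance_fraction` (numeric vector).
#' @export
pca_samples <- function(transformed, n_components = 2) {
  m <- counts_matrix(transformed)
  if (ncol(m) < 2) abort("PCA requires at least 2 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  nondeg <- sum(pc$sdev^2 > total_var * 1e-12)
  if (n_components > nondeg) {
    warn(sprintf("only %d non-degenerate component(s); truncating from %d",
                 nondeg, n_components))
    n_components <- nondeg
  }
  k <- seq_len(n_components)
  scores <- dplyr::bind_cols(tibble(sample_id = colnames(m)),
                             as_tibble(pc$x[, k, drop = FALSE]))
  structure(list(scores = scores,
                 variance_fraction = pc$sdev[k]^2 / total_var),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat(sprintf("sample_pca: %d samples; variance fractions: %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sample_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.sample_pca <- function(x, ...) {
  tibble(n_components = length(x$variance_fraction),
         pc1_fraction = x$variance_fraction[1],
         total_fraction = sum(x$variance_fraction))
}

#' @exportS3Method ggplot2::autoplot
autoplot.sample_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) df$group <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%% of variance)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.0f%% of variance)", 100 * object$variance_fraction[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}

#' Row-scaled heat-map table
#'
#' Scales each gene's transformed values to `[0, 1]` by row min-max (the
#' usual row-normalized heat-map convention); constant rows map to 0.5
#' everywhere, with a warning.
#'
#' @param transformed A transformed tibble.
#' @param genes Gene subset (row order of the output).
#' @param sample_order Optional column order.
#' @return A tibble, `gene_id` plus one column per sample, values in
#'   `[0, 1]`.
#' @export
heatmap_table <- function(transformed, genes, sample_order = NULL) {
  if (length(genes) == 0) abort("gene subset is empty")
  m <- counts_matrix(transformed)
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes) > 0) {
    abort(sprintf("gene '%s' not present in the matrix", missing_genes[1]))
  }
  m <- m[genes, sample_order %||% colnames(m), drop = FALSE]
  rng <- apply(m, 1, range)
  span <- rng[2, ] - rng[1, ]
  flat <- span == 0
  if (any(flat)) {
    warn(sprintf("%d constant row(s) set to 0.5", sum(flat)))
    span[flat] <- 1
  }
  scaled <- (m - rng[1, ]) / span
  scaled[flat, ] <- 0.5
  counts_tibble(scaled)
}

#' @rdname heatmap_table
#' @param path Output path for the tab-separated table.
#' @export
export_heatmap_table <- function(transformed, genes, path, sample_order = NULL) {
  tab <- heatmap_table(transformed, genes, sample_order)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(tab)
}

#' Row-scaled expression heat map
#'
#' Renders [heatmap_table()] with the blue-to-red colour scale (blue =
#' lowest expression in the row, red = highest).
#'
#' @inheritParams heatmap_table
#' @return A ggplot object.
#' @export
plot_heatmap <- function(transformed, genes, sample_order = NULL) {
  tab <- heatmap_table(transformed, genes, sample_order)
  long <- tidyr::pivot_longer(tab, -"gene_id",
                              names_to = "sample_id", values_to = "value") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = setdiff(names(tab), "gene_id")),
                  gene_id = factor(.data$gene_id, levels = rev(tab$gene_id)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row-scaled\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}
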