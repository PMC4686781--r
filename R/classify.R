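gene_categories <- c("correct", "intermediate", "not_reprogrammed", "novel")

#' Select the fibroblast-versus-ES signature gene set
#'
#' The signature set is the union of genes significantly differentially
#' expressed (BH-adjusted `q < alpha_sig`) between the fibroblast line and
#' *either* ES line. Reprogramming completeness is scored over this set.
#' For each signature gene the fibroblast normalized mean and the pooled ES
#' normalized mean (unweighted average of the two ES lines' means) are
#' stored for the between-ness rules of the classifier.
#'
#' @param de_es1,de_es2 [nb_wald_test()] results for the fibroblast (group
#'   a) versus each ES line (group b), on the same gene universe.
#' @param alpha_sig Significance threshold on adjusted p (default 0.05).
#' @return A tibble with one row per signature gene: `gene_id`, `sig_es1`,
#'   `sig_es2` (which contrasts were significant), `q_es1`, `q_es2`,
#'   `mu_ef`, `mu_es1`, `mu_es2`, `mu_es_pooled`.
#' @export
select_signature_genes <- function(de_es1, de_es2, alpha_sig = 0.05) {
  if (!identical(de_es1$gene_id, de_es2$gene_id)) {
    abort("the two ES contrasts cover different gene universes")
  }
  hit1 <- de_es1$qvalue < alpha_sig & de_es1$flag != "untestable"
  hit2 <- de_es2$qvalue < alpha_sig & de_es2$flag != "untestable"
  keep <- hit1 | hit2
  tibble(
    gene_id = de_es1$gene_id[keep],
    sig_es1 = hit1[keep], sig_es2 = hit2[keep],
    q_es1 = de_es1$qvalue[keep], q_es2 = de_es2$qvalue[keep],
    mu_ef = (de_es1$base_mean_a[keep] + de_es2$base_mean_a[keep]) / 2,
    mu_es1 = de_es1$base_mean_b[keep],
    mu_es2 = de_es2$base_mean_b[keep]
  ) |>
    dplyr::mutate(mu_es_pooled = (.data$mu_es1 + .data$mu_es2) / 2)
}

#' Classify signature genes in one iPS line
#'
#' Assigns each signature gene exactly one of four categories describing
#' how completely it was reprogrammed in a given iPS line, from three
#' per-gene tests (iPS vs fibroblast, iPS vs each ES line) and the
#' normalized means. The decision tree, evaluated in order:
#'
#' 1. *correct* — not significantly different from both ES lines
#'    (`q_ips_es1 >= alpha_sig` or `q_ips_es2 >= alpha_sig`): the gene is
#'    expressed at the ES level.
#' 2. *not_reprogrammed* — different from both ES lines but not from the
#'    fibroblasts (`q_ips_ef >= alpha_sig`): residual somatic memory.
#' 3. *intermediate* — different from fibroblasts and both ES lines, with
#'    the iPS mean strictly between the fibroblast and pooled-ES means.
#' 4. *novel* — different from everything and outside the
#'    fibroblast-to-ES interval (boundary ties included here).
#'
#' Between-ness is evaluated strictly on the normalized-mean scale.
#'
#' @param q_ips_ef,q_ips_es1,q_ips_es2 Adjusted p-values of the three
#'   per-gene tests.
#' @param mu_ef,mu_es_pooled,mu_ips Normalized means.
#' @param alpha_sig Significance threshold.
#' @return Character vector of categories, one per gene.
#' @export
classify_genes <- function(q_ips_ef, q_ips_es1, q_ips_es2,
                           mu_ef, mu_es_pooled, mu_ips, alpha_sig = 0.05) {
  n <- length(q_ips_ef)
  args <- list(q_ips_es1, q_ips_es2, mu_ef, mu_es_pooled, mu_ips)
  if (any(vapply(args, length, 1L) != n)) abort("classifier inputs differ in length")
  if (anyNA(q_ips_ef) || anyNA(q_ips_es1) || anyNA(q_ips_es2)) {
    abort("missing test results for some signature genes")
  }
  diff_es <- q_ips_es1 < alpha_sig & q_ips_es2 < alpha_sig
  lo <- pmin(mu_ef, mu_es_pooled)
  hi <- pmax(mu_ef, mu_es_pooled)
  dplyr::case_when(
    !diff_es ~ "correct",
    q_ips_ef >= alpha_sig ~ "not_reprogrammed",
    mu_ips > lo & mu_ips < hi ~ "intermediate",
    TRUE ~ "novel"
  )
}

#' Classify every signature gene in every iPS line
#'
#' @param signature Output of [select_signature_genes()].
#' @param ips_tests Named list (one element per iPS line); each element is a
#'   list with [nb_wald_test()] results `vs_ef`, `vs_es1`, `vs_es2`, each
#'   with the iPS line as group b.
#' @param alpha_sig Significance threshold.
#' @return A tibble with one row per (gene, iPS line): `gene_id`,
#'   `ips_line`, `category`, the three q-values, the three means and a
#'   `flags` column marking genes significant against only one ES line in
#'   the signature selection (`"single_es"`), for which the pooled ES mean
#'   is still used as the reference.
#' @export
classify_all <- function(signature, ips_tests, alpha_sig = 0.05) {
  if (length(ips_tests) < 1) abort("at least one iPS line is required")
  if (is.null(names(ips_tests)) || any(names(ips_tests) == "")) {
    abort("ips_tests must be a named list (names are iPS line ids)")
  }
  purrr::imap(ips_tests, function(tests, line) {
    need <- c("vs_ef", "vs_es1", "vs_es2")
    if (!all(need %in% names(tests))) {
      abort(sprintf("iPS line '%s' is missing test table(s): %s", line,
                    paste(setdiff(need, names(tests)), collapse = ", ")))
    }
    pick <- function(de, col) {
      v <- de[[col]][match(signature$gene_id, de$gene_id)]
      if (anyNA(v)) abort(sprintf("iPS line '%s': tests missing for some signature genes", line))
      v
    }
    q_ef <- pick(tests$vs_ef, "qvalue")
    q_es1 <- pick(tests$vs_es1, "qvalue")
    q_es2 <- pick(tests$vs_es2, "qvalue")
    mu_ips <- pick(tests$vs_ef, "base_mean_b")
    tibble(
      gene_id = signature$gene_id,
      ips_line = line,
      category = classify_genes(q_ef, q_es1, q_es2,
                                signature$mu_ef, signature$mu_es_pooled,
                                mu_ips, alpha_sig),
      q_vs_ef = q_ef, q_vs_es1 = q_es1, q_vs_es2 = q_es2,
      mu_ef = signature$mu_ef,
      mu_es_pooled = signature$mu_es_pooled,
      mu_ips = mu_ips,
      flags = ifelse(signature$sig_es1 & signature$sig_es2, "", "single_es")
    )
  }) |>
    purrr::list_rbind()
}

#' Count genes sharing a category across all iPS lines
#'
#' @param classification Output of [classify_all()] covering >= 2 iPS lines
#'   on the same gene universe.
#' @return A tibble with columns `category`, `shared_count`: the number of
#'   genes assigned that category in every iPS line.
#' @export
shared_categories <- function(classification) {
  lines <- unique(classification$ips_line)
  if (length(lines) < 2) abort("shared categories require at least 2 iPS lines")
  wide <- classification |>
    dplyr::select("gene_id", "ips_line", "category") |>
    tidyr::pivot_wider(names_from = "ips_line", values_from = "category")
  if (anyNA(wide)) abort("iPS lines cover different gene universes")
  lab <- wide[[lines[1]]]
  same <- rep(TRUE, nrow(wide))
  for (l in lines[-1]) same <- same & wide[[l]] == lab
  tibble(category = gene_categories) |>
    dplyr::left_join(
      tibble(category = lab[same]) |> dplyr::count(.data$category, name = "shared_count"),
      by = "category") |>
    tidyr::replace_na(list(shared_count = 0L))
}

#' Percentage of a total, printed-table convention
#'
#' `100 * count / total`, rounded half-up. Two decimals is the convention
#' of the category tables; one decimal reproduces prose figures such as
#' colony-formation efficiency.
#'
#' @param count Non-negative integer(s), `count <= total`.
#' @param total Positive integer total.
#' @param digits 2 (default) or 1.
#' @return Numeric percentage(s).
#' @export
#' @examples
#' percent_of(2569, 3201)      # 80.26
#' percent_of(722, 60000, 1)   # 1.2
percent_of <- function(count, total, digits = 2) {
  if (length(total) != 1 || total <= 0) abort("total must be a single positive integer")
  if (any(count < 0) || any(count > total)) abort("count must lie in [0, total]")
  if (!digits %in% c(1, 2)) abort("digits must be 1 or 2")
  round_half_up(100 * count / total, digits)
}

#' Build a category report across iPS lines
#'
#' Tabulates, per iPS line, the number and percentage of signature genes in
#' each reprogramming category, plus a shared row counting genes assigned
#' the same category in all lines (when >= 2 lines are present). The
#' percentages in every row use the signature total as denominator.
#'
#' @param classification Output of [classify_all()].
#' @param total Signature-set size; per-line counts must sum to it.
#' @param digits Decimals for percentages (default 2).
#' @return A tibble of class `reprog_report` with columns `row_id`,
#'   `category`, `count`, `percent`. Per-line rows come first, then the
#'   shared row (`row_id = "shared"`).
#' @export
build_report <- function(classification, total, digits = 2) {
  lines <- unique(classification$ips_line)
  per_line <- classification |>
    dplyr::count(.data$ips_line, .data$category) |>
    tidyr::complete(ips_line = lines, category = gene_categories,
                    fill = list(n = 0L)) |>
    dplyr::rename(row_id = "ips_line", count = "n")
  sums <- per_line |>
    dplyr::summarise(s = sum(.data$count), .by = "row_id")
  bad <- sums$row_id[sums$s != total]
  if (length(bad) > 0) {
    abort(sprintf("category counts for line '%s' sum to %d, not the signature total %d",
                  bad[1], sums$s[sums$row_id == bad[1]], total))
  }
  out <- per_line
  if (length(lines) >= 2) {
    out <- dplyr::bind_rows(
      out,
      shared_categories(classification) |>
        dplyr::transmute(row_id = "shared", .data$category,
                         count = .data$shared_count))
  }
  out <- out |>
    dplyr::mutate(
      row_id = factor(.data$row_id, levels = c(lines, "shared")),
      category = factor(.data$category, levels = gene_categories),
      percent = percent_of(.data$count, total, digits)) |>
    dplyr::arrange(.data$row_id, .data$category) |>
    dplyr::mutate(row_id = as.character(.data$row_id),
                  category = as.character(.data$category))
  attr(out, "total") <- total
  attr(out, "digits") <- digits
  class(out) <- c("reprog_report", class(out))
  out
}

#' Render a report as a printed-table-style text block
#'
#' @param report A `reprog_report`.
#' @return Character vector of lines, one per row, cells as
#'   `"count (percent%)"`.
#' @export
format_report <- function(report) {
  digits <- attr(report, "digits") %||% 2
  wide <- report |>
    dplyr::mutate(cell = sprintf("%d (%.*f%%)", .data$count, digits,
                                 .data$percent)) |>
    dplyr::select("row_id", "category", "cell") |>
    tidyr::pivot_wider(names_from = "category", values_from = "cell")
  header <- paste(c("line", gene_categories), collapse = "\t")
  rows <- apply(wide, 1, paste, collapse = "\t")
  c(header, unname(rows))
}

#' @export
print.reprog_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.reprog_report <- function(x, ...) {
  tibble(
    total = attr(x, "total"),
    n_lines = length(setdiff(unique(x$row_id), "shared")),
    has_shared_row = "shared" %in% x$row_id
  )
}

#' @exportS3Method generics::tidy
tidy.reprog_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "reprog_report")
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.reprog_report <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(category = factor(.data$category, levels = gene_categories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row_id, y = .data$percent,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of signature genes", fill = "category") +
    ggplot2::theme_minimal()
}
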