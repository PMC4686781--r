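as_counts <- function(x, allow_fractional = FALSE) {
  if (is.character(x)) read_count_matrix(x, allow_fractional) else x
}

as_sheet <- function(x) {
  if (is.character(x)) read_sample_sheet(x) else x
}

# Enumerate the study design from the sample sheet: the single fibroblast
# line, exactly two ES reference lines (es_pool selects two when more are
# present) and >= 1 iPS lines.
derive_design <- function(sheet, es_pool = NULL) {
  validate_sample_sheet(sheet)
  lines <- dplyr::distinct(sheet, .data$line_id, .data$cell_class)
  fib <- lines$line_id[lines$cell_class == "fibroblast"]
  es <- lines$line_id[lines$cell_class == "es"]
  ips <- lines$line_id[lines$cell_class == "ips"]
  if (!is.null(es_pool)) {
    if (length(es_pool) != 2 || !all(es_pool %in% es)) {
      abort("es_pool must name two es lines present in the sheet")
    }
    es <- es_pool
  }
  if (length(es) != 2) {
    abort(sprintf(
      "the classifier needs exactly 2 ES reference lines; found %d (%s); use es_pool to select two",
      length(es), paste(es, collapse = ", ")))
  }
  if (length(ips) < 1) {
    abort(sprintf("no ips line in the sample sheet; found classes: %s",
                  paste(unique(sheet$cell_class), collapse = ", ")))
  }
  list(fibroblast = fib, es = es, ips = ips)
}

line_samples <- function(sheet, line) sheet$sample_id[sheet$line_id == line]

#' Run the differential-expression stage
#'
#' Estimates size factors and dispersions, then runs every contrast the
#' design implies: fibroblast versus each ES line (the signature
#' contrasts) and each iPS line versus fibroblast, ES1 and ES2 (the
#' classifier contrasts). In every contrast the reference is group a, so
#' positive `log2fc` means higher in the ES/iPS line.
#'
#' @param counts Counts tibble or path to one.
#' @param sheet Sample sheet tibble or path.
#' @param es_pool Optional pair of ES line ids when the sheet has more
#'   than two.
#' @param allow_fractional Accept fractional counts on ingest.
#' @return A list: `size_factors`, `dispersions`, `design`,
#'   `es_contrasts` (list `es1`, `es2`) and `ips_contrasts` (per iPS line,
#'   list `vs_ef`, `vs_es1`, `vs_es2`).
#' @export
run_de <- function(counts, sheet, es_pool = NULL, allow_fractional = FALSE) {
  counts <- as_counts(counts, allow_fractional)
  sheet <- as_sheet(sheet)
  validate_sample_sheet(sheet, counts = counts)
  design <- derive_design(sheet, es_pool)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, sheet)

  test <- function(ref, target) {
    nb_wald_test(counts, sf, disp,
                 group_a = line_samples(sheet, ref),
                 group_b = line_samples(sheet, target),
                 label = sprintf("%s_vs_%s", target, ref))
  }
  es_contrasts <- list(es1 = test(design$fibroblast, design$es[1]),
                       es2 = test(design$fibroblast, design$es[2]))
  ips_contrasts <- lapply(stats::setNames(design$ips, design$ips), function(line) {
    list(vs_ef = test(design$fibroblast, line),
         vs_es1 = test(design$es[1], line),
         vs_es2 = test(design$es[2], line))
  })
  list(size_factors = sf, dispersions = disp, design = design,
       es_contrasts = es_contrasts, ips_contrasts = ips_contrasts)
}

#' Run the classification stage
#'
#' @param de A [run_de()] result.
#' @param alpha_sig Significance threshold for both signature selection and
#'   classification.
#' @param digits Report percentage decimals (1 or 2).
#' @return A list: `signature`, `classification`, `report` and (with >= 2
#'   iPS lines) `shared`.
#' @export
run_classify <- function(de, alpha_sig = 0.05, digits = 2) {
  sig <- select_signature_genes(de$es_contrasts$es1, de$es_contrasts$es2, alpha_sig)
  cls <- classify_all(sig, de$ips_contrasts, alpha_sig)
  out <- list(signature = sig, classification = cls,
              report = build_report(cls, total = nrow(sig), digits = digits))
  if (length(de$design$ips) >= 2) out$shared <- shared_categories(cls)
  out
}

#' Run the exploratory stage
#'
#' Log-transforms normalized counts, keeps the `top_k` most variable
#' genes, and computes the sample dendrogram (average linkage on
#' 1 - Pearson r) and gene-centred PCA.
#'
#' @inheritParams run_de
#' @param size_factors Optional precomputed size factors.
#' @param top_k Number of top-variance genes (default 100).
#' @param n_components PCA components to report.
#' @return A list: `transformed`, `top_genes`, `clust` (`sample_clust`),
#'   `pca` (`sample_pca`).
#' @export
run_explore <- function(counts, sheet, size_factors = NULL, top_k = 100,
                        n_components = 2, allow_fractional = FALSE) {
  counts <- as_counts(counts, allow_fractional)
  sheet <- as_sheet(sheet)
  validate_sample_sheet(sheet, counts = counts)
  sf <- size_factors %||% estimate_size_factors(counts)
  tr <- transform_counts(counts, sf)
  top <- top_variance_genes(tr, top_k)
  tr_top <- tr[match(top, tr$gene_id), , drop = FALSE]
  list(transformed = tr, top_genes = top,
       clust = cluster_samples(tr_top),
       pca = pca_samples(tr_top, n_components))
}

write_manifest <- function(path, config, files, seed = NULL) {
  manifest <- list(
    config = config,
    seed = seed,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline stage: simulate
#'
#' Writes a synthetic experiment (counts, sample sheet, truth table) plus a
#' manifest echoing the configuration and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @return Invisibly, the [generate_experiment()] result.
#' @export
pipeline_simulate <- function(out_dir, cfg = sim_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_experiment(cfg)
  files <- file.path(out_dir, c("counts.tsv", "sample_sheet.tsv", "truth.tsv"))
  write_count_matrix(sim$counts, files[1])
  write_sample_sheet(sim$sample_sheet, files[2])
  readr::write_tsv(sim$truth, files[3], progress = FALSE)
  write_manifest(file.path(out_dir, "manifest_simulate.json"),
                 config = unclass(cfg), files = files, seed = cfg$seed)
  invisible(sim)
}

de_table_file <- function(label) sprintf("de_%s.tsv", label)

#' Pipeline stage: differential expression
#'
#' Runs [run_de()] and writes size factors, dispersions and one DE table
#' per contrast, plus a manifest recording the design.
#'
#' @inheritParams run_de
#' @param out_dir Output directory.
#' @return Invisibly, the [run_de()] result.
#' @export
pipeline_de <- function(counts, sheet, out_dir, es_pool = NULL,
                        allow_fractional = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  de <- run_de(counts, sheet, es_pool, allow_fractional)
  files <- c(file.path(out_dir, "size_factors.tsv"),
             file.path(out_dir, "dispersions.tsv"))
  readr::write_tsv(de$size_factors, files[1], progress = FALSE)
  readr::write_tsv(de$dispersions, files[2], progress = FALSE)
  all_tables <- c(de$es_contrasts, unlist(de$ips_contrasts, recursive = FALSE))
  for (tab in all_tables) {
    f <- file.path(out_dir, de_table_file(attr(tab, "contrast")))
    readr::write_tsv(tidy(tab), f, progress = FALSE)
    files <- c(files, f)
  }
  write_manifest(file.path(out_dir, "manifest_de.json"),
                 config = list(design = de$design), files = files)
  invisible(de)
}

read_de_table <- function(dir, label) {
  f <- file.path(dir, de_table_file(label))
  if (!file.exists(f)) abort(sprintf("missing DE table '%s'", basename(f)))
  out <- readr::read_tsv(f, col_types = readr::cols(
    gene_id = readr::col_character(), flag = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  attr(out, "contrast") <- label
  class(out) <- c("reprog_de", class(out))
  out
}

#' Pipeline stage: classify
#'
#' Reads the DE tables written by [pipeline_de()] from `de_dir`, selects
#' the signature set, classifies every signature gene in every iPS line
#' and writes the per-gene table, the category report (structured TSV and
#' a text table) and a manifest.
#'
#' @param de_dir Directory holding `manifest_de.json` and the DE tables.
#' @param out_dir Output directory (defaults to `de_dir`).
#' @param alpha_sig Significance threshold.
#' @param digits Report percentage decimals.
#' @return Invisibly, the [run_classify()] result.
#' @export
pipeline_classify <- function(de_dir, out_dir = de_dir, alpha_sig = 0.05,
                              digits = 2) {
  mf <- file.path(de_dir, "manifest_de.json")
  if (!file.exists(mf)) abort(sprintf("missing manifest '%s'", mf))
  design <- jsonlite::read_json(mf, simplifyVector = TRUE)$config$design
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lab <- function(target, ref) sprintf("%s_vs_%s", target, ref)
  de <- list(
    design = design,
    es_contrasts = list(
      es1 = read_de_table(de_dir, lab(design$es[1], design$fibroblast)),
      es2 = read_de_table(de_dir, lab(design$es[2], design$fibroblast))),
    ips_contrasts = lapply(stats::setNames(design$ips, design$ips), function(line) {
      list(vs_ef = read_de_table(de_dir, lab(line, design$fibroblast)),
           vs_es1 = read_de_table(de_dir, lab(line, design$es[1])),
           vs_es2 = read_de_table(de_dir, lab(line, design$es[2])))
    }))
  cl <- run_classify(de, alpha_sig, digits)
  files <- c(file.path(out_dir, "signature.tsv"),
             file.path(out_dir, "classification.tsv"),
             file.path(out_dir, "report.tsv"),
             file.path(out_dir, "report.txt"))
  readr::write_tsv(cl$signature, files[1], progress = FALSE)
  readr::write_tsv(cl$classification, files[2], progress = FALSE)
  readr::write_tsv(tidy(cl$report), files[3], progress = FALSE)
  writeLines(format_report(cl$report), files[4])
  write_manifest(file.path(out_dir, "manifest_classify.json"),
                 config = list(alpha_sig = alpha_sig, digits = digits,
                               total = nrow(cl$signature)),
                 files = files)
  invisible(cl)
}

#' Pipeline stage: explore
#'
#' Writes the Newick dendrogram, PCA scores and variance fractions, and —
#' when a classification table is supplied — row-scaled heat-map matrices
#' for the genes classified *correct* and *not_reprogrammed* in every iPS
#' line.
#'
#' @inheritParams run_explore
#' @param out_dir Output directory.
#' @param classification Optional classification tibble (or path) from
#'   [pipeline_classify()].
#' @return Invisibly, the [run_explore()] result.
#' @export
pipeline_explore <- function(counts, sheet, out_dir, top_k = 100,
                             classification = NULL, allow_fractional = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- as_counts(counts, allow_fractional)
  sheet <- as_sheet(sheet)
  ex <- run_explore(counts, sheet, top_k = top_k,
                    allow_fractional = allow_fractional)
  files <- c(file.path(out_dir, "dendrogram.nwk"),
             file.path(out_dir, "pca_scores.tsv"),
             file.path(out_dir, "pca_variance.tsv"))
  cluster_newick(ex$clust, files[1])
  readr::write_tsv(tidy(ex$pca), files[2], progress = FALSE)
  readr::write_tsv(tibble(component = paste0("PC", seq_along(ex$pca$variance_fraction)),
                          variance_fraction = ex$pca$variance_fraction),
                   files[3], progress = FALSE)
  if (!is.null(classification)) {
    if (is.character(classification)) {
      classification <- readr::read_tsv(classification, progress = FALSE,
                                        show_col_types = FALSE)
    }
    n_lines <- length(unique(classification$ips_line))
    for (cat in c("correct", "not_reprogrammed")) {
      genes <- classification |>
        dplyr::filter(.data$category == cat) |>
        dplyr::count(.data$gene_id) |>
        dplyr::filter(.data$n == n_lines) |>
        dplyr::pull(.data$gene_id)
      if (length(genes) > 0) {
        f <- file.path(out_dir, sprintf("heatmap_%s.tsv", cat))
        export_heatmap_table(ex$transformed, genes, f,
                             sample_order = sheet$sample_id)
        files <- c(files, f)
      }
    }
  }
  write_manifest(file.path(out_dir, "manifest_explore.json"),
                 config = list(top_k = top_k), files = files)
  invisible(ex)
}

#' Run the whole pipeline on a synthetic experiment
#'
#' simulate -> differential expression -> classification -> exploration,
#' with one master manifest capturing the configuration, the seed and the
#' digest of every output file. Deterministic given `cfg$seed`: a rerun
#' writes byte-identical classification tables and reports.
#'
#' @param out_dir Output directory.
#' @param cfg A [sim_config()].
#' @param alpha_sig Significance threshold.
#' @param top_k Top-variance gene count for the exploratory stage.
#' @param digits Report percentage decimals.
#' @return Invisibly, a list with the stage results (`sim`, `de`,
#'   `classify`, `explore`).
#' @export
pipeline_all <- function(out_dir, cfg = sim_config(), alpha_sig = 0.05,
                         top_k = 100, digits = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- pipeline_simulate(out_dir, cfg)
  de <- pipeline_de(sim$counts, sim$sample_sheet, out_dir)
  cl <- pipeline_classify(out_dir, out_dir, alpha_sig = alpha_sig,
                          digits = digits)
  ex <- pipeline_explore(sim$counts, sim$sample_sheet, out_dir, top_k = top_k,
                         classification = cl$classification)
  outputs <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(sim = unclass(cfg), alpha_sig = alpha_sig,
                               top_k = top_k, digits = digits),
                 files = outputs, seed = cfg$seed)
  invisible(list(sim = sim, de = de, classify = cl, explore = ex))
}
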