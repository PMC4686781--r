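#' Read a gene-by-sample count matrix
#'
#' Reads a tab-separated count table whose first column holds gene (or
#' contig) identifiers and whose remaining columns hold one sample each.
#' The file is validated on ingest: identifiers must be unique, every cell
#' must be a non-negative number, and counts must be whole numbers unless
#' `allow_fractional = TRUE` (bias-corrected counting tools can emit
#' fractional expected counts).
#'
#' @param path Path to a tab-separated text file. The first header cell
#'   names the identifier column; the remaining header cells are sample ids.
#' @param allow_fractional Accept non-integral counts (default `FALSE`).
#' @return A tibble with a `gene_id` character column followed by one
#'   numeric column per sample, preserving file row and column order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tf)
#' read_count_matrix(tf)
read_count_matrix <- function(path, allow_fractional = FALSE) {
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, na = character()))
  if (nrow(readr::problems(raw)) > 0) {
    pr <- readr::problems(raw)
    abort(sprintf("malformed count matrix '%s': %s at row %d, column %d",
                  path, pr$expected[1], pr$row[1], pr$col[1]))
  }
  names(raw)[1] <- "gene_id"
  validate_count_matrix(raw, allow_fractional = allow_fractional)
  raw
}

#' Write a count matrix to tab-separated text
#'
#' @param counts A counts tibble as returned by [read_count_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts, allow_fractional = TRUE)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Validate a count matrix tibble
#'
#' Checks the structural invariants of the pipeline's central object:
#' unique gene ids, at least one sample column, all counts finite,
#' non-negative and (optionally) integral.
#'
#' @inheritParams write_count_matrix
#' @param allow_fractional Accept non-integral counts.
#' @return `counts`, invisibly.
#' @export
validate_count_matrix <- function(counts, allow_fractional = FALSE) {
  if (!is.data.frame(counts) || !"gene_id" %in% names(counts)) {
    abort("count matrix must be a data frame with a 'gene_id' column")
  }
  sample_ids <- count_sample_ids(counts)
  if (length(sample_ids) == 0) abort("count matrix has no sample columns")
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample id '%s'", sample_ids[duplicated(sample_ids)][1]))
  }
  if (anyDuplicated(counts$gene_id)) {
    dup <- counts$gene_id[duplicated(counts$gene_id)][1]
    abort(sprintf("duplicate gene id '%s' in count matrix", dup))
  }
  for (sid in sample_ids) {
    v <- counts[[sid]]
    if (!is.numeric(v)) abort(sprintf("column '%s' is not numeric", sid))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative or missing count at row %d, column '%s'", bad[1], sid))
    }
    if (!allow_fractional) {
      frac <- which(abs(v - round(v)) > 1e-8)
      if (length(frac) > 0) {
        abort(sprintf(
          "non-integer count %.4g at row %d, column '%s' (use allow_fractional to accept)",
          v[frac[1]], frac[1], sid))
      }
    }
  }
  invisible(counts)
}

sample_classes <- c("fibroblast", "es", "ips")

#' Read a sample sheet
#'
#' The sample sheet assigns each sequencing sample to a cell line, a cell
#' class and a replicate number, and drives every contrast downstream.
#' Required columns: `sample_id`, `line_id`, `cell_class`
#' (`fibroblast`/`es`/`ips`) and `replicate`. The design must contain
#' exactly one fibroblast line, at least one ES line, and at least two
#' replicates per line (within-line variance is needed for dispersion
#' estimation).
#'
#' @param path Path to a tab-separated file with the four named columns.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    line_id = readr::col_character(),
    cell_class = readr::col_character(),
    replicate = readr::col_double()
  ), progress = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet tibble.
#' @param counts Optional companion count matrix; if given, every
#'   `sample_id` must appear among its columns.
#' @export
validate_sample_sheet <- function(sheet, counts = NULL) {
  need <- c("sample_id", "line_id", "cell_class", "replicate")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample sheet is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort(sprintf("duplicate sample id '%s' in sample sheet",
                  sheet$sample_id[duplicated(sheet$sample_id)][1]))
  }
  bad_class <- setdiff(unique(sheet$cell_class), sample_classes)
  if (length(bad_class) > 0) {
    abort(sprintf("unknown cell_class '%s'; allowed: %s",
                  bad_class[1], paste(sample_classes, collapse = ", ")))
  }
  if (any(sheet$replicate < 1 | sheet$replicate != round(sheet$replicate))) {
    abort("replicate must be a positive integer")
  }
  lines <- dplyr::distinct(sheet, .data$line_id, .data$cell_class)
  if (anyDuplicated(lines$line_id)) {
    abort("a line_id is assigned to more than one cell_class")
  }
  if (sum(lines$cell_class == "fibroblast") != 1) {
    abort("sample sheet must contain exactly one fibroblast line")
  }
  if (sum(lines$cell_class == "es") < 1) {
    abort("sample sheet must contain at least one es line")
  }
  n_rep <- table(sheet$line_id)
  singletons <- names(n_rep)[n_rep < 2]
  if (length(singletons) > 0) {
    abort(sprintf("line '%s' has a single replicate; >= 2 are required for variance estimation",
                  singletons[1]))
  }
  if (!is.null(counts)) {
    absent <- setdiff(sheet$sample_id, count_sample_ids(counts))
    if (length(absent) > 0) {
      abort(sprintf("sample '%s' is not a column of the count matrix", absent[1]))
    }
  }
  invisible(sheet)
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Read a contig-to-gene map
#'
#' Two tab-separated columns, `contig_id` and `gene_id`; contig ids must be
#' unique (each contig belongs to one gene).
#'
#' @param path Path to the map file.
#' @return A tibble with columns `contig_id`, `gene_id`.
#' @export
read_contig_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    contig_id = readr::col_character(), gene_id = readr::col_character()
  ), progress = FALSE)
  if (anyDuplicated(map$contig_id)) {
    abort(sprintf("contig '%s' mapped more than once",
                  map$contig_id[duplicated(map$contig_id)][1]))
  }
  map
}

#' Aggregate contig-level counts to gene level
#'
#' De novo transcriptome assemblies represent one gene by several contigs;
#' counts of all contigs assigned to the same gene are summed. Contigs
#' absent from the map (unannotated contigs, the typical majority of a de
#' novo assembly) are dropped and their number reported via a message.
#'
#' @param contig_counts A counts tibble keyed by contig id.
#' @param map A tibble with columns `contig_id`, `gene_id`.
#' @return A counts tibble with one row per gene, sample order preserved.
#'   Genes appear in order of first appearance of their contigs.
#' @export
aggregate_contigs <- function(contig_counts, map) {
  validate_count_matrix(contig_counts, allow_fractional = TRUE)
  if (any(is.na(map$gene_id) | map$gene_id == "")) {
    abort("contig map contains an empty gene_id")
  }
  sample_ids <- count_sample_ids(contig_counts)
  idx <- match(contig_counts$gene_id, map$contig_id)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0) {
    inform(sprintf("dropping %d unmapped contig(s) of %d (%.1f%%)",
                   n_drop, nrow(contig_counts),
                   100 * n_drop / nrow(contig_counts)))
  }
  kept <- contig_counts[!is.na(idx), , drop = FALSE]
  kept$gene_id <- map$gene_id[idx[!is.na(idx)]]
  out <- kept |>
    dplyr::group_by(gene_id = factor(.data$gene_id, levels = unique(.data$gene_id))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sample_ids), sum), .groups = "drop") |>
    dplyr::mutate(gene_id = as.character(.data$gene_id))
  out
}
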