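#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Round half-up at `digits` decimals (the convention of printed percentage
# tables; base round() rounds half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Derive an independent sub-seed from one master seed and a stream label, so
# each stochastic stage draws from its own stream. Kept below 2^31.
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(what))
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Extract the numeric count matrix (genes x samples) from a counts tibble.
counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene_id
  m
}

count_sample_ids <- function(counts) setdiff(names(counts), "gene_id")

# Assemble a counts tibble back from a matrix with dimnames.
counts_tibble <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}
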