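test_that("signature selection is the union over the two ES contrasts", {
  genes <- sprintf("g%02d", 1:4)
  de1 <- fake_de(genes, qvalue = c(0.01, 0.2, 0.001, 0.5))
  de2 <- fake_de(genes, qvalue = c(0.90, 0.2, 0.002, 0.01))
  sig <- select_signature_genes(de1, de2, alpha_sig = 0.05)
  expect_setequal(sig$gene_id, c("g01", "g03", "g04"))
  expect_true(sig$sig_es1[sig$gene_id == "g01"])
  expect_false(sig$sig_es2[sig$gene_id == "g01"])

  expect_error(select_signature_genes(de1, fake_de(rev(genes), 0.5)),
               "gene universes")
})

test_that("signature selection equals a brute-force union filter on random inputs", {
  set.seed(61)
  for (rep in 1:10) {
    genes <- sprintf("g%03d", 1:200)
    q1 <- runif(200); q2 <- runif(200)
    sig <- select_signature_genes(fake_de(genes, q1), fake_de(genes, q2), 0.1)
    expect_setequal(sig$gene_id, genes[q1 < 0.1 | q2 < 0.1])
  }
})

test_that("the four-way decision tree fires in order", {
  # rule 1: indistinguishable from both ES lines
  expect_equal(classify_genes(0.001, 0.9, 0.8, 10, 1000, 100), "correct")
  # rule 2: different from ES, EF-like
  expect_equal(classify_genes(0.5, 1e-6, 1e-5, 10, 1000, 12), "not_reprogrammed")
  # rule 3: strictly between EF and pooled ES
  expect_equal(classify_genes(1e-4, 1e-6, 1e-6, 10, 1000, 100), "intermediate")
  # rule 4: outside the interval
  expect_equal(classify_genes(1e-4, 1e-6, 1e-6, 10, 1000, 5000), "novel")
  # boundary tie goes to novel, not intermediate
  expect_equal(classify_genes(1e-4, 1e-6, 1e-6, 10, 1000, 1000), "novel")
  # significance vs a single ES line is not enough to leave correct
  expect_equal(classify_genes(1e-4, 1e-6, 0.9, 10, 1000, 5000), "correct")

  expect_error(classify_genes(NA, 0.5, 0.5, 1, 2, 3), "missing")
  expect_error(classify_genes(c(0.1, 0.2), 0.5, 0.5, 1, 2, 3), "length")
})

test_that("classification is an exhaustive partition with consistent counts", {
  set.seed(62)
  genes <- sprintf("g%03d", 1:300)
  sig <- tibble::tibble(gene_id = genes, sig_es1 = TRUE, sig_es2 = TRUE,
                        q_es1 = 0.01, q_es2 = 0.01,
                        mu_ef = runif(300, 1, 100),
                        mu_es1 = runif(300, 100, 1000),
                        mu_es2 = runif(300, 100, 1000))
  sig$mu_es_pooled <- (sig$mu_es1 + sig$mu_es2) / 2
  ips <- list(
    lineA = list(vs_ef = fake_de(genes, runif(300), base_mean_b = runif(300, 1, 2000)),
                 vs_es1 = fake_de(genes, runif(300)),
                 vs_es2 = fake_de(genes, runif(300))),
    lineB = list(vs_ef = fake_de(genes, runif(300), base_mean_b = runif(300, 1, 2000)),
                 vs_es1 = fake_de(genes, runif(300)),
                 vs_es2 = fake_de(genes, runif(300))))
  cls <- classify_all(sig, ips, alpha_sig = 0.05)
  expect_equal(nrow(cls), 600)
  expect_true(all(cls$category %in%
                  c("correct", "intermediate", "not_reprogrammed", "novel")))
  counts <- dplyr::count(cls, ips_line)
  expect_equal(counts$n, c(300, 300))

  # rule 1 is monotone in alpha_sig: a smaller threshold makes fewer genes
  # significant vs the ES lines, so the correct set can only grow
  strict <- classify_all(sig, ips, alpha_sig = 0.01)
  expect_true(all(strict$category[cls$category == "correct"] == "correct"))

  # missing table errors
  expect_error(classify_all(sig, list(lineA = ips$lineA[c("vs_ef", "vs_es1")])),
               "vs_es2")
})

test_that("shared categories equal a brute-force intersection", {
  genes <- sprintf("g%02d", 1:6)
  base <- tibble::tibble(
    gene_id = rep(genes, 2),
    ips_line = rep(c("A", "B"), each = 6),
    category = c("correct", "correct", "novel", "intermediate", "not_reprogrammed", "correct",
                 "correct", "novel", "novel", "intermediate", "correct", "novel"))
  sh <- shared_categories(base)
  expect_equal(sh$shared_count[sh$category == "correct"], 1L)
  expect_equal(sh$shared_count[sh$category == "novel"], 1L)
  expect_equal(sh$shared_count[sh$category == "intermediate"], 1L)
  expect_equal(sh$shared_count[sh$category == "not_reprogrammed"], 0L)

  ident <- dplyr::mutate(base, category = rep(base$category[1:6], 2))
  sh2 <- shared_categories(ident)
  per_line <- dplyr::count(ident[ident$ips_line == "A", ], category)
  for (cat in per_line$category) {
    expect_equal(sh2$shared_count[sh2$category == cat],
                 per_line$n[per_line$category == cat])
  }

  set.seed(63)
  rand <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:100), 3),
    ips_line = rep(c("A", "B", "C"), each = 100),
    category = sample(c("correct", "intermediate", "not_reprogrammed", "novel"),
                      300, replace = TRUE))
  sh3 <- shared_categories(rand)
  wide <- tidyr::pivot_wider(rand, names_from = ips_line, values_from = category)
  brute <- sapply(c("correct", "intermediate", "not_reprogrammed", "novel"),
                  function(cat) sum(wide$A == cat & wide$B == cat & wide$C == cat))
  expect_equal(sh3$shared_count, unname(brute))
  # never exceeds the per-line minimum
  per_line_min <- sapply(c("correct", "intermediate", "not_reprogrammed", "novel"),
                         function(cat) min(table(factor(rand$category, levels = cat),
                                                 rand$ips_line)))
  expect_true(all(sh3$shared_count <= per_line_min))

  expect_error(shared_categories(base[base$ips_line == "A", ]), "at least 2")
})

test_that("percentages follow the half-up printed-table convention", {
  expect_identical(percent_of(2569, 3201), 80.26)
  expect_identical(percent_of(2232, 3201), 69.73)
  expect_identical(percent_of(722, 60000, digits = 1), 1.2)
  expect_identical(percent_of(0, 10), 0)
  expect_error(percent_of(1, 0), "positive")
  expect_error(percent_of(5, 3), "\\[0, total\\]")
})

test_that("reports tabulate counts and percentages per line plus a shared row", {
  labels <- rep(c("correct", "intermediate", "not_reprogrammed", "novel"),
                c(3201, 0, 0, 0))
  cls <- tibble::tibble(gene_id = sprintf("g%04d", 1:3201), ips_line = "L1",
                        category = labels)
  rep1 <- build_report(cls, total = 3201)
  expect_equal(rep1$count, c(3201L, 0L, 0L, 0L))
  expect_equal(rep1$percent, c(100, 0, 0, 0))

  short <- cls[1:1000, ]
  expect_error(build_report(short, total = 3201), "sum to")
})

test_that("identical iPS lines give a shared row equal to the per-line rows", {
  set.seed(64)
  labels <- sample(c("correct", "intermediate", "not_reprogrammed", "novel"),
                   500, replace = TRUE, prob = c(0.8, 0.07, 0.07, 0.06))
  cls <- tibble::tibble(gene_id = rep(sprintf("g%03d", 1:500), 2),
                        ips_line = rep(c("A", "B"), each = 500),
                        category = rep(labels, 2))
  rp <- build_report(cls, total = 500)
  a_row <- rp[rp$row_id == "A", ]
  shared_row <- rp[rp$row_id == "shared", ]
  expect_equal(shared_row$count, a_row$count)
  expect_equal(shared_row$percent, a_row$percent)
})
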