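toy_genes <- function() {
  tibble::tibble(record = "r",
                 start = c(50L, 600L, 900L),
                 end = c(500L, 800L, 1200L),
                 strand = c("+", "-", "+"),
                 label = c("g1", "g2", "g3"))
}

test_that("spans classify as gene / intergenic / overlap", {
  genes <- toy_genes()
  spans <- tibble::tibble(record = "r",
                          start = c(100L, 10L, 490L, 520L, 850L),
                          end = c(120L, 30L, 510L, 560L, 870L))
  cls <- classify_occurrence(spans, genes)
  expect_equal(cls, c("gene", "intergenic", "overlap", "intergenic",
                      "intergenic"))
  # no annotation: everything intergenic
  expect_equal(classify_occurrence(spans, genes[0, ]),
               rep("intergenic", 5))
})

test_that("containment in any one gene suffices, strand-agnostic", {
  genes <- tibble::tibble(record = "r", start = c(100L, 150L),
                          end = c(300L, 400L), strand = c("+", "-"),
                          label = c("a", "b"))
  # inside both overlapping genes, and inside only the minus-strand one
  spans <- tibble::tibble(record = "r", start = c(200L, 320L),
                          end = c(250L, 350L))
  expect_equal(classify_occurrence(spans, genes), c("gene", "gene"))
})

test_that("flanking-gene orientation follows the strand arrows", {
  genes <- toy_genes() # strands + - +
  # between g1 (+) and g2 (-): -> <- convergent
  # between g2 (-) and g3 (+): <- -> divergent
  spans <- tibble::tibble(record = "r",
                          start = c(520L, 850L, 10L),
                          end = c(560L, 870L, 30L))
  ori <- orientation_context(spans, genes)
  expect_equal(ori[1], "convergent")
  expect_equal(ori[2], "divergent")
  expect_equal(ori[3], "none") # no gene to the left

  genes2 <- dplyr::mutate(genes, strand = c("+", "+", "-"))
  expect_equal(orientation_context(spans, genes2)[1], "co_oriented")
})

test_that("location summaries aggregate percentages and orientations", {
  genes <- toy_genes()
  all_inter <- tibble::tibble(record = "r",
                              start = rep(520L, 9) + 0:8,
                              end = rep(560L, 9) + 0:8)
  s <- summarize_locations(all_inter, genes)
  expect_equal(s$intergenic_pct, 100)
  expect_equal(s$gene_pct, 0)
  expect_equal(s$n_convergent, 9L)

  mixed <- tibble::tibble(record = "r", start = c(100L, 520L),
                          end = c(120L, 560L))
  s <- summarize_locations(mixed, genes)
  expect_equal(c(s$gene_pct, s$intergenic_pct, s$overlap_pct),
               c(50, 50, 0))
  expect_error(summarize_locations(mixed[0, ], genes), "no occurrences")
})

test_that("percentages always sum to 100 on random fixtures", {
  genes <- generate_annotation(20000, 15, 600, seed = 61)
  withr::with_seed(62, {
    spans <- tibble::tibble(record = "synthetic",
                            start = sort(sample(0:19900, 40)))
    spans$end <- spans$start + 30L
  })
  spans$record <- genes$record[1]
  s <- summarize_locations(spans, genes)
  expect_equal(s$gene_pct + s$intergenic_pct + s$overlap_pct, 100,
               tolerance = 0.1)
})

test_that("classification is invariant under translation", {
  genes <- toy_genes()
  spans <- tibble::tibble(record = "r",
                          start = c(100L, 10L, 490L, 520L, 850L),
                          end = c(120L, 30L, 510L, 560L, 870L))
  shift <- 7919L
  genes2 <- dplyr::mutate(genes, start = start + shift, end = end + shift)
  spans2 <- dplyr::mutate(spans, start = start + shift, end = end + shift)
  expect_equal(classify_occurrence(spans2, genes2),
               classify_occurrence(spans, genes))
  expect_equal(orientation_context(spans2, genes2),
               orientation_context(spans, genes))
})

test_that("nearest-gene distance is signed by upstream/downstream", {
  genes <- toy_genes()
  # span at 520..560: left flank g1 (+) ends at 500 (gap 20),
  # right flank g2 (-) starts at 600 (gap 40) -> nearest is g1, span is
  # downstream of a + gene: +20
  ann <- annotate_occurrences(
    tibble::tibble(record = "r", start = 520L, end = 560L), genes)
  expect_equal(ann$nearest_gene_distance, 20L)
  # span at 560..590: right flank g2 (-) at gap 10 is nearest; span is
  # downstream of a - gene: +10
  ann <- annotate_occurrences(
    tibble::tibble(record = "r", start = 560L, end = 590L), genes)
  expect_equal(ann$nearest_gene_distance, 10L)
  # inside a gene: 0
  ann <- annotate_occurrences(
    tibble::tibble(record = "r", start = 100L, end = 120L), genes)
  expect_equal(ann$nearest_gene_distance, 0L)
})
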