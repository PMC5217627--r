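test_that("generation is reproducible bit-for-bit from the seed", {
  g1 <- generate_genome(20000, gc = 0.5, seed = 71)
  g2 <- generate_genome(20000, gc = 0.5, seed = 71)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_false(identical(
    g1$genome$sequence,
    generate_genome(20000, gc = 0.5, seed = 72)$genome$sequence))
  a1 <- generate_annotation(20000, 10, 500, seed = 73)
  expect_identical(a1, generate_annotation(20000, 10, 500, seed = 73))
})

test_that("truth-table loci are exactly recoverable by the scanner", {
  spec <- plant_spec("AAGGA", "ATGAA", 6, 20, "distinct", "both")
  syn <- generate_genome(50000, gc = 0.5, plants = spec, seed = 79)
  expect_equal(nrow(syn$truth), 20)
  occ_f <- collect_occurrences(syn$genome, "AAGGA", "ATGAA", scan_params())
  occ_f <- occ_f[occ_f$d == 6, ]
  plus <- syn$truth[syn$truth$strand == "+", ]
  expect_true(all(plus$start %in% occ_f$start))
  rc <- rc_pair("AAGGA", "ATGAA", 6)
  occ_r <- collect_occurrences(syn$genome, rc$A, rc$B, scan_params())
  minus <- syn$truth[syn$truth$strand == "-", ]
  expect_true(all(minus$start %in% occ_r$start[occ_r$d == 6]))
  # planted spacers survive verbatim on the plus strand
  sp <- occ_f$spacer[match(plus$start, occ_f$start)]
  expect_equal(sp, plus$spacer)
})

test_that("GC content and background occurrence rate behave as specified", {
  g <- generate_genome(200000, gc = 0.35, seed = 83)$genome$sequence
  gc_obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_equal(gc_obs, 0.35, tolerance = 0.01)

  # background rate of a fixed pentamer pair over the whole distance
  # range: Poisson with mean ~ K * L / 4^10, checked within 4 SD
  g5 <- generate_genome(500000, gc = 0.5, seed = 89)$genome
  occ <- collect_occurrences(g5, "CTAGT", "GATCC", scan_params())
  lambda <- 85 * 500000 / 4^10
  expect_lt(abs(nrow(occ) - lambda), 4 * sqrt(lambda))
})

test_that("spacer modes produce the intended diversity structure", {
  dup <- generate_genome(30000, plants = plant_spec("CGTAC", "GTACG", 10, 8,
                                                    "duplicated"),
                         seed = 91)
  expect_equal(length(unique(dup$truth$spacer)), 1)

  dis <- generate_genome(30000, plants = plant_spec("CGTAC", "GTACG", 10, 8,
                                                    "distinct"),
                         seed = 92)
  expect_equal(length(unique(dis$truth$spacer)), 8)

  mut <- generate_genome(60000,
                         plants = plant_spec("CGTAC", "GTACG", 20, 12,
                                             "mutant",
                                             mutant_identity = 0.9),
                         seed = 93)
  r <- greedy_reduce(unique(mut$truth$spacer))
  expect_lte(length(r$kept), 3) # family collapses at the 70% cutoff
})

test_that("order-1 Markov backgrounds are supported", {
  trans <- matrix(0.25, 4, 4)
  trans[1, ] <- c(0.7, 0.1, 0.1, 0.1) # A-rich runs after A
  g <- generate_genome(5000, seed = 94, markov = trans)$genome$sequence
  expect_equal(nchar(g), 5000)
  aa <- sum(strsplit(g, "")[[1]][-1] == "A" &
              strsplit(g, "")[[1]][-5000] == "A")
  expect_gt(aa, 0.05 * 5000) # far above the 1/16 iid rate would be ~0.0625
})

test_that("annotations cover the edge cases", {
  expect_equal(nrow(generate_annotation(1000, 0, 100, seed = 1)), 0)
  genes <- generate_annotation(10000, 12, 700, seed = 95)
  expect_true(all(genes$start < genes$end))
  expect_true(all(genes$end[-12] <= genes$start[-1])) # non-overlapping
  expect_true(all(genes$end <= 10000))
  # genes tiling almost everything: short spans are gene or overlap
  tiles <- tibble::tibble(record = "synthetic", start = 0L, end = 10000L,
                          strand = "+", label = "g")
  spans <- tibble::tibble(record = "synthetic", start = c(10L, 500L),
                          end = c(40L, 530L))
  expect_true(all(classify_occurrence(spans, tiles) == "gene"))
})

test_that("infeasible packing raises an error", {
  expect_error(generate_genome(100, plants = plant_spec("AAAAA", "CCCCC", 50,
                                                        10, "distinct"),
                               seed = 96),
               "footprint")
})

test_that("fixtures survive the real FASTA/GFF3 round trip", {
  syn <- generate_genome(5000, plants = plant_spec("CGAAA", "TTTCG", 19, 3,
                                                   "distinct"),
                         seed = 97)
  genes <- generate_annotation(5000, 4, 400, seed = 98)
  fa <- withr::local_tempfile(fileext = ".fna")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(syn$genome, fa)
  write_gff3(genes, gff, seq_lengths = c(synthetic = 5000L))
  expect_equal(read_genome_fasta(fa)$sequence, syn$genome$sequence)
  back <- read_annotation(gff, "gff3")
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
})
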