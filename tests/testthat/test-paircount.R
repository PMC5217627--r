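test_that("toy sequences produce the expected raw counts", {
  g <- make_genome(paste0("AAAAA", "GCGTC", "CCCCC"))
  sc <- scan_pair_counts(g, scan_params(5, 5, 10))
  row <- dplyr::filter(sc, A == "AAAAA", B == "CCCCC")
  expect_equal(row$d, 5L)
  expect_equal(row$count, 1L)

  # 16 consecutive A: AAAAA at starts 0..11; (AAAAA, AAAAA) with d = 5
  # needs windows of 15 -> starts 0 and 1
  g <- make_genome(strrep("A", 16))
  sc <- scan_pair_counts(g, scan_params(5, 5, 9))
  expect_equal(dplyr::filter(sc, d == 5)$count, 2L)
  expect_equal(dplyr::filter(sc, d == 6)$count, 1L)
})

test_that("scan matches a brute-force double loop on random sequences", {
  par <- scan_params(5, 5, 20)
  for (seed in c(3, 4)) {
    s <- random_dna(3000, seed)
    got <- scan_pair_counts(make_genome(s), par) |>
      dplyr::arrange(A, B, d)
    want <- naive_scan_counts(s, 5, 5, 20) |>
      dplyr::arrange(A, B, d)
    expect_equal(got, want)
  }
})

test_that("multi-record genomes aggregate counts over records", {
  s1 <- random_dna(1500, 5); s2 <- random_dna(1500, 6)
  par <- scan_params(5, 5, 12)
  both <- scan_pair_counts(make_genome(s1, s2), par)
  want <- naive_scan_counts(c(s1, s2), 5, 5, 12)
  expect_equal(sum(both$count), sum(want$count))
  expect_equal(dplyr::arrange(both, A, B, d),
               dplyr::arrange(want, A, B, d))
})

test_that("k-mers containing N are skipped", {
  g <- make_genome(paste0("AAAAA", "GCGTC", "CCNCC", "TTTTT", "GGGGG"))
  sc <- scan_pair_counts(g, scan_params(5, 5, 10))
  expect_false(any(grepl("N", sc$A) | grepl("N", sc$B)))
  expect_false(any(sc$A == "CCNCC" | sc$B == "CCNCC"))
})

test_that("occurrence collection extracts spacers and respects bounds", {
  g <- make_genome(paste0("AAAAA", "GCGTC", "CCCCC"))
  occ <- collect_occurrences(g, "AAAAA", "CCCCC", scan_params(5, 5, 10))
  expect_equal(occ$spacer, "GCGTC")
  expect_equal(occ$start, 0L)
  expect_equal(occ$d, 5L)

  # pair absent
  expect_equal(nrow(collect_occurrences(g, "TTTTT", "CCCCC",
                                        scan_params(5, 5, 10))), 0)
  # B would run off the end -> excluded
  g2 <- make_genome(paste0("AAAAA", "GCGTC", "CCCC"))
  expect_equal(nrow(collect_occurrences(g2, "AAAAA", "CCCCC",
                                        scan_params(5, 5, 10))), 0)
})

test_that("identical spacers are counted once; distinct ones separately", {
  par <- scan_params(5, 5, 9)
  occ <- tibble::tibble(record = "r", start = c(0L, 100L),
                        d = c(5L, 5L), spacer = c("GCGTC", "GCGTC"))
  h <- unique_spacer_histogram(occ, par)
  expect_equal(h$counts$count[h$counts$d == 5], 1L)

  occ$spacer[2] <- "GCGTA"
  h <- unique_spacer_histogram(occ, par)
  expect_equal(h$counts$count[h$counts$d == 5], 2L)
})

test_that("histogram totals, modal distance and fmax are derived correctly", {
  par <- scan_params(5, 5, 9)
  occ <- tibble::tibble(
    record = "r", start = 1:5 * 100L,
    d = c(5L, 5L, 5L, 7L, 7L),
    spacer = c("AAAAA", "CCCCC", "GGGGG", "TTTTTTT", "ACGTACG"))
  h <- unique_spacer_histogram(occ, par, "XXXXX", "YYYYY")
  expect_equal(h$n, 5L)
  expect_equal(h$d_star, 5L)
  expect_equal(h$fmax, 3L)
  td <- tidy(h)
  expect_equal(sum(td$count), 5L)
  expect_equal(td$d[td$modal], 5L)
})

test_that("unique-spacer counts never exceed raw counts", {
  par <- scan_params(5, 5, 15)
  s <- paste0(random_dna(2000, 9), strrep(paste0("AAGGA", "GCGTCC", "ATGAA"), 3))
  g <- make_genome(s)
  raw <- scan_pair_counts(g, par)
  top <- head(dplyr::arrange(raw, dplyr::desc(count)), 10)
  for (i in seq_len(nrow(top))) {
    occ <- collect_occurrences(g, top$A[i], top$B[i], par)
    h <- unique_spacer_histogram(occ, par)
    rawpair <- dplyr::filter(raw, A == top$A[i], B == top$B[i])
    cmp <- dplyr::left_join(h$counts, rawpair, by = "d",
                            suffix = c("_uni", "_raw"))
    cmp$count_raw[is.na(cmp$count_raw)] <- 0L
    expect_true(all(cmp$count_uni <= cmp$count_raw))
  }
})

test_that("strand symmetry: rc pair counts on the reverse complement match", {
  par <- scan_params(5, 5, 15)
  for (seed in c(11, 12)) {
    s <- paste0(random_dna(1500, seed),
                strrep(paste0("AAGGA", random_dna(6, seed + 50), "ATGAA"), 2))
    grc <- make_genome(revcomp(s))
    occ_f <- collect_occurrences(make_genome(s), "AAGGA", "ATGAA", par)
    rc <- rc_pair("AAGGA", "ATGAA", 6)
    occ_r <- collect_occurrences(grc, rc$A, rc$B, par)
    hf <- unique_spacer_histogram(occ_f, par)
    hr <- unique_spacer_histogram(occ_r, par)
    expect_equal(hf$counts, hr$counts)
  }
})

test_that("raw per-pair stats agree with the raw count table", {
  s <- random_dna(4000, 21)
  par <- scan_params(5, 5, 20)
  tab <- scan_pair_counts(make_genome(s), par)
  st <- scan_pair_stats(make_genome(s), par)
  agg <- tab |>
    dplyr::group_by(A, B) |>
    dplyr::summarise(n_raw = sum(count), fmax_raw = max(count),
                     occupied = dplyr::n(), .groups = "drop")
  got <- st |> dplyr::select(A, B, n_raw, fmax_raw, occupied) |>
    dplyr::arrange(A, B)
  expect_equal(got, dplyr::arrange(agg, A, B))
})
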