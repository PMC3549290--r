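test_that("length filtering keeps 18-34 nt inclusive and drops excluded regions", {
  reads <- dplyr::bind_rows(
    read_row("chr1", 100, 117),  # 17 nt
    read_row("chr1", 100, 118),  # 18 nt
    read_row("chr1", 100, 134),  # 34 nt
    read_row("chr1", 100, 135),  # 35 nt
    read_row("chrM", 100, 124))
  kept <- filter_small_rnas(reads, organelle_chroms = "chrM")
  expect_equal(kept$length, c(18L, 34L))

  ann <- make_ann(tx("R1", "LR1", "chr1", "+", "rRNA", list(c(1000, 1400))))
  reads2 <- dplyr::bind_rows(read_row("chr1", 1100, 1124),
                             read_row("chr1", 5000, 5024))
  kept2 <- filter_small_rnas(reads2, exclusion_ann = ann)
  expect_equal(kept2$start, 5000L)
})

test_that("a planted mixed library filters to the expected survivor count", {
  ann <- make_ann(tx("R1", "LR1", "chr1", "+", "rRNA", list(c(1000, 2000))))
  set.seed(7)
  good <- purrr::map_dfr(1:85, \(i) read_row("chr1", 5000 + i * 40,
                                             5000 + i * 40 + 24))
  in_rrna <- purrr::map_dfr(1:10, \(i) read_row("chr1", 1000 + i * 50,
                                                1000 + i * 50 + 21))
  bad_len <- purrr::map_dfr(1:5, \(i) read_row("chr1", 60000 + i * 50,
                                               60000 + i * 50 + 16))
  all_reads <- dplyr::bind_rows(good, in_rrna, bad_len)
  expect_equal(nrow(all_reads), 100L)
  expect_equal(nrow(filter_small_rnas(all_reads, exclusion_ann = ann)), 85L)
})

test_that("nat-siRNA assignment requires full containment in one overlap interval", {
  pair <- pair_row("P", "M", "chr1", list(c(150, 200)))
  expect_equal(nrow(assign_nat_sirnas(read_row("chr1", 160, 184), pair)$plus), 1L)
  expect_equal(nrow(assign_nat_sirnas(read_row("chr1", 140, 164), pair)$plus), 0L)
  split_pair <- pair_row("P", "M", "chr1", list(c(50, 100), c(200, 250)))
  # spans the gap: no single interval contains it
  r <- read_row("chr1", 90, 210)
  expect_equal(nrow(assign_nat_sirnas(r, split_pair)$plus), 0L)
  # minus-strand reads are attributed to the minus member
  rm <- read_row("chr1", 60, 84, strand = "-")
  expect_equal(nrow(assign_nat_sirnas(rm, split_pair)$minus), 1L)
})

test_that("assignment agrees with a brute-force containment oracle", {
  set.seed(11)
  for (i in 1:200) {
    iv_raw <- sort(sample.int(500, 4))
    pair <- pair_row("P", "M", "chr1",
                     list(c(iv_raw[1], iv_raw[2]), c(iv_raw[3], iv_raw[4])))
    s <- sample.int(480, 1)
    r <- read_row("chr1", s, min(s + sample(18:34, 1), 500))
    got <- nrow(assign_nat_sirnas(r, pair)$plus) == 1L
    want <- containment_oracle(r$start, r$end, pair$overlap_intervals[[1]])
    expect_identical(got, want)
  }
})

test_that("strand-bias classes follow the one-strand / fold / balanced rules", {
  expect_equal(classify_strand_bias(10, 0), "one-strand-plus")
  expect_equal(classify_strand_bias(0, 7), "one-strand-minus")
  expect_equal(classify_strand_bias(10, 2, fold = 5), "plus-biased")
  expect_equal(classify_strand_bias(10, 2, fold = 2), "plus-biased")
  expect_equal(classify_strand_bias(9, 2, fold = 5), "balanced")
  expect_equal(classify_strand_bias(4, 8, fold = 2), "minus-biased")
  expect_equal(classify_strand_bias(0, 0), "balanced")
  expect_error(classify_strand_bias(1, 1, fold = -1), "non-negative")
})

test_that("densities are unique reads per kb with an infinite marker for empty flanks", {
  ann <- make_ann(
    tx("P", "LP", "chr1", "+", "CDS-p", list(c(0, 2500))),
    tx("M", "LM", "chr1", "-", "ncRNA", list(c(1000, 1500))))
  pair <- dplyr::bind_cols(pair_row("P", "M", "chr1", list(c(1000, 1500))))
  reads <- purrr::map_dfr(1:10, \(i) read_row("chr1", 1000 + i * 40,
                                              1000 + i * 40 + 24))
  flank_reads <- purrr::map_dfr(1:4, \(i) read_row("chr1", i * 100,
                                                   i * 100 + 24))
  d <- sirna_density(pair, dplyr::bind_rows(reads, flank_reads), ann)
  expect_equal(d$density_overlap, 20)      # 10 reads / 0.5 kb
  expect_equal(d$density_flank, 2)         # 4 reads / 2 kb
  expect_equal(d$enrichment_ratio, 10)
  expect_true(d$enriched)

  d2 <- sirna_density(pair, reads, ann)
  expect_equal(d2$enrichment_ratio, Inf)
  expect_true(d2$enriched)
})

test_that("overlap exclusivity needs all pair reads inside and more than five uniques", {
  ann <- make_ann(
    tx("P", "LP", "chr1", "+", "CDS-p", list(c(0, 2500))),
    tx("M", "LM", "chr1", "-", "ncRNA", list(c(1000, 1500))))
  pair <- pair_row("P", "M", "chr1", list(c(1000, 1500)))
  six <- purrr::map_dfr(1:6, \(i) read_row("chr1", 1000 + i * 40,
                                           1000 + i * 40 + 24))
  expect_true(overlap_exclusivity(pair, six, ann))
  with_flank <- dplyr::bind_rows(
    purrr::map_dfr(1:10, \(i) read_row("chr1", 1000 + i * 40,
                                       1000 + i * 40 + 24)),
    read_row("chr1", 100, 124))
  expect_false(overlap_exclusivity(pair, with_flank, ann))
  five <- six[1:5, ]
  expect_false(overlap_exclusivity(pair, five, ann))  # strict > 5
})

test_that("sequence statistics histogram lengths and 5' nucleotides", {
  reads <- dplyr::bind_rows(
    read_row("chr1", 0, 21, first_nt = "A"),
    read_row("chr1", 100, 124, first_nt = "A"),
    read_row("chr1", 200, 224, first_nt = "G"),
    read_row("chr1", 300, 324, first_nt = "N"))
  st <- sequence_stats(reads)
  expect_equal(st$length_histogram$n_unique[st$length_histogram$length == 21], 1L)
  expect_equal(st$length_histogram$n_unique[st$length_histogram$length == 24], 3L)
  # N excluded from the denominator
  freq <- stats::setNames(st$first_nt$frequency, st$first_nt$first_nt)
  expect_equal(unname(freq["A"]), 2 / 3)
  expect_equal(unname(freq["G"]), 1 / 3)
  empty <- sequence_stats(reads[0, ])
  expect_true(all(empty$length_histogram$n_unique == 0))
  expect_true(all(empty$first_nt$frequency == 0))
})

test_that("genomic context follows the precedence hierarchy", {
  ann <- make_ann(
    tx("TE", "LTE", "chr1", "+", "transposon", list(c(10000, 12000))),
    tx("G1", "LG1", "chr1", "+", "CDS-p", list(c(9500, 10500), c(11500, 13000))),
    tx("G2", "LG2", "chr1", "+", "CDS-p", list(c(20000, 20500), c(21500, 22000))))
  reads <- dplyr::bind_rows(
    read_row("chr1", 11000, 11024),   # transposon even though in G1 intron
    read_row("chr1", 20100, 20124),   # exon of G2
    read_row("chr1", 21000, 21024),   # intron of G2
    read_row("chr1", 19780, 19804),   # 200 bp 5' of + strand G2: upstream
    read_row("chr1", 22400, 22424),   # downstream window of G2
    read_row("chr1", 50000, 50024))   # > flank_bp from everything
  ctx <- classify_genomic_context(reads, ann)
  expect_equal(ctx, c("transposon", "exon", "intron", "upstream",
                      "downstream", "intergenic"))
})

test_that("profiles conserve counts and respect containment", {
  fc <- default_fixture()
  reads <- purrr::imap_dfr(as.list(fixture_beds(fc)),
                           \(p, cond) read_smallrna_bed(p, cond))
  reads <- filter_small_rnas(reads, exclusion_ann = fc$fx$ann,
                             organelle_chroms = fc$cfg$organelle_chrom)
  pairs <- select_representatives(detect_candidate_pairs(fc$fx$ann))
  prof <- sirna_profiles(reads, pairs, fc$fx$ann)
  expect_equal(nrow(prof), nrow(pairs) * length(fc$cfg$conditions))
  expect_true(all(prof$plus_total >= prof$plus_unique))
  expect_true(all(prof$minus_total >= prof$minus_unique))
  expect_true(all(prof$plus_unique >= 0 & prof$minus_unique >= 0))
  # spot-check containment invariant on a handful of pairs
  for (i in seq(1, nrow(pairs), by = 17)) {
    nat <- assign_nat_sirnas(reads[reads$condition == fc$cfg$conditions[1] &
                                     reads$chrom == pairs$chrom[i], ], pairs[i, ])
    iv <- pairs$overlap_intervals[[i]]
    both <- dplyr::bind_rows(nat$plus, nat$minus)
    if (nrow(both)) {
      expect_true(all(vapply(seq_len(nrow(both)), \(j)
        containment_oracle(both$start[j], both$end[j], iv), logical(1))))
    }
  }
})
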