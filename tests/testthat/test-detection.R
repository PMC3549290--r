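test_that("exonic overlap is the merged union of exon intersections", {
  a <- tibble::tibble(exon_start = 100L, exon_end = 200L)
  b <- tibble::tibble(exon_start = 150L, exon_end = 250L)
  ov <- exonic_overlap(a, b)
  expect_equal(ov$intervals, tibble::tibble(start = 150L, end = 200L))
  expect_equal(ov$length, 50L)

  a2 <- tibble::tibble(exon_start = c(0L, 200L), exon_end = c(100L, 300L))
  b2 <- tibble::tibble(exon_start = 50L, exon_end = 250L)
  ov2 <- exonic_overlap(a2, b2)
  expect_equal(ov2$intervals, tibble::tibble(start = c(50L, 200L),
                                             end = c(100L, 250L)))
  expect_equal(ov2$length,
               overlap_length_oracle(a2, b2, max_pos = 300))

  # half-open abutment is not overlap
  ov3 <- exonic_overlap(tibble::tibble(exon_start = 0L, exon_end = 50L),
                        tibble::tibble(exon_start = 50L, exon_end = 80L))
  expect_equal(ov3$length, 0L)
  expect_equal(nrow(ov3$intervals), 0L)
})

test_that("overlap length matches the per-base oracle on random exon sets", {
  set.seed(42)
  for (i in 1:200) {
    a <- random_exons()
    b <- random_exons()
    expect_equal(exonic_overlap(a, b)$length,
                 overlap_length_oracle(a, b, max_pos = 400))
  }
})

test_that("orientation classifies on spans: enclosed, convergent, divergent", {
  expect_equal(classify_orientation(100L, 500L, 200L, 300L), "enclosed")
  expect_equal(classify_orientation(100L, 300L, 250L, 400L), "convergent")
  expect_equal(classify_orientation(250L, 400L, 100L, 300L), "divergent")
  # equal spans: containment in both directions
  expect_equal(classify_orientation(100L, 300L, 100L, 300L), "enclosed")
  # vectorised
  expect_equal(classify_orientation(c(100L, 100L), c(500L, 300L),
                                    c(200L, 250L), c(300L, 400L)),
               c("enclosed", "convergent"))
})

test_that("candidate detection applies the strict >25 rule and biotype exclusion", {
  ann <- make_ann(
    # three genuine antisense pairs, overlaps 100 nt
    tx("A1", "LA1", "chr1", "+", "CDS-p", list(c(0, 500))),
    tx("B1", "LB1", "chr1", "-", "ncRNA", list(c(400, 900))),
    tx("A2", "LA2", "chr1", "+", "CDS-n", list(c(2000, 2500))),
    tx("B2", "LB2", "chr1", "-", "CDS-p", list(c(2400, 2900))),
    tx("A3", "LA3", "chr2", "+", "ncRNA", list(c(0, 500))),
    tx("B3", "LB3", "chr2", "-", "ncRNA", list(c(400, 900))),
    # same-strand overlap: never a pair
    tx("S1", "LS1", "chr1", "+", "CDS-p", list(c(5000, 5600))),
    tx("S2", "LS2", "chr1", "+", "CDS-p", list(c(5500, 6100))),
    # exactly 25 nt: excluded by the strict inequality
    tx("E1", "LE1", "chr2", "+", "CDS-p", list(c(5000, 5500))),
    tx("E2", "LE2", "chr2", "-", "ncRNA", list(c(5475, 6000))),
    # transposon partner: counted pre-exclusion, dropped after
    tx("X1", "LX1", "chr2", "+", "CDS-p", list(c(8000, 8500))),
    tx("X2", "LX2", "chr2", "-", "transposon", list(c(8400, 8900))))
  pairs <- detect_candidate_pairs(ann)
  expect_equal(nrow(pairs), 3L)
  expect_equal(attr(pairs, "n_candidates"), 4L)
  expect_setequal(pairs$plus_id, c("A1", "A2", "A3"))
  full <- detect_candidate_pairs(ann, keep_excluded = TRUE)
  expect_equal(nrow(full), 4L)
  expect_equal(full$plus_id[full$excluded], "X1")
  expect_true(is.na(full$partner_class[full$excluded]))

  # raising the threshold never increases the pair count
  n_prev <- Inf
  for (mo in c(25, 50, 99, 100, 250)) {
    n <- nrow(detect_candidate_pairs(ann, min_overlap = mo))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_equal(nrow(detect_candidate_pairs(ann, min_overlap = 100)), 0L)

  # symmetry: row order of the annotation does not matter
  shuffled <- cisnat:::new_annotation(ann[rev(seq_len(nrow(ann))), ])
  pairs2 <- detect_candidate_pairs(shuffled)
  expect_equal(pairs[, names(pairs) != "overlap_intervals"],
               pairs2[, names(pairs2) != "overlap_intervals"])
})

test_that("representative selection keeps the longest overlap with lexicographic ties", {
  ann <- make_ann(
    tx("A1", "LA", "chr1", "+", "CDS-p", list(c(0, 1000))),
    tx("A2", "LA", "chr1", "+", "CDS-p", list(c(0, 520))),
    tx("B1", "LB", "chr1", "-", "ncRNA", list(c(400, 700))),
    # distinct locus pair: never compared with the LA-LB group
    tx("C1", "LC", "chr1", "+", "CDS-p", list(c(5000, 5500))),
    tx("D1", "LD", "chr1", "-", "ncRNA", list(c(5400, 5900))))
  pairs <- detect_candidate_pairs(ann)
  expect_equal(nrow(pairs), 3L)
  rep <- select_representatives(pairs)
  expect_equal(nrow(rep), 2L)
  expect_true(all(pair_key(c("A1", "C1"), c("B1", "D1")) %in%
                    pair_key(rep$plus_id, rep$minus_id)))

  # tie on overlap length: smallest (plus_id, minus_id) wins
  tie <- make_ann(
    tx("A1", "LA", "chr1", "+", "CDS-p", list(c(0, 500))),
    tx("B1", "LB", "chr1", "-", "ncRNA", list(c(300, 800))),
    tx("B2", "LB", "chr1", "-", "ncRNA", list(c(300, 900))))
  rep_tie <- select_representatives(detect_candidate_pairs(tie))
  expect_equal(rep_tie$minus_id, "B1")
})

test_that("partner classes are unordered labels over the six combinations", {
  expect_equal(partner_class("CDS-p", "ncRNA"), "CDS-p vs ncRNA")
  expect_equal(partner_class("ncRNA", "CDS-p"), "CDS-p vs ncRNA")
  expect_equal(partner_class("CDS-n", "CDS-n"), "CDS-n vs CDS-n")
  combos <- tidyr::expand_grid(a = c("CDS-p", "CDS-n", "ncRNA"),
                               b = c("CDS-p", "CDS-n", "ncRNA"))
  expect_length(unique(partner_class(combos$a, combos$b)), 6L)
  expect_error(partner_class("CDS-p", "transposon"), "filtered")
})

test_that("every emitted pair has exactly one orientation (partition)", {
  fc <- default_fixture()
  pairs <- detect_candidate_pairs(fc$fx$ann)
  counts <- table(factor(pairs$orientation,
                         levels = c("enclosed", "convergent", "divergent")))
  expect_equal(sum(counts), nrow(pairs))
})
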