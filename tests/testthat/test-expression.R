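test_that("the expressed call needs both FPKMs positive and nat-siRNA evidence", {
  expect_true(call_expressed(3.2, 0.8, 2))
  expect_false(call_expressed(3.2, 0, 9))
  expect_false(call_expressed(3.2, 0.8, 0))
  expect_true(call_expressed(0.01, 0.01, 1))
})

test_that("pair expression errors name the missing transcript and condition", {
  pairs <- pair_row("P1", "M1", "chr1", list(c(0, 100)))
  expr <- tibble::tibble(transcript_id = c("P1", "M1", "P1"),
                         condition = c("control", "control", "cold"),
                         fpkm = 1, fragment_count = 5, library_size = 1e6)
  profiles <- tibble::tibble(pair_id = "P1|M1",
                             condition = c("control", "cold"),
                             plus_unique = 1L, minus_unique = 0L)
  expect_error(pair_expression(pairs, expr, profiles), "M1.*cold")
})

test_that("co-expression sets reproduce a planted membership matrix", {
  # 4 pairs x 3 conditions with known membership
  member <- tibble::tibble(
    pair_id = rep(c("a", "b", "c", "d"), each = 3),
    condition = rep(c("cold", "control", "salt"), 4),
    expressed = c(TRUE, TRUE, TRUE,     # a: everywhere
                  TRUE, FALSE, FALSE,   # b: cold only
                  FALSE, TRUE, TRUE,    # c: control + salt
                  FALSE, FALSE, FALSE)) # d: nowhere
  sets <- coexpression_sets(member)
  expect_setequal(sets$sets$co_expressed, "a")
  expect_setequal(sets$sets$union, c("a", "b", "c"))
  expect_setequal(sets$sets$cold, c("a", "b"))
  counts <- stats::setNames(sets$counts$n, sets$counts$set)
  expect_equal(unname(counts[c("cold", "control", "salt", "co_expressed", "union")]),
               c(2L, 2L, 2L, 1L, 3L))
})

test_that("subgroup rules partition the ratio plane", {
  expect_equal(classify_subgroup(2.0, -1.5), "2")
  expect_equal(classify_subgroup(-2.0, 1.5), "3")
  expect_equal(classify_subgroup(2.0, 1.5), "4")
  expect_equal(classify_subgroup(-2.0, -1.5), "5")
  expect_equal(classify_subgroup(0.2, -0.3), "1")
  expect_equal(classify_subgroup(2.0, -0.2), "outlier")
  # exactly one label everywhere on a grid
  grid <- tidyr::expand_grid(ds = seq(-3, 3, 0.5), da = seq(-3, 3, 0.5))
  labels <- classify_subgroup(grid$ds, grid$da)
  expect_true(all(labels %in% c("1", "2", "3", "4", "5", "outlier")))
  expect_false(anyNA(labels))
})

test_that("pearson_r2 matches hand computation and rejects degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r2(x, x), 1)
  expect_equal(pearson_r2(x, -2 * x), 1)
  expect_equal(pearson_r2(x, c(1, 2, 4)), 0.96428571, tolerance = 1e-7)
  expect_error(pearson_r2(x, c(2, 2, 2)), "variance")
  expect_error(pearson_r2(x, c(1, 2)), "equal length")
})

test_that("the Fisher exact p matches independent oracles", {
  # degenerate identical libraries
  expect_equal(fisher_exact_p(0, 1000, 0, 1000), 1)
  # full enumeration example
  expect_equal(fisher_exact_p(3, 997, 30, 970), fisher_oracle(3, 997, 30, 970),
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(3, 997, 30, 970),
               stats::fisher.test(matrix(c(3, 997, 30, 970), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  set.seed(5)
  for (i in 1:100) {
    r1 <- sample.int(200, 1); r2 <- sample.int(200, 1)
    a <- sample.int(r1 + 1, 1) - 1L
    cc <- sample.int(r2 + 1, 1) - 1L
    p <- fisher_exact_p(a, r1 - a, cc, r2 - cc)
    expect_equal(p, fisher_oracle(a, r1 - a, cc, r2 - cc), tolerance = 1e-12)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  expect_error(fisher_exact_p(-1, 10, 2, 8), "negative")
})

test_that("DEG calls combine FPKM fold change with count-based significance", {
  res <- fisher_exact_deg(count_stress = 3, lib_stress = 1000,
                          count_control = 30, lib_control = 1000,
                          fpkm_stress = 8, fpkm_control = 2)
  expect_equal(res$fold_change, 8.1 / 2.1, tolerance = 1e-12)
  expect_equal(res$p_value, fisher_oracle(3, 997, 30, 970), tolerance = 1e-12)
  expect_equal(res$is_deg, abs(log2(8.1 / 2.1)) >= 1 & res$p_value < 0.001)
  # fold criterion alone is not enough
  res2 <- fisher_exact_deg(12, 1e6, 10, 1e6, 8, 2)
  expect_false(res2$is_deg)
  # neither is significance without fold
  res3 <- fisher_exact_deg(500, 1e6, 250, 1e6, 3, 2)
  expect_false(res3$is_deg)
  expect_error(fisher_exact_deg(10, 5, 1, 100, 1, 1), "library size")
})

test_that("stress-preferential flags require absence under control", {
  pe <- tibble::tibble(
    pair_id = rep(c("a", "b", "c"), each = 4),
    condition = rep(c("control", "cold", "salt", "drought"), 3),
    expressed = c(FALSE, TRUE, FALSE, FALSE,   # a: cold only
                  TRUE, TRUE, FALSE, FALSE,    # b: control + cold
                  FALSE, FALSE, TRUE, TRUE))   # c: salt + drought
  sp <- stress_preferential(pe, "control")
  expect_equal(sp$cold, c(TRUE, FALSE, FALSE))
  expect_equal(sp$salt, c(FALSE, FALSE, TRUE))
  expect_equal(sp$drought, c(FALSE, FALSE, TRUE))
  expect_equal(sp$any_stress, c(TRUE, FALSE, TRUE))
})

test_that("domain enrichment tests terms against the background-only set", {
  target <- sprintf("t%02d", 1:10)
  background <- c(target, sprintf("b%03d", 1:1000))
  dmap <- tibble::tibble(
    transcript_id = c(target, sprintf("b%03d", 1:10)),
    domain_term = "KINASE")
  res <- domain_enrichment(target, background, dmap)
  expect_equal(res$direction, "enriched")
  expect_true(res$significant)
  expect_equal(res$p_value, fisher_oracle(10, 0, 10, 990), tolerance = 1e-12)

  # identical frequency: not significant
  dmap2 <- tibble::tibble(transcript_id = c(target[1:5], sprintf("b%03d", 1:500)),
                          domain_term = "PPR")
  res2 <- domain_enrichment(target, background, dmap2)
  expect_false(res2$significant)
  expect_gt(res2$p_value, 0.5)

  # absent from target: depleted
  dmap3 <- tibble::tibble(transcript_id = sprintf("b%03d", 1:300),
                          domain_term = "LRR")
  expect_equal(domain_enrichment(target, background, dmap3)$direction, "depleted")

  expect_error(domain_enrichment("zzz", background, dmap), "subset")
  expect_error(domain_enrichment(character(0), character(0), dmap), "empty")
})
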