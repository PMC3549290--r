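test_that("the planted annotation is recovered exactly by detection", {
  fc <- default_fixture()
  truth <- fc$fx$truth$pairs
  cand <- detect_candidate_pairs(fc$fx$ann, keep_excluded = TRUE)
  # every candidate is planted and every planted pair is found
  expect_setequal(pair_key(cand$plus_id, cand$minus_id), truth$pair_id)
  m <- dplyr::inner_join(cand |> dplyr::mutate(pair_id = pair_key(plus_id, minus_id)),
                         truth, by = "pair_id", suffix = c("", "_t"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$orientation, m$orientation_t)
  expect_equal(m$overlap_length, m$overlap_length_t)
  expect_equal(m$excluded, m$excluded_t)
  keep <- !m$excluded
  expect_equal(m$partner_class[keep], m$partner_class_t[keep])
  # representative selection matches the planted flags
  rep <- select_representatives(detect_candidate_pairs(fc$fx$ann))
  expect_setequal(pair_key(rep$plus_id, rep$minus_id),
                  truth$pair_id[truth$representative & !truth$excluded])
})

test_that("decoys behave as planted: counted before, absent after exclusion", {
  fc <- default_fixture()
  cand <- detect_candidate_pairs(fc$fx$ann)
  n_excluded <- sum(fc$fx$truth$pairs$excluded)
  expect_equal(attr(cand, "n_candidates") - nrow(cand), n_excluded)
  expect_gt(n_excluded, 0L)
  # sub-threshold (exactly 25 nt) decoys never appear, even pre-exclusion
  full <- detect_candidate_pairs(fc$fx$ann, keep_excluded = TRUE)
  expect_false(any(full$overlap_length <= 25))
})

test_that("fixture bundles load cleanly and match the manifest", {
  fc <- default_fixture()
  ann <- read_gff3(fc$fx$gff3)
  expect_equal(as.data.frame(ann), as.data.frame(fc$fx$ann))
  reads <- read_smallrna_bed(fc$fx[[paste0("bed_", fc$cfg$conditions[1])]],
                             fc$cfg$conditions[1])
  expect_gt(nrow(reads), 0)
  expect_true(all(reads$copies >= 1))
  expr <- read_expression_table(fc$fx$expression)
  expect_setequal(unique(expr$condition), fc$cfg$conditions)
  manifest <- read_truth(file.path(fc$dir, "truth.json"))
  expect_equal(nrow(manifest$pairs), nrow(fc$fx$truth$pairs))
  rep <- select_representatives(detect_candidate_pairs(ann))
  expect_equal(nrow(rep),
               sum(manifest$pairs$representative & !manifest$pairs$excluded))
})

test_that("silent pairs are never called expressed", {
  fc <- default_result()
  res <- fc$result
  silent_ids <- fc$fx$truth$pairs$pair_id[fc$fx$truth$pairs$silent]
  pe <- res$pair_expr[res$pair_expr$pair_id %in% silent_ids, ]
  expect_gt(nrow(pe), 0)
  expect_false(any(pe$expressed))
})

test_that("identical seeds reproduce a fixture byte for byte", {
  cfg <- replicate_config(seed = 77)
  d1 <- file.path(tempdir(), "cisnat-det-1")
  d2 <- file.path(tempdir(), "cisnat-det-2")
  write_fixture(cfg, d1, overwrite = TRUE)
  write_fixture(cfg, d2, overwrite = TRUE)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed produces different data
  d3 <- file.path(tempdir(), "cisnat-det-3")
  write_fixture(replicate_config(seed = 78), d3, overwrite = TRUE)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "annotation.gff3"))),
                         unname(tools::md5sum(file.path(d3, "annotation.gff3")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("the fixture writer refuses to clobber and sizing errors are caught", {
  d <- file.path(tempdir(), "cisnat-nonempty")
  dir.create(d, showWarnings = FALSE)
  writeLines("x", file.path(d, "existing.txt"))
  expect_error(write_fixture(replicate_config(1), d), "not empty")
  unlink(d, recursive = TRUE)
  cfg_small <- replicate_config(1)
  cfg_small$chromosome_length <- 1000
  expect_error(generate_annotation(cfg_small), "too small")
})

test_that("zero-read and planted-bias behaviour survives the generator", {
  cfg <- replicate_config(seed = 3)
  gen <- generate_annotation(cfg)
  reads <- generate_smallrna_reads(cfg, gen$ann, gen$truth, gen$chrom_lengths)
  truth <- gen$truth$pairs
  one_strand <- truth[!is.na(truth$bias_class) &
                        truth$bias_class == "one-strand-plus", ]
  for (i in seq_len(nrow(one_strand))) {
    pr <- one_strand[i, ]
    pairs <- detect_candidate_pairs(gen$ann)
    pair <- pairs[pairs$plus_id == pr$plus_id & pairs$minus_id == pr$minus_id, ]
    nat <- assign_nat_sirnas(reads[reads$condition == "control", ], pair)
    expect_gt(nrow(nat$plus), 0)
    expect_equal(nrow(nat$minus), 0)
  }
})

test_that("flat key-value config files round into simulation_config", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\tvalue",
               "seed\t9",
               "conditions\tcontrol,cold",
               "pairs_per_orientation\tenclosed=3,convergent=3,divergent=3",
               "n_stress_exclusive\tcold=1",
               "n_silent_pairs\t0"), path)
  cfg <- simulation_config_from_file(path)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$conditions, c("control", "cold"))
  expect_equal(unname(cfg$pairs_per_orientation["enclosed"]), 3)
  expect_equal(cfg$n_silent_pairs, 0)
  writeLines(c("key\tvalue", "no_such_key\t1"), path)
  expect_error(simulation_config_from_file(path), "unknown configuration")
})
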