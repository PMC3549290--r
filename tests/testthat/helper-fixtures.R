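# hand-built annotation rows: tx("T1", "L1", "chr1", "+", "CDS-p", list(c(0, 100), c(200, 300)))
tx <- function(id, locus, chrom, strand, biotype, exons) {
  ex <- do.call(rbind, exons)
  tibble::tibble(transcript_id = id, locus_id = locus, chrom = chrom,
                 strand = strand, biotype = biotype,
                 exon_start = as.integer(ex[, 1]), exon_end = as.integer(ex[, 2]))
}

make_ann <- function(...) cisnat:::new_annotation(dplyr::bind_rows(...))

# minimal one-row pair tibble for the small-RNA operations
pair_row <- function(plus_id, minus_id, chrom, intervals) {
  iv <- tibble::tibble(start = as.integer(vapply(intervals, `[`, double(1), 1)),
                       end = as.integer(vapply(intervals, `[`, double(1), 2)))
  tibble::tibble(plus_id = plus_id, minus_id = minus_id, chrom = chrom,
                 overlap_intervals = list(iv),
                 overlap_length = sum(iv$end - iv$start))
}

read_row <- function(chrom, start, end, strand = "+", copies = 1L,
                     condition = "control", first_nt = "A",
                     read_id = sprintf("r_%d_%d", start, end)) {
  tibble::tibble(read_id = read_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 length = as.integer(end - start), copies = as.integer(copies),
                 first_nt = first_nt, condition = condition)
}

# the default seeded fixture is expensive; build it once per test run
fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(fixture_cache$fx)) {
    dir <- file.path(tempdir(), "cisnat-default-fixture")
    cfg <- simulation_config(seed = 101)
    fixture_cache$cfg <- cfg
    fixture_cache$dir <- dir
    fixture_cache$fx <- write_fixture(cfg, dir, overwrite = TRUE)
  }
  fixture_cache
}

fixture_beds <- function(fc) {
  stats::setNames(
    file.path(fc$dir, paste0("smallrna_", fc$cfg$conditions, ".bed")),
    fc$cfg$conditions)
}

default_result <- function() {
  fc <- default_fixture()
  if (is.null(fixture_cache$result)) {
    fixture_cache$result <- run_pipeline(
      fc$fx$gff3, fixture_beds(fc), fc$fx$expression, fc$fx$domain_map,
      control = fc$cfg$control_condition,
      subgroup_stress = fc$cfg$subgroup_stress)
  }
  fixture_cache
}

# a lighter configuration for replicated stochastic-recovery runs
replicate_config <- function(seed) {
  simulation_config(
    seed = seed,
    pairs_per_orientation = c(enclosed = 5, convergent = 5, divergent = 5),
    one_to_two_subtypes = c("enclosed+enclosed" = 0),
    n_one_to_three = 0, n_two_to_two = 0, n_one_to_four = 0,
    n_same_strand_decoys = 1, n_threshold_decoys = 1,
    n_excluded_biotype_decoys = 1, n_isoform_cases = 0,
    n_exclusion_features = 2, n_context_transposons = 1,
    conditions = c("control", "cold"),
    n_exclusive_pairs = 2, n_enriched_pairs = 2, n_silent_pairs = 0,
    n_intergenic_reads = 10, n_excluded_reads = 5, n_organelle_reads = 5,
    n_out_of_range_reads = 4,
    n_deg_pairs = 1, n_stress_exclusive = c(cold = 0))
}
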