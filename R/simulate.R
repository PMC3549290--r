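#' Simulation configuration for desk-scale fixtures
#'
#' Bundles every parameter of the synthetic-data generator: planted pair,
#' network and decoy counts, overlap and transcript geometry, small-RNA
#' library composition (length and 5'-nucleotide weights, planted strand-bias
#' classes, overlap/flank density ratios, background and excluded reads), and
#' expression structure (log-normal FPKM baselines, planted subgroups, DEG
#' effects, stress-exclusive pairs, library sizes). A fixed seed makes every
#' generated file byte-identical across runs.
#'
#' @param seed Master integer seed; per-file sub-seeds derive from it.
#' @param n_chromosomes Number of nuclear chromosomes.
#' @param chromosome_length Optional fixed chromosome length in bp; when
#'   `NULL` chromosomes are auto-sized to fit the planted layout, and a fixed
#'   length too small for the layout is a sizing error.
#' @param pairs_per_orientation Named counts of planted one-to-one pairs per
#'   orientation class.
#' @param one_to_two_subtypes Named counts of planted one-to-two groups per
#'   orientation-combination subtype.
#' @param n_one_to_three,n_two_to_two,n_one_to_four Planted network counts.
#' @param n_same_strand_decoys,n_threshold_decoys,n_excluded_biotype_decoys
#'   Decoy structures: same-strand overlaps, opposite-strand overlaps of
#'   exactly 25 nt (sub-threshold under the strict rule), and pairs whose
#'   minus member carries an excluded biotype.
#' @param n_isoform_cases Loci with two isoforms overlapping the same partner
#'   (exercises representative selection).
#' @param n_exclusion_features Standalone rRNA/tRNA/snRNA/snoRNA features.
#' @param n_context_transposons Standalone transposon features.
#' @param organelle_chrom,organelle_length Name and length of an organelle
#'   chromosome that only carries excluded background reads.
#' @param overlap_range Planted exonic overlap lengths (uniform, all > 25 nt).
#' @param transcript_length_range Planted transcript span lengths.
#' @param intron_probability Chance that a pair member is spliced into two
#'   exons (the overlap window always stays inside a single exon).
#' @param conditions,control_condition Condition labels; exactly one control.
#' @param reads_per_pair Planted overlap reads per pair per condition.
#' @param length_weights Named weights over read lengths 18-34 nt.
#' @param first_nt_weights Named weights over the 5' first nucleotide.
#' @param bias_fractions Named fractions of read-bearing one-to-one pairs per
#'   planted strand-bias class.
#' @param bias_strand_fraction Plus-strand read fraction for a plus-biased
#'   pair (mirrored for minus-biased).
#' @param n_exclusive_pairs Pairs planted with all reads inside the overlap
#'   (and more than five unique reads).
#' @param n_enriched_pairs Pairs planted at `enriched_density_ratio`.
#' @param enriched_density_ratio,background_flank_ratio Planted overlap/flank
#'   density ratios for enriched and ordinary pairs.
#' @param n_silent_pairs Pairs planted with no small RNAs at all.
#' @param n_intergenic_reads,n_excluded_reads,n_organelle_reads,
#'   n_out_of_range_reads Background reads per condition: intergenic, inside
#'   exclusion features, on the organelle chromosome, and with out-of-range
#'   lengths (17 and 35 nt).
#' @param copy_geom_prob Copy counts are `1 + rgeom(copy_geom_prob)`.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal FPKM baseline parameters.
#' @param noise_sdlog Multiplicative per-condition log-normal FPKM noise.
#' @param subgroup_fractions Named fractions of co-expressed one-to-one pairs
#'   planted per ratio subgroup (1-5).
#' @param subgroup_effect Fold applied under `subgroup_stress` (4 = twice the
#'   2-fold calling threshold).
#' @param subgroup_stress Stress condition carrying the subgroup contrasts.
#' @param n_deg_pairs Subgroup-4 pairs promoted to DEG carriers: both members
#'   get `deg_effect` fold and a floored baseline.
#' @param deg_effect,deg_min_baseline_fpkm DEG fold change and baseline floor.
#' @param n_stress_exclusive Named counts of pairs expressed exclusively under
#'   one stress (FPKM 0 elsewhere).
#' @param library_size Mapped fragments per condition library.
#' @param n_domain_terms,domain_term_prob Size and density of the synthetic
#'   transcript-to-domain-term map.
#' @return A list of class `cisnat_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 2,
                              chromosome_length = NULL,
                              pairs_per_orientation = c(enclosed = 15, convergent = 15, divergent = 15),
                              one_to_two_subtypes = c("enclosed+enclosed" = 2,
                                                      "enclosed+convergent" = 1,
                                                      "enclosed+divergent" = 1,
                                                      "convergent+divergent" = 1,
                                                      "convergent+convergent" = 1),
                              n_one_to_three = 1,
                              n_two_to_two = 1,
                              n_one_to_four = 1,
                              n_same_strand_decoys = 3,
                              n_threshold_decoys = 3,
                              n_excluded_biotype_decoys = 3,
                              n_isoform_cases = 2,
                              n_exclusion_features = 4,
                              n_context_transposons = 2,
                              organelle_chrom = "chrM",
                              organelle_length = 20000,
                              overlap_range = c(150, 400),
                              transcript_length_range = c(800, 2000),
                              intron_probability = 0.5,
                              conditions = c("control", "salt", "cold", "drought"),
                              control_condition = "control",
                              reads_per_pair = 60,
                              length_weights = NULL,
                              first_nt_weights = c(A = 0.5, C = 0.12, G = 0.13, T = 0.25),
                              bias_fractions = c("one-strand-plus" = 0.05,
                                                 "one-strand-minus" = 0.05,
                                                 "plus-biased" = 0.15,
                                                 "minus-biased" = 0.15,
                                                 "balanced" = 0.60),
                              bias_strand_fraction = 0.9,
                              n_exclusive_pairs = 6,
                              n_enriched_pairs = 4,
                              enriched_density_ratio = 10,
                              background_flank_ratio = 3,
                              n_silent_pairs = 2,
                              n_intergenic_reads = 40,
                              n_excluded_reads = 20,
                              n_organelle_reads = 10,
                              n_out_of_range_reads = 10,
                              copy_geom_prob = 0.5,
                              fpkm_meanlog = 1.5,
                              fpkm_sdlog = 1,
                              noise_sdlog = 0.15,
                              subgroup_fractions = c("1" = 0.6, "2" = 0.1, "3" = 0.1,
                                                     "4" = 0.1, "5" = 0.1),
                              subgroup_effect = 4,
                              subgroup_stress = "cold",
                              n_deg_pairs = 2,
                              deg_effect = 8,
                              deg_min_baseline_fpkm = 30,
                              n_stress_exclusive = c(salt = 1, cold = 2, drought = 1),
                              library_size = 2e6,
                              n_domain_terms = 8,
                              domain_term_prob = 0.3) {
  if (is.null(length_weights)) {
    # unimodal over 18-34 peaking at 24 nt, heavier on 21-25
    lens <- 18:34
    w <- exp(-abs(lens - 24) / 2.2)
    length_weights <- stats::setNames(w / sum(w), lens)
  }
  cfg <- as.list(environment())
  stopifnot(cfg$control_condition %in% cfg$conditions,
            all(cfg$overlap_range > 25),
            cfg$reads_per_pair >= 0,
            abs(sum(cfg$bias_fractions) - 1) < 1e-8,
            abs(sum(cfg$subgroup_fractions) - 1) < 1e-8,
            all(names(cfg$n_stress_exclusive) %in% cfg$conditions))
  class(cfg) <- "cisnat_sim_config"
  cfg
}

# ---- geometry helpers -------------------------------------------------------

# split a span into one or two exons keeping [protect_start, protect_end)
# inside a single exon; the intron is cut from the larger unprotected side
make_member_exons <- function(span_start, span_end, protect_start, protect_end,
                              spliced, min_piece = 60, intron_len = 100) {
  if (spliced) {
    room_left <- protect_start - span_start
    room_right <- span_end - protect_end
    if (room_left >= room_right && room_left >= min_piece + intron_len + 10) {
      cut_at <- span_start + min_piece
      return(tibble::tibble(exon_start = c(span_start, cut_at + intron_len),
                            exon_end = c(cut_at, span_end)))
    }
    if (room_right >= min_piece + intron_len + 10) {
      cut_at <- span_end - min_piece - intron_len
      return(tibble::tibble(exon_start = c(span_start, cut_at + intron_len),
                            exon_end = c(cut_at, span_end)))
    }
  }
  tibble::tibble(exon_start = span_start, exon_end = span_end)
}

# relative geometry of one antisense pair with exact exonic overlap `ov`
pair_geometry <- function(orientation, ov, lp, lm, spliced_p, spliced_m) {
  if (orientation == "enclosed") {
    # minus member fully inside the plus span
    m_start <- 200L
    p <- list(start = 0L, end = lp, prot = c(m_start, m_start + ov))
    m <- list(start = m_start, end = m_start + ov, prot = c(m_start, m_start + ov))
  } else if (orientation == "convergent") {
    # plus upstream; 3' ends meet in the overlap
    p <- list(start = 0L, end = lp, prot = c(lp - ov, lp))
    m <- list(start = lp - ov, end = lp - ov + lm, prot = c(lp - ov, lp))
  } else if (orientation == "divergent") {
    # minus upstream; 5' ends meet in the overlap
    m <- list(start = 0L, end = lm, prot = c(lm - ov, lm))
    p <- list(start = lm - ov, end = lm - ov + lp, prot = c(lm - ov, lm))
  } else {
    abort(paste0("unknown orientation: ", orientation))
  }
  list(plus = make_member_exons(p$start, p$end, p$prot[1], p$prot[2], spliced_p),
       minus = make_member_exons(m$start, m$end, m$prot[1], m$prot[2],
                                 if (orientation == "enclosed") FALSE else spliced_m))
}

# ---- annotation generation --------------------------------------------------

#' Generate a planted annotation with ground truth
#'
#' Places cis-NAT pair cassettes (one-to-one pairs of each orientation and
#' partner class, many-to-many network cassettes, isoform cases), decoys
#' (same-strand overlaps, exactly-25-nt overlaps, excluded-biotype partners)
#' and standalone features (rRNA-class exclusion features, transposons) along
#' the configured chromosomes without unplanned antisense overlaps, realising
#' every requested orientation and exonic overlap length exactly by
#' construction.
#'
#' @param config A [simulation_config()].
#' @return A list with `ann` (exon-level annotation tibble), `truth` (list of
#'   tibbles `pairs`, `groups`, plus planted per-pair small-RNA and expression
#'   labels filled in by the later generators), and `chrom_lengths` (named
#'   integer vector, organelle included).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "cisnat_sim_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  tx_n <- 0L
  locus_n <- 0L
  next_tx <- function() {
    tx_n <<- tx_n + 1L
    sprintf("T%04d", tx_n)
  }
  next_locus <- function() {
    locus_n <<- locus_n + 1L
    sprintf("L%04d", locus_n)
  }
  partner_cycle <- c("CDS-p vs ncRNA", "CDS-p vs CDS-n", "CDS-p vs CDS-p",
                     "CDS-n vs ncRNA", "CDS-n vs CDS-n", "ncRNA vs ncRNA")
  class_biotypes <- function(label) strsplit(label, " vs ", fixed = TRUE)[[1]]

  cassettes <- list()
  pair_rows <- list()
  group_rows <- list()
  group_n <- 0L

  add_cassette <- function(ann) {
    cassettes[[length(cassettes) + 1L]] <<- ann
  }
  tx_rows <- function(id, locus, strand, biotype, exons) {
    tibble::tibble(transcript_id = id, locus_id = locus, chrom = NA_character_,
                   strand = strand, biotype = biotype,
                   exon_start = exons$exon_start, exon_end = exons$exon_end)
  }

  rint <- function(range) sample(range[1]:range[2], 1)

  # --- one-to-one pairs, cycling the six partner classes
  cls_i <- 0L
  for (orient in names(config$pairs_per_orientation)) {
    for (k in seq_len(config$pairs_per_orientation[[orient]])) {
      cls_i <- cls_i + 1L
      label <- partner_cycle[((cls_i - 1L) %% 6L) + 1L]
      bts <- class_biotypes(label)
      ov <- rint(config$overlap_range)
      lp <- rint(config$transcript_length_range)
      lm <- rint(config$transcript_length_range)
      lp <- max(lp, ov + 300L)
      lm <- max(lm, ov + 300L)
      if (orient == "enclosed") lp <- max(lp, ov + 500L)
      geo <- pair_geometry(orient, ov,
                           if (orient == "enclosed") lp else lp,
                           if (orient == "enclosed") ov else lm,
                           runif(1) < config$intron_probability,
                           runif(1) < config$intron_probability)
      p_id <- next_tx(); m_id <- next_tx()
      p_loc <- next_locus(); m_loc <- next_locus()
      add_cassette(bind_rows(
        tx_rows(p_id, p_loc, "+", bts[1], geo$plus),
        tx_rows(m_id, m_loc, "-", bts[2], geo$minus)))
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        plus_id = p_id, minus_id = m_id, orientation = orient,
        partner_class = label, overlap_length = ov, role = "one-to-one",
        group_id = NA_character_, representative = TRUE, excluded = FALSE)
    }
  }

  # --- isoform cases: locus with two plus isoforms over one minus partner
  for (k in seq_len(config$n_isoform_cases)) {
    ov1 <- 300L; ov2 <- 120L
    p_loc <- next_locus(); m_loc <- next_locus()
    a1 <- next_tx(); a2 <- next_tx(); b1 <- next_tx()
    # minus partner enclosed in the long isoform, partially under the short one
    m_start <- 400L
    add_cassette(bind_rows(
      tx_rows(a1, p_loc, "+", "CDS-p",
              tibble::tibble(exon_start = 0L, exon_end = 1200L)),
      tx_rows(a2, p_loc, "+", "CDS-p",
              tibble::tibble(exon_start = 0L, exon_end = m_start + ov2)),
      tx_rows(b1, m_loc, "-", "ncRNA",
              tibble::tibble(exon_start = m_start, exon_end = m_start + ov1))))
    pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
      plus_id = a1, minus_id = b1,
      orientation = classify_orientation(0L, 1200L, m_start, m_start + ov1),
      partner_class = "CDS-p vs ncRNA", overlap_length = ov1,
      role = "one-to-one", group_id = NA_character_, representative = TRUE,
      excluded = FALSE)
    pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
      plus_id = a2, minus_id = b1,
      orientation = classify_orientation(0L, m_start + ov2, m_start, m_start + ov1),
      partner_class = "CDS-p vs ncRNA", overlap_length = ov2,
      role = "isoform-alternate", group_id = NA_character_,
      representative = FALSE, excluded = FALSE)
  }

  # --- network cassettes: a long central transcript with enclosed /
  # convergent / divergent partners realised by span geometry
  plant_star <- function(partner_orients, group_type, subtype = NA_character_) {
    group_n <<- group_n + 1L
    gid <- sprintf("NET%03d", group_n)
    n_part <- length(partner_orients)
    n_enc <- sum(partner_orients == "enclosed")
    lc <- 1500L + 700L * n_enc
    c_id <- next_tx(); c_loc <- next_locus()
    rows <- tx_rows(c_id, c_loc, "+", "CDS-p",
                    tibble::tibble(exon_start = 0L, exon_end = lc))
    enc_slot <- 0L
    for (orient in partner_orients) {
      ov <- rint(config$overlap_range)
      lm <- 700L
      if (orient == "enclosed") {
        enc_slot <- enc_slot + 1L
        m_start <- 150L + (enc_slot - 1L) * 650L
        exons <- tibble::tibble(exon_start = m_start, exon_end = m_start + ov)
      } else if (orient == "convergent") {
        # partner overlaps the central 3' end and extends right
        exons <- tibble::tibble(exon_start = lc - ov, exon_end = lc - ov + lm)
      } else {
        # divergent: partner overlaps the central 5' end and extends left
        exons <- tibble::tibble(exon_start = -(lm - ov), exon_end = ov)
      }
      m_id <- next_tx(); m_loc <- next_locus()
      rows <- bind_rows(rows, tx_rows(m_id, m_loc, "-", "ncRNA", exons))
      pair_rows[[length(pair_rows) + 1L]] <<- tibble::tibble(
        plus_id = c_id, minus_id = m_id, orientation = orient,
        partner_class = "CDS-p vs ncRNA", overlap_length = ov,
        role = "network", group_id = gid, representative = TRUE,
        excluded = FALSE)
    }
    group_rows[[length(group_rows) + 1L]] <<- tibble::tibble(
      group_id = gid, group_type = group_type, subtype = subtype,
      n_transcripts = n_part + 1L, n_pairs = n_part)
    add_cassette(rows)
  }

  # two convergent pairs sharing a central minus transcript: both plus
  # partners cross the central 5' boundary from upstream (they overlap each
  # other on the plus strand, which forms no pair)
  plant_double_convergent <- function() {
    group_n <<- group_n + 1L
    gid <- sprintf("NET%03d", group_n)
    ov1 <- rint(config$overlap_range)
    ov2 <- rint(config$overlap_range)
    lc <- 2200L
    c_id <- next_tx(); c_loc <- next_locus()
    rows <- tx_rows(c_id, c_loc, "-", "ncRNA",
                    tibble::tibble(exon_start = 0L, exon_end = lc))
    p1 <- next_tx(); p2 <- next_tx()
    rows <- bind_rows(
      rows,
      tx_rows(p1, next_locus(), "+", "CDS-p",
              tibble::tibble(exon_start = ov1 - 900L, exon_end = ov1)),
      tx_rows(p2, next_locus(), "+", "CDS-p",
              tibble::tibble(exon_start = ov2 - 1400L, exon_end = ov2)))
    for (pp in list(list(p1, ov1), list(p2, ov2))) {
      pair_rows[[length(pair_rows) + 1L]] <<- tibble::tibble(
        plus_id = pp[[1]], minus_id = c_id, orientation = "convergent",
        partner_class = "CDS-p vs ncRNA",
        overlap_length = as.integer(pp[[2]]),
        role = "network", group_id = gid, representative = TRUE,
        excluded = FALSE)
    }
    group_rows[[length(group_rows) + 1L]] <<- tibble::tibble(
      group_id = gid, group_type = "one-to-two",
      subtype = "convergent+convergent", n_transcripts = 3L, n_pairs = 2L)
    add_cassette(rows)
  }

  for (st in names(config$one_to_two_subtypes)) {
    orients <- strsplit(st, "+", fixed = TRUE)[[1]]
    for (k in seq_len(config$one_to_two_subtypes[[st]])) {
      if (identical(sort(orients), c("convergent", "convergent"))) {
        plant_double_convergent()
      } else {
        plant_star(orients, "one-to-two", st)
      }
    }
  }

  if (config$n_one_to_three > 0) {
    for (k in seq_len(config$n_one_to_three)) {
      plant_star(c("enclosed", "enclosed", "divergent"), "one-to-three")
    }
  }
  if (config$n_one_to_four > 0) {
    for (k in seq_len(config$n_one_to_four)) {
      plant_star(c("enclosed", "enclosed", "enclosed", "convergent"),
                 "one-to-four")
    }
  }
  # two-to-two: alternating chain A+ C- B+ D-
  if (config$n_two_to_two > 0) {
    for (k in seq_len(config$n_two_to_two)) {
      group_n <- group_n + 1L
      gid <- sprintf("NET%03d", group_n)
      a <- next_tx(); cc <- next_tx(); b <- next_tx(); d <- next_tx()
      rows <- bind_rows(
        tx_rows(a, next_locus(), "+", "CDS-p",
                tibble::tibble(exon_start = 0L, exon_end = 1200L)),
        tx_rows(cc, next_locus(), "-", "CDS-n",
                tibble::tibble(exon_start = 1000L, exon_end = 2200L)),
        tx_rows(b, next_locus(), "+", "CDS-p",
                tibble::tibble(exon_start = 2000L, exon_end = 3200L)),
        tx_rows(d, next_locus(), "-", "CDS-n",
                tibble::tibble(exon_start = 3000L, exon_end = 4200L)))
      add_cassette(rows)
      chain <- list(list(a, cc, classify_orientation(0L, 1200L, 1000L, 2200L)),
                    list(b, cc, classify_orientation(2000L, 3200L, 1000L, 2200L)),
                    list(b, d, classify_orientation(2000L, 3200L, 3000L, 4200L)))
      for (e in chain) {
        pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
          plus_id = e[[1]], minus_id = e[[2]], orientation = e[[3]],
          partner_class = partner_class("CDS-p", "CDS-n"),
          overlap_length = 200L, role = "network", group_id = gid,
          representative = TRUE, excluded = FALSE)
      }
      group_rows[[length(group_rows) + 1L]] <- tibble::tibble(
        group_id = gid, group_type = "two-to-two", subtype = NA_character_,
        n_transcripts = 4L, n_pairs = 3L)
    }
  }

  # --- decoys
  for (k in seq_len(config$n_same_strand_decoys)) {
    t1 <- next_tx(); t2 <- next_tx()
    add_cassette(bind_rows(
      tx_rows(t1, next_locus(), "+", "CDS-p",
              tibble::tibble(exon_start = 0L, exon_end = 900L)),
      tx_rows(t2, next_locus(), "+", "ncRNA",
              tibble::tibble(exon_start = 500L, exon_end = 1400L))))
  }
  for (k in seq_len(config$n_threshold_decoys)) {
    t1 <- next_tx(); t2 <- next_tx()
    # exonic overlap of exactly 25 nt: excluded by the strict > 25 rule
    add_cassette(bind_rows(
      tx_rows(t1, next_locus(), "+", "CDS-p",
              tibble::tibble(exon_start = 0L, exon_end = 800L)),
      tx_rows(t2, next_locus(), "-", "ncRNA",
              tibble::tibble(exon_start = 775L, exon_end = 1600L))))
  }
  for (k in seq_len(config$n_excluded_biotype_decoys)) {
    t1 <- next_tx(); t2 <- next_tx()
    add_cassette(bind_rows(
      tx_rows(t1, next_locus(), "+", "CDS-p",
              tibble::tibble(exon_start = 0L, exon_end = 900L)),
      tx_rows(t2, next_locus(), "-", "transposon",
              tibble::tibble(exon_start = 600L, exon_end = 1500L))))
    pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
      plus_id = t1, minus_id = t2, orientation = "convergent",
      partner_class = NA_character_, overlap_length = 300L,
      role = "excluded-biotype", group_id = NA_character_,
      representative = FALSE, excluded = TRUE)
  }

  # --- standalone features: exclusion classes and transposons
  excl_classes <- rep(srna_exclusion_biotypes(),
                      length.out = config$n_exclusion_features)
  for (bt in excl_classes) {
    t1 <- next_tx()
    add_cassette(tx_rows(t1, next_locus(), "+", bt,
                         tibble::tibble(exon_start = 0L, exon_end = 400L)))
  }
  for (k in seq_len(config$n_context_transposons)) {
    t1 <- next_tx()
    add_cassette(tx_rows(t1, next_locus(), "+", "transposon",
                         tibble::tibble(exon_start = 0L, exon_end = 1500L)))
  }

  # --- place cassettes round-robin over chromosomes
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  cursor <- stats::setNames(rep(3000L, config$n_chromosomes), chroms)
  placed <- vector("list", length(cassettes))
  for (i in seq_along(cassettes)) {
    cs <- cassettes[[i]]
    chrom <- chroms[((i - 1L) %% config$n_chromosomes) + 1L]
    shift <- cursor[[chrom]] - min(cs$exon_start)
    cs$exon_start <- cs$exon_start + shift
    cs$exon_end <- cs$exon_end + shift
    cs$chrom <- chrom
    cursor[[chrom]] <- max(cs$exon_end) + 1500L + sample(0:500, 1)
    placed[[i]] <- cs
  }
  ann <- bind_rows(placed)
  need <- max(cursor) + 3000L
  if (!is.null(config$chromosome_length)) {
    if (config$chromosome_length < need) {
      abort(sprintf("chromosome_length %d too small for the planted layout (needs >= %d)",
                    config$chromosome_length, need))
    }
    chrom_lengths <- stats::setNames(rep(as.integer(config$chromosome_length),
                                         config$n_chromosomes), chroms)
  } else {
    chrom_lengths <- stats::setNames(rep(as.integer(need), config$n_chromosomes),
                                     chroms)
  }
  chrom_lengths[config$organelle_chrom] <- as.integer(config$organelle_length)
  ann <- new_annotation(ann[order_c(ann$chrom, ann$transcript_id, ann$exon_start), ])

  pairs_truth <- bind_rows(pair_rows) |>
    mutate(pair_id = pair_key(.data$plus_id, .data$minus_id), .before = 1)
  truth <- list(pairs = pairs_truth, groups = bind_rows(group_rows))
  truth <- plant_srna_labels(config, truth)
  truth <- plant_expression_labels(config, truth)
  list(ann = ann, truth = truth, chrom_lengths = chrom_lengths)
}

# assign planted strand-bias / exclusivity / enrichment / silent labels
plant_srna_labels <- function(config, truth) {
  pairs <- truth$pairs
  rep11 <- which(pairs$role == "one-to-one" & pairs$representative)
  n11 <- length(rep11)
  n_silent <- min(config$n_silent_pairs, n11)
  silent_idx <- rep11[seq_len(n_silent)]
  active11 <- setdiff(rep11, silent_idx)
  counts <- round(config$bias_fractions * length(active11))
  # fix rounding drift on the balanced class
  counts["balanced"] <- length(active11) - sum(counts[names(counts) != "balanced"])
  bias <- rep(names(counts), times = pmax(counts, 0))
  bias <- rep(bias, length.out = length(active11))

  pairs$silent <- FALSE
  pairs$silent[silent_idx] <- TRUE
  pairs$bias_class <- NA_character_
  pairs$bias_class[active11] <- bias
  net <- which(pairs$role == "network")
  pairs$bias_class[net] <- "balanced"
  # exclusivity and enrichment planted on active one-to-one pairs
  pairs$exclusive <- FALSE
  pairs$enriched <- FALSE
  excl_idx <- active11[seq_len(min(config$n_exclusive_pairs, length(active11)))]
  rest <- setdiff(active11, excl_idx)
  enr_idx <- rest[seq_len(min(config$n_enriched_pairs, length(rest)))]
  pairs$exclusive[excl_idx] <- TRUE
  pairs$enriched[c(excl_idx, enr_idx)] <- TRUE   # exclusive => no flank reads => Inf ratio
  truth$pairs <- pairs
  truth
}

# assign planted subgroup / DEG / stress-exclusive labels
plant_expression_labels <- function(config, truth) {
  pairs <- truth$pairs
  pairs$stress_exclusive <- NA_character_
  pairs$subgroup <- NA_character_
  pairs$deg_carrier <- FALSE
  rep11 <- which(pairs$role == "one-to-one" & pairs$representative & !pairs$silent)
  # stress-exclusive pairs come from the tail of the roster so they do not
  # coincide with the sRNA-exclusive/enriched pairs planted at its head
  tail_pool <- rev(rep11)
  i <- 1L
  for (s in names(config$n_stress_exclusive)) {
    k <- config$n_stress_exclusive[[s]]
    if (k > 0 && i + k - 1L <= length(tail_pool)) {
      pairs$stress_exclusive[tail_pool[i:(i + k - 1L)]] <- s
      i <- i + k
    }
  }
  eligible <- rep11[is.na(pairs$stress_exclusive[rep11])]
  counts <- round(config$subgroup_fractions * length(eligible))
  counts["1"] <- length(eligible) - sum(counts[names(counts) != "1"])
  sg <- rep(names(counts), times = pmax(counts, 0))
  sg <- rep(sg, length.out = length(eligible))
  pairs$subgroup[eligible] <- sg
  sg4 <- eligible[pairs$subgroup[eligible] == "4"]
  if (config$n_deg_pairs > 0 && length(sg4) > 0) {
    pairs$deg_carrier[sg4[seq_len(min(config$n_deg_pairs, length(sg4)))]] <- TRUE
  }
  truth$pairs <- pairs
  truth$deg_transcripts <- c(pairs$plus_id[pairs$deg_carrier],
                             pairs$minus_id[pairs$deg_carrier])
  truth
}

# ---- small-RNA generation ---------------------------------------------------

random_seq <- function(len, first_nt) {
  rest <- sample(c("A", "C", "G", "T"), len - 1L, replace = TRUE)
  paste0(first_nt, paste(rest, collapse = ""))
}

# sample read intervals fully inside the given merged intervals
sample_read_positions <- function(intervals, lens) {
  n <- length(lens)
  out_start <- integer(n)
  keep <- logical(n)
  widths <- intervals$end - intervals$start
  for (i in seq_len(n)) {
    ok <- which(widths >= lens[i])
    if (length(ok) == 0L) next
    iv <- if (length(ok) == 1L) ok else sample(ok, 1, prob = widths[ok])
    out_start[i] <- intervals$start[iv] +
      sample.int(widths[iv] - lens[i] + 1L, 1) - 1L
    keep[i] <- TRUE
  }
  list(start = out_start[keep], len = lens[keep])
}

#' Generate planted small-RNA libraries
#'
#' Draws, per condition, overlap reads for every read-bearing planted pair at
#' the configured count with the pair's planted strand-bias fraction, flank
#' reads at the planted overlap/flank density ratio (none for exclusive
#' pairs), and background reads: intergenic, inside exclusion features, on the
#' organelle chromosome, and out-of-range lengths. Copy counts are geometric;
#' read names carry a synthetic sequence whose first nucleotide follows the
#' configured weights.
#'
#' @param config A [simulation_config()].
#' @param ann The generated annotation.
#' @param truth The ground-truth list from [generate_annotation()].
#' @param chrom_lengths Named chromosome lengths from [generate_annotation()].
#' @return A read tibble covering all conditions (column `condition`).
#' @export
generate_smallrna_reads <- function(config, ann, truth, chrom_lengths) {
  set.seed(derive_seed(config$seed, "smallrna"))
  lens_vocab <- as.integer(names(config$length_weights))
  spans <- transcript_spans(ann)
  exons_by_tx <- split(ann[, c("exon_start", "exon_end")], ann$transcript_id)
  pairs <- truth$pairs |>
    filter(.data$representative, !.data$excluded, !.data$silent)
  read_i <- 0L
  rows <- list()

  strand_p <- function(bias) {
    switch(bias,
           "one-strand-plus" = 1, "one-strand-minus" = 0,
           "plus-biased" = config$bias_strand_fraction,
           "minus-biased" = 1 - config$bias_strand_fraction,
           0.5)
  }

  emit <- function(chrom, starts, lens, strands, cond) {
    n <- length(starts)
    if (n == 0L) return(invisible(NULL))
    first <- sample(names(config$first_nt_weights), n, replace = TRUE,
                    prob = config$first_nt_weights)
    rest_pool <- sample(c("A", "C", "G", "T"), sum(lens) - n, replace = TRUE)
    rest <- vapply(split(rest_pool, rep.int(seq_len(n), lens - 1L)),
                   paste, character(1), collapse = "")
    seqs <- paste0(first, rest[as.character(seq_len(n))])
    ids <- sprintf("r%07d_%s", read_i + seq_len(n), seqs)
    read_i <<- read_i + n
    rows[[length(rows) + 1L]] <<- tibble::new_tibble(list(
      read_id = ids, chrom = rep(chrom, n), start = as.integer(starts),
      end = as.integer(starts + lens), strand = strands,
      length = as.integer(lens),
      copies = 1L + stats::rgeom(n, config$copy_geom_prob),
      first_nt = first, condition = rep(cond, n)), nrow = n)
  }

  # per-pair geometry is condition-invariant: compute once
  geoms <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    p_ex <- exons_by_tx[[pr$plus_id]]
    m_ex <- exons_by_tx[[pr$minus_id]]
    ov <- intersect_intervals0(p_ex$exon_start, p_ex$exon_end,
                               m_ex$exon_start, m_ex$exon_end)
    flank <- setdiff_intervals0(
      c(p_ex$exon_start, m_ex$exon_start), c(p_ex$exon_end, m_ex$exon_end),
      ov$start, ov$end)
    list(chrom = spans$chrom[spans$transcript_id == pr$plus_id],
         overlap = ov, ov_len = sum(ov$end - ov$start), flank = flank,
         flank_len = sum(flank$end - flank$start))
  })
  for (cond in config$conditions) {
    for (i in seq_len(nrow(pairs))) {
      pr <- pairs[i, ]
      g <- geoms[[i]]
      n_ov <- config$reads_per_pair
      lens <- sample(lens_vocab, n_ov, replace = TRUE,
                     prob = config$length_weights)
      pos <- sample_read_positions(g$overlap, lens)
      strands <- ifelse(runif(length(pos$start)) < strand_p(pr$bias_class),
                        "+", "-")
      emit(g$chrom, pos$start, pos$len, strands, cond)
      if (!pr$exclusive && g$flank_len > 40) {
        ratio <- if (pr$enriched) config$enriched_density_ratio else
          config$background_flank_ratio
        expect <- n_ov / (g$ov_len / 1000) * (g$flank_len / 1000) / ratio
        n_fl <- stats::rpois(1, expect)
        if (n_fl > 0) {
          lens_f <- sample(lens_vocab, n_fl, replace = TRUE,
                           prob = config$length_weights)
          pos_f <- sample_read_positions(g$flank, lens_f)
          emit(g$chrom, pos_f$start, pos_f$len,
               sample(c("+", "-"), length(pos_f$start), replace = TRUE), cond)
        }
      }
    }
    # intergenic background: positions clear of any transcript span
    nuclear <- setdiff(names(chrom_lengths), config$organelle_chrom)
    if (config$n_intergenic_reads > 0) {
      placed <- 0L
      guard <- 0L
      while (placed < config$n_intergenic_reads && guard < 50L) {
        guard <- guard + 1L
        need <- config$n_intergenic_reads - placed
        chrom <- sample(nuclear, need, replace = TRUE)
        lens <- sample(lens_vocab, need, replace = TRUE,
                       prob = config$length_weights)
        starts <- vapply(seq_len(need), function(j)
          sample.int(chrom_lengths[[chrom[j]]] - 40L, 1), integer(1))
        clear <- vapply(seq_len(need), function(j) {
          sp <- spans[spans$chrom == chrom[j], ]
          !any(sp$start - 1200L < starts[j] + lens[j] &
                 starts[j] < sp$end + 1200L)
        }, logical(1))
        for (ch in unique(chrom[clear])) {
          sel <- clear & chrom == ch
          emit(ch, starts[sel], lens[sel],
               sample(c("+", "-"), sum(sel), replace = TRUE), cond)
        }
        placed <- placed + sum(clear)
      }
    }
    # reads inside exclusion-class features
    excl <- spans[spans$biotype %in% srna_exclusion_biotypes(), ]
    if (config$n_excluded_reads > 0 && nrow(excl) > 0) {
      pick <- sample.int(nrow(excl), config$n_excluded_reads, replace = TRUE)
      lens <- sample(lens_vocab, config$n_excluded_reads, replace = TRUE,
                     prob = config$length_weights)
      starts <- excl$start[pick] +
        vapply(seq_along(pick), function(j)
          sample.int(excl$end[pick[j]] - excl$start[pick[j]] - lens[j], 1),
          integer(1))
      for (ch in unique(excl$chrom[pick])) {
        sel <- excl$chrom[pick] == ch
        emit(ch, starts[sel], lens[sel],
             sample(c("+", "-"), sum(sel), replace = TRUE), cond)
      }
    }
    # organelle reads
    if (config$n_organelle_reads > 0) {
      lens <- sample(lens_vocab, config$n_organelle_reads, replace = TRUE,
                     prob = config$length_weights)
      starts <- sample.int(config$organelle_length - 40L,
                           config$n_organelle_reads, replace = TRUE)
      emit(config$organelle_chrom, starts, lens,
           sample(c("+", "-"), config$n_organelle_reads, replace = TRUE), cond)
    }
    # out-of-range lengths (17 and 35 nt), intergenic placement
    if (config$n_out_of_range_reads > 0) {
      lens <- rep(c(17L, 35L), length.out = config$n_out_of_range_reads)
      chrom <- rep(nuclear[1], config$n_out_of_range_reads)
      starts <- seq(100L, by = 50L, length.out = config$n_out_of_range_reads)
      emit(nuclear[1], starts, lens,
           rep("+", config$n_out_of_range_reads), cond)
    }
  }
  out <- bind_rows(rows)
  out[order_c(out$condition, out$chrom, out$start, out$read_id), ]
}

# ---- expression generation --------------------------------------------------

#' Generate planted per-condition expression tables
#'
#' FPKM per transcript and condition is a log-normal baseline times
#' multiplicative log-normal noise times the planted effect: subgroup
#' contrasts under the subgroup stress (sense/antisense 4-fold moves), DEG
#' carriers at the DEG fold with a floored baseline, and stress-exclusive
#' pairs at FPKM 0 outside their stress. Fragment counts are Poisson draws of
#' FPKM x exonic kb x library millions.
#'
#' @inheritParams generate_smallrna_reads
#' @return An expression tibble (`transcript_id`, `condition`, `fpkm`,
#'   `fragment_count`, `library_size`).
#' @export
generate_expression <- function(config, ann, truth) {
  set.seed(derive_seed(config$seed, "expression"))
  spans <- transcript_spans(ann)
  tx <- spans$transcript_id
  baseline <- stats::rlnorm(length(tx), config$fpkm_meanlog, config$fpkm_sdlog)
  names(baseline) <- tx
  deg_tx <- truth$deg_transcripts
  baseline[deg_tx] <- pmax(baseline[deg_tx], config$deg_min_baseline_fpkm)

  pairs <- truth$pairs |> filter(.data$representative, !.data$excluded)
  effect <- matrix(1, nrow = length(tx), ncol = length(config$conditions),
                   dimnames = list(tx, config$conditions))
  st <- config$subgroup_stress
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    if (!is.na(pr$subgroup) && st %in% config$conditions) {
      e <- if (pr$deg_carrier) config$deg_effect else config$subgroup_effect
      up <- e; down <- 1 / e
      if (pr$subgroup == "2") {
        effect[pr$plus_id, st] <- up; effect[pr$minus_id, st] <- down
      } else if (pr$subgroup == "3") {
        effect[pr$plus_id, st] <- down; effect[pr$minus_id, st] <- up
      } else if (pr$subgroup == "4") {
        effect[pr$plus_id, st] <- up; effect[pr$minus_id, st] <- up
      } else if (pr$subgroup == "5") {
        effect[pr$plus_id, st] <- down; effect[pr$minus_id, st] <- down
      }
    }
    if (!is.na(pr$stress_exclusive)) {
      off <- setdiff(config$conditions, pr$stress_exclusive)
      effect[pr$plus_id, off] <- 0
      effect[pr$minus_id, off] <- 0
    }
  }

  len_kb <- stats::setNames(spans$exonic_length / 1000, tx)
  out <- purrr::map_dfr(config$conditions, function(cond) {
    noise <- stats::rlnorm(length(tx), 0, config$noise_sdlog)
    fpkm <- baseline * noise * effect[, cond]
    frag <- stats::rpois(length(tx),
                         fpkm * len_kb * config$library_size / 1e6)
    tibble::tibble(transcript_id = tx, condition = cond,
                   fpkm = round(fpkm, 4), fragment_count = frag,
                   library_size = as.integer(config$library_size))
  })
  out[order_c(out$condition, out$transcript_id), ]
}

# ---- fixture bundle ---------------------------------------------------------

#' Generate a synthetic transcript-to-domain-term map
#'
#' Assigns generic domain terms to CDS-p transcripts at the configured
#' density; every CDS-p transcript receives at least one term.
#'
#' @inheritParams generate_smallrna_reads
#' @return A tibble `transcript_id`, `domain_term`.
#' @export
generate_domain_map <- function(config, ann) {
  set.seed(derive_seed(config$seed, "domains"))
  spans <- transcript_spans(ann)
  coding <- spans$transcript_id[spans$biotype == "CDS-p"]
  terms <- sprintf("DOM%02d", seq_len(config$n_domain_terms))
  rows <- purrr::map_dfr(coding, function(id) {
    hit <- terms[runif(length(terms)) < config$domain_term_prob]
    if (length(hit) == 0L) hit <- sample(terms, 1)
    tibble::tibble(transcript_id = id, domain_term = hit)
  })
  rows[order_c(rows$transcript_id, rows$domain_term), ]
}

#' Write a complete fixture bundle
#'
#' Emits, into one directory: `genome.fa` (random sequence), `annotation.gff3`,
#' one `smallrna_<condition>.bed` per condition, `expression.tsv`,
#' `domain_map.tsv` and `truth.json` (the ground-truth manifest). Re-running
#' with the same seed reproduces every file byte-for-byte.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a named list of the written paths plus the generated
#'   objects (`ann`, `truth`, `reads`, `expression`, `domain_map`).
#' @export
write_fixture <- function(config, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    abort(paste0("output directory not empty (use overwrite = TRUE): ", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_annotation(config)
  reads <- generate_smallrna_reads(config, gen$ann, gen$truth, gen$chrom_lengths)
  expr <- generate_expression(config, gen$ann, gen$truth)
  dmap <- generate_domain_map(config, gen$ann)

  set.seed(derive_seed(config$seed, "genome"))
  genome <- Biostrings::DNAStringSet(vapply(
    names(gen$chrom_lengths),
    function(ch) paste(sample(c("A", "C", "G", "T"), gen$chrom_lengths[[ch]],
                              replace = TRUE), collapse = ""),
    character(1)))
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "annotation.gff3"),
    expression = file.path(out_dir, "expression.tsv"),
    domain_map = file.path(out_dir, "domain_map.tsv"),
    truth_json = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(genome, paths$genome)
  write_gff3(gen$ann, paths$gff3)
  for (cond in config$conditions) {
    p <- file.path(out_dir, paste0("smallrna_", cond, ".bed"))
    write_smallrna_bed(reads[reads$condition == cond, ], p)
    paths[[paste0("bed_", cond)]] <- p
  }
  readr::write_tsv(expr, paths$expression, progress = FALSE)
  readr::write_tsv(dmap, paths$domain_map, progress = FALSE)
  manifest <- list(
    seed = config$seed,
    conditions = as.list(config$conditions),
    control_condition = config$control_condition,
    subgroup_stress = config$subgroup_stress,
    chrom_lengths = as.list(gen$chrom_lengths),
    pairs = gen$truth$pairs,
    groups = gen$truth$groups,
    deg_transcripts = gen$truth$deg_transcripts)
  jsonlite::write_json(manifest, paths$truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(ann = gen$ann, truth = gen$truth, reads = reads,
                          expression = expr, domain_map = dmap,
                          chrom_lengths = gen$chrom_lengths)))
}

#' Read a ground-truth manifest
#'
#' @param path Path to a `truth.json` written by [write_fixture()].
#' @return A list with `pairs` and `groups` tibbles, `deg_transcripts`, and
#'   the run metadata fields.
#' @export
read_truth <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$pairs <- tibble::as_tibble(m$pairs)
  m$groups <- tibble::as_tibble(m$groups)
  m
}

#' Read a simulation configuration from a flat key-value file
#'
#' Accepts a two-column TSV (`key`, `value`) whose keys are
#' [simulation_config()] argument names. Scalar values are coerced to numeric
#' where possible; comma-separated values become vectors; `name=value`
#' entries become named numeric vectors (e.g.
#' `enclosed=15,convergent=15,divergent=15` for `pairs_per_orientation`).
#' Unlisted keys keep their defaults.
#'
#' @param path Path to the key-value TSV.
#' @return A `cisnat_sim_config`.
#' @export
simulation_config_from_file <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  kv <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("key", "value") %in% names(kv))) {
    abort("config file needs columns 'key' and 'value'")
  }
  known <- names(formals(simulation_config))
  bad <- setdiff(kv$key, known)
  if (length(bad)) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  parse_value <- function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (all(grepl("=", parts, fixed = TRUE))) {
      nm <- sub("=.*$", "", parts)
      val <- sub("^[^=]*=", "", parts)
      num <- suppressWarnings(as.numeric(val))
      if (anyNA(num)) abort(paste0("non-numeric named value in: ", v))
      return(stats::setNames(num, nm))
    }
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) return(num)
    parts
  }
  args <- lapply(kv$value, parse_value)
  names(args) <- kv$key
  do.call(simulation_config, args)
}
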