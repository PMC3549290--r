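#' Filter small-RNA reads by length and exclusion features
#'
#' Keeps reads whose length lies in `[min_len, max_len]` and discards reads
#' overlapping any exclusion-class feature (rRNA, tRNA, snRNA, snoRNA spans)
#' or lying on an organelle chromosome. Reads are assumed pre-collapsed,
#' uniquely and perfectly mapped (multi-mappers and mismatched reads were
#' removed upstream).
#'
#' @param reads A read tibble from [read_smallrna_bed()].
#' @param exclusion_ann Optional annotation tibble whose rRNA/tRNA/sn/snoRNA
#'   transcripts define exclusion regions.
#' @param min_len,max_len Inclusive length bounds in nt (defaults 18 and 34).
#' @param organelle_chroms Chromosome names (e.g. mitochondrion, chloroplast)
#'   whose reads are removed.
#' @return The surviving subset of `reads`.
#' @export
filter_small_rnas <- function(reads, exclusion_ann = NULL, min_len = 18,
                              max_len = 34, organelle_chroms = character()) {
  keep <- reads$length >= min_len & reads$length <= max_len
  keep <- keep & !(reads$chrom %in% organelle_chroms)
  if (!is.null(exclusion_ann) && nrow(exclusion_ann) > 0L) {
    feats <- transcript_spans(exclusion_ann)
    feats <- feats[feats$biotype %in% srna_exclusion_biotypes(), ]
    if (nrow(feats) > 0L && any(keep)) {
      gr_f <- GenomicRanges::GRanges(feats$chrom, as_iranges0(feats$start, feats$end))
      gr_r <- GenomicRanges::GRanges(reads$chrom, as_iranges0(reads$start, reads$end))
      hit <- IRanges::overlapsAny(gr_r, gr_f, ignore.strand = TRUE)
      keep <- keep & !hit
    }
  }
  reads[keep, ]
}

# logical: read fully contained in a single merged interval of `intervals`
contained_in_intervals <- function(reads, chrom, intervals) {
  if (nrow(reads) == 0L) return(logical(0))
  ok <- reads$chrom == chrom
  if (nrow(intervals) == 0L || !any(ok)) return(rep(FALSE, nrow(reads)))
  hit <- IRanges::overlapsAny(as_iranges0(reads$start[ok], reads$end[ok]),
                              as_iranges0(intervals$start, intervals$end),
                              type = "within")
  out <- rep(FALSE, nrow(reads))
  out[ok] <- hit
  out
}

#' Assign nat-siRNAs of a pair
#'
#' A filtered read is a putative nat-siRNA of a pair iff its interval is wholly
#' contained in a single merged overlap interval of that pair. Reads are split
#' by their genome strand; strand determines only which member the read is
#' attributed to.
#'
#' @param reads A filtered read tibble.
#' @param pair A one-row pair tibble (from [detect_candidate_pairs()]).
#' @return A list with tibbles `plus` and `minus` of assigned reads.
#' @export
assign_nat_sirnas <- function(reads, pair) {
  stopifnot(nrow(pair) == 1L)
  inside <- contained_in_intervals(reads, pair$chrom, pair$overlap_intervals[[1]])
  nat <- reads[inside, ]
  list(plus = nat[nat$strand == "+", ], minus = nat[nat$strand == "-", ])
}

#' Classify strand bias of nat-siRNA production
#'
#' One-strand classes when one strand has zero reads and the other does not;
#' biased classes when the larger count is at least `fold` times the smaller;
#' balanced otherwise (including both-zero).
#'
#' @param plus_unique,minus_unique Unique nat-siRNA record counts per strand.
#' @param fold Ratio threshold (default 5; the secondary screen uses 2).
#' @return Character vector in `one-strand-plus`, `one-strand-minus`,
#'   `plus-biased`, `minus-biased`, `balanced`.
#' @export
classify_strand_bias <- function(plus_unique, minus_unique, fold = 5) {
  if (any(fold < 0)) abort("classify_strand_bias: fold must be non-negative")
  hi <- pmax(plus_unique, minus_unique)
  lo <- pmin(plus_unique, minus_unique)
  dplyr::case_when(
    hi == 0 ~ "balanced",
    lo == 0 & plus_unique > 0 ~ "one-strand-plus",
    lo == 0 ~ "one-strand-minus",
    hi / lo >= fold & plus_unique > minus_unique ~ "plus-biased",
    hi / lo >= fold & minus_unique > plus_unique ~ "minus-biased",
    TRUE ~ "balanced")
}

# flank region of a pair: union of both members' exons minus the overlap
pair_flank_intervals <- function(pair, ann) {
  ex <- ann[ann$transcript_id %in% c(pair$plus_id, pair$minus_id), ]
  setdiff_intervals0(ex$exon_start, ex$exon_end,
                     pair$overlap_intervals[[1]]$start,
                     pair$overlap_intervals[[1]]$end)
}

#' Small-RNA density in overlap versus flank
#'
#' Densities are unique reads per kb: reads fully inside the merged overlap
#' over the overlap length, and reads fully inside the flank (union of both
#' members' exons minus the overlap) over the flank length. The enrichment
#' ratio is overlap density over flank density; a zero flank density with a
#' positive overlap density reports `Inf`.
#'
#' @param pair A one-row pair tibble.
#' @param reads A filtered read tibble (single condition).
#' @param ann The exon-level annotation.
#' @param enrich_fold Ratio above which the pair is flagged enriched
#'   (default 5, strict).
#' @return A one-row tibble: `density_overlap`, `density_flank`,
#'   `enrichment_ratio`, `enriched`, `flank_length`.
#' @export
sirna_density <- function(pair, reads, ann, enrich_fold = 5) {
  stopifnot(nrow(pair) == 1L)
  n_ov <- sum(contained_in_intervals(reads, pair$chrom, pair$overlap_intervals[[1]]))
  flank <- pair_flank_intervals(pair, ann)
  flank_len <- sum(flank$end - flank$start)
  n_fl <- sum(contained_in_intervals(reads, pair$chrom, flank))
  d_ov <- n_ov / (pair$overlap_length / 1000)
  d_fl <- if (flank_len > 0) n_fl / (flank_len / 1000) else NA_real_
  ratio <- if (d_ov == 0 && (is.na(d_fl) || d_fl == 0)) {
    NA_real_
  } else if (is.na(d_fl) || d_fl == 0) {
    Inf
  } else {
    d_ov / d_fl
  }
  tibble::tibble(density_overlap = d_ov, density_flank = d_fl,
                 enrichment_ratio = ratio,
                 enriched = !is.na(ratio) & ratio > enrich_fold,
                 flank_length = flank_len)
}

#' Overlap exclusivity of a pair's small RNAs
#'
#' `TRUE` iff every read intersecting either member's exons lies fully within
#' the overlap region and the pair has strictly more than `min_unique` unique
#' nat-siRNA reads.
#'
#' @inheritParams sirna_density
#' @param min_unique Strict lower bound on unique nat-siRNA reads (default 5,
#'   i.e. at least 6 reads).
#' @return A logical scalar.
#' @export
overlap_exclusivity <- function(pair, reads, ann, min_unique = 5) {
  stopifnot(nrow(pair) == 1L)
  ex <- ann[ann$transcript_id %in% c(pair$plus_id, pair$minus_id), ]
  on_chrom <- reads$chrom == pair$chrom
  touches <- rep(FALSE, nrow(reads))
  if (any(on_chrom) && nrow(ex) > 0L) {
    touches[on_chrom] <- IRanges::overlapsAny(
      as_iranges0(reads$start[on_chrom], reads$end[on_chrom]),
      as_iranges0(ex$exon_start, ex$exon_end))
  }
  inside <- contained_in_intervals(reads, pair$chrom, pair$overlap_intervals[[1]])
  sum(inside) > min_unique && !any(touches & !inside)
}

#' Per-pair per-condition nat-siRNA profiles
#'
#' Computes, for every pair and every condition present in `reads`, the
#' strand-resolved unique and copy-summed nat-siRNA counts, overlap and flank
#' densities with the enrichment flag, the strand-bias class, and the
#' exclusivity flag.
#'
#' @param reads A filtered read tibble covering one or more conditions
#'   (`condition` column).
#' @param pairs A pair tibble.
#' @param ann The exon-level annotation.
#' @param bias_fold Strand-bias ratio threshold (default 5).
#' @param enrich_fold Density-enrichment threshold (default 5).
#' @param min_exclusive_unique Strict unique-read bound for exclusivity
#'   (default 5).
#' @return A tibble with one row per pair and condition.
#' @export
sirna_profiles <- function(reads, pairs, ann, bias_fold = 5, enrich_fold = 5,
                           min_exclusive_unique = 5) {
  conditions <- sort(unique(reads$condition), method = "radix")
  if (length(conditions) == 0L) conditions <- "all"
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(pair_id = character(), condition = character(),
                          plus_unique = integer(), minus_unique = integer(),
                          plus_total = integer(), minus_total = integer(),
                          density_overlap = double(), density_flank = double(),
                          enrichment_ratio = double(), enriched = logical(),
                          bias_class = character(), exclusive = logical()))
  }
  # pre-bucket reads by the pair whose exon footprint they touch: one overlap
  # query replaces per-pair scans of the whole library
  exons_by_tx <- split(ann[, c("chrom", "exon_start", "exon_end")],
                       ann$transcript_id)
  pair_geoms <- lapply(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, ]
    ex <- bind_rows(exons_by_tx[[pair$plus_id]], exons_by_tx[[pair$minus_id]])
    ov <- pair$overlap_intervals[[1]]
    flank <- setdiff_intervals0(ex$exon_start, ex$exon_end, ov$start, ov$end)
    list(chrom = pair$chrom, exons = ex, overlap = ov, flank = flank,
         flank_len = sum(flank$end - flank$start))
  })
  gr_reads <- GenomicRanges::GRanges(reads$chrom,
                                     as_iranges0(reads$start, reads$end))
  gr_exons <- GenomicRanges::GRanges(
    rep(vapply(pair_geoms, `[[`, character(1), "chrom"),
        vapply(pair_geoms, function(g) nrow(g$exons), integer(1))),
    as_iranges0(unlist(lapply(pair_geoms, function(g) g$exons$exon_start)),
                unlist(lapply(pair_geoms, function(g) g$exons$exon_end))))
  exon_pair_idx <- rep(seq_along(pair_geoms),
                       vapply(pair_geoms, function(g) nrow(g$exons), integer(1)))
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_exons, ignore.strand = TRUE)
  touched <- unique(tibble::tibble(
    read = S4Vectors::queryHits(hits),
    pair = exon_pair_idx[S4Vectors::subjectHits(hits)]))
  reads_by_pair <- split(touched$read, touched$pair)

  within_any <- function(rd, iv) {
    if (nrow(rd) == 0L || nrow(iv) == 0L) return(rep(FALSE, nrow(rd)))
    IRanges::overlapsAny(as_iranges0(rd$start, rd$end),
                         as_iranges0(iv$start, iv$end), type = "within")
  }
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, ]
    geom <- pair_geoms[[i]]
    rd_all <- reads[reads_by_pair[[as.character(i)]] %||% integer(0), ]
    purrr::map_dfr(conditions, function(cond) {
      rd <- rd_all[rd_all$condition == cond, ]
      in_ov <- within_any(rd, geom$overlap)
      in_fl <- within_any(rd, geom$flank)
      nat <- rd[in_ov, ]
      pu <- sum(nat$strand == "+")
      mu <- sum(nat$strand == "-")
      d_ov <- sum(in_ov) / (pair$overlap_length / 1000)
      d_fl <- if (geom$flank_len > 0) sum(in_fl) / (geom$flank_len / 1000) else NA_real_
      ratio <- if (d_ov == 0 && (is.na(d_fl) || d_fl == 0)) NA_real_
      else if (is.na(d_fl) || d_fl == 0) Inf
      else d_ov / d_fl
      tibble::tibble(
        pair_id = pair_key(pair$plus_id, pair$minus_id),
        condition = cond,
        plus_unique = pu, minus_unique = mu,
        plus_total = sum(nat$copies[nat$strand == "+"]),
        minus_total = sum(nat$copies[nat$strand == "-"]),
        density_overlap = d_ov, density_flank = d_fl,
        enrichment_ratio = ratio,
        enriched = !is.na(ratio) & ratio > enrich_fold,
        bias_class = classify_strand_bias(pu, mu, fold = bias_fold),
        exclusive = sum(in_ov) > min_exclusive_unique && !any(!in_ov))
    })
  })
  rows
}

#' Size and 5'-nucleotide composition of small RNAs
#'
#' Histogram of unique-read lengths over 18-34 nt and relative frequencies of
#' the 5'-first nucleotide (reads with unknown `N` first nucleotide are
#' excluded from the frequency denominator; empty input reports zeros).
#'
#' @param reads A read tibble.
#' @return A list with tibbles `length_histogram` (`length`, `n_unique`,
#'   `n_total`) and `first_nt` (`first_nt`, `n`, `frequency`).
#' @export
sequence_stats <- function(reads) {
  lens <- tibble::tibble(length = 18:34) |>
    left_join(reads |> count(.data$length, wt = NULL, name = "n_unique"),
              by = "length") |>
    left_join(reads |> count(.data$length, wt = .data$copies, name = "n_total"),
              by = "length") |>
    mutate(n_unique = coalesce(.data$n_unique, 0L),
           n_total = coalesce(as.integer(.data$n_total), 0L))
  nts <- tibble::tibble(first_nt = c("A", "C", "G", "T")) |>
    left_join(reads |> filter(.data$first_nt != "N") |>
                count(.data$first_nt, name = "n"), by = "first_nt") |>
    mutate(n = coalesce(.data$n, 0L),
           frequency = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0)
  list(length_histogram = lens, first_nt = nts)
}

#' Genomic context of small-RNA reads
#'
#' Assigns each read a context with precedence transposon > exon > intron >
#' upstream > downstream > intergenic. Transposon regions are spans of
#' transposon-biotype transcripts; exon and intron regions come from all other
#' transcripts; upstream/downstream are strand-aware windows of `flank_bp`
#' adjacent to transcript spans.
#'
#' @param reads A read tibble.
#' @param ann The exon-level annotation.
#' @param flank_bp Width of the upstream/downstream windows (default 1000).
#' @return Character vector of contexts, one per read.
#' @export
classify_genomic_context <- function(reads, ann, flank_bp = 1000) {
  if (nrow(reads) == 0L) return(character(0))
  gr_r <- GenomicRanges::GRanges(reads$chrom, as_iranges0(reads$start, reads$end))
  spans <- transcript_spans(ann)
  hit_region <- function(region) {
    if (nrow(region) == 0L) return(rep(FALSE, nrow(reads)))
    gr <- GenomicRanges::GRanges(region$chrom, as_iranges0(region$start, region$end))
    IRanges::overlapsAny(gr_r, gr, ignore.strand = TRUE)
  }
  tes <- spans[spans$biotype == "transposon", c("chrom", "start", "end")]
  genic <- spans[spans$biotype != "transposon", ]
  exons <- ann[ann$transcript_id %in% genic$transcript_id, ] |>
    transmute(chrom = .data$chrom, start = .data$exon_start, end = .data$exon_end)
  introns <- purrr::map_dfr(split(ann[ann$transcript_id %in% genic$transcript_id, ],
                                  ann$transcript_id[ann$transcript_id %in% genic$transcript_id]),
                            function(ex) {
    iv <- setdiff_intervals0(min(ex$exon_start), max(ex$exon_end),
                             ex$exon_start, ex$exon_end)
    if (nrow(iv) == 0L) return(NULL)
    tibble::tibble(chrom = ex$chrom[1], start = iv$start, end = iv$end)
  })
  upstream <- tibble::tibble(
    chrom = genic$chrom,
    start = pmax(0L, ifelse(genic$strand == "+", genic$start - flank_bp, genic$end)),
    end = ifelse(genic$strand == "+", genic$start, genic$end + flank_bp)) |>
    filter(.data$end > .data$start)
  downstream <- tibble::tibble(
    chrom = genic$chrom,
    start = pmax(0L, ifelse(genic$strand == "+", genic$end, genic$start - flank_bp)),
    end = ifelse(genic$strand == "+", genic$end + flank_bp, genic$start)) |>
    filter(.data$end > .data$start)
  dplyr::case_when(
    hit_region(tes) ~ "transposon",
    hit_region(exons) ~ "exon",
    hit_region(introns) ~ "intron",
    hit_region(upstream) ~ "upstream",
    hit_region(downstream) ~ "downstream",
    TRUE ~ "intergenic")
}
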