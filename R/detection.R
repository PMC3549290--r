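#' Exonic overlap between two transcripts
#'
#' Computes the merged union of all pairwise exon-by-exon intersections of two
#' transcripts and its total length (each base counted once however many exon
#' pairs cover it). Disjoint exon sets are a valid result (empty intervals,
#' length 0). Half-open abutment is not overlap.
#'
#' @param exons_a,exons_b Tibbles with columns `exon_start`, `exon_end`
#'   (0-based half-open), both on the same chromosome.
#' @return A list with `intervals` (tibble of disjoint sorted `start`/`end`)
#'   and `length` (total overlapped bases).
#' @export
exonic_overlap <- function(exons_a, exons_b) {
  iv <- intersect_intervals0(exons_a$exon_start, exons_a$exon_end,
                             exons_b$exon_start, exons_b$exon_end)
  list(intervals = iv, length = sum(iv$end - iv$start))
}

#' Classify the orientation of an antisense pair
#'
#' Orientation is decided on genomic spans: `enclosed` when one span contains
#' the other; otherwise `convergent` (3'-3' overlap) when the plus-strand
#' member lies upstream of the minus-strand member, else `divergent` (5'-5').
#' Equal spans are containment in both directions and classify as enclosed.
#'
#' @param plus_start,plus_end Span of the plus-strand member (0-based half-open).
#' @param minus_start,minus_end Span of the minus-strand member.
#' @return Character vector in `c("enclosed", "convergent", "divergent")`.
#' @export
classify_orientation <- function(plus_start, plus_end, minus_start, minus_end) {
  enclosed <- (plus_start <= minus_start & minus_end <= plus_end) |
    (minus_start <= plus_start & plus_end <= minus_end)
  dplyr::case_when(enclosed ~ "enclosed",
                   plus_start < minus_start ~ "convergent",
                   TRUE ~ "divergent")
}

#' Partner-class label for a pair of biotypes
#'
#' Unordered six-value label over the retained biotypes CDS-p (coding with a
#' protein-domain hit), CDS-n (predicted CDS without one) and ncRNA.
#'
#' @param biotype_a,biotype_b Character vectors of biotypes; each value must be
#'   one of `"CDS-p"`, `"CDS-n"`, `"ncRNA"`.
#' @return Character vector such as `"CDS-p vs ncRNA"`.
#' @export
partner_class <- function(biotype_a, biotype_b) {
  ord <- c("CDS-p" = 1L, "CDS-n" = 2L, "ncRNA" = 3L)
  if (!all(biotype_a %in% names(ord)) || !all(biotype_b %in% names(ord))) {
    abort("partner_class: biotypes must be CDS-p, CDS-n or ncRNA (excluded biotypes must be filtered before this call)")
  }
  ra <- ord[biotype_a]
  rb <- ord[biotype_b]
  first <- ifelse(ra <= rb, biotype_a, biotype_b)
  second <- ifelse(ra <= rb, biotype_b, biotype_a)
  paste(first, "vs", second)
}

#' Detect candidate cis-NAT pairs
#'
#' Enumerates all opposite-strand transcript pairs whose exonic overlap is
#' strictly greater than `min_overlap` nucleotides, then removes pairs where
#' either member carries an excluded biotype. Exclusion happens after
#' enumeration so the pre-exclusion candidate count stays reportable (attribute
#' `n_candidates`, also a column when `keep_excluded = TRUE`).
#'
#' @inheritParams validate_annotation
#' @param min_overlap Minimum exonic overlap in nt; retained pairs satisfy
#'   `overlap_length > min_overlap` (strict). Default 25.
#' @param excluded_biotypes Biotypes whose pairs are removed after enumeration.
#' @param keep_excluded If `TRUE`, retain excluded pairs with a logical
#'   `excluded` column instead of dropping them.
#' @return A tibble with one row per pair: `plus_id`, `minus_id`, `chrom`,
#'   `plus_locus`, `minus_locus`, `plus_biotype`, `minus_biotype`,
#'   `overlap_start`, `overlap_length`, `overlap_intervals` (list column of
#'   tibbles), `orientation`, and `partner_class` (NA for excluded pairs).
#'   Sorted by (chrom, overlap start, plus id). Attribute `n_candidates` holds
#'   the pre-exclusion count.
#' @export
detect_candidate_pairs <- function(ann, min_overlap = 25,
                                   excluded_biotypes = default_excluded_biotypes(),
                                   keep_excluded = FALSE) {
  validate_annotation(ann)
  spans <- transcript_spans(ann)
  empty <- tibble::tibble(
    plus_id = character(), minus_id = character(), chrom = character(),
    plus_locus = character(), minus_locus = character(),
    plus_biotype = character(), minus_biotype = character(),
    overlap_start = integer(), overlap_length = integer(),
    overlap_intervals = list(), orientation = character(),
    partner_class = character())
  if (keep_excluded) empty$excluded <- logical()
  plus <- spans[spans$strand == "+", ]
  minus <- spans[spans$strand == "-", ]
  if (nrow(plus) == 0L || nrow(minus) == 0L) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  gr_p <- GenomicRanges::GRanges(plus$chrom, as_iranges0(plus$start, plus$end))
  gr_m <- GenomicRanges::GRanges(minus$chrom, as_iranges0(minus$start, minus$end))
  hits <- GenomicRanges::findOverlaps(gr_p, gr_m, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  exons_by_tx <- split(ann[, c("exon_start", "exon_end")], ann$transcript_id)
  ih <- tibble::tibble(pi = S4Vectors::queryHits(hits),
                       mi = S4Vectors::subjectHits(hits))
  res <- purrr::pmap_dfr(ih, function(pi, mi) {
    p <- plus[pi, ]
    m <- minus[mi, ]
    ov <- exonic_overlap(exons_by_tx[[p$transcript_id]],
                         exons_by_tx[[m$transcript_id]])
    if (ov$length <= min_overlap) return(NULL)
    tibble::tibble(
      plus_id = p$transcript_id, minus_id = m$transcript_id, chrom = p$chrom,
      plus_locus = p$locus_id, minus_locus = m$locus_id,
      plus_biotype = p$biotype, minus_biotype = m$biotype,
      overlap_start = ov$intervals$start[1],
      overlap_length = as.integer(ov$length),
      overlap_intervals = list(ov$intervals),
      orientation = classify_orientation(p$start, p$end, m$start, m$end))
  })
  if (is.null(res) || nrow(res) == 0L) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  n_candidates <- nrow(res)
  res$excluded <- res$plus_biotype %in% excluded_biotypes |
    res$minus_biotype %in% excluded_biotypes
  res$partner_class <- NA_character_
  if (any(!res$excluded)) {
    res$partner_class[!res$excluded] <-
      partner_class(res$plus_biotype[!res$excluded], res$minus_biotype[!res$excluded])
  }
  if (!keep_excluded) {
    res <- res[!res$excluded, ]
    res$excluded <- NULL
  }
  res <- res[order_c(res$chrom, res$overlap_start, res$plus_id, res$minus_id), ]
  attr(res, "n_candidates") <- n_candidates
  res
}

#' Select representative pairs across isoforms
#'
#' Isoform combinations of the same (unordered) locus pair are collapsed to the
#' single pair with the longest exonic overlap; ties break to the
#' lexicographically smallest `(plus_id, minus_id)`.
#'
#' @param pairs A pair tibble from [detect_candidate_pairs()].
#' @return The representative subset, same columns and order convention.
#' @export
select_representatives <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  keyed <- pairs |>
    mutate(locus_key = paste(pmin(.data$plus_locus, .data$minus_locus),
                             pmax(.data$plus_locus, .data$minus_locus),
                             sep = "|"))
  keep <- keyed |>
    group_by(.data$locus_key) |>
    arrange(desc(.data$overlap_length), .data$plus_id, .data$minus_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"locus_key")
  keep <- keep[order_c(keep$chrom, keep$overlap_start, keep$plus_id, keep$minus_id), ]
  attr(keep, "n_candidates") <- attr(pairs, "n_candidates")
  keep
}
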