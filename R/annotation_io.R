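#' Read strand-resolved transcript models from GFF3
#'
#' Parses a GFF3 file containing `transcript` features (attributes `ID`,
#' `locus_id`, `biotype`) and `exon` features (attribute `Parent`) into an
#' exon-level annotation tibble. GFF3 1-based closed coordinates are converted
#' to the internal 0-based half-open convention at this boundary.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble of class `cisnat_annotation` with one row per exon and
#'   columns `transcript_id`, `locus_id`, `chrom`, `strand`, `biotype`,
#'   `exon_start`, `exon_end` (0-based half-open). Exons are sorted by start
#'   within each transcript.
#' @seealso [write_gff3()], [transcript_spans()]
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  body <- which(!startsWith(raw, "#") & nzchar(trimws(raw)))
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- body[which(nfield != 9L)[1]]
    abort(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields", bad, path))
  }
  if (length(body) == 0L) {
    return(new_annotation(tibble::tibble(
      transcript_id = character(), locus_id = character(), chrom = character(),
      strand = character(), biotype = character(),
      exon_start = integer(), exon_end = integer())))
  }
  gff <- suppressWarnings(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent", "locus_id", "biotype")))
  gff <- tibble::as_tibble(as.data.frame(gff, stringsAsFactors = FALSE))
  gff$Parent <- vapply(gff$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))

  tx <- gff |>
    filter(.data$type == "transcript") |>
    transmute(transcript_id = as.character(.data$ID),
              locus_id = as.character(.data$locus_id),
              tx_strand = as.character(.data$strand),
              biotype = as.character(.data$biotype))
  if (anyDuplicated(tx$transcript_id)) {
    abort(paste0("duplicate transcript ID in ", path))
  }
  ex <- gff |>
    filter(.data$type == "exon") |>
    transmute(transcript_id = .data$Parent,
              chrom = as.character(.data$seqid),
              strand = as.character(.data$strand),
              exon_start = as.integer(.data$start) - 1L,
              exon_end = as.integer(.data$end))
  orphan <- setdiff(ex$transcript_id, tx$transcript_id)
  if (length(orphan)) {
    abort(paste0("exon Parent without transcript record: ", orphan[1]))
  }
  ann <- ex |>
    inner_join(tx, by = "transcript_id") |>
    select("transcript_id", "locus_id", "chrom", "strand", "biotype",
           "exon_start", "exon_end", "tx_strand")
  conflict <- ann |>
    group_by(.data$transcript_id) |>
    summarise(bad = n_distinct(.data$strand) > 1L ||
                any(.data$strand != .data$tx_strand), .groups = "drop") |>
    filter(.data$bad)
  if (nrow(conflict)) {
    abort(paste0("exon strand conflict within transcript ", conflict$transcript_id[1]))
  }
  ann$tx_strand <- NULL
  ann <- ann[order_c(ann$chrom, ann$transcript_id, ann$exon_start), ]
  new_annotation(ann)
}

new_annotation <- function(ann) {
  validate_annotation(ann)
  class(ann) <- c("cisnat_annotation", class(tibble::tibble()))
  ann
}

#' Validate an exon-level annotation tibble
#'
#' Checks the annotation invariants: positive-length exons, per-transcript
#' consistency of chromosome/strand/locus/biotype, sorted pairwise
#' non-overlapping exons, and the closed biotype vocabulary.
#'
#' @param ann An exon-level annotation tibble (see [read_gff3()]).
#' @return `ann`, invisibly, if valid; otherwise an error.
#' @export
validate_annotation <- function(ann) {
  req <- c("transcript_id", "locus_id", "chrom", "strand", "biotype",
           "exon_start", "exon_end")
  miss <- setdiff(req, names(ann))
  if (length(miss)) abort(paste0("annotation missing columns: ", paste(miss, collapse = ", ")))
  if (nrow(ann) == 0L) return(invisible(ann))
  if (!all(ann$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  bad_bt <- setdiff(unique(ann$biotype), cisnat_biotypes())
  if (length(bad_bt)) {
    abort(paste0("unknown biotype value(s): ", paste(bad_bt, collapse = ", ")))
  }
  if (any(ann$exon_start >= ann$exon_end)) abort("exon with start >= end")
  per_tx <- ann |>
    group_by(.data$transcript_id) |>
    summarise(
      one_chrom = n_distinct(.data$chrom) == 1L,
      one_strand = n_distinct(.data$strand) == 1L,
      one_locus = n_distinct(.data$locus_id) == 1L,
      one_biotype = n_distinct(.data$biotype) == 1L,
      sorted_disjoint = all(diff(order(.data$exon_start)) == 1L) &&
        (n() == 1L || all(utils::head(sort(.data$exon_end), -1) <=
                            sort(.data$exon_start)[-1])),
      .groups = "drop")
  if (!all(per_tx$one_chrom)) abort("transcript with exons on multiple chromosomes")
  if (!all(per_tx$one_strand)) abort("exon strand conflict within a transcript")
  if (!all(per_tx$one_locus)) abort("transcript with inconsistent locus_id")
  if (!all(per_tx$one_biotype)) abort("transcript with inconsistent biotype")
  if (!all(per_tx$sorted_disjoint)) abort("exons must be sorted and pairwise non-overlapping")
  invisible(ann)
}

#' Summarise transcripts to spans
#'
#' Collapses an exon-level annotation to one row per transcript with its
#' genomic span (min exon start to max exon end), exon count and summed exonic
#' length.
#'
#' @inheritParams validate_annotation
#' @return A tibble with columns `transcript_id`, `locus_id`, `chrom`,
#'   `strand`, `biotype`, `start`, `end`, `n_exons`, `exonic_length`.
#' @export
transcript_spans <- function(ann) {
  ann |>
    group_by(.data$transcript_id) |>
    summarise(locus_id = .data$locus_id[1], chrom = .data$chrom[1],
              strand = .data$strand[1], biotype = .data$biotype[1],
              start = min(.data$exon_start), end = max(.data$exon_end),
              n_exons = n(),
              exonic_length = sum(.data$exon_end - .data$exon_start),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start, .data$transcript_id)
}

#' Write transcript models to GFF3
#'
#' Emits the dialect read by [read_gff3()]: one `transcript` feature per
#' transcript (attributes `ID`, `locus_id`, `biotype`) followed by its `exon`
#' features (attribute `Parent`), converted back to 1-based closed
#' coordinates. Record order is deterministic (chromosome, span start, id).
#'
#' @inheritParams validate_annotation
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  validate_annotation(ann)
  con <- tryCatch(file(path, "wt"), error = function(e)
    abort(paste0("cannot open for writing: ", path)))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann) == 0L) return(invisible(path))
  spans <- transcript_spans(ann)
  spans <- spans[order_c(spans$chrom, spans$start, spans$transcript_id), ]
  exons <- split(ann, ann$transcript_id)
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    writeLines(sprintf("%s\tcisnat\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;locus_id=%s;biotype=%s",
                       s$chrom, s$start + 1L, s$end, s$strand,
                       s$transcript_id, s$locus_id, s$biotype), con)
    ex <- exons[[s$transcript_id]]
    ex <- ex[order(ex$exon_start), ]
    writeLines(sprintf("%s\tcisnat\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       ex$chrom, ex$exon_start + 1L, ex$exon_end, ex$strand,
                       s$transcript_id), con)
  }
  invisible(path)
}

#' Read collapsed small-RNA alignments from BED6
#'
#' Reads a BED6 file of pre-collapsed small-RNA alignments: one record per
#' unique (sequence, position), the collapsed copy count in the score column,
#' and optionally the read sequence (in read orientation) as the final
#' underscore-separated token of the name column. BED coordinates are already
#' 0-based half-open and are kept as-is.
#'
#' @param path Path to a BED6 file.
#' @param condition Condition label attached to every read.
#' @return A tibble with columns `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `length`, `copies`, `first_nt`, `condition`. `first_nt` is the first
#'   character of the supplied read sequence (U normalised to T) or `"N"` when
#'   no sequence is present.
#' @export
read_smallrna_bed <- function(path, condition = "unknown") {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         col_types = "ciicic", comment = "#", progress = FALSE)
  if (nrow(bed) == 0L) {
    return(tibble::tibble(read_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          copies = integer(), first_nt = character(),
                          condition = character()))
  }
  if (any(bed$start >= bed$end)) abort(paste0("BED record with start >= end in ", path))
  if (any(bed$score < 1L)) abort(paste0("BED copy count < 1 in ", path))
  if (!all(bed$strand %in% c("+", "-"))) abort(paste0("BED strand must be +/- in ", path))
  tail_tok <- stringr::str_extract(bed$name, "[^_]+$")
  is_seq <- !is.na(tail_tok) & stringr::str_detect(tail_tok, "^[ACGTUNacgtun]+$")
  first_nt <- ifelse(is_seq, toupper(stringr::str_sub(tail_tok, 1, 1)), "N")
  first_nt[first_nt == "U"] <- "T"
  tibble::tibble(read_id = bed$name, chrom = bed$chrom, start = bed$start,
                 end = bed$end, strand = bed$strand,
                 length = bed$end - bed$start, copies = bed$score,
                 first_nt = first_nt, condition = condition)
}

#' Write small-RNA reads to BED6
#'
#' Inverse of [read_smallrna_bed()]; copy counts go to the score column.
#'
#' @param reads A read tibble as returned by [read_smallrna_bed()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_smallrna_bed <- function(reads, path) {
  reads <- reads[order_c(reads$chrom, reads$start, reads$read_id), ]
  readr::write_tsv(reads[, c("chrom", "start", "end", "read_id", "copies", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a per-condition expression table
#'
#' Reads a TSV with columns `transcript_id`, `condition`, `fpkm`,
#' `fragment_count`, `library_size`, keyed by (transcript, condition).
#'
#' @param path Path to the TSV file.
#' @return A validated tibble with those columns.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) abort(paste0("expression table not found: ", path))
  expr <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    transcript_id = "c", condition = "c", fpkm = "d",
    fragment_count = "d", library_size = "d"), progress = FALSE))
  miss <- setdiff(c("transcript_id", "condition", "fpkm", "fragment_count",
                    "library_size"), names(expr))
  if (length(miss)) {
    abort(paste0("expression table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(is.na(expr$fpkm)) || any(expr$fpkm < 0)) abort("fpkm must be >= 0")
  if (any(is.na(expr$fragment_count)) || any(expr$fragment_count < 0)) {
    abort("fragment_count must be >= 0")
  }
  if (any(is.na(expr$library_size)) || any(expr$library_size <= 0)) {
    abort("library_size must be > 0")
  }
  dup <- duplicated(expr[, c("transcript_id", "condition")])
  if (any(dup)) {
    abort(sprintf("duplicate (transcript, condition) key: (%s, %s)",
                  expr$transcript_id[dup][1], expr$condition[dup][1]))
  }
  expr
}

#' Read a transcript-to-domain-term map
#'
#' @param path Path to a TSV with columns `transcript_id`, `domain_term`.
#' @return A tibble with those columns (duplicate rows dropped).
#' @export
read_domain_map <- function(path) {
  if (!file.exists(path)) abort(paste0("domain map not found: ", path))
  map <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  miss <- setdiff(c("transcript_id", "domain_term"), names(map))
  if (length(miss)) abort(paste0("domain map missing column(s): ", paste(miss, collapse = ", ")))
  distinct(map)
}
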