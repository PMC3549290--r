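# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# GFF3 I/O converts at the boundary; BED is native.

# closed biotype vocabulary
cisnat_biotypes <- function() {
  c("CDS-p", "CDS-n", "ncRNA", "transposon", "rRNA", "tRNA",
    "snRNA", "snoRNA", "miRNA")
}

# biotypes whose pairs are dropped after candidate enumeration
default_excluded_biotypes <- function() {
  c("transposon", "rRNA", "tRNA", "snRNA", "snoRNA", "miRNA")
}

# feature classes whose overlapping small-RNA reads are discarded
srna_exclusion_biotypes <- function() {
  c("rRNA", "tRNA", "snRNA", "snoRNA")
}

# 0-based half-open -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L,
                   width = as.integer(end) - as.integer(start))
}

from_iranges0 <- function(x) {
  tibble::tibble(start = BiocGenerics::start(x) - 1L,
                 end   = BiocGenerics::end(x))
}

merge_intervals0 <- function(start, end) {
  if (length(start) == 0L) return(tibble::tibble(start = integer(), end = integer()))
  from_iranges0(IRanges::reduce(as_iranges0(start, end)))
}

# intersection of two interval sets by a two-pointer sweep over the merged,
# sorted representations (avoids cross-package generic clashes on intersect)
intersect_intervals0 <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  a <- merge_intervals0(s1, e1)
  b <- merge_intervals0(s2, e2)
  out_s <- integer(0)
  out_e <- integer(0)
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (s < e) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, e)
    }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  tibble::tibble(start = out_s, end = out_e)
}

setdiff_intervals0 <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L) return(tibble::tibble(start = integer(), end = integer()))
  if (length(s2) == 0L) return(merge_intervals0(s1, e1))
  a <- merge_intervals0(s1, e1)
  b <- merge_intervals0(s2, e2)
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_len(nrow(a))) {
    cur <- a$start[i]
    for (j in seq_len(nrow(b))) {
      if (b$end[j] <= cur || b$start[j] >= a$end[i]) next
      if (b$start[j] > cur) {
        out_s <- c(out_s, cur)
        out_e <- c(out_e, b$start[j])
      }
      cur <- max(cur, b$end[j])
    }
    if (cur < a$end[i]) {
      out_s <- c(out_s, cur)
      out_e <- c(out_e, a$end[i])
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# deterministic sub-seed per generation role; kept below 2^31
derive_seed <- function(seed, role) {
  roles <- c(annotation = 11L, smallrna = 23L, expression = 37L,
             genome = 53L, domains = 71L, replicate = 89L)
  stopifnot(role %in% names(roles))
  (as.integer(seed) %% 1000000L) * 1000L + roles[[role]]
}

# radix order => locale-independent, reproducible report ordering
order_c <- function(...) order(..., method = "radix")

pair_key <- function(plus_id, minus_id) paste(plus_id, minus_id, sep = "|")

spell_count <- function(n) {
  words <- c("one", "two", "three", "four")
  ifelse(n >= 1 & n <= 4, words[pmin(n, 4L)], as.character(n))
}

#' Format overlap intervals as a 1-based location string
#'
#' Renders a set of internal 0-based half-open intervals as the
#' `chrom:start-end;...` string used in report tables (1-based, closed).
#'
#' @param chrom Chromosome name (length 1).
#' @param start,end Integer vectors of 0-based half-open interval bounds.
#' @return A single character string.
#' @keywords internal
format_locations <- function(chrom, start, end) {
  paste(sprintf("%s:%d-%d", chrom, start + 1L, end), collapse = ";")
}
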