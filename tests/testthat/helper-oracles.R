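# brute-force per-base exonic-overlap oracle: counts genome positions covered
# by an exon of both transcripts
overlap_length_oracle <- function(exons_a, exons_b, max_pos = NULL) {
  if (is.null(max_pos)) max_pos <- max(exons_a$exon_end, exons_b$exon_end)
  cov <- function(ex) {
    v <- rep(FALSE, max_pos)
    for (i in seq_len(nrow(ex))) {
      if (ex$exon_end[i] > ex$exon_start[i]) {
        v[(ex$exon_start[i] + 1):ex$exon_end[i]] <- TRUE
      }
    }
    v
  }
  sum(cov(exons_a) & cov(exons_b))
}

# brute-force read-in-overlap oracle: every base of the read covered by the
# interval set AND the read inside a single interval
containment_oracle <- function(read_start, read_end, intervals) {
  any(intervals$start <= read_start & read_end <= intervals$end)
}

# independent two-sided Fisher oracle via exact log-binomial coefficients
fisher_oracle <- function(a, b, cc, d) {
  m <- a + cc
  n1 <- a + b
  N <- a + b + cc + d
  if (N == 0) return(1)
  k <- max(0, m - (N - n1)):min(m, n1)
  logp <- lchoose(m, k) + lchoose(N - m, n1 - k) - lchoose(N, n1)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(N - m, n1 - a) - lchoose(N, n1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# random multi-exon transcript on [0, max_pos) for property tests
random_exons <- function(max_pos = 400, max_exons = 3) {
  n <- sample.int(max_exons, 1)
  bounds <- sort(sample.int(max_pos, 2 * n))
  tibble::tibble(exon_start = bounds[seq(1, 2 * n, 2)] - 1L,
                 exon_end = bounds[seq(2, 2 * n, 2)])
}
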