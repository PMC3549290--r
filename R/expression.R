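#' Per-pair per-condition expression records
#'
#' Joins the transcript-level expression table onto pairs, computes the
#' sense/antisense log-ratio with a pseudocount, and makes the expressed call:
#' FPKM of both members strictly positive and at least `min_sirna` unique
#' nat-siRNA reads in the same condition's small-RNA library.
#'
#' @param pairs A pair tibble (typically the one-to-one representatives).
#' @param expr An expression tibble from [read_expression_table()].
#' @param profiles A profile tibble from [sirna_profiles()].
#' @param eps Pseudocount added to FPKM in ratios (default 0.1).
#' @param min_sirna Minimum unique nat-siRNA reads for the expressed call
#'   (default 1).
#' @return A tibble with one row per pair and condition: `pair_id`,
#'   `condition`, `fpkm_plus`, `fpkm_minus`, `count_plus`, `count_minus`,
#'   `lib_size`, `n_sirna`, `log_ratio`, `expressed`.
#' @export
pair_expression <- function(pairs, expr, profiles, eps = 0.1, min_sirna = 1) {
  conditions <- sort(unique(expr$condition), method = "radix")
  base <- tidyr::expand_grid(
    tibble::tibble(pair_id = pair_key(pairs$plus_id, pairs$minus_id),
                   plus_id = pairs$plus_id, minus_id = pairs$minus_id),
    condition = conditions)
  ex <- expr |> select("transcript_id", "condition", "fpkm",
                       "fragment_count", "library_size")
  out <- base |>
    left_join(ex, by = c(plus_id = "transcript_id", "condition")) |>
    rename(fpkm_plus = "fpkm", count_plus = "fragment_count",
           lib_size = "library_size") |>
    left_join(ex, by = c(minus_id = "transcript_id", "condition")) |>
    rename(fpkm_minus = "fpkm", count_minus = "fragment_count") |>
    select(-"library_size")
  missing <- out |>
    filter(is.na(.data$fpkm_plus) | is.na(.data$fpkm_minus))
  if (nrow(missing) > 0L) {
    m <- missing[1, ]
    tx <- if (is.na(m$fpkm_plus)) m$plus_id else m$minus_id
    abort(sprintf("missing expression record for transcript %s under condition %s",
                  tx, m$condition))
  }
  out <- out |>
    left_join(profiles |> select("pair_id", "condition", "plus_unique",
                                 "minus_unique"),
              by = c("pair_id", "condition")) |>
    mutate(n_sirna = coalesce(.data$plus_unique, 0L) +
             coalesce(.data$minus_unique, 0L),
           log_ratio = log2((.data$fpkm_plus + eps) / (.data$fpkm_minus + eps)),
           expressed = .data$fpkm_plus > 0 & .data$fpkm_minus > 0 &
             .data$n_sirna >= min_sirna) |>
    select("pair_id", "condition", "fpkm_plus", "fpkm_minus", "count_plus",
           "count_minus", "lib_size", "n_sirna", "log_ratio", "expressed")
  out
}

#' Expressed call for a single pair and condition
#'
#' @param fpkm_plus,fpkm_minus FPKM of the two members.
#' @param n_sirna Unique nat-siRNA reads of the pair in the same condition.
#' @param min_sirna Minimum nat-siRNA evidence (default 1).
#' @return Logical.
#' @export
call_expressed <- function(fpkm_plus, fpkm_minus, n_sirna, min_sirna = 1) {
  fpkm_plus > 0 & fpkm_minus > 0 & n_sirna >= min_sirna
}

#' Co-expression sets across conditions
#'
#' Per-condition expressed sets, their all-condition intersection
#' ("co-expressed") and union ("expressed in at least one condition").
#'
#' @param pair_expr A tibble from [pair_expression()].
#' @return A list with `membership` (wide logical tibble, one row per pair),
#'   `sets` (named list of pair-id vectors, including `co_expressed` and
#'   `union`), and `counts` (tibble of set sizes).
#' @export
coexpression_sets <- function(pair_expr) {
  wide <- pair_expr |>
    select("pair_id", "condition", "expressed") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "expressed")
  conds <- setdiff(names(wide), "pair_id")
  mat <- as.matrix(wide[, conds])
  sets <- lapply(conds, function(cn) wide$pair_id[mat[, cn]])
  names(sets) <- conds
  sets$co_expressed <- wide$pair_id[rowSums(mat) == length(conds)]
  sets$union <- wide$pair_id[rowSums(mat) > 0]
  counts <- tibble::tibble(set = names(sets),
                           n = vapply(sets, length, integer(1)))
  list(membership = wide, sets = sets, counts = counts)
}

#' Classify sense/antisense ratio subgroups
#'
#' With `ds = log2((fpkm_plus_stress + eps) / (fpkm_plus_control + eps))` and
#' `da` likewise for the minus member, and `t = log2(fc_threshold)`:
#' subgroup 2 when sense up and antisense down (`ds >= t`, `da <= -t`);
#' subgroup 3 the reverse; subgroup 4 both up; subgroup 5 both down;
#' subgroup 1 when both moves are below threshold; remaining mixed patterns are
#' `outlier`.
#'
#' @param delta_sense,delta_antisense Log2 stress/control FPKM ratios of the
#'   plus- and minus-strand members.
#' @param fc_threshold Fold-change threshold (default 2).
#' @return Character vector in `"1"`..`"5"`, `"outlier"`.
#' @export
classify_subgroup <- function(delta_sense, delta_antisense, fc_threshold = 2) {
  t <- log2(fc_threshold)
  dplyr::case_when(
    delta_sense >= t & delta_antisense <= -t ~ "2",
    delta_sense <= -t & delta_antisense >= t ~ "3",
    delta_sense >= t & delta_antisense >= t ~ "4",
    delta_sense <= -t & delta_antisense <= -t ~ "5",
    abs(delta_sense) < t & abs(delta_antisense) < t ~ "1",
    TRUE ~ "outlier")
}

#' Subgroup classification of co-expressed pairs
#'
#' Restricts to pairs expressed under both the control and the stress
#' condition, computes per-member log2 stress/control ratios and assigns
#' subgroup labels via [classify_subgroup()].
#'
#' @param pair_expr A tibble from [pair_expression()].
#' @param control,stress Condition labels.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param eps FPKM pseudocount (default 0.1).
#' @return A tibble `pair_id`, `delta_sense`, `delta_antisense`, `subgroup`,
#'   plus the control and stress log sense/antisense ratios
#'   (`log_ratio_control`, `log_ratio_stress`).
#' @export
subgroup_classification <- function(pair_expr, control, stress,
                                    fc_threshold = 2, eps = 0.1) {
  both <- pair_expr |>
    filter(.data$condition %in% c(control, stress)) |>
    group_by(.data$pair_id) |>
    filter(all(.data$expressed)) |>
    ungroup()
  if (nrow(both) == 0L) {
    return(tibble::tibble(pair_id = character(), delta_sense = double(),
                          delta_antisense = double(), subgroup = character(),
                          log_ratio_control = double(),
                          log_ratio_stress = double()))
  }
  ctl <- both |> filter(.data$condition == control)
  stb <- both |> filter(.data$condition == stress)
  merged <- inner_join(ctl, stb, by = "pair_id", suffix = c("_control", "_stress"))
  merged |>
    transmute(pair_id = .data$pair_id,
              delta_sense = log2((.data$fpkm_plus_stress + eps) /
                                   (.data$fpkm_plus_control + eps)),
              delta_antisense = log2((.data$fpkm_minus_stress + eps) /
                                       (.data$fpkm_minus_control + eps)),
              subgroup = classify_subgroup(.data$delta_sense,
                                           .data$delta_antisense, fc_threshold),
              log_ratio_control = .data$log_ratio_control,
              log_ratio_stress = .data$log_ratio_stress)
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return The square of the Pearson product-moment correlation, in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("pearson_r2: x and y must have equal length >= 2")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("pearson_r2: zero variance input, correlation undefined")
  }
  cor(x, y)^2
}

#' Two-sided Fisher exact probability of a 2x2 table
#'
#' Computed by hypergeometric enumeration: the sum of the probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (with the conventional `1 + 1e-7` relative tie tolerance).
#'
#' @param a,b,c,d Non-negative cell counts, row-wise
#'   (`[a, b; c, d]`).
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("fisher_exact_p: negative cell count")
  m <- a + c          # first-column margin
  n1 <- a + b         # first-row margin
  N <- a + b + c + d
  if (N == 0) return(1)
  k <- max(0, m - (N - n1)):min(m, n1)
  p_k <- dhyper(k, m, N - m, n1)
  p_obs <- dhyper(a, m, N - m, n1)
  min(1, sum(p_k[p_k <= p_obs * (1 + 1e-7)]))
}

#' Fisher-exact differential expression between two libraries
#'
#' Significance is computed on raw fragment counts via the two-sided Fisher
#' exact test on the table `[count_stress, lib_stress - count_stress;
#' count_control, lib_control - count_control]`; the fold change is computed
#' on FPKM with a pseudocount. A transcript is a DEG when
#' `|log2(fold_change)| >= log2(fold_threshold)` and `p < p_threshold`.
#'
#' @param count_stress,count_control Fragment counts in the two libraries.
#' @param lib_stress,lib_control Library sizes (total mapped fragments),
#'   strictly greater than the corresponding counts.
#' @param fpkm_stress,fpkm_control FPKM values used for the fold change.
#' @param eps FPKM pseudocount (default 0.1).
#' @param fold_threshold DEG fold-change cutoff (default 2).
#' @param p_threshold DEG significance cutoff (default 0.001).
#' @return A tibble `fold_change`, `log2_fold_change`, `p_value`, `is_deg`
#'   (vectorised over the inputs).
#' @export
fisher_exact_deg <- function(count_stress, lib_stress, count_control,
                             lib_control, fpkm_stress, fpkm_control,
                             eps = 0.1, fold_threshold = 2, p_threshold = 0.001) {
  if (any(count_stress < 0) || any(count_control < 0)) {
    abort("fisher_exact_deg: negative counts")
  }
  if (any(lib_stress <= count_stress) || any(lib_control <= count_control)) {
    abort("fisher_exact_deg: library size must exceed the fragment count")
  }
  p <- mapply(function(cs, ls, cc, lc)
    fisher_exact_p(cs, ls - cs, cc, lc - cc),
    count_stress, lib_stress, count_control, lib_control)
  fold <- (fpkm_stress + eps) / (fpkm_control + eps)
  tibble::tibble(fold_change = fold, log2_fold_change = log2(fold),
                 p_value = p,
                 is_deg = abs(log2(fold)) >= log2(fold_threshold) &
                   p < p_threshold)
}

#' Stress-preferential pairs
#'
#' Flags, per stress condition, pairs expressed under that stress but not
#' under the control, plus a combined any-stress flag.
#'
#' @param pair_expr A tibble from [pair_expression()].
#' @param control The control condition label.
#' @return A tibble with one row per pair: `pair_id`, one logical column per
#'   stress condition, and `any_stress`.
#' @export
stress_preferential <- function(pair_expr, control) {
  wide <- pair_expr |>
    select("pair_id", "condition", "expressed") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "expressed")
  if (!control %in% names(wide)) {
    abort(paste0("control condition not present: ", control))
  }
  stresses <- setdiff(names(wide), c("pair_id", control))
  out <- tibble::tibble(pair_id = wide$pair_id)
  for (s in stresses) {
    out[[s]] <- wide[[s]] & !wide[[control]]
  }
  out$any_stress <- if (length(stresses)) {
    Reduce(`|`, out[stresses])
  } else {
    rep(FALSE, nrow(out))
  }
  out
}

#' Domain-term enrichment of a target set
#'
#' For every term in the map, a two-sided Fisher exact test on
#' `[targets with term, targets without; background-only with, without]`,
#' where the background-only set is the background minus the target (the
#' target must be a subset of the background). Direction is by comparing term
#' rates in target versus background-only.
#'
#' @param target_transcripts,background_transcripts Character vectors of
#'   transcript ids; `target_transcripts` must be contained in
#'   `background_transcripts`.
#' @param domain_map A tibble `transcript_id`, `domain_term`.
#' @param p_threshold Significance cutoff (default 0.001).
#' @return A tibble per term: `domain_term`, `count_target`,
#'   `count_background`, `p_value`, `direction`
#'   (`"enriched"`/`"depleted"`/`"equal"`), `significant`.
#' @export
domain_enrichment <- function(target_transcripts, background_transcripts,
                              domain_map, p_threshold = 0.001) {
  target <- unique(target_transcripts)
  background <- unique(background_transcripts)
  if (length(background) == 0L) abort("domain_enrichment: empty background")
  if (!all(target %in% background)) {
    abort("domain_enrichment: target must be a subset of the background")
  }
  bg_only <- setdiff(background, target)
  terms <- sort(unique(domain_map$domain_term), method = "radix")
  nt <- length(target)
  nb <- length(bg_only)
  rows <- purrr::map_dfr(terms, function(term) {
    with_term <- unique(domain_map$transcript_id[domain_map$domain_term == term])
    a <- sum(target %in% with_term)
    cc <- sum(bg_only %in% with_term)
    p <- fisher_exact_p(a, nt - a, cc, nb - cc)
    rate_t <- if (nt > 0) a / nt else 0
    rate_b <- if (nb > 0) cc / nb else 0
    tibble::tibble(domain_term = term, count_target = a, count_background = cc,
                   p_value = p,
                   direction = dplyr::case_when(rate_t > rate_b ~ "enriched",
                                                rate_t < rate_b ~ "depleted",
                                                TRUE ~ "equal"),
                   significant = p < p_threshold)
  })
  rows
}
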