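#' Tidy a cis-NAT analysis result
#'
#' One row per retained representative pair with its orientation, partner
#' class, network group type, and (when computed) expression and subgroup
#' summaries.
#'
#' @param x A `cisnat_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cisnat_result <- function(x, ...) {
  key2group <- x$groups |>
    select("group_id", "group_type", "pair_keys") |>
    tidyr::unnest_longer("pair_keys", values_to = "pair_id")
  out <- x$pairs |>
    mutate(pair_id = pair_key(.data$plus_id, .data$minus_id)) |>
    select("pair_id", "chrom", "plus_id", "minus_id", "overlap_length",
           "orientation", "partner_class") |>
    left_join(key2group, by = "pair_id")
  if (nrow(x$pair_expr)) {
    expressed_any <- x$pair_expr |>
      group_by(.data$pair_id) |>
      summarise(expressed_any = any(.data$expressed),
                expressed_all = all(.data$expressed), .groups = "drop")
    out <- out |> left_join(expressed_any, by = "pair_id")
  }
  if (nrow(x$subgroups)) {
    out <- out |>
      left_join(x$subgroups |> select("pair_id", "subgroup"), by = "pair_id")
  }
  out
}

#' One-row summary of a cis-NAT analysis result
#'
#' @inheritParams tidy.cisnat_result
#' @return A one-row tibble: candidate and retained pair counts, orientation
#'   shares, one-to-one and group counts, expressed-pair counts, DEG count.
#' @export
glance.cisnat_result <- function(x, ...) {
  gt <- x$groups$group_type
  tibble::tibble(
    n_candidates = x$candidates_n,
    n_pairs = nrow(x$pairs),
    pct_enclosed = 100 * mean(x$pairs$orientation == "enclosed"),
    pct_convergent = 100 * mean(x$pairs$orientation == "convergent"),
    pct_divergent = 100 * mean(x$pairs$orientation == "divergent"),
    n_one_to_one = sum(gt == "one-to-one"),
    n_groups = sum(gt != "one-to-one"),
    n_expressed_union = length(x$coexpression$sets$union),
    n_coexpressed = length(x$coexpression$sets$co_expressed),
    n_deg_transcripts = length(unique(x$degs$transcript_id[x$degs$is_deg])))
}

#' Scatter plot of sense/antisense ratio subgroups
#'
#' The classic control-versus-stress log-ratio scatter with pairs coloured by
#' subgroup: subgroup 1 on the diagonal, 2/3 in the off-diagonal quadrants,
#' 4/5 shifted along both axes, outliers grey.
#'
#' @param object A `cisnat_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cisnat_result <- function(object, ...) {
  sg <- object$subgroups
  if (nrow(sg) == 0L) abort("no subgroup classification in this result")
  ggplot2::ggplot(sg, ggplot2::aes(x = .data$log_ratio_control,
                                   y = .data$log_ratio_stress,
                                   colour = .data$subgroup)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("log2 sense/antisense FPKM ratio (%s)", object$control),
      y = sprintf("log2 sense/antisense FPKM ratio (%s)", object$subgroup_stress),
      colour = "subgroup") +
    ggplot2::theme_minimal()
}

#' Length distribution of small RNAs
#'
#' @param reads A read tibble.
#' @param by_condition Facet by condition when `TRUE`.
#' @return A ggplot bar chart of unique reads per length (18-34 nt).
#' @export
plot_length_distribution <- function(reads, by_condition = TRUE) {
  p <- ggplot2::ggplot(reads, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_bar() +
    ggplot2::scale_x_continuous(breaks = seq(18, 34, 2), limits = c(17.5, 34.5)) +
    ggplot2::labs(x = "read length (nt)", y = "unique reads") +
    ggplot2::theme_minimal()
  if (by_condition && "condition" %in% names(reads)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}

#' Strand-bias class composition of nat-siRNA profiles
#'
#' @param profiles A tibble from [sirna_profiles()].
#' @return A ggplot stacked bar chart of bias classes per condition.
#' @export
plot_strand_bias <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$condition,
                                         fill = .data$bias_class)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = NULL, y = "pairs", fill = "strand bias") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
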