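#' Run configuration
#'
#' Collects every threshold of the analysis with its conventional default:
#' minimum exonic overlap (> 25 nt, strict), strand-bias folds (5 primary, 2
#' secondary), density-enrichment fold (> 5), exclusivity unique-read bound
#' (> 5), DEG fold (2) and p cutoff (0.001), subgroup fold-change (2), FPKM
#' pseudocount (0.1), context flank width (1000 bp), and the nat-siRNA
#' evidence minimum for the expressed call (1 unique read).
#'
#' @param min_overlap Strict exonic-overlap threshold in nt.
#' @param bias_fold,bias_fold_secondary Strand-bias ratio thresholds.
#' @param enrich_fold Density-enrichment ratio threshold (strict).
#' @param min_exclusive_unique Strict unique-read bound for exclusivity.
#' @param deg_fold,deg_p DEG fold-change and significance cutoffs.
#' @param subgroup_fc Subgroup fold-change threshold.
#' @param eps FPKM pseudocount.
#' @param flank_bp Upstream/downstream context window.
#' @param min_sirna Minimum unique nat-siRNA reads for the expressed call.
#' @param excluded_biotypes Biotypes removed from candidate pairs.
#' @return A list of class `cisnat_run_config`.
#' @export
run_config <- function(min_overlap = 25, bias_fold = 5, bias_fold_secondary = 2,
                       enrich_fold = 5, min_exclusive_unique = 5, deg_fold = 2,
                       deg_p = 0.001, subgroup_fc = 2, eps = 0.1,
                       flank_bp = 1000, min_sirna = 1,
                       excluded_biotypes = default_excluded_biotypes()) {
  cfg <- as.list(environment())
  num <- vapply(cfg[setdiff(names(cfg), "excluded_biotypes")], is.numeric, logical(1))
  if (!all(num)) abort("run_config: thresholds must be numeric")
  class(cfg) <- "cisnat_run_config"
  cfg
}

#' Run the full cis-NAT analysis
#'
#' Executes detection, network grouping, small-RNA profiling and expression
#' analysis in order, logging record counts at every filter step. Expression
#' analysis (expressed calls, co-expression, subgroups, DEGs,
#' stress-preferential flags) is restricted to one-to-one pairs; network
#' groups are reported with their own expression evidence.
#'
#' @param gff3 Path to the transcript-model GFF3.
#' @param srna_beds Named character vector of BED6 paths, one per condition.
#' @param expression_tsv Path to the expression table.
#' @param domain_map_tsv Optional path to a transcript-to-domain-term map.
#' @param control Control condition label (must name one of `srna_beds`).
#' @param subgroup_stress Stress condition used for subgroup classification;
#'   defaults to the first non-control condition.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, [write_reports()] is called.
#' @return An object of class `cisnat_result`: a list with `pairs`,
#'   `candidates_n`, `groups`, `profiles`, `pair_expr`, `coexpression`,
#'   `subgroups`, `degs`, `stress_pref`, `enrichment`, `table_pairs`,
#'   `table_expression`, `log`, and the inputs' metadata.
#' @export
run_pipeline <- function(gff3, srna_beds, expression_tsv, domain_map_tsv = NULL,
                         control = "control", subgroup_stress = NULL,
                         config = run_config(), out_dir = NULL) {
  if (is.null(names(srna_beds)) || any(!nzchar(names(srna_beds)))) {
    abort("srna_beds must be a named vector (names are condition labels)")
  }
  if (!control %in% names(srna_beds)) {
    abort(paste0("control condition has no small-RNA library: ", control))
  }
  missing_bed <- names(srna_beds)[!file.exists(srna_beds)]
  if (length(missing_bed)) {
    abort(paste0("missing BED file for condition: ",
                 paste(missing_bed, collapse = ", ")))
  }
  log_rows <- list()
  log_step <- function(stage, n_in, n_out, params = "") {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      stage = stage, records_in = n_in, records_out = n_out, params = params)
  }

  ann <- read_gff3(gff3)
  spans <- transcript_spans(ann)
  log_step("read_annotation", NA_integer_, nrow(spans))

  candidates <- detect_candidate_pairs(ann, min_overlap = config$min_overlap,
                                       excluded_biotypes = config$excluded_biotypes)
  n_cand <- attr(candidates, "n_candidates")
  log_step("detect_pairs", n_cand, nrow(candidates),
           paste0("min_overlap>", config$min_overlap, "; biotype exclusion"))
  pairs <- select_representatives(candidates)
  log_step("select_representatives", nrow(candidates), nrow(pairs))

  groups <- build_groups(pairs)
  log_step("build_groups", nrow(pairs), nrow(groups))
  one_to_one_keys <- unlist(groups$pair_keys[groups$group_type == "one-to-one"])
  pairs11 <- pairs[pair_key(pairs$plus_id, pairs$minus_id) %in% one_to_one_keys, ]

  reads_raw <- purrr::imap_dfr(as.list(srna_beds), function(p, cond)
    read_smallrna_bed(p, condition = cond))
  organelles <- setdiff(unique(reads_raw$chrom), unique(ann$chrom))
  reads <- filter_small_rnas(reads_raw, exclusion_ann = ann,
                             organelle_chroms = organelles)
  log_step("filter_small_rnas", nrow(reads_raw), nrow(reads),
           "length 18-34; rRNA/tRNA/sn/snoRNA and organelle removed")

  profiles <- sirna_profiles(reads, pairs, ann, bias_fold = config$bias_fold,
                             enrich_fold = config$enrich_fold,
                             min_exclusive_unique = config$min_exclusive_unique)
  profiles$bias_class_secondary <- classify_strand_bias(
    profiles$plus_unique, profiles$minus_unique,
    fold = config$bias_fold_secondary)
  log_step("sirna_profiles", nrow(reads), nrow(profiles))

  expr <- read_expression_table(expression_tsv)
  pair_expr <- pair_expression(pairs11, expr, profiles, eps = config$eps,
                               min_sirna = config$min_sirna)
  log_step("pair_expression", nrow(expr), nrow(pair_expr))
  coex <- coexpression_sets(pair_expr)

  stresses <- setdiff(sort(unique(expr$condition), method = "radix"), control)
  if (is.null(subgroup_stress)) subgroup_stress <- stresses[1]
  subgroups <- subgroup_classification(pair_expr, control, subgroup_stress,
                                       fc_threshold = config$subgroup_fc,
                                       eps = config$eps)
  log_step("subgroup_classification", nrow(pair_expr), nrow(subgroups),
           paste0(control, " vs ", subgroup_stress))

  pair_tx <- tibble::tibble(
    transcript_id = c(pairs11$plus_id, pairs11$minus_id))
  degs <- purrr::map_dfr(stresses, function(s) {
    e_s <- expr |> filter(.data$condition == s)
    e_c <- expr |> filter(.data$condition == control)
    d <- pair_tx |>
      inner_join(e_s, by = "transcript_id") |>
      inner_join(e_c, by = "transcript_id", suffix = c("_stress", "_control"))
    res <- fisher_exact_deg(d$fragment_count_stress, d$library_size_stress,
                            d$fragment_count_control, d$library_size_control,
                            d$fpkm_stress, d$fpkm_control, eps = config$eps,
                            fold_threshold = config$deg_fold,
                            p_threshold = config$deg_p)
    bind_cols(tibble::tibble(transcript_id = d$transcript_id, stress = s,
                             fpkm_stress = d$fpkm_stress,
                             fpkm_control = d$fpkm_control), res)
  })
  log_step("fisher_exact_deg", nrow(pair_tx) * length(stresses),
           sum(degs$is_deg), paste0("|log2 FC| >= ", log2(config$deg_fold),
                                    ", p < ", config$deg_p))

  stress_pref <- stress_preferential(pair_expr, control)

  enrichment <- NULL
  if (!is.null(domain_map_tsv)) {
    dmap <- read_domain_map(domain_map_tsv)
    expressed_tx <- pairs11 |>
      filter(pair_key(.data$plus_id, .data$minus_id) %in% coex$sets$union)
    enrichment <- domain_enrichment(
      c(expressed_tx$plus_id, expressed_tx$minus_id),
      spans$transcript_id, dmap, p_threshold = config$deg_p)
  }

  result <- structure(list(
    ann = ann, spans = spans, pairs = pairs, candidates_n = n_cand,
    groups = groups, pairs_one_to_one = pairs11, profiles = profiles,
    reads_n = nrow(reads), pair_expr = pair_expr, coexpression = coex,
    subgroups = subgroups, degs = degs, stress_pref = stress_pref,
    enrichment = enrichment, control = control,
    subgroup_stress = subgroup_stress, config = config,
    table_pairs = NULL, table_expression = NULL, log = NULL),
    class = "cisnat_result")
  result$table_pairs <- summarize_pairs(pairs, spans)
  result$table_expression <- summarize_expression(pair_expr, profiles)
  result$log <- bind_rows(log_rows)
  if (!is.null(out_dir)) write_reports(result, out_dir)
  result
}

#' Per-chromosome pair summary
#'
#' One row per chromosome plus a closing `Total` row: transcript count, pair
#' count, the three orientation counts and the six partner-class counts.
#' Orientation and partner-class columns sum to the pair column in every row.
#'
#' @param pairs A representative pair tibble.
#' @param spans A transcript-span tibble from [transcript_spans()] (for the
#'   per-chromosome transcript totals); optional.
#' @return A tibble shaped like the classic per-chromosome cis-NAT summary.
#' @export
summarize_pairs <- function(pairs, spans = NULL) {
  chroms <- sort(unique(c(pairs$chrom, spans$chrom)), method = "radix")
  orient_lv <- c("enclosed", "convergent", "divergent")
  class_lv <- c("CDS-p vs ncRNA", "CDS-p vs CDS-n", "CDS-p vs CDS-p",
                "CDS-n vs ncRNA", "CDS-n vs CDS-n", "ncRNA vs ncRNA")
  per <- purrr::map_dfr(chroms, function(ch) {
    p <- pairs[pairs$chrom == ch, ]
    row <- tibble::tibble(
      chrom = ch,
      transcripts = if (is.null(spans)) NA_integer_ else
        sum(spans$chrom == ch),
      pairs = nrow(p))
    for (o in orient_lv) row[[o]] <- sum(p$orientation == o)
    for (cl in class_lv) row[[cl]] <- sum(p$partner_class == cl)
    row
  })
  total <- per |>
    summarise(across(-"chrom", \(x) sum(x))) |>
    mutate(chrom = "Total", .before = 1)
  bind_rows(per, total)
}

#' Orientation and partner-class percentage shares
#'
#' Recomputes, from a pair summary table (or any table with the same
#' columns), the percentage of pairs per orientation and per partner class,
#' rounded to one decimal as conventionally printed.
#'
#' @param tbl A summary tibble from [summarize_pairs()]; the `Total` row is
#'   used when present, otherwise columns are summed.
#' @return A tibble `category`, `count`, `percent`.
#' @export
summary_percentages <- function(tbl) {
  row <- if ("Total" %in% tbl$chrom) tbl[tbl$chrom == "Total", ] else
    tbl |> summarise(across(-any_of("chrom"), \(x) sum(x)))
  cats <- setdiff(names(row), c("chrom", "transcripts", "pairs"))
  tibble::tibble(category = cats,
                 count = as.integer(unlist(row[cats])),
                 percent = round(100 * unlist(row[cats]) / row$pairs[[1]], 1))
}

#' Per-condition expression summary
#'
#' One row per condition with expressed-pair, overlap-exclusive and
#' density-enriched counts, a `Co-` row (pairs meeting the column's criterion
#' in every condition) and a `Total` row (union across conditions).
#'
#' @param pair_expr A tibble from [pair_expression()].
#' @param profiles A tibble from [sirna_profiles()].
#' @return A summary tibble with columns `condition`, `expressed`,
#'   `exclusive`, `enriched`.
#' @export
summarize_expression <- function(pair_expr, profiles) {
  conds <- sort(unique(pair_expr$condition), method = "radix")
  prof <- profiles |>
    inner_join(pair_expr |> select("pair_id", "condition", "expressed"),
               by = c("pair_id", "condition"))
  flag <- function(cond) {
    pe <- pair_expr[pair_expr$condition == cond, ]
    pf <- prof[prof$condition == cond, ]
    list(expressed = pe$pair_id[pe$expressed],
         exclusive = pf$pair_id[pf$exclusive & pf$expressed],
         enriched = pf$pair_id[pf$enriched & pf$expressed])
  }
  sets <- lapply(conds, flag)
  names(sets) <- conds
  per <- purrr::map_dfr(conds, function(cond) {
    tibble::tibble(condition = cond,
                   expressed = length(sets[[cond]]$expressed),
                   exclusive = length(sets[[cond]]$exclusive),
                   enriched = length(sets[[cond]]$enriched))
  })
  inter <- tibble::tibble(
    condition = "Co-",
    expressed = length(Reduce(intersect, lapply(sets, `[[`, "expressed"))),
    exclusive = length(Reduce(intersect, lapply(sets, `[[`, "exclusive"))),
    enriched = length(Reduce(intersect, lapply(sets, `[[`, "enriched"))))
  total <- tibble::tibble(
    condition = "Total",
    expressed = length(Reduce(union, lapply(sets, `[[`, "expressed"))),
    exclusive = length(Reduce(union, lapply(sets, `[[`, "exclusive"))),
    enriched = length(Reduce(union, lapply(sets, `[[`, "enriched"))))
  bind_rows(per, inter, total)
}

#' Write all report tables
#'
#' Emits deterministic TSV reports into `out_dir`: the pair table (ids,
#' lengths, 1-based overlap locations, orientation, partner class), the group
#' table, per-condition nat-siRNA profiles, per-condition pair expression,
#' DEG calls, stress-preferential flags, the two summary tables, the run log,
#' and domain enrichment when computed.
#'
#' @param result A `cisnat_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spans <- result$spans
  len_of <- stats::setNames(spans$exonic_length, spans$transcript_id)
  pair_tbl <- result$pairs |>
    mutate(pair_id = pair_key(.data$plus_id, .data$minus_id),
           plus_length = unname(len_of[.data$plus_id]),
           minus_length = unname(len_of[.data$minus_id]),
           overlap_locations = purrr::map2_chr(
             .data$chrom, .data$overlap_intervals,
             \(ch, iv) format_locations(ch, iv$start, iv$end))) |>
    select("pair_id", "chrom", "plus_id", "plus_length", "minus_id",
           "minus_length", "overlap_length", "overlap_locations",
           "orientation", "partner_class")
  group_tbl <- result$groups |>
    mutate(transcripts = purrr::map_chr(.data$transcripts, paste, collapse = ","),
           pairs = purrr::map_chr(.data$pair_keys, paste, collapse = ",")) |>
    select("group_id", "group_type", "subtype", "n_plus", "n_minus",
           "n_transcripts", "n_pairs", "transcripts", "pairs")
  paths <- c(
    pairs = file.path(out_dir, "pairs.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    profiles = file.path(out_dir, "sirna_profiles.tsv"),
    expression = file.path(out_dir, "pair_expression.tsv"),
    subgroups = file.path(out_dir, "subgroups.tsv"),
    degs = file.path(out_dir, "degs.tsv"),
    stress_pref = file.path(out_dir, "stress_preferential.tsv"),
    table_pairs = file.path(out_dir, "summary_pairs.tsv"),
    table_expression = file.path(out_dir, "summary_expression.tsv"),
    log = file.path(out_dir, "run_log.tsv"))
  readr::write_tsv(pair_tbl, paths[["pairs"]], progress = FALSE)
  readr::write_tsv(group_tbl, paths[["groups"]], progress = FALSE)
  readr::write_tsv(result$profiles, paths[["profiles"]], progress = FALSE)
  readr::write_tsv(result$pair_expr, paths[["expression"]], progress = FALSE)
  readr::write_tsv(result$subgroups, paths[["subgroups"]], progress = FALSE)
  readr::write_tsv(result$degs, paths[["degs"]], progress = FALSE)
  readr::write_tsv(result$stress_pref, paths[["stress_pref"]], progress = FALSE)
  readr::write_tsv(result$table_pairs, paths[["table_pairs"]], progress = FALSE)
  readr::write_tsv(result$table_expression, paths[["table_expression"]],
                   progress = FALSE)
  readr::write_tsv(result$log, paths[["log"]], progress = FALSE)
  if (!is.null(result$enrichment)) {
    paths[["enrichment"]] <- file.path(out_dir, "domain_enrichment.tsv")
    readr::write_tsv(result$enrichment, paths[["enrichment"]], progress = FALSE)
  }
  invisible(paths)
}

#' @export
print.cisnat_result <- function(x, ...) {
  cat("cis-NAT analysis result\n")
  cat(sprintf("  candidate pairs:       %d\n", x$candidates_n))
  cat(sprintf("  retained pairs:        %d\n", nrow(x$pairs)))
  cat(sprintf("  one-to-one pairs:      %d\n", nrow(x$pairs_one_to_one)))
  cat(sprintf("  many-to-many groups:   %d\n",
              sum(x$groups$group_type != "one-to-one")))
  cat(sprintf("  expressed pairs (any): %d\n",
              length(x$coexpression$sets$union)))
  invisible(x)
}
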