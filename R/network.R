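#' Build cis-NAT networks from representative pairs
#'
#' Treats transcripts as vertices and pairs as edges and extracts connected
#' components. Components with exactly two transcripts are one-to-one pairs;
#' larger components are many-to-many groups, typed by their strand-wise
#' member counts, with an orientation-combination subtype for one-to-two
#' groups.
#'
#' @param pairs A representative pair tibble from [select_representatives()]
#'   (or [detect_candidate_pairs()]).
#' @return A tibble with one row per component, sorted by smallest member id:
#'   `group_id`, `n_plus`, `n_minus`, `n_transcripts`, `n_pairs`,
#'   `group_type` (e.g. `"one-to-one"`, `"one-to-two"`, `"two-to-two"`),
#'   `subtype` (orientation combination, one-to-two groups only, else `NA`),
#'   `transcripts` and `pair_keys` (list columns).
#' @export
build_groups <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(group_id = character(), n_plus = integer(),
                          n_minus = integer(), n_transcripts = integer(),
                          n_pairs = integer(), group_type = character(),
                          subtype = character(), transcripts = list(),
                          pair_keys = list()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$plus_id, to = pairs$minus_id,
               stringsAsFactors = FALSE), directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  plus_set <- unique(pairs$plus_id)
  keys <- pair_key(pairs$plus_id, pairs$minus_id)
  orientations <- stats::setNames(pairs$orientation, keys)
  pair_comp <- membership[pairs$plus_id]

  rows <- lapply(seq_len(comp$no), function(ci) {
    members <- sort(names(membership)[membership == ci], method = "radix")
    n_plus <- sum(members %in% plus_set)
    n_minus <- length(members) - n_plus
    ks <- sort(keys[pair_comp == ci], method = "radix")
    a <- min(n_plus, n_minus)
    b <- max(n_plus, n_minus)
    gtype <- paste0(spell_count(a), "-to-", spell_count(b))
    subtype <- if (gtype == "one-to-two" && length(ks) == 2L) {
      subtype_one_to_two(unname(orientations[ks]))
    } else NA_character_
    tibble::tibble(first_member = members[1], n_plus = n_plus,
                   n_minus = n_minus, n_transcripts = length(members),
                   n_pairs = length(ks), group_type = gtype, subtype = subtype,
                   transcripts = list(members), pair_keys = list(ks))
  })
  out <- bind_rows(rows)
  out <- out[order_c(out$first_member), ]
  out$group_id <- sprintf("G%04d", seq_len(nrow(out)))
  out |>
    select("group_id", "n_plus", "n_minus", "n_transcripts", "n_pairs",
           "group_type", "subtype", "transcripts", "pair_keys")
}

#' Type a group by strand-wise member counts
#'
#' @param n_plus,n_minus Integer vectors of plus- and minus-strand transcript
#'   counts per group.
#' @return Labels `min-to-max` with counts up to four spelled out
#'   (`"one-to-two"`, ...) and numeric beyond (`"5-to-7"`).
#' @export
classify_group <- function(n_plus, n_minus) {
  a <- pmin(n_plus, n_minus)
  b <- pmax(n_plus, n_minus)
  paste0(spell_count(a), "-to-", spell_count(b))
}

#' Orientation-combination subtype of a one-to-two group
#'
#' @param orientations Character vector of exactly two pair orientations.
#' @return An unordered label such as `"enclosed+convergent"` (components in
#'   the fixed order enclosed, convergent, divergent).
#' @export
subtype_one_to_two <- function(orientations) {
  if (length(orientations) != 2L) {
    abort("subtype_one_to_two: exactly two pair orientations required (one-to-two groups only)")
  }
  lv <- c("enclosed", "convergent", "divergent")
  if (!all(orientations %in% lv)) abort("unknown orientation label")
  paste(lv[sort(match(orientations, lv))], collapse = "+")
}
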