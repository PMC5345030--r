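#' Restraint-count selection rule
#'
#' How many top-ranked predicted contacts to keep for a molecule of length
#' `L`. The default rule `N = 5 + floor(L / 4)` sits between the 1% and 2%
#' false-prediction error-rate curves and below the `L / 3` line traced by
#' the number of base pairs a thermodynamic secondary-structure predictor
#' returns.
#'
#' @param L molecule length in nucleotides (`L >= 1`).
#' @param rule a [cutoff_rule()].
#' @return Integer count of contacts to retain.
#' @examples
#' cutoff_count(100) # 30
#' cutoff_count(94) # 28
#' @export
cutoff_count <- function(L, rule = cutoff_rule()) {
  stopifnot(all(L >= 1))
  as.integer(rule$intercept + L %/% rule$divisor)
}

#' @rdname cutoff_count
#' @param intercept additive constant of the rule (contacts).
#' @param divisor length divisor of the rule.
#' @param comparison_line_divisor divisor of the comparison line (`L / 3`)
#'   used in diagnostics and plots.
#' @export
cutoff_rule <- function(intercept = 5, divisor = 4,
                        comparison_line_divisor = 3) {
  stopifnot(intercept >= 0, divisor > 0, comparison_line_divisor > 0)
  structure(
    list(
      intercept = intercept, divisor = divisor,
      comparison_line_divisor = comparison_line_divisor
    ),
    class = "cutoff_rule"
  )
}

#' Keep the top-ranked predicted contacts
#'
#' Truncates a ranked contact table to the first [cutoff_count()] entries.
#' If fewer predictions are available than the cutoff asks for, all are
#' retained with a warning.
#'
#' @param contacts a ranked contact tibble (see [rank_contacts()]).
#' @param L molecule length.
#' @param rule a [cutoff_rule()].
#' @return The truncated contact tibble.
#' @export
select_top <- function(contacts, L, rule = cutoff_rule()) {
  n <- cutoff_count(L, rule)
  if (nrow(contacts) < n) {
    rlang::warn(sprintf(
      "Only %d prediction(s) available; cutoff asked for %d. Keeping all.",
      nrow(contacts), n
    ))
    return(contacts)
  }
  utils::head(contacts, n)
}

#' Classify predicted contacts against the native structure
#'
#' Each predicted contact is labelled with one of four exhaustive, mutually
#' exclusive categories, in order of precedence:
#' \describe{
#'   \item{`shared_local`}{the pair is among the base pairs predicted by the
#'     thermodynamic secondary-structure method (e.g. RNAfold);}
#'   \item{`extra_local`}{otherwise, the pair is among the nested observed
#'     base pairs;}
#'   \item{`non_local`}{otherwise, the native phosphate-phosphate distance
#'     is at most `false_threshold` (default 21 Angstroms) -- a true
#'     tertiary contact;}
#'   \item{`false`}{the native distance exceeds the threshold.}
#' }
#' A distance of exactly 21 Angstroms classifies as `non_local`; only
#' strictly larger distances are false.
#'
#' @param contacts a ranked contact tibble.
#' @param native the native [ptrace()].
#' @param observed the observed secondary structure (anything accepted by
#'   [as_rna_ss()]); only its nested subset defines `extra_local`.
#' @param rnafold_pairs base pairs from the secondary-structure predictor
#'   (a base-pair tibble, dot-bracket string, or `NULL` for none).
#' @param false_threshold native-distance boundary between `non_local` and
#'   `false`, Angstroms.
#' @return `contacts` with added columns `native_distance` (Angstroms) and
#'   `category` (factor with the four levels above).
#' @export
classify_contacts <- function(contacts, native, observed,
                              rnafold_pairs = NULL, false_threshold = 21) {
  contacts <- tibble::as_tibble(contacts)
  L <- pt_length(native)
  if (nrow(contacts) > 0 && (any(contacts$i < 1) || any(contacts$j > L))) {
    rlang::abort("Contact index out of range of the native trace.")
  }
  observed <- as_rna_ss(observed)
  rnafold_pairs <- if (is.null(rnafold_pairs)) {
    tibble::tibble(i = integer(), j = integer())
  } else if (is.character(rnafold_pairs)) {
    parse_dotbracket(rnafold_pairs)
  } else {
    tibble::as_tibble(rnafold_pairs)
  }
  levels <- c("shared_local", "extra_local", "non_local", "false")
  if (nrow(contacts) == 0) {
    contacts$native_distance <- double()
    contacts$category <- factor(character(), levels = levels)
    return(contacts)
  }
  key <- pair_key(contacts$i, contacts$j)
  in_fold <- key %in% pair_key(rnafold_pairs$i, rnafold_pairs$j)
  in_obs <- key %in% pair_key(observed$nested$i, observed$nested$j)
  d <- pair_distance(native, contacts$i, contacts$j)
  cat <- dplyr::case_when(
    in_fold ~ "shared_local",
    in_obs ~ "extra_local",
    d <= false_threshold ~ "non_local",
    TRUE ~ "false"
  )
  contacts$native_distance <- d
  contacts$category <- factor(cat, levels = levels)
  contacts
}

#' Error-rate cutoff over a ranked, categorised contact list
#'
#' The largest prefix length `k` such that the fraction of false contacts
#' among the top `k` does not exceed `max_error_fraction`; 0 if even the
#' first entry violates it.
#'
#' @param categories a character/factor vector of categories in rank order,
#'   or a classified contact tibble with a `category` column.
#' @param max_error_fraction allowed fraction of false contacts, in `[0, 1]`.
#' @return Integer prefix length.
#' @export
error_rate_cutoff <- function(categories, max_error_fraction) {
  if (is.data.frame(categories)) categories <- categories$category
  if (max_error_fraction < 0 || max_error_fraction > 1) {
    rlang::abort("`max_error_fraction` must be in [0, 1].")
  }
  n <- length(categories)
  if (n == 0) {
    return(0L)
  }
  frac <- cumsum(as.character(categories) == "false") / seq_len(n)
  ok <- which(frac <= max_error_fraction)
  if (length(ok) == 0) 0L else max(ok)
}

#' Incremental prefix restraint sets
#'
#' The denaturation protocol introduces restraints in ranked order of their
#' predicted confidence, strongest first, and re-runs the simulation for
#' each prefix. This returns the subsets of sizes `0, 1, ..., N` (each a
#' prefix of the ranked order, so subset k is contained in subset k+1).
#'
#' @param contacts a ranked contact tibble.
#' @return A list of `N + 1` tibbles.
#' @export
incremental_sets <- function(contacts) {
  contacts <- tibble::as_tibble(contacts)
  lapply(0:nrow(contacts), function(k) utils::head(contacts, k))
}
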