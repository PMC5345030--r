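#' Denaturation profile under incremental restraints
#'
#' The package's central experiment: starting from the native structure,
#' run the perturbing simulation with increasingly larger prefixes of the
#' ranked restraint set (sizes 0, 1, ..., N, strongest predictions first)
#' and record, for each prefix size, the mean superposition RMSD of the
#' replicate ensemble from the native structure. A sharp drop at the rank
#' where a non-local contact enters marks the point at which the molecule's
#' conformational freedom becomes restricted. The local-window term is
#' always anchored to the native starting structure; only the restraint set
#' under test varies with k.
#'
#' @param trace the native [ptrace()].
#' @param ss the secondary structure (defines the rigid SSEs).
#' @param contacts a ranked contact tibble; if it carries a `category`
#'   column (see [classify_contacts()]) the per-rank categories are kept in
#'   the profile for plotting.
#' @param config a [sim_config()]; `config$replicates` models are built per
#'   prefix size. Replicate seeds are derived from `config$seed`
#'   independently per (prefix size, replicate).
#' @param max_k largest prefix size (defaults to all contacts).
#' @return A `denat_profile`: tibble with columns `k`, `rmsd_mean`,
#'   `drmsd_mean`, `drmsd_max` and `category` (category of the k-th
#'   restraint, `NA` at k = 0).
#' @export
denaturation_profile <- function(trace, ss, contacts,
                                 config = sim_config(),
                                 max_k = nrow(contacts)) {
  contacts <- tibble::as_tibble(contacts)
  prefixes <- incremental_sets(utils::head(contacts, max_k))
  rows <- purrr::imap(prefixes, function(pre, idx) {
    k <- idx - 1L
    res <- simulate_trace(
      trace,
      ss = ss, restraints = pre, config = config,
      seed_offset = k
    )
    ms <- metric_summary(res$models, trace)
    tibble::tibble(
      k = k,
      rmsd_mean = ms$rmsd_mean,
      drmsd_mean = ms$drmsd_mean,
      drmsd_max = ms$drmsd_max,
      category = if (k == 0 || !"category" %in% names(contacts)) {
        NA_character_
      } else {
        as.character(contacts$category[k])
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "denat_profile")
}

#' Control profiles from local-only restraint sets
#'
#' Runs the same incremental procedure with the observed base pairs and
#' with the thermodynamically predicted base pairs -- restraint sets that
#' contain no non-local pairs and therefore should show no RMSD drop.
#'
#' @inheritParams denaturation_profile
#' @param observed_pairs observed base pairs (tibble or dot-bracket).
#' @param rnafold_pairs predicted base pairs (tibble or dot-bracket).
#' @return A named list of two `denat_profile` objects
#'   (`observed`, `rnafold`).
#' @export
control_profiles <- function(trace, ss, observed_pairs, rnafold_pairs,
                             config = sim_config()) {
  as_ranked <- function(pairs) {
    if (is.character(pairs)) pairs <- parse_dotbracket(pairs)
    pairs <- dplyr::arrange(tibble::as_tibble(pairs), .data$i)
    tibble::tibble(
      i = pairs$i, j = pairs$j,
      score = rev(seq_len(nrow(pairs))), rank = seq_len(nrow(pairs))
    )
  }
  list(
    observed = denaturation_profile(trace, ss, as_ranked(observed_pairs),
      config = config
    ),
    rnafold = denaturation_profile(trace, ss, as_ranked(rnafold_pairs),
      config = config
    )
  )
}

#' Perturbation-level sweep
#'
#' Repeats the replicate simulation at a series of random-displacement
#' levels (translation in Angstroms; the rotation level in radians is
#' numerically coupled) for each named restraint set, summarising each
#' level x set combination. Used to choose a working level that separates
#' the predicted-contact set from the local-only sets; 0.08 is the default
#' working level.
#'
#' @inheritParams denaturation_profile
#' @param restraint_sets a named list of restraint pair tibbles (may
#'   include an empty tibble for the unrestrained reference).
#' @param levels perturbation levels to sweep.
#' @return A `perturb_sweep` tibble with columns `level`, `set`,
#'   `rmsd_mean`, `drmsd_mean`, `drmsd_max`.
#' @export
perturbation_sweep <- function(trace, ss, restraint_sets,
                               config = sim_config(),
                               levels = c(0.02, 0.04, 0.06, 0.08, 0.10)) {
  stopifnot(length(names(restraint_sets)) == length(restraint_sets))
  rows <- list()
  for (lv_idx in seq_along(levels)) {
    lv <- levels[lv_idx]
    cfg <- config
    cfg$perturb_translation <- lv
    cfg$perturb_rotation <- lv
    for (set_name in names(restraint_sets)) {
      res <- simulate_trace(
        trace,
        ss = ss, restraints = restraint_sets[[set_name]],
        config = cfg, seed_offset = 1000L + lv_idx
      )
      ms <- metric_summary(res$models, trace)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level = lv, set = set_name,
        rmsd_mean = ms$rmsd_mean, drmsd_mean = ms$drmsd_mean,
        drmsd_max = ms$drmsd_max
      )
    }
  }
  tibble::new_tibble(dplyr::bind_rows(rows), class = "perturb_sweep")
}

#' Restrained folding from a circular start
#'
#' Runs `n_runs` independent simulations starting from the extended
#' circular conformation ([make_circle_start()]), with the base pairs of
#' the secondary structure plus any extra restraints all imposed as
#' one-sided 17 Angstrom pair restraints, and reports the mean RMSD of the
#' ten models closest to the native structure (best-10; fewer if fewer
#' runs). The local-window term is disabled (its reference would be the
#' circle); SSE templates, bonds and repulsion still apply. The native
#' structure is used for scoring only.
#'
#' @param native the native [ptrace()] (scoring reference).
#' @param ss secondary structure whose pairs are imposed as restraints and
#'   define the SSEs.
#' @param restraints extra (e.g. predicted non-local) restraint pairs, or
#'   `NULL`.
#' @param config a [sim_config()].
#' @param n_runs number of independent folding runs (one model each).
#' @param restraint_source label recorded on the result (`"observed"` for
#'   base-pairs-only runs, `"predicted"` when extra contacts are imposed).
#' @return A `fold_result`: list with `n_models`, `best10_mean_rmsd`,
#'   `rmsd` (all runs, sorted), `models` and `restraint_source`.
#' @export
fold_trace <- function(native, ss, restraints = NULL,
                       config = sim_config(), n_runs = 20,
                       restraint_source = if (is.null(restraints)) "observed" else "predicted") {
  ss <- as_rna_ss(ss)
  all_restraints <- dplyr::bind_rows(
    ss$pairs[c("i", "j")],
    if (!is.null(restraints)) tibble::as_tibble(restraints)[c("i", "j")]
  ) |> dplyr::distinct()
  cfg <- config
  cfg$replicates <- as.integer(n_runs)
  start <- make_circle_start(pt_length(native), bond = config$bond_ideal)
  start$chain <- native$chain
  start$resno <- native$resno
  res <- simulate_trace(
    native,
    ss = ss, restraints = all_restraints, config = cfg,
    start = start, use_local_window = FALSE, seed_offset = 5000L
  )
  rmsd <- sort(vapply(res$models, superpose_rmsd, numeric(1), b = native))
  nbest <- min(10L, length(rmsd))
  structure(
    list(
      n_models = length(rmsd),
      best10_mean_rmsd = mean(rmsd[seq_len(nbest)]),
      rmsd = rmsd, models = res$models,
      restraint_source = restraint_source
    ),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "<fold_result (%s restraints): %d model(s), best-10 mean RMSD %.2f A>\n",
    x$restraint_source, x$n_models, x$best10_mean_rmsd
  ))
  invisible(x)
}

#' @export
#' @method glance fold_result
glance.fold_result <- function(x, ...) {
  tibble::tibble(
    restraint_source = x$restraint_source,
    n_models = x$n_models,
    best10_mean_rmsd = x$best10_mean_rmsd
  )
}

#' @export
#' @method tidy fold_result
tidy.fold_result <- function(x, ...) {
  tibble::tibble(run = seq_along(x$rmsd), rmsd = x$rmsd)
}
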