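#' Engine configuration
#'
#' All numeric rules of the coarse-grained engine in one place. Per cycle,
#' secondary-structure elements are rigidly displaced and rotated by a small
#' random factor, then geometry is refined by fixed per-cycle steps:
#' virtual bonds towards 6 Angstroms, intra-SSE geometry towards the ideal
#' helix, local within-window distances towards their starting values
#' (gated at 18 Angstroms so large conformational changes can still be
#' accepted), restrained pairs one-sidedly towards a 17 Angstrom target
#' (only pairs further apart than the target are contracted), and any
#' non-bonded contact under 10 Angstroms repelled.
#'
#' @param cycles simulation cycles per run.
#' @param perturb_translation random SSE displacement magnitude per cycle,
#'   Angstroms (swept 0 to 0.1; 0.08 is the working default).
#' @param perturb_rotation random SSE rotation angle per cycle, radians
#'   (numerically coupled to the translation level by default).
#' @param bond_ideal ideal phosphate/phosphate virtual bond length, Angstroms.
#' @param repel_below repulsion activation threshold for non-bonded
#'   contacts, Angstroms.
#' @param local_window number of consecutive phosphates whose internal
#'   distances are restored towards their starting values.
#' @param local_gate the local restoration step only acts while the current
#'   distance is below this gate, Angstroms.
#' @param restraint_target target separation of restrained pairs, Angstroms.
#' @param step fixed per-cycle refinement shift applied to a pair's
#'   separation, Angstroms (split equally between the two atoms).
#' @param replicates models per restraint/parameter combination.
#' @param seed master RNG seed; replicate and prefix seeds are derived from
#'   it deterministically.
#' @param diagnostics collect per-cycle mean bond length and restraint
#'   satisfaction counts.
#' @return A `sim_config` object (a named list).
#' @export
sim_config <- function(cycles = 1000, perturb_translation = 0.08,
                       perturb_rotation = perturb_translation,
                       bond_ideal = 6, repel_below = 10,
                       local_window = 10, local_gate = 18,
                       restraint_target = 17, step = 0.5,
                       replicates = 10, seed = 1, diagnostics = FALSE) {
  stopifnot(
    cycles >= 1, perturb_translation >= 0, perturb_rotation >= 0,
    bond_ideal > 0, repel_below > 0, local_window >= 2, local_gate > 0,
    restraint_target > 0, step > 0, replicates >= 1
  )
  structure(
    list(
      cycles = as.integer(cycles),
      perturb_translation = perturb_translation,
      perturb_rotation = perturb_rotation,
      bond_ideal = bond_ideal, repel_below = repel_below,
      local_window = as.integer(local_window), local_gate = local_gate,
      restraint_target = restraint_target, step = step,
      replicates = as.integer(replicates), seed = as.integer(seed),
      diagnostics = isTRUE(diagnostics)
    ),
    class = "sim_config"
  )
}

seq2_safe <- function(from, to) if (to < from) integer() else seq(from, to)

# Deterministic seed mixing, kept below 2^31 so set.seed() accepts it.
derive_seed <- function(master, a, b = 0L) {
  s <- (as.double(master) %% 2147483647) * 69069 + a * 1013904223 + b * 69069
  as.integer(s %% 2147483629)
}

# Shared pairwise-shift kernel. Moves each (ii, jj) pair's separation by at
# most `step` according to `mode`:
#   "toward":   towards `target` (capped at the remaining deficit);
#   "gated":    as "toward", but only while the current distance is < gate;
#   "contract": one-sided, only pairs with separation > target, capped;
#   "repel":    pairs closer than `target` pushed apart, capped at the
#               distance still missing to `target`.
# Shifts are split equally between the two atoms along their axis and
# averaged per atom within the step (order-free; averaging rather than
# summing keeps chains of shared atoms numerically stable). Coincident
# atoms separate along a fixed fallback axis.
step_core <- function(X, ii, jj, target, step, mode, gate = NULL) {
  if (length(ii) == 0) {
    return(X)
  }
  dv <- X[jj, , drop = FALSE] - X[ii, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  zero <- d < 1e-9
  if (any(zero)) {
    dv[zero, ] <- matrix(c(1, 0, 0), sum(zero), 3, byrow = TRUE)
    d[zero] <- 1e-9
  }
  delta <- target - d
  m <- switch(mode,
    toward = sign(delta) * pmin(step, abs(delta)),
    gated = ifelse(d < gate, sign(delta) * pmin(step, abs(delta)), 0),
    contract = ifelse(d > target, -pmin(step, d - target), 0),
    repel = ifelse(d < target, pmin(step, target - d), 0)
  )
  act <- which(m != 0)
  if (length(act) == 0) {
    return(X)
  }
  half <- m[act] / (2 * d[act])
  dj <- dv[act, , drop = FALSE] * half
  grp <- c(ii[act], jj[act])
  acc <- rowsum(rbind(-dj, dj), grp)
  idx <- as.integer(rownames(acc))
  # average (not sum) the corrections arriving at one atom: an isolated
  # pair still moves by the full amount, while summing full corrections
  # along chains of shared atoms is an unstable over-relaxation
  n_contrib <- as.vector(table(factor(grp, levels = idx)))
  X[idx, ] <- X[idx, , drop = FALSE] + acc / n_contrib
  X
}

# Rodrigues rotation matrix: angle about unit axis.
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(
    c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
    3, 3,
    byrow = TRUE
  )
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Each SSE is rigidly displaced by `trans_level` Angstroms in a random
# direction and rotated by `rot_level` radians about a random axis through
# its centroid; the level sets the magnitude, the direction is random.
perturb_sses_core <- function(X, sse_members, trans_level, rot_level) {
  for (mem in sse_members) {
    v <- stats::rnorm(3)
    trans <- v / sqrt(sum(v^2)) * trans_level
    axis <- stats::rnorm(3)
    ctr <- colMeans(X[mem, , drop = FALSE])
    R <- rotation_about(axis, rot_level)
    X[mem, ] <- sweep(X[mem, , drop = FALSE], 2, ctr) %*% t(R) +
      rep(ctr + trans, each = length(mem))
  }
  X
}

#' Individual engine steps
#'
#' The engine's per-cycle operations, exposed individually on phosphate
#' traces so that each geometric rule can be exercised (and its threshold
#' measured) in isolation. All shifts are capped at `config$step` per cycle
#' and split equally between the two atoms of a pair.
#'
#' * `step_bonded()` refines consecutive same-chain phosphate/phosphate
#'   virtual bonds towards `bond_ideal` (6 Angstroms).
#' * `step_pair_restraints()` contracts restrained pairs towards
#'   `restraint_target` (17 Angstroms), one-sidedly: pairs at or below the
#'   target are never touched, so restraints can only be exceeded, never
#'   undershot, in final models.
#' * `step_repulsion()` pushes every non-excluded pair closer than
#'   `repel_below` (10 Angstroms) apart by the step (capped at the
#'   remaining deficit). Bonded neighbours, intra-SSE pairs and restrained
#'   pairs are excluded.
#' * `step_local_window()` restores distances between phosphates within
#'   `local_window` consecutive residues towards their reference (native)
#'   values, but only while the current distance is under `local_gate`
#'   (18 Angstroms), so large conformational changes are still accepted.
#' * `step_sse_ideal()` refines intra-SSE pairwise distances towards the
#'   ideal helical template stored on each SSE.
#' * `perturb_sses()` applies a rigid displacement of magnitude
#'   `perturb_translation` in a random direction and a rotation of
#'   `perturb_rotation` radians about a random axis through the SSE
#'   centroid to each SSE; loop residues are untouched. Uses the current
#'   RNG state.
#'
#' @param trace a [ptrace()].
#' @param config a [sim_config()].
#' @param restraints a pair tibble with columns `i`, `j`.
#' @param sses an `sse_set` from [detect_sses()].
#' @param reference a [ptrace()] supplying native local distances, or a
#'   tibble with columns `i`, `j`, `dist` as returned by
#'   [local_native_distances()].
#' @return The shifted [ptrace()].
#' @name engine-steps
NULL

#' @rdname engine-steps
#' @export
step_bonded <- function(trace, config = sim_config()) {
  b <- bond_pairs(trace)
  X <- step_core(
    pt_coords(trace), b$i, b$j, config$bond_ideal, config$step, "toward"
  )
  pt_set_coords(trace, X)
}

#' @rdname engine-steps
#' @export
step_pair_restraints <- function(trace, restraints, config = sim_config()) {
  X <- step_core(
    pt_coords(trace), restraints$i, restraints$j,
    config$restraint_target, config$step, "contract"
  )
  pt_set_coords(trace, X)
}

#' @rdname engine-steps
#' @param exclude extra pairs (tibble with `i`, `j`) excluded from
#'   repulsion, in addition to bonded neighbours, intra-SSE pairs and
#'   restrained pairs.
#' @export
step_repulsion <- function(trace, config = sim_config(), sses = NULL,
                           restraints = NULL, exclude = NULL) {
  cand <- repulsion_candidates(trace, sses, restraints, exclude)
  X <- step_core(
    pt_coords(trace), cand$i, cand$j, config$repel_below, config$step, "repel"
  )
  pt_set_coords(trace, X)
}

#' @rdname engine-steps
#' @export
step_local_window <- function(trace, reference = trace,
                              config = sim_config()) {
  loc <- if (is.data.frame(reference)) {
    if (inherits(reference, "ptrace")) {
      local_native_distances(reference, config)
    } else {
      reference
    }
  } else {
    rlang::abort("`reference` must be a ptrace or a (i, j, dist) tibble.")
  }
  X <- pt_coords(trace)
  if (nrow(loc) > 0) {
    dv <- X[loc$j, , drop = FALSE] - X[loc$i, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    act <- which(d < config$local_gate)
    X <- step_core(
      X, loc$i[act], loc$j[act], loc$dist[act], config$step, "toward"
    )
  }
  pt_set_coords(trace, X)
}

#' @rdname engine-steps
#' @export
step_sse_ideal <- function(trace, sses, config = sim_config()) {
  tmpl <- sse_template_pairs(sses)
  X <- step_core(
    pt_coords(trace), tmpl$i, tmpl$j, tmpl$dist, config$step, "toward"
  )
  pt_set_coords(trace, X)
}

#' @rdname engine-steps
#' @export
perturb_sses <- function(trace, sses, config = sim_config()) {
  if (length(sses) == 0 ||
    (config$perturb_translation == 0 && config$perturb_rotation == 0)) {
    return(trace)
  }
  X <- perturb_sses_core(
    pt_coords(trace), lapply(sses, `[[`, "members"),
    config$perturb_translation, config$perturb_rotation
  )
  pt_set_coords(trace, X)
}

#' Reference distances for the local-window restoration step
#'
#' All same-chain residue pairs with sequence separation 2 to
#' `local_window - 1` (adjacent pairs are handled by the bond term), with
#' their distances in `trace`.
#'
#' @param trace the reference [ptrace()] (the simulation's starting
#'   structure).
#' @param config a [sim_config()].
#' @return A tibble with columns `i`, `j`, `dist`.
#' @export
local_native_distances <- function(trace, config = sim_config()) {
  L <- pt_length(trace)
  w <- config$local_window - 1L
  ii <- integer()
  jj <- integer()
  for (s in seq2_safe(2L, min(w, L - 1L))) {
    k <- seq_len(L - s)
    ok <- trace$chain[k] == trace$chain[k + s]
    ii <- c(ii, k[ok])
    jj <- c(jj, k[ok] + s)
  }
  tibble::tibble(i = ii, j = jj, dist = pair_distance(trace, ii, jj))
}

# Flatten the intra-SSE ideal templates into one (i, j, dist) pair table.
sse_template_pairs <- function(sses) {
  if (is.null(sses) || length(sses) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), dist = double()))
  }
  purrr::map_dfr(sses, function(s) {
    n <- length(s$members)
    idx <- which(upper.tri(s$template), arr.ind = TRUE)
    tibble::tibble(
      i = s$members[idx[, 1]], j = s$members[idx[, 2]],
      dist = s$template[idx]
    )
  })
}

# Non-bonded candidate pairs for the repulsion term: sequence separation
# >= 2, not within one SSE, not restrained, not explicitly excluded.
repulsion_candidates <- function(trace, sses = NULL, restraints = NULL,
                                 exclude = NULL) {
  L <- pt_length(trace)
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  ii <- idx[, 1]
  jj <- idx[, 2]
  keep <- (jj - ii) >= 2L
  drop_key <- character()
  if (!is.null(sses) && length(sses) > 0) {
    for (s in sses) {
      mem <- s$members
      grid <- expand.grid(a = mem, b = mem)
      grid <- grid[grid$a < grid$b, ]
      drop_key <- c(drop_key, pair_key(grid$a, grid$b))
    }
  }
  if (!is.null(restraints) && nrow(restraints) > 0) {
    drop_key <- c(drop_key, pair_key(restraints$i, restraints$j))
  }
  if (!is.null(exclude) && nrow(exclude) > 0) {
    drop_key <- c(drop_key, pair_key(exclude$i, exclude$j))
  }
  if (length(drop_key) > 0) {
    keep <- keep & !(pair_key(ii, jj) %in% drop_key)
  }
  tibble::tibble(i = ii[keep], j = jj[keep])
}

#' Extended circular starting conformation
#'
#' `L` points equally spaced on a circle in the xy-plane whose circumference
#' is `bond * L`, so consecutive chords are just under the ideal bond
#' length. This emulates the extended circular default start used for
#' folding runs.
#'
#' @param L number of residues (`L >= 3`).
#' @param bond target bond length, Angstroms.
#' @return A [ptrace()].
#' @export
make_circle_start <- function(L, bond = 6) {
  stopifnot(L >= 3)
  r <- bond * L / (2 * pi)
  a <- 2 * pi * (seq_len(L) - 1) / L
  ptrace(cbind(r * cos(a), r * sin(a), 0))
}

#' Run the coarse-grained simulation
#'
#' Per replicate, the starting structure is subjected to `config$cycles`
#' cycles; each cycle applies, in order: random rigid SSE perturbation,
#' intra-SSE ideal-geometry refinement, bond refinement, local-window
#' restoration (anchored to the starting structure), one-sided pair
#' restraints, and non-bonded repulsion. Restraints are applied identically
#' whether a pair is a local base pair or a non-local contact. Replicate
#' seeds are derived deterministically from `config$seed`, so identical
#' configurations reproduce identical ensembles.
#'
#' @param trace the starting [ptrace()] (the native structure for
#'   denaturation runs).
#' @param ss secondary structure (anything accepted by [as_rna_ss()]) used
#'   to detect SSEs; `NULL` for none.
#' @param restraints pair restraints to impose (tibble with columns `i`,
#'   `j`), or `NULL`.
#' @param config a [sim_config()].
#' @param start optional alternative starting conformation (e.g.
#'   [make_circle_start()]); defaults to `trace`.
#' @param use_local_window apply the local-window restoration term
#'   (anchored to `start`). Folding runs from a circular start disable it.
#' @param seed_offset integer mixed into the derived replicate seeds, used
#'   by protocols to decorrelate runs that share a master seed.
#' @return A `sim_result`: list with `models` (list of final traces),
#'   `start`, `reference`, `restraints`, `config` and (optionally)
#'   per-cycle `diagnostics`.
#' @export
simulate_trace <- function(trace, ss = NULL, restraints = NULL,
                           config = sim_config(), start = NULL,
                           use_local_window = TRUE, seed_offset = 0L) {
  start <- if (is.null(start)) trace else start
  stopifnot(pt_length(start) == pt_length(trace))
  sses <- if (is.null(ss)) list() else detect_sses(as_rna_ss(ss)$pairs)
  if (is.null(restraints)) {
    restraints <- tibble::tibble(i = integer(), j = integer())
  }
  restraints <- tibble::as_tibble(restraints)[, c("i", "j")]
  validate_restraint_indices(restraints, pt_length(trace))

  bonds <- bond_pairs(start)
  tmpl <- sse_template_pairs(sses)
  loc <- if (use_local_window) {
    local_native_distances(start, config)
  } else {
    tibble::tibble(i = integer(), j = integer(), dist = double())
  }
  rep_cand <- repulsion_candidates(start, sses, restraints)
  sse_members <- lapply(sses, `[[`, "members")
  X0 <- pt_coords(start)
  do_perturb <- length(sse_members) > 0 &&
    (config$perturb_translation > 0 || config$perturb_rotation > 0)

  models <- vector("list", config$replicates)
  diags <- if (config$diagnostics) vector("list", config$replicates) else NULL
  for (r in seq_len(config$replicates)) {
    set.seed(derive_seed(config$seed, r, seed_offset))
    X <- X0
    if (config$diagnostics) {
      mb <- numeric(config$cycles)
      rs <- integer(config$cycles)
    }
    for (cyc in seq_len(config$cycles)) {
      if (do_perturb) {
        X <- perturb_sses_core(
          X, sse_members, config$perturb_translation, config$perturb_rotation
        )
      }
      X <- step_core(X, tmpl$i, tmpl$j, tmpl$dist, config$step, "toward")
      X <- step_core(X, bonds$i, bonds$j, config$bond_ideal, config$step, "toward")
      if (nrow(loc) > 0) {
        dcur <- sqrt(rowSums(
          (X[loc$j, , drop = FALSE] - X[loc$i, , drop = FALSE])^2
        ))
        act <- which(dcur < config$local_gate)
        X <- step_core(X, loc$i[act], loc$j[act], loc$dist[act], config$step, "toward")
      }
      X <- step_core(
        X, restraints$i, restraints$j,
        config$restraint_target, config$step, "contract"
      )
      X <- step_core(
        X, rep_cand$i, rep_cand$j, config$repel_below, config$step, "repel"
      )
      if (config$diagnostics) {
        bd <- sqrt(rowSums(
          (X[bonds$j, , drop = FALSE] - X[bonds$i, , drop = FALSE])^2
        ))
        mb[cyc] <- mean(bd)
        if (nrow(restraints) > 0) {
          rd <- sqrt(rowSums(
            (X[restraints$j, , drop = FALSE] - X[restraints$i, , drop = FALSE])^2
          ))
          rs[cyc] <- sum(rd <= config$restraint_target + config$step / 2)
        }
      }
    }
    models[[r]] <- pt_set_coords(start, X)
    if (config$diagnostics) {
      diags[[r]] <- tibble::tibble(
        replicate = r, cycle = seq_len(config$cycles),
        mean_bond = mb, restraints_satisfied = rs
      )
    }
  }
  structure(
    list(
      models = models, start = start, reference = trace,
      restraints = restraints, config = config,
      diagnostics = if (config$diagnostics) dplyr::bind_rows(diags) else NULL
    ),
    class = "sim_result"
  )
}

validate_restraint_indices <- function(restraints, L) {
  if (nrow(restraints) == 0) {
    return(invisible(restraints))
  }
  if (any(restraints$i < 1) || any(restraints$j > L) ||
    any(restraints$i >= restraints$j)) {
    rlang::abort("Restraint indices must satisfy 1 <= i < j <= L.")
  }
  invisible(restraints)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result: %d model(s) of %d residues, %d cycles, %d restraint(s)>\n",
    length(x$models), pt_length(x$start), x$config$cycles, nrow(x$restraints)
  ))
  invisible(x)
}
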