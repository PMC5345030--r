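#' Superposition RMSD between two equal-length traces
#'
#' Root-mean-square deviation between equivalent phosphate atoms after
#' least-squares optimal rigid-body superposition (Kabsch algorithm;
#' rotation constrained to be proper, determinant +1, so mirror images are
#' not superposable -- the standard structural-biology convention).
#'
#' @param a,b [ptrace()] objects or L x 3 coordinate matrices of equal
#'   length (`L >= 3`).
#' @return RMSD in Angstroms.
#' @export
superpose_rmsd <- function(a, b) {
  A <- as_coords(a)
  B <- as_coords(b)
  if (nrow(A) != nrow(B)) {
    rlang::abort("Traces must have equal length.")
  }
  if (nrow(A) < 3) {
    rlang::abort("Superposition needs at least 3 points.")
  }
  Af <- superpose_onto(A, B)
  sqrt(mean(rowSums((Af - sweep(B, 2, colMeans(B)))^2)))
}

as_coords <- function(x) {
  if (inherits(x, "ptrace") || is.data.frame(x)) pt_coords(x) else as.matrix(x)
}

# Kabsch: returns A centred and rotated onto centred B (proper rotation).
superpose_onto <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  C <- crossprod(Ac, Bc)
  sv <- svd(C)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  Ac %*% t(R)
}

#' Superpose one trace onto another
#'
#' Applies the optimal proper rigid-body transform of [superpose_rmsd()]
#' and returns the moved copy of `a` in the frame of `b`.
#'
#' @inheritParams superpose_rmsd
#' @return `a` with transformed coordinates.
#' @export
superpose <- function(a, b) {
  A <- as_coords(a)
  B <- as_coords(b)
  moved <- superpose_onto(A, B)
  moved <- sweep(moved, 2, colMeans(B), `+`)
  if (inherits(a, "ptrace")) pt_set_coords(a, moved) else moved
}

#' Distance-matrix RMSD (dRMSD)
#'
#' Root-mean-square deviation over all pairwise phosphate/phosphate
#' distances: `sqrt(mean over i < j of (d_ij_a - d_ij_b)^2)`. Needs no
#' superposition, so it focuses on internal-structure change rather than
#' rigid displacement, and it is blind to reflection. The mean is over the
#' `L(L-1)/2` pairs so values are comparable across molecule lengths.
#'
#' @inheritParams superpose_rmsd
#' @return dRMSD in Angstroms.
#' @export
drmsd <- function(a, b) {
  A <- as_coords(a)
  B <- as_coords(b)
  if (nrow(A) != nrow(B)) {
    rlang::abort("Traces must have equal length.")
  }
  da <- stats::dist(A)
  db <- stats::dist(B)
  sqrt(mean((da - db)^2))
}

#' Per-pair maximum distance matrix over an ensemble
#'
#' Entry (i, j) is the maximum distance between residues i and j seen in
#' any model -- the extreme envelope of the ensemble's conformational
#' freedom.
#'
#' @param models a list of equal-length [ptrace()] objects (or matrices),
#'   or a `sim_result`.
#' @return An L x L symmetric matrix, Angstroms.
#' @export
max_distance_matrix <- function(models) {
  models <- ensemble_models(models)
  mats <- lapply(models, function(m) coord_dist(as_coords(m)))
  Reduce(pmax, mats)
}

ensemble_models <- function(models) {
  if (inherits(models, "sim_result")) models <- models$models
  if (inherits(models, "ptrace") || (is.matrix(models))) models <- list(models)
  stopifnot(length(models) >= 1)
  L <- nrow(as_coords(models[[1]]))
  for (m in models) {
    if (nrow(as_coords(m)) != L) rlang::abort("Models must have equal length.")
  }
  models
}

#' Ensemble dRMSDmax against a native structure
#'
#' The dRMSD computed between the per-pair maximum-distance matrix of the
#' ensemble and the native distance matrix. Because the mean dRMSD over the
#' models may not reflect the full extent to which the structure is free to
#' deviate, this uses the maximum observed value of each pairwise distance.
#' The alternative reading -- the maximum of the per-model dRMSD values --
#' is available as `drmsd_max_permodel()`.
#'
#' @param models as in [max_distance_matrix()].
#' @param native the native [ptrace()].
#' @return dRMSDmax in Angstroms.
#' @export
drmsd_max <- function(models, native) {
  mm <- max_distance_matrix(models)
  nd <- coord_dist(as_coords(native))
  if (!all(dim(mm) == dim(nd))) {
    rlang::abort("Ensemble and native must have equal length.")
  }
  ut <- upper.tri(mm)
  sqrt(mean((mm[ut] - nd[ut])^2))
}

#' @rdname drmsd_max
#' @export
drmsd_max_permodel <- function(models, native) {
  models <- ensemble_models(models)
  max(vapply(models, drmsd, numeric(1), b = native))
}

#' Per-residue RMSD profile of an ensemble
#'
#' Each model is globally superposed onto the native structure, then the
#' root-mean-square deviation of each position across models is reported.
#' Plotting this profile along the sequence identifies which segments a
#' restraint set actually holds in place.
#'
#' @inheritParams drmsd_max
#' @return A tibble with columns `position` and `rmsd`.
#' @export
per_residue_rmsd <- function(models, native) {
  models <- ensemble_models(models)
  N <- as_coords(native)
  dev2 <- matrix(0, nrow(N), length(models))
  for (k in seq_along(models)) {
    M <- superpose(as_coords(models[[k]]), N)
    dev2[, k] <- rowSums((M - N)^2)
  }
  tibble::tibble(position = seq_len(nrow(N)), rmsd = sqrt(rowMeans(dev2)))
}

#' Metric summary of an ensemble against a native structure
#'
#' @inheritParams drmsd_max
#' @return A one-row tibble with `n_models`, `rmsd_mean`, `drmsd_mean`,
#'   `drmsd_max` (max-distance-matrix definition) and
#'   `drmsd_max_permodel`.
#' @export
metric_summary <- function(models, native) {
  models <- ensemble_models(models)
  tibble::tibble(
    n_models = length(models),
    rmsd_mean = mean(vapply(models, superpose_rmsd, numeric(1), b = native)),
    drmsd_mean = mean(vapply(models, drmsd, numeric(1), b = native)),
    drmsd_max = drmsd_max(models, native),
    drmsd_max_permodel = drmsd_max_permodel(models, native)
  )
}

#' @export
#' @method glance sim_result
glance.sim_result <- function(x, native = x$reference, ...) {
  metric_summary(x$models, native)
}

#' @export
#' @method tidy sim_result
tidy.sim_result <- function(x, native = x$reference, ...) {
  tibble::tibble(
    model = seq_along(x$models),
    rmsd = vapply(x$models, superpose_rmsd, numeric(1), b = native),
    drmsd = vapply(x$models, drmsd, numeric(1), b = native)
  )
}
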