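#' Phosphate traces
#'
#' A phosphate trace (`ptrace`) is the coarse-grained representation of an RNA
#' molecule used throughout this package: one 3D point per nucleotide, taken
#' from the phosphate (P) atom, held in a tibble with columns `chain`,
#' `resno`, `x`, `y`, `z`. Residues are kept in file order; multi-chain
#' molecules are concatenated into a single indexed trace so that every
#' residue has one integer position `1..L`.
#'
#' @param coords numeric matrix with L rows and 3 columns (x, y, z), in
#'   Angstroms.
#' @param resno integer residue numbers, one per row of `coords`. Defaults to
#'   `1:L`. Must be strictly increasing within each chain.
#' @param chain chain identifier(s), recycled to length L.
#'
#' @return A `ptrace`: a tibble of L rows with columns `chain`, `resno`,
#'   `x`, `y`, `z`.
#' @examples
#' tr <- ptrace(matrix(c(0, 0, 0, 3, 4, 0), ncol = 3, byrow = TRUE))
#' pair_distance(tr, 1, 2) # 5
#' @export
ptrace <- function(coords, resno = NULL, chain = "A") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) {
    rlang::abort("`coords` must have three columns (x, y, z).")
  }
  mode(coords) <- "double"
  L <- nrow(coords)
  if (is.null(resno)) resno <- seq_len(L)
  resno <- as.integer(resno)
  chain <- as.character(rep_len(chain, L))
  out <- tibble::tibble(
    chain = chain, resno = resno,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  out <- tibble::new_tibble(out, class = "ptrace")
  validate_ptrace(out)
}

#' @rdname ptrace
#' @param df a data frame with columns `x`, `y`, `z` and optionally
#'   `chain`, `resno`.
#' @export
as_ptrace <- function(df) {
  if (inherits(df, "ptrace")) {
    return(validate_ptrace(df))
  }
  df <- tibble::as_tibble(df)
  for (col in c("x", "y", "z")) {
    if (!col %in% names(df)) {
      rlang::abort(sprintf("`df` must contain a `%s` column.", col))
    }
  }
  ptrace(
    cbind(df$x, df$y, df$z),
    resno = if ("resno" %in% names(df)) df$resno else NULL,
    chain = if ("chain" %in% names(df)) df$chain else "A"
  )
}

validate_ptrace <- function(x) {
  L <- nrow(x)
  if (L < 2) {
    rlang::abort("A phosphate trace needs at least 2 residues.")
  }
  m <- cbind(x$x, x$y, x$z)
  if (!all(is.finite(m))) {
    rlang::abort("Trace coordinates must all be finite.")
  }
  id <- paste(x$chain, x$resno)
  if (anyDuplicated(id)) {
    rlang::abort("Residue identifiers (chain + resno) must be unique.")
  }
  same <- x$chain[-1] == x$chain[-L]
  if (any(same & diff(x$resno) <= 0)) {
    rlang::abort("Residue numbers must be strictly increasing within a chain.")
  }
  x
}

#' @rdname ptrace
#' @param x a `ptrace`.
#' @export
pt_coords <- function(x) {
  unname(cbind(x$x, x$y, x$z))
}

#' @rdname ptrace
#' @export
pt_length <- function(x) nrow(x)

# Replace coordinates, keeping residue identity. Used by the engine to map
# its internal coordinate matrix back to a trace.
pt_set_coords <- function(x, coords) {
  x$x <- coords[, 1]
  x$y <- coords[, 2]
  x$z <- coords[, 3]
  x
}

# Indices (into 1..L-1) of consecutive residue pairs that are covalently
# bonded, i.e. belong to the same chain. The phosphate/phosphate virtual
# bond between them is refined towards 6 A by the engine.
bond_pairs <- function(trace) {
  L <- nrow(trace)
  k <- which(trace$chain[-L] == trace$chain[-1])
  tibble::tibble(i = k, j = k + 1L)
}

#' Distance between two residues of a trace
#'
#' Euclidean distance between the phosphate coordinates of residues `i` and
#' `j` (1-based positions in the trace).
#'
#' @param trace a [ptrace()].
#' @param i,j residue positions with `i < j`.
#' @return Distance in Angstroms.
#' @export
pair_distance <- function(trace, i, j) {
  L <- nrow(trace)
  if (any(i < 1L) || any(j > L)) {
    rlang::abort("Residue index out of range.")
  }
  if (any(i >= j)) {
    rlang::abort("`i` must be strictly less than `j`.")
  }
  m <- pt_coords(trace)
  sqrt(rowSums((m[j, , drop = FALSE] - m[i, , drop = FALSE])^2))
}

# All-pairs Euclidean distance matrix of a coordinate matrix (L x 3).
coord_dist <- function(m) {
  as.matrix(stats::dist(m))
}
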