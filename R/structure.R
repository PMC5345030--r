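#' Base-pair tables
#'
#' Base pairs are held as a tibble with integer columns `i` and `j`,
#' 1-based residue positions with `i < j`. A residue may appear in at most
#' one pair.
#'
#' @param i,j residue positions (vectors of equal length); pairs given with
#'   `i > j` are swapped.
#' @return A tibble with columns `i`, `j`, sorted by `i`.
#' @export
base_pairs <- function(i = integer(), j = integer()) {
  ii <- as.integer(pmin(i, j))
  jj <- as.integer(pmax(i, j))
  out <- tibble::tibble(i = ii, j = jj)
  validate_pairs(out)
  dplyr::arrange(out, .data$i)
}

validate_pairs <- function(pairs, L = NULL) {
  if (nrow(pairs) == 0) {
    return(invisible(pairs))
  }
  if (any(pairs$i >= pairs$j)) {
    rlang::abort("Base pairs must have i < j.")
  }
  res <- c(pairs$i, pairs$j)
  if (any(res < 1L)) {
    rlang::abort("Base-pair indices must be >= 1.")
  }
  if (!is.null(L) && any(res > L)) {
    rlang::abort("Base-pair index exceeds the trace length.")
  }
  dup <- res[duplicated(res)]
  if (length(dup) > 0) {
    rlang::abort(sprintf(
      "Invalid secondary structure: residue %d appears in more than one pair.",
      dup[1]
    ))
  }
  invisible(pairs)
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Detect secondary-structure elements (SSEs)
#'
#' Ladders of three or more consecutive base pairs are treated as
#' secondary-structure elements: rigid tubular units whose internal geometry
#' the engine continually refines towards an ideal double helix. Consecutive
#' means strictly antidiagonal -- pair (i, j) is followed by (i+1, j-1); any
#' bulge terminates the ladder. Runs shorter than 3 bp are not SSEs.
#'
#' @param pairs a base-pair tibble (see [base_pairs()]).
#' @return An object of class `sse_set`: a list of SSEs in 5' order, each a
#'   list with elements `i`, `j` (the pair run), `members` (residue
#'   positions, both strands in residue order) and `template` (ideal
#'   intra-SSE distance matrix, Angstroms, indexed like `members`).
#' @examples
#' detect_sses(base_pairs(c(1, 2, 3), c(20, 19, 18)))
#' @export
detect_sses <- function(pairs) {
  validate_pairs(pairs)
  pairs <- dplyr::arrange(tibble::as_tibble(pairs)[c("i", "j")], .data$i)
  sses <- list()
  n <- nrow(pairs)
  k <- 1L
  while (k <= n) {
    run_end <- k
    while (run_end < n &&
      pairs$i[run_end + 1L] == pairs$i[run_end] + 1L &&
      pairs$j[run_end + 1L] == pairs$j[run_end] - 1L) {
      run_end <- run_end + 1L
    }
    len <- run_end - k + 1L
    if (len >= 3L) {
      ii <- pairs$i[k:run_end]
      jj <- pairs$j[k:run_end]
      sses[[length(sses) + 1L]] <- list(
        i = ii, j = jj,
        members = c(ii, rev(jj)), # both strands in ascending residue order
        n_bp = len,
        template = ideal_sse_template(len)
      )
    }
    k <- run_end + 1L
  }
  structure(sses, class = "sse_set")
}

#' @export
print.sse_set <- function(x, ...) {
  cat(sprintf("<sse_set: %d element(s)>\n", length(x)))
  for (s in x) {
    cat(sprintf(
      "  %d bp ladder: %d-%d paired with %d-%d\n",
      s$n_bp, min(s$i), max(s$i), min(s$j), max(s$j)
    ))
  }
  invisible(x)
}

#' @export
#' @method tidy sse_set
tidy.sse_set <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(s, idx) {
    tibble::tibble(sse = idx, i = s$i, j = s$j, n_bp = s$n_bp)
  })
}

#' Split base pairs into nested and crossing (pseudoknot) subsets
#'
#' Finds a maximum-cardinality subset of the pairs that is free of crossings
#' (no two pairs (a, b), (c, d) with a < c < b < d), i.e. expressible in
#' single-layer nested bracket notation; the remainder are the crossing
#' (pseudoknot) pairs. Ties between equal-cardinality nested subsets are
#' broken by preferring pairs with smaller `i`, which makes the result
#' deterministic. Computed by dynamic programming over intervals of the
#' pair endpoints.
#'
#' @param pairs a base-pair tibble.
#' @return An object of class `rna_ss`: a list with tibbles `pairs`,
#'   `nested` and `crossing` (`nested` and `crossing` partition `pairs`).
#' @examples
#' ss <- split_nested(base_pairs(c(1, 2, 5), c(10, 9, 15)))
#' ss$crossing # the (5, 15) pseudoknot pair
#' @export
split_nested <- function(pairs) {
  validate_pairs(pairs)
  pairs <- dplyr::arrange(tibble::as_tibble(pairs)[c("i", "j")], .data$i)
  P <- nrow(pairs)
  if (P == 0) {
    empty <- tibble::tibble(i = integer(), j = integer())
    return(new_rna_ss(empty, empty, empty))
  }
  pos <- sort(unique(c(pairs$i, pairs$j)))
  np <- length(pos)
  left <- match(pairs$i, pos)
  right <- match(pairs$j, pos)
  pair_at <- rep(NA_integer_, np)
  pair_at[left] <- seq_len(P)

  # M[l, r]: maximum number of non-crossing pairs entirely within
  # endpoint positions l..r (inclusive).
  M <- matrix(0L, nrow = np + 1L, ncol = np + 1L)
  val <- function(l, r) if (l > r) 0L else M[l, r]
  for (l in rev(seq_len(np))) {
    for (r in l:np) {
      best <- val(l + 1L, r)
      p <- pair_at[l]
      if (!is.na(p) && right[p] <= r) {
        take <- 1L + val(l + 1L, right[p] - 1L) + val(right[p] + 1L, r)
        if (take >= best) best <- take # >=: prefer taking the smaller-i pair
      }
      M[l, r] <- best
    }
  }

  keep <- logical(P)
  stack <- list(c(1L, np))
  while (length(stack) > 0) {
    lr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- lr[1]
    r <- lr[2]
    if (l > r) next
    p <- pair_at[l]
    if (!is.na(p) && right[p] <= r) {
      take <- 1L + val(l + 1L, right[p] - 1L) + val(right[p] + 1L, r)
      if (take >= val(l + 1L, r)) {
        keep[p] <- TRUE
        stack[[length(stack) + 1L]] <- c(l + 1L, right[p] - 1L)
        stack[[length(stack) + 1L]] <- c(right[p] + 1L, r)
        next
      }
    }
    stack[[length(stack) + 1L]] <- c(l + 1L, r)
  }

  new_rna_ss(pairs, pairs[keep, ], pairs[!keep, ])
}

new_rna_ss <- function(pairs, nested, crossing) {
  structure(
    list(pairs = pairs, nested = nested, crossing = crossing),
    class = "rna_ss"
  )
}

#' Coerce base pairs to a secondary-structure object
#'
#' @param x a base-pair tibble, a dot-bracket string, or an `rna_ss`.
#' @return An `rna_ss` (see [split_nested()]).
#' @export
as_rna_ss <- function(x) {
  if (inherits(x, "rna_ss")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1) {
    return(split_nested(parse_dotbracket(x)))
  }
  split_nested(x)
}

#' @export
print.rna_ss <- function(x, ...) {
  cat(sprintf(
    "<rna_ss: %d pair(s), %d nested, %d crossing>\n",
    nrow(x$pairs), nrow(x$nested), nrow(x$crossing)
  ))
  invisible(x)
}

#' @export
#' @method tidy rna_ss
tidy.rna_ss <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$nested, layer = "nested"),
    dplyr::mutate(x$crossing, layer = "crossing")
  ) |> dplyr::arrange(.data$i)
}
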