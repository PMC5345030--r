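#' Read a phosphate trace from a PDB file
#'
#' Extracts one coordinate per residue from the P atom of each nucleotide.
#' Residues without a P atom (typically the 5' terminus) are skipped with a
#' warning. Multi-chain files are concatenated into a single indexed trace
#' in file order. Parsing is done with \pkg{bio3d} after a light validation
#' pass that reports malformed ATOM records with their line number.
#'
#' @param file path to a PDB file. For multi-model files only the first
#'   model is read; see [read_ensemble()] for ensembles.
#' @return A [ptrace()].
#' @export
read_phosphate_trace <- function(file) {
  check_pdb_lines(file)
  pdb <- suppressWarnings(bio3d::read.pdb(file, verbose = FALSE))
  atoms <- pdb$atom
  p <- atoms[trimws(atoms$elety) == "P", , drop = FALSE]
  if (nrow(p) == 0) {
    rlang::abort(sprintf("No P atoms found in '%s': empty chain.", file))
  }
  n_res <- nrow(unique(atoms[c("chain", "resno", "insert")]))
  if (nrow(p) < n_res) {
    rlang::warn(sprintf(
      "%d residue(s) without a P atom were skipped.", n_res - nrow(p)
    ))
  }
  ptrace(cbind(p$x, p$y, p$z), resno = p$resno, chain = p$chain)
}

#' Read an ensemble of phosphate traces from a multi-model PDB file
#'
#' @param file path to a PDB file with MODEL/ENDMDL blocks (a single-model
#'   file yields a list of one trace).
#' @return A list of [ptrace()] objects, one per model.
#' @export
read_ensemble <- function(file) {
  check_pdb_lines(file)
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE))
  sel <- which(trimws(pdb$atom$elety) == "P")
  if (length(sel) == 0) {
    rlang::abort(sprintf("No P atoms found in '%s': empty chain.", file))
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  resno <- pdb$atom$resno[sel]
  chain <- pdb$atom$chain[sel]
  idx <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, idx], ncol = 3, byrow = TRUE)
    ptrace(co, resno = resno, chain = chain)
  })
}

# Reject obviously malformed ATOM records before handing the file to the
# parser, so errors carry a line number.
check_pdb_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (k in which(rec)) {
    ln <- lines[k]
    if (nchar(ln) < 54) {
      rlang::abort(sprintf("Malformed ATOM record at line %d: too short.", k))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(xyz))) {
      rlang::abort(sprintf(
        "Malformed ATOM record at line %d: non-numeric coordinates.", k
      ))
    }
  }
  invisible(lines)
}

#' Write phosphate traces as a (multi-model) PDB file
#'
#' Each trace is written as one MODEL block of ATOM records, one P atom per
#' residue; a single trace is written without MODEL/ENDMDL wrappers.
#' Coordinates use the standard fixed-width PDB format (3 decimals).
#'
#' @param traces a [ptrace()] or a list of traces of equal length.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_phosphate_trace <- function(traces, file) {
  if (inherits(traces, "ptrace")) traces <- list(traces)
  multi <- length(traces) > 1
  con <- base::file(file, "w")
  on.exit(close(con))
  for (m in seq_along(traces)) {
    tr <- traces[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d  P     U %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
      seq_len(nrow(tr)), substr(tr$chain, 1, 1), tr$resno, tr$x, tr$y, tr$z
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Parse a dot-bracket string into base pairs
#'
#' Supports up to four bracket layers `()`, `[]`, `{}`, `<>`; layers beyond
#' the first encode crossing (pseudoknot) pairs. Dots (and any other
#' character) are unpaired.
#'
#' @param text a single dot-bracket string.
#' @return A base-pair tibble (1-based positions, sorted by `i`).
#' @examples
#' parse_dotbracket("((..))") # pairs (1,6) and (2,5)
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  openers <- c("(", "[", "{", "<")
  closers <- c(")", "]", "}", ">")
  stacks <- rep(list(integer()), 4)
  ii <- integer()
  jj <- integer()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    lo <- match(ch, openers)
    lc <- match(ch, closers)
    if (!is.na(lo)) {
      stacks[[lo]] <- c(stacks[[lo]], k)
    } else if (!is.na(lc)) {
      s <- stacks[[lc]]
      if (length(s) == 0) {
        rlang::abort(sprintf(
          "Unbalanced dot-bracket string: unmatched '%s' at position %d.",
          ch, k
        ))
      }
      ii <- c(ii, s[length(s)])
      jj <- c(jj, k)
      stacks[[lc]] <- s[-length(s)]
    }
  }
  for (l in 1:4) {
    if (length(stacks[[l]]) > 0) {
      rlang::abort(sprintf(
        "Unbalanced dot-bracket string: unmatched '%s' at position %d.",
        openers[l], stacks[[l]][1]
      ))
    }
  }
  base_pairs(ii, jj)
}

#' Write base pairs as a dot-bracket string
#'
#' Crossing pairs are assigned to square/curly/angle bracket layers greedily
#' (each pair goes to the first layer where it crosses nothing already
#' placed), so pseudoknotted structures round-trip through text.
#'
#' @param pairs a base-pair tibble.
#' @param L molecule length (number of characters in the output).
#' @return A dot-bracket string.
#' @export
write_dotbracket <- function(pairs, L) {
  validate_pairs(pairs, L = L)
  pairs <- dplyr::arrange(tibble::as_tibble(pairs), .data$i)
  openers <- c("(", "[", "{", "<")
  closers <- c(")", "]", "}", ">")
  layers <- rep(list(tibble::tibble(i = integer(), j = integer())), 4)
  out <- rep(".", L)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]
    j <- pairs$j[r]
    placed <- FALSE
    for (l in 1:4) {
      lay <- layers[[l]]
      crosses <- (lay$i < i & i < lay$j & lay$j < j) |
        (i < lay$i & lay$i < j & j < lay$j)
      if (!any(crosses)) {
        layers[[l]] <- dplyr::bind_rows(lay, tibble::tibble(i = i, j = j))
        out[i] <- openers[l]
        out[j] <- closers[l]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rlang::abort("Structure needs more than four bracket layers.")
    }
  }
  paste(out, collapse = "")
}

#' Read a scored contact-prediction table
#'
#' Reads a whitespace/tab-separated table of `i j score` rows (1-based
#' positions, as produced by correlated-mutation contact predictors). The
#' reader is permissive: an optional header line is detected and skipped,
#' comment lines starting with `#` are ignored, and `i > j` rows are
#' canonicalised. Duplicate `(i, j)` entries keep the maximum score. The
#' result is sorted by descending score (ties broken by ascending `i`, then
#' `j`) and given contiguous 1-based ranks.
#'
#' @param file path to the table, or a literal string containing it.
#' @param L optional molecule length used to range-check positions.
#' @return A tibble with columns `i`, `j`, `score`, `rank`.
#' @export
read_contacts <- function(file, L = NULL) {
  txt <- if (length(file) == 1 && !grepl("[\n\t ]", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  if (length(txt) == 0) {
    return(rank_contacts(tibble::tibble(i = integer(), j = integer(), score = double())))
  }
  first <- strsplit(trimws(txt[1]), "\\s+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first[1:2]))))) {
    txt <- txt[-1] # header line
  }
  df <- utils::read.table(text = txt, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) {
    rlang::abort("Contact table needs at least three columns: i, j, score.")
  }
  tb <- tibble::tibble(
    i = as.integer(df[[1]]), j = as.integer(df[[2]]), score = as.numeric(df[[3]])
  )
  bad <- which(tb$i == tb$j)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Contact row %d has i == j.", bad[1]))
  }
  if (!is.null(L)) {
    bad <- which(tb$i < 1 | tb$j < 1 | tb$i > L | tb$j > L)
    if (length(bad) > 0) {
      rlang::abort(sprintf("Contact row %d is out of range 1..%d.", bad[1], L))
    }
  }
  rank_contacts(tb)
}

#' Rank a contact table
#'
#' Canonicalises `i < j`, drops duplicate pairs keeping the maximum score,
#' sorts by descending score (ties: ascending `i`, then `j`) and assigns
#' contiguous ranks from 1.
#'
#' @param contacts a data frame with columns `i`, `j`, `score`.
#' @return A tibble with columns `i`, `j`, `score`, `rank`.
#' @export
rank_contacts <- function(contacts) {
  tb <- tibble::as_tibble(contacts)
  ii <- pmin(tb$i, tb$j)
  jj <- pmax(tb$i, tb$j)
  tb$i <- as.integer(ii)
  tb$j <- as.integer(jj)
  tb <- tb |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$score), .data$i, .data$j)
  tb$rank <- seq_len(nrow(tb))
  tb
}

#' Write a contact table
#'
#' @param contacts a tibble with columns `i`, `j`, `score`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_contacts <- function(contacts, file) {
  readr::write_tsv(contacts[c("i", "j", "score")], file, col_names = FALSE)
  invisible(file)
}

#' Format/write SimRNA-dialect restraint lines
#'
#' Renders each pair as one `WELL` line (a deep square distance well) and
#' one `SLOPE` line (a flanking V-shaped slope that lets an escaped
#' restraint re-establish), addressing the base-centroid pseudo-atom `MB`:
#' `WELL A/16/MB A/39/MB 5.0 10.0 5.0`. Numbers carry one decimal place.
#'
#' @param pairs a base-pair tibble (1-based residue numbers).
#' @param chain single-character chain identifier.
#' @param well numeric `c(min, max, weight)` of the square well, Angstroms
#'   and a dimensionless weight.
#' @param slope numeric `c(min, max, weight)` of the flanking slope.
#' @return `format_simrna_restraints()` returns a character vector of lines
#'   (two per pair); `write_simrna_restraints()` writes them to `file` and
#'   returns `file` invisibly.
#' @export
format_simrna_restraints <- function(pairs, chain = "A",
                                     well = c(5, 10, 5),
                                     slope = c(5, 10, 1)) {
  stopifnot(nchar(chain) == 1, length(well) == 3, length(slope) == 3)
  if (nrow(pairs) == 0) {
    return(character())
  }
  if (any(pairs$i >= pairs$j)) {
    rlang::abort("Restraint pairs must have i < j.")
  }
  atoms <- sprintf("%s/%d/MB %s/%d/MB", chain, pairs$i, chain, pairs$j)
  as.vector(rbind(
    sprintf("WELL %s %.1f %.1f %.1f", atoms, well[1], well[2], well[3]),
    sprintf("SLOPE %s %.1f %.1f %.1f", atoms, slope[1], slope[2], slope[3])
  ))
}

#' @rdname format_simrna_restraints
#' @param file output path.
#' @export
write_simrna_restraints <- function(pairs, file, chain = "A",
                                    well = c(5, 10, 5),
                                    slope = c(5, 10, 1)) {
  writeLines(format_simrna_restraints(pairs, chain, well, slope), file)
  invisible(file)
}
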