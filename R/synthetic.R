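# Synthetic ideal-geometry fixtures: toy RNA topologies whose phosphate
# traces are fixed points of the engine's geometric ideals (6 A bonds,
# 17 A paired phosphates, >= 10 A non-bonded separation), plus scored
# contact lists with planted signal and noise.

# --- low-level geometry -----------------------------------------------------

unit3 <- function(v) v / sqrt(sum(v^2))

# Place an ideal double helix: axis direction `axis`, strand-1 base at
# radius HELIX_RADIUS from `origin` at phase `phase` (measured from the
# projection of `ref` onto the plane normal to the axis). Returns both
# strands in residue order plus the four end anchors.
place_helix <- function(n_bp, origin, axis = c(0, 0, 1), ref = c(1, 0, 0),
                        phase = 0) {
  w <- unit3(axis)
  u <- ref - sum(ref * w) * w
  if (sqrt(sum(u^2)) < 1e-8) {
    rlang::abort("Helix reference vector is parallel to the axis.")
  }
  u <- unit3(u)
  v <- c(
    w[2] * u[3] - w[3] * u[2],
    w[3] * u[1] - w[1] * u[3],
    w[1] * u[2] - w[2] * u[1]
  )
  k <- seq_len(n_bp) - 1
  ang <- phase + k * HELIX_TWIST
  radial <- HELIX_RADIUS * (outer(cos(ang), u) + outer(sin(ang), v))
  rise <- outer(k * HELIX_RISE, w)
  base <- matrix(origin, n_bp, 3, byrow = TRUE)
  s1 <- base + radial + rise
  s2 <- base - radial + rise
  s2 <- s2[rev(seq_len(n_bp)), , drop = FALSE] # residue order, antiparallel
  list(
    s1 = s1, s2 = s2,
    s1_bottom = s1[1, ], s1_top = s1[n_bp, ],
    s2_top = s2[1, ], s2_bottom = s2[n_bp, ]
  )
}

# Hairpin loop: a tangent-matched cubic Hermite spline from the top of
# strand 1 to the top of strand 2. Matching the end tangents to the helix
# backbone means the first and last loop residues sit where the next
# phosphate of each strand would have been -- automatically clear of the
# stem -- and the tangent scale is solved so the m + 1 chords come out at
# the 6 A spacing. An optional `lean` displacement (applied as a sin^2
# bump, so end tangents are untouched) pulls the loop apex sideways; it is
# used to bring cross-linked loops of adjacent arms within the 17 A
# restraint target.
loop_spline <- function(p0, t0, p1, t1, m, lean = c(0, 0, 0), spacing = 6) {
  d <- sqrt(sum((p1 - p0)^2))
  tt <- seq(0, 1, length.out = 801)
  path_for <- function(scale) {
    s0 <- unit3(t0) * d * scale
    s1 <- unit3(t1) * d * scale
    outer((2 * tt^3 - 3 * tt^2 + 1), p0) + outer((tt^3 - 2 * tt^2 + tt), s0) +
      outer((-2 * tt^3 + 3 * tt^2), p1) + outer((tt^3 - tt^2), s1) +
      outer(sin(pi * tt)^4, lean)
  }
  arclen <- function(scale) sum(sqrt(rowSums(diff(path_for(scale))^2)))
  if (arclen(0.2) > spacing * (m + 1) || arclen(14) < spacing * (m + 1)) {
    rlang::abort(sprintf(
      "Loop of %d residues cannot span %.1f A with %.0f A chords.", m, d, spacing
    ))
  }
  solve_scale_and_resample(path_for, arclen, p0, p1, m, spacing)
}

# Inter-segment connector: a cubic Hermite spline whose end tangents match
# the backbone directions of the flanking helices (so chain direction turns
# smoothly through junctions and sequence-separation-2 pairs stay outside
# the 10 A repulsion shell), resampled to m interior points at equal arc
# length. Hairpin loops, whose anchors are helix tops, use circular arcs;
# junction linkers need the tangent matching.
spline_connector <- function(p0, t0, p1, t1, m = NULL, spacing = 6) {
  d <- sqrt(sum((p1 - p0)^2))
  tt <- seq(0, 1, length.out = 401)
  path_for <- function(scale) {
    s0 <- unit3(t0) * d * scale
    s1 <- unit3(t1) * d * scale
    outer((2 * tt^3 - 3 * tt^2 + 1), p0) + outer((tt^3 - 2 * tt^2 + tt), s0) +
      outer((-2 * tt^3 + 3 * tt^2), p1) + outer((tt^3 - tt^2), s1)
  }
  arclen <- function(scale) sum(sqrt(rowSums(diff(path_for(scale))^2)))
  if (is.null(m)) m <- max(1L, as.integer(round(arclen(1) / spacing)) - 1L)
  solve_scale_and_resample(path_for, arclen, p0, p1, m, spacing)
}

# Solve the tangent scale of a parametric path so that, after equal-chord
# resampling, the chord length is the spacing itself (6 A): built fixtures
# are then exact fixed points of the engine's bond term.
solve_scale_and_resample <- function(path_for, arclen, p0, p1, m,
                                     spacing = 6) {
  q_of <- function(scale) {
    pts <- resample_equal_chords(path_for(scale), p0, p1, m, spacing,
      strict = FALSE
    )
    if (is.null(pts)) {
      return(NA_real_)
    }
    sqrt(sum((pts[1, ] - p0)^2))
  }
  # q is only defined on a window of scales; scan for a sign change of
  # q - spacing, then bisect inside it.
  grid <- seq(0.2, 14, by = 0.1)
  qs <- vapply(grid, q_of, numeric(1))
  fs <- qs - spacing
  cross <- which(!is.na(fs[-length(fs)]) & !is.na(fs[-1]) &
    fs[-length(fs)] * fs[-1] <= 0)
  scale <- if (length(cross) > 0) {
    lo <- grid[cross[1]]
    hi <- grid[cross[1] + 1]
    if (fs[cross[1]] > 0) {
      tmp <- lo
      lo <- hi
      hi <- tmp
    } # ensure q(lo) <= spacing <= q(hi)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      fm <- q_of(mid) - spacing
      if (is.na(fm) || fm < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  } else {
    # no crossing: fall back to matching total arc length
    lo <- 0.2
    hi <- 14
    al <- function(s) arclen(s) - spacing * (m + 1) * 1.02
    if (al(lo) > 0) {
      lo
    } else if (al(hi) < 0) {
      hi
    } else {
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (al(mid) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
  }
  resample_equal_chords(path_for(scale), p0, p1, m, spacing)
}

# March m points along a finely sampled path at chord length q, bisecting
# q so the final chord to p1 equals q too: all m + 1 chords equal.
resample_equal_chords <- function(path, p0, p1, m, spacing = 6,
                                  strict = TRUE) {
  march <- function(q) {
    pts <- matrix(0, m, 3)
    cur <- p0
    at <- 1L
    for (k in seq_len(m)) {
      dd <- sqrt(rowSums((path[at:nrow(path), , drop = FALSE] -
        rep(cur, each = nrow(path) - at + 1))^2))
      nxt <- which(dd >= q)[1]
      if (is.na(nxt)) {
        return(NULL)
      }
      # interpolate on the crossing segment so the chord is exactly q
      hit <- at + nxt - 1L
      if (nxt > 1L && dd[nxt] > dd[nxt - 1L]) {
        f <- (q - dd[nxt - 1L]) / (dd[nxt] - dd[nxt - 1L])
        cur <- path[hit - 1L, ] + f * (path[hit, ] - path[hit - 1L, ])
      } else {
        cur <- path[hit, ]
      }
      at <- hit
      pts[k, ] <- cur
    }
    list(pts = pts, final = sqrt(sum((p1 - cur)^2)))
  }
  f <- function(q) {
    w <- march(q)
    if (is.null(w)) {
      return(-q)
    }
    w$final - q
  }
  lo <- spacing - 1.5
  hi <- spacing + 1.5
  if (f(lo) < 0 || f(hi) > 0) {
    if (!strict) {
      return(NULL)
    }
    rlang::abort("Construction error: connector cannot be evenly spaced.")
  }
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  q <- (lo + hi) / 2
  pts <- march(q)$pts
  gaps <- sqrt(rowSums(diff(rbind(p0, pts, p1))^2))
  if (any(gaps < spacing - 1 | gaps > spacing + 1)) {
    if (!strict) {
      return(NULL)
    }
    rlang::abort(sprintf(
      "Construction error: connector spacing %.2f A outside %.0f +/- 1 A.",
      gaps[which.max(abs(gaps - spacing))], spacing
    ))
  }
  pts
}

entry_dir <- function(block) block[2, ] - block[1, ]
exit_dir <- function(block) block[nrow(block), ] - block[nrow(block) - 1, ]

# --- public builders --------------------------------------------------------

#' Build an ideal double helix fixture
#'
#' A 2 x n_bp phosphate trace on the package's ideal helix template:
#' consecutive intra-strand P-P steps of exactly 6 Angstroms and paired
#' cross-strand P-P of exactly 17 Angstroms. The two strands are separate
#' chains (A and B), paired as (k, 2n + 1 - k).
#'
#' @param n_bp number of base pairs (`>= 3` so the ladder is an SSE).
#' @return A list with elements `trace` (a [ptrace()]) and `pairs`.
#' @export
build_helix <- function(n_bp) {
  if (n_bp < 3) {
    rlang::abort("`n_bp` must be at least 3.")
  }
  co <- ideal_helix_coords(n_bp)
  trace <- ptrace(co,
    resno = c(seq_len(n_bp), seq_len(n_bp)),
    chain = rep(c("A", "B"), each = n_bp)
  )
  list(trace = trace, pairs = base_pairs(seq_len(n_bp), 2 * n_bp + 1 - seq_len(n_bp)))
}

#' Topology specification for synthetic fixtures
#'
#' @param kind one of `"helix"`, `"stemloop"`, `"Y"`, `"cruciform"`.
#' @param stems base-pair counts of the stems, each `>= 3` (one value for
#'   helix/stemloop; for `"Y"`, `c(trunk, arm1, arm2)`; for `"cruciform"`,
#'   four arm values).
#' @param loops loop lengths in nucleotides (one per stem-loop; `>= 3`).
#' @param cross_links number of planted distal loop-loop contacts (0 or 1
#'   for `"Y"` and `"cruciform"`, planted between the first pair of arms;
#'   0 otherwise). Cross-linked arm pairs
#'   have their loop apexes leant towards each other so the planted contact
#'   sits within the 17 Angstrom restraint target in the built structure.
#' @return A `topology_spec` (named list).
#' @export
topology_spec <- function(kind = c("Y", "helix", "stemloop", "cruciform"),
                          stems = NULL, loops = NULL, cross_links = 0) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    helix = list(stems = 6, loops = integer()),
    stemloop = list(stems = 6, loops = 6),
    Y = list(stems = c(4, 6, 6), loops = c(7, 7)),
    cruciform = list(stems = c(6, 6, 6, 6), loops = c(7, 7, 7, 7))
  )
  if (is.null(stems)) stems <- defaults$stems
  if (is.null(loops)) loops <- defaults$loops
  n_stems <- switch(kind, helix = 1, stemloop = 1, Y = 3, cruciform = 4)
  n_loops <- switch(kind, helix = 0, stemloop = 1, Y = 2, cruciform = 4)
  max_links <- switch(kind, helix = 0, stemloop = 0, Y = 1, cruciform = 1)
  stopifnot(
    length(stems) == n_stems, all(stems >= 3),
    length(loops) == n_loops, all(loops >= 3),
    cross_links >= 0, cross_links <= max_links
  )
  structure(
    list(
      kind = kind, stems = as.integer(stems), loops = as.integer(loops),
      cross_links = as.integer(cross_links)
    ),
    class = "topology_spec"
  )
}

# Junction layout constants (Angstroms / radians), chosen once so the
# default fixtures satisfy the engine ideals: arm axis separation keeps
# inter-helix phosphates >= 10 A apart while the inward loop tilt brings
# cross-linked loop apexes inside the 17 A restraint target. Arm phases
# are set so the strand tangential direction at each arm base points
# towards the partner arm, letting the junction connectors run smoothly.
ARM_SEP <- 28
ARM_BASE_Z <- 18
LOOP_LEAN <- 8 # A sideways pull on cross-linked loop apexes, towards the partner
PHASE_TANG_PLUS_X <- 3 * pi / 2 - HELIX_TWIST / 2 # base tangential = +x
PHASE_TANG_MINUS_X <- pi / 2 - HELIX_TWIST / 2 # base tangential = -x
PHASE_TANG_FRAME_V <- -HELIX_TWIST / 2 # base tangential = frame v axis

#' Build a synthetic topology fixture
#'
#' Assembles ideal helix segments and circular loop arcs into a
#' self-avoiding phosphate trace: a bare `helix`, a single `stemloop`, a
#' `Y` (two stem-loop arms branching off a double-strand trunk that locks
#' the termini) or a `cruciform` (four stem-loop arms around a junction).
#' Built structures satisfy the engine's ideals -- 6 Angstrom bonds within
#' segments, 17 Angstrom paired phosphates, non-bonded separations of at
#' least 10 Angstroms except planted cross-link contacts, which sit between
#' 10 and 17 Angstroms. The build is deterministic; a construction error is
#' raised if the requested geometry cannot satisfy those constraints.
#'
#' @param spec a [topology_spec()] (or arguments passed to it).
#' @param ... passed to [topology_spec()] when `spec` is a kind string.
#' @return An `rna_topology`: list with `trace`, `ss` (an `rna_ss`),
#'   `cross_links` (tibble of planted distal pairs), and `spec`.
#' @examples
#' topo <- build_topology(topology_spec("Y", cross_links = 1))
#' length(detect_sses(topo$ss$pairs)) # 3 SSEs
#' @export
build_topology <- function(spec = topology_spec(), ...) {
  if (is.character(spec)) spec <- topology_spec(spec, ...)
  stopifnot(inherits(spec, "topology_spec"))
  built <- switch(spec$kind,
    helix = build_topo_helix(spec),
    stemloop = build_topo_stemloop(spec),
    Y = build_topo_y(spec),
    cruciform = build_topo_cruciform(spec)
  )
  out <- structure(
    list(
      trace = built$trace,
      ss = split_nested(built$pairs),
      cross_links = built$cross_links,
      spec = spec
    ),
    class = "rna_topology"
  )
  check_topology(out)
  out
}

#' @export
print.rna_topology <- function(x, ...) {
  cat(sprintf(
    "<rna_topology '%s': %d nt, %d bp, %d planted cross-link(s)>\n",
    x$spec$kind, pt_length(x$trace), nrow(x$ss$pairs), nrow(x$cross_links)
  ))
  invisible(x)
}

build_topo_helix <- function(spec) {
  h <- build_helix(spec$stems[1])
  list(
    trace = h$trace, pairs = h$pairs,
    cross_links = tibble::tibble(i = integer(), j = integer())
  )
}

# One stem-loop segment: strand 1 up, loop spline over the top, strand 2
# down. Returns coords in residue order, local pair indices, and the loop
# span.
stemloop_segment <- function(n_bp, loop_len, origin, axis, ref, phase,
                             lean = c(0, 0, 0)) {
  H <- place_helix(n_bp, origin, axis, ref, phase)
  loop <- loop_spline(
    H$s1_top, H$s1[n_bp, ] - H$s1[n_bp - 1, ],
    H$s2_top, H$s2[2, ] - H$s2[1, ],
    loop_len,
    lean = lean
  )
  n <- 2 * n_bp + loop_len
  list(
    coords = rbind(H$s1, loop, H$s2),
    pairs_i = seq_len(n_bp),
    pairs_j = n + 1 - seq_len(n_bp),
    loop_idx = n_bp + seq_len(loop_len)
  )
}

build_topo_stemloop <- function(spec) {
  seg <- stemloop_segment(
    spec$stems[1], spec$loops[1],
    origin = c(0, 0, 0), axis = c(0, 0, 1), ref = c(1, 0, 0), phase = 0
  )
  list(
    trace = ptrace(seg$coords),
    pairs = base_pairs(seg$pairs_i, seg$pairs_j),
    cross_links = tibble::tibble(i = integer(), j = integer())
  )
}

# Pick the planted cross-link between two arms: the loop-residue pair whose
# built distance is closest to 16.5 A -- just inside the 17 A restraint
# target (so the tether clamps essentially at the native separation) and
# well outside the 10 A repulsion shell.
pick_cross_link <- function(coords, loop_a, loop_b) {
  grid <- expand.grid(a = loop_a, b = loop_b)
  d <- sqrt(rowSums(
    (coords[grid$a, , drop = FALSE] - coords[grid$b, , drop = FALSE])^2
  ))
  best <- which.min(abs(d - 16.5))
  tibble::tibble(
    i = min(grid$a[best], grid$b[best]),
    j = max(grid$a[best], grid$b[best]),
    dist = d[best]
  )
}

build_topo_y <- function(spec) {
  t_bp <- spec$stems[1]
  arm_bp <- spec$stems[2:3]
  lean <- if (spec$cross_links > 0) LOOP_LEAN else 0
  # trunk: axis +z, strand-1 top anchored at azimuth 160 degrees so the
  # junction connectors to both arms run smoothly
  trunk_phase <- 8 * pi / 9 - (t_bp - 1) * HELIX_TWIST
  trunk <- place_helix(
    t_bp, c(0, 0, -(t_bp - 1) * HELIX_RISE),
    axis = c(0, 0, 1), ref = c(1, 0, 0), phase = trunk_phase
  )
  armA <- stemloop_segment(
    arm_bp[1], spec$loops[1],
    origin = c(-ARM_SEP / 2, 0, ARM_BASE_Z), axis = c(0, 0, 1),
    ref = c(1, 0, 0), phase = PHASE_TANG_PLUS_X,
    lean = c(lean, 0, 0)
  )
  armB <- stemloop_segment(
    arm_bp[2], spec$loops[2],
    origin = c(ARM_SEP / 2, 0, ARM_BASE_Z), axis = c(0, 0, 1),
    ref = c(1, 0, 0), phase = PHASE_TANG_PLUS_X,
    lean = c(-lean, 0, 0)
  )
  link1 <- spline_connector(
    trunk$s1_top, exit_dir(trunk$s1), armA$coords[1, ], entry_dir(armA$coords)
  )
  link2 <- spline_connector(
    armA$coords[nrow(armA$coords), ], exit_dir(armA$coords),
    armB$coords[1, ], entry_dir(armB$coords)
  )
  link3 <- spline_connector(
    armB$coords[nrow(armB$coords), ], exit_dir(armB$coords),
    trunk$s2_top, entry_dir(trunk$s2)
  )

  blocks <- list(
    trunk$s1, link1, armA$coords, link2, armB$coords, link3, trunk$s2
  )
  offs <- cumsum(c(0, vapply(blocks, nrow, integer(1))))
  coords <- do.call(rbind, blocks)
  n <- nrow(coords)
  armA_off <- offs[3]
  armB_off <- offs[5]
  pairs <- base_pairs(
    c(
      seq_len(t_bp), # trunk strand 1 ...
      armA_off + armA$pairs_i,
      armB_off + armB$pairs_i
    ),
    c(
      n + 1 - seq_len(t_bp), # ... pairs with trunk strand 2
      armA_off + armA$pairs_j,
      armB_off + armB$pairs_j
    )
  )
  cross <- if (spec$cross_links > 0) {
    pick_cross_link(coords, armA_off + armA$loop_idx, armB_off + armB$loop_idx)
  } else {
    tibble::tibble(i = integer(), j = integer())
  }
  list(trace = ptrace(coords), pairs = pairs, cross_links = cross)
}

build_topo_cruciform <- function(spec) {
  bp <- spec$stems
  lp <- spec$loops
  lean_top <- if (spec$cross_links >= 1) LOOP_LEAN else 0
  up <- c(0, 0, 1)
  dn <- c(0, 0, -1)
  armA <- stemloop_segment(bp[1], lp[1],
    origin = c(-ARM_SEP / 2, 0, ARM_BASE_Z),
    axis = up, ref = c(1, 0, 0), phase = PHASE_TANG_PLUS_X,
    lean = c(lean_top, 0, 0)
  )
  armB <- stemloop_segment(bp[2], lp[2],
    origin = c(ARM_SEP / 2, 0, ARM_BASE_Z),
    axis = up, ref = c(1, 0, 0), phase = PHASE_TANG_PLUS_X,
    lean = c(-lean_top, 0, 0)
  )
  armC <- stemloop_segment(bp[3], lp[3],
    origin = c(ARM_SEP / 2, 0, -ARM_BASE_Z),
    axis = dn, ref = c(1, 0, 0), phase = PHASE_TANG_FRAME_V
  )
  armD <- stemloop_segment(bp[4], lp[4],
    origin = c(-ARM_SEP / 2, 0, -ARM_BASE_Z),
    axis = dn, ref = c(1, 0, 0), phase = PHASE_TANG_MINUS_X
  )
  conn <- function(from, to) {
    spline_connector(
      from$coords[nrow(from$coords), ], exit_dir(from$coords),
      to$coords[1, ], entry_dir(to$coords)
    )
  }
  linkAB <- conn(armA, armB)
  linkBC <- conn(armB, armC)
  linkCD <- conn(armC, armD)
  blocks <- list(armA$coords, linkAB, armB$coords, linkBC, armC$coords, linkCD, armD$coords)
  offs <- cumsum(c(0, vapply(blocks, nrow, integer(1))))
  coords <- do.call(rbind, blocks)
  arm_offs <- offs[c(1, 3, 5, 7)]
  segs <- list(armA, armB, armC, armD)
  pairs <- base_pairs(
    unlist(purrr::map2(segs, arm_offs, ~ .y + .x$pairs_i)),
    unlist(purrr::map2(segs, arm_offs, ~ .y + .x$pairs_j))
  )
  cross <- if (spec$cross_links >= 1) {
    pick_cross_link(
      coords, arm_offs[1] + armA$loop_idx, arm_offs[2] + armB$loop_idx
    )
  } else {
    tibble::tibble(i = integer(), j = integer())
  }
  list(trace = ptrace(coords), pairs = pairs, cross_links = cross)
}

# Build-time feasibility check: bonds near 6 A, pairs near 17 A, planted
# contacts in (10, 17], and everything else non-bonded >= 10 A.
check_topology <- function(topo) {
  trace <- topo$trace
  b <- bond_pairs(trace)
  bd <- pair_distance(trace, b$i, b$j)
  if (any(abs(bd - 6) > 1.0)) {
    rlang::abort(sprintf(
      "Construction error: bond of %.2f A (should be near 6).", bd[which.max(abs(bd - 6))]
    ))
  }
  pr <- topo$ss$pairs
  pd <- pair_distance(trace, pr$i, pr$j)
  if (any(abs(pd - HELIX_PAIR_DIST) > 1)) {
    rlang::abort("Construction error: paired phosphates off the 17 A ideal.")
  }
  if (nrow(topo$cross_links) > 0) {
    cd <- pair_distance(trace, topo$cross_links$i, topo$cross_links$j)
    if (any(cd > 17 + 1e-6) || any(cd <= 10)) {
      rlang::abort("Construction error: planted cross-link outside (10, 17] A.")
    }
  }
  sses <- detect_sses(pr)
  cand <- repulsion_candidates(trace, sses, topo$cross_links)
  cd <- pair_distance(trace, cand$i, cand$j)
  if (any(cd < 10 - 1e-6)) {
    k <- which.min(cd)
    rlang::abort(sprintf(
      "Construction error: clash between residues %d and %d (%.2f A).",
      cand$i[k], cand$j[k], cd[k]
    ))
  }
  invisible(topo)
}

#' Generate a scored synthetic contact table with planted truth
#'
#' Emulates the output of a correlated-mutation contact predictor for a
#' synthetic fixture: base pairs, planted true non-local contacts (the
#' topology's cross-links) and planted false contacts (random pairs whose
#' native phosphate distance exceeds 21 Angstroms), each in its own score
#' band so the composition of any top-k prefix is controlled. Ground-truth
#' labels are returned alongside (and written to a sidecar file by the CLI,
#' never into the contact table itself).
#'
#' @param topology an `rna_topology` from [build_topology()].
#' @param n_true_nonlocal planted true non-local contacts to include
#'   (taken from the topology's cross-links).
#' @param n_false planted false contacts.
#' @param false_min_distance minimum native distance of planted false
#'   contacts, Angstroms. The classification boundary is 21; contacts just
#'   beyond it still act as weak long-range tethers, so demonstrations of
#'   the disruptive effect of false contacts should plant them well beyond
#'   the boundary (e.g. 30).
#' @param n_basepairs base pairs to include (default all).
#' @param score_gap score separation between bands and between consecutive
#'   entries within a band.
#' @param nonlocal_first if `TRUE`, the non-local band scores above the
#'   base-pair band (so planted cross-links take the top ranks); by default
#'   base pairs score highest, mirroring the typical strength ordering of
#'   covariation signals.
#' @param seed RNG seed for the false-pair sampling.
#' @return A list with `contacts` (ranked tibble: `i`, `j`, `score`,
#'   `rank`) and `labels` (tibble: `i`, `j`, `label` in
#'   `basepair`/`nonlocal`/`false`).
#' @export
synth_predictions <- function(topology,
                              n_true_nonlocal = nrow(topology$cross_links),
                              n_false = 0, n_basepairs = Inf,
                              false_min_distance = 21,
                              score_gap = 0.1, nonlocal_first = FALSE,
                              seed = 1) {
  stopifnot(false_min_distance >= 21)
  stopifnot(inherits(topology, "rna_topology"))
  if (n_true_nonlocal > nrow(topology$cross_links)) {
    rlang::abort("Not enough planted cross-links in the topology.")
  }
  trace <- topology$trace
  L <- pt_length(trace)
  bp <- dplyr::arrange(topology$ss$pairs, .data$i)
  if (is.finite(n_basepairs)) bp <- utils::head(bp, n_basepairs)
  nl <- utils::head(topology$cross_links[c("i", "j")], n_true_nonlocal)

  fp <- tibble::tibble(i = integer(), j = integer())
  if (n_false > 0) {
    set.seed(derive_seed(seed, 77L))
    taken <- c(
      pair_key(bp$i, bp$j), pair_key(nl$i, nl$j),
      pair_key(topology$ss$pairs$i, topology$ss$pairs$j)
    )
    tries <- 0
    while (nrow(fp) < n_false) {
      i <- sample.int(L - 2, 1)
      j <- i + 1L + sample.int(L - i - 1L, 1)
      key <- pair_key(i, j)
      if (!(key %in% taken) && pair_distance(trace, i, j) > false_min_distance) {
        fp <- dplyr::bind_rows(fp, tibble::tibble(i = i, j = j))
        taken <- c(taken, key)
      }
      tries <- tries + 1
      if (tries > 2000 * n_false) {
        rlang::abort("Could not plant enough false pairs beyond 21 A.")
      }
    }
  }

  band <- function(tb, top) {
    if (nrow(tb) == 0) {
      return(tibble::tibble(i = integer(), j = integer(), score = double()))
    }
    tibble::tibble(
      i = tb$i, j = tb$j,
      score = top - score_gap * (seq_len(nrow(tb)) - 1)
    )
  }
  bands <- if (nonlocal_first) {
    list(band(nl, 30), band(bp, 20), band(fp, 10))
  } else {
    list(band(bp, 30), band(nl, 20), band(fp, 10))
  }
  contacts <- rank_contacts(dplyr::bind_rows(bands))
  labels <- dplyr::bind_rows(
    dplyr::mutate(bp[c("i", "j")], label = "basepair"),
    dplyr::mutate(nl, label = "nonlocal"),
    dplyr::mutate(fp, label = "false")
  )
  list(contacts = contacts, labels = labels)
}
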