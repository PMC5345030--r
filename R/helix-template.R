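# Ideal coarse-grained double-helix template.
#
# The engine refines consecutive phosphate/phosphate virtual bonds towards
# 6 A and holds restrained (paired) phosphates at a 17 A target, so the
# template helix is parameterised to satisfy both ideals exactly rather
# than copying literature A-form constants (which give ~5.9 A bonds):
#   - paired phosphates sit diametrically opposite on the helix cylinder,
#     so the radius is 17/2;
#   - the twist per base pair is 2*pi/11 (11 bp per turn, A-form-like);
#   - the rise is solved so the intra-strand P-P step is exactly 6 A.
HELIX_RADIUS <- 17 / 2
HELIX_TWIST <- 2 * pi / 11
HELIX_RISE <- sqrt(36 - (17 * sin(HELIX_TWIST / 2))^2)
HELIX_PAIR_DIST <- 17

# Coordinates of an ideal n_bp double helix in residue order: rows 1..n are
# strand 1 ascending (5' -> 3'), rows n+1..2n are the antiparallel strand 2,
# so that row m pairs with row 2n + 1 - m. Local frame: helix axis +z,
# strand 1 starts at phase `phase`.
ideal_helix_coords <- function(n_bp, phase = 0) {
  stopifnot(n_bp >= 1)
  k <- seq_len(n_bp) - 1
  a <- phase + k * HELIX_TWIST
  s1 <- cbind(HELIX_RADIUS * cos(a), HELIX_RADIUS * sin(a), k * HELIX_RISE)
  s2 <- cbind(-HELIX_RADIUS * cos(a), -HELIX_RADIUS * sin(a), k * HELIX_RISE)
  rbind(s1, s2[rev(seq_len(n_bp)), , drop = FALSE])
}

# Ideal intra-SSE distance template for a ladder of n_bp base pairs, with
# members ordered as c(i ascending, j ascending) -- i.e. both strands in
# residue order. Stored on each SSE at construction and used by the
# ideal-geometry refinement step.
ideal_sse_template <- function(n_bp) {
  coord_dist(ideal_helix_coords(n_bp))
}
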