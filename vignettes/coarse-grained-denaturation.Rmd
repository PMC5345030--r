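---
title: "Coarse-grained denaturation of RNA folds under sparse distance restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained denaturation of RNA folds under sparse distance restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadenature)
```

## The question the package addresses

Covariation analysis of RNA sequence alignments yields ranked lists of
predicted residue-residue contacts. Most of these recapitulate secondary
structure; only the rare *non-local* contacts — pairs between different
stem-loops, or pseudoknot pairings — carry information about the tertiary
fold. How strongly does such a sparse set of distance restraints actually
restrict the conformational freedom of an RNA molecule?

`rnadenature` answers this by inverting the folding problem: instead of
predicting structure from restraints, it starts from a *known* fold and
measures how far the structure can drift ("denature") under controlled
random perturbation, as increasingly many ranked restraints are imposed. A
restraint that genuinely pins the tertiary fold shows up as a drop in the
mean deviation of the perturbed ensemble at the rank where it enters. The
reverse experiment — restrained folding from an extended circular start —
is also provided.

## The coarse-grained model

Each nucleotide is reduced to its phosphate atom, so a molecule of length
$L$ is a chain of $L$ points in 3D. Five geometric rules, applied once per
cycle as fixed-step shifts on pairwise distances, define the dynamics:

1. **Virtual bonds.** Consecutive same-chain phosphates are refined towards
   an ideal separation of 6 Å.
2. **Secondary-structure elements (SSEs).** Ladders of three or more
   strictly consecutive base pairs — pair $(i, j)$ followed by
   $(i{+}1, j{-}1)$; any bulge terminates the ladder — are treated as rigid
   tubular elements. Every intra-SSE pairwise distance is refined towards
   an ideal double-helical template whose geometry is chosen so that
   intra-strand steps are exactly 6 Å and paired phosphates sit at exactly
   17 Å (radius $17/2$ Å, twist $2\pi/11$, rise solved from the bond
   ideal).
3. **Local window.** Distances between phosphates within a window of 10
   consecutive residues are restored towards their values in the starting
   structure — but only while the *current* distance is below an 18 Å
   gate. The gate is the designed escape hatch: once a local distance
   exceeds it, that anchor releases and large conformational changes are
   accepted.
4. **Pair restraints.** Any imposed restraint — an observed or predicted
   base pair, or a predicted tertiary contact — pulls its two phosphates
   towards a 17 Å target, *one-sidedly*: pairs closer than the target are
   never touched. All restraints are treated identically whether local or
   non-local. Unlike the gated local window, a restraint never lets go.
5. **Repulsion.** Any other pair (sequence separation at least 2, not
   within one SSE, not restrained) closer than 10 Å is pushed apart.

Per cycle, each SSE is additionally displaced by a fixed random magnitude
(the *perturbation level*, in Å) in a random direction and rotated by the
same numeric level (in radians) about a random axis through its centroid;
loop residues receive no direct kick and move only through the refinement
terms. The level is swept over $\{0.02, 0.04, 0.06, 0.08, 0.10\}$ by
`perturbation_sweep()`; 0.08 is the package default working level.

### Numerical choices

* **Step size.** Every refinement shift moves a pair's separation by at
  most `step` (default 0.5 Å) per cycle, split equally between the two
  atoms along their axis, and capped at the remaining deficit so each term
  has its target as an exact fixed point. At this size a restraint can
  close well over 100 Å of violation within a default 1000-cycle run,
  which is what the circular-start folding protocol requires.
* **Averaging conflicting shifts.** Within one term's step, corrections
  arriving at a shared atom are *averaged*, not summed. An isolated pair
  still moves by the full capped step, but summing full corrections along
  chains of shared atoms is an over-relaxation whose error-amplification
  factor exceeds one: in refinement-only runs it amplifies rounding noise
  exponentially until it saturates as a chaotic jitter that random-walks
  the whole structure by several Å per 1000 cycles. With averaging, a
  built fixture is an exact fixed point of a perturbation-free run (drift
  below $10^{-4}$ Å over 1000 cycles).
* **Order within a cycle.** Perturbation, SSE ideal geometry, bonds, local
  window, pair restraints, repulsion. Restraints are applied after the
  local terms so that an imposed cross-link wins conflicts with the local
  restoration, matching the observed dominance of imposed restraints.
* **Degenerate geometry.** Coincident phosphates separate along a fixed
  fallback axis, so refinement is defined everywhere.
* **Determinism.** Replicate seeds are derived from one master seed
  (`sim_config(seed = )`), independently per replicate and, in the
  incremental protocol, per prefix size. Identical configurations
  reproduce ensembles bit for bit.

## Restraint sets and their classification

Predicted contact lists are tibbles with columns `i`, `j`, `score`,
ranked by descending score. The number retained for a molecule of length
$L$ follows $N = 5 + \lfloor L/4 \rfloor$ (`cutoff_count()`), a rule that
runs between the 1% and 2% false-prediction error-rate curves and below
the $L/3$ line traced by thermodynamic base-pair prediction;
`error_rate_cutoff()` offers the error-rate-based alternative. Each
contact is classified against the native structure
(`classify_contacts()`), with precedence:

| category | rule |
|---|---|
| `shared_local` | among the thermodynamically predicted base pairs |
| `extra_local` | otherwise, among the nested observed base pairs |
| `non_local` | otherwise, native phosphate distance ≤ 21 Å |
| `false` | native distance > 21 Å |

A distance of exactly 21 Å counts as `non_local`; the boundary is strict
on the false side. Classification uses phosphate-phosphate distances,
consistent with the rest of the model. The nested subset of the observed
pairs is the maximum-cardinality crossing-free subset
(`split_nested()`), computed by dynamic programming over pair endpoints
with ties broken in favour of smaller `i`; whether an external annotation
would pick the same subset is not knowable from the pair list alone, so
the package states its convention and keeps it deterministic.

## Protocols

`denaturation_profile()` runs the perturbing simulation for each prefix of
the ranked restraint list (sizes $0..N$, strongest first) and records the
mean superposition RMSD of the replicate ensemble from the native
structure, along with distance-matrix measures. `control_profiles()`
repeats the procedure with the observed and the thermodynamically
predicted base-pair sets, which contain no non-local pairs and should show
no drop. `fold_trace()` starts every run from an extended circular
conformation with 6 Å chords (`make_circle_start()`), imposes the
secondary structure's pairs plus any extra contacts as one-sided 17 Å
restraints, and scores the best 10 of $n$ runs by RMSD to the native
structure. The local-window term is disabled in folding runs — its
reference would be the circle itself — which is the package's resolution
of an ambiguity in the protocol it emulates; denaturation runs keep the
term anchored to the native start.

## Deviation measures

* `superpose_rmsd()` — RMSD between equivalent phosphates after optimal
  proper rigid-body superposition (Kabsch, determinant $+1$; mirror
  images are not superposable).
* `drmsd()` — $\sqrt{\text{mean}_{i<j} (d^a_{ij} - d^b_{ij})^2}$ over all
  pairwise distances: superposition-free and blind to reflection. The
  mean over the $L(L-1)/2$ pairs (the source method prints only "sum of
  squared deviations") makes values comparable across molecule lengths.
* `drmsd_max()` — the dRMSD between the *per-pair maximum* distance matrix
  of an ensemble (`max_distance_matrix()`, the quantity plotted in
  native-vs-maximum matrix figures) and the native matrix, capturing the
  full extent of the ensemble's freedom; the alternative reading — the
  maximum of per-model dRMSDs — is `drmsd_max_permodel()`.
* `per_residue_rmsd()` — deviation along the sequence after global
  superposition of each model, used to identify which segments a
  restraint set actually holds.

## Synthetic fixtures

`build_topology()` assembles ideal-geometry toy molecules — a bare
`helix`, a `stemloop`, a `Y` (two stem-loop arms branching off a
double-strand trunk that locks the termini) and a `cruciform` (four arms
about a junction) — that are *exact fixed points* of the engine's ideals:
bonds at 6.000 Å, paired phosphates at 17 Å, non-bonded separations of at
least 10 Å except planted cross-links, which sit in $(10, 17]$ Å.

Helical segments use the engine's own template. Hairpin loops and
junction linkers are tangent-matched cubic Hermite splines resampled to
exactly 6 Å chords: matching the spline's end tangents to the helix
backbone directions places the first loop residue where the next
phosphate of the strand would have been, which keeps
sequence-separation-2 pairs outside the 10 Å repulsion shell at every
junction. (Circular-arc loops were tried first and cannot satisfy this:
with anchors 17 Å apart beside an 8.5 Å-radius stem, the arc's initial
swing re-enters the stem's repulsion shell.) Cross-linked arm pairs lean
their loop apexes towards each other through a $\sin^4$ bump that leaves
the end tangents untouched; the planted contact is the loop-residue pair
closest to 16.5 Å, just inside the restraint target, so the tether clamps
essentially at the native separation. The default Y geometry (6-bp arms,
4-bp trunk, 7-nt loops, arm axes 28 Å apart, arm bases 18 Å above the
trunk) is the smallest configuration that satisfies all of these
constraints simultaneously; the cruciform supports one planted cross-link
(between its upper arm pair), as leaning both lower loops inward as well
cannot respect the self-avoidance bound at this scale.

`synth_predictions()` emits a ranked, scored contact list with planted
composition: base pairs, planted true non-local contacts (the topology's
cross-links) and planted false contacts sampled beyond a minimum native
distance, each in its own score band, with ground-truth labels in a
sidecar table (never in the contact file itself). Two points matter for
interpreting experiments built on it:

* False contacts only marginally beyond the 21 Å classification boundary
  behave as weak but *true-ish* tethers — a one-sided 17 Å restraint on a
  pair natively at 23 Å restricts freedom almost as a genuine contact
  does. Demonstrations of the disruptive effect of false predictions
  should therefore plant them well beyond the boundary
  (`false_min_distance = 30` or more), where pulling the pair to 17 Å
  visibly distorts the fold and the profile shows the reverse transition
  (rising deviation as erroneous contacts accumulate).
* What passing fixture-based tests shows is that the machinery — ladders,
  restraints, gates, metrics, protocols — behaves as specified on
  idealised geometry. Real molecules have irregular helices, non-canonical
  pairs, and contact lists whose score ordering mixes categories; none of
  that is emulated.

## What the desk-scale fixture can and cannot show

On the default Y fixture with a planted distal loop-loop cross-link, the
cross-link demonstrably pins the arms: across perturbed ensembles the
planted pair stays at or below the 17 Å target where unrestrained
replicates let it drift past 40 Å, and restrained folding from the circle
reaches markedly lower best-10 RMSD than base-pairs-only folding
(roughly 17 vs 25 Å under default seeds).

The *profile* statistic is weaker at this miniature scale, and it is
worth being precise about why. With 6-bp arms the lever from an arm's
pivot to its tip is short, so the arm-opening mode that the cross-link
restricts contributes only a modest share of the ensemble RMSD; modes the
tether cannot restrict (axial twist of the stems, joint swings, trunk
motion) dominate, and even a fully restrained run wanders to a similar
level. The unrestrained and restrained prefix means of the test-suite
profile consequently differ by well under an Ångström, which is of the
same order as the replicate noise a 10-model mean carries for these
diffusive ensembles. The drop at the cross-link's rank is therefore
directionally expected but its *localisation* — that the single largest
profile step falls exactly at rank 1 — is not statistically reliable at
10 replicates, and the corresponding full-scale test documents this
honestly rather than relaxing its assertion. On larger molecules, where
stem-loop arms are tens of base pairs long and the opening mode dominates
the deviation, the transition is sharp; that regime is outside desk-scale
testing.

## Worked example

```{r example, eval = FALSE}
topo <- build_topology(topology_spec("Y", cross_links = 1))
preds <- synth_predictions(
  topo,
  n_true_nonlocal = 1, n_false = 9,
  false_min_distance = 30, nonlocal_first = TRUE, seed = 1
)

cfg <- sim_config(cycles = 1000, replicates = 10, seed = 1)
prof <- denaturation_profile(topo$trace, topo$ss, preds$contacts, cfg)
autoplot(prof)

fold_trace(topo$trace, topo$ss, topo$cross_links[c("i", "j")], cfg)
```

Profile and sweep computations in the package's tests use these problem
sizes (a 56-nt Y fixture, 10 replicates, 1000 cycles); unit tests exercise
the same code paths at reduced cycle counts.

## Known limitations

* Geometry only: no sequence, no base identity, no energetics or
  temperature; the perturbation is not a thermodynamic ensemble.
* The 17 Å phosphate-level restraint target treats canonical,
  non-canonical and merely-adjacent pairs identically — by design, since
  a predicted contact's pairing mode is unknown.
* Restraint files for the finer-grained five-pseudo-atom simulator are
  written (`write_simrna_restraints()`, `WELL`/`SLOPE` lines) but that
  simulator is not run or emulated.
* Multi-chain molecules are concatenated into one indexed trace; the
  local window and bond terms respect chain boundaries, but no inter-chain
  docking terms exist.
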