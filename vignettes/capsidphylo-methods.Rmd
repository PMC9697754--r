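---
title: "capsidphylo: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capsidphylo: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidphylo)
```

# Scope

`capsidphylo` turns pairwise structural comparison of homologous single-chain
proteins — viral capsid VP1s being the motivating case — into family-level
analyses: per-residue divergence maps, all-vs-all RMSD distance matrices,
structure- and sequence-based neighbor-joining trees, and host-annotation
reports. Everything operates on Cα traces; side chains, maps and model
refinement are out of scope, as are likelihood-based phylogenetics.

# Rigid superposition and the core RMSD

The elementary operation is the least-squares rigid fit of matched Cα sets
(`kabsch_superpose`): centroids are subtracted, the 3×3 covariance is
decomposed by SVD, and the sign of the smallest singular vector is flipped
whenever the rotation would otherwise be improper. Chirality is therefore
always preserved; a mirrored copy of a structure does *not* superpose to
RMSD 0. Degenerate inputs (fewer than 3 points, mismatched lengths) are
rejected up front. The unit throughout is the Ångström.

Published pairwise comparisons typically quote an RMSD "over k Cα" with k
well below the chain length, implying that some subset selection rule was
applied by the comparison tool. No such rule is printed with the values this
package is designed to reproduce, so `core_rmsd` states one explicitly and
makes it configurable: superpose on the current pair set, drop pairs
deviating by more than `core_cutoff`, and repeat to a fixed point. The
default cutoff is 4.0 Å — comfortably above secondary-structure breathing,
comfortably below loop-scale divergence. `core_cutoff = Inf` reproduces the
plain all-pair RMSD; a core that falls below 5 pairs is an error rather than
a number, since an RMSD over a handful of atoms is not meaningful. Because
different tools select cores differently, reproduction of published values
should always be reported together with the achieved core size.

# Structure-based correspondence

`pair_align` derives the residue correspondence iteratively, in the style of
TM-align: score matrix `S(i,j) = 1 / (1 + (d_ij/d0)^2)` after the current
superposition, affine-gap dynamic programming over S, re-superposition on
the new pairs, until the pair set is stationary or `max_iter` (default 20)
is reached. Two seeds are tried — a global Needleman–Wunsch alignment of the
amino-acid sequences under BLOSUM62 (affine gaps −11/−1, the standard
BLOSUM62 scale), and the best gapless threading of one chain along the
other — and the best-scoring refinement wins. The threading seed is what
makes the procedure robust when sequences have diverged beyond easy
alignability, which is precisely the regime that motivates structural
phylogenies.

Parameters (all in `align_params()`):

* `d0 = 5.0` Å — the distance scale of the TM-style score. Pairs closer
  than d0 score near 1, pairs much beyond it near 0; 5 Å keeps
  well-superposed cores strongly favored while letting diverged loops
  contribute weakly.
* `gap_open = −1.0`, `gap_extend = −0.1` — on a score bounded by 1 per
  matched pair, an opening cost of 1 means a gap must "buy" at least one
  well-matched pair; these defaults keep toy alignments stable and are
  deliberately mild, since structural gaps are real features of diverged
  loops.
* Dynamic-programming tie-breaks are fixed (match preferred over gap-in-A
  over gap-in-B), so alignments are deterministic.
* The structural DP uses free end gaps (chains of different lengths align
  without penalty for overhangs); the sequence seed uses global alignment.

`pair_align` fails loudly if no correspondence of at least 5 pairs exists —
silent misalignments would otherwise propagate into every distance matrix.

# Divergence profiles

`per_residue_deviation` measures, for every matched reference residue, the
Euclidean Cα–Cα deviation under a *single global* superposition. There is no
per-window refitting: local refits would hide exactly the loop excursions
the profile exists to show. `windowed_profile` optionally smooths by the
root mean square over a centered odd-width window on matched residues; the
default window is 1 (no smoothing), since the per-residue plots being
emulated state no smoothing. `average_profiles` takes the arithmetic mean
per residue over the profiles in which that residue is present — a residue
is missing only if missing everywhere, so a partially covered family still
yields a full-length map. `region_summary` reports mean/max/n over named
regions; region definitions for the VP1 CD, E₁E₂ and EF loops ship as an
editable TSV (`inst/extdata/vp1_loops.tsv`) keyed to CsfrRNAV VP1 author
numbering, because the loop boundaries are published only graphically —
treat those spans as defaults to refine, not as measurements.

The conformationally variable N-terminal arms are removed before distance
calculations with `trim_nterm_arm`. The boundaries are per-structure inputs:
no universal residue number exists across homologs, so the package refuses
to guess them.

# Distance matrices and trees

`all_vs_all_matrix` computes each unordered pair once (i < j) — symmetry by
construction — and feeds core RMSDs in Å to the tree builder unnormalized,
matching the published procedure of using "the obtained RMSD values" as the
distance matrix. RMSD is not a metric (the triangle inequality can fail),
and the package deliberately does not assert it.

`nj_build` implements Saitou–Nei neighbor joining in full: the Q criterion,
the rate-corrected branch-length split, and the distance reduction formula.
Determinism is guaranteed by an explicit tie rule — among tied minimal Q
pairs, the pair earliest in label-sorted order is joined (internal nodes are
ranked by the smallest leaf label beneath them). Negative branch lengths are
clamped to zero with the deficit moved to the sibling branch, preserving the
pairwise path length of the joined pair. On an additive matrix the
generating topology and all branch lengths are recovered exactly (this is a
tested invariant). UPGMA is available behind a flag purely for sensitivity
analysis.

Sequence trees use p-distances — the proportion of differing sites over
columns where neither row is gapped — because the published tree states no
substitution model and p-distance is the plainest choice consistent with a
distance-based NJ tree; a Poisson correction (−log(1−p)) is available behind
a flag. The progressive aligner (`progressive_msa`) builds a guide tree by
NJ on fractional common-k-mer distances (k = 3) and merges blocks by
profile–profile Needleman–Wunsch under BLOSUM62; duplicate sequences are
collapsed before alignment and re-expanded afterwards, which both speeds
things up and makes the result invariant under added duplicates. The
aligner targets topology-level fidelity of downstream distances, not
column-identical agreement with production aligners such as MUSCLE.

`bootstrap_support` resamples alignment columns with replacement, rebuilds
NJ on each replicate, and scores each internal bipartition of the full-data
tree by the percentage of completed replicates containing it. Replicates in
which some pair retains no comparable column are skipped, counted and
reported (warning plus an `n_skipped` attribute); supports are percentages
of completed replicates, since a degenerate resample carries no information
about any split. The replicate default is 1000; the test suite uses 100 to
stay fast.

`host_monophyly` reports, per host taxon, whether its leaves form one side
of a bipartition of the unrooted tree, plus a best-clade purity: the
maximum over bipartition sides containing *all* the host's leaves of
(host leaves / side size). Purity is 1 exactly when the host is
monophyletic, and a single stray leaf inside the smallest enclosing clade
drives it below 1. (A purity over sides containing merely *some* host leaf
would be degenerate — any pendant edge of a host leaf would give 1 — so the
all-leaves reading is used.)

# The synthetic family generator

`sim_family` gives every downstream stage a ground truth. Its model:

* a random unrooted binary topology by sequential leaf addition, branch
  lengths i.i.d. exponential with mean 0.1;
* coordinates evolve by Brownian displacement: per edge of length t, each
  residue receives i.i.d. Gaussian noise N(0, σ²·t·wᵢ) per coordinate, with
  wᵢ = 4 inside a designated "loop" segment (default: 40–52% of the chain)
  and 1 elsewhere — emulating the loop-concentrated divergence seen on real
  capsid surfaces; each leaf then gets a random rigid transform, so the
  superposition machinery is genuinely load-bearing in every test;
* sequences evolve by a Poisson process: per edge, each site substitutes
  with probability 1 − exp(−rate·t), uniformly over the other 19 residues;
* hosts are the clades hanging off the tree's basal node;
* optional N-terminal deletions (uniform up to `terminal_indel_max`,
  default 0) are applied consistently to sequence and structure, to
  exercise offset handling in the aligner.

Defaults — 12 taxa, 250 residues, σ = 0.4 Å, 0.3 substitutions/site, both
per unit branch length — describe a family of the size and divergence the
pipeline targets. The base fold is an idealized helical trace (rise 1.5 Å,
radius 2.3 Å, 100°/residue); note that a *perfect* helix is invariant under
its own screw operation, so tests that need a unique correspondence jitter
the base fold first.

What the generator does not emulate: real secondary-structure geometry,
internal indels, correlated sequence–structure divergence beyond the shared
tree, and assembly-level (capsid lattice) context. Passing tests therefore
demonstrate the pipeline's correctness on tree-structured divergence, not
that any particular biological family will be recovered perfectly.

## A known structural limitation: RMSD is not tree-additive

Under Brownian coordinate evolution the *squared* deviation is additive
along the tree, so the RMSD between two leaves grows like the square root
of the path length between them. A square root of an additive metric is no
longer additive, and neighbor joining is only guaranteed exact on
(near-)additive inputs. Consequently, even with perfectly measured RMSDs,
NJ on an RMSD matrix can misplace splits — increasingly so for deep
divergences, where the compression is strongest. The same caveat applies to
uncorrected p-distances, which saturate with path length. The acceptance
script quantifies both effects honestly: it reports the fraction of
simulated families (at the default conditions) whose structure- and
sequence-trees exactly match the generating topology, and those fractions
are substantially below 1 for this reason, not because of implementation
error — the same script shows NJ recovering *additive* matrices exactly,
and the unit tests show correspondences and alignments are exact on these
families. Users should read published structure phylogenies with the same
caution: an RMSD matrix orders neighbors well but is not an evolutionary
distance.

# Numerical and I/O choices

* Altloc resolution keeps the highest-occupancy alternate, ties broken by
  the lexicographically smallest altloc identifier; HETATM records are
  ignored and only the first MODEL of a multi-model file is read.
* B-factors are interpreted as pLDDT confidences only when the caller flags
  the file as a predicted model — experimental B-factors are never
  mistaken for confidences.
* Insertion codes order after their bare residue number; residue numbering
  is 1-based author numbering and all ranges are inclusive, matching the
  "A34–L275" style of structural papers.
* FASTA input is uppercased, `*` stripped, gaps rejected outside alignment
  context; output wraps at 60 columns.
* Newick supports travel as internal-node labels; branch lengths survive a
  round trip to at least 1e-9.
* Emitted PDB files carry standard 3-decimal coordinates, so coordinate
  round trips are exact to 5e-4 Å.
* The pipeline configuration is YAML (a single file, CLI flags mirroring
  it); the run directory receives every artifact plus a plain-text log and
  a JSON manifest with all parameters and the seed, and reruns are
  byte-identical for a fixed configuration and seed.

# Problem sizes used in validation

The shipped validation works at sizes a laptop handles in minutes: 100
random 8-point sets against an independent quaternion-eigenvalue RMSD
oracle; 50 random additive matrices of 6–10 taxa for NJ; 10 simulated
families at the default conditions (12 taxa × 250 residues) for end-to-end
recovery; 100 bootstrap replicates where the published analysis used 1000.
These sizes were chosen as the smallest at which each property is sharply
testable; all are parameters, not limits.

# Reproducing published capsid numbers

The package can reproduce published pairwise VP RMSDs (e.g. VP1 core RMSD
with an explicit core rule) and loop-divergence profiles when the deposited
coordinate sets are supplied as PDB-format files under
`inst/extdata/depositions/` — they are too large to ship and must be
fetched from the public archives. Algorithmic differences from the
originally used aligners (MUSTANG, TM-align's own DP) mean agreement is
expected within ~0.15 Å on core RMSDs, with core sizes reported alongside.
The corresponding test states exactly which files it needs and fails
informatively when they are absent rather than passing silently.
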