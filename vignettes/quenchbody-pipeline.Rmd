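---
title: "Designing and evaluating nanobody quenchbodies with quenchkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating nanobody quenchbodies with quenchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchkit)
```

## The problem

A quenchbody is an antibody fragment carrying a fluorophore on a short
N-terminal tether. In the antigen-free state the dye docks onto
tryptophan side chains in the antigen-binding loops (CDRs) and its
emission is quenched by photo-induced electron transfer (PET), which is
effective at donor--acceptor separations of roughly 10 angstrom or
less. Antigen binding sterically displaces the dye, emission recovers,
and the ratio of bound to free intensity -- the *fold-sense* -- becomes
a wash-free readout of antigen concentration. Nanobodies (VHH domains,
~15 kDa) are attractive quenchbody scaffolds, but their sensing
performance depends on where tryptophans sit in the CDRs and how the
dye samples them.

quenchkit implements the computational workflow for engineering such
sensors: quantifying dye--tryptophan proximity from structural
trajectories, planning tryptophan substitutions, building randomised
selection libraries in silico, scoring multi-round selection
sequencing, and analysing plate titrations. Each stage has a paired
synthetic-data generator so the entire pipeline can be exercised and
validated without any external dataset.

## Quench geometry

For a trajectory (multi-model PDB or XYZ; one file per replicate) the
package computes, per frame, the Euclidean distance between the
mass-weighted centre of mass (COM) of the dye and the COM of each
candidate quencher residue, plus the frame-wise minimum over quenchers
("distance to any quencher"). The *quench-time fraction* is the
proportion of frames at or below the cutoff, reported per replicate and
aggregated as mean ± sample SD (n−1) over replicates -- the same
dispersion convention used for the plate assays.

Choices a user should know about:

* **Cutoff**: 10 angstrom, *inclusive*. The PET literature gives an
  approximate threshold, not an inclusivity convention; a frame at
  exactly 10.0 counts as quenched here.
* **COM granularity**: whole-residue heavy atoms for quenchers and all
  heavy atoms of the dye residue. A `sidechain_only` flag drops
  backbone atoms (N, CA, C, O) for users who prefer side-chain COMs;
  for tryptophan the two differ by well under a bin width in typical
  geometries.
* **Histograms**: 0.5-angstrom bins on [0, max distance],
  count-normalised so the bin masses sum to 1. With the cutoff on a
  bin edge, the histogram mass below the cutoff reproduces the raw
  quench fraction to within one bin's mass.
* **Framework exclusions**: buried framework tryptophans (canonically
  position 36 in contiguous VHH numbering) cannot engage the dye and
  are excluded from the quencher set by default.
* **No periodic-boundary handling**: input trajectories are assumed
  whole and unwrapped. Re-image before analysis if needed.

`compare_states()` contrasts apo and antigen-bound profiles; the
any-quencher fraction difference (apo − bound) is the design score: a
promising quenchbody spends most of its apo time quenched and almost
none once bound.

## Scaffold design

`annotate_cdrs()` accepts user-supplied CDR intervals (the reliable
route) or locates them from conserved VHH framework anchors: the
framework-1 cysteine, the `W[FIVY]RQ` framework-2 tryptophan motif, a
canonical 14-residue framework 2, the `RF[TS]IS` framework-3 start, the
framework-3-terminal `YYC` cysteine, and the *last* `WG.G` match as the
J-segment start (tryptophan-rich CDR3s can contain `WG.G` internally,
so the first match is not safe). Sequences without these anchors are
refused with a pointer to user mode. Display numbering is 1-based
contiguous over the mature sequence; IMGT/Kabat renumbering is out of
scope, and numbering is strictly per-record -- position 110 in one
nanobody is not assumed to correspond to position 110 in another.

`enumerate_candidates()` proposes knockouts (CDR tryptophans, default
substitution tyrosine to preserve aromatic character, alanine as an
option) and reverse substitutions (CDR tyrosines to tryptophan).
`apply_plan()` mutates protein and, when present, DNA by the
minimal-nucleotide-change rule with alphabetical tie-break, so mutants
stay as close as possible to the parent gene. `check_scaffold()`
verifies the optimised constellation -- tryptophans at 59 (CDR2) and
101, 103, 110, 115 (CDR3) -- and `trp_scaffold()` ships a synthetic
consensus-framework record carrying it, which also serves as ground
truth for the annotation heuristic.

Stability screening of plans is represented as an optional
user-supplied score table; the package computes no folding energies.

## Library construction

Three library modes mirror the selection campaign designs:

* **full_trim** -- every listed CDR position is replaced by a codon
  drawn from a trimer (TRIM) alphabet. The default alphabet is 19
  amino acids (no cysteine) with uniform weights and one preferred
  codon per amino acid; this is a documented stand-in, since commercial
  TRIM mixes vary, and it is fully configurable. Stop codons are
  excluded by construction.
* **single_codon_maturation** -- exactly one randomly chosen codon per
  CDR is randomised per variant (light-touch affinity maturation).
* **cdr_shuffle** -- each child draws CDR1/2/3 cassettes uniformly from
  parent pools over one shared framework.

`assemble_cassette()` wraps a variant in the fixed expression elements:
fixed forward/reverse PCR handles, a T7 promoter/terminator and
ribosome-binding spacer (canonical defaults, all configurable). Golden-gate
assembly chemistry is modelled as concatenation: only final sequence
identity matters computationally. Sampling is bit-reproducible under a
seed.

## Selection analysis

Selection campaigns report pass rates for correctly assembled genes,
but rarely a concrete filter, so the filter is *defined* here and
every criterion is toggleable and counted separately: both constant
anchors present in order on either strand; the enclosed region a whole
number of codons starting ATG and translating without internal stops;
the four framework segments matching the reference (0 mismatches by
default); CDR lengths within the allowed set. Variant identity is the
translated protein (silent DNA variants merge). Quality strings are
ignored by design -- the filter is sequence-based -- and malformed
FASTQ records are skipped and counted, never silently.

Per-round abundances are counts over the round's passed reads. The
enrichment score is final-round abundance divided by blank-control
abundance, with absent-from-blank variants assigned the pseudo-floor
1/(blank total + 1) -- a conservative upper bound on an unobserved
abundance that keeps scores finite. Hits follow two
rules: score > 200, or top-12 by final-round abundance; ties break
lexicographically so hit lists are deterministic. The final round
defaults to the last round present and is overridable, since maturation
screens are often scored at an earlier round than primary screens.

`droplet_loading()` gives the Poisson occupancy statistics of droplet
encapsulation (lambda = C·N~A~·V); at ~125 pM in ~1.33 fL droplets,
lambda ≈ 0.1 genes/droplet and fewer than 0.5% of droplets carry more
than one gene, preserving the genotype--phenotype link.

## Plate assays

`fold_sense()` divides every well by the mean of the 0 nM wells;
per-concentration SD is computed over replicate ratios (not propagated
from raw SDs), and the maximal mean fold is the headline number. The
normalisation makes the result invariant to global instrument scaling.

`fit_binding()` background-subtracts the 0 nM mean and fits
S(c) = B~max~·c^h^/(EC50^h^ + c^h^) by Levenberg--Marquardt least
squares on per-concentration means with uniform weights, h free.
Initialisation is a multi-start grid (7 log-spaced EC50 values across
the tested range × h in {0.5, 1, 2}); the best converged start by RSS
wins. Flat responses are refused as unidentifiable rather than fitted.
The fitted EC50 is reported as the binding-affinity (K~D~) proxy, the
convention used for these sensors. Fitting raw background-subtracted
means and fitting fold-normalised means give the same EC50 (the
transform is affine); the package fits whichever representation it is
given.

`detection_limit()` runs a one-way ANOVA over concentration groups and
Tukey HSD comparisons; only the comparisons against the 0 nM group are
consulted (the full ANOVA error term and studentized-range correction
over all groups are retained), alpha = 0.05. The limit is the lowest
significant concentration; a non-monotone significance pattern above it
is reported with a warning rather than hidden. Flat data (zero residual
variance) yields an undefined limit, not a spurious one.

`labelling_stoichiometry()` implements the corrected-absorbance
arithmetic: protein = (A280 − 0.178·A555)/47,000, dye = A555/90,000,
DOL = 100·dye/protein, with explicit clipping/undefined-DOL behaviour
at the boundaries.

## Synthetic data: what it emulates, and what it does not

`simulate_trajectory()` models the dye end-point as an isotropic
Gaussian around the tether anchor (scale sigma), with fixed quencher
positions; the antigen-bound state adds an occlusion sphere that
rejection-samples the dye out of the quencher-proximal region. The
default geometry (sigma 4 angstrom; three quenchers 6.5--8 angstrom
from the anchor; occlusion sphere of radius 12 centred on the quencher
cluster) yields an apo any-quencher contact fraction of ~0.68 and a
bound fraction of ~0.11 at the 10-angstrom cutoff -- the qualitative
regime observed for working quenchbodies, between the strongly
switching and weakly switching systems that motivated the design. The
generator's analytic contact probability comes from midpoint-rule
quadrature of the Gaussian on a 161³ grid over ±6 sigma -- deliberately
not Monte Carlo, so the sampled trajectories are checked against an
independent numeric oracle. Written trajectories use mass-balanced
3-atom pseudo-residues for dye and quenchers so COM code paths are
exercised with non-trivial masses. This is controllable statistics, not
physics: no excluded volume (a hard-sphere option is off by default),
no tether chain entropy, no dye photophysics, and passing tests say
nothing about force-field accuracy on real systems.

`simulate_selection()` draws round-r counts from a multinomial with
probabilities proportional to realised round-(r−1) frequencies times
fitness, starting uniform. Junk reads are cassettes with a single
nucleotide deleted inside a CDR -- guaranteed frameshifts, so the
filter's frame criterion is specifically exercised -- rather than
random DNA. Uniform per-base substitution error is available but
defaults to 0; real sequencer error profiles, paired ends and UMIs are
out of scope.

`simulate_plate()` generates I0 + Hill signal + Gaussian noise (SD as a
fraction of B~max~) over the standard 14-point concentration grid (0,
1, 2, 4, 8, 16, 32, 64, 125, 250, 500, 1000, 2000, 4000, 8000 nM) in
triplicate; defaults emulate a well-behaved titration (EC50 14 nM,
h = 1, plateau 1.5× baseline).

All generators are bit-reproducible under a fixed seed and emit ground
truth beside the data.

## Validation scale and numerical notes

The test suite validates each operation against independent oracles:
direct-sum COM computation, brute-force per-frame distance
recomputation, hand-counted quench fractions, occupancy/birthday
combinatorics for library diversity, studentized-range hand
computations for Tukey p-values, and closed-form Poisson and
labelling arithmetic. Property checks run at desk scale chosen for
sub-minute runtimes: 10^4 frames for trajectory convergence (within 3
binomial SEs of the quadrature value), 10^4 reads for pass-rate
recovery, 2×10^4 reads/round × 5 rounds for the fitness-monotonicity
rank correlation (≥ 0.9), and 200 replicate fits for EC50 noise
robustness (median error < 25% at 5% noise, triplicate wells).
Noiseless Hill fits recover EC50 across 1--1000 nM within 1% on the
standard grid.

Degenerate inputs are handled explicitly rather than silently: empty
atom selections, missing quenchers, mismatched state profiles, flat
titrations, single-replicate significance requests, zero-protein DOL
and support-covering occlusion spheres all raise informative errors.

## Limitations

* CDR annotation is heuristic outside canonical VHH frameworks; supply
  intervals for engineered or exotic scaffolds.
* Exact-match protein collapse means sequencing errors inflate variant
  counts; there is no error clustering.
* The Hill fit uses per-concentration means with uniform weights;
  strongly heteroscedastic plates may warrant user-supplied weights.
* The trajectory reader supports multi-model PDB and XYZ only; convert
  binary MD formats upstream.
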