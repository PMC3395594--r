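---
title: "Methods: evolution-guided design of deregulated allosteric sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolution-guided design of deregulated allosteric sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosite)
```

## The scientific problem

Catalytic residues must perform chemistry and are therefore under strong
purifying selection; allosteric pockets merely bind a regulator, and
their residues drift across species as regulatory needs change. Two
consequences follow. First, within one enzyme the allosteric site sits
between the catalytic site and the bulk surface on the conservation
scale. Second, allosteric pockets are enriched in hydrophobic residues
with only a few charged residues anchoring the (typically anionic)
effector. `allosite` operationalizes both observations: mutate the
*variable*, *charged or large-contact* residues of an allosteric pocket
into *similar-volume neutral residues that rarely occur at that
alignment position*, and the effector loses its grip while catalysis is
untouched. The package covers the full analysis loop — conservation
scoring, structural classification, enrichment statistics, candidate
design, and kinetic verification of the resulting inhibition constants.

## Conservation scoring

`filter_homologs()` reproduces the usual homolog-curation rules before
scoring: candidates more than 95 % identical to the query are discarded
(they carry no divergence signal), candidates shorter than 60 % of the
query are discarded (fragment alignments distort column statistics), and
remaining redundancy is removed by greedy longest-first clustering at
95 % pairwise identity. Identity is defined as matches over the length
of a global alignment with affine gap penalties (BLOSUM62, open 10,
extend 0.5) — the convention of the standard clustering tools. The
thresholds are exposed as arguments; the defaults are the conventional
values above.

`score_conservation()` scores each query-ungapped column. The default
is the Jensen–Shannon divergence (base 2, hence in [0, 1]) between the
column's amino-acid distribution and a fixed BLOSUM62-derived background;
the alternative is one minus the normalized Shannon entropy. The
established conservation servers in this area use Bayesian evolutionary
rate estimation; published method comparisons show the alternative
scores agree on the catalytic/allosteric contrast, and JSD is
deterministic, fast, and dependency-free, so it is the default here. Columns are weighted with
Henikoff position-based sequence weights so that clusters of near-identical
homologs do not dominate; gaps are excluded from the distribution, and
columns with more than 50 % gaps are flagged low-confidence rather than
dropped (the information is weak but not absent).

`percentile_normalize()` maps raw scores to `(rank − 1)/(N − 1)` with
average ranks for ties. Normalization is computed over **all** residues
of the analyzed chain, not over any subset being compared: the purpose
of the percentile step is cross-protein comparability, which requires a
fixed within-protein reference population. The transform is
order-preserving and idempotent, so re-normalizing a normalized profile
is harmless.

`map_to_structure()` transfers scores onto structure numbering through a
global alignment and refuses to map below 90 % identity over the aligned
region — a mismatched chain is an analysis error, not something to paper
over.

## Structural site classification

`classify_sites()` applies the structure-derived definitions: a residue
is *catalytic* when any of its heavy atoms lies within 6.0 Å
(inclusive) of a heavy atom of the substrate ligand, *allosteric* when
within 6.0 Å of an allosteric effector and not catalytic (catalytic
precedence, with a dual-contact flag), *surface* when neither and its
relative solvent accessibility exceeds 0.50, and *other* otherwise.
Hydrogens are ignored throughout — deposited crystal structures rarely
have them and the distance convention is heavy-atom. Waters are
stripped; for alternate locations the highest-occupancy copy is kept.

SASA is computed with the Shrake–Rupley method: a deterministic
golden-spiral point set (default 960 points) on each atom's
probe-expanded sphere (probe 1.4 Å), with standard van der Waals radii
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å). Relative accessibility
divides residue SASA by its theoretical maximum in an extended
Gly-X-Gly context, so values may slightly exceed 1 for unusually exposed
residues. At 960 points per atom the per-residue values are converged to
well under 2 % against a 3840-point reference on the test fixtures, and
an isolated atom reproduces the closed form 4π(r + 1.4)² to numerical
precision. Residue–ligand contact areas are computed by difference:
SASA of the residue with the ligand deleted minus SASA with it present.

Oligomeric structures are analyzed per subunit by default (`chain`
argument): binding-site residue counts in the literature are almost
always per-subunit accountings, but which subunit and which ligand
copies were counted is rarely stated, so the choice is exposed rather
than hard-coded.

## Statistics

Class comparisons use the Mann–Whitney U test (conservation scores are
bounded and non-normal) — exact when the combined sample is ≤ 20 without
ties, otherwise normal approximation with tie and continuity
corrections — and a two-sided variance-ratio F test for the *spread* of
conservation in allosteric versus catalytic sites. Composition
enrichment uses Fisher's exact test per amino acid (and per charged /
hydrophobic / other group) with the point-probability two-sided
convention, the dominant convention in scientific software; odds ratios
are sample cross-product ratios with a Haldane 0.5 correction at zero
cells; Holm-adjusted p-values accompany the raw ones across the 20
per-amino-acid tests. The wrappers delegate to the standard base-R
implementations; the test suite checks them against independent
enumeration oracles on small instances and verifies their size under
null simulations.

## Mutation design

The three design rules are implemented as:

1. **Variable positions**: allosteric-class residues with normalized
   conservation < 0.5 (`select_candidates()`, threshold exposed). The
   rule is anti-monotone in the threshold by construction.
2. **Selectivity residues**: the candidate record flags charged wild
   types ({D,E,K,R,H}) and large ligand-contact areas (≥ 40 Å², which
   covers the tyrosine-scale contact patches seen in effector pockets).
3. **Rare, similar-volume, neutral replacements**: proposals come from a
   fixed wild-type → substitution table anchored to experimentally
   successful deregulating substitutions (K→Q/I/M, R→I/M/Q, Y→F/I, …),
   are filtered to alignment-column frequency < 0.05 (successful
   deregulating substitutions average ~3 % column frequency; 5 % is a
   permissive ceiling), and are ranked by absolute side-chain volume
   difference (Zamyatnin volumes), then ascending column frequency, with
   residue number as the deterministic tie-break.

`design_report()` additionally evaluates a retrospective outcome table
when one is supplied: attempted mutations are partitioned at the
conservation threshold and, when per-mutation success labels exist, the
success × partition 2×2 table is tested with Fisher's exact test. The
packaged FBPase record ships residue-level outcomes only (which
individual substitutions succeeded is not recoverable from the published
table), so per-mutation labels are user-supplied.

## Kinetics

Equation 1 is the Hill model `v = V_max·S^H/(K_m^H + S^H)`; Equation 2
multiplies it by a noncompetitive inhibition factor `1/(1 + I/K_i)`.
The literature phrase "nonlinear noncompetitive inhibition" does not pin
down the inhibitor exponent, so `inhibition_velocity()` exposes `h_I`
(default 1, the classical hyperbolic term); parameter-recovery results
are self-consistent under either choice. `H` is estimated from the
uninhibited data and held fixed in the Eq. 2 fit, matching the standard
two-stage protocol, and is refit per dataset rather than shared across
genotypes.

Fitting is Levenberg–Marquardt least squares on log-parameters
(positivity by construction) with method-of-moments starting values
(`V_max` from the velocity ceiling, `K_m` from the half-saturation
point, `K_i` from inverted velocity ratios at matched substrate) and up
to 10 log-spaced multi-starts; the best residual sum of squares wins.
Fits with R² < 0.95 are flagged poor — the conventional floor for
accepting titration fits. Noise-free data are recovered to ~1e-9
relative error, and fits are invariant to row order and to velocity-unit
rescaling (K_i unchanged, V_max rescaled).

Fold changes are ratios of mean K_i with a Welch t-test on log K_i
across replicate fits — K_i ratios are multiplicative, so the log scale
is the right place for a location test. `activity_grid()` evaluates the
relative activity `1/((1 + I_A/K_iA)(1 + I_G/K_iG))` over a
two-inhibitor grid (default 0–500 µM × 0–5000 µM) under independent
multiplicative inhibition terms; this is a model-based extrapolation —
the single-inhibitor fits do not constrain an interaction term.

## Synthetic data: what it does and does not show

`gen_msa()` draws each non-query row per column from class equilibrium
frequencies with probability `rate`, else copies the query. This is not
a phylogenetic simulator — there is no tree, no rate matrix, no
autocorrelation — but it produces exactly the conserved/variable column
contrast the scoring stage must detect, with rate 0.05 emulating
catalytic-like columns and 0.8 surface-like ones. Passing tests
demonstrate the scores rank such columns correctly; they do not
demonstrate robustness to phylogenetic correlation or alignment error.

`gen_toy_structure()` builds widely spaced poly-residue backbones with
side-chain pseudo-atoms, one ligand heavy atom per assigned residue
placed at the target distance (verified to ±0.1 Å; distances below the
van der Waals contact sum are rejected), and occluding atom cages around
residues planned as buried. Only distances and accessibility matter
downstream, and those are exact by construction; the models have no
conformational realism.

`gen_kinetic_data()` multiplies model velocities by `(1 + ε)`,
ε ~ N(0, CV), truncated at zero — proportional error is what velocity
assays show, and published fits with R² > 0.95 imply a small CV; the
default is 5 %. The recovery study (`simulate_ki_recovery()`) uses 8 × 8
concentration grids spanning 0.2–5× the respective constants (each
genotype's inhibitor range spans its own K_i — a mutant with a 170-fold
larger K_i must be titrated on its own scale to be identifiable), 3
replicates, and 20 simulated dataset pairs per design; medians of the
fitted mutant/WT ratios sit within a few percent of the generating fold
changes at this size. All generators take explicit integer seeds and
restore the global RNG state.

## Degenerate inputs and numerical choices

Empty candidate sets filter to empty results with a warning (not an
error); single-position profiles cannot be percentile-normalized;
scoring requires at least two non-query rows; Eq. 2 fitting refuses
all-zero inhibitor data (K_i unidentifiable) and requires an I = 0
series; the variance-ratio test refuses a zero-variance denominator.
Distance cutoffs are inclusive (a residue at exactly 6.00 Å is in the
site). Ties in candidate ranking break by residue number.

## Known limitations

- Conservation is column-independent: no coevolution, no tree-aware rate
  inference.
- Per-subunit site counts on deposited oligomers are sensitive to chain
  and ligand-copy conventions; the package exposes them but cannot guess
  the convention used for any particular published count.
- The two-inhibitor activity surface assumes independent inhibition
  terms.
- The substitution table encodes prior experimental practice; it is a
  starting point, not a ΔΔG predictor — no structural modeling of the
  proposed mutants is attempted.
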