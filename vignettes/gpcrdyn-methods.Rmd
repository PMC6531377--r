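---
title: "Methods: conformational-state analysis of receptor MD ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-state analysis of receptor MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrdyn)
```

## Scope and data model

`gpcrdyn` analyses multi-run molecular dynamics ensembles of a receptor
(typically a GPCR) in one or more conformational states and quantifies what
distinguishes those states: torsional entropy of the extracellular and
intracellular regions, allosteric communication pathways inferred from
torsion-angle mutual information, ligand--receptor contact statistics,
flexibility (RMSF/B-factor) maps, binding-pocket volume, activation-state
projections, and ligand-binding free energies estimated from alchemical
work samples. The package does not run molecular dynamics; it consumes a
PDB topology plus per-run coordinate series (a documented plain-text
dialect, exact under round-trip) and, for free energies, per-window
forward/reverse work values.

Two conventions run through every module:

* **Replicate ensembles with a trailing analysis window.** A state is
  represented by several independent production runs. Analyses use only the
  trailing fraction of each run (`select_analysis_frames()`, default 0.5,
  mirroring the common practice of discarding the first half of each
  replicate as residual equilibration), applied per run so that no window
  ever straddles a run boundary. Frames from all runs are then pooled;
  every histogram-based statistic is ordering-invariant, so pooling is
  exactly equivalent to per-run accumulation.
* **1-based author residue numbering.** Region definitions ("I64-L78") are
  inclusive ranges over PDB author numbering. Insertion codes are rejected
  rather than silently misread.

## Torsional entropy

For each torsion (backbone $\phi$, $\psi$, and side-chain $\chi_1$ where
the atoms exist), angles are binned into $M$ equal bins over the circle and
the first-order Gibbs entropy is

$$S_{\mathrm{raw}} = -\sum_{k=1}^{M} p_k \ln p_k, \qquad
S = S_{\mathrm{raw}} + \frac{M_{\mathrm{occ}} - 1}{2N},$$

in units of $k_B$ (nats). The additive term is the Miller--Madow
undersampling correction, with $M_{\mathrm{occ}}$ the number of occupied
bins and $N$ the sample count; it cancels the leading $O(1/N)$ downward
bias of the plug-in estimator. The correction is switchable
(`correction = "none"`) because different published torsional-entropy
protocols use different finite-sampling corrections and the choice should
be explicit in any comparison. Bond and angle degrees of freedom are
ignored throughout — their contribution to conformational entropy
differences is small compared with torsions.

**Bin count.** The default is $M = 30$ (12° bins). That is the common
resolution for side-chain rotamer work: wide enough that $10^4$--$10^5$
frames populate the histogram well, narrow enough to resolve the three
staggered $\chi_1$ wells. With fewer than $M$ samples the estimator warns.

Region entropies (extracellular vs intracellular) are sums of corrected
per-torsion entropies over all torsions of all residues in the region, with
per-loop subtotals when the region carries loop definitions. The A2A
adenosine receptor region tables (EC/IC loops including two helical turns,
orthosteric binding site, G-protein interface, broad EC region) ship as a
plain-text fixture (`load_region_fixture("A2AR")`).

## Mutual information and allosteric pathways

Pairwise MI between two torsions uses the same histogram estimator on the
$M \times M$ joint grid:

$$\widehat{I}(a, b) = \widehat{S}(a) + \widehat{S}(b) - \widehat{S}(a, b),$$

with the undersampling correction applied to each term. The corrections
nearly cancel the classical $\,(M_a M_b - M_a - M_b + 1)/2N$ upward bias of
raw histogram MI, which is what makes the independent-pair calibration in
the test suite possible (corrected MI below 0.02 nats at $n = 5 \times
10^4$). Negative corrected estimates are clamped to zero with the raw value
retained. Residue-level MI aggregates over all torsion pairs of the two
residues; the default is the maximum (recording the attaining pair), with
`sum` and `mean` as options — the maximum is the natural choice when MI is
then used as an edge weight for path search, because a single strongly
coupled torsion pair is a real communication channel regardless of how many
uncoupled torsions the residues also carry.

The residue graph keeps edge $(i, j)$ only if the residues are spatially
proximal — minimum heavy-atom distance within 5 Å in at least 75% of
analysis frames — and MI is positive. Without the proximity gate a complete
MI graph would admit "pathways" that hop between residues that never touch,
which is physically meaningless. Both thresholds are configurable.

Path search maximises total MI along a path. Edge costs are
$c_{ij} = -\ln(I_{ij} / I_{\max})$, which maps the multiplicative objective
onto an additive non-negative shortest-path problem solved by Dijkstra's
algorithm; the strongest edge has cost exactly zero. Ties in total cost are
broken toward the lexicographically smallest residue sequence, so results
are bit-reproducible. For every (source, sink) pair between the declared
regions one optimal path is computed and retained only if it passes through
the binding-site region. **Pipelines** are connected components of the
pathway-overlap graph (two pathways overlap when they share at least one
edge); a pipeline's *strength* is its number of member pathways and a
residue's *hub count* is the number of member pathways through it. The
suite checks the search against exhaustive simple-path enumeration on 200
random graphs and against an independent graph library.

## Ligand--receptor contacts

Two contact kinds, with the standard MD geometric gates:

* **Hydrogen bond**: heteroatom (N/O) pair within 3.5 Å *and*
  donor--H--acceptor angle ≥ 120°. Both heavy atoms are tried as donor;
  when neither carries an explicit hydrogen, an ideal H is inferred 1.0 Å
  from the donor pointing away from its bonded heavy neighbours, and the
  result is flagged (`h_inferred`). Inference can be disabled, in which
  case missing hydrogens are an error.
* **van der Waals**: any ligand-carbon to residue-carbon distance within
  4.0 Å. A residue without carbons can never be in vdW contact.

Occupancy is the fraction of pooled analysis frames in contact; a contact
is **sustained** when occupancy is *strictly* greater than 0.40 — exactly
40% does not qualify. Mean contact distances are reported both over
in-contact frames and over all frames (the all-frame mean is the right
quantity for state-to-state contraction comparisons, since it does not
condition on the gate). A simple nonbonded interaction energy (Coulomb plus
Lennard-Jones over all inter-group pairs, Lorentz--Berthelot combining, no
cutoff) is provided for toy systems and user-supplied parameters; it makes
no attempt to reproduce any specific force-field implementation.

## Flexibility, density, pocket volume, projections

**RMSF.** Frames are superposed by least squares (Kabsch) onto the
ensemble-average structure of the pooled analysis window — computed by a
two-pass fit (fit to the first frame, average, refit to the average) — and
$\mathrm{RMSF}_i = \sqrt{\langle |x_i - \langle x_i \rangle|^2 \rangle}$.
The fit selection defaults to the reported selection (all Cα in the
pipeline). B-factors follow $B = (8\pi^2/3)\,\mathrm{RMSF}^2$ and can be
written into the PDB B-factor column for heat-map rendering. For isotropic
per-axis Gaussian jitter of amplitude $\sigma$ the expected RMSF is
$\sigma\sqrt{3}$; note that superposition absorbs six rigid-body degrees of
freedom, shrinking the estimate by a factor of about
$\sqrt{1 - 2/N_{\mathrm{fit}}}$, which is why calibration fixtures use a
few hundred fit atoms.

**Spatial distribution.** After superposition on a rigid selection, tracked
atom positions (canonically the ligand's primary-amine N and hydroxyl O)
are binned on a regular grid (default 1 Å); out-of-grid events are tallied,
never silently dropped.

**Pocket volume.** A cubic box (default 12 Å, 1 Å resolution) is centred on
the ligand centroid; grid points within the van der Waals radius (Bondi
set: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å) of any receptor atom are
deleted; the volume is the retained count times the voxel volume. Points
are anchored so that one grid point sits at the box centre (centre-outward
construction). The alternative half-offset convention was rejected after
measurement: for a centred 3 Å probe sphere it counts 136 deleted points
against the analytic 113.1 ų (+20%), because the sphere centre then sits
on a corner shared by eight voxels, while the centre-anchored grid gives
123 (+9%), inside ordinary first-order grid error. Retained points not
6-connected to the core region (a 4 Å sphere at the box centre) are pruned
by region growing, so disconnected crevices elsewhere in the box do not
inflate the pocket; pruning can be disabled. Volume is reported per frame
with pooled mean ± SD (runs are pooled rather than averaged per run; with
equal-length runs the mean is identical and the pooled SD is the more
conservative spread estimate).

**State projection.** Per-frame Cα--Cα distances for two residue pairs
(canonically TM3--TM6 and TM3--TM7, e.g. R102–E228 and R102–Y288 for the
A2A receptor) with a 2D occupancy histogram (default 0.25 Å bins) and
optional crystal-structure reference markers.

## Free energy: Bennett Acceptance Ratio

Given forward and reverse work samples per coupling-parameter window (the
shipped fixtures emulate 20 windows at equidistant $\Delta\lambda = 0.05$),
the per-window estimate solves the self-consistent Bennett equation

$$\sum_{i \in F} f(M + w^F_i - \Delta G) =
  \sum_{j \in R} f(-M + w^R_j + \Delta G), \qquad
  f(x) = \frac{1}{1 + e^{x}},\; M = \ln(n_F / n_R),$$

by bracketed root finding — the left side is increasing and the right side
decreasing in $\Delta G$, so the root is unique; the default tolerance is
$10^{-10}$ reduced units. The standard asymptotic variance estimator
supplies the per-window SE; window SEs combine in quadrature (per-window
estimates are computed from disjoint samples, hence independent). When the
forward and reverse distributions barely overlap the estimate is still
returned but its SE is flagged unreliable with a warning rather than an
error. All internal math is reduced ($k_B T = 1$); kcal/mol conversion uses
$k_B = 0.0019872$ kcal/mol/K at a default 310 K. For Gaussian forward work
$W \sim \mathcal{N}(\mu, \sigma^2)$ obeying Crooks symmetry, the exact
window free energy is $\mu - \sigma^2/2$, which is the ground truth used
throughout the tests; the suite also confirms that BAR has smaller median
bias than one-sided exponential averaging at $\sigma = 2$.

## Synthetic generators: what they emulate, and what they do not

Every analysis stage is validated against generators whose statistical
structure is known exactly:

* `gen_coupled_torsions()` samples a pairwise angular Markov field with von
  Mises marginal fields $e^{\kappa_m \cos\theta}$ and cosine couplings
  $e^{\kappa_c \cos(\theta_i - \theta_j)}$ on declared residue pairs. The
  density is evaluable in closed form, so `oracle_mi()` (dense 720×720
  quadrature, converged to $<10^{-4}$ nats under grid doubling) and
  `oracle_torsion_entropy()` provide estimator-free ground truth. Because
  frames are independent replicates, sampling runs one short Gibbs chain
  per frame, vectorised across frames (60 sweeps from a marginal start;
  at the concentrations used, chain-start bias is far below the 5%
  comparison tolerance, as the oracle comparison itself verifies).
  $\kappa_c = 0$ pairs are exactly independent by construction.
* `gen_toy_trajectory()` builds a helical-bundle receptor (ideal helices on
  a 12 Å circle around a small ligand) whose atoms jitter isotropically
  with prescribed per-axis $\sigma$, and realises scheduled ligand contacts
  *exactly*: the contact-defining atom is pinned (no jitter) and switched
  between an in-contact and out-of-contact position by a seeded
  permutation, stratified within the first and last half of each run so
  that both the full-run and the default trailing-half window see the
  target occupancy to within one frame.
* `gen_bar_samples()` draws Gaussian Crooks-consistent work pairs with
  closed-form per-window truth, as above.

The fixtures deliberately omit most of what makes real trajectories hard:
there is no force field, no solvent or membrane, no correlated collective
motion, no anharmonic multi-well torsion landscapes beyond the declared
couplings, and contacts are switched geometrically rather than emerging
from dynamics. Passing tests therefore demonstrate that the *estimators
and algorithms* are correct and calibrated on data of known structure —
not that any particular biological conclusion transfers; on real
ensembles, convergence of the input sampling remains the user's
responsibility.

## Numerical choices and degenerate inputs

* Angles live in $[-180, 180)$ degrees; binning is exact at bin edges
  (half-open bins, the top edge folded into the last bin).
* Dihedrals with a collinear atom triplet are undefined: those frames
  become `NA` and are excluded from histograms rather than invented.
* Frame-window length is $\lfloor f \cdot n \rfloor$ from the run's tail; a
  window that would be empty is an error, not an empty result.
* Dijkstra ties are resolved lexicographically (documented above); pipeline
  ordering is by strength, then smallest member residue id.
* The trajectory dialect stores 17 significant digits, so disk round-trips
  are bit-exact and the rerun-determinism guarantee extends through I/O.
* Seeds: every generator takes an explicit integer seed; identical seeds
  give byte-identical fixtures and pipeline outputs.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run at sizes chosen to make
the statistical assertions sharp but cheap: $10^5$ frames for MI/entropy
calibration against quadrature oracles, 100 replicates of $5\times10^4$
frames for the independence calibration, 200 random graphs (≤ 12 nodes)
for the path-search oracle, $10^4$ frames for RMSF calibration, $10^5$
work samples for the single-window BAR check, and a two-state, 12-residue,
2×120-frame end-to-end fixture for pipeline determinism. These sizes are
the package's own validation design; all thresholds were fixed from the
closed-form error analysis above, not tuned to outcomes.

## Orchestration

`run_pipeline()` executes the enabled stages for each configured state and
writes per-state TSV/JSON artifacts plus a manifest (inputs, parameters,
package version, seed) sufficient to re-run bit-identically;
`compare_states()` joins two states' artifacts into delta tables (region
entropies, contact occupancy and mean-distance shifts, volume, per-residue
B-factor, pipeline strength), refusing to compare states analysed with
different parameters. The YAML config plus these two functions are the
package's command surface; all stages are equally usable as plain
functions, which is how the examples in the README are written.

## Known limitations

Higher-order entropy expansions (MIST/MIE) and quasi-harmonic entropy are
out of scope, as are periodic-boundary unwrapping, solvent-mediated
hydrogen-bond networks, k-shortest-path enumeration (one optimal path per
source–sink pair), and MBAR. The interaction energy is a pedagogical
pairwise sum, not a force-field reproduction. Insertion-coded PDBs are
rejected in this version.
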