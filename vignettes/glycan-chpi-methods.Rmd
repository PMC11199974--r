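---
title: "Methods: quantifying glycan-protein CH-pi recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying glycan-protein CH-pi recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycontact)
```

## The scientific problem

Lectins recognize glycans largely through CH-pi interactions: the polarized
C-H bonds of pyranose rings (GlcNAc, fucose, mannose) stack against the pi
face of aromatic side chains (Trp, Tyr, Phe). `glycontact` quantifies this
recognition along four axes: a smooth CH-pi contact statistic over
structural trajectories, residue-glycan interaction-frequency networks, 1:1
binding-isotherm fitting of titration data to estimate dissociation
constants and fold changes between protein variants, and the compound
enrichment filter used in proximity-labeling interactome proteomics. Each
stage is exercised on seeded synthetic data with known ground truth, so the
whole pipeline is testable without any external download.

## The CH-pi coordination number

For a hydrogen atom $i$ of a glycan C-H group at distance $r_{ij}$ from the
center $j$ of an aromatic ring, the contact is scored with the rational
switching function

$$
c(r_{ij}) \;=\; \frac{1 - (r_{ij}/r_0)^n}{1 - (r_{ij}/r_0)^m},
\qquad r_0 = 0.3\ \mathrm{nm},\ n = 6,\ m = 12 ,
$$

and the per-frame coordination number of a residue is the sum of
$c(r_{ij})$ over all (donor hydrogen, ring center) pairs. The function is a
smooth count: near 1 at short range, $n/m$ at exactly $r_0$ (a removable
singularity), and decaying as $r^{-6}$ beyond. For the default exponents
$m = 2n$ the algebraic identity $1 - x^{12} = (1-x^6)(1+x^6)$ collapses it
to $1/(1 + (r/r_0)^6)$, which the implementation uses: it is exact
everywhere, including the singular point. For general exponents an explicit
limit branch returns $n/m$ within $10^{-9}$ nm of $r_0$.

Numerical notes. Below roughly 0.02 nm the ratio $(r/r_0)^6$ underflows and
$c(r)$ evaluates to exactly 1 in double precision; this is harmless (no
physical H sits inside the ring). No neighbor-list cutoff is applied beyond
the switching function itself: contributions past 1.2 nm are below
$1.6\times10^{-4}$ each and are retained for exactness.

### Geometric entities

* **Rings.** Trp contributes two rings — the six-membered benzene ring
  (CD2, CE2, CE3, CZ2, CZ3, CH2) and the five-membered pyrrole ring
  (CG, CD1, NE1, CE2, CD2) — while Phe and Tyr each contribute one
  six-membered ring. Both Trp rings enter the coordination sum; the
  dominant-ring-only reading is recoverable by passing a single ring to
  `coordination_number()`. His rings are excluded by default
  (`include_histidine = TRUE` enables the imidazole). The ring center is
  the unweighted mean of the member-atom positions; with near-uniform
  heavy-atom masses in these rings a mass-weighted center differs
  negligibly, and the unweighted mean keeps the statistic purely geometric.
* **Donors.** Every hydrogen in a whitelisted glycan residue
  (`r paste(default_glycan_residues(), collapse = ", ")` by default) whose
  nearest heavy atom in frame 1 is a carbon within 0.13 nm is a C-H donor;
  hydroxyl and amide hydrogens are excluded by the same rule. Ties break by
  smaller distance, then lower atom serial. Explicit hydrogens are
  required — placing them is out of scope, and a glycan residue without any
  hydrogen raises an error rather than silently contributing zero.
* **Units.** All internal lengths are nm, because $r_0$ is defined in nm;
  PDB Angstroms are converted on read (x 0.1) and back on write. Residues
  are identified by (chain, number, insertion code) and never pooled across
  chains implicitly — for homotrimeric lectins with three glycan copies,
  pooling across protomers is a reporting decision left to the caller.

## Interaction-frequency networks

The published interaction diagrams weight residue-glycan edges by
occurrence frequency over the simulation, but the underlying contact
criterion is tool-specific and not printed. This module operationalizes
"interaction" as **minimum heavy-atom distance at or below 0.45 nm** — a
standard heavy-atom contact cutoff — and reports, per (protein residue,
glycan residue) pair, the fraction of frames in contact plus the mean
minimum distance. This is a stated substitute, not a claim of equivalence
to any particular contact tool's edge weights; the cutoff is configurable,
and raising it can only add edges and raise frequencies (a tested
monotonicity property).

## 1:1 binding isotherms and fold changes

Titration of a fixed fluorescently labeled species $T$ (default
$0.05\ \mu M$, i.e. 50 nM) against a partner at concentration $L$ follows
the exact mass-action solution with target depletion,

$$
f_b(L) = \frac{(L + T + K_D) - \sqrt{(L + T + K_D)^2 - 4LT}}{2T},
\qquad
R(L) = R_{\mathrm{free}} + (R_{\mathrm{bound}} - R_{\mathrm{free}})\, f_b(L).
$$

The depletion form is the default because 50 nM is not negligible against
sub-micromolar dissociation constants; the hyperbolic approximation
$L/(L+K_D)$ is available for comparison and agrees within $10^{-6}$ once
$T \le K_D/10^4$. The fit optimizes $\log_{10} K_D$ (Brent, bounded to
$[10^{-6}, 10^{6}]\ \mu M$) with each replicate's baseline and amplitude
profiled out by linear least squares at every candidate $K_D$ — replicates
share $K_D$ but keep their own plateaus. Flat response vectors are rejected
as non-identifiable. Fold changes between variants are reported as the
ratio max/min with a direction call, both raw and rounded to one decimal
(the conventional reporting style); the raw ratio is always retained
because published rounding conventions vary.

## The proximity-labeling enrichment filter

Starting from a protein-level two-channel table (experiment = medium
dimethyl label, control = light label, per-replicate intensities and
unique-peptide counts):

1. **Minimum imputation** — each missing intensity is replaced by the
   minimum observed value of its replicate column (deterministic,
   idempotent; a per-protein-row variant is available via `scope = "row"`).
2. **Statistics** — fold change as the ratio of channel means on linear
   intensities; p-value from an unpaired two-tailed equal-variance
   Student's t-test on log2 intensities (variance-stabilized, matching
   common practice; the scale is not dictated by the filter definition).
   Zero-variance comparisons are flagged degenerate and reported as
   p = 0 (unequal means) or p = 1 (equal), never a silent infinity.
3. **The compound call** — enriched iff fold change > 5, p < 0.01, and at
   least 2 unique peptides in at least 2 replicates. Benjamini-Hochberg FDR
   is always computed and reported; `strict_fdr = TRUE` swaps it in as the
   operative threshold, since published descriptions mention both a raw-p
   cut and a 1% FDR without fixing which is operative.

## What the synthetic generators emulate — and what they do not

All generators take an explicit integer seed, draw from a local RNG stream
(the caller's random state is saved and restored), and are bit-reproducible.

**Two-state contact trajectory.** A Markov chain over {bound, unbound}
with stationary occupancy $p$ and dwell persistence $d$: leave-state
probabilities are scaled by $(1-d)$ so the stationary law is exactly $p$
for any $d$, and $d = 0$ recovers i.i.d. frames. The default $d = 0.9$
produces the dwell segments characteristic of real contact traces. Each
frame holds a Phe-like hexagonal ring (circumradius 0.14 nm, standard PDB
atom names so detection code paths are exercised, not bypassed) and a
NAG-like residue whose H1 sits at the state's distance from the ring center
along the ring normal — 0.3 nm bound, 1.0 nm unbound — plus isotropic
Gaussian noise (default SD 0.02 nm); C1 tracks H1 rigidly at 0.109 nm. The
ground-truth expected mean contact averages the switching function over
$10^5$ noise draws from a seeded child stream, so noise-induced bias is
part of the reference value. Not emulated: force-field dynamics, solvent,
glycosidic-torsion sampling, ring flexibility — so passing tests show the
*statistic* is computed correctly at a stated occupancy, not that any MD
observable is reproduced.

**Titrations.** Responses on the depletion isotherm plus Gaussian noise,
per replicate. Defaults: 16 titrant concentrations log-spaced
$10^{-3}$–$10^{2}\ \mu M$, plateaus 800/900 response units. Not emulated:
thermophoresis physics, normalization artifacts, aggregation.

**Quantification tables.** Log-normal intensities (baseline
$\log_2$-intensity $\mathcal N(20, 2^2)$ per protein), a designated
enriched subset whose experiment channel is shifted by $\log_2$(true FC),
within-group variability given as a linear CV and mapped to $\log_2$ SD by
$\sqrt{\log(1+\mathrm{CV}^2)}/\log 2$, unique-peptide counts Poisson with
mean 4 (a realistic count for confidently identified proteins), and
missingness in two modes: completely at random, or — the default —
**left-censoring at a detection limit**: within each replicate column the
lowest `missing_rate` fraction of intensities is unobserved. Left
censoring is the missingness mechanism that deterministic minimum
imputation is designed for, and the standard model of intensity-dependent
missingness in MS proteomics; under it the imputed column minimum
approximates the detection limit, so imputation distorts low-abundance
proteins only mildly. Proteins whose control channel lies entirely below
the detection limit still lose fold-change signal to imputation — an
intrinsic, realistic failure mode of the filter, visible as the few percent
of designated proteins the recovery tests do not reclaim (alongside
proteins that simply draw too few peptides). Not emulated: peptide-level
quantification, shared peptides, batch effects, label efficiency.

## Problem sizes and test design

The test and acceptance workloads use 2000-frame trajectories of an
8-atom synthetic system, 16-point titrations with up to 3 replicates, and
1000-protein tables (60 enriched at true FC 8, 10% censoring) — sizes at
which every statistic is exact or tightly concentrated, and the entire
suite runs in seconds. Optimized pairwise computations are checked against
a plain double loop over (hydrogen, ring-center) pairs; fits are checked by
generate-and-refit at the published dissociation constants (1.52 and
0.66 uM, target 50 nM) to within 0.1%.

## Known limitations

* Published MD-scale observables — per-residue contact averages such as
  1.6 vs 1.9 for a binding-site Trp, and the published interaction-network
  edge weights — require microsecond explicit-solvent simulations of the
  real complexes and are **not** reproduced here; the property suites above
  substitute for them. Likewise the published interactome list and its
  membrane fraction depend on deposited raw MS data and external
  annotation databases, which this package deliberately does not consume.
* The trajectory reader accepts multi-model PDB only (any MD toolchain can
  emit it); mmCIF and compressed trajectory formats are out of scope.
* The contact-network criterion is a heavy-atom distance cutoff, not a
  typed interaction classification (no H-bond/vdW/pi-cation subtypes).
* The isotherm is strictly 1:1 — no Hill coefficients or cooperative
  models.
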