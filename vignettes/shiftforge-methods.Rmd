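---
title: "ShiftForge: methods and design"
author: "ShiftForge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ShiftForge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Protein NMR chemical shifts depend sensitively on the local structural
and electronic environment of each nucleus, which makes them both hard
to predict and valuable as structural information. ShiftForge is an
automated pipeline that builds shift-prediction training sets from
paired protein structures (PDB format) and deposited chemical-shift
lists (NMRStar 2.1/3.1), trains one regression model per *atom super
class*, evaluates the models, and applies them to new structures.

The pipeline stages are: (a) read an initial structure-to-accession
mapping, (b) restrict it with type-1 filters (protein-only content,
perfect sequence agreement, homology culling) and a type-2
structure-quality filter, (c) link every deposited shift to a structure
atom, (d) compute a per-atom feature table and persist both tables in
an SQLite store, and (e) train and evaluate the per-class models.

# The model

## Hybrid architecture

The fitted predictor for an atom of super class $k$ is

$$\hat\delta \;=\; \underbrace{\delta_{\mathrm{rc}} +
\delta_{\mathrm{ring}}}_{\text{semi-classical baseline}} \;+\;
f_k(\mathbf{x}),$$

where $\delta_{\mathrm{rc}}$ is the random-coil table value (0 where
the table has no entry, e.g. side-chain protons),
$\delta_{\mathrm{ring}}$ the aromatic ring-current term, and $f_k$ a
random forest trained on the *residual* shift over the full feature
vector $\mathbf{x}$. The semi-classical terms are steep functions of
geometry ($r^{-3}$ in the ring term); adding them analytically instead
of asking the forest to approximate them removes the dominant source of
extrapolation error, which is the defining property of hybrid shift
predictors. The remaining semi-classical terms (electric field,
hydrogen bond) enter only as features, because their coefficients are
less transferable than their functional shapes; the forest is free to
weight them.

## Semi-classical terms

* **Random coil**: lookup of standard published random-coil values
  (ppm, DSS-referenced) for N, CA, CB, C, H, HA over the 20 residues
  (no GLY CB, no PRO H).
* **Ring current**: point-dipole model
  $\delta = \sum_\mathrm{rings} B\, i\, (1-3\cos^2\theta)/r^3$ with
  $B = 30.42\ \mathrm{ppm\,\AA^3}$ and relative intensities
  PHE 1.00, TYR 0.84, HIS 0.90, TRP 1.04 (five-ring) / 1.02
  (six-ring); $r$ is the distance to the ring centroid, $\theta$ the
  angle between ring normal and centroid-to-atom vector. Rings of
  which the atom itself is a member are excluded. The Haigh–Mallion
  loop-integral model is deliberately out of scope; the registry
  accepts replacements.
* **Electric field**: uniaxial form $\delta = \varepsilon E_z$,
  $E_z = \sum_q q\cos\alpha / r^2$ over the built-in minimal partial
  charges beyond a two-bond exclusion, $\alpha$ measured against the
  target's single covalent bond axis, $\varepsilon = 1$ ppm per field
  unit by default.
* **Hydrogen bond**: $\delta = a/r^3 - b$ ($a = 19.2\ \mathrm{ppm\,
  \AA^3}$, $b = 2.3$ ppm) for the nearest acceptor within 3.5 Å,
  else 0.

## Features

The feature engine is a string-keyed registry; the active set is read
from a plain-text definition file (one name per line, `#` comments).
The default set covers sequential descriptors (residue and neighbour
types with NTER/CTER sentinels, sequence length, alignment score),
structural descriptors (φ/ψ/χ₁ torsions, H-bond-pattern secondary
structure, explicit backbone distances, Shrake–Rupley solvent
accessible surface per atom and summed per residue, heavy-atom density
within 5 Å, hydrogen and disulfide bond flags), force-field descriptors
(a coarse Amber-flavoured atom typing; the structure-quality score),
experimental metadata (shift-type availability, temperature, pH,
pressure, solvent, spectrometer), and the four semi-classical terms.

Missing numeric features are imputed at training time by the per-class
training median and accompanied by a parallel missing-indicator
column; missing categoricals become an explicit `"missing"` level.
Categorical features are one-hot encoded with the encoding stored in
the model sidecar, so prediction-time design matrices align exactly.

## Atom super classes

The default scheme partitions atom names into ten classes (N, CA, CB,
C, H, HA, HB, HD, HG, HEHZ) with fixed vocabularies; one model is
trained per class. The vocabularies mix the two hydrogen-naming
dialects, so lookups normalize each name to the leading-digit spelling
for the residue and test both spellings. Names outside the
vocabularies (carbonyl O, side-chain carbons beyond CB, some methyl
partners such as 3HB) belong to no class and are skipped — the
vocabulary is authoritative, not inferred. An alternative scheme can
be auto-generated by element-segregated greedy merging of force-field
atom types into classes of comparable size, or supplied as plain text
(`label: name, name, ...`).

## Training and evaluation

The dataset is split **by structure** (all atoms of one PDB id land on
one side) to avoid leaking intra-protein correlation; the training
share of structures is `floor(n * fraction + 0.5)` with a default
fraction of 0.6 (a 60:40 split). The default backend is a random
forest with 500 trees; `mtry` is chosen by an out-of-bag
doubling/halving sweep around $p/3$ (the literature also suggests
using all variables at every split; the sweep can and does reach $p$
when that helps, which resolves the tension in favour of the tuned
value). Classes with fewer than 50 training rows are skipped with a
warning.

Evaluation reports, per class and pooled,

$$\mathrm{rmse} = \sqrt{\tfrac1n\sum_i (\delta_i^{\exp} -
\delta_i^{\mathrm{pred}})^2}, \qquad
\mathrm{corr} = \tfrac1{n-1}\sum_i
\frac{\delta_i^{\exp}-\hat\delta^{\exp}}{s_{\delta^{\exp}}}\,
\frac{\delta_i^{\mathrm{pred}}-\hat\delta^{\mathrm{pred}}}{s_{\delta^{\mathrm{pred}}}},$$

with sample ($n-1$) standard deviations. `corr` is reported as missing
(not 0) for $n<2$ or zero-variance vectors.

# The synthetic study

Because the full shift-archive corpora cannot be processed at desk
scale, the package ships a first-class fixture generator that defines
the study conditions for validation.

**Structures** are built from ideal internal coordinates (N–CA
1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, standard angles, ω = 180°) by a
stated backbone dihedral program — helix (φ −57°, ψ −47°), extended
(φ −135°, ψ 135°), or mixed — over seven buildable residue types
(G, A, S, V, L, F, K). The programmed dihedrals are the exact
geometry: the builder inverts the torsion computation, so recomputed
torsions match to well below 10⁻⁶ degrees, and every geometric feature
has a closed-form expectation. Side-chain χ₁ rotamers are chosen per
residue from {−60°, 180°, +60°} to maximize the minimum nonbonded
contact, with a 2.0 Å clearance required where attainable — without
this, ideal-geometry packing produces physically impossible overlaps
whose ring-current values are absurd.

**Shifts** follow the generator formula
`shift = base(residue, class) + ss_offset + ring_current +
0.01 · atomic_density + N(0, σ²)`, i.e. a random-coil-style base, a
linear term in chosen features (one-hot secondary structure and the
density count), the ring-current term, and seeded Gaussian noise.
Base values are constant within (residue, super class) — equivalent or
near-equivalent protons share one resonance — because atom name is
deliberately not a model feature. Ground truth is computed from the
structure **as re-parsed from the written PDB file**, so
threshold-sensitive terms (the H-bond criterion behind secondary
structure) agree bit-for-bit with what any consumer of the file
computes.

**Study size.** The default cohort is 24 proteins of 35–45 residues
(≈ 7,000 atom records, ≈ 400+ per class), which trains all ten classes
well above the minimum class size and completes a full
parse→filter→featurize→train→evaluate cycle in roughly two minutes on
one CPU. The homology cull is skipped *in this study*: random
sequences over a 7-letter alphabet are pairwise ≈ 15–40 % identical
under global alignment and cannot satisfy a 10 % cutoff, so the
culling contract is validated separately on its own sequence sets.
What the study demonstrates: the pipeline's plumbing is lossless
(σ = 0 recovery to ≈ 0.01–0.03 ppm pooled), its error tracks the noise
floor (σ = 0.3 ppm → rmse ≈ 0.30–0.33), and it learns nothing from
permuted labels. What it does not demonstrate: accuracy on real
proteins — real side-chain heterogeneity, ensemble/dynamics effects,
referencing errors and feature-model mismatch are all absent by
construction.

# Filters

* **Perfect alignment**: identity is matched columns over total
  alignment columns (×100) under global alignment with match +1,
  mismatch 0, linear gap −1; any gap or mismatch breaks 100 %. The
  filter keeps exactly the identity-100 chains.
* **Homology culling**: removal-based greedy culling — while any
  retained pair exceeds the cutoff (default 10 %), drop the sequence
  in conflict with the most others (ties: the shorter sequence, then
  the later one in input order). This was chosen over accept-greedy
  ("add each sequence iff compatible with all retained") because
  accept-greedy yields only a *maximal* compatible set, which on
  randomized small inputs can fall two or more sequences short of the
  *maximum* one; the removal heuristic is equally deterministic,
  prefers long sequences, and stayed within one sequence of a
  brute-force optimum across several hundred randomized cases.
  Retained sets never violate the cutoff by construction.
* **Structure quality ("energy")**: a registered scorer returns a
  kJ/mol-scaled value; the default `"default-nb"` scorer sums a
  Lennard-Jones clash term and a Coulomb term over the built-in partial
  charges for atom pairs more than three covalent bonds apart (a
  coarse stand-in for the bonded terms and 1–4 scaling of a full force
  field). Structures at or below the cutoff (default 1000 kJ/mol) are
  kept; well-formed geometry scores far below it, while overlapping
  atoms blow up through the $r^{-12}$ term. A scorer failure drops the
  entry as "unscorable".

# Numerical and degenerate-input choices

* Dihedrals use the IUPAC sign convention, results in (−180°, 180°];
  incomplete four-atom chains give NA, never an error.
* Surface areas use 240 deterministic golden-spiral points per atom
  (≤ 2 % error on an isolated sphere); vdW radii H 1.20, C 1.70,
  N 1.55, O 1.52, S 1.80 Å, probe 1.4 Å.
* Covalent bonds are detected by distance against covalent radii
  (+0.4 Å); hydrogen bonds need H···acceptor < 2.5 Å and a donor
  angle > 120°; disulfides need SG–SG in [1.8, 2.5] Å.
* Chain matching ties (homodimers) go to the first chain in file
  order; chains are re-indexed 1..k in file order; residues are
  re-indexed 1-based per chain with the depositor numbering kept as an
  auxiliary column.
* NMR ensembles contribute MODEL 1 only.
* The NMRStar reader re-synchronizes a shift loop by dropping single
  tokens until a row passes structural validation; non-numeric shift
  values drop that row only; duplicated (entity, residue, atom) rows
  keep the first occurrence; all recoveries are counted by category in
  the parse report. A file with no recognizable shift loop is fatal.
* A no-op shift-transform hook sits between parsing and assignment
  where re-referencing tools could be attached; the default is the
  identity (re-referencing itself is out of scope).
* The store keeps exactly two tables (`chain_mapping`,
  `atomic_properties`); the schema version lives in SQLite's
  `user_version` pragma; booleans are declared BOOLEAN and restored to
  logical on read; missing conditions are explicit NULLs.

# Known limitations

* The fixture builder covers seven residue types; the name converter,
  typing and random-coil tables cover all twenty.
* The ring-current parameterization is the point-dipole form with
  literature-standard starting intensities; it is configurable but not
  fitted.
* The default structure-quality scorer is a pseudo-energy on an
  arbitrary but fixed scale, not a force-field energy; only its
  contrast between sound and clashed geometry is meaningful.
* Auto-clustering merges by name distance, a heuristic; the default
  ten-class scheme is the recommended partition.
* Live archive retrieval, re-referencing algorithms, and comparisons
  against external predictors are out of scope.
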