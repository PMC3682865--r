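# ShiftForge

Automated construction and training of protein NMR chemical-shift
predictors from structure and shift archives.

## What it does, and for whom

Protein NMR chemical shifts (δ, in ppm) encode fine structural detail,
and predicting them from a 3D model is a standard tool in structure
validation, refinement and docking. Building a shift predictor,
however, is mostly data plumbing: shift depositions (NMRStar format)
and structures (PDB format) use different atom nomenclatures, chain
and residue numbering, and the files are famously error-ridden.
ShiftForge is for structural bioinformaticians who want to go from
*paired structure/shift files* to *trained, evaluated, applicable
per-atom shift models* without hand curation:

1. **Map & filter** — read a PDB-id ↔ accession mapping; keep
   protein-only entries, demand 100 % sequence identity between the
   shift-side and structure-side sequences, cull homologs to ≤ 10 %
   pairwise identity, and drop structures whose quality score exceeds
   1000 (kJ/mol scale).
2. **Link** — parse both files fault-tolerantly, match chains by best
   global alignment (ties → first chain in file order), re-anchor
   residues through the alignment, convert atom names between the
   NMRStar/PDB-v3 and PDB-v2 dialects, and attach every shift to one
   atom or report it with a reason.
3. **Featurize & store** — compute sequential, structural,
   force-field, experimental and semi-classical features per atom, and
   persist a chain-mapping table plus an atomic property table in one
   SQLite file.
4. **Train & evaluate** — split by structure 60:40, train one hybrid
   model per *atom super class* (10 classes: N, CA, CB, C, H, HA, HB,
   HD, HG, HEHZ), and report per-class rmse and Pearson correlation.
5. **Predict** — apply saved models to a new PDB file; output is CSV.

## The model

The predictor is a **hybrid**: a fixed semi-classical baseline plus a
statistical model of the residual,

    δ_pred  =  δ_randomcoil + δ_ringcurrent + RF_k(x)

where `δ_ringcurrent = Σ B·i·(1−3cos²θ)/r³` (point-dipole over
aromatic rings, B = 30.42 ppm·Å³) and `RF_k` is a 500-tree random
forest for super class *k* over ~34 features (torsions, secondary
structure, solvent-accessible surface, atomic density, hydrogen and
disulfide bonds, electric-field and hydrogen-bond terms, neighbour
residue types, experimental conditions, ...). Evaluation uses
`rmse = sqrt(Σ(δ_exp − δ_pred)²/n)` and the sample-normalized Pearson
correlation.

## Worked example

Everything below runs offline: the package generates its own study
cohort — toy proteins built from ideal geometry with ground-truth
shifts.

```r
library(ShiftForge)

dir <- tempfile("cohort")
fx  <- buildFixtureSet(dir, nProteins = 24, sigma = 0, seed = 1)
built <- buildDataset(fx$pairs, homologyCutoff = NA,
                      storePath = file.path(dir, "study.sqlite"))
ds  <- splitDataset(built$dataset, trainFraction = 0.6, seed = 2)
mv  <- trainModels(ds, seed = 3)
evaluateModels(mv, ds)
```

```
EvaluationResult (per atom super class):
 super_class   n   rmse   corr
           N 363 0.0021 1.0000
          CA 363 0.0022 1.0000
          CB 310 0.0012 1.0000
           C 363 0.0022 1.0000
           H 363 0.0064 0.9999
          HA 416 0.0025 1.0000
          HB 578 0.0024 1.0000
          HD 380 0.0147 1.0000
          HG 298 0.0023 1.0000
        HEHZ 400 0.0058 1.0000
pooled: n=3834 rmse=0.0057 corr=1.0000
```

Reading this: with noise-free synthetic shifts the pipeline recovers
the generating values essentially exactly (pooled rmse 0.006 ppm,
correlation 1.000) — parsing, chain/residue/atom mapping, feature
computation and the hybrid models are lossless end to end. With
σ = 0.3 ppm of added noise the test rmse lands at the noise floor
(≈ 0.30 ppm), and with permuted shift labels the test correlation is
≈ 0: the models learn structure, not bookkeeping.

Applying models to a new structure:

```r
predictStructure(fx$pairs$pdb_path[1], mv, out = "pred.csv")
```

writes `pdb_id,chain,residue_index,residue_type,atom_name,
super_class,predicted_shift_ppm` rows, skipping atoms outside the ten
classes. A thin command-line interface with the same stages ships as
`exec/shiftforge` (subcommands `build-dataset`, `train`, `evaluate`,
`predict`).

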