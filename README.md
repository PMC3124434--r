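# stereocheck

Detection and correction of stereochemical errors — chirality flips and
cis peptide bonds — in protein and nucleic-acid structure models, with
harmonic restraint generation for molecular dynamics.

## Why

Biomolecular force fields carry no terms that enforce stereochemistry:
they are equally happy with an L- or a D-amino acid, and with a cis or a
trans peptide bond. An error present in the input structure — introduced
during homology modelling, system setup, flexible fitting into density
maps, or simply inherited from a deposited model — therefore persists
through an entire simulation and can wreck secondary structure. A single
D-residue or cis bond placed mid-helix is enough to kink or unwind it.

`stereocheck` is aimed at simulators and modellers preparing systems for
MD: it finds these errors, lets the user correct the ones that are
genuinely wrong (D-amino acids and cis prolines do occur in nature, so
nothing is corrected automatically), and emits restraints that keep the
stereochemistry in place during subsequent restrained relaxation.

## What it computes

- **Cis peptide bonds.** For each bonded residue pair the backbone
  torsion ω = ∠(Cα,ₙ, Cₙ, Nₙ₊₁, Cα,ₙ₊₁) and the detection torsion
  ω′ = ∠(Oₙ, Cₙ, Nₙ₊₁, Cα,ₙ₊₁) are measured. ω′ ≈ 0° for a trans bond
  and ≈ 180° for a cis bond; a bond is flagged when **|ω′| > 85°**
  (strict). Pre-proline bonds, the common genuine cis case, are
  annotated separately.
- **Chirality.** Every chiral center — Cα of all standard amino acids
  except glycine, Cβ of Thr/Ile, the sugar carbons C1′/C3′/C4′ of
  nucleotides and C2′ of ribonucleotides — carries a signed improper
  dihedral over its non-hydrogen substituents, with orderings calibrated
  so that every naturally occurring configuration is positive. A
  **negative improper** flags an unusual configuration.
- **Corrections** are reflection moves (carbonyl O through C, amide H
  through N, or a center's H through the center — Cα atoms never move)
  followed by a local restrained regularization of a harmonic
  bonded-term model, confined to residues within a cutoff of the site.
- **Restraints**: one harmonic dihedral per peptide bond (reference
  180° trans / 0° cis) and one harmonic improper per chiral center
  (reference = its current value), written in the extra-bonds text
  format consumed by NAMD's `extraBonds` facility. They are meant for
  relaxation stages only and should be removed before production
  equilibrium runs.
- **Survey**: batch scanning of many PDB files, cross-validation of
  detections against CISPEP / CAVEAT / REMARK 500 header records, and
  per-experimental-method aggregation (totals, residues-per-error,
  structures with errors).

## Worked example

Build a 15-residue alanine/glutamine α-helix with a cis bond injected at
residues 8–9 and a D-center at residue 3, then scan it:

```r
library(stereocheck)
s <- build_peptide(build_spec(cis_bonds = 8, d_residues = 3))
report <- check_structure(s)
print(report)
#> <detection_report> 14 peptide bond(s), 15 chiral center(s), 15 residue(s) checked (15 total)
#>   cis bonds: 1  chirality flags: 1  unevaluable: 0 bond(s), 0 center(s)
#>   cis peptide bond GLN A8 - ALA A9 (omega' = 180.00)
#>   chirality flag at GLN A3 CA (improper = -121.59)
```

Both injected errors are recovered, at exactly their sites: the cis bond
shows |ω′| ≈ 180° and the D-center a negative improper (an L-center
measures about +121.6° with the calibrated templates). Correct the cis
bond by reflecting the carbonyl oxygen and relaxing locally:

```r
bond <- report$peptide_bonds[8, ]
s2 <- flip_peptide_bond(s, bond, move = "O")
target <- restraint_spec("dihedral",
                         c(bond$row_CA_i, bond$row_C_i,
                           bond$row_N_j, bond$row_CA_j) - 1L,
                         force_constant = 200, reference_angle = 180)
s2 <- regularize_local(s2, bond, cutoff = 8, target = target)
check_structure(s2)$counts$cis_count
#> [1] 0
```

Restraints preserving the (corrected) state:

```r
rs <- generate_restraints(s2)
head(write_extrabonds(rs), 3)
#> dihedral 1 2 7 8 200.0 180.0
#> dihedral 8 9 14 15 200.0 180.0
#> dihedral 15 16 25 26 200.0 180.0
```

### Command line

The same workflow from a shell, with exit status 0 = clean,
1 = anomalies found, 2 = failure, so "correct and re-check until clean"
is scriptable. The launcher installs to
`system.file("scripts", "stereocheck", package = "stereocheck")`; link
it onto your `PATH` (or call it through `Rscript`):

```sh
stereocheck build-fixtures --out fixtures/
stereocheck check fixtures/one_cis.pdb          # exit status 1
stereocheck fix fixtures/one_cis.pdb --out fixed.pdb --flip-bond A:8:O
stereocheck check fixed.pdb                     # exit status 0
stereocheck restraints fixed.pdb --out extra.txt
stereocheck survey fixtures/*.pdb --out survey/
```

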