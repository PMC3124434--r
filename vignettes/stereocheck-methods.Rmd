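---
title: "Detecting and correcting stereochemical errors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting stereochemical errors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereocheck)
```

This vignette documents the models, conventions, numerical choices and
limitations behind `stereocheck`. The package addresses two kinds of
stereochemical error that biomolecular force fields cannot repair on
their own — flipped chirality at tetrahedral centers and cis/trans
isomerization of peptide bonds — and follows a four-step, user-driven
protocol: identify, inspect, move atoms, locally relax.

## Detection model

### Cis peptide bonds

The peptide bond between residues $n$ and $n+1$ is characterized by the
backbone dihedral $\omega$ over (C$_{\alpha,n}$, C$_n$, N$_{n+1}$,
C$_{\alpha,n+1}$): $\omega \approx 180°$ for trans, $\approx 0°$ for
cis. Detection instead measures the equivalent dihedral $\omega'$ over
(O$_n$, C$_n$, N$_{n+1}$, C$_{\alpha,n+1}$), which is $\approx 0°$ for
trans and $\approx 180°$ for cis. Using $\omega'$ keeps the four atom
names unique within the bonded pair, which makes the scan a plain
name-based lookup. A bond is flagged when $|\omega'| > 85°$, a strict
inequality; the threshold sits far from both ideal values so that
thermal/refinement distortions of either isomer do not cross it. The
magnitude is used, never the sign, so the verdict is independent of the
torsion sign convention and survives mirroring.

Bonds are enumerated between consecutive standard amino-acid residues of
a chain whose C–N distance is at most 2.0 Å (larger separations are
chain breaks, not bonds). Candidates missing any of the five required
heavy atoms are reported as unevaluable with the missing atom named
rather than silently dropped — missing atoms in deposited models are a
documented source of disagreement between scans and file headers.
Pre-proline bonds are flagged like any other but annotated
(`pre_proline`), since Xaa-Pro is where genuine cis bonds overwhelmingly
occur; the package never decides on its own whether a flagged
configuration is an error.

### Chirality

Each supported center carries a signed improper dihedral
`dihedral_angle(s1, center, s2, s3)` over three non-hydrogen
substituents. For any non-degenerate arrangement the sign of this
improper is opposite to the sign of the triple product
$\det[r_{s1}-r_c,\; r_{s2}-r_c,\; r_{s3}-r_c]$, which is what makes it
an orientation (handedness) test: the two mirror images of a center give
equal magnitudes of opposite sign. The substituent orderings in
`chiral_templates()` were calibrated once against ideal residue
geometry (the chemical-component reference coordinates of the standard
amino acids and nucleotides) so that every naturally occurring
configuration — L-amino-acid C$_\alpha$, the (3R) Thr and (3S) Ile
C$_\beta$, and the D-ribose/deoxyribose sugar carbons — measures a
*positive* improper (about +120° at an ideal C$_\alpha$); a negative
value therefore flags an unusual configuration. The orderings are
frozen in the template table; the test suite pins the semantics with a
triple-product oracle over randomized arrangements and with mirrored
structures.

Hydrogens are excluded from the quadruples deliberately: most X-ray
models carry none, and the heavy-atom improper is just as discriminating.

### Scan policies

Files are read from fixed PDB columns. Only the first model of a
multi-model file is scanned, and for residues with alternate
conformations only the first-encountered altLoc identifier is kept —
"first conformation" is interpreted as file order, matching the
semantics of the records themselves. HETATM records are parsed but only
checked when their residue name is a standard amino acid or nucleotide;
cofactor and ligand chirality is out of scope. Malformed coordinate
records are skipped with a warning and counted, never fatal, so that a
batch survey is total over arbitrary archives.

## Correction model

Corrections are reflection moves followed by a local restrained
relaxation:

- a peptide bond is toggled by reflecting the carbonyl O through C or
  the amide H through N (X-ray models and Xaa-Pro bonds leave only the
  O move). C$_\alpha$ atoms are never moved, which keeps the structural
  perturbation minimal. Which atom to move depends on the local
  hydrogen-bonding environment and is left to the user.
- a chiral center is toggled by reflecting its hydrogen through the
  center — the hydrogen is the smallest substituent, so this is the
  least perturbing seed for the inversion; the heavy-atom rearrangement
  is completed by the relaxation step under an improper restraint at
  the mirrored reference.

### The bonded-term model

`regularize_local()` minimizes a harmonic bonded model over the atoms of
all residues having any atom within a cutoff (default 8 Å) of the site;
all other atoms are left bit-identical, which is what keeps the
procedure local. The model contains:

| term | form | default constant |
|---|---|---|
| bonds | $k_b (r - r_0)^2$ | $k_b$ = 300 kcal mol⁻¹ Å⁻² |
| angles | $k_\theta (\theta - \theta_0)^2$ | $k_\theta$ = 50 kcal mol⁻¹ rad⁻² |
| peptide planarity impropers | $k_i (\phi - 180°)^2$ on (C$_\alpha$, C, N, O) and (C$_\alpha'$, N, C, H) | $k_i$ = 40 kcal mol⁻¹ rad⁻² |
| peptide two-fold torsion | $k_\omega (1 - \cos 2\omega)$ | $k_\omega$ = 10 kcal mol⁻¹ |
| target restraint | $k (\Delta\phi)^2$, periodic-wrapped | $k$ = 200 kcal mol⁻¹ rad⁻² |

The two planarity impropers equal 180° in *either* isomer, so they
enforce the sp² planarity of the peptide group without biasing cis
versus trans; the two-fold torsion gives the group its rotational
stiffness with minima at both 0° and 180° (barrier $2k_\omega$ =
20 kcal mol⁻¹, matching the physical isomerization barrier's order of
magnitude) — without it, strain released during a correction could
silently twist a neighboring bond through 90°. Isomer preference enters
only through the explicit target restraint. There are no non-bonded
terms: the model's job is to restore ideal covalent geometry around a
stereochemical move, not to fold proteins, and omitting them keeps the
relaxation strictly local and fast.

Reference values $r_0$, $\theta_0$ are measured once from
template-built ideal tripeptides and cached, so the builder's ideal
geometry is *exactly* a minimum of the model; unknown residues fall
back to element-pair bond lengths and hybridization-typical angles.
Connectivity comes from name-based tables covering the 20 standard
amino acids, with distance-based perception (1.25 Å to hydrogen,
1.85 Å heavy–heavy, 2.1 Å to S/P) only for residues without a table.

### Minimization

The energy is minimized with L-BFGS using analytic gradients, polished
with a second solver (PORT/`nlminb`) because the L-BFGS line search can
stall in the stiff, nearly singular valleys this model produces, with
up to four deterministic-jitter restarts as a saddle-escape mechanism
(the jitter is a fixed sinusoidal perturbation of 2×10⁻³ Å, so repeated
runs are identical). The iteration budget is 2000 per solver call and
convergence is declared at a maximum gradient component of
0.1 kcal mol⁻¹ Å⁻¹; on non-convergence the best-found coordinates are
returned with a warning and `attr(, "converged") = FALSE`.

Two initial-guess constructions make the large-angle corrections
reliable rather than hopeful:

- **dihedral targets** more than 30° from their reference: the mobile
  part of the downstream segment is rigidly rotated about the bond
  axis onto the target isomer, and any peptide O or amide H that ends
  up on the wrong side of its (always-180°) planarity improper is
  reflected through its bonded heavy atom. Rotating a mid-chain bond
  with the far end held fixed is a loop-closure problem; with ~10 free
  backbone torsions inside the mobile zone a closed solution exists,
  and the minimizer only has to polish it.
- **improper targets** on the wrong side of the reference (chirality
  inversions): the branch hanging off the `s2` substituent is mirrored
  through the plane of (`s1`, center, `s3`) — this inverts the center
  while preserving every bond length and angle exactly — and hydrogens
  on the center are re-idealized to the tetrahedral completion.

### Restraints

`generate_restraints()` emits one harmonic dihedral per evaluable
peptide bond on the $\omega$ atoms (reference 180° if currently trans,
0° if cis — a genuine cis bond the user keeps is preserved as cis) and
one harmonic improper per evaluable center at its current value. The
extra-bonds text format (`keyword, four 0-based atom indices into the
written atom order, force constant, reference angle`) is the side-file
dialect of NAMD's `extraBonds` facility. These restraints are meant for
relaxation stages where large forces could flip stereochemistry (e.g.
flexible fitting, high-temperature protocols) and should be removed
before production equilibrium simulations, where they would be an
unnecessary modification of the force field.

## The synthetic test bed

`build_peptide()` constructs peptides atom-by-atom from internal
coordinates (natural-extension frame placement) with ideal backbone
geometry — N–C$_\alpha$ 1.458 Å, C$_\alpha$–C 1.525 Å, C–N 1.329 Å,
C=O 1.231 Å, standard backbone angles — user-set φ/ψ/ω (default
−57/−47/180, an ideal α-helix), and side chains from per-residue
templates (Ala, Gly, Gln, Thr, Ile, Pro, Ser, Val; the glutamine
rotamer is an arbitrary fixed choice, irrelevant to every test). The
default sequence is the 15-residue helix AAQAAAAQAAAAQAA, a minimal
system in which a single mid-chain error has maximal, unambiguous
consequences. Perturbations are injected exactly: `cis_bonds` sets the
listed ω to 0°, and `d_residues` negates the C$_\alpha$ branch torsions
(equivalently, mirrors H and side chain about the backbone plane),
inverting the center without touching the backbone. Proline's
pyrrolidine ring is closed only approximately (its CD–N distance comes
from fixed ring torsions); this is irrelevant to detection and noted
here for completeness.

What the fixtures emulate: exact topology, ideal geometry, deterministic
anomalies at known sites, PDB headers (EXPDTA, matching and deliberately
false CISPEP records), chain breaks and missing atoms. What they do not
emulate: thermal noise, refinement artifacts, alternate conformations
with genuinely different geometry, solvent, or the borderline
$|\omega'|$ distortions of real distorted models. Passing the battery
therefore demonstrates correctness of the decision logic and the
correction machinery, not robustness to every pathology of the archive;
the malformed-record and threshold-boundary tests cover the latter
separately and deliberately.

## Survey and aggregation

`survey_structures()` scans files independently (order-invariant,
failures recorded per file) with an optional JSON-lines cache keyed by
file checksum, so interrupted archive-scale runs resume. Header
cross-validation matches each detected cis bond against CISPEP records
on (chain, residue number, insertion code) of both partners; chirality
is compared at structure level only, because CAVEAT records are free
text and chirality outliers are documented inconsistently (often in
REMARK 500) — per-site matching would manufacture precision the records
do not carry. `aggregate_by_method()` reduces results to one row per
experimental method plus an "All" row: total errors,
residues-per-error (total residues checked ÷ total errors, rounded),
structures analyzed, and structures with errors with an integer
percentage. Both the evaluable-residue count and the total residue
count are reported per structure, since "residues per error" depends on
which denominator a survey chooses.

## Conventions and numerical choices

- **Torsion sign**: IUPAC — looking from the second atom toward the
  third, clockwise rotation from the near to the far substituent is
  positive. The convention is pinned in the tests by a brute-force
  rotation oracle; detection itself depends only on $|\omega'|$ and on
  the calibrated improper sign, so any self-consistent convention would
  give identical verdicts.
- **Angle range** $(-180°, +180°]$, with the boundary mapped to +180 so
  trans is one representable value.
- **Degeneracy**: frames with a cross-product norm below $10^{-10}$ Å²
  (collinear or coincident atoms) raise an explicit error in the
  geometry kernel; during a scan the affected record is marked
  unevaluable instead, and the scan continues.
- **Insertion codes** are carried through and are part of residue
  identity everywhere (enumeration, matching, site parsing).
- Problem sizes in the shipped tests and the acceptance script: the
  15-residue default helix and its 8-file battery, 50 random build
  specs for the mirror suite, 1000 random arrangements for the
  improper-sign oracle, 100 random rigid motions and placements for the
  geometry kernel — sizes at which every property is exhaustively
  checkable in seconds on one core.

## Known limitations

- PDB dialect only; mmCIF is not parsed (every header record used for
  cross-validation is a PDB-format construct).
- The regularizer's named connectivity covers the standard amino acids;
  nucleic-acid correction is limited to detection plus reflection moves
  (sugar re-regularization would need a sugar-pucker-aware model).
- Side-chain sp² planarity beyond the peptide group is maintained only
  by angle terms during regularization.
- The fixture builder covers eight residue types; sequences outside
  them must come from files.
- D-amino acids and cis bonds can be genuine biology; the package
  flags, reports, and waits for the user — by design it has no
  auto-correct.
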