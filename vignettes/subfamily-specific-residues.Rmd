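---
title: "Detecting subfamily-specific residues and their structural roles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting subfamily-specific residues and their structural roles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subspec)
```

## The problem

A protein domain family often splits into subfamilies defined not by the
domain's own sequence but by its *context*: the ordered series of domains it
is embedded in (the domain architecture, DA). The pleckstrin homology (PH)
domain is the canonical example — the same fold sits behind a Sec7 exchange
domain in ARNO and behind an RGS + kinase pair in GRK2, and in each context
it has acquired residues that the other subfamily does not conserve. Those
DA-specific residues are candidates for the interfaces, linker contacts,
ligand specificity and conformational switches that make each multidomain
protein work.

`subspec` implements that analysis end to end:

1. **Homologue selection** (`match_architecture()`, `greedy_cluster()`):
   keep only proteins whose annotated domains reproduce the query DA, then
   collapse redundancy above 90% identity.
2. **Column classification** (`classify_alignment_pair()`): compare the two
   subfamily alignments column by column and call each position
   shared-conserved, DA-specific to one side, to both, or nonspecific.
3. **Burial filter** (`shrake_rupley()`, `apply_burial_filter()`): discard
   positions whose reference-structure residue is buried (relative
   accessibility at or below 7%), since those maintain the fold rather than
   a subfamily-specific function.
4. **Role assignment** (`hydrogen_bonds()` and friends,
   `assign_direct_roles()`, `second_shell_roles()`, `conformer_diff()`):
   read 3D structures, type the contacts, and classify each DA-specific
   residue as directly interacting with a partner
   (domain, linker, partner chain, or ligand), as maintaining such an
   interaction from the second shell, or as having no assignable role.

## The classification rule

Let $f_\mathrm{res}(c)$ be the largest single-residue fraction in column
$c$ of one subfamily alignment (gaps count in the denominator), and
$f_\mathrm{grp}(c)$ the largest fraction of any Clustal-X *strong* group.
A column is **conserved** when $f_\mathrm{res}\ge 0.85$ or
$f_\mathrm{grp}\ge 0.85$ (the threshold is inclusive), and
**semi-conserved** when only a Clustal-X *weak* group reaches 0.85.

A column pair is:

* **shared-conserved** — both sides conserved with the same residue or with
  overlapping strong groups;
* **DA-specific to A** — side A conserved, while side B shows *neither* the
  same residue above 50%, *nor* a single residue of the same type (a strong
  group-mate of A's majority) above 50%, *nor* semi-conservation of a weak
  group containing A's majority; symmetrically for B;
* **DA-specific to both** — both candidate rules fire with different
  conserved residues (e.g. Ser on one side, Val on the other);
* **nonspecific** — otherwise.

Two definitions here are genuinely open choices and are worth stating:

* *"Conservative substitution"* has no single standard definition; we adopt
  the Clustal-X strong groups
  (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW) and weak groups
  (CSA, ATV, SAG, STNK, STPA, SGND, SNDEQK, NDEQHK, NEQHRK, FVLIM, HFY),
  the convention used by the alignment viewers this kind of analysis is
  inspected with.
* The *">50% same residue type"* exclusion is implemented as the largest
  **single-residue** fraction among strong-group mates of the majority
  residue, not the group sum. A column scattered over several type-mates
  (say 40% Lys + 40% Glu) does not veto specificity; a single dominating
  type-mate (55% Glu against a Lys-conserved column) does. The group-sum
  reading would additionally let a 40/45 Lys/Glu split count as
  group-conserved at exactly the inclusive 0.85 threshold and collapse such
  columns into the shared class, which contradicts the intent of the
  exclusion (the other side being *diffusely* similar is not conservation).

Gaps count as evidence of non-conservation: a column with more than 15%
gaps can never be conserved. This is deliberate and visible in the rule
rather than hidden in preprocessing.

Thresholds (0.85 conservation, 0.50 cross-family exclusion, 7% burial) are
arguments with these defaults throughout.

## Mapping columns between alignments

The combined alignment and the two subfamily alignments come from separate
alignment runs, so their columns must be reconciled. `build_column_map()`
pairs a combined column with the subfamily column that holds the same
ungapped residue of each shared sequence and takes a majority vote across
shared sequences, recording the agreeing fraction as support. Ties and
columns gapped in every shared sequence stay unmapped, and the map is
forced injective (the better-supported claim wins). When the combined
alignment is a row-stack of the subfamily alignments — as the synthetic
generator builds it — the map is the identity with support 1.

`column_to_reference()` converts columns to residue numbers of a chosen
reference row plus an offset, so classified columns can be reported in PDB
author numbering (the numbering used in structure-derived tables).

## Solvent accessibility

`shrake_rupley()` computes accessible surface area with the classic
sphere-sampling construction: each heavy atom gets a deterministic
golden-spiral point set (default 960 points) on its solvent sphere (van der
Waals radius + 1.4 Å probe), and its area is the fraction of points outside
all neighbouring spheres. There is no random number use anywhere in the
computation, so results are bit-stable across runs and platforms.

Element-based van der Waals radii are used (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å) with hydrogens ignored. Relative accessibility divides the
summed residue area by the theoretical maximum for that residue type in an
extended Gly-X-Gly tripeptide (all-atom reference values). The burial
cutoff, RSA ≤ 7%, is inclusive. Atom-type-specific radius sets would shift
raw areas by a few percent, but the downstream decision is a set membership
(buried or not) at 7%, which is robust to that choice; the tests check
per-atom areas against an independent 10⁴-point quadrature (2%) and
per-residue areas against an independent SASA implementation (5%).

## Contact typing

All detectors are distance-criterion re-implementations of the interaction
classes used by protein-interaction calculators, chosen for
reproducibility — angle terms would require hydrogen placement that crystal
structures at this resolution do not support:

| type | atoms | default cutoff |
|---|---|---|
| hydrogen bond (MM/MS/SS) | tabulated donor N/O to acceptor O/N | 3.5 Å |
| salt bridge | Asp/Glu carboxylate O × Lys/Arg/His N | 6.0 Å (strong ≤ 4.0) |
| hydrophobic | side-chain C × side-chain C, apolar residues | 5.0 Å |
| water bridge | protein N/O — water O — ligand O/P | 3.5 Å per leg |
| ligand polar | protein N/O × ligand O/P | 3.5 Å |
| generic | any heavy atom pair | 4.5 Å |

Main-chain/main-chain hydrogen bonds within a chain require a sequence
separation of at least two residues, the usual convention that keeps
covalently adjacent backbone N/O pairs out of the list. His is treated as
chargeable. One interaction is reported per residue pair per type, with the
closest atom pair recorded; counts of "unique residue pairs" then fall out
naturally. Because the exact cutoffs used by any particular calculator
version are not recoverable, all cutoffs are arguments, and structure-based
counts should be read across the plausible grid (H-bond 3.2–3.5 Å, salt
bridge 4–6 Å) rather than at a single point.

## Roles: "interacts" vs "maintains"

`assign_direct_roles()` gives a residue a direct role toward partner $P$
when at least one labelled interaction crosses from it into $P$ (another
segment, another chain, or a ligand/water bridge). `second_shell_roles()`
gives a residue a *maintains* role when it is **not** a direct contactor of
$P$ but has any intraprotein interaction with a residue that is — one hop
only, since the language of such annotations ("maintains the interface")
never chains further, and direct always wins. Conformer membership flags a
residue per conformer when it holds at least one direct interdomain or
interchain role there. `conformer_diff()` collapses interactions to unique
unordered residue pairs *ignoring type* (a pair trading a hydrogen bond for
a hydrophobic contact has not lost its interaction), filters to pairs
touching the selected region (either member suffices), and reports set
differences.

## What the synthetic generator emulates — and what it does not

`gen_alignment_pair()` reproduces the statistical structure the
classification assumes: per-column planted classes with the subfamily
sizes, column count and class mix of the motivating PH-domain study
(88 + 21 sequences, 120 columns; 16 shared, 40 A-specific and 21 B-specific
positions of which 10 overlap, the rest variable). Planted recipes are
constructed to be exactly recoverable at zero noise: the non-conserved side
cycles through residues sharing no strong or weak group with the planted
residue, no three of which share a strong group, so neither reading of the
type exclusion is ever at stake. Substitution noise replaces cells with
uniform residues at a given rate, which is what makes the recovery-vs-noise
curve checkable against a direct multinomial resampling oracle.

The generator deliberately does **not** emulate phylogenetic correlation
between rows, realistic indel placement, or alignment error; columns are
independent. Passing the recovery tests therefore shows the *rule* is
implemented correctly and degrades gracefully, not that real subfamily
alignments of any particular depth will yield a fixed residue count —
database-snapshot-dependent counts are out of reach by construction.

`gen_annotation_set()` plants exactly one rule violation per defective
entry (overlap, extra domain, wrong order, truncated domain, 95-residue
linker vs an 8-residue reference, oversized terminal extension, fragment
flag) around a Sec7+PH query with a 20-residue relaxation on linkers and
termini, plus near-duplicates for clustering. `gen_toy_structure()` builds
coordinate files whose planted geometry is exact: an ideal helix from
standard backbone geometry (phi −57°, psi −47°), an Asp/Arg pair at a
stated charged-atom distance, a carbon buried under an overlapping
icosahedral shell, and a star-shaped ligand pocket with four planted polar
contacts, two water bridges and one decoy water.

## Numerical and degenerate-input choices

* Identity for redundancy removal is global (Needleman–Wunsch, BLOSUM62,
  gap open 10 / extend 0.5) with identities divided by the **shorter**
  ungapped length, so database entries differing only by terminal
  extensions reach 1.0 and cluster together; `X` never counts as identical.
  Clustering is greedy in length order (ties by identifier), membership
  strictly above the cutoff.
* Linker/extension relaxation is a symmetric band: |observed − reference|
  ≤ 20 residues. Domain lengths use the seed-alignment extremes with no
  extra slack.
* Majority residues, clustering ties and altloc ties (equal occupancy →
  altloc "A") break deterministically; profile ties break alphabetically.
* Rejection reasons are evaluated in a fixed order (fragment, extra domain,
  order, overlap, domain length, linker, extension), so a multiply
  defective entry reports the first applicable code.
* Problem sizes in the shipped checks: recovery curves use 200+ columns per
  noise level at the study's 88/21 depths against a multinomial oracle of
  about 1000 columns; SASA oracles use 10⁴-point quadrature on ≤ 50-atom
  toys; clustering oracles use ≤ 20 sequences with the exhaustive identity
  matrix. These sizes make every check exact or tight while keeping the
  full suite to a couple of minutes.

## Limitations

* Conservation is frequency-based by design; no entropy or
  mutual-information statistics, no phylogenetic weighting. Deeply
  unbalanced subfamilies (here 21 sequences on one side) make the 85%
  threshold coarse — with 21 rows, one sequence is ~4.8 percentage points.
* Contact detection is heavy-atom distance only; borderline hydrogen bonds
  (3.4–3.6 Å) can differ from angle-aware tools, which is why cutoffs are
  exposed and grids reported.
* The burial filter depends on which structure represents the subfamily;
  that choice is the caller's, via the reference-mapping closure passed to
  `apply_burial_filter()`.
* Alignment construction itself (e.g. MAFFT) is an upstream step; the
  package validates and maps alignments but never re-aligns.
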