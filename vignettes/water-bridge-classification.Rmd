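---
title: "Classifying water-mediated hydrogen-bond bridges at RNA-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying water-mediated hydrogen-bond bridges at RNA-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HydroBridge)
```

## The model

Crystallographic waters at the interface of an RNA-protein complex can
simultaneously hydrogen-bond an amino-acid residue and a ribonucleotide.
Such a *water bridge* is treated as a small graph: the central water,
each participating amino acid and each participating ribonucleotide are
nodes, and hydrogen bonds are edges. The *order* of the multiplet is
the number of participating residues plus the central water, and equals
the degree of the water node plus one. A bridge with `a` amino acids
and `n` ribonucleotides carries the topology label `A<a>:w:N<n>`
(triplet for order 3, quartet for 4, quintet for 5, and so on). When at
least one *direct* amino-acid-to-ribonucleotide hydrogen bond connects
two members of the same bridge, the topology is *cyclic* (`cyc-`
prefix); otherwise every non-water node has degree one and the topology
is acyclic.

Each water-ribonucleotide contact is sub-classified by the moiety that
touches the water - nucleobase (`Nb`), phosphate (`Ph`) or ribose
(`Rb`) - and nucleobase contacts are further assigned to one of the
three hydrogen-bonding faces of the base: the Watson-Crick (`WC`),
Hoogsteen (`HG`) or Sugar (`SG`) edge. Amino-acid contacts are
classified by portion: main chain (`m`), side chain (`s`) or both
(`ms`).

## Hydrogen-bond detection

A hydrogen bond is called from three geometric criteria:
donor-heteroatom to acceptor-heteroatom distance at most 3.35 Å,
hydrogen-acceptor distance at most 2.7 Å, and donor-hydrogen-acceptor
angle at least 90°. These are the package defaults
(`hbondCriteria()`), and all three are tunable.

Two detection modes are provided. The default `heavy_atom` mode
enforces only the D-A distance: hydrogen positions for water,
hydroxyls, Lys NZ and the ribose 2'-OH are rotationally
underdetermined from heavy atoms, so a uniform distance-only treatment
avoids an arbitrary asymmetry between donor classes. `with_hydrogens`
mode places idealized hydrogens (N-H 1.00 Å, sp2/sp3 standard
geometry) on donors whose hydrogen geometry *is* fixed by the heavy
atoms - backbone amides (when the preceding residue's carbonyl carbon
is present), side-chain amides, guanidinium, ring NH, nucleobase
amines - and applies the full three-criterion test to those, while
rotatable donors remain distance-only. His ND1/NE2 are treated as
donor-or-acceptor, reflecting protonation ambiguity.

The same bond list can instead be ingested from HBPLUS `.hb2` output
(`readHB2()`), in which case downstream classification is identical;
this reproduces the pipeline used to compile the survey statistics this
package's scheme was designed around. Only the donor/acceptor
identities and the D-A / H-A / D-H-A fields of an `.hb2` record are
consumed.

Water-water hydrogen bonds are never enumerated: a bridge here has a
single central water, and multi-water chains are out of scope.

## Bridging waters and topology labels

A water is bridging when it appears in both the water-RNA and the
water-protein bond lists (`findBridgingWaters()`). One
bridge is built per bridging water (`buildBridge()`): distinct
hydrogen-bonded residues become members (several bonds from one residue
collapse to one member, though every bond is retained for the
statistics), and direct protein-RNA bonds *between members* set the
cyclic flag - protein-RNA bonds elsewhere in the structure are
irrelevant to the bridge. Waters with more than four hydrogen bonds
(above the tetrahedral limit, usually reflecting positional ambiguity
in the crystal) are retained and flagged `overTetrahedral` rather than
filtered, so they can be excluded downstream if desired. No cap is
placed on the order.

## Edge assignment rules

For each water-nucleotide contact the interacting atoms (`int_atoms`)
decide the classification, in this order:

1. **Ribose rule**: `O2'` together with `O3'` is ribose-sugar mediated
   (`Rb`, no edge).
2. **`O2'` alone** carries Sugar-edge semantics (annotation `SG`) on
   the ribose moiety.
3. **Two nucleobase atoms** (a water can bond at most two atoms of one
   base, a geometric constraint the code enforces by keeping the two
   closest and warning): residue-aware pair lists. WC:
   `[N1,N6] [N1,N2] [N1,O6] [N3,N4] [N3,O2] [N3,O4]`; HG:
   `[N6,N7] [N7,O6]`; SG: `[N3,N9] [N3,O2'] [N1,O2] [N2,N3] [O2,O2']`.
   The published lists mix purine and pyrimidine atom names; the
   shipped table (`inst/extdata/edge_rules.tsv`, editable without code
   changes) expands them per residue so lookups are unambiguous, and
   restricts `[N1,O2]` to pyrimidines (purine N1 pairs are WC
   context, and pyrimidine N1 is glycosidic). Pairs citing glycosidic
   nitrogens (`N9` purine, `N1` pyrimidine) are retained in the table
   for completeness but cannot arise from hydrogen bonds, since those
   atoms have no donor or acceptor capacity in a nucleotide.
4. **One unambiguous atom**: e.g. purine `N1` is WC, `N7` is HG,
   purine `N3` is SG, pyrimidine `N3`/`N4`/`O4` are WC.
5. **One ambiguous atom** (an exocyclic atom shared by two edges):
   the Euclidean distance from the water oxygen to the two atoms
   adjacent to the contact atom decides. For rA `N6`, the adjacent
   atoms are `N1` and `C5`: if `d(N1, O) < d(C5, O)` the contact is
   WC, otherwise HG. The full table - rA N6 (N1→WC / C5→HG), rG O6
   (N1→WC / C5→HG), rG N2 (N1→WC / N3→SG), rC/rU O2 (N3→WC / N1→SG) -
   is a reconstruction from chemistry (each entry is an exocyclic atom
   shared by exactly two edges) anchored on the rA N6 worked example;
   it ships as data so an amended version can be dropped in.

The rule uses a strict inequality, so an exact tie falls to the
second-listed edge. Ties are measure-zero on real coordinates; the
choice is documented rather than consequential. Contacts touching both
the nucleobase and the phosphate are annotated by the nucleobase edge
(group precedence Nb > Ph > Rb) and the multiplicity is logged.

Pure phosphate or non-`O2'` ribose contacts carry no edge; they are
reported with method `moiety_rule`, a value added here because the four
published method categories do not cover edge-less contacts.

## Nomenclature

`renderName()` produces systematic names such as
`cyc-Thr(s)|Gly(m):w:rU(Ph)|rC(Rb)|rG(Rb)`. Amino acids sit left of
the central `:w:` token grouped by portion - main-chain terms
immediately left, then `ms`, then side-chain terms - with names in
descending alphabetical order reading left to right within each group.
Ribonucleotides sit to the right: nucleobase terms first (WC, then HG,
then SG), then phosphate, then ribose, alphabetically within each
group. Repeated identical terms are rendered repeatedly, ordered by
chain and residue number for determinism (the scheme itself is silent
on collisions). The `cyc-` prefix does not sub-type which direct bond
closes the cycle; finer splitting would create a profusion of empty
classes. `parseName()` inverts the grammar and reports the character
position of any malformed term.

The theoretical size of the nucleobase-mediated triplet classification
follows from the scheme's combinatorics
(`enumerateTheoreticalClasses()`): 4 nucleobases × 3 edges ×
(18 amino acids × 2 portions + 2 × 1) = 456 single-portion classes,
plus 4 × 3 × 18 = 216 dual-portion (`ms`) classes, 672 in total, for
acyclic and cyclic triplets alike. The scheme's convention counts
exactly Gly and Leu as lacking a hydrogen-bonding side-chain portion;
chemically Ala, Val, Ile, Phe and Pro side chains are also apolar, and
the package's donor/acceptor tables reflect the chemistry - the
convention matters only for the class-count combinatorics, which this
function reproduces as published.

## Survey statistics

`aggregateSurvey()` counts hydrogen bonds (one water-to-residue-atom
bond = one count) for the residue-level tables, bridges for the
topology tables, and weights each water oxygen once in B-factor means.
Percentages are reported to one decimal. The amino acid ×
ribonucleotide pair matrix counts co-membership within a bridge, once
per (aa, nt) pair per bridge; counting bond pairs instead is a
plausible alternative reading and is documented here so the choice is
explicit. `tripletClassTable()` tabulates only nucleobase-mediated
`A1:w:N1` / `cyc-A1:w:N1` bridges, one cell per bridge, keyed by the
nomenclature terms. Outputs are deterministic TSVs plus a single JSON
summary (`writeReports()`), and per-structure inventories are emitted
as JSON-lines (`writeBridgeInventory()`).

One bridge is counted per bridging water per retained model; bridges
are not deduplicated across crystallographically identical chains.

## Structure input choices

Parsing is delegated to bio3d. One model is retained per run (model 1
by default; multi-model files are an NMR convention outside the X-ray
scope of this analysis, but the model is selectable). Alternate
locations resolve to the highest-occupancy conformer, ties to the
lexicographically first altloc, giving a single coherent geometry per
residue. Water residue names default to HOH/WAT/DOD/H2O and only the
water oxygen participates in geometry. Atom-name dialects (`*` and
typographic primes, `O1P`/`O2P`) normalize to PDB v3 conventions
(ASCII prime). Hydrogens in the input are dropped and re-derived only
where `with_hydrogens` mode needs them, for uniform treatment across
structures. Only the four canonical ribonucleotides and the twenty
canonical amino acids are classified; modified residues, DNA, ligands
and ions are `OTHER` and ignored. The phosphate/ribose split is
`Ph = {P, OP1, OP2, OP3, O5'}`, `Rb = {O2', O3', O4'}`: the `O2'+O3'`
combination is called ribose-sugar mediated, so `O3'` rides with the
sugar, while `O5'` stays with the phosphate ester it belongs to. This
partition shifts the Ph/Rb percentage split and is therefore stated
here and kept in one place in the code.

## The synthetic-data generator

`generateFixture()` realizes a requested inventory of bridges as a
small PDB file. Each bridge occupies a cell on a 30 Å grid; members
are rigid idealized residue templates (regular-polygon rings,
standard-ish bond lengths) rotated so the requested contact atoms sit
2.8-2.85 Å from the cell's water. Idealized geometry suffices because
the pipeline never inspects covalent geometry - only inter-residue
hydrogen-bond criteria - and because every placement is validated:
intended contacts satisfy the default criteria with at least 0.2 Å
margin, and every unintended donor/acceptor pair is kept beyond
3.55 Å, so no contact sits in the ambiguous band around the cutoff.
Orientation freedom (spin about each contact axis, plus permutation of
the nucleotide slot directions) is searched deterministically; an
unsatisfiable request - for example a seven-partner water - fails
loudly before anything is written. For cyclic entries a joint spin
search brings one role-compatible member pair to direct-bond distance.
B-factors come from the manifest (seeded draws centred at 36 Å² for
bridging waters and 45 Å² for decoy waters, echoing the observation
that bridge waters are more ordered than bulk solvent), which makes the
B-factor statistics exactly recoverable.

The default ensemble (`defaultEnsembleManifest()`, 45 bridges) covers
every topology from triplet to order six in cyclic and acyclic form,
all 14 realizable two-atom pair-list cases, both branches of every
ambiguous-atom distance rule, the ribose rule, `O2'`-alone SG
semantics, phosphate contacts, an `ms` portion contact, an
over-tetrahedral water, the worked nomenclature examples above, plus
non-bridging decoy waters and within-class (protein-protein, RNA-RNA)
decoy bonds that must not become bridges.

What passing on synthetic fixtures does and does not show: the
fixtures exercise the full decision logic - detection cutoffs,
bridging, topology, edges, names, statistics - on geometry that is
unambiguous by construction. They do not emulate crystallographic
disorder, symmetry mates, chain redundancy, marginal contacts near the
cutoffs, or modified residues; conclusions about real structures
additionally depend on those factors, and on HBPLUS parameter choices
when the `.hb2` route is used.

## Numerical and design notes

- Distances are plain Euclidean; the neighbour search bins atoms into
  cutoff-sized cells, and a brute-force all-pairs oracle in the test
  suite checks equivalence on small structures.
- PDB coordinates carry three decimals; the edge-probe generator
  computes its expected edge from coordinates at that precision so the
  expectation matches what any reader of the file computes.
- Loosening any criterion can only add bonds (tested as a monotonicity
  property).
- A worked scale note: the shipped tests and the acceptance script run
  on the 45-bridge ensemble (roughly 1,900 atoms), where the full
  pipeline takes well under a minute; survey of a typical real
  structure is dominated by the neighbour search and scales with the
  number of polar atoms.

## Known limitations

- Native detection in `heavy_atom` mode is more permissive than HBPLUS
  for rotatable donors (no hydrogen-based pruning); `.hb2` ingestion is
  the faithful route to that pipeline.
- The ambiguous-atom table is a reconstruction (see above) and is
  deliberately shipped as data.
- Edge assignment is defined only for canonical ribonucleotides; there
  is no scheme for modified bases, and no edge concept for protein
  atoms.
- Occupancy-weighted treatment of partially occupied waters is not
  attempted; the altloc rule keeps one conformer.
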