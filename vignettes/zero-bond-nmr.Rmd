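---
title: "Zero-order bonds: one graph model for organic and organometallic NMR work"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-order bonds: one graph model for organic and organometallic NMR work}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zobmol)
```

## The representation problem

Classical cheminformatics treats a molecule as a graph whose edges are
covalent bonds of order 1, 2 or 3. That model breaks down for
organometallic and coordination compounds: a ferrocene drawn with a
multi-center bond into the ring midpoint is not a graph at all, a drawing
with ionic Cp⁻ rings misstates charges, and a drawing with ten ordinary
single bonds wrecks the carbon valences. Every downstream algorithm --
implicit hydrogen assignment, aromaticity perception, canonical
identifiers, substructure search, HOSE-code shift prediction -- assumes the
graph model, so each broken depiction breaks the whole toolchain.

`zobmol` adopts the minimal repair: a **zero-order bond** ("zero bond"), an
ordinary two-endpoint edge of bond order 0 that records *any interaction
that is not a well-defined covalent bond*, plus an **explicit per-atom
hydrogen count**. A metallocene becomes a perfectly ordinary graph: each
ring carbon touches the metal through a zero bond (or one σ bond, see
below), each carbon keeps one hydrogen by rule, and the metal carries an
explicit count of 0. Because zero bonds contribute nothing to valence,
every organic-molecule algorithm keeps working unchanged, and because they
are real edges, graph algorithms see all the significant interactions.

```{r ferrocene}
fc <- make_metallocene("Fe")
fc
add_implicit_hydrogens(fc)$atoms$hcount
```

The same device covers the whole family of non-classical interactions:
3-centre-2-electron bridges, coordinate bridge bonds, agostic contacts,
charged coordination complexes and ηⁿ hapticity, each exemplified by
`make_fixture_corpus()`.

## Hydrogen and valence rules

Implicit hydrogens are computed **only for C, N, P, O and S**; every other
element -- metals above all -- requires an explicit count. The standard
valences are the single lowest common value per element (C 4, N 3, P 3,
O 2, S 2), adjusted by formal charge (N⁺ 4, O⁻ 1, carbanion/carbocation 3);
higher valence states (sulfate-like S, phosphate-like P) must be entered
with explicit counts. The bond-order sum counts each bond at its stored
order, so zero bonds add nothing: inserting a zero bond anywhere never
changes a hydrogen count, which the test suite asserts over hundreds of
random molecules. Over-valent atoms get a count of 0 and a warning rather
than an error, since they do occur in deposited data.

## Aromaticity

Two routes set the aromatic flag on the bonds of a ring:

* **Hückel 4n+2** over in-ring π electrons: an atom in an in-ring double
  bond (or an already-flagged aromatic bond) contributes 1, an anionic
  carbon or an uncharged N/O/S/P lone pair contributes 2, anything else
  breaks conjugation.
* **The η-ring rule**: an all-carbon ring whose every atom touches one
  common listed metal through a zero-order or single bond is aromatic.
  Hückel counting alone cannot flag the rings of a charge-free metallocene
  drawing, yet their π character is exactly what the coordination
  expresses; the rule makes it visible to HOSE codes and SMILES.

Rings come from a minimum-cycle-basis computation; for ring perception the
bonds incident to listed metals are excluded first, otherwise the ten
metal contacts of a metallocene shatter the carbocycles into C--C--metal
triangles. Perception only ever sets flags -- Kekulé bond orders survive in
the stored molecule -- and is idempotent. Known limitation: cations whose
aromaticity needs an empty p orbital (tropylium) are not recognized.

## Molfile and SDF extensions

Two deliberate extensions to V2000, both read and written:

* bond order 0 in the bond block (written literally; query bond type 8,
  "any bond", is accepted on input as a drawing-tool workaround and
  converted to a zero bond with a notice);
* one property line `M  ZHC  1 <atom> <count>` per atom with an explicit
  hydrogen count. The tag is configurable (`zob_options(hcount_tag=)`)
  because no fixed tag is standardized for this extension.

Bond type 4 maps to order 1 plus the aromatic flag. Wedge marks are kept on
covalent bonds but dropped (with a warning) from zero bonds: zero-order
wedge bonds do not exist, even though the format's separate stereo column
could technically carry them. Output is deterministic, and
`parse_molfile(write_molfile(m))` reproduces every atom and bond attribute.

## Identity, canonical ranking, extended SMILES

Compound identity is decided by an internal **identity key**: Morgan-style
iterative refinement over (element, charge, isotope, hydrogen count,
degree, incident bond classes including zero, aromatic membership),
followed by exhaustive individualization of residual ties taking the
lexicographically smallest serialized form. The key is invariant under
atom renumbering and separates non-isomorphic molecules in the test
corpus. It deliberately plays the role that external identifiers (InChI
for organics, TUCAN for organometallics) play for a production database;
those algorithms are published black boxes, so the package exposes
`is_organometallic()` -- at least one zero bond *and* at least one listed
metal (default Hf, Co, Zr, W, Ni, Pt, Os, Ti, Rh, Fe, deduplicated and
configurable) -- to let a caller dispatch to the identifier regime of
their choice, while the internal key is computed for everything.

SMILES output is canonical (atom order follows the canonical labels) and
extends the bond alphabet with an apostrophe for zero bonds, giving
`.'-=#$` from light to heavy. For a zero bond closing a ring the
apostrophe is written before the ring-closure digit at its opening
occurrence, so the number of apostrophes equals the number of zero bonds.
The dialect is write-only: stored SMILES are informational, never
re-parsed.

```{r smiles}
write_smiles(fc)
identity_table(list(ferrocene = fc))[, c("id", "organometallic")]
```

## Extended HOSE codes

A HOSE code encodes an atom's environment sphere by sphere. The extension
is the `<` symbol for zero bonds, traversed like any other bond. (Legacy
codes use `>` for coordinate bonds -- a related but different concept; it
is tolerated in stored reference text, normalized to `<` on comparison,
and never emitted.)

One normative layout is used everywhere:

```
<focus token>;<sphere 1>/<sphere 2>/.../<sphere n>
```

with bond symbols `%` (triple), `=` (double), `*` (aromatic), nothing
(single), `<` (zero); atom tokens are element symbols with trailing
charge; `&` closes a ring; `,` separates the neighbor groups of
consecutive parent atoms within a sphere. The symbol priority for ordering
is `%` > `=` > `*` > single > `<` -- the zero bond is the lightest bond,
consistent with the SMILES ordering above. Within a parent, neighbors sort
by bond symbol, ring-closure status, element priority, a depth-bounded
extended-connectivity key, and finally canonical rank, which makes codes
invariant under renumbering and identical for symmetry-equivalent atoms.
The depth-s code is a prefix of the depth-(s+1) code, so `hose_truncate()`
equals regeneration at the smaller depth.

Before encoding, `normalize_for_hose()` restores chemical equivalence that
a drawing hides: a single bond from a listed metal to a ring atom whose
ring already holds another atom zero-bonded to that metal is reclassified
as a zero bond (the σ+4-zero metallocene drawing becomes ten equivalent
contacts), and in-ring double bonds of aromatic rings are demoted to the
aromatic class (Kekulé independence -- the same normalization classic HOSE
codes apply to pyrrole). The result: all five atoms of a metallocene ring
share one code at every depth.

```{r hose}
generate_hose(fc, 1, 4)$text
length(unique(vapply(1:5, function(a) generate_hose(fc, a, 4)$text, character(1))))
```

Open design point, resolved as follows: a metal reached through a zero
bond *does* contribute its own neighbors to deeper spheres, so the second
ring of a sandwich is visible from sphere 2 on. This is what makes two
differently-substituted ferrocenes distinguishable at depth 3--4; set
`zob_options(hose_through_metals = FALSE)` to stop expansion at metals.

## Shift prediction

`build_shift_index()` stores every reference assignment (atom, nucleus,
shift) under its code at every depth 1..4 (default; four spheres is the
depth at which environment similarity saturates for typical ¹³C work).
`predict_shift()` looks the query code up at full depth and falls back one
sphere at a time; the first depth with at least one example wins, and the
prediction is the arithmetic mean of the matched shifts (median available
via `zob_options(aggregate = "median")` for outlier-heavy reference sets).
Proton shifts ride on their carbon's code under the `1H` nucleus, so
CH-group protons are predicted from carbon environments -- grouped rows
report the mean over equivalent positions.

A **reliability warning** is raised when the matched depth is below 3
spheres or fewer than 2 examples contributed (both thresholds
configurable). The exact warning criterion of production systems is not
standardized; depth and evidence count are the two quantities the fallback
actually measures, so the rule is stated in those terms. Leave-out
evaluation of a compound already in the index is supported through
record-level molecule ids (`exclude=`), since an exact-match method always
predicts a stored structure from itself.

Reports round both nuclei to two decimals and compute the error column as
|observed − predicted| rounded half away from zero at two decimals --
`shift_error(69.58, 69.36)` is `0.22`.

```{r predict}
fam <- list(f1 = make_metallocene("Fe", c(`6` = "methyl")),
            f2 = make_metallocene("Fe", c(`7` = "acetyl")),
            f3 = make_metallocene("Fe", c(`6` = "chloro")))
db <- make_shift_db(fam, noise_sd = 0.3, seed = 42)
idx <- build_shift_index(fam, db)
predict_molecule(idx, fc, nuclei = c("13C", "1H"))
```

## Two-stage substructure search

Stage one is a screen on path fingerprints: 1024 hashed bits from all
simple paths of up to 7 bonds (atoms annotated by element, bonds by order
class including zero and aromatic; one bit per path via a fixed-seed
32-bit FNV-1a hash), plus two reserved bits at the top: **Z** (a zero bond
is present) and **M** (a listed metal is present). A candidate survives iff
`query AND candidate == query`. Path features of a subgraph are a subset
of the supergraph's, so the screen has no false negatives; the reserved
bits keep organometallic fragment queries from drowning in organic false
positives, and they live outside the hashed region so organic fingerprints
stay comparable to a pure path fingerprint. Bit count and path depth are
conventional choices, not prescribed values.

Stage two verifies survivors with a backtracking subgraph-isomorphism
matcher: injective on atoms, preserving element and charge, and mapping
each query bond to a target bond of the same class -- **zero bonds match
zero bonds only**, aromatic match aromatic (both sides are
aromaticity-perceived first, so Kekulé drawings cannot leak through).
Hydrogen counts are not query constraints. Candidate ordering is
rarest-label-first with connected extension. The search stops after 300
verified hits by default; longer hit lists are not realistically
inspected. `tanimoto()` supplies fingerprint similarity for ranking.

## The synthetic-data generators

`make_metallocene()` builds the σ+4-zero sandwich described above (the
alternative five-zero-bonds-per-ring drawing is equally valid; HOSE
normalization maps both to the same ten-contact form, which is why the
package standardizes on one). `make_fixture_corpus(n, seed)` emits one
exemplar per coordination-bond family followed by a mix of random organic
molecules and substituted metallocenes; `make_shift_db()` assigns every
carbon its coarse-environment class mean plus Gaussian noise
(`noise_sd = 0.3` ppm by default -- the order of scatter a tight
structural class shows in curated ¹³C data). The class anchors are
chemically plausible magnitudes (metal-ring CH 69.4, carbonyl 200, methyl
27.3, aromatic CH 128.5 ppm, with matching ¹H values), chosen once so
reports look like real spectroscopy.

What the generator emulates: families of related structures whose
equivalent atoms share tight shift distributions, observed with
independent Gaussian noise. What it does not emulate: solvent and
referencing offsets, temperature effects, heavy-atom relativistic shifts
near metals, assignment errors, or the long-tailed coverage of a real
deposition database. Passing the recovery test therefore demonstrates that
indexing, equivalence grouping, fallback and averaging are correct -- not
that predictions on sparse real organometallic data reach any particular
accuracy; with scarce references the method honestly degrades to shallow
matches and warnings, which is exactly the behavior the report surfaces.

Test and acceptance problem sizes (hundreds of molecules, 500
subgraph/supergraph pairs with an exhaustive-enumeration oracle on up to
12-atom targets, 100 permutations-times-molecules sweeps) were chosen so
the exhaustive oracles stay exact while the whole suite runs in a couple
of minutes.

## Numerical and degenerate-input choices

* Rounding of printed shifts and errors: half away from zero, two
  decimals, with a 1e-9 fuzz against binary representation artifacts.
* Empty molecules, isolated atoms and disconnected graphs are legal
  everywhere: an isolated atom's HOSE code keeps its empty spheres
  (`"C;///"`), an empty fingerprint has Tanimoto similarity 1 with itself.
* At most one bond per atom pair; zero bonds with wedge marks are a parse
  warning (mark dropped), self-bonds and dangling bonds are errors naming
  the line.
* Ties in canonical ranking that survive refinement are resolved by
  exhaustive branching, so regular highly-symmetric graphs cost more time
  but never lose correctness.

## Limitations

* No V3000, CIF/XYZ, 3D geometry, tautomer handling or stereo-aware
  identity; wedge marks are stored but do not enter the key.
* The apostrophe SMILES dialect is write-only.
* The fingerprint is path-based only; ring-membership or count features
  could tighten screening further.
* Metal-nucleus shifts and coupling constants are out of scope (zero
  bonds do, usefully, mark where no J-coupling is expected).
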