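---
title: "Auditing structure-identifier consistency with inchiaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing structure-identifier consistency with inchiaudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large small-molecule archives store several descriptions of the same
compound side by side: a 3D structure file, a standard InChI string, and a
molecular formula. These are deposited and updated independently, so they
drift apart — a structure may encode the *trans* isomer while the archived
InChI declares the geometry ambiguous, or a formula may count a proton
that the covalent structure does not carry. `inchiaudit` regenerates the
standard InChI from the deposited 3D structure, derives unique and
reproducible atom labels from the InChI canonical numbering, and compares
the regenerated identifiers layer by layer with what the archive asserts,
classifying every disagreement. The audit flags; it never adjudicates
which side is correct.

## The identifier model

A standard InChI (`InChI=1S/...`) is a stack of `/`-delimited layers:

| layer | meaning |
|-------|---------|
| formula | Hill-notation composition of the *core parent* |
| `/c` | covalent connectivity between heavy atoms |
| `/h` | hydrogen counts/positions on heavy atoms (incl. mobile-H groups) |
| `/q` | net charge intrinsic to the covalent structure |
| `/p` | protons added to/removed from the core parent |
| `/b` | sp² double-bond geometry (*cis*/*trans*) |
| `/t`, `/m`, `/s` | chiral-center parities plus their reference frame |
| `/i` | isotopic labeling |

The core parent is the composition *before* any charge is imposed by
(de)protonation. Two identities connect the layers to the species actually
described, and both are enforced as package invariants:

- H(charged species) = H(core parent) + `/p`
- charge(charged species) = `/q` + `/p`

This arithmetic is what makes charged archived formulas reconcilable: a
formula `C15H17N4O3S+` is consistent with a core `C15H16N4O3S` plus
`/p+1` (charge by protonation — one extra H), while `C15H16N+` is
consistent with a core `C15H16N` plus `/q+1` (a quaternary nitrogen — no
extra H). `reconcile_formula()` distinguishes exactly these two
mechanisms in its explanation.

## Layer diffing and the category map

`diff_layers()` compares component-expanded layer texts; `/q` and `/p`
compare as per-component integer vectors so an absent layer equals an
explicit zero. Differing layers map onto discrepancy categories:

- `/c`, `/h` → atom connectivity
- `/p`, `/q` → charge
- `/b`, `/t` (and the dependent `/m`, `/s`) → stereochemistry
- `/i` → isotope; formula-level disagreement keeps its own category

`/m` and `/s` are folded into stereochemistry because a `/t` parity is
meaningless without its reference frame; the report still records raw
layer names so tallies restricted to `/b` or `/t` alone remain
computable. An entry can fall into several categories at once.

**Formula-layer rule.** The formula layer is flagged only when the two
strings disagree about *both* the core-parent composition *and* the
charged-species composition. Rationale: a record that writes an anion as
"neutral formula + `/p-1`" where the structure yields "anion formula +
`/q-1`" differs textually in its formula layer, yet both strings describe
the same charged species — the real disagreement lives in `/h`, `/p`,
`/q` and is reported there. A genuine composition error (wrong heavy-atom
count) fails both comparisons and is flagged as a formula discrepancy.

**Ambiguity.** A `?` in `/b` or `/t` (an undefined stereo element) is a
defined-vs-ambiguous difference and is reported like any other layer
difference, with an `ambiguous_stereo` flag on the report.

**Non-standard strings.** A deposited `InChI=1/` (non-standard options)
string is reported via `non_standard_deposited` and excluded from layer
diffing: comparing across option sets would produce spurious category
flags.

## Atom labeling

The InChI canonicalization itself is delegated to a conforming
implementation of the IUPAC algorithm (the InChI library bundled with
RDKit, driven through a small Python shim shipped with the package). The
delegate's name and version are stamped into every result and batch log,
because different library versions can legitimately disagree; drift is
surfaced, never hidden.

Labels are derived from the AuxInfo original-atom-numbering (`/N:`)
layer: heavy atom `j` in canonical order gets `<element><j>` (numbering
continues across components of multi-component records). Hydrogens take
their heavy neighbor's number: a lone hydrogen is `H<j>`; several
hydrogens on one heavy atom get suffixes `a, b, ...` ordered by distance
from the parent, then lexicographically by (x, y, z).

Two tie-breaks make the labeling reproducible where the standard leaves
freedom:

1. **Equivalent atoms.** The AuxInfo `/E:` layer lists canonical numbers
   of topologically equivalent atoms (e.g. the two carboxylate oxygens
   under a mobile hydrogen, or the four methyls of tetramethylammonium).
   The delegate's numbering *within* such a class depends on input atom
   order, so `assign_labels()` re-anchors it with the same geometric
   sort. Without this, labels like `O5`/`O6` swap under input
   permutation.
2. **Orphan hydrogens** (no heavy neighbor, e.g. molecular H₂) are
   numbered sequentially after all heavy atoms, with a warning.

With both rules, the derived InChI and the label-to-geometry assignment
are invariant under any permutation of the input atom order — the
property the test suite checks over 20 seeded permutations per fixture.

## Batch workflow

`run_batch()` reads every `.sdf`/`.sdf.gz` under a directory, drops
obsoleted duplicates (the last occurrence of a compound id wins, in file
read order), skips entries without 3D information (listed in
`skipped_2d_only.txt`), audits the rest, and writes the relational output
as three CSVs — the 11-field per-entry outputs table (structures in
SDF/PDB/XYZ with labels, InChI, Hill formula, warnings/errors, atom
maps), the metadata table, and the names table (first synonym +
count) — plus per-layer and per-category flagged-CID lists and a run log
carrying the delegate version and seed. Sharding assigns consecutive
18-file chunks round-robin to worker slots; results are merged in
deterministic cid order, so output is byte-identical for any worker
count, and re-running a completed directory is a no-op that rewrites
identical bytes.

## The synthetic corpus

`builtin_molecules()` provides twelve hand-frozen 3D structures (explicit
hydrogens, energy-minimized once, coordinates frozen into the source)
covering every mechanism the audit distinguishes: an achiral scaffold
pair of connectivity isomers (ethanol / dimethyl ether), a chiral pair
(L-/D-alanine), a geometry pair (cis-/trans-2-butene), an intrinsic
cation (tetramethylammonium), a (de)protonatable amino acid in two
tautomer geometries (glycine neutral and zwitterion — the InChI model
normalizes both to the same string, which the suite asserts), and a
two-component salt (sodium acetate) for multi-component layers and
labels.

`perturb()` realizes each discrepancy mechanism as a
(structure, deposited-InChI) pair; the deposited string is always
*generated by the delegate from a modified structure*, never hand-edited,
so ground truth rests on the delegate alone. Two chemistry facts shaped
the kinds:

- The InChI proton normalization writes a carboxylate as
  core + `/p-1` but an alkoxide as an intrinsic `/q-1` (with shifted
  `/h` and formula layers). `deprotonate` therefore targets carboxylic
  acids and expects a pure `/p` (charge) flag, while the alkoxide path
  is its own kind (`set_formal_charge`) expecting
  {formula, `/h`, `/q`}.
- A neutral sodium *atom* is not constructible as a clean fixture with
  this delegate (it acquires an implicit hydrogen and the InChI metal
  disconnection emits a spurious lone-H component), so no perturbation
  "neutralizes" the salt.

`make_corpus(n, seed, rate, dir)` samples entries (exactly
`floor(rate * n)` perturbed; clean entries get a random atom permutation,
which must never flag), writes sharded SDF files with the deposited
identifiers as data items, and a `truth.csv`. The default acceptance
world is 50 entries at rate 0.2. What a green corpus test establishes:
the audit recovers injected, delegate-backed discrepancies with category
precision and recall 1.0 and never flags permuted clean entries. What it
does not establish: behavior on real archive chemistry — tautomer-rich
systems, organometallics, polymers, or records whose deposited strings
were produced by other toolkits with other perception settings.

## Numerical and grammar choices

- Coordinates are Angstrom, read/written at fixed `%10.4f` molfile
  precision; geometric tie-breaks round to 4 decimals (well above the
  1e-4 file resolution, so ties are exact file duplicates).
- Figure-style typesetting (`InChI = 1 S/`, emphasis markers, unicode
  minus) is stripped before parsing, so strings transcribed from print
  are valid fixtures.
- Charge-suffix grammar for archived formulas: a trailing sign means
  ±1 (`C2H3O2-` is the singly charged acetate — digits before a trailing
  sign bind to the element, matching archive practice), and
  sign-then-digits carries a magnitude (`SO4-2`). The digit-before-sign
  dialect (`"2-"` as a charge) is deliberately not guessed at: it is
  syntactically ambiguous against element counts.
- V2000 only; V3000 records produce a distinct per-record error and the
  stream continues. Malformed records never abort a batch.
- Obsoleted duplicates: last occurrence wins; ties across files resolve
  by sorted file name order, which is the read order.

## Limitations

- The audit consumes 3D (or explicit-stereo) input only; 2D records are
  listed and skipped, and no 2D-to-3D projection is attempted.
- Non-standard InChI layers beyond flagging (`/r`, fixed-H) and InChIKey
  computation are out of scope.
- Stereo perception is the delegate's: structures whose stereochemistry
  the delegate cannot perceive from geometry are reported with the
  delegate's own warnings attached to the entry.
- The parallel contract is "each entry exactly once, deterministic
  merge"; the in-process scheduler is sequential, which is the honest
  desk-scale reading of a 300-core archive workflow.
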