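# inchiaudit

Structure-identifier consistency auditing for small-molecule databases.

Small-molecule archives store a 3D structure, a standard InChI string and
a molecular formula for each entry — deposited independently, and
therefore able to contradict one another. `inchiaudit` regenerates the
standard InChI from the deposited V2000 structure (delegating the
canonicalization to a conforming IUPAC InChI implementation), derives
unique, reproducible atom labels from the InChI canonical numbering, and
compares the result layer by layer with the archived identifiers:

* **formula reconciliation** — the InChI formula layer records the *core
  parent* (composition before charging); the species actually deposited
  has `H_core + /p` hydrogens and charge `/q + /p`. A charged formula
  like `C15H17N4O3S+` can therefore be checked exactly against a core
  `C15H16N4O3S` + `/p+1` (protonation) or `C15H16N` + `/q+1` (intrinsic
  quaternary-nitrogen charge);
* **layer diffing and categorization** — `/c`,`/h` mismatches are
  atom-connectivity discrepancies, `/p`,`/q` charge, `/b`,`/t` (with
  `/m`,`/s`) stereochemistry, `/i` isotope; one entry may fall in several
  categories;
* **canonical atom labels** — heavy atom *j* in canonical order is
  `<element><j>`; hydrogens inherit their parent's number with geometric
  `a, b, ...` suffixes; labels are invariant under input atom
  permutation;
* **batch auditing** — sharded multi-record `.sdf`/`.sdf.gz` archives,
  obsoleted-duplicate handling, relational CSV outputs (entry bundle,
  metadata, names), per-layer/per-category flagged-CID lists, seeded and
  byte-idempotent;
* **synthetic corpus** — builtin 3D fixtures plus delegate-backed
  perturbations with ground-truth labels for every discrepancy category.

## Requirements

R (>= 4.1) with `jsonlite`, plus Python 3 with RDKit on the `PATH` (the
InChI generation delegate; override the interpreter with
`options(inchiaudit.python = ...)`).

## Worked example

Audit a known discrepant record: the archive stores an anion written as
"one extra hydrogen + `/p-1`" while the structure carries the intrinsic
`/q-1` charge.

```r
library(inchiaudit)

ex <- worked_examples()                  # bundled public PubChem examples
derived   <- parse_inchi(ex$value[ex$cid == "2179800" &
                                  ex$field == "derived_inchi"])
deposited <- parse_inchi(ex$value[ex$cid == "2179800" &
                                  ex$field == "deposited_inchi"])
diff_layers(derived, deposited)
#> [1] "h" "q" "p"
categorize(diff_layers(derived, deposited))
#> [1] "atom_connectivity" "charge"
proton_delta(deposited);  net_charge(derived)
#> [1] -1
#> [1] -1
```

The formula layers differ textually (`C15H9N3O5` vs `C15H8N3O5`) but are
*not* flagged: after the `/p` arithmetic both strings describe the same
charged species, so the disagreement is reported where it lives — in the
hydrogen and charge layers.

Formula reconciliation distinguishes the two charging mechanisms:

```r
f <- parse_inchi(ex$value[ex$cid == "91929631" & ex$field == "derived_inchi"])
reconcile_formula("C15H17N4O3S+", f)$explanation
#> [1] "consistent; protonation case: deposited H = core H + 1, charge +1
#>      from /q+0 /p+1; expected C15H17N4O3S+, archived C15H17N4O3S+"
```

End-to-end on a synthetic corpus with known ground truth:

```r
make_corpus(50, seed = 424242, discrepancy_rate = 0.2, "corpus")
summary <- run_batch("corpus", "audit_out", batch_config(seed = 424242))
summary$entries_flagged
#> [1] 10
unlist(summary$flagged_by_category)
#> atom_connectivity    charge  stereochemistry  isotope  formula
#>                 4         4                2        0        0
```

(Flagged counts vary with the seed; one entry may carry several
categories. `audit_out/` then holds `outputs.csv`, `meta_data.csv`,
`names.csv`, `reports.csv`, the flagged-CID lists, and a run log stamped
with the delegate version.)

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","audit.R",package="inchiaudit"))')" \
    run --input corpus --output audit_out --workers 2 --seed 1
```

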