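# Shared fixtures. The builtin set is deterministic; computing it once and
# warming the delegate cache with a single batch call keeps the suite fast
# (every later generate_inchi() on an unmodified builtin is a cache hit).

builtins <- builtin_molecules()
builtin_inchi <- local({
  res <- generate_inchi_batch(builtins)
  stats::setNames(vapply(res, `[[`, "", "inchi"), names(builtins))
})

examples <- worked_examples()

ex_val <- function(cid, field) {
  v <- examples$value[examples$cid == cid & examples$field == field]
  stopifnot(length(v) == 1L)
  v
}

# A hand-written water record, the minimal well-formed V2000 fixture.
water_sdf_lines <- c(
  "water",
  "  handmade          3D",
  "",
  "  3  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.1173 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    0.7572   -0.4692 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000   -0.7572   -0.4692 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0",
  "  1  3  1  0",
  "M  END",
  "$$$$"
)

# Fixed seed stream for property-style loops.
perm_seeds <- function(n) seq(101L, by = 7L, length.out = n)

# Merged (single-formula view) core composition of a parsed InChI.
merge_comp <- function(layers) core_parent_formula(layers)$composition
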