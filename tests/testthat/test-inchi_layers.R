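test_that("parse_inchi decomposes the charged worked examples", {
  f2b <- parse_inchi(ex_val("91124997", "derived_inchi"))
  expect_true(f2b$standard)
  expect_equal(merge_comp(f2b), c(C = 15L, H = 16L, N = 1L))
  expect_equal(f2b$layers$q, "+1")
  expect_equal(f2b$layers$t, "12-")
  expect_equal(f2b$layers$m, "0")
  expect_equal(f2b$layers$s, "1")
  expect_equal(f2b$layers$p, "")

  f2a <- parse_inchi(ex_val("91929631", "derived_inchi"))
  expect_equal(f2a$layers$p, "+1")
  expect_equal(f2a$layers$q, "")
  expect_match(f2a$layers$h, "\\(H3,16,17\\)\\(H,19,20\\)$")
})

test_that("typeset whitespace and emphasis are normalized before parsing", {
  messy <- "InChI = 1 S/C15H16N/c1-11-6-5-9-15-14-8-4-3-7-13(14)10-12(2)16(11)15/h3-9,12 H,10H2,1-2H3/**q + 1**/t12-/m0/s1"
  expect_equal(serialize_inchi(parse_inchi(messy)),
               ex_val("91124997", "derived_inchi"))
})

test_that("water InChI parses to {H2,O1} with no charge/stereo layers", {
  w <- parse_inchi("InChI=1S/H2O/h1H2")
  expect_equal(merge_comp(w), c(H = 2L, O = 1L))
  expect_true(all(vapply(w$layers[c("q", "p", "b", "t", "m", "s", "i")],
                         identical, TRUE, "")))
})

test_that("parse errors and the non-standard prefix are surfaced", {
  expect_error(parse_inchi("C2H6O"), "missing 'InChI='")
  old <- parse_inchi("InChI=1/C2H6O/c1-2-3/h3H,2H2,1H3")
  expect_false(old$standard)
  expect_equal(old$version, "1")
})

test_that("serialize is the inverse of parse on every printed string", {
  for (v in examples$value[examples$field != "archived_formula"]) {
    norm <- serialize_inchi(parse_inchi(v))
    expect_equal(norm, v)
    # idempotence
    expect_equal(serialize_inchi(parse_inchi(norm)), norm)
  }
  for (v in unname(builtin_inchi)) {
    expect_equal(serialize_inchi(parse_inchi(v)), v)
  }
})

test_that("net_charge and proton_delta sum components; absent layers are 0", {
  expect_equal(net_charge(parse_inchi(ex_val("91124997", "derived_inchi"))), 1L)
  expect_equal(proton_delta(parse_inchi(ex_val("91124997", "derived_inchi"))), 0L)
  f4 <- parse_inchi(ex_val("2179800", "deposited_inchi"))
  expect_equal(proton_delta(f4), -1L)
  expect_equal(net_charge(f4), 0L)
  salt <- parse_inchi(builtin_inchi[["sodium_acetate"]])
  expect_equal(salt$q_values, c(0L, 1L))
  expect_equal(net_charge(salt), 1L)
  expect_equal(proton_delta(salt), -1L)
})

test_that("core-parent vs charged-species arithmetic follows /p and /q", {
  f2a <- parse_inchi(ex_val("91929631", "derived_inchi"))
  core <- core_parent_formula(f2a)
  sp <- charged_species_formula(f2a)
  expect_equal(core$composition, c(C = 15L, H = 16L, N = 4L, O = 3L, S = 1L))
  expect_equal(sp$composition, c(C = 15L, H = 17L, N = 4L, O = 3L, S = 1L))
  expect_equal(sp$charge, 1L)

  f2b <- parse_inchi(ex_val("91124997", "derived_inchi"))
  expect_equal(core_parent_formula(f2b)$composition,
               charged_species_formula(f2b)$composition)
  expect_equal(charged_species_formula(f2b)$charge, 1L)

  neutral <- parse_inchi("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")
  expect_equal(core_parent_formula(neutral), charged_species_formula(neutral))
})

test_that("H(charged) - H(core) == /p and charge == /q + /p on all strings", {
  all_inchis <- c(examples$value[examples$field != "archived_formula"],
                  unname(builtin_inchi))
  for (v in all_inchis) {
    l <- parse_inchi(v)
    core <- core_parent_formula(l)
    sp <- charged_species_formula(l)
    h <- function(f) if ("H" %in% names(f$composition)) f$composition[["H"]] else 0L
    expect_equal(h(sp) - h(core), proton_delta(l), info = v)
    expect_equal(sp$charge, net_charge(l) + proton_delta(l), info = v)
  }
})

test_that("charged_species_formula rejects impossible proton removal", {
  l <- parse_inchi("InChI=1S/CH4/h1H4")
  l$p_values <- -5L
  expect_error(charged_species_formula(l), "removes more hydrogens")
})

test_that("hill_format orders C, H, then alphabetical; no-C is alphabetical", {
  expect_equal(hill_format(c(C = 15L, H = 16L, N = 4L, O = 3L, S = 1L)),
               "C15H16N4O3S")
  expect_equal(hill_format(c(H = 2L, O = 1L)), "H2O")
  expect_equal(hill_format(c(C = 1L, H = 3L, Cl = 1L)), "CH3Cl")
  expect_equal(hill_format(c(H = 1L, Cl = 1L)), "ClH")  # no carbon: alphabetical
  expect_equal(hill_format(c(C = 4L, H = 12L, N = 1L), 1L), "C4H12N+")
  expect_equal(hill_format(c(O = 4L, S = 1L), -2L), "O4S-2")
})

test_that("hill ordering matches a brute-force sort oracle on random sets", {
  oracle <- function(els) {
    # independent restatement of the Hill rule via explicit rank vectors
    if ("C" %in% els) {
      rank <- ifelse(els == "C", "0", ifelse(els == "H", "1",
                                             paste0("2", els)))
    } else {
      rank <- paste0("2", els)
    }
    els[order(rank)]
  }
  pool <- c("C", "H", "O", "N", "S", "Cl", "Br", "Na", "Fe", "B", "Se", "I")
  set.seed(42)
  for (i in 1:50) {
    els <- sample(pool, sample(1:10, 1))
    comp <- stats::setNames(sample(1:9, length(els), replace = TRUE), els)
    got <- names(parse_formula_string(hill_format(comp))$composition)
    expect_equal(got, oracle(sort(els)), info = paste(els, collapse = ","))
  }
})

test_that("parse_formula_string handles the charge-suffix dialects", {
  r <- parse_formula_string("C15H17N4O3S+")
  expect_equal(r$composition[["H"]], 17L)
  expect_equal(r$charge, 1L)
  expect_true(r$was_charged)
  expect_equal(parse_formula_string("C15H16N+")$charge, 1L)
  expect_equal(parse_formula_string("H2O")$was_charged, FALSE)
  r <- parse_formula_string("SO4-2")
  expect_equal(r$charge, -2L)
  expect_equal(r$composition, c(O = 4L, S = 1L))
  expect_equal(parse_formula_string("Fe+3")$charge, 3L)
  # digits before a trailing sign bind to the element (acetate is -1)
  acet <- parse_formula_string("C2H3O2-")
  expect_equal(acet$charge, -1L)
  expect_equal(acet$composition, c(C = 2L, H = 3L, O = 2L))
  expect_error(parse_formula_string("C2Xx"), "unknown element")
  expect_error(parse_formula_string(""), "empty")
})

test_that("hill_format output re-parses to the same composition and charge", {
  set.seed(7)
  pool <- c("C", "H", "O", "N", "S", "Cl", "Na", "P")
  for (i in 1:25) {
    els <- sample(pool, sample(1:6, 1))
    comp <- stats::setNames(sample(1:20, length(els), replace = TRUE), els)
    chg <- sample(-3:3, 1)
    r <- parse_formula_string(hill_format(comp, chg))
    expect_equal(r$charge, chg)
    expect_equal(sort(names(r$composition)), sort(els))
    expect_equal(unname(r$composition[sort(names(r$composition))]),
                 unname(comp[sort(els)]))
  }
})

test_that("multi-component formulas expand multipliers", {
  l <- parse_inchi("InChI=1S/2C2H4O2.Na/c2*1-2(3)4;/h2*1H3,(H,3,4);/q;;+1/p-2")
  expect_length(l$formula, 3L)
  expect_equal(merge_comp(l), c(C = 4L, H = 8L, Na = 1L, O = 4L))
  expect_equal(l$q_values, c(0L, 0L, 1L))
  expect_equal(proton_delta(l), -2L)
})

test_that("has_ambiguous_stereo detects '?' in /b or /t only", {
  expect_true(has_ambiguous_stereo(parse_inchi(ex_val("1551886",
                                                      "deposited_inchi"))))
  expect_false(has_ambiguous_stereo(parse_inchi(ex_val("91124997",
                                                       "derived_inchi"))))
  expect_false(has_ambiguous_stereo(parse_inchi("InChI=1S/H2O/h1H2")))
})
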