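test_that("generate_inchi yields standard strings matching composition", {
  w <- generate_inchi(builtins$water)
  expect_match(w$inchi, "^InChI=1S/")
  expect_match(w$auxinfo, "^AuxInfo=")
  expect_null(w$error)
  expect_match(w$delegate, "rdkit")
  expect_equal(merge_comp(parse_inchi(w$inchi)), c(H = 2L, O = 1L))
})

test_that("formula layer equals atom counts modulo the proton delta", {
  for (nm in names(builtins)) {
    l <- parse_inchi(builtin_inchi[[nm]])
    sp <- charged_species_formula(l)
    expect_equal(sp$composition, atom_counts(builtins[[nm]]), info = nm)
    expect_equal(sp$charge, sum(builtins[[nm]]$atoms$charge), info = nm)
  }
})

test_that("mirror-image structures differ only in the /m layer", {
  l <- parse_inchi(builtin_inchi[["l_alanine"]])
  d <- parse_inchi(builtin_inchi[["d_alanine"]])
  expect_equal(diff_layers(l, d), "m")
  expect_equal(l$layers$m, "0")
  expect_equal(d$layers$m, "1")
})

test_that("empty molecules are rejected", {
  empty <- molecule(data.frame(element = character(), x = numeric(),
                               y = numeric(), z = numeric()))
  expect_error(generate_inchi(empty), "empty")
})

test_that("parse_auxinfo_numbering handles the layer grammar", {
  expect_equal(parse_auxinfo_numbering("AuxInfo=1/0/N:3,1,2/rA:..."),
               list(c(3L, 1L, 2L)))
  expect_equal(parse_auxinfo_numbering("AuxInfo=1/0/N:1,2,3/E:(1,2)"),
               list(1:3))
  expect_equal(parse_auxinfo_numbering("AuxInfo=1/1/N:2,1;3/rA:..."),
               list(c(2L, 1L), 3L))
  expect_error(parse_auxinfo_numbering("AuxInfo=1/0/rA:..."), "/N:")
})

test_that("two-component salt numbering agrees with the delegate", {
  aux <- generate_inchi(builtins$sodium_acetate)$auxinfo
  numbering <- parse_auxinfo_numbering(aux)
  expect_length(numbering, 2L)
  # component 2 is the bare sodium
  na_idx <- which(builtins$sodium_acetate$atoms$element == "Na")
  expect_equal(numbering[[2L]], na_idx)
  # the two carboxylate oxygens form an equivalence class
  eq <- parse_auxinfo_equivalence(aux)
  expect_equal(eq[[1L]], list(c(3L, 4L)))
  lab <- assign_labels(builtins$sodium_acetate, auxinfo = aux)
  expect_equal(lab$map$label[na_idx], "Na5")
  expect_equal(lab$map$component[na_idx], 2L)
})

test_that("water labels are O1, H1a, H1b fixed by geometry", {
  lab <- assign_labels(builtins$water)
  expect_setequal(lab$map$label, c("O1", "H1a", "H1b"))
  expect_equal(lab$map$label[1L], "O1")
})

test_that("methane gets one C label and four distinct H labels", {
  lab <- assign_labels(builtins$methane)
  expect_equal(sum(grepl("^C", lab$map$label)), 1L)
  expect_equal(sort(lab$map$label[-1L]), c("H1a", "H1b", "H1c", "H1d"))
})

test_that("hydrogens without a heavy neighbor get sequential labels + warning", {
  h2 <- molecule(data.frame(element = c("H", "H"),
                            x = c(0, 0.74), y = 0, z = 0),
                 data.frame(a1 = 1, a2 = 2))
  lab <- assign_labels(h2, numbering = list())
  expect_setequal(lab$map$label, c("H1", "H2"))
  expect_match(attr(lab, "warnings"), "heavy neighbor")
})

test_that("labels and InChI are invariant under atom permutation", {
  for (nm in c("ethanol", "glycine", "sodium_acetate")) {
    mol <- builtins[[nm]]
    ref_lab <- assign_labels(mol)
    ref_geom <- ref_lab$map
    ref_geom$x <- mol$atoms$x[ref_geom$original_index]
    ref_geom$y <- mol$atoms$y[ref_geom$original_index]
    key <- function(df) {
      df <- df[order(df$label), ]
      paste(df$label, round(df$x, 4), round(df$y, 4), collapse = ";")
    }
    perms <- lapply(perm_seeds(5), function(s) {
      set.seed(s)
      permute_molecule(mol, sample(nrow(mol$atoms)))
    })
    inchis <- generate_inchi_batch(perms)
    for (i in seq_along(perms)) {
      expect_equal(inchis[[i]]$inchi, builtin_inchi[[nm]],
                   info = paste(nm, i))
      lab <- assign_labels(perms[[i]], auxinfo = inchis[[i]]$auxinfo)
      g <- lab$map
      g$x <- perms[[i]]$atoms$x[g$original_index]
      g$y <- perms[[i]]$atoms$y[g$original_index]
      expect_equal(key(g), key(ref_geom), info = paste(nm, i))
    }
  }
})

test_that("labels are unique and bijective for every builtin", {
  for (nm in names(builtins)) {
    lab <- assign_labels(builtins[[nm]])
    expect_equal(nrow(lab$map), nrow(builtins[[nm]]$atoms), info = nm)
    expect_false(anyDuplicated(lab$map$label) > 0, info = nm)
    expect_setequal(lab$map$original_index,
                    seq_len(nrow(builtins[[nm]]$atoms)))
  }
})

test_that("labeled SDF molfile blocks are identical across input orders", {
  mol <- builtins$ethanol
  molblock_of <- function(m) {
    txt <- strsplit(write_labeled_sdf(m, assign_labels(m)), "\n")[[1L]]
    paste(txt[3:(which(txt == "M  END"))], collapse = "\n")  # skip title
  }
  set.seed(303)
  permuted <- permute_molecule(mol, sample(nrow(mol$atoms)))
  expect_equal(molblock_of(permuted), molblock_of(mol))
  # and the labeled output re-reads to the same compound
  rt <- read_sdf(write_labeled_sdf(mol, assign_labels(mol)),
                 text = TRUE)$molecules[[1L]]
  expect_equal(generate_inchi(rt)$inchi, builtin_inchi[["ethanol"]])
})

test_that("label_map_csv serializes original_index,label pairs", {
  csv <- label_map_csv(assign_labels(builtins$water))
  lines <- strsplit(csv, "\n")[[1L]]
  expect_equal(lines[1L], "original_index,label")
  expect_length(lines, 4L)
})
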