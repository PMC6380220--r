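# Synthetic-data generator: a small set of hand-frozen 3D molecules and
# controlled perturbations carrying ground-truth discrepancy labels, so
# every audit path is testable without downloading any archive.
#
# Coordinates were energy-minimized once and frozen into this file; they
# are part of the stated test world, not tunable parameters. All
# structures carry explicit hydrogens, as 3D archive records do.

AVERAGE_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  Na = 22.990, S = 32.06)
MONOISOTOPIC_MASS <- c(H = 1.007825, C = 12, N = 14.003074, O = 15.994915,
                       Na = 22.989769, S = 31.972071)

#' Built-in fixture molecules
#'
#' A named list of small molecules with frozen 3D coordinates and
#' explicit hydrogens: water, methane, ethanol, dimethyl ether, glycine
#' (neutral and zwitterion geometries), L- and D-alanine, cis- and
#' trans-2-butene, the tetramethylammonium cation (intrinsic charge), and
#' sodium acetate (a two-component salt). The set covers every
#' discrepancy mechanism the audit distinguishes: connectivity isomers,
#' (de)protonation vs intrinsic charge, double-bond geometry, chiral
#' centers, and multi-component records.
#'
#' @return Named list of [molecule()] objects.
#' @export
builtin_molecules <- function() {
  mk <- function(el, x, y, z, a1, a2, ord, chg_idx, chg_val) {
    atoms <- data.frame(element = el, x = x, y = y, z = z,
                        charge = 0L, stringsAsFactors = FALSE)
    atoms$charge[chg_idx] <- as.integer(chg_val)
    molecule(atoms, data.frame(a1 = a1, a2 = a2, order = ord),
             is_3d = TRUE)
  }
  mols <- list(
  water = mk(
    el = c("O", "H", "H"),
    x = c(0.0075, -0.7671, 0.7596),
    y = c(0.3977, -0.1844, -0.2134),
    z = c(0.0000, 0.0000, 0.0000),
    a1 = c(1, 1),
    a2 = c(2, 3),
    ord = c(1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  methane = mk(
    el = c("C", "H", "H", "H", "H"),
    x = c(0.0000, -0.6753, -0.3949, 0.0848, 0.9855),
    y = c(0.0000, 0.8541, -0.8359, -0.2937, 0.2756),
    z = c(0.0000, -0.0854, -0.5815, 1.0485, -0.3817),
    a1 = c(1, 1, 1, 1),
    a2 = c(2, 3, 4, 5),
    ord = c(1, 1, 1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  ethanol = mk(
    el = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    x = c(-0.8883, 0.4658, 1.4311, -0.8487, -1.6471, -1.1964, 0.7920, 0.4246, 1.4671),
    y = c(0.1670, -0.5116, 0.3229, 1.1175, -0.4704, 0.3978, -0.7224, -1.4559, 1.1550),
    z = c(-0.0273, -0.0368, 0.5867, -0.5695, -0.4896, 0.9977, -1.0597, 0.5138, 0.0848),
    a1 = c(1, 2, 1, 1, 1, 2, 2, 3),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9),
    ord = c(1, 1, 1, 1, 1, 1, 1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  dimethyl_ether = mk(
    el = c("C", "O", "C", "H", "H", "H", "H", "H", "H"),
    x = c(-1.1682, -0.0267, 1.1656, -2.0518, -1.0843, -1.2877, 1.1213, 2.0070, 1.3248),
    y = c(-0.0027, 0.8393, 0.0857, 0.6273, -0.6728, -0.5837, -0.4924, 0.7810, -0.5816),
    z = c(-0.4041, -0.3158, -0.1419, -0.5366, -1.2651, 0.5156, 0.7862, -0.0806, -0.9944),
    a1 = c(1, 2, 1, 1, 1, 3, 3, 3),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9),
    ord = c(1, 1, 1, 1, 1, 1, 1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  glycine = mk(
    el = c("N", "C", "C", "O", "O", "H", "H", "H", "H", "H"),
    x = c(-1.6199, -0.5347, 0.8281, 1.0483, 1.8434, -1.4505, -1.5183, -0.6597, -0.5844, 2.6477),
    y = c(0.4090, -0.5604, 0.1128, 1.2922, -0.7458, 0.8537, 1.1730, -0.9945, -1.3492, -0.1907),
    z = c(0.1524, -0.0905, -0.0127, 0.2166, -0.2302, 1.0574, -0.5194, -1.0866, 0.6654, -0.1524),
    a1 = c(1, 2, 3, 3, 1, 1, 2, 2, 5),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
    ord = c(1, 1, 2, 1, 1, 1, 1, 1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  glycine_zwitterion = mk(
    el = c("N", "C", "C", "O", "O", "H", "H", "H", "H", "H"),
    x = c(-1.0578, 0.0717, 1.3277, 1.0548, 2.3575, -1.3391, -0.5654, -1.8296, 0.2475, -0.2674),
    y = c(0.4300, -0.3958, -0.2243, 0.5642, -0.8416, 1.2119, 0.8455, -0.1266, -0.0290, -1.4344),
    z = c(-0.0595, 0.5182, -0.3678, -1.3336, -0.0312, 0.5303, -0.8954, -0.4240, 1.5324, 0.5304),
    a1 = c(1, 2, 3, 3, 1, 1, 1, 2, 2),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
    ord = c(1, 1, 2, 1, 1, 1, 1, 1, 1),
    chg_idx = c(1, 5), chg_val = c(1, -1)
  ),
  l_alanine = mk(
    el = c("N", "C", "C", "C", "O", "O", "H", "H", "H", "H", "H", "H", "H"),
    x = c(-0.6550, -0.2877, -1.1932, 1.1855, 1.9711, 1.5966, 0.0113, -0.4776, -0.4160, -2.2489, -0.9893, -1.0416, 2.5450),
    y = c(1.5862, 0.2076, -0.7788, -0.0613, 0.7257, -1.2910, 2.2275, 1.6906, 0.1207, -0.5711, -1.8060, -0.7407, -1.3094),
    z = c(0.0227, 0.4185, -0.3060, 0.0947, -0.4126, 0.4613, 0.4593, -0.9788, 1.5027, -0.0998, 0.0155, -1.3909, 0.2133),
    a1 = c(1, 2, 2, 4, 4, 1, 1, 2, 3, 3, 3, 6),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13),
    ord = c(1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  trans_2_butene = mk(
    el = c("C", "C", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(1.9496, 0.5096, -0.5096, -1.9496, 2.4518, 2.4433, 2.0787, 0.3074, -0.3074, -2.4518, -2.4433, -2.0787),
    y = c(-0.0055, -0.1614, 0.1614, 0.0055, -0.9768, 0.6680, 0.4029, -0.5633, 0.5633, 0.9768, -0.6680, -0.4028),
    z = c(-0.0385, -0.4053, 0.4053, 0.0385, -0.0800, -0.7457, 0.9689, -1.3958, 1.3958, 0.0801, 0.7457, -0.9689),
    a1 = c(1, 2, 3, 1, 1, 1, 2, 3, 4, 4, 4),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    ord = c(1, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  cis_2_butene = mk(
    el = c("C", "C", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(1.5617, 0.6708, -0.6525, -1.5713, 2.3429, 1.0362, 2.0466, 1.1780, -1.1368, -1.0685, -2.3517, -2.0555),
    y = c(-0.4137, 0.7696, 0.7768, -0.3965, -0.4185, -1.3692, -0.3495, 1.7329, 1.7456, -1.3577, -0.3254, -0.3943),
    z = c(0.2813, 0.0834, -0.1414, -0.2510, -0.4853, 0.2299, 1.2605, 0.1315, -0.2618, -0.1277, 0.5132, -1.2326),
    a1 = c(1, 2, 3, 1, 1, 1, 2, 3, 4, 4, 4),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    ord = c(1, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    chg_idx = integer(), chg_val = integer()
  ),
  tetramethylammonium = mk(
    el = c("C", "N", "C", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(0.7298, 0.0000, -1.3873, 0.7844, -0.1268, 0.8117, 0.1527, 1.7233, -1.8964, -1.9359, -1.2770, 0.8656, 0.2461, 1.7771, -0.6924, 0.8782, -0.6529),
    y = c(-1.0800, 0.0000, -0.4982, 0.3262, 1.2520, -1.9709, -1.3014, -0.7052, 0.2896, -0.7274, -1.3969, -0.5837, 1.1028, 0.6821, 0.9993, 1.5955, 2.0163),
    z = c(-0.7858, 0.0000, 0.3789, 1.2628, -0.8560, -0.1562, -1.6885, -1.0492, 0.9421, -0.5394, 0.9929, 1.8649, 1.8141, 0.9719, -1.7578, -1.1185, -0.2763),
    a1 = c(1, 2, 2, 2, 1, 1, 1, 3, 3, 3, 4, 4, 4, 5, 5, 5),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17),
    ord = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    chg_idx = c(2), chg_val = c(1)
  ),
  sodium_acetate = mk(
    el = c("C", "C", "O", "O", "Na", "H", "H", "H"),
    x = c(-0.6270, 0.8595, 1.3247, 1.4400, 3.5000, -0.8356, -0.9701, -1.1916),
    y = c(-0.0336, 0.0517, -0.9235, 1.0823, 0.0000, -0.9329, 0.8371, -0.0811),
    z = c(-0.1277, 0.1719, 0.8259, -0.2686, 0.0000, -0.7149, -0.6948, 0.8082),
    a1 = c(1, 2, 2, 1, 1, 1),
    a2 = c(2, 3, 4, 6, 7, 8),
    ord = c(1, 2, 1, 1, 1, 1),
    chg_idx = c(4, 5), chg_val = c(-1, 1)
  ))
  # D-alanine: mirror image of the frozen L geometry
  d <- mols$l_alanine
  d$atoms$x <- -d$atoms$x
  mols$d_alanine <- molecule(d$atoms, d$bonds, is_3d = TRUE)
  mols
}

PERTURBATION_KINDS <- c("protonate", "deprotonate", "set_formal_charge",
                        "rewire_bond", "invert_chiral_center",
                        "flip_double_bond_geometry", "drop_stereo",
                        "permute_atoms")

# Which perturbation kinds apply to which builtin.
perturbation_table <- function() {
  list(
    protonate = c("glycine", "l_alanine", "d_alanine"),
    deprotonate = c("glycine", "l_alanine", "d_alanine"),
    set_formal_charge = "ethanol",
    rewire_bond = c("ethanol", "dimethyl_ether"),
    invert_chiral_center = c("l_alanine", "d_alanine"),
    flip_double_bond_geometry = c("trans_2_butene", "cis_2_butene"),
    drop_stereo = c("l_alanine", "d_alanine"),
    permute_atoms = names(builtin_molecules())
  )
}

bond_neighbors <- function(mol, i) {
  c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
}

# Add one proton to atom i, placed opposite the mean of its bond vectors.
add_proton <- function(mol, i) {
  nbs <- bond_neighbors(mol, i)
  p <- c(mol$atoms$x[i], mol$atoms$y[i], mol$atoms$z[i])
  v <- c(0, 0, 0)
  for (nb in nbs) {
    d <- p - c(mol$atoms$x[nb], mol$atoms$y[nb], mol$atoms$z[nb])
    v <- v + d / sqrt(sum(d^2))
  }
  v <- v / sqrt(sum(v^2))
  h <- p + 1.02 * v
  atoms <- rbind(mol$atoms,
                 data.frame(element = "H", x = h[1], y = h[2], z = h[3],
                            charge = 0L, isotope = NA_integer_))
  bonds <- rbind(mol$bonds,
                 data.frame(a1 = i, a2 = nrow(atoms), order = 1L,
                            stereo = 0L))
  atoms$charge[i] <- atoms$charge[i] + 1L
  molecule(atoms, bonds, cid = mol$cid, is_3d = TRUE)
}

# Remove the single hydrogen bonded to atom i and decrement its charge.
remove_proton <- function(mol, i) {
  hs <- Filter(function(j) mol$atoms$element[j] == "H", bond_neighbors(mol, i))
  if (!length(hs)) stop("atom ", i, " carries no hydrogen", call. = FALSE)
  h <- hs[[1L]]
  atoms <- mol$atoms[-h, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds[mol$bonds$a1 != h & mol$bonds$a2 != h, , drop = FALSE]
  bonds$a1 <- bonds$a1 - (bonds$a1 > h)
  bonds$a2 <- bonds$a2 - (bonds$a2 > h)
  i2 <- i - (i > h)
  atoms$charge[i2] <- atoms$charge[i2] - 1L
  molecule(atoms, bonds, cid = mol$cid, is_3d = TRUE)
}

# Hydroxyl oxygen: an O bonded to exactly one H and one heavy atom (the
# deprotonation site of alcohols and carboxylic acids).
find_acidic_oxygen <- function(mol) {
  for (i in which(mol$atoms$element == "O")) {
    nbs <- bond_neighbors(mol, i)
    if (sum(mol$atoms$element[nbs] == "H") == 1L) return(i)
  }
  stop("no protonated oxygen found", call. = FALSE)
}

# Basic nitrogen: an N with fewer than four connections.
find_basic_nitrogen <- function(mol) {
  for (i in which(mol$atoms$element == "N")) {
    if (length(bond_neighbors(mol, i)) < 4L) return(i)
  }
  stop("no protonatable nitrogen found", call. = FALSE)
}

#' Apply a controlled perturbation with known ground truth
#'
#' Produces a `(structure, deposited identifiers)` pair whose audit must
#' flag exactly the expected categories. The deposited side is always an
#' InChI generated by the delegate from a deliberately modified
#' structure, never a hand-edited string, so the ground truth rests on
#' the delegate alone. The deposited formula is kept truthful (derived
#' from the unmodified structure): the perturbations model identifier
#' discrepancies, and the formula reconciliation path is exercised by its
#' own unit tests.
#'
#' Kinds and mechanisms: `protonate`/`deprotonate` change the deposited
#' protonation state (`/p`); `set_formal_charge` deposits the
#' intrinsically charged alkoxide for a neutral alcohol structure (`/q`,
#' with the attendant `/h` and formula-layer shifts, since the InChI
#' model treats an alkoxide charge as covalent rather than a proton
#' removal); `rewire_bond` swaps in a connectivity isomer of identical
#' composition (`/c`, `/h`); `invert_chiral_center` deposits the mirror
#' image (`/m`); `flip_double_bond_geometry` deposits the opposite
#' double-bond geometry (`/b`); `drop_stereo` deposits the InChI of the
#' flattened structure (missing `/t`, `/m`, `/s`); `permute_atoms`
#' shuffles the input atom order and deposits the structure's own InChI
#' (must never flag).
#'
#' @param name name of a [builtin_molecules()] entry.
#' @param kind one of `protonate`, `deprotonate`, `set_formal_charge`,
#'   `rewire_bond`, `invert_chiral_center`, `flip_double_bond_geometry`,
#'   `drop_stereo`, `permute_atoms`.
#' @param seed integer controlling any randomness (atom permutations).
#' @return List with `structure` (the molecule to audit),
#'   `deposited_inchi`, `deposited_formula`, `expected_layers`,
#'   `expected_categories`, `kind`, `name`, `seed`.
#' @export
perturb <- function(name, kind, seed = 1L) {
  kind <- match.arg(kind, PERTURBATION_KINDS)
  builtins <- builtin_molecules()
  if (!name %in% names(builtins)) {
    stop("unknown builtin molecule '", name, "'", call. = FALSE)
  }
  if (!name %in% perturbation_table()[[kind]]) {
    stop("perturbation '", kind, "' is not applicable to '", name, "'",
         call. = FALSE)
  }
  mol <- builtins[[name]]
  counterpart <- c(ethanol = "dimethyl_ether", dimethyl_ether = "ethanol",
                   l_alanine = "d_alanine", d_alanine = "l_alanine",
                   trans_2_butene = "cis_2_butene",
                   cis_2_butene = "trans_2_butene")
  structure_out <- mol
  modified <- switch(
    kind,
    protonate = add_proton(mol, find_basic_nitrogen(mol)),
    deprotonate = remove_proton(mol, find_acidic_oxygen(mol)),
    # alkoxide: InChI writes R-O(-) as an intrinsic /q charge (unlike a
    # carboxylate, which it normalizes to the neutral core via /p), so
    # this kind exercises the /q path of the charge category
    set_formal_charge = remove_proton(mol, find_acidic_oxygen(mol)),
    rewire_bond = builtins[[counterpart[[name]]]],
    invert_chiral_center = builtins[[counterpart[[name]]]],
    flip_double_bond_geometry = builtins[[counterpart[[name]]]],
    drop_stereo = {
      m <- mol
      m$atoms$z <- 0
      molecule(m$atoms, m$bonds, is_3d = FALSE)
    },
    permute_atoms = {
      old_seed <- set_local_seed(seed)
      perm <- sample(nrow(mol$atoms))
      restore_seed(old_seed)
      structure_out <- permute_molecule(mol, perm)
      mol  # deposited side: the original, identical compound
    }
  )
  dep <- generate_inchi(modified)
  if (!is.null(dep$error)) {
    stop("delegate failed while building the deposited side: ", dep$error,
         call. = FALSE)
  }
  derived_for_formula <- generate_inchi(mol)
  expected <- switch(
    kind,
    protonate = list(layers = c("p"), categories = "charge"),
    deprotonate = list(layers = c("p"), categories = "charge"),
    set_formal_charge = list(
      layers = c("formula", "h", "q"),
      categories = c("atom_connectivity", "charge", "formula")),
    rewire_bond = list(layers = c("c", "h"),
                       categories = "atom_connectivity"),
    invert_chiral_center = list(layers = "m", categories = "stereochemistry"),
    flip_double_bond_geometry = list(layers = "b",
                                     categories = "stereochemistry"),
    drop_stereo = list(layers = c("t", "m", "s"),
                       categories = "stereochemistry"),
    permute_atoms = list(layers = character(), categories = character())
  )
  list(structure = structure_out,
       deposited_inchi = dep$inchi,
       deposited_formula =
         hill_format(charged_species_formula(parse_inchi(derived_for_formula$inchi))),
       expected_layers = expected$layers,
       expected_categories = expected$categories,
       kind = kind, name = name, seed = as.integer(seed))
}

set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

molecule_masses <- function(mol) {
  counts <- atom_counts(mol)
  charge <- sum(mol$atoms$charge)
  els <- names(counts)
  if (!all(els %in% names(AVERAGE_MASS))) return(c(NA_real_, NA_real_))
  c(sum(AVERAGE_MASS[els] * counts),
    sum(MONOISOTOPIC_MASS[els] * counts) - charge * 0.000549)
}

#' Generate a seeded synthetic corpus with ground truth
#'
#' Samples `n` entries from the builtin molecules; a fraction
#' `discrepancy_rate` (exactly `floor(rate * n)` entries) receives a
#' random applicable perturbation, the rest are clean entries whose atom
#' order is randomly permuted (a correct audit must not flag them). Each
#' entry is written as one SDF record carrying the deposited InChI,
#' formula, molecular weight and exact mass as data items, sharded into
#' files of `records_per_file` records. The truth table lists the
#' expected differing layers and categories per cid. Byte-reproducible
#' for a fixed seed.
#'
#' @param n number of entries.
#' @param seed integer seed.
#' @param discrepancy_rate fraction in `[0, 1]` of perturbed entries.
#' @param out_dir output directory (created if needed).
#' @param records_per_file SDF records per output file (default 25).
#' @return Invisibly, the truth table data.frame (`cid`, `molecule`,
#'   `kind`, `expected_layers`, `expected_categories`), also written to
#'   `truth.csv` in `out_dir`.
#' @export
make_corpus <- function(n, seed, discrepancy_rate, out_dir,
                        records_per_file = 25L) {
  stopifnot(n >= 0, discrepancy_rate >= 0, discrepancy_rate <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  n_pert <- floor(discrepancy_rate * n)
  pert_idx <- if (n_pert) sort(sample(n, n_pert)) else integer()
  tab <- perturbation_table()
  inject_kinds <- setdiff(PERTURBATION_KINDS, "permute_atoms")
  perturbable <- unique(unlist(tab[inject_kinds]))

  rows <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cid <- sprintf("SYN%05d", i)
    entry_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    if (i %in% pert_idx) {
      nm <- sample(perturbable, 1L)
      applicable <- inject_kinds[vapply(inject_kinds,
                                        function(k) nm %in% tab[[k]], TRUE)]
      kind <- sample(applicable, 1L)
    } else {
      nm <- sample(names(builtin_molecules()), 1L)
      kind <- "permute_atoms"
    }
    p <- perturb(nm, kind, seed = entry_seed)
    mol <- p$structure
    mol$cid <- cid
    masses <- molecule_masses(mol)
    mol$properties <- list(
      PUBCHEM_COMPOUND_CID = cid,
      PUBCHEM_IUPAC_INCHI = p$deposited_inchi,
      PUBCHEM_MOLECULAR_FORMULA = p$deposited_formula,
      PUBCHEM_MOLECULAR_WEIGHT = sprintf("%.3f", masses[1]),
      PUBCHEM_EXACT_MASS = sprintf("%.6f", masses[2]),
      PUBCHEM_SYNONYMS = paste0(p$name, " (synthetic)")
    )
    records[[i]] <- mol
    rows[[i]] <- data.frame(
      cid = cid, molecule = p$name, kind = p$kind,
      expected_layers = paste(p$expected_layers, collapse = "|"),
      expected_categories = paste(p$expected_categories, collapse = "|"),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    truth <- data.frame(cid = character(), molecule = character(),
                        kind = character(), expected_layers = character(),
                        expected_categories = character())
  }
  utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  if (n > 0L) {
    starts <- seq(1L, n, by = records_per_file)
    for (f in seq_along(starts)) {
      idx <- starts[f]:min(starts[f] + records_per_file - 1L, n)
      writeLines(write_sdf(records[idx]),
                 file.path(out_dir, sprintf("corpus_%03d.sdf", f)))
    }
  }
  invisible(truth)
}
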