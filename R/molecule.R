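#' @keywords internal
"_PACKAGE"

# Recognized IUPAC element symbols (1-118).
ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Construct a molecule
#'
#' A toolkit-neutral container for one structure record: an ordered atom
#' table (element, Cartesian coordinates in Angstrom, formal charge,
#' optional mass number), a bond table (1-based atom indices, order 1-3,
#' wedge/hash mark), the verbatim SDF data items, and an optional compound
#' identifier. Atom index is the 1-based row position, matching the order
#' in the source file.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (integer, default 0) and `isotope` (mass number,
#'   default `NA`).
#' @param bonds data.frame with columns `a1`, `a2` and optionally `order`
#'   (default 1) and `stereo` (default 0; the raw SDF wedge/hash flag).
#' @param cid optional compound identifier (coerced to character).
#' @param properties named list of SDF data items (values kept verbatim).
#' @param is_3d logical; when `NULL` it is inferred as `any(z != 0)`.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, cid = NA_character_,
                     properties = list(), is_3d = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, nrow(atoms))
  if (is.null(atoms$isotope)) atoms$isotope <- rep(NA_integer_, nrow(atoms))
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  atoms$isotope <- as.integer(atoms$isotope)
  bad <- setdiff(unique(atoms$element), ELEMENTS)
  if (length(bad)) {
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) &&
      !all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (is.null(bonds) || !NROW(bonds)) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        stereo = integer())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("a1", "a2") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- 1L
    if (is.null(bonds$stereo)) bonds$stereo <- 0L
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
    bonds$stereo <- as.integer(bonds$stereo)
    n <- nrow(atoms)
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n)) {
      stop("bond atom index out of range", call. = FALSE)
    }
    if (any(bonds$a1 == bonds$a2)) stop("bond joining an atom to itself",
                                        call. = FALSE)
    if (!all(bonds$order %in% 1:3)) stop("bond order must be 1, 2 or 3",
                                         call. = FALSE)
  }
  if (length(properties) && anyDuplicated(names(properties))) {
    stop("duplicated SDF property names", call. = FALSE)
  }
  if (is.null(is_3d)) is_3d <- nrow(atoms) > 0L && any(atoms$z != 0)
  structure(
    list(cid = if (is.na(cid)) NA_character_ else as.character(cid),
         atoms = atoms, bonds = bonds,
         properties = as.list(properties), is_3d = isTRUE(is_3d)),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule%s: %d atoms, %d bonds, %s>\n",
              if (is.na(x$cid)) "" else paste0(" ", x$cid),
              nrow(x$atoms), nrow(x$bonds),
              if (x$is_3d) "3D" else "2D"))
  invisible(x)
}

#' Count explicit atoms by element
#'
#' Tallies the explicit atoms of a molecule (3D SDF archives carry explicit
#' hydrogens, so the tally is the full composition of the record as
#' deposited). The sum of the counts equals the atom-block length.
#'
#' @param mol a [molecule()].
#' @return Named integer vector, elements sorted in Hill order.
#' @export
atom_counts <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  if (!nrow(mol$atoms)) return(stats::setNames(integer(), character()))
  tab <- table(mol$atoms$element)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[hill_order(names(counts))]
}

# Hill ordering of element symbols: C then H then the rest alphabetical;
# fully alphabetical when no carbon is present.
hill_order <- function(elements) {
  if ("C" %in% elements) {
    c(intersect(c("C", "H"), elements),
      sort(setdiff(elements, c("C", "H"))))
  } else {
    sort(elements)
  }
}

# Apply a permutation to atom order: perm[new_index] = old_index.
permute_molecule <- function(mol, perm) {
  stopifnot(inherits(mol, "molecule"),
            length(perm) == nrow(mol$atoms),
            !anyDuplicated(perm))
  inv <- order(perm)  # old index -> new index
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds)) {
    bonds$a1 <- inv[bonds$a1]
    bonds$a2 <- inv[bonds$a2]
  }
  molecule(atoms, bonds, cid = mol$cid, properties = mol$properties,
           is_3d = mol$is_3d)
}
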