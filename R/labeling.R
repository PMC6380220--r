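#' Generate the standard InChI and AuxInfo for a molecule
#'
#' Serializes the molecule to a V2000 molblock and hands it to the InChI
#' delegate (see [delegate_version()]). Stereochemistry is perceived from
#' the 3D coordinates (or explicit wedge/hash marks) by the delegate; the
#' result is deterministic for a fixed structure and delegate version.
#'
#' @param mol a [molecule()] with at least one atom.
#' @return List with `inchi` (begins `InChI=1S`), `auxinfo` (begins
#'   `AuxInfo=`), `warnings` (character vector of delegate warnings),
#'   `error` (`NULL` on success) and `delegate` (name/version stamp).
#' @export
generate_inchi <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  if (!nrow(mol$atoms)) stop("cannot generate an InChI for an empty molecule",
                             call. = FALSE)
  generate_inchi_batch(list(mol))[[1L]]
}

#' @rdname generate_inchi
#' @param mols list of molecules, processed in one delegate invocation
#'   (much faster than per-molecule calls).
#' @export
generate_inchi_batch <- function(mols) {
  stopifnot(is.list(mols), all(vapply(mols, inherits, TRUE, "molecule")))
  if (any(!vapply(mols, function(m) nrow(m$atoms) > 0L, TRUE))) {
    stop("cannot generate an InChI for an empty molecule", call. = FALSE)
  }
  blocks <- vapply(mols, function(m) {
    paste(write_molblock(m), collapse = "\n")
  }, "")
  res <- delegate_inchi(blocks)
  lapply(res, function(r) {
    list(inchi = if (is.null(r$inchi)) NA_character_ else r$inchi,
         auxinfo = if (is.null(r$auxinfo)) NA_character_ else r$auxinfo,
         warnings = as.character(unlist(r$warnings)),
         error = if (is.null(r$error)) NULL else as.character(r$error),
         delegate = as.character(r$delegate))
  })
}

#' Extract the canonical atom numbering from AuxInfo
#'
#' The `/N:` layer of the auxiliary information lists, for each component
#' and in canonical order, the original (input) 1-based positions of the
#' canonically numbered heavy atoms. Components are `;`-separated, entries
#' `,`-separated.
#'
#' @param auxinfo AuxInfo text from [generate_inchi()].
#' @return List of integer vectors, one per component;
#'   `component[[k]][j]` is the original atom index of canonical atom `j`
#'   of component `k`.
#' @export
parse_auxinfo_numbering <- function(auxinfo) {
  stopifnot(is.character(auxinfo), length(auxinfo) == 1L, !is.na(auxinfo))
  m <- regmatches(auxinfo, regexec("/N:([0-9,;]+)", auxinfo))[[1L]]
  if (length(m) < 2L) stop("AuxInfo has no /N: numbering layer", call. = FALSE)
  comps <- strsplit(m[2L], ";", fixed = TRUE)[[1L]]
  lapply(comps, function(cmp) as.integer(strsplit(cmp, ",")[[1L]]))
}

#' Extract the atom-equivalence classes from AuxInfo
#'
#' The `/E:` layer lists groups of canonical atom numbers that are
#' topologically equivalent under the InChI model (for example the two
#' oxygens of a carboxylate sharing a mobile hydrogen, or the four
#' methyl carbons of tetramethylammonium). Within such a group the
#' canonical numbering is arbitrary with respect to input atom order, so
#' reproducible labeling needs a tie-break (see [assign_labels()]).
#'
#' @param auxinfo AuxInfo text from [generate_inchi()].
#' @return List (one element per component) of lists of integer vectors
#'   (canonical numbers within the component), or `NULL` when no `/E:`
#'   layer is present.
#' @export
parse_auxinfo_equivalence <- function(auxinfo) {
  stopifnot(is.character(auxinfo), length(auxinfo) == 1L, !is.na(auxinfo))
  m <- regmatches(auxinfo, regexec("/E:([0-9,;()]+)", auxinfo))[[1L]]
  if (length(m) < 2L) return(NULL)
  comps <- strsplit(m[2L], ";", fixed = TRUE)[[1L]]
  lapply(comps, function(cmp) {
    groups <- regmatches(cmp, gregexpr("\\([0-9,]+\\)", cmp))[[1L]]
    lapply(groups, function(g) {
      as.integer(strsplit(gsub("[()]", "", g), ",", fixed = TRUE)[[1L]])
    })
  })
}

#' Assign unique, reproducible atom labels
#'
#' Heavy atoms are labeled `<element><n>` where `n` is the canonical
#' number from the InChI AuxInfo numbering (numbering continues across
#' components, so labels are unique within multi-component records). A
#' hydrogen takes the label `H<n>` of its heavy neighbor; when a heavy
#' atom bears several hydrogens they are disambiguated with suffixes
#' `a`, `b`, ... ordered by distance from the parent and then
#' lexicographically by (x, y, z). Canonical numbers inside an InChI
#' equivalence class (AuxInfo `/E:` groups, where the delegate's
#' assignment is input-order dependent) are re-assigned by the same
#' lexicographic geometric rule. Because every rule depends only on the
#' canonical numbering and the geometry, the labeling is invariant under
#' permutation of the input atom order. A hydrogen with no heavy neighbor
#' (e.g. molecular H2) is labeled `H<k>` with `k` continuing after the
#' last heavy number, and a warning is attached.
#'
#' @param mol a [molecule()].
#' @param auxinfo AuxInfo text from [generate_inchi()]; when `NULL` (and
#'   `numbering` is also `NULL`) the delegate is run on `mol`.
#' @param numbering canonical numbering from [parse_auxinfo_numbering()],
#'   overriding `auxinfo`.
#' @param equivalence equivalence classes from
#'   [parse_auxinfo_equivalence()]; only used with `numbering`.
#' @return An object of class `atom_label_map` with a data.frame `map`
#'   (`original_index`, `label`, `component`, `sort_key`) plus the
#'   delegate result used, and any labeling warnings in
#'   `attr(, "warnings")`.
#' @export
assign_labels <- function(mol, auxinfo = NULL, numbering = NULL,
                          equivalence = NULL) {
  stopifnot(inherits(mol, "molecule"))
  gen <- NULL
  if (is.null(numbering)) {
    if (is.null(auxinfo)) {
      gen <- generate_inchi(mol)
      if (!is.null(gen$error)) {
        stop("InChI delegate failed: ", gen$error, call. = FALSE)
      }
      auxinfo <- gen$auxinfo
    }
    numbering <- parse_auxinfo_numbering(auxinfo)
    equivalence <- parse_auxinfo_equivalence(auxinfo)
  }
  n_atoms <- nrow(mol$atoms)
  heavy <- which(mol$atoms$element != "H")
  flat <- unlist(numbering)
  if (!setequal(flat, heavy)) {
    stop("AuxInfo numbering does not cover exactly the heavy atoms",
         call. = FALSE)
  }
  geo_order <- function(idx) {
    order(round(mol$atoms$x[idx], 4), round(mol$atoms$y[idx], 4),
          round(mol$atoms$z[idx], 4))
  }
  # tie-break within equivalence classes: the delegate's choice among
  # equivalent atoms is input-order dependent, so re-anchor it to geometry
  for (k in seq_along(equivalence)) {
    for (grp in equivalence[[k]]) {
      grp <- sort(grp)
      orig <- numbering[[k]][grp]
      numbering[[k]][grp] <- orig[geo_order(orig)]
    }
  }
  canon <- integer(n_atoms)     # original index -> global canonical number
  comp_of <- integer(n_atoms)   # original index -> component ordinal
  offset <- 0L
  for (k in seq_along(numbering)) {
    idx <- numbering[[k]]
    canon[idx] <- offset + seq_along(idx)
    comp_of[idx] <- k
    offset <- offset + length(idx)
  }
  labels <- character(n_atoms)
  sort_key <- character(n_atoms)
  labels[heavy] <- paste0(mol$atoms$element[heavy], canon[heavy])
  sort_key[heavy] <- sprintf("%06d", canon[heavy])
  warnings_out <- character()

  # hydrogens: group by first heavy neighbor
  hydro <- setdiff(seq_len(n_atoms), heavy)
  parent <- rep(NA_integer_, n_atoms)
  b <- mol$bonds
  for (h in hydro) {
    nb <- c(b$a2[b$a1 == h], b$a1[b$a2 == h])
    nb <- nb[mol$atoms$element[nb] != "H"]
    if (length(nb)) parent[h] <- nb[1L]
  }
  for (p in unique(parent[!is.na(parent)])) {
    hs <- hydro[!is.na(parent[hydro]) & parent[hydro] == p]
    if (length(hs) == 1L) {
      labels[hs] <- paste0("H", canon[p])
      sort_key[hs] <- sprintf("%06d.%06d.", canon[p], canon[p])
    } else {
      d <- sqrt((mol$atoms$x[hs] - mol$atoms$x[p])^2 +
                (mol$atoms$y[hs] - mol$atoms$y[p])^2 +
                (mol$atoms$z[hs] - mol$atoms$z[p])^2)
      ord <- order(round(d, 6), round(mol$atoms$x[hs], 6),
                   round(mol$atoms$y[hs], 6), round(mol$atoms$z[hs], 6))
      suf <- letters[seq_along(hs)]
      labels[hs[ord]] <- paste0("H", canon[p], suf)
      sort_key[hs[ord]] <- sprintf("%06d.%06d.%s", canon[p], canon[p], suf)
    }
  }
  comp_of[hydro] <- ifelse(is.na(parent[hydro]), NA_integer_,
                           comp_of[parent[hydro]])
  orphan <- hydro[is.na(parent[hydro])]
  if (length(orphan)) {
    ord <- order(round(mol$atoms$x[orphan], 6), round(mol$atoms$y[orphan], 6),
                 round(mol$atoms$z[orphan], 6))
    nums <- offset + seq_along(orphan)
    labels[orphan[ord]] <- paste0("H", nums)
    sort_key[orphan[ord]] <- sprintf("zz%06d", nums)
    warnings_out <- c(warnings_out, sprintf(
      "%d hydrogen(s) without a heavy neighbor labeled sequentially",
      length(orphan)))
  }
  # hydrogens sort after all heavy atoms: prefix with parent's canonical
  # number plus a marker so heavy "000007" < hydrogen "000007.000007."
  map <- data.frame(original_index = seq_len(n_atoms), label = labels,
                    component = comp_of, sort_key = sort_key,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$label)) stop("internal: duplicate atom labels",
                                     call. = FALSE)
  structure(list(map = map, inchi = gen), class = "atom_label_map",
            warnings = warnings_out)
}

#' @export
print.atom_label_map <- function(x, ...) {
  cat("<atom_label_map:", nrow(x$map), "atoms>\n")
  print(utils::head(x$map[, c("original_index", "label", "component")], 10L))
  invisible(x)
}

#' Serialize a label map as two-column CSV text
#'
#' @param labels an `atom_label_map`.
#' @return Character scalar: `original_index,label` lines with a header.
#' @export
label_map_csv <- function(labels) {
  stopifnot(inherits(labels, "atom_label_map"))
  lm <- labels$map[order(labels$map$original_index), ]
  paste(c("original_index,label",
          sprintf("%d,%s", lm$original_index, lm$label)), collapse = "\n")
}

# Multi-component map: component ordinal per label, for records holding
# several compounds.
component_map_csv <- function(labels) {
  stopifnot(inherits(labels, "atom_label_map"))
  lm <- labels$map[order(labels$map$original_index), ]
  paste(c("original_index,label,component",
          sprintf("%d,%s,%s", lm$original_index, lm$label,
                  ifelse(is.na(lm$component), "", lm$component))),
        collapse = "\n")
}
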