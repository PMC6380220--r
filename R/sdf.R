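#' Read a multi-record SDF (V2000) file
#'
#' Parses zero or more V2000 records terminated by `$$$$`. Gzip-compressed
#' files are decompressed transparently. Malformed records (corrupted
#' counts line, truncated atom/bond block, non-V2000 version tag) do not
#' abort the stream: each produces an error entry and parsing continues
#' with the next record, mirroring the per-entry `error.txt` bookkeeping
#' of large archive runs.
#'
#' @param source path to a `.sdf` / `.sdf.gz` file, or a character vector
#'   of lines when `text = TRUE`.
#' @param text logical; interpret `source` as SDF text instead of a path.
#' @param cid_from where to take the compound id: `"title"` uses the first
#'   header line; otherwise the name of an SDF data item (e.g.
#'   `"PUBCHEM_COMPOUND_CID"`), falling back to the title when absent.
#' @return A list with `molecules` (list of [molecule()], record order
#'   preserved) and `errors` (data.frame `record`, `message`).
#' @export
read_sdf <- function(source, text = FALSE, cid_from = "title") {
  if (text) {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n",
                             fixed = TRUE))
  } else {
    con <- gzfile(source, "rt")  # reads plain files transparently too
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
  }
  recs <- split_sdf_records(lines)
  molecules <- list()
  errors <- data.frame(record = integer(), message = character())
  for (i in seq_along(recs)) {
    m <- tryCatch(parse_sdf_record(recs[[i]], cid_from = cid_from),
                  error = function(e) e)
    if (inherits(m, "error")) {
      errors <- rbind(errors,
                      data.frame(record = i, message = conditionMessage(m)))
    } else {
      molecules[[length(molecules) + 1L]] <- m
    }
  }
  list(molecules = molecules, errors = errors)
}

split_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  recs <- list()
  start <- 1L
  for (e in ends) {
    recs[[length(recs) + 1L]] <- lines[start:(e - 1L)]
    start <- e + 1L
  }
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)])))) {
    recs[[length(recs) + 1L]] <- lines[start:length(lines)]
  }
  recs
}

fixed_int <- function(line, from, to, what) {
  x <- suppressWarnings(as.integer(trimws(substr(line, from, to))))
  if (is.na(x)) stop("unparseable ", what, call. = FALSE)
  x
}

parse_sdf_record <- function(rl, cid_from = "title") {
  if (length(rl) < 4L) stop("truncated record: no counts line", call. = FALSE)
  title <- trimws(rl[1L])
  counts <- rl[4L]
  version <- trimws(substr(counts, 34L, 39L))
  if (version == "V3000") {
    stop("V3000 record not supported", call. = FALSE)
  }
  if (version != "" && version != "V2000") {
    stop("unknown counts-line version tag '", version, "'", call. = FALSE)
  }
  na <- fixed_int(counts, 1L, 3L, "counts line (atom count)")
  nb <- fixed_int(counts, 4L, 6L, "counts line (bond count)")
  if (length(rl) < 4L + na + nb) stop("truncated record: atom/bond block",
                                      call. = FALSE)
  dim_flag <- trimws(substr(rl[2L], 21L, 22L))
  atom_lines <- rl[seq_len(na) + 4L]
  atoms <- data.frame(
    element = trimws(substr(atom_lines, 32L, 34L)),
    x = as.numeric(substr(atom_lines, 1L, 10L)),
    y = as.numeric(substr(atom_lines, 11L, 20L)),
    z = as.numeric(substr(atom_lines, 21L, 30L)),
    charge = 0L, isotope = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("unparseable atom coordinates", call. = FALSE)
  }
  bond_lines <- if (nb) rl[seq_len(nb) + 4L + na] else character()
  bonds <- if (nb) {
    data.frame(
      a1 = vapply(bond_lines, fixed_int, 0L, from = 1L, to = 3L,
                  what = "bond line", USE.NAMES = FALSE),
      a2 = vapply(bond_lines, fixed_int, 0L, from = 4L, to = 6L,
                  what = "bond line", USE.NAMES = FALSE),
      order = vapply(bond_lines, fixed_int, 0L, from = 7L, to = 9L,
                     what = "bond line", USE.NAMES = FALSE),
      stereo = vapply(bond_lines, function(l) {
        v <- suppressWarnings(as.integer(trimws(substr(l, 10L, 12L))))
        if (is.na(v)) 0L else v
      }, 0L, USE.NAMES = FALSE)
    )
  } else NULL
  # M-block: charges and isotopes override the (obsolete) atom-line fields
  rest <- rl[-seq_len(4L + na + nb)]
  for (l in rest[startsWith(rest, "M  CHG")]) {
    for (p in m_line_pairs(l)) atoms$charge[p[1L]] <- p[2L]
  }
  for (l in rest[startsWith(rest, "M  ISO")]) {
    for (p in m_line_pairs(l)) atoms$isotope[p[1L]] <- p[2L]
  }
  properties <- parse_property_block(rest)
  cid <- title
  if (!identical(cid_from, "title") && !is.null(properties[[cid_from]])) {
    cid <- trimws(properties[[cid_from]])
  }
  molecule(atoms, bonds, cid = if (nzchar(cid)) cid else NA_character_,
           properties = properties,
           is_3d = identical(dim_flag, "3D") || any(atoms$z != 0))
}

m_line_pairs <- function(line) {
  n <- fixed_int(line, 7L, 9L, "M-block count")
  lapply(seq_len(n), function(i) {
    off <- 10L + (i - 1L) * 8L
    c(fixed_int(line, off, off + 3L, "M-block atom"),
      fixed_int(line, off + 4L, off + 7L, "M-block value"))
  })
}

parse_property_block <- function(rest) {
  properties <- list()
  i <- 1L
  while (i <= length(rest)) {
    l <- rest[i]
    if (startsWith(l, "> ")) {
      name <- sub(".*<([^>]*)>.*", "\\1", l)
      vals <- character()
      i <- i + 1L
      while (i <= length(rest) && nzchar(trimws(rest[i]))) {
        vals <- c(vals, rest[i])
        i <- i + 1L
      }
      properties[[name]] <- paste(vals, collapse = "\n")
    }
    i <- i + 1L
  }
  properties
}

fmt_atom_line <- function(el, x, y, z) {
  sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          x, y, z, el)
}

m_block_lines <- function(tag, idx, val) {
  out <- character()
  while (length(idx)) {
    take <- seq_len(min(8L, length(idx)))
    out <- c(out, paste0("M  ", tag, sprintf("%3d", length(take)),
                         paste0(sprintf("%4d%4d", idx[take], val[take]),
                                collapse = "")))
    idx <- idx[-take]; val <- val[-take]
  }
  out
}

# Serialize one molecule to a V2000 molfile block (no $$$$, no data items).
# Deterministic: fixed program field, no timestamp.
write_molblock <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  a <- mol$atoms
  b <- mol$bonds
  header <- c(
    if (is.na(mol$cid)) "" else mol$cid,
    sprintf("  inchiaud          %s", if (mol$is_3d) "3D" else "2D"),
    ""
  )
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atom_lines <- if (nrow(a)) {
    vapply(seq_len(nrow(a)),
           function(i) fmt_atom_line(a$element[i], a$x[i], a$y[i], a$z[i]),
           "")
  } else character()
  bond_lines <- if (nrow(b)) {
    sprintf("%3d%3d%3d%3d", b$a1, b$a2, b$order, b$stereo)
  } else character()
  chg <- which(a$charge != 0L)
  iso <- which(!is.na(a$isotope))
  c(header, counts, atom_lines, bond_lines,
    m_block_lines("CHG", chg, a$charge[chg]),
    m_block_lines("ISO", iso, a$isotope[iso]),
    "M  END")
}

sdf_property_lines <- function(properties) {
  unlist(lapply(names(properties), function(nm) {
    c(sprintf("> <%s>", nm), properties[[nm]], "")
  }), use.names = FALSE)
}

#' Write an SDF record (optionally multi-record) to text
#'
#' @param mols a [molecule()] or list of them.
#' @return Character scalar of SDF text.
#' @export
write_sdf <- function(mols) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  paste(unlist(lapply(mols, function(m) {
    c(write_molblock(m), sdf_property_lines(m$properties), "$$$$")
  })), collapse = "\n")
}

# Atom order implied by a label map: heavy atoms by canonical number,
# each followed by its hydrogens (by suffix); orphan hydrogens last.
label_permutation <- function(mol, labels) {
  stopifnot(inherits(labels, "atom_label_map"))
  lm <- labels$map
  if (nrow(lm) != nrow(mol$atoms) ||
      !setequal(lm$original_index, seq_len(nrow(mol$atoms)))) {
    stop("label map does not cover every atom of the molecule",
         call. = FALSE)
  }
  lm[order(lm$sort_key), "original_index"]
}

#' Write an SDF record with atoms in canonical label order
#'
#' Reorders the atom block so that position follows the canonical atom
#' labels (heavy atoms by canonical number, each followed by its
#' hydrogens in suffix order), rewrites the bond block accordingly, and
#' records the original-index-to-label map in an `ATOM_LABELS` data item.
#' Two differently-ordered inputs describing the same molecule produce an
#' identical molfile block; the `ATOM_LABELS` item necessarily reflects
#' each input's own original indices.
#'
#' @param mol a [molecule()].
#' @param labels an `atom_label_map` from [assign_labels()] covering every
#'   atom of `mol`.
#' @return Character scalar of SDF text (one record).
#' @export
write_labeled_sdf <- function(mol, labels) {
  perm <- label_permutation(mol, labels)
  out <- permute_molecule(mol, perm)
  if (nrow(out$bonds)) {
    lo <- pmin(out$bonds$a1, out$bonds$a2)
    hi <- pmax(out$bonds$a1, out$bonds$a2)
    out$bonds <- out$bonds[order(lo, hi), , drop = FALSE]
    out$bonds$a1 <- lo[order(lo, hi)]
    out$bonds$a2 <- hi[order(lo, hi)]
    rownames(out$bonds) <- NULL
  }
  lm <- labels$map[order(labels$map$sort_key), ]
  out$properties[["ATOM_LABELS"]] <-
    paste(sprintf("%d,%s", lm$original_index, lm$label), collapse = "\n")
  write_sdf(out)
}

#' Write XYZ text with canonical atom labels
#'
#' Standard XYZ layout: atom count, comment line, then one
#' `element x y z` line per atom with the canonical label as a trailing
#' comment column. Atom order follows the label order.
#'
#' @inheritParams write_labeled_sdf
#' @return Character scalar of XYZ text.
#' @export
write_xyz <- function(mol, labels) {
  if (!nrow(mol$atoms)) stop("cannot write XYZ for an empty molecule",
                             call. = FALSE)
  perm <- label_permutation(mol, labels)
  a <- mol$atoms[perm, , drop = FALSE]
  lm <- labels$map[order(labels$map$sort_key), ]
  paste(c(
    nrow(a),
    sprintf("%s labeled by inchiaudit",
            if (is.na(mol$cid)) "molecule" else mol$cid),
    sprintf("%-3s %12.4f %12.4f %12.4f  # %s",
            a$element, a$x, a$y, a$z, lm$label)
  ), collapse = "\n")
}

#' Write PDB HETATM text with canonical atom labels
#'
#' One HETATM line per atom (residue `LIG 1`), the canonical label in the
#' atom-name field (truncated to the 4-character field if longer), element
#' symbol in columns 77-78, terminated by `END`.
#'
#' @inheritParams write_labeled_sdf
#' @return Character scalar of PDB text.
#' @export
write_pdb <- function(mol, labels) {
  if (!nrow(mol$atoms)) stop("cannot write PDB for an empty molecule",
                             call. = FALSE)
  perm <- label_permutation(mol, labels)
  a <- mol$atoms[perm, , drop = FALSE]
  lm <- labels$map[order(labels$map$sort_key), ]
  lines <- sprintf(
    "HETATM%5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), substr(lm$label, 1L, 4L), "LIG", 1L,
    a$x, a$y, a$z, a$element
  )
  paste(c(lines, "END"), collapse = "\n")
}
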