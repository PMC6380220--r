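#' @name inchi-layers
#' @title Standard InChI layer model
#'
#' @description
#' A standard InChI string is a stack of `/`-delimited layers: the Hill
#' formula of the core parent, heavy-atom connectivity (`/c`), hydrogen
#' positions (`/h`), net intrinsic charge (`/q`), protonation delta
#' (`/p`), double-bond geometry (`/b`), chiral-center parity (`/t`),
#' stereo reference and type (`/m`, `/s`), and isotopes (`/i`). The core
#' parent is the composition before any charge is imposed by adding or
#' removing protons; `/q` carries charges intrinsic to the covalent
#' structure (e.g. a quaternary nitrogen) while `/p` counts protons added
#' to or removed from the core. Multi-component records separate formula
#' components with `.` and per-component layer entries with `;`.
#'
#' [parse_inchi()] decomposes a string into this model; [serialize_inchi()]
#' is its inverse on valid input.
NULL

LAYER_KEYS <- c("c", "h", "q", "p", "b", "t", "m", "s", "i")

# Strip typesetting artifacts: all whitespace, emphasis markers, and
# unicode minus/dash variants. Figure-legend strings such as
# "InChI = 1 S/.../**p + 1**" become machine-valid after this.
normalize_inchi_text <- function(text) {
  text <- gsub("−|–|—", "-", text)
  gsub("[[:space:]*]+", "", text)
}

#' Parse a standard InChI string into layers
#'
#' @param text an InChI string; typeset whitespace and emphasis markers
#'   are normalized away first, so strings transcribed from print are
#'   acceptable.
#' @return An object of class `inchi_layers`: version, `standard` flag,
#'   per-component formula compositions, raw layer texts, parsed
#'   per-component `/q` and `/p` integers, and an `extras` list of any
#'   unrecognized trailing layers.
#' @export
parse_inchi <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- normalize_inchi_text(text)
  if (!startsWith(s, "InChI=")) {
    stop("not an InChI string (missing 'InChI=' prefix): ", text,
         call. = FALSE)
  }
  body <- substr(s, 7L, nchar(s))
  segs <- strsplit(body, "/", fixed = TRUE)[[1L]]
  if (length(segs) < 2L || !nzchar(segs[1L])) {
    stop("InChI string has no formula layer: ", text, call. = FALSE)
  }
  version <- segs[1L]
  formula_raw <- segs[2L]
  layers <- stats::setNames(rep("", length(LAYER_KEYS)), LAYER_KEYS)
  extras <- character()
  seen_i <- FALSE
  for (seg in segs[-(1:2)]) {
    if (!nzchar(seg)) next
    key <- substr(seg, 1L, 1L)
    val <- substr(seg, 2L, nchar(seg))
    if (seen_i && key == "h") {
      # isotopic-hydrogen sublayer of the /i block
      layers[["i"]] <- paste0(layers[["i"]], "/h", val)
    } else if (key %in% LAYER_KEYS && layers[[key]] == "" && !seen_i ||
               key == "i" && !seen_i) {
      layers[[key]] <- val
      if (key == "i") seen_i <- TRUE
    } else {
      extras <- c(extras, seg)
    }
  }
  structure(list(
    version = version,
    standard = identical(version, "1S"),
    formula = parse_formula_components(formula_raw),
    formula_raw = formula_raw,
    layers = as.list(layers),
    q_values = parse_charge_layer(layers[["q"]]),
    p_values = parse_charge_layer(layers[["p"]]),
    extras = extras,
    source = s
  ), class = "inchi_layers")
}

#' @export
print.inchi_layers <- function(x, ...) {
  cat("<inchi_layers", if (!x$standard) "(non-standard)", x$source, ">\n")
  invisible(x)
}

# "C2H4O2.Na" / "2C6H6.Cl" -> list of named integer vectors, multipliers
# expanded into repeated components.
parse_formula_components <- function(formula_raw) {
  comps <- strsplit(formula_raw, ".", fixed = TRUE)[[1L]]
  out <- list()
  for (comp in comps) {
    mult <- 1L
    m <- regmatches(comp, regexec("^([0-9]+)(.*)$", comp))[[1L]]
    if (length(m) && nzchar(m[2L])) {
      mult <- as.integer(m[2L])
      comp <- m[3L]
    }
    comp_counts <- parse_composition(comp)
    for (k in seq_len(mult)) out[[length(out) + 1L]] <- comp_counts
  }
  out
}

# One formula component, e.g. "C15H16N4O3S" -> named integer vector.
parse_composition <- function(s) {
  if (!nzchar(s)) stop("empty formula component", call. = FALSE)
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*|.", s))[[1L]]
  counts <- integer()
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([A-Z][a-z]?)([0-9]*)$", tok))[[1L]]
    if (!length(m)) stop("unparseable formula token '", tok, "' in '", s,
                         "'", call. = FALSE)
    el <- m[2L]
    if (!el %in% ELEMENTS) stop("unknown element symbol '", el, "' in '",
                                s, "'", call. = FALSE)
    n <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

# /q or /p layer text -> per-component integer vector. Components are
# ";"-separated; an empty component is 0; "n*x" repeats x n times.
parse_charge_layer <- function(txt) {
  if (is.null(txt) || !nzchar(txt)) return(integer())
  comps <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  if (endsWith(txt, ";")) comps <- c(comps, "")
  unlist(lapply(comps, function(cmp) {
    if (!nzchar(cmp)) return(0L)
    rep_n <- 1L
    if (grepl("*", cmp, fixed = TRUE)) {
      parts <- strsplit(cmp, "*", fixed = TRUE)[[1L]]
      rep_n <- as.integer(parts[1L])
      cmp <- parts[2L]
    }
    v <- suppressWarnings(as.integer(cmp))
    if (is.na(v)) stop("unparseable charge layer component '", cmp, "'",
                       call. = FALSE)
    rep(v, rep_n)
  }))
}

#' Serialize parsed layers back to an InChI string
#'
#' Inverse of [parse_inchi()]: emits the layers in standard order with
#' canonical spacing, so `serialize_inchi(parse_inchi(x))` equals the
#' whitespace-normalized `x` for any valid standard InChI.
#'
#' @param layers an `inchi_layers` object.
#' @return Character scalar.
#' @export
serialize_inchi <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  if (!length(layers$formula) || !nzchar(layers$formula_raw)) {
    stop("cannot serialize layers without a formula layer", call. = FALSE)
  }
  parts <- c(paste0("InChI=", layers$version), layers$formula_raw)
  for (k in LAYER_KEYS) {
    v <- layers$layers[[k]]
    if (nzchar(v)) parts <- c(parts, paste0(k, v))
  }
  parts <- c(parts, layers$extras)
  paste(parts, collapse = "/")
}

#' Net intrinsic charge and protonation delta
#'
#' `net_charge()` sums the `/q` layer over all components (charges
#' intrinsic to the covalent structure); `proton_delta()` sums the `/p`
#' layer (protons added to or removed from the core parent). An absent
#' layer means zero.
#'
#' @param layers an `inchi_layers` object.
#' @return Integer scalar.
#' @export
net_charge <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  sum(layers$q_values, 0L)
}

#' @rdname net_charge
#' @export
proton_delta <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  sum(layers$p_values, 0L)
}

merge_compositions <- function(comps) {
  out <- integer()
  for (cc in comps) {
    for (el in names(cc)) {
      out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + cc[[el]]
    }
  }
  out[hill_order(names(out))]
}

new_hill_formula <- function(composition, charge) {
  composition <- composition[hill_order(names(composition))]
  structure(list(composition = composition, charge = as.integer(charge)),
            class = "hill_formula")
}

#' @export
print.hill_formula <- function(x, ...) {
  cat("<hill_formula", hill_format(x$composition, x$charge), ">\n")
  invisible(x)
}

#' Core-parent and charged-species formulas
#'
#' The formula layer of a standard InChI records the core parent: the
#' composition before charges are imposed by (de)protonation. The charged
#' species actually described by the string has `proton_delta` hydrogens
#' added to (or removed from) that core, and total charge
#' `net_charge + proton_delta`. `core_parent_formula()` returns the layer
#' verbatim (merged across components) with charge `net_charge`;
#' `charged_species_formula()` applies the `/p` arithmetic.
#'
#' @param layers an `inchi_layers` object.
#' @return A `hill_formula`: named integer composition plus charge.
#' @export
core_parent_formula <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  new_hill_formula(merge_compositions(layers$formula), net_charge(layers))
}

#' @rdname core_parent_formula
#' @export
charged_species_formula <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  comp <- merge_compositions(layers$formula)
  p <- proton_delta(layers)
  if (p != 0L) {
    h <- if ("H" %in% names(comp)) comp[["H"]] else 0L
    if (h + p < 0L) {
      stop("protonation delta ", p, " removes more hydrogens than the ",
           "core parent has (", h, ")", call. = FALSE)
    }
    comp["H"] <- h + p
    comp <- comp[comp > 0L]
  }
  new_hill_formula(comp, net_charge(layers) + p)
}

#' Format a composition in Hill notation
#'
#' Hill convention: carbon first, hydrogen second, all other elements
#' alphabetical; when no carbon is present every element (hydrogen
#' included) sorts alphabetically. Unit counts are elided. A non-zero
#' charge is appended as `+`, `-`, `+n`, `-n`.
#'
#' @param composition named integer vector (element -> count, counts >= 1),
#'   or a `hill_formula`.
#' @param charge integer; ignored when `composition` is a `hill_formula`.
#' @return Character scalar.
#' @export
hill_format <- function(composition, charge = 0L) {
  if (inherits(composition, "hill_formula")) {
    charge <- composition$charge
    composition <- composition$composition
  }
  stopifnot(all(composition >= 1L))
  els <- hill_order(names(composition))
  body <- paste(vapply(els, function(el) {
    n <- composition[[el]]
    if (n == 1L) el else paste0(el, n)
  }, ""), collapse = "")
  suffix <- if (charge == 0L) "" else {
    paste0(if (charge > 0L) "+" else "-",
           if (abs(charge) > 1L) abs(charge) else "")
  }
  paste0(body, suffix)
}

#' Parse a molecular-formula string with optional charge suffix
#'
#' Accepts the charge-suffix dialects found in archived formulas: a bare
#' trailing sign (`"C15H17N4O3S+"`, charge +/-1) or a sign followed by a
#' magnitude (`"SO4-2"`); unicode minus variants are normalized. Digits
#' *before* a trailing sign deliberately bind to the last element, not
#' the charge, because that is how the archive writes polyatomic ions
#' (`"C2H3O2-"` is the acetate anion, charge -1, not a doubly charged
#' species). Two-letter element symbols are read greedily by
#' capitalization.
#'
#' @param text a formula string such as `"C15H17N4O3S+"`.
#' @return List with `composition` (named integer vector in Hill order),
#'   `charge` (integer) and `was_charged` (logical: a suffix was present).
#' @export
parse_formula_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("−|–|—", "-", gsub("[[:space:]_]+", "", text))
  if (!nzchar(s)) stop("empty formula string", call. = FALSE)
  charge <- 0L
  was_charged <- FALSE
  m <- regmatches(s, regexec("^(.*?)([+-])([0-9]*)$", s))[[1L]]
  if (length(m)) {
    mag <- if (nzchar(m[4L])) as.integer(m[4L]) else 1L
    charge <- if (m[3L] == "+") mag else -mag
    was_charged <- TRUE
    s <- m[2L]
    if (!nzchar(s)) stop("formula string is only a charge suffix: ", text,
                         call. = FALSE)
  }
  comp <- parse_composition(s)
  list(composition = comp[hill_order(names(comp))],
       charge = charge, was_charged = was_charged)
}

#' Does an InChI declare ambiguous stereochemistry?
#'
#' True when a question mark occurs in the `/b` (double-bond geometry) or
#' `/t` (chiral-center parity) layer, meaning the configuration of at
#' least one stereo element is undefined.
#'
#' @param layers an `inchi_layers` object.
#' @return Logical scalar.
#' @export
has_ambiguous_stereo <- function(layers) {
  stopifnot(inherits(layers, "inchi_layers"))
  grepl("?", layers$layers$b, fixed = TRUE) ||
    grepl("?", layers$layers$t, fixed = TRUE)
}
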