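# The audit engine: layer-by-layer InChI comparison, discrepancy
# categorization, and deposited-formula reconciliation.

CATEGORY_MAP <- c(
  c = "atom_connectivity", h = "atom_connectivity",
  p = "charge", q = "charge",
  b = "stereochemistry", t = "stereochemistry",
  m = "stereochemistry", s = "stereochemistry",
  i = "isotope",
  formula = "formula"
)

# Normalize one raw layer text for comparison: expand "n*x" component
# repetitions so e.g. "2*+1" and "+1;+1" compare equal.
expand_layer_components <- function(txt) {
  if (!nzchar(txt)) return(txt)
  comps <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  if (endsWith(txt, ";")) comps <- c(comps, "")
  out <- unlist(lapply(comps, function(cmp) {
    m <- regmatches(cmp, regexec("^([0-9]+)\\*(.*)$", cmp))[[1L]]
    if (length(m) && nzchar(m[2L])) rep(m[3L], as.integer(m[2L])) else cmp
  }))
  paste(out, collapse = ";")
}

comp_key <- function(comp) {
  comp <- comp[comp > 0L]
  paste(sprintf("%s:%d", hill_order(names(comp)), comp[hill_order(names(comp))]),
        collapse = ",")
}

#' Diff two parsed InChI strings layer by layer
#'
#' A text layer (`/c`, `/h`, `/b`, `/t`, `/m`, `/s`, `/i`) differs when
#' its component-expanded text differs; absent counts as differing from
#' present. The `/q` and `/p` layers compare as per-component integer
#' vectors, so an absent layer equals an explicit zero. The formula layer
#' is flagged as `"formula"` only when the two strings describe genuinely
#' different compositions: the core-parent compositions differ *and* the
#' charged-species compositions (after applying each side's `/p`
#' arithmetic) also differ. A deposited record that writes the same anion
#' as `CxHn+1.../p-1` where the structure yields `CxHn.../q-1` therefore
#' flags `/h`, `/p` and `/q` but not the formula, because both strings
#' agree on the charged species actually present.
#'
#' @param derived `inchi_layers` generated from the structure.
#' @param deposited `inchi_layers` parsed from the archived string.
#' @return Character vector of differing layer names (subset of
#'   `formula, c, h, q, p, b, t, m, s, i`).
#' @export
diff_layers <- function(derived, deposited) {
  stopifnot(inherits(derived, "inchi_layers"),
            inherits(deposited, "inchi_layers"))
  out <- character()
  core_eq <- identical(comp_key(core_parent_formula(derived)$composition),
                       comp_key(core_parent_formula(deposited)$composition))
  charged_eq <- tryCatch({
    a <- charged_species_formula(derived)
    b <- charged_species_formula(deposited)
    identical(comp_key(a$composition), comp_key(b$composition)) &&
      a$charge == b$charge
  }, error = function(e) FALSE)
  if (!core_eq && !charged_eq) out <- c(out, "formula")
  for (k in c("c", "h", "b", "t", "m", "s", "i")) {
    if (!identical(expand_layer_components(derived$layers[[k]]),
                   expand_layer_components(deposited$layers[[k]]))) {
      out <- c(out, k)
    }
  }
  pad <- function(v, n) c(v, rep(0L, n - length(v)))
  n <- max(length(derived$q_values), length(deposited$q_values))
  if (!identical(pad(derived$q_values, n), pad(deposited$q_values, n))) {
    out <- c(out, "q")
  }
  n <- max(length(derived$p_values), length(deposited$p_values))
  if (!identical(pad(derived$p_values, n), pad(deposited$p_values, n))) {
    out <- c(out, "p")
  }
  intersect(c("formula", "c", "h", "q", "p", "b", "t", "m", "s", "i"), out)
}

#' Map differing layers to discrepancy categories
#'
#' The category scheme: `/c` and `/h` mismatches are atom-connectivity
#' discrepancies; `/p` and `/q` are charge discrepancies; `/b`, `/t` (and
#' the dependent `/m`, `/s` reference layers) are stereochemistry
#' discrepancies; `/i` is an isotope discrepancy; `"formula"` keeps its
#' own category. An entry may fall into several categories at once.
#'
#' @param differing_layers character vector of layer names from
#'   [diff_layers()].
#' @return Character vector of category names (sorted, unique).
#' @export
categorize <- function(differing_layers) {
  if (!length(differing_layers)) return(character())
  unknown <- setdiff(differing_layers, names(CATEGORY_MAP))
  if (length(unknown)) {
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sort(unique(unname(CATEGORY_MAP[differing_layers])))
}

#' Reconcile an archived formula against a structure-derived InChI
#'
#' Archived formulas describe the charged species as deposited (charge
#' suffix included), while the InChI formula layer records the core
#' parent. Consistency therefore means: the parsed formula equals the
#' charged-species formula implied by the InChI, i.e. core composition
#' with `/p` protons added and total charge `/q + /p`. The explanation
#' distinguishes the protonation case (`/p != 0`: deposited H = core H +
#' p, charge from added/removed protons) from the intrinsic-charge case
#' (`/p == 0`: deposited H = core H, charge carried by the covalent
#' structure, e.g. a quaternary nitrogen).
#'
#' @param deposited_formula formula string with optional charge suffix.
#' @param derived `inchi_layers` generated from the structure.
#' @return List with `consistent` (logical) and `explanation` (character).
#' @export
reconcile_formula <- function(deposited_formula, derived) {
  stopifnot(inherits(derived, "inchi_layers"))
  parsed <- tryCatch(parse_formula_string(deposited_formula),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    return(list(consistent = FALSE,
                explanation = paste0("formula parse error: ",
                                     conditionMessage(parsed))))
  }
  species <- charged_species_formula(derived)
  p <- proton_delta(derived)
  ok <- identical(comp_key(parsed$composition), comp_key(species$composition)) &&
    parsed$charge == species$charge
  case <- if (p != 0L) {
    sprintf("protonation case: deposited H = core H %s %d, charge %+d from /q%+d /p%+d",
            if (p > 0L) "+" else "-", abs(p), species$charge,
            net_charge(derived), p)
  } else if (net_charge(derived) != 0L) {
    sprintf("intrinsic-charge case: deposited H = core H, charge %+d from /q",
            net_charge(derived))
  } else {
    "neutral: formula equals core parent"
  }
  list(consistent = ok,
       explanation = paste0(if (ok) "consistent; " else "inconsistent; ",
                            case, "; expected ", hill_format(species),
                            ", archived ",
                            hill_format(parsed$composition, parsed$charge)))
}

new_discrepancy_report <- function(cid, differing_layers = character(),
                                   categories = NULL,
                                   ambiguous_stereo = FALSE,
                                   non_standard_deposited = FALSE,
                                   notes = character(),
                                   derived_inchi = NA_character_,
                                   deposited_inchi = NA_character_) {
  if (is.null(categories)) categories <- categorize(differing_layers)
  structure(list(cid = cid,
                 differing_layers = differing_layers,
                 categories = categories,
                 ambiguous_stereo = ambiguous_stereo,
                 non_standard_deposited = non_standard_deposited,
                 notes = notes,
                 derived_inchi = derived_inchi,
                 deposited_inchi = deposited_inchi),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("<discrepancy_report %s: layers {%s} -> categories {%s}%s%s>\n",
              x$cid,
              paste(x$differing_layers, collapse = ","),
              paste(x$categories, collapse = ","),
              if (x$ambiguous_stereo) " [ambiguous stereo]" else "",
              if (x$non_standard_deposited) " [non-standard deposited]" else ""))
  if (length(x$notes)) cat(" notes:", paste(x$notes, collapse = " | "), "\n")
  invisible(x)
}

#' Audit one database entry
#'
#' Runs the full per-entry audit: generate the standard InChI from the 3D
#' structure, parse both the derived and the deposited strings, diff the
#' layers, categorize, and reconcile the archived formula against the
#' structure-derived charged-species formula. A deposited non-standard
#' string (prefix `InChI=1/`) is reported via `non_standard_deposited`
#' and excluded from layer diffing rather than producing spurious flags.
#' The audit flags disagreement; it never adjudicates which side is
#' correct.
#'
#' @param mol a [molecule()] (the archived 3D structure).
#' @param deposited_inchi archived InChI string, or `""`/`NA` when absent.
#' @param deposited_formula archived formula string, or `""`/`NA`.
#' @param derived optional precomputed [generate_inchi()] result for
#'   `mol` (used by the batch layer to avoid duplicate delegate calls).
#' @return A `discrepancy_report`.
#' @export
check_entry <- function(mol, deposited_inchi = NA_character_,
                        deposited_formula = NA_character_,
                        derived = NULL) {
  stopifnot(inherits(mol, "molecule"))
  cid <- if (is.na(mol$cid)) "" else mol$cid
  if (is.null(derived)) derived <- generate_inchi(mol)
  if (!is.null(derived$error)) {
    return(new_discrepancy_report(
      cid, notes = paste0("delegate error: ", derived$error)))
  }
  derived_layers <- parse_inchi(derived$inchi)
  have_inchi <- !is.na(deposited_inchi) && nzchar(trimws(deposited_inchi))
  have_formula <- !is.na(deposited_formula) && nzchar(trimws(deposited_formula))
  layers_out <- character()
  notes <- character()
  ambiguous <- has_ambiguous_stereo(derived_layers)
  non_standard <- FALSE
  deposited_layers <- NULL
  if (have_inchi) {
    deposited_layers <- tryCatch(parse_inchi(deposited_inchi),
                                 error = function(e) e)
    if (inherits(deposited_layers, "error")) {
      notes <- c(notes, paste0("deposited InChI unparseable: ",
                               conditionMessage(deposited_layers)))
      deposited_layers <- NULL
    } else if (!deposited_layers$standard) {
      non_standard <- TRUE
      notes <- c(notes, "deposited InChI is non-standard; layer diff skipped")
    } else {
      layers_out <- diff_layers(derived_layers, deposited_layers)
      ambiguous <- ambiguous || has_ambiguous_stereo(deposited_layers)
    }
  }
  if (have_formula) {
    rec <- reconcile_formula(deposited_formula, derived_layers)
    if (!rec$consistent) {
      layers_out <- union(layers_out, "formula")
      notes <- c(notes, paste0("formula reconciliation: ", rec$explanation))
    }
  }
  layers_out <- intersect(c("formula", "c", "h", "q", "p", "b", "t", "m",
                            "s", "i"), layers_out)
  new_discrepancy_report(cid, layers_out,
                         ambiguous_stereo = ambiguous,
                         non_standard_deposited = non_standard,
                         notes = c(notes, derived$warnings),
                         derived_inchi = derived$inchi,
                         deposited_inchi = if (have_inchi) deposited_inchi
                                           else NA_character_)
}

# One CSV row per report (RFC 4180 via write.csv at the batch layer).
report_row <- function(rep) {
  data.frame(
    cid = rep$cid,
    differing_layers = paste(rep$differing_layers, collapse = "|"),
    categories = paste(rep$categories, collapse = "|"),
    ambiguous_stereo = rep$ambiguous_stereo,
    non_standard_deposited = rep$non_standard_deposited,
    notes = paste(rep$notes, collapse = " | "),
    stringsAsFactors = FALSE
  )
}
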