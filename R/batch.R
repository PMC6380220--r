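# Desk-scale batch workflow: shard the input archive, audit every entry,
# and emit the run's relational output as three CSV tables (outputs,
# metadata, names) plus per-layer and per-category flagged-CID lists.

#' Default batch configuration
#'
#' @param formula_key,inchi_key,weight_key,mass_key,synonym_key SDF data
#'   item names carrying the archived formula, InChI, molecular weight,
#'   exact mass and synonyms (defaults follow the PubChem property
#'   naming).
#' @param cid_key data item holding the compound identifier.
#' @param workers number of worker slots for shard planning.
#' @param chunk_size files per shard (default 18, the archive-scale
#'   chunking constant).
#' @param seed integer seed recorded in the run log.
#' @return Named list of configuration values.
#' @export
batch_config <- function(formula_key = "PUBCHEM_MOLECULAR_FORMULA",
                         inchi_key = "PUBCHEM_IUPAC_INCHI",
                         weight_key = "PUBCHEM_MOLECULAR_WEIGHT",
                         mass_key = "PUBCHEM_EXACT_MASS",
                         synonym_key = "PUBCHEM_SYNONYMS",
                         cid_key = "PUBCHEM_COMPOUND_CID",
                         workers = 1L, chunk_size = 18L, seed = 1L) {
  list(formula_key = formula_key, inchi_key = inchi_key,
       weight_key = weight_key, mass_key = mass_key,
       synonym_key = synonym_key, cid_key = cid_key,
       workers = as.integer(workers), chunk_size = as.integer(chunk_size),
       seed = as.integer(seed))
}

#' Plan shard assignment of input files to workers
#'
#' Files are grouped into consecutive chunks of `chunk_size` and chunks
#' are dealt round-robin to worker slots. Deterministic: the same file
#' list always yields the same assignment, and every file is assigned
#' exactly once.
#'
#' @param files character vector of input file paths.
#' @param workers number of worker slots (>= 1).
#' @param chunk_size files per chunk (default 18).
#' @return List of length `workers`; element `w` is a list of chunks
#'   (character vectors) assigned to worker `w`.
#' @export
plan_shards <- function(files, workers, chunk_size = 18L) {
  stopifnot(workers >= 1L, chunk_size >= 1L)
  assignment <- rep(list(list()), workers)
  if (!length(files)) return(assignment)
  n_chunks <- ceiling(length(files) / chunk_size)
  for (j in seq_len(n_chunks)) {
    chunk <- files[((j - 1L) * chunk_size + 1L):min(j * chunk_size,
                                                    length(files))]
    w <- ((j - 1L) %% workers) + 1L
    assignment[[w]][[length(assignment[[w]]) + 1L]] <- chunk
  }
  assignment
}

#' Drop obsoleted duplicate records
#'
#' Archives preserve superseded structures for updated entries; only the
#' latest version (the last occurrence in read order) is audited. The
#' superseded records are logged, not processed.
#'
#' @param mols list of molecules in read order.
#' @return List with `kept` (last occurrence per cid, in order of that
#'   occurrence) and `superseded` (data.frame `cid`, `position`).
#' @export
dedupe_obsolete <- function(mols) {
  cids <- vapply(mols, function(m) if (is.na(m$cid)) "" else m$cid, "")
  keep_idx <- !duplicated(cids, fromLast = TRUE) | cids == ""
  superseded <- data.frame(cid = cids[!keep_idx],
                           position = which(!keep_idx),
                           stringsAsFactors = FALSE)
  list(kept = mols[keep_idx], superseded = superseded)
}

batch_entry_record <- function(mol, derived, labels, report, input_text) {
  lab_ok <- inherits(labels, "atom_label_map")
  multi <- lab_ok && length(unique(stats::na.omit(labels$map$component))) > 1L
  data.frame(
    cid = report$cid,
    input_structure = input_text,
    sdf_out = if (lab_ok) write_labeled_sdf(mol, labels) else "",
    pdb_out = if (lab_ok) write_pdb(mol, labels) else "",
    xyz_out = if (lab_ok) write_xyz(mol, labels) else "",
    inchi = if (is.na(derived$inchi)) "" else derived$inchi,
    alatis_formula = if (is.na(derived$inchi)) "" else
      hill_format(charged_species_formula(parse_inchi(derived$inchi))),
    warnings = paste(c(derived$warnings,
                       if (lab_ok) attr(labels, "warnings")),
                     collapse = " | "),
    errors = paste(c(if (!is.null(derived$error)) derived$error),
                   collapse = " | "),
    atom_map = if (lab_ok) label_map_csv(labels) else "",
    multi_compound_map = if (multi) component_map_csv(labels) else "",
    stringsAsFactors = FALSE
  )
}

#' Run the batch audit over a directory of SDF archives
#'
#' Reads every `.sdf` / `.sdf.gz` file under `input_dir` (sorted name
#' order), drops obsoleted duplicates (last occurrence of a cid wins,
#' across files in read order), audits every surviving 3D entry, and
#' writes to `output_dir`:
#' `outputs.csv` (the 11-column per-entry record: cid, input structure,
#' labeled SDF/PDB/XYZ, standard InChI, Hill formula, warnings, errors,
#' atom map, multi-compound map), `meta_data.csv` (cid, formula,
#' molecular weight, exact mass), `names.csv` (cid, first synonym,
#' synonym count), `reports.csv` (per-entry discrepancy rows),
#' `flagged_<layer>.txt` and `flagged_<category>.txt` CID lists,
#' `skipped_2d_only.txt`, `obsoleted.txt`, `errors.csv`, `run_log.txt`
#' and `summary.json`. Entries already present in an existing
#' `outputs.csv` are skipped, so re-running a completed directory is
#' idempotent. Output content is independent of `workers`: sharding only
#' plans the work units, and results are merged in deterministic cid
#' order.
#'
#' @param input_dir directory holding `.sdf` / `.sdf.gz` files.
#' @param output_dir directory for results (created if needed).
#' @param config a [batch_config()].
#' @return Summary list: entries processed, skipped, flagged per
#'   category, errored.
#' @export
run_batch <- function(input_dir, output_dir, config = batch_config()) {
  files <- sort(list.files(input_dir, pattern = "\\.sdf(\\.gz)?$",
                           full.names = TRUE))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  shards <- plan_shards(files, config$workers, config$chunk_size)

  mols <- list()
  errors <- data.frame(file = character(), record = integer(),
                       message = character())
  for (f in files) {
    res <- read_sdf(f, cid_from = config$cid_key)
    mols <- c(mols, res$molecules)
    if (nrow(res$errors)) {
      errors <- rbind(errors, cbind(file = basename(f), res$errors))
    }
  }
  dd <- dedupe_obsolete(mols)
  kept <- dd$kept

  is3d <- vapply(kept, function(m) m$is_3d, TRUE)
  skipped_2d <- vapply(kept[!is3d], function(m) m$cid, "")
  kept <- kept[is3d]

  done <- character()
  outputs_path <- file.path(output_dir, "outputs.csv")
  prev_outputs <- NULL
  if (file.exists(outputs_path)) {
    prev_outputs <- utils::read.csv(outputs_path, colClasses = "character")
    done <- prev_outputs$cid
  }
  todo <- kept[!vapply(kept, function(m) m$cid %in% done, TRUE)]

  derived_all <- if (length(todo)) generate_inchi_batch(todo) else list()

  out_rows <- list(); meta_rows <- list(); name_rows <- list()
  rep_rows <- list()
  for (i in seq_along(todo)) {
    mol <- todo[[i]]
    derived <- derived_all[[i]]
    labels <- tryCatch(
      if (is.null(derived$error)) {
        assign_labels(mol, auxinfo = derived$auxinfo)
      } else NULL,
      error = function(e) NULL)
    dep_inchi <- mol$properties[[config$inchi_key]]
    dep_formula <- mol$properties[[config$formula_key]]
    report <- check_entry(mol,
                          if (is.null(dep_inchi)) NA_character_ else dep_inchi,
                          if (is.null(dep_formula)) NA_character_ else dep_formula,
                          derived = derived)
    out_rows[[i]] <- batch_entry_record(mol, derived, labels, report,
                                        write_sdf(mol))
    meta_rows[[i]] <- data.frame(
      cid = report$cid,
      formula = if (is.null(dep_formula)) "" else dep_formula,
      molecular_weight = prop_or(mol, config$weight_key),
      exact_mass = prop_or(mol, config$mass_key),
      stringsAsFactors = FALSE)
    syn <- mol$properties[[config$synonym_key]]
    syn_list <- if (is.null(syn)) character() else
      strsplit(syn, "\n", fixed = TRUE)[[1L]]
    name_rows[[i]] <- data.frame(
      cid = report$cid,
      first_synonym = if (length(syn_list)) syn_list[1L] else "",
      synonym_count = length(syn_list),
      stringsAsFactors = FALSE)
    rep_rows[[i]] <- report_row(report)
  }

  outputs <- rbind(prev_outputs, do.call(rbind, out_rows))
  reports_path <- file.path(output_dir, "reports.csv")
  reports <- rbind(
    if (file.exists(reports_path))
      utils::read.csv(reports_path,
                      colClasses = c(cid = "character",
                                     differing_layers = "character",
                                     categories = "character",
                                     notes = "character")),
    do.call(rbind, rep_rows))
  meta <- rbind(
    if (file.exists(file.path(output_dir, "meta_data.csv")))
      utils::read.csv(file.path(output_dir, "meta_data.csv"),
                      colClasses = "character"),
    do.call(rbind, meta_rows))
  names_tab <- rbind(
    if (file.exists(file.path(output_dir, "names.csv")))
      utils::read.csv(file.path(output_dir, "names.csv"),
                      colClasses = c(cid = "character",
                                     first_synonym = "character")),
    do.call(rbind, name_rows))

  # deterministic merge order regardless of sharding or resumption
  ord <- function(df) if (is.null(df) || !nrow(df)) df else
    df[order(df$cid), , drop = FALSE]
  outputs <- ord(outputs); reports <- ord(reports)
  meta <- ord(meta); names_tab <- ord(names_tab)

  write_csv0 <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  if (!is.null(outputs)) write_csv0(outputs, outputs_path)
  if (!is.null(reports)) write_csv0(reports, reports_path)
  if (!is.null(meta)) write_csv0(meta, file.path(output_dir, "meta_data.csv"))
  if (!is.null(names_tab)) write_csv0(names_tab,
                                      file.path(output_dir, "names.csv"))

  all_layers <- c("formula", "c", "h", "q", "p", "b", "t", "m", "s", "i")
  all_categories <- c("atom_connectivity", "charge", "stereochemistry",
                      "isotope", "formula")
  flag_counts <- stats::setNames(integer(length(all_categories)),
                                 all_categories)
  if (!is.null(reports) && nrow(reports)) {
    layer_sets <- strsplit(reports$differing_layers, "|", fixed = TRUE)
    cat_sets <- strsplit(reports$categories, "|", fixed = TRUE)
    for (lay in all_layers) {
      hit <- vapply(layer_sets, function(s) lay %in% s, TRUE)
      writeLines(sort(reports$cid[hit]),
                 file.path(output_dir, sprintf("flagged_layer_%s.txt", lay)))
    }
    for (ct in all_categories) {
      hit <- vapply(cat_sets, function(s) ct %in% s, TRUE)
      writeLines(sort(reports$cid[hit]),
                 file.path(output_dir, sprintf("flagged_%s.txt", ct)))
      flag_counts[ct] <- sum(hit)
    }
  } else {
    for (lay in all_layers) {
      writeLines(character(),
                 file.path(output_dir, sprintf("flagged_layer_%s.txt", lay)))
    }
    for (ct in all_categories) {
      writeLines(character(), file.path(output_dir,
                                        sprintf("flagged_%s.txt", ct)))
    }
  }
  writeLines(sort(skipped_2d), file.path(output_dir, "skipped_2d_only.txt"))
  writeLines(sort(dd$superseded$cid), file.path(output_dir, "obsoleted.txt"))
  write_csv0(errors, file.path(output_dir, "errors.csv"))

  n_flagged <- if (!is.null(reports) && nrow(reports)) {
    sum(nzchar(reports$categories))
  } else 0L
  # summary.json describes the completed output state (not this run's
  # increment), so resuming a finished directory rewrites identical bytes
  summary <- list(
    files = length(files),
    shards = sum(vapply(shards, length, 0L)),
    entries_total = length(mols),
    entries_obsoleted = nrow(dd$superseded),
    entries_skipped_2d = length(skipped_2d),
    entries_audited = if (is.null(outputs)) 0L else nrow(outputs),
    entries_flagged = n_flagged,
    flagged_by_category = as.list(flag_counts),
    read_errors = nrow(errors),
    delegate = if (length(todo)) derived_all[[1L]]$delegate
               else delegate_version(),
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_lines <- c(
    sprintf("inchiaudit batch run"),
    sprintf("delegate: %s", summary$delegate),
    sprintf("seed: %d", config$seed),
    sprintf("files: %d; entries: %d; audited: %d; flagged: %d",
            summary$files, summary$entries_total, summary$entries_audited,
            summary$entries_flagged))
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  summary$entries_processed_this_run <- length(todo)
  invisible(summary)
}

prop_or <- function(mol, key, default = "") {
  v <- mol$properties[[key]]
  if (is.null(v)) default else v
}
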