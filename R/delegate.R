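# Delegation boundary for InChI generation.
#
# The InChI canonicalization algorithm is deliberately not reimplemented:
# the IUPAC standard defines the string, and a conforming implementation
# (the InChI library bundled with RDKit, driven through a small Python
# shim) is invoked as an external program. The contract is: structure in,
# standard InChI + AuxInfo + warnings out, with the delegate name and
# version stamped on every result so version drift is visible, never
# hidden.

.delegate_env <- new.env(parent = emptyenv())

delegate_python <- function() {
  py <- getOption("inchiaudit.python", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no python interpreter found for the InChI delegate",
                        call. = FALSE)
  py
}

delegate_script <- function() {
  p <- system.file("python", "inchi_delegate.py", package = "inchiaudit")
  if (!nzchar(p)) stop("inchi_delegate.py not found in installed package",
                       call. = FALSE)
  p
}

#' Identify the InChI delegate
#'
#' @return Character scalar naming the external program and version that
#'   performs InChI canonicalization (stamped into every batch log).
#' @export
delegate_version <- function() {
  if (is.null(.delegate_env$version)) {
    out <- suppressWarnings(
      system2(delegate_python(), c(shQuote(delegate_script()), "--version"),
              stdout = TRUE, stderr = FALSE))
    .delegate_env$version <- trimws(out[1L])
  }
  .delegate_env$version
}

# Run the delegate on a character vector of molfile blocks; returns a list
# of lists (inchi, auxinfo, warnings, error, delegate). Results are cached
# per molblock within the session, so repeated structures cost one call.
delegate_inchi <- function(molblocks) {
  keys <- vapply(molblocks, function(b) paste(b, collapse = "\n"), "")
  cache <- .delegate_env
  if (is.null(cache$results)) cache$results <- new.env(parent = emptyenv())
  miss <- which(!vapply(keys, function(k) {
    exists(k, envir = cache$results, inherits = FALSE)
  }, TRUE))
  if (length(miss)) {
    sdf_text <- paste(vapply(keys[miss], function(k) paste0(k, "\n$$$$"), ""),
                      collapse = "\n")
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf), add = TRUE)
    writeLines(sdf_text, tf)
    out <- suppressWarnings(
      system2(delegate_python(), shQuote(delegate_script()),
              stdout = TRUE, stderr = FALSE, stdin = tf))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0L) {
      stop("InChI delegate exited with status ", status, call. = FALSE)
    }
    parsed <- lapply(out, jsonlite::fromJSON)
    if (length(parsed) != length(miss)) {
      stop("InChI delegate returned ", length(parsed), " results for ",
           length(miss), " records", call. = FALSE)
    }
    for (j in seq_along(miss)) {
      assign(keys[miss[j]], parsed[[j]], envir = cache$results)
    }
  }
  lapply(keys, function(k) get(k, envir = cache$results, inherits = FALSE))
}
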