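## Bridge to the bundled RDKit helper (inst/python/chemtools.py).
##
## All cheminformatics primitives — InChI canonicalization, SMARTS reaction
## application, substructure matching and Morgan fingerprint similarity —
## are served by one Python subprocess per batch, with results memoised for
## the session so repeated rule applications (e.g. across search runs) cost
## a single call.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- getOption("phenoflux.python", Sys.which("python"))
  if (!nzchar(py)) pf_error("no python interpreter found on PATH", "chem_backend_error")
  py
}

chem_helper_path <- function() {
  p <- system.file("python", "chemtools.py", package = "phenoflux")
  if (!nzchar(p)) pf_error("chemtools.py helper not found", "chem_backend_error")
  p
}

#' Execute a batch of chemistry requests against the RDKit helper
#' @noRd
chem_call <- function(requests) {
  if (length(requests) == 0) return(list())
  payload <- jsonlite::toJSON(list(requests = requests),
                              auto_unbox = TRUE, null = "null", digits = NA)
  out <- suppressWarnings(system2(chem_python(), shQuote(chem_helper_path()),
                                  input = payload, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    pf_error(sprintf("chemistry helper failed (exit %d)", status),
             "chem_backend_error")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)$results
}

cache_get <- function(key) {
  if (exists(key, envir = .chem_cache, inherits = FALSE))
    get(key, envir = .chem_cache) else NULL
}
cache_set <- function(key, value) assign(key, value, envir = .chem_cache)

## ---- standardization -------------------------------------------------------

#' Standardize compound structures to canonical InChI
#'
#' Each record may supply a SMILES string, an InChI string, or a MOL block;
#' identical molecules given in different representations yield identical
#' InChI strings.  The elemental formula (hydrogens included) and formal
#' charge are derived from the parsed structure.
#'
#' @param records data frame with column `id` and at least one of `smiles`,
#'   `inchi`, `molblock`.
#' @param on_error `"stop"` (default) raises a structure error naming the
#'   first offending record; `"omit"` drops unparseable records and attaches
#'   them as the `"errors"` attribute.
#' @return data frame with columns `id`, `inchi`, `smiles`, `formula`
#'   (formula string, e.g. `"C15H10O4"`) and `charge`.
#' @examples
#' \dontrun{
#' standardize_structure(data.frame(id = "water", smiles = "O"))
#' }
#' @export
standardize_structure <- function(records, on_error = c("stop", "omit")) {
  on_error <- match.arg(on_error)
  records <- as.data.frame(records)
  if (!"id" %in% names(records)) pf_error("records need an 'id' column", "structure_error")
  n <- nrow(records)
  get_col <- function(col) {
    if (col %in% names(records)) as.character(records[[col]]) else rep(NA_character_, n)
  }
  smiles <- get_col("smiles"); inchi <- get_col("inchi"); mol <- get_col("molblock")
  keys <- vapply(seq_len(n), function(i) {
    paste0("std|", smiles[i] %||% "", "|", inchi[i] %||% "", "|", mol[i] %||% "")
  }, character(1))
  todo <- unname(which(!duplicated(keys) & vapply(keys, function(k) is.null(cache_get(k)), TRUE, USE.NAMES = FALSE)))
  if (length(todo) > 0) {
    recs <- lapply(todo, function(i) {
      r <- list(id = as.character(records$id[i]))
      if (!is.na(smiles[i]) && nzchar(smiles[i])) r$smiles <- smiles[i]
      if (!is.na(inchi[i]) && nzchar(inchi[i])) r$inchi <- inchi[i]
      if (!is.na(mol[i]) && nzchar(mol[i])) r$molblock <- mol[i]
      r
    })
    res <- chem_call(list(list(op = "standardize", records = recs)))[[1]]
    for (j in seq_along(todo)) cache_set(keys[todo[j]], res[[j]])
  }
  rows <- vector("list", n)
  errors <- character(0)
  for (i in seq_len(n)) {
    r <- cache_get(keys[i])
    if (!is.null(r$error)) {
      msg <- sprintf("record '%s': %s", records$id[i], r$error)
      if (on_error == "stop") pf_error(msg, "structure_error",
                                       data = list(id = records$id[i]))
      errors <- c(errors, msg)
      next
    }
    rows[[i]] <- data.frame(
      id = as.character(records$id[i]), inchi = r$inchi, smiles = r$smiles,
      formula = format_formula(unlist(r$formula)), charge = as.integer(r$charge),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(id = character(0), inchi = character(0),
                      smiles = character(0), formula = character(0),
                      charge = integer(0), stringsAsFactors = FALSE)
  }
  attr(out, "errors") <- errors
  out
}

## ---- fingerprints ----------------------------------------------------------

#' Tanimoto similarity of Morgan (radius 2, 2048-bit) fingerprints
#'
#' @param a,b character vectors of SMILES or InChI strings, recycled to a
#'   common length.
#' @return numeric vector of similarities in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  keys <- paste0("tan|", pmin(a, b), "|", pmax(a, b))
  todo <- unname(which(!duplicated(keys) & vapply(keys, function(k) is.null(cache_get(k)), TRUE, USE.NAMES = FALSE)))
  if (length(todo) > 0) {
    pairs <- lapply(todo, function(i) list(a = a[i], b = b[i]))
    res <- chem_call(list(list(op = "tanimoto", pairs = pairs)))[[1]]
    for (j in seq_along(todo)) {
      r <- res[[j]]
      if (is.list(r) && !is.null(r$error))
        pf_error(r$error, "structure_error")
      cache_set(keys[todo[j]], as.numeric(r))
    }
  }
  vapply(keys, cache_get, numeric(1), USE.NAMES = FALSE)
}

#' Does a structure match a SMARTS pattern?
#' @noRd
smarts_matches <- function(smarts, structure) {
  key <- paste0("match|", smarts, "|", structure)
  hit <- cache_get(key)
  if (is.null(hit)) {
    res <- chem_call(list(list(op = "match",
                               tasks = list(list(smarts = smarts,
                                                 structure = structure)))))[[1]][[1]]
    if (is.list(res) && !is.null(res$error)) pf_error(res$error, "structure_error")
    hit <- isTRUE(res)
    cache_set(key, hit)
  }
  hit
}

#' Apply reaction SMARTS to substrates, returning standardized product sets
#' @noRd
chem_apply_smarts <- function(tasks) {
  keys <- vapply(tasks, function(t) paste0("apply|", t$smarts, "|", t$substrate),
                 character(1))
  todo <- unname(which(!duplicated(keys) & vapply(keys, function(k) is.null(cache_get(k)), TRUE, USE.NAMES = FALSE)))
  if (length(todo) > 0) {
    res <- chem_call(list(list(op = "apply", tasks = tasks[todo])))[[1]]
    for (j in seq_along(todo)) cache_set(keys[todo[j]], res[[j]])
  }
  lapply(keys, cache_get)
}
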