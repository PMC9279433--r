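## Readers and writers for the tabular and SBML network dialects.
##
## The tabular dialect is two UTF-8 tab-separated tables sharing a file stem:
## `<stem>.metabolites.tsv` with columns id, name, inchi, smiles, formula,
## charge, compartment, and `<stem>.reactions.tsv` with columns id,
## reversible, lb, ub, provenance, taxa, ec_numbers, stoichiometry.  The
## stoichiometry column encodes the sparse reaction column as
## `met=coef;met=coef` with negative coefficients for substrates.

#' Load a metabolic network from disk
#'
#' @param path for the `"tsv"` dialect, the file stem (with or without the
#'   `.reactions.tsv` suffix); for `"sbml"`, the SBML file.
#' @param dialect `"tsv"` or `"sbml"`.
#' @return a validated `metabolic_network`.
#' @export
load_network <- function(path, dialect = c("tsv", "sbml")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = read_network_tsv(path),
         sbml = read_network_sbml(path))
}

#' Write a metabolic network to disk
#'
#' @param net a `metabolic_network`.
#' @param path file stem (tsv) or file path (sbml).
#' @param dialect `"tsv"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("tsv", "sbml")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = write_network_tsv(net, path),
         sbml = write_network_sbml(net, path))
  invisible(path)
}

tsv_paths <- function(stem) {
  stem <- sub("\\.(reactions|metabolites)\\.tsv$", "", stem)
  list(reactions = paste0(stem, ".reactions.tsv"),
       metabolites = paste0(stem, ".metabolites.tsv"))
}

#' @rdname load_network
#' @export
read_network_tsv <- function(path) {
  p <- tsv_paths(path)
  for (f in unlist(p)) {
    if (!file.exists(f)) pf_error(sprintf("file not found: %s", f), "parse_error")
  }
  mets <- utils::read.delim(p$metabolites, stringsAsFactors = FALSE,
                            na.strings = "NA", quote = "",
                            colClasses = c(id = "character", name = "character",
                                           inchi = "character", smiles = "character",
                                           formula = "character", charge = "integer",
                                           compartment = "character"))
  rxns <- utils::read.delim(p$reactions, stringsAsFactors = FALSE,
                            na.strings = "NA", quote = "",
                            colClasses = c(id = "character", reversible = "logical",
                                           lb = "numeric", ub = "numeric",
                                           provenance = "character", taxa = "character",
                                           ec_numbers = "character",
                                           stoichiometry = "character"))
  need_m <- c("id", "name", "inchi", "smiles", "formula", "charge", "compartment")
  need_r <- c("id", "reversible", "lb", "ub", "provenance", "taxa",
              "ec_numbers", "stoichiometry")
  if (!all(need_m %in% names(mets))) {
    pf_error(sprintf("%s: missing columns %s", p$metabolites,
                     paste(setdiff(need_m, names(mets)), collapse = ", ")),
             "parse_error")
  }
  if (!all(need_r %in% names(rxns))) {
    pf_error(sprintf("%s: missing columns %s", p$reactions,
                     paste(setdiff(need_r, names(rxns)), collapse = ", ")),
             "parse_error")
  }
  for (col in c("taxa", "ec_numbers", "stoichiometry")) {
    rxns[[col]][is.na(rxns[[col]])] <- ""
  }
  stoi_rows <- lapply(seq_len(nrow(rxns)), function(i) {
    enc <- rxns$stoichiometry[i]
    if (!nzchar(enc)) {
      pf_error(sprintf("%s, record %d (reaction '%s'): empty stoichiometry",
                       p$reactions, i, rxns$id[i]), "parse_error")
    }
    terms <- strsplit(enc, ";", fixed = TRUE)[[1]]
    kv <- strsplit(terms, "=", fixed = TRUE)
    bad <- which(vapply(kv, length, 0L) != 2)
    if (length(bad) > 0) {
      pf_error(sprintf("%s, record %d (reaction '%s'): malformed term '%s'",
                       p$reactions, i, rxns$id[i], terms[bad[1]]), "parse_error")
    }
    coefs <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
    if (anyNA(coefs)) {
      pf_error(sprintf("%s, record %d (reaction '%s'): non-numeric coefficient",
                       p$reactions, i, rxns$id[i]), "parse_error")
    }
    stoichiometry_table(rxns$id[i], vapply(kv, `[`, "", 1), coefs)
  })
  rxns$stoichiometry <- NULL
  metabolic_network(mets, rxns, do.call(rbind, stoi_rows))
}

#' @rdname write_network
#' @export
write_network_tsv <- function(net, path) {
  p <- tsv_paths(path)
  by_rxn <- split(net$stoichiometry, net$stoichiometry$reaction_id)
  enc <- vapply(net$reactions$id, function(rid) {
    s <- by_rxn[[rid]]
    o <- order(s$metabolite_id)
    paste(paste0(s$metabolite_id[o], "=", s$coefficient[o]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  rxns <- net$reactions
  rxns$stoichiometry <- enc
  utils::write.table(net$metabolites, p$metabolites, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  utils::write.table(rxns, p$reactions, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a species-to-phylum lookup table
#'
#' @param path TSV file with columns `species`, `phylum`.
#' @export
read_phylum_lookup <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("species", "phylum") %in% names(x))) {
    pf_error("phylum lookup needs columns species, phylum", "parse_error")
  }
  x
}
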