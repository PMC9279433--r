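## Minimal SBML Level 3 (core + fbc-style flux bounds) interchange.
##
## Covers the subset this package produces: compartments, species with
## chemical annotations stored as fbc attributes, reactions with
## speciesReference stoichiometries, and per-reaction flux bounds exposed as
## fbc:lowerFluxBound / fbc:upperFluxBound parameters.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(x) {
  ## SBML SIds cannot contain brackets or leading digits
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("x", x), x)
}

#' @rdname write_network
#' @export
write_network_sbml <- function(net, path) {
  ids <- sbml_id(net$metabolites$id)
  rids <- sbml_id(net$reactions$id)
  if (anyDuplicated(ids) || anyDuplicated(rids)) {
    pf_error("network ids collide after SBML identifier sanitization", "parse_error")
  }
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3", version = "1",
                            "xmlns:fbc" = FBC_NS, "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = "phenoflux_model")

  comps <- unique(net$metabolites$compartment)
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = sbml_id(cp), constant = "true")
  }

  ## flux-bound parameters (deduplicated by value)
  bounds <- sort(unique(c(net$reactions$lb, net$reactions$ub)))
  bnames <- stats::setNames(paste0("fb_", seq_along(bounds)), sprintf("%.15g", bounds))
  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(lp, "parameter", id = bnames[[i]],
                        value = sprintf("%.15g", bounds[i]), constant = "true")
  }

  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = ids[i], name = m$name,
                              compartment = sbml_id(m$compartment),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false",
                              "fbc:charge" = as.character(m$charge %||% 0L))
    if (!is.na(m$formula) && nzchar(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
    notes <- character(0)
    if (!is.na(m$inchi) && nzchar(m$inchi)) notes <- c(notes, paste0("INCHI: ", m$inchi))
    if (!is.na(m$smiles) && nzchar(m$smiles)) notes <- c(notes, paste0("SMILES: ", m$smiles))
    notes <- c(notes, paste0("ORIGINAL_ID: ", m$id))
    nn <- xml2::xml_add_child(sp, "notes")
    body <- xml2::xml_add_child(nn, "body", xmlns = "http://www.w3.org/1999/xhtml")
    for (line in notes) xml2::xml_add_child(body, "p", line)
  }

  by_rxn <- split(net$stoichiometry, net$stoichiometry$reaction_id)
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    rx <- xml2::xml_add_child(lr, "reaction", id = rids[i],
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false",
                              "fbc:lowerFluxBound" = bnames[[sprintf("%.15g", r$lb)]],
                              "fbc:upperFluxBound" = bnames[[sprintf("%.15g", r$ub)]])
    nn <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(nn, "body", xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("PROVENANCE: ", r$provenance))
    if (nzchar(r$taxa)) xml2::xml_add_child(body, "p", paste0("TAXA: ", r$taxa))
    if (nzchar(r$ec_numbers)) xml2::xml_add_child(body, "p", paste0("EC: ", r$ec_numbers))
    xml2::xml_add_child(body, "p", paste0("ORIGINAL_ID: ", r$id))
    s <- by_rxn[[r$id]]
    subs <- s[s$coefficient < 0, , drop = FALSE]
    prods <- s[s$coefficient > 0, , drop = FALSE]
    if (nrow(subs) > 0) {
      ln <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in seq_len(nrow(subs))) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = sbml_id(subs$metabolite_id[j]),
                            stoichiometry = sprintf("%.15g", -subs$coefficient[j]),
                            constant = "true")
      }
    }
    if (nrow(prods) > 0) {
      ln <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in seq_len(nrow(prods))) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = sbml_id(prods$metabolite_id[j]),
                            stoichiometry = sprintf("%.15g", prods$coefficient[j]),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

note_field <- function(node, key) {
  ps <- xml2::xml_find_all(node, ".//d1:p", ns = c(d1 = "http://www.w3.org/1999/xhtml"))
  txt <- xml2::xml_text(ps)
  hit <- grep(paste0("^", key, ": "), txt, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub(paste0("^", key, ": "), "", hit[1])
}

#' @rdname load_network
#' @export
read_network_sbml <- function(path) {
  if (!file.exists(path)) pf_error(sprintf("file not found: %s", path), "parse_error")
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) pf_error(sprintf("%s: %s", path,
                                                       conditionMessage(e)),
                                               "parse_error"))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp_nodes, function(nd) {
    orig <- note_field(nd, "ORIGINAL_ID") %||% xml2::xml_attr(nd, "id")
    data.frame(sbml_id = xml2::xml_attr(nd, "id"),
               id = orig,
               name = xml2::xml_attr(nd, "name") %||% orig,
               inchi = note_field(nd, "INCHI"),
               smiles = note_field(nd, "SMILES"),
               formula = xml2::xml_attr(nd, "chemicalFormula") %||% NA_character_,
               charge = as.integer(xml2::xml_attr(nd, "charge") %||% 0L),
               compartment = xml2::xml_attr(nd, "compartment"),
               stringsAsFactors = FALSE)
  }))
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_rows <- vector("list", length(rx_nodes))
  stoi_rows <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    nd <- rx_nodes[[i]]
    orig <- note_field(nd, "ORIGINAL_ID") %||% xml2::xml_attr(nd, "id")
    lb_ref <- xml2::xml_attr(nd, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(nd, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    rev_attr <- xml2::xml_attr(nd, "reversible")
    reversible <- if (!is.na(rev_attr)) identical(rev_attr, "true") else lb < 0
    rxn_rows[[i]] <- reaction_table(orig, reversible = reversible, lb = lb, ub = ub,
                                    provenance = note_field(nd, "PROVENANCE") %||% "annotated",
                                    taxa = note_field(nd, "TAXA") %||% "",
                                    ec_numbers = note_field(nd, "EC") %||% "")
    reacts <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)
    prods <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)
    sid <- c(xml2::xml_attr(reacts, "species"), xml2::xml_attr(prods, "species"))
    coef <- c(-as.numeric(xml2::xml_attr(reacts, "stoichiometry")),
              as.numeric(xml2::xml_attr(prods, "stoichiometry")))
    if (length(sid) == 0) {
      pf_error(sprintf("%s: reaction '%s' has empty stoichiometry", path, orig),
               "parse_error")
    }
    met_ids <- mets$id[match(sid, mets$sbml_id)]
    if (anyNA(met_ids)) {
      pf_error(sprintf("%s: reaction '%s' references undeclared species '%s'",
                       path, orig, sid[which(is.na(met_ids))[1]]),
               "validation_error")
    }
    stoi_rows[[i]] <- stoichiometry_table(orig, met_ids, coef)
  }
  mets$sbml_id <- NULL
  metabolic_network(mets, do.call(rbind, rxn_rows), do.call(rbind, stoi_rows))
}
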