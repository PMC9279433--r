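## Core data model: metabolites, stoichiometric reactions and networks.
##
## A `metabolic_network` holds three aligned tables: a metabolite table, a
## reaction table and a stoichiometry table in triplet form (reaction id,
## metabolite id, signed coefficient; negative = substrate).  The universal
## reaction database, the base reconstruction and every extended network are
## all instances of this one class.

PROVENANCE_LEVELS <- c("annotated", "predicted", "gapfilled", "exchange", "transport")

#' Construct a metabolite table
#'
#' @param id,name character vectors; `id` must be unique.
#' @param inchi,smiles optional structure identifiers (`NA` when unknown).
#' @param formula optional elemental formula strings (e.g. `"C6H12O6"`).
#' @param charge optional integer formal charges.
#' @param compartment compartment tag (`"c"`, `"e"`, `"lumen"`, ...).
#' @return data frame of class-free metabolite rows.
#' @export
metabolite_table <- function(id, name = id, inchi = NA_character_,
                             smiles = NA_character_, formula = NA_character_,
                             charge = 0L, compartment = "c") {
  n <- length(id)
  data.frame(id = as.character(id), name = rep_len(as.character(name), n),
             inchi = rep_len(as.character(inchi), n),
             smiles = rep_len(as.character(smiles), n),
             formula = rep_len(as.character(formula), n),
             charge = rep_len(as.integer(charge), n),
             compartment = rep_len(as.character(compartment), n),
             stringsAsFactors = FALSE)
}

#' Construct a reaction table
#'
#' Bounds default to the conventional caps `[0, 1000]` for irreversible and
#' `[-1000, 1000]` for reversible reactions (flux units on an arbitrary
#' mmol/gDW/h scale); reversibility and `lb < 0` are kept consistent.
#'
#' @param id reaction identifiers (unique).
#' @param reversible logical.
#' @param lb,ub flux bounds; derived from `reversible` when omitted.
#' @param provenance one of `"annotated"`, `"predicted"`, `"gapfilled"`,
#'   `"exchange"`, `"transport"`.
#' @param taxa,ec_numbers semicolon-separated set columns (may be `""`).
#' @export
reaction_table <- function(id, reversible = FALSE, lb = NULL, ub = NULL,
                           provenance = "annotated", taxa = "", ec_numbers = "") {
  n <- length(id)
  reversible <- rep_len(as.logical(reversible), n)
  if (is.null(lb)) lb <- ifelse(reversible, -1000, 0)
  if (is.null(ub)) ub <- rep_len(1000, n)
  data.frame(id = as.character(id), reversible = reversible,
             lb = as.numeric(rep_len(lb, n)), ub = as.numeric(rep_len(ub, n)),
             provenance = rep_len(as.character(provenance), n),
             taxa = rep_len(as.character(taxa), n),
             ec_numbers = rep_len(as.character(ec_numbers), n),
             stringsAsFactors = FALSE)
}

#' Construct a stoichiometry table (triplet form)
#' @param reaction_id,metabolite_id identifiers.
#' @param coefficient signed numeric coefficients (negative = substrate).
#' @export
stoichiometry_table <- function(reaction_id, metabolite_id, coefficient) {
  data.frame(reaction_id = as.character(reaction_id),
             metabolite_id = as.character(metabolite_id),
             coefficient = as.numeric(coefficient), stringsAsFactors = FALSE)
}

#' Assemble and validate a metabolic network
#'
#' @param metabolites data frame as from [metabolite_table()].
#' @param reactions data frame as from [reaction_table()].
#' @param stoichiometry data frame as from [stoichiometry_table()].
#' @param species_catalog character vector of species identifiers; defaults
#'   to the union of reaction taxa.
#' @param validate run full invariant validation (default `TRUE`).
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              species_catalog = NULL, validate = TRUE) {
  net <- structure(list(metabolites = as.data.frame(metabolites),
                        reactions = as.data.frame(reactions),
                        stoichiometry = as.data.frame(stoichiometry),
                        species_catalog = species_catalog %||% character(0)),
                   class = "metabolic_network")
  if (is.null(species_catalog)) {
    net$species_catalog <- sort(unique(unlist(lapply(net$reactions$taxa, split_set))))
  }
  if (validate) validate_network(net)
  net
}

#' Validate network invariants
#'
#' Checks id uniqueness, dangling stoichiometry references, non-empty
#' stoichiometries, bound ordering and the reversibility/bound consistency
#' (`reversible` iff `lb < 0`).
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly; signals a `validation_error` otherwise.
#' @export
validate_network <- function(net) {
  m <- net$metabolites; r <- net$reactions; s <- net$stoichiometry
  if (anyDuplicated(m$id)) {
    pf_error(sprintf("duplicate metabolite id: %s", m$id[duplicated(m$id)][1]),
             "validation_error")
  }
  if (anyDuplicated(r$id)) {
    pf_error(sprintf("duplicate reaction id: %s", r$id[duplicated(r$id)][1]),
             "validation_error")
  }
  dangling <- setdiff(s$metabolite_id, m$id)
  if (length(dangling) > 0) {
    pf_error(sprintf("reaction references undeclared metabolite: %s", dangling[1]),
             "validation_error", data = list(metabolites = dangling))
  }
  orphan <- setdiff(s$reaction_id, r$id)
  if (length(orphan) > 0) {
    pf_error(sprintf("stoichiometry references unknown reaction: %s", orphan[1]),
             "validation_error")
  }
  empty <- setdiff(r$id, s$reaction_id)
  if (length(empty) > 0) {
    pf_error(sprintf("reaction with empty stoichiometry: %s", empty[1]),
             "validation_error")
  }
  if (any(r$lb > r$ub)) {
    pf_error(sprintf("lb > ub for reaction %s", r$id[which(r$lb > r$ub)[1]]),
             "validation_error")
  }
  bad_rev <- r$reversible != (r$lb < 0)
  if (any(bad_rev)) {
    pf_error(sprintf("reversibility flag inconsistent with bounds for %s",
                     r$id[which(bad_rev)[1]]), "validation_error")
  }
  if (!all(r$provenance %in% PROVENANCE_LEVELS)) {
    pf_error("unknown provenance level", "validation_error")
  }
  bad_f <- !is.na(m$formula) & nzchar(m$formula) &
    vapply(m$formula, function(f) any(parse_formula(f) < 0), TRUE)
  if (any(bad_f)) pf_error("negative formula count", "validation_error")
  invisible(net)
}

#' Sparse stoichiometric matrix of a network
#'
#' @param net a `metabolic_network`.
#' @return a `dgCMatrix` with metabolites as rows and reactions as columns.
#' @export
stoich_matrix <- function(net) {
  mi <- match(net$stoichiometry$metabolite_id, net$metabolites$id)
  ri <- match(net$stoichiometry$reaction_id, net$reactions$id)
  Matrix::sparseMatrix(i = mi, j = ri, x = net$stoichiometry$coefficient,
                       dims = c(nrow(net$metabolites), nrow(net$reactions)),
                       dimnames = list(net$metabolites$id, net$reactions$id))
}

#' Restrict a network to a subset of reactions
#'
#' Metabolites are restricted to those used by the kept reactions.
#' @param net a `metabolic_network`.
#' @param reaction_ids ids to keep.
#' @param drop_metabolites drop now-unused metabolites (default `TRUE`).
#' @export
subset_network <- function(net, reaction_ids, drop_metabolites = TRUE) {
  r <- net$reactions[net$reactions$id %in% reaction_ids, , drop = FALSE]
  s <- net$stoichiometry[net$stoichiometry$reaction_id %in% reaction_ids, , drop = FALSE]
  m <- net$metabolites
  if (drop_metabolites) m <- m[m$id %in% s$metabolite_id, , drop = FALSE]
  rownames(r) <- rownames(s) <- rownames(m) <- NULL
  metabolic_network(m, r, s, species_catalog = net$species_catalog,
                    validate = FALSE)
}

#' Is a reaction an exchange reaction?
#'
#' Exchange reactions are single-metabolite boundary reactions.
#' @noRd
exchange_ids <- function(net) {
  tab <- table(net$stoichiometry$reaction_id)
  single <- names(tab)[tab == 1]
  union(net$reactions$id[net$reactions$provenance == "exchange"], single)
}

## ---- universal database filtering -----------------------------------------

#' Filter a universal database on taxonomy and structural coverage
#'
#' Keeps exactly the reactions with at least one taxon among `allowed_taxa`
#' and all of whose participating metabolites carry an InChI; metabolites
#' are restricted to those used by the surviving reactions.  Exchange and
#' transport reactions can be exempted from the taxon requirement.
#'
#' @param net a `metabolic_network`.
#' @param allowed_taxa non-empty character vector of species identifiers.
#' @param keep_boundary exempt exchange reactions from the taxon filter
#'   (default `FALSE`, the strict behaviour).
#' @return the filtered `metabolic_network` (possibly empty).
#' @export
filter_universal <- function(net, allowed_taxa, keep_boundary = FALSE) {
  if (length(allowed_taxa) == 0) {
    pf_error("allowed_taxa must be non-empty", "input_error")
  }
  has_taxon <- vapply(net$reactions$taxa,
                      function(t) length(intersect(split_set(t), allowed_taxa)) > 0,
                      TRUE, USE.NAMES = FALSE)
  if (keep_boundary) {
    has_taxon <- has_taxon | net$reactions$id %in% exchange_ids(net)
  }
  structured <- net$metabolites$id[!is.na(net$metabolites$inchi) &
                                     nzchar(net$metabolites$inchi)]
  by_rxn <- split(net$stoichiometry$metabolite_id, net$stoichiometry$reaction_id)
  all_structured <- vapply(net$reactions$id, function(rid) {
    all((by_rxn[[rid]] %||% character(0)) %in% structured)
  }, TRUE, USE.NAMES = FALSE)
  keep <- net$reactions$id[has_taxon & all_structured]
  out <- subset_network(net, keep)
  out$species_catalog <- intersect(net$species_catalog, allowed_taxa)
  out
}

## ---- merging ---------------------------------------------------------------

#' Canonical stoichiometry signature of a reaction over identity keys
#' @noRd
reaction_signature <- function(met_keys, coefs) {
  o <- order(met_keys)
  keys <- met_keys[o]; cf <- coefs[o]
  fwd <- paste(paste0(keys, ":", cf), collapse = "|")
  rev_ <- paste(paste0(keys, ":", -cf), collapse = "|")
  ## direction-agnostic canonical form: the lexicographically smaller of the
  ## two orientations, remembering whether we flipped
  if (fwd <= rev_) list(sig = fwd, flipped = FALSE) else list(sig = rev_, flipped = TRUE)
}

#' Merge two networks, deduplicating by structure
#'
#' Metabolites are identified across the inputs by canonical InChI (ids are
#' the fallback key for structure-less metabolites).  Reactions with
#' identical canonical stoichiometry over the merged metabolite identities
#' and compatible directionality are collapsed, unioning their taxa and EC
#' sets.  Metabolites sharing an InChI but disagreeing on the stored
#' elemental formula are recorded in the `"conflicts"` attribute (the
#' structure-derived entry wins).
#'
#' @param a,b `metabolic_network` objects.
#' @return merged `metabolic_network` with a `"conflicts"` attribute.
#' @export
merge_networks <- function(a, b) {
  met_key <- function(m) ifelse(!is.na(m$inchi) & nzchar(m$inchi), m$inchi, m$id)
  conflicts <- character(0)

  mets <- rbind(a$metabolites, b$metabolites)
  side <- rep(c("a", "b"), c(nrow(a$metabolites), nrow(b$metabolites)))
  keys <- met_key(mets)
  rep_idx <- match(keys, keys)           # first occurrence represents the group
  for (g in unique(rep_idx[duplicated(rep_idx)])) {
    grp <- which(rep_idx == g)
    f <- mets$formula[grp]
    f <- unique(f[!is.na(f) & nzchar(f)])
    if (length(f) > 1) {
      conflicts <- c(conflicts,
                     sprintf("metabolite '%s': conflicting formulas %s",
                             mets$id[g], paste(f, collapse = " vs ")))
    }
  }
  merged_mets <- mets[!duplicated(keys), , drop = FALSE]
  rownames(merged_mets) <- NULL
  ## per-side original id -> representative merged id
  id_map <- stats::setNames(mets$id[rep_idx], paste0(side, "|", mets$id))
  remap <- function(net, tag) {
    s <- net$stoichiometry
    s$metabolite_id <- unname(id_map[paste0(tag, "|", s$metabolite_id)])
    s
  }
  stoi <- rbind(remap(a, "a"), remap(b, "b"))
  rxns <- rbind(a$reactions, b$reactions)
  rxn_side <- rep(c("a", "b"), c(nrow(a$reactions), nrow(b$reactions)))
  rxn_key <- paste0(rxn_side, "#", rxns$id)
  stoi_key <- paste0(rep(c("a", "b"), c(nrow(a$stoichiometry), nrow(b$stoichiometry))),
                     "#", stoi$reaction_id)

  by_rxn <- split(seq_len(nrow(stoi)), stoi_key)
  sigs <- vapply(seq_len(nrow(rxns)), function(i) {
    rows <- by_rxn[[rxn_key[i]]]
    sg <- reaction_signature(stoi$metabolite_id[rows], stoi$coefficient[rows])
    dir_tag <- if (rxns$reversible[i]) "rev" else paste0("irr", sg$flipped)
    paste0(sg$sig, "#", dir_tag)
  }, character(1))

  groups <- split(seq_len(nrow(rxns)), sigs)
  reps <- sort(vapply(groups, min, integer(1)))   # keep input order
  out_rxns <- rxns[reps, , drop = FALSE]
  used_ids <- character(0)
  out_stoi_list <- vector("list", length(reps))
  for (k in seq_along(reps)) {
    i <- reps[k]
    grp <- groups[[match(sigs[i], names(groups))]]
    if (length(grp) > 1) {
      out_rxns$taxa[k] <- collapse_set(unlist(lapply(rxns$taxa[grp], split_set)))
      out_rxns$ec_numbers[k] <- collapse_set(unlist(lapply(rxns$ec_numbers[grp], split_set)))
    }
    if (out_rxns$id[k] %in% used_ids) {          # id collision across inputs
      out_rxns$id[k] <- paste0(out_rxns$id[k], "_", rxn_side[i])
    }
    used_ids <- c(used_ids, out_rxns$id[k])
    rows <- by_rxn[[rxn_key[i]]]
    out_stoi_list[[k]] <- data.frame(reaction_id = out_rxns$id[k],
                                     metabolite_id = stoi$metabolite_id[rows],
                                     coefficient = stoi$coefficient[rows],
                                     stringsAsFactors = FALSE)
  }
  out_stoi <- do.call(rbind, out_stoi_list)
  out_mets <- merged_mets[merged_mets$id %in% out_stoi$metabolite_id, , drop = FALSE]
  rownames(out_rxns) <- rownames(out_mets) <- NULL
  net <- metabolic_network(out_mets, out_rxns, out_stoi,
                           species_catalog = sort(union(a$species_catalog,
                                                        b$species_catalog)))
  attr(net, "conflicts") <- conflicts
  net
}

## ---- summaries -------------------------------------------------------------

#' Summarize a network
#'
#' @param net a `metabolic_network`.
#' @param phylum_lookup optional data frame with columns `species`, `phylum`;
#'   species missing from the lookup are counted under `"unclassified"`.
#' @return object of class `network_summary`: counts of metabolites and
#'   reactions, reactions by provenance, and (when a lookup is given)
#'   reactions by phylum.
#' @export
network_summary <- function(net, phylum_lookup = NULL) {
  prov <- table(factor(net$reactions$provenance, levels = PROVENANCE_LEVELS))
  by_phylum <- NULL
  if (!is.null(phylum_lookup)) {
    counts <- new.env(parent = emptyenv())
    for (t in net$reactions$taxa) {
      for (sp in split_set(t)) {
        ph <- phylum_lookup$phylum[match(sp, phylum_lookup$species)]
        if (is.na(ph)) ph <- "unclassified"
        assign(ph, (get0(ph, envir = counts) %||% 0L) + 1L, envir = counts)
      }
    }
    by_phylum <- sort(unlist(as.list(counts)), decreasing = TRUE)
    if (is.null(by_phylum)) by_phylum <- integer(0)
  }
  structure(list(n_metabolites = nrow(net$metabolites),
                 n_reactions = nrow(net$reactions),
                 by_provenance = stats::setNames(as.integer(prov), names(prov)),
                 by_phylum = by_phylum,
                 n_species = length(net$species_catalog)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Metabolic network: %d metabolites, %d reactions, %d species\n",
              x$n_metabolites, x$n_reactions, x$n_species))
  nz <- x$by_provenance[x$by_provenance > 0]
  if (length(nz)) cat("  provenance:", paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  if (length(x$by_phylum)) {
    cat("  reactions by phylum:",
        paste(names(x$by_phylum), x$by_phylum, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.metabolic_network <- function(x, ...) {
  print(network_summary(x))
  invisible(x)
}
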