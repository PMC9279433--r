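## End-to-end network-update pipeline: sequential gap-filling of predicted
## reactions into a base reconstruction, annotation pruning, consistency
## cleanup, single-species repair and version comparison reporting.

#' Merge predicted reactions into a universal network
#'
#' Fragment metabolites are identified against the universal network by
#' InChI: a fragment compound whose structure already exists is remapped to
#' the existing metabolite id, others are added.  Fragment reactions are
#' appended (ids already present are skipped).  For every newly added
#' compound a species transport and an extracellular exchange are created,
#' annotated to the taxa of the predicted reactions touching the compound,
#' so that predicted routes are reachable during gap-filling and community
#' assembly.
#'
#' @param net universal `metabolic_network`.
#' @param fragment list with `reactions`, `stoichiometry`, `metabolites`
#'   (e.g. from [pathway_reactions()]).
#' @param add_boundary add transport/exchange pairs for new compounds
#'   (default `TRUE`).
#' @return list with `network` (extended universal) and `reaction_ids` (the
#'   ids of the fragment reactions as integrated).
#' @export
add_predicted_reactions <- function(net, fragment, add_boundary = TRUE) {
  if (nrow(fragment$reactions) == 0) {
    return(list(network = net, reaction_ids = character(0)))
  }
  ## remap fragment metabolites onto existing structures
  map <- character(0)
  new_mets <- list()
  for (i in seq_len(nrow(fragment$metabolites))) {
    m <- fragment$metabolites[i, ]
    hit <- which(!is.na(net$metabolites$inchi) & net$metabolites$inchi == m$inchi &
                   net$metabolites$compartment == m$compartment)
    if (length(hit) > 0) {
      map[m$id] <- net$metabolites$id[hit[1]]
    } else {
      map[m$id] <- m$id
      new_mets[[m$id]] <- m
    }
  }
  stoi <- fragment$stoichiometry
  stoi$metabolite_id <- ifelse(stoi$metabolite_id %in% names(map),
                               unname(map[stoi$metabolite_id]),
                               stoi$metabolite_id)
  rxns <- fragment$reactions[!fragment$reactions$id %in% net$reactions$id, , drop = FALSE]
  stoi <- stoi[stoi$reaction_id %in% rxns$id, , drop = FALSE]

  net$metabolites <- rbind(net$metabolites, do.call(rbind, new_mets))
  net$reactions <- rbind(net$reactions, rxns)
  net$stoichiometry <- rbind(net$stoichiometry, stoi)

  if (add_boundary && length(new_mets) > 0) {
    for (mid in names(new_mets)) {
      rid_touch <- stoi$reaction_id[stoi$metabolite_id == mid]
      taxa <- sort(unique(unlist(lapply(
        rxns$taxa[rxns$id %in% rid_touch], split_set))))
      base <- strip_compartment(mid)
      emet <- paste0(base, "[e]")
      if (!emet %in% net$metabolites$id) {
        row <- new_mets[[mid]]
        row$id <- emet; row$compartment <- "e"
        net$metabolites <- rbind(net$metabolites, row)
      }
      for (sp in taxa) {
        tid <- paste0("T_", base, "_", sp)
        if (tid %in% net$reactions$id) next
        net$reactions <- rbind(net$reactions,
                               reaction_table(tid, reversible = TRUE,
                                              provenance = "transport", taxa = sp))
        net$stoichiometry <- rbind(net$stoichiometry,
                                   stoichiometry_table(c(tid, tid), c(mid, emet),
                                                       c(-1, 1)))
      }
      xid <- paste0("EX_", base)
      if (!xid %in% net$reactions$id) {
        net$reactions <- rbind(net$reactions,
                               reaction_table(xid, reversible = TRUE,
                                              provenance = "exchange"))
        net$stoichiometry <- rbind(net$stoichiometry,
                                   stoichiometry_table(xid, emet, -1))
      }
    }
  }
  rownames(net$metabolites) <- rownames(net$reactions) <-
    rownames(net$stoichiometry) <- NULL
  validate_network(net)
  list(network = net, reaction_ids = rxns$id)
}

#' Sequential weighted-FASTCORE gap-filling
#'
#' For each source compound (in sorted-id order for determinism) the core is
#' set to the base network's reactions plus that compound's predicted
#' reactions, and weighted FASTCORE selects a flux-consistent superset from
#' the universal network, penalizing reactions without taxonomic annotation.
#' Compounds whose core is infeasible are skipped and reported, not fatal.
#'
#' @param universal `metabolic_network` already containing the predicted
#'   reactions.
#' @param base `metabolic_network`; every base reaction must be in the
#'   universal network.
#' @param predictions named list: compound id -> character vector of
#'   predicted reaction ids (must exist in `universal`).
#' @param annotated_weight,unannotated_weight penalties for annotated and
#'   unannotated non-core reactions (defaults 1 and 100).
#' @param tol flux tolerance.
#' @return list with `network` (base plus all selections, as a subset of the
#'   universal network), `integrated` and `skipped` compound ids, and
#'   `selection` (per-compound added reaction ids).
#' @export
sequential_gapfill <- function(universal, base, predictions,
                               annotated_weight = 1, unannotated_weight = 100,
                               tol = 1e-6) {
  missing_rxns <- setdiff(base$reactions$id, universal$reactions$id)
  if (length(missing_rxns) > 0) {
    pf_error(sprintf("base reaction not in universal network: %s", missing_rxns[1]),
             "input_error")
  }
  if (length(predictions) == 0) {
    return(list(network = base, integrated = character(0),
                skipped = character(0), selection = list()))
  }
  p <- as_flux_problem(universal, tol = tol)
  w <- ifelse(nzchar(universal$reactions$taxa) |
                universal$reactions$provenance %in% c("exchange", "transport"),
              annotated_weight, unannotated_weight)
  names(w) <- universal$reactions$id

  compounds <- sort(names(predictions))
  selected <- character(0)
  integrated <- character(0); skipped <- character(0)
  selection <- list()
  for (cpd in compounds) {
    pred_rxns <- predictions[[cpd]]
    unknown <- setdiff(pred_rxns, universal$reactions$id)
    if (length(unknown) > 0) {
      pf_error(sprintf("predicted reaction '%s' for compound '%s' not in universal",
                       unknown[1], cpd), "input_error")
    }
    core <- union(base$reactions$id, pred_rxns)
    sel <- tryCatch(fastcore_weighted(p, core, weights = w),
                    core_infeasible_error = function(e) NULL)
    if (is.null(sel)) {
      skipped <- c(skipped, cpd)
      next
    }
    integrated <- c(integrated, cpd)
    selection[[cpd]] <- setdiff(sel, base$reactions$id)
    selected <- union(selected, sel)
  }
  keep <- union(base$reactions$id, selected)
  list(network = subset_network(universal, keep),
       integrated = integrated, skipped = skipped, selection = selection)
}

#' Remove unannotated reactions and restore flux consistency
#'
#' Drops non-exchange, non-transport reactions lacking taxonomic annotation,
#' then iteratively removes blocked reactions until a fixpoint; the result
#' is flux-consistent.
#'
#' @param net a `metabolic_network`.
#' @param tol flux tolerance.
#' @return pruned `metabolic_network`.
#' @export
prune_and_consistency <- function(net, tol = 1e-6) {
  boundary <- net$reactions$provenance %in% c("exchange", "transport")
  keep <- net$reactions$id[nzchar(net$reactions$taxa) | boundary]
  net <- subset_network(net, keep)
  repeat {
    if (nrow(net$reactions) == 0) break
    blocked <- blocked_reactions(as_flux_problem(net, tol = tol))
    if (length(blocked) == 0) break
    net <- subset_network(net, setdiff(net$reactions$id, blocked))
  }
  net
}

#' Induced single-species sub-network
#'
#' The reactions annotated to a species, plus exchange reactions touching
#' the metabolites those reactions use.
#' @noRd
species_subnetwork <- function(net, species) {
  has_sp <- vapply(net$reactions$taxa, function(t) species %in% split_set(t),
                   TRUE, USE.NAMES = FALSE)
  ids <- net$reactions$id[has_sp]
  mets <- unique(net$stoichiometry$metabolite_id[net$stoichiometry$reaction_id %in% ids])
  exch <- intersect(exchange_ids(net),
                    net$stoichiometry$reaction_id[net$stoichiometry$metabolite_id %in% mets])
  subset_network(net, union(ids, exch))
}

#' Dead-end metabolites of a network
#'
#' A metabolite is a dead end when, under the bounds, it can only be
#' produced or only be consumed (reversible reactions count on both sides).
#' @param net a `metabolic_network`.
#' @return character vector of metabolite ids.
#' @export
dead_end_metabolites <- function(net) {
  s <- net$stoichiometry
  rev <- net$reactions$reversible[match(s$reaction_id, net$reactions$id)]
  producible <- unique(s$metabolite_id[s$coefficient > 0 | rev])
  consumable <- unique(s$metabolite_id[s$coefficient < 0 | rev])
  setdiff(union(producible, consumable), intersect(producible, consumable))
}

#' Repair per-species dead ends using transport evidence
#'
#' For each species' induced sub-network, dead-end metabolites are detected;
#' where the (species, metabolite) pair appears in the evidence table, a
#' transport reaction to the extracellular space and an exchange reaction
#' are added (annotated to the species).  Dead-end-producing reactions
#' without evidence are stripped of that species' annotation, and reactions
#' left without any taxon are removed.  Whole-network consistency is then
#' re-verified.
#'
#' @param net a `metabolic_network`.
#' @param evidence data frame with columns `species`, `metabolite`.
#' @param tol flux tolerance.
#' @return repaired `metabolic_network`.
#' @export
single_species_repair <- function(net, evidence, tol = 1e-6) {
  stopifnot(all(c("species", "metabolite") %in% names(evidence)))
  for (sp in net$species_catalog) {
    sub <- species_subnetwork(net, sp)
    if (nrow(sub$reactions) == 0) next
    dead <- dead_end_metabolites(sub)
    for (met in dead) {
      has_evidence <- any(evidence$species == sp & evidence$metabolite == met)
      if (has_evidence) {
        base_id <- sub("\\[[^]]*\\]$", "", met)
        emet <- paste0(base_id, "[e]")
        if (!emet %in% net$metabolites$id) {
          row <- net$metabolites[net$metabolites$id == met, , drop = FALSE]
          row$id <- emet; row$compartment <- "e"
          net$metabolites <- rbind(net$metabolites, row)
        }
        tid <- paste0("T_", base_id, "_", sp)
        xid <- paste0("EX_", base_id)
        if (!tid %in% net$reactions$id) {
          net$reactions <- rbind(net$reactions,
                                 reaction_table(tid, reversible = TRUE,
                                                provenance = "transport", taxa = sp))
          net$stoichiometry <- rbind(net$stoichiometry,
                                     stoichiometry_table(c(tid, tid), c(met, emet),
                                                         c(-1, 1)))
        }
        if (!xid %in% net$reactions$id) {
          net$reactions <- rbind(net$reactions,
                                 reaction_table(xid, reversible = TRUE,
                                                provenance = "exchange"))
          net$stoichiometry <- rbind(net$stoichiometry,
                                     stoichiometry_table(xid, emet, -1))
        }
      } else {
        ## remove this species' annotation from the reactions stranded on the
        ## dead end; drop reactions left unannotated
        touching <- unique(sub$stoichiometry$reaction_id[
          sub$stoichiometry$metabolite_id == met])
        for (rid in touching) {
          k <- match(rid, net$reactions$id)
          if (is.na(k) || net$reactions$provenance[k] %in% c("exchange", "transport")) next
          taxa <- setdiff(split_set(net$reactions$taxa[k]), sp)
          net$reactions$taxa[k] <- collapse_set(taxa)
        }
      }
    }
  }
  rownames(net$reactions) <- rownames(net$stoichiometry) <- rownames(net$metabolites) <- NULL
  drop <- net$reactions$id[!nzchar(net$reactions$taxa) &
                             !net$reactions$provenance %in% c("exchange", "transport")]
  net <- subset_network(net, setdiff(net$reactions$id, drop))
  prune_and_consistency(net, tol = tol)
}

#' Coverage and version-difference report
#'
#' Compares two network versions: added metabolites and reactions,
#' per-sub-class compound coverage with the percentage-point difference
#' (rounded to the nearest integer percent), and per-phylum counts for the
#' added reactions.
#'
#' @param net_old,net_new `metabolic_network` versions.
#' @param compound_classes data frame with columns `compound`, `subclass`,
#'   `catalogue_size` (reference catalogue size per sub-class).  Compounds
#'   missing a class are counted under `"unclassified"`.
#' @param phylum_lookup optional species-to-phylum data frame.
#' @return list of class `coverage_report` with `added_metabolites`,
#'   `added_reactions`, `coverage` (per-sub-class data frame with columns
#'   `subclass`, `catalogue_size`, `covered_old`, `covered_new`,
#'   `coverage_diff_pct`) and `phylum_additions`.
#' @export
coverage_and_diff_report <- function(net_old, net_new, compound_classes,
                                     phylum_lookup = NULL) {
  stopifnot(all(c("compound", "subclass", "catalogue_size") %in%
                  names(compound_classes)))
  added_mets <- setdiff(net_new$metabolites$id, net_old$metabolites$id)
  added_rxns <- setdiff(net_new$reactions$id, net_old$reactions$id)

  cls <- compound_classes
  cls$subclass[is.na(cls$subclass) | !nzchar(cls$subclass)] <- "unclassified"
  subclasses <- unique(cls$subclass)
  cov <- do.call(rbind, lapply(subclasses, function(sc) {
    cpds <- cls$compound[cls$subclass == sc]
    size <- cls$catalogue_size[cls$subclass == sc][1]
    old_n <- sum(cpds %in% net_old$metabolites$id)
    new_n <- sum(cpds %in% net_new$metabolites$id)
    data.frame(subclass = sc, catalogue_size = size,
               covered_old = old_n, covered_new = new_n,
               coverage_diff_pct = round(100 * new_n / size - 100 * old_n / size),
               stringsAsFactors = FALSE)
  }))

  phylum_additions <- NULL
  if (!is.null(phylum_lookup) && length(added_rxns) > 0) {
    added_net <- subset_network(net_new, added_rxns)
    phylum_additions <- network_summary(added_net, phylum_lookup)$by_phylum
  }
  structure(list(added_metabolites = added_mets, added_reactions = added_rxns,
                 coverage = cov, phylum_additions = phylum_additions),
            class = "coverage_report")
}

#' Coverage difference from printed catalogue counts
#'
#' Convenience form of the coverage computation when only the covered counts
#' are known: the percentage-point difference between `new_count/size` and
#' `old_count/size`, rounded to the nearest integer percent.
#'
#' @param old_count,new_count covered compounds per version.
#' @param size sub-class catalogue size.
#' @return integer percentage-point difference.
#' @export
coverage_diff_pct <- function(old_count, new_count, size) {
  round(100 * new_count / size - 100 * old_count / size)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Version diff: +%d metabolites, +%d reactions\n",
              length(x$added_metabolites), length(x$added_reactions)))
  print(x$coverage, row.names = FALSE)
  if (!is.null(x$phylum_additions) && length(x$phylum_additions)) {
    cat("added reactions by phylum:",
        paste(names(x$phylum_additions), x$phylum_additions, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}
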