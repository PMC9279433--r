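## Compartmentalized multi-species community models and FVA-based
## output-metabolite prediction.
##
## Each species occupies its own compartment; extracellular metabolites are
## pooled in a shared lumen through which species exchange metabolites, and
## lumen exchange reactions carry dietary uptake (negative flux) and
## microbial secretion (positive flux).

strip_compartment <- function(id) sub("\\[[^]]*\\]$", "", id)

#' Build a compartmentalized community model
#'
#' Every reaction annotated to a species is replicated into that species'
#' compartment; metabolites tagged extracellular in the single-species
#' models map to the shared lumen, so transport reactions become the
#' species-to-lumen links.  One exchange reaction per lumen metabolite is
#' created.  Species without any annotated reaction are dropped with a
#' warning.
#'
#' @param net a `metabolic_network` (single-species style, compartments
#'   `"c"`/`"e"`).
#' @param species character vector of species ids forming the community.
#' @return object of class `community_model` wrapping the expanded network.
#' @export
build_community <- function(net, species) {
  if (length(species) == 0) pf_error("empty species set: no community", "input_error")
  has_rxn <- vapply(species, function(sp) {
    any(vapply(net$reactions$taxa, function(t) sp %in% split_set(t), TRUE))
  }, TRUE)
  if (any(!has_rxn)) {
    warning("dropping species without annotated reactions: ",
            paste(species[!has_rxn], collapse = ", "))
    species <- species[has_rxn]
  }
  if (length(species) == 0) pf_error("no species with reactions", "input_error")

  exch <- exchange_ids(net)
  met_rows <- list(); rxn_rows <- list(); stoi_rows <- list()
  seen_mets <- character(0)

  tag_met <- function(mid, sp) {
    base <- strip_compartment(mid)
    comp <- net$metabolites$compartment[match(mid, net$metabolites$id)]
    if (comp %in% c("e", "lumen")) {
      list(id = paste0(base, "[lumen]"), comp = "lumen")
    } else {
      list(id = paste0(base, "[", sp, "]"), comp = sp)
    }
  }
  add_met <- function(new_id, old_id, comp) {
    if (new_id %in% seen_mets) return(invisible())
    seen_mets <<- c(seen_mets, new_id)
    row <- net$metabolites[match(old_id, net$metabolites$id), , drop = FALSE]
    row$id <- new_id; row$compartment <- comp
    met_rows[[length(met_rows) + 1]] <<- row
  }

  for (sp in species) {
    rids <- net$reactions$id[vapply(net$reactions$taxa,
                                    function(t) sp %in% split_set(t), TRUE)]
    rids <- setdiff(rids, exch)
    for (rid in rids) {
      k <- match(rid, net$reactions$id)
      s <- net$stoichiometry[net$stoichiometry$reaction_id == rid, , drop = FALSE]
      new_rid <- paste0(rid, "[", sp, "]")
      r <- net$reactions[k, , drop = FALSE]
      r$id <- new_rid; r$taxa <- sp
      rxn_rows[[length(rxn_rows) + 1]] <- r
      for (j in seq_len(nrow(s))) {
        tm <- tag_met(s$metabolite_id[j], sp)
        add_met(tm$id, s$metabolite_id[j], tm$comp)
        stoi_rows[[length(stoi_rows) + 1]] <-
          stoichiometry_table(new_rid, tm$id, s$coefficient[j])
      }
    }
  }
  ## lumen exchanges: one per lumen metabolite
  lumen_mets <- unique(unlist(lapply(met_rows, function(m)
    if (m$compartment == "lumen") m$id else NULL)))
  for (lm in sort(lumen_mets)) {
    xid <- paste0("EX_", strip_compartment(lm), "[lumen]")
    rxn_rows[[length(rxn_rows) + 1]] <-
      reaction_table(xid, reversible = TRUE, provenance = "exchange")
    stoi_rows[[length(stoi_rows) + 1]] <- stoichiometry_table(xid, lm, -1)
  }
  cm_net <- metabolic_network(do.call(rbind, met_rows),
                              do.call(rbind, rxn_rows),
                              do.call(rbind, stoi_rows),
                              species_catalog = sort(species))
  structure(list(network = cm_net, species = sort(species), lumen = "lumen"),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("Community model: %d species + shared lumen\n", length(x$species)))
  print(x$network)
  invisible(x)
}

#' A dietary/microbial context
#'
#' @param input_compounds metabolite ids supplied by the food (compartment
#'   suffixes are ignored when matching lumen exchanges).
#' @param present_species species ids present in the sample.
#' @param sample_id,food_id optional labels.
#' @export
community_context <- function(input_compounds, present_species,
                              sample_id = NA_character_, food_id = NA_character_) {
  structure(list(input_compounds = unique(as.character(input_compounds)),
                 present_species = unique(as.character(present_species)),
                 sample_id = sample_id, food_id = food_id),
            class = "community_context")
}

#' Contextualize a community model into a flux problem
#'
#' Uptake (negative exchange flux) is opened only for the context's input
#' compounds; all other uptakes are closed.  Secretion (positive exchange
#' flux) stays open for every exchange.  All reactions of absent species are
#' closed to `[0, 0]`.  Unknown compound or species ids are recorded as
#' warnings in the `"context_warnings"` attribute and ignored.
#'
#' @param cm a `community_model`.
#' @param ctx a [community_context()].
#' @param tol flux tolerance.
#' @return a `flux_problem` over the community network.
#' @export
contextualize <- function(cm, ctx, tol = 1e-6) {
  net <- cm$network
  p <- as_flux_problem(net, tol = tol)
  warnings <- character(0)

  exch <- exchange_ids(net)
  is_exch <- p$reaction_ids %in% exch
  ## close every uptake, keep secretion open
  p$lb[is_exch] <- 0
  p$ub[is_exch] <- 1000

  wanted <- strip_compartment(ctx$input_compounds)
  lumen_of <- strip_compartment(sub("^EX_", "", p$reaction_ids))
  known <- wanted %in% lumen_of[is_exch]
  if (any(!known)) {
    warnings <- c(warnings, sprintf("unknown input compound: %s",
                                    wanted[!known]))
  }
  open <- is_exch & lumen_of %in% wanted
  p$lb[open] <- -1000

  unknown_sp <- setdiff(ctx$present_species, cm$species)
  if (length(unknown_sp) > 0) {
    warnings <- c(warnings, sprintf("unknown species: %s", unknown_sp))
  }
  absent <- setdiff(cm$species, ctx$present_species)
  rxn_sp <- net$reactions$taxa[match(p$reaction_ids, net$reactions$id)]
  closed <- rxn_sp %in% absent & nzchar(rxn_sp)
  p$lb[closed] <- 0
  p$ub[closed] <- 0
  attr(p, "context_warnings") <- warnings
  attr(p, "exchange_ids") <- p$reaction_ids[is_exch]
  p
}

#' Predict output microbial metabolites
#'
#' An output metabolite is one whose lumen exchange can carry strictly
#' positive secretion flux: the FVA maximum of its exchange exceeds the
#' tolerance.  Input compounds may appear when they are re-secretable.
#'
#' @param p contextualized `flux_problem` (from [contextualize()]).
#' @param eps secretion threshold (defaults to the problem tolerance).
#' @return character vector of output metabolite ids (lumen names without
#'   compartment suffix).
#' @export
predict_outputs <- function(p, eps = NULL) {
  eps <- eps %||% p$tol
  exch <- attr(p, "exchange_ids") %||% p$reaction_ids[grepl("^EX_", p$reaction_ids)]
  v <- fva(p, exch)
  out <- v$reaction_id[v$max > eps]
  sort(strip_compartment(sub("^EX_", "", out)))
}

#' Compare output predictions of two network versions
#'
#' For each context, predicts output metabolites under both versions and
#' counts the outputs gained by the new version.  When the old network's
#' reactions are a subset of the new one's, the old outputs are asserted to
#' be a subset of the new outputs (flux-polytope monotonicity).
#'
#' @param net_old,net_new `metabolic_network` versions sharing a species
#'   catalogue.
#' @param contexts list of [community_context()] objects.
#' @param eps secretion threshold.
#' @return object of class `output_comparison`: per-context data frame plus
#'   summary statistics (mean/min/max of new-output counts).
#' @export
compare_outputs <- function(net_old, net_new, contexts, eps = 1e-6) {
  nested <- all(net_old$reactions$id %in% net_new$reactions$id)
  rows <- vector("list", length(contexts))
  details <- vector("list", length(contexts))
  for (i in seq_along(contexts)) {
    ctx <- contexts[[i]]
    cm_old <- build_community(net_old, ctx$present_species)
    cm_new <- build_community(net_new, ctx$present_species)
    out_old <- predict_outputs(contextualize(cm_old, ctx), eps = eps)
    out_new <- predict_outputs(contextualize(cm_new, ctx), eps = eps)
    if (nested && !all(out_old %in% out_new)) {
      pf_error(sprintf(
        "monotonicity violation in context %d: old outputs not a subset", i),
        "internal_error")
    }
    gained <- setdiff(out_new, out_old)
    rows[[i]] <- data.frame(context = i,
                            sample_id = ctx$sample_id %||% NA_character_,
                            food_id = ctx$food_id %||% NA_character_,
                            n_old = length(out_old), n_new = length(out_new),
                            n_gained = length(gained), stringsAsFactors = FALSE)
    details[[i]] <- list(outputs_old = out_old, outputs_new = out_new,
                         gained = gained)
  }
  per_context <- do.call(rbind, rows)
  structure(list(per_context = per_context, details = details,
                 summary = c(mean = mean(per_context$n_gained),
                             min = min(per_context$n_gained),
                             max = max(per_context$n_gained))),
            class = "output_comparison")
}

#' @export
print.output_comparison <- function(x, ...) {
  cat(sprintf("Output comparison over %d contexts: mean %.1f new outputs (min %d, max %d)\n",
              nrow(x$per_context), x$summary[["mean"]],
              x$summary[["min"]], x$summary[["max"]]))
  invisible(x)
}
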