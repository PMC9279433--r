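## Guided biosensor-mode search over the extended metabolic space.
##
## The search expands compounds with the admitted reaction rules, scoring
## each transformation by the product of its rule's biological score and the
## fingerprint similarity between query and template substrate, and explores
## nodes best-first until every frontier compound is a sink, the iteration
## cap is reached, or the time budget expires.  Monte Carlo components of
## the original retrosynthesis tool are replaced by this deterministic
## best-first policy; the contract (sources, sinks, rules, cutoffs, scope
## output) is unchanged.

#' Search parameters
#'
#' @param diameters admitted rule diameters (even integers, default 6-16).
#' @param bio_cutoff biological score cutoff (inclusive, default 0.1).
#' @param chem_cutoff chemical similarity cutoff (inclusive, default 0.6).
#' @param itermax maximum node expansions (default 1000).
#' @param time_budget wall-clock budget in seconds (default 28800).
#' @param max_depth maximum transformations along any path (default 6).
#' @param seed integer seed (the default policy is deterministic; the seed
#'   fixes tie-breaks should a stochastic policy be plugged in).
#' @return list of class `search_params`.
#' @export
search_params <- function(diameters = seq(6L, 16L, 2L), bio_cutoff = 0.1,
                          chem_cutoff = 0.6, itermax = 1000L,
                          time_budget = 28800, max_depth = 6L, seed = 1L) {
  stopifnot(bio_cutoff >= 0, bio_cutoff <= 1, chem_cutoff >= 0, chem_cutoff <= 1,
            itermax >= 0)
  structure(list(diameters = as.integer(diameters), bio_cutoff = bio_cutoff,
                 chem_cutoff = chem_cutoff, itermax = as.integer(itermax),
                 time_budget = time_budget, max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "search_params")
}

#' Expand a compound with all admitted rules
#'
#' Applies every rule whose diameter is admitted and whose biological score
#' passes the cutoff, computes chemical scores against template substrates,
#' filters with [score_match()], deduplicates by (template reaction, product
#' InChI set) keeping the highest diameter, and orders the result by
#' descending combined score with rule id as tie-break.
#'
#' @param node structure row (`inchi`, `smiles`).
#' @param rules rule table.
#' @param params a [search_params()].
#' @param structures structure lookup resolving template substrates.
#' @return list of scored transformations.
#' @export
expand_node <- function(node, rules, params, structures) {
  if (nrow(rules) == 0) return(list())
  rules <- rules[rules$diameter %in% params$diameters &
                   rules$biological_score >= params$bio_cutoff, , drop = FALSE]
  if (nrow(rules) == 0) return(list())
  node_str <- node$smiles %||% node$inchi
  tmpl_idx <- match(rules$template_substrate_id, structures$id)
  if (anyNA(tmpl_idx)) {
    pf_error(sprintf("template substrate '%s' not in structure lookup",
                     rules$template_substrate_id[which(is.na(tmpl_idx))[1]]),
             "input_error")
  }
  tmpl_str <- ifelse(!is.na(structures$smiles[tmpl_idx]),
                     structures$smiles[tmpl_idx], structures$inchi[tmpl_idx])
  chem <- tanimoto_similarity(rep(node_str, nrow(rules)), tmpl_str)
  ok <- chem >= params$chem_cutoff
  rules <- rules[ok, , drop = FALSE]
  chem <- chem[ok]
  if (nrow(rules) == 0) return(list())

  tasks <- lapply(seq_len(nrow(rules)), function(i) {
    list(rule_id = rules$rule_id[i], smarts = rules$smarts[i],
         substrate = node_str)
  })
  applied <- chem_apply_smarts(tasks)
  out <- list()
  for (i in seq_len(nrow(rules))) {
    res <- applied[[i]]
    if (!is.null(res$error)) {
      pf_error(sprintf("rule '%s': %s", rules$rule_id[i], res$error), "rule_error")
    }
    for (ps in res$product_sets) {
      prods <- do.call(rbind, lapply(ps, function(d) {
        data.frame(inchi = d$inchi, smiles = d$smiles,
                   formula = format_formula(unlist(d$formula)),
                   charge = as.integer(d$charge), stringsAsFactors = FALSE)
      }))
      out[[length(out) + 1]] <- list(
        rule_id = rules$rule_id[i],
        diameter = rules$diameter[i],
        template_reaction_id = rules$template_reaction_id[i],
        substrate_inchi = node$inchi,
        substrate_smiles = node$smiles,
        substrate_formula = node$formula %||% NA_character_,
        substrate_charge = node$charge %||% 0L,
        products = prods,
        chemical_score = chem[i],
        biological_score = rules$biological_score[i],
        combined_score = chem[i] * rules$biological_score[i])
    }
  }
  if (length(out) == 0) return(out)
  ## dedupe by (template, product InChI set): keep highest diameter
  key <- vapply(out, function(t) paste(t$template_reaction_id,
                                       paste(sort(t$products$inchi), collapse = "|")),
                character(1))
  ord <- order(vapply(out, function(t) -t$diameter, numeric(1)))
  keep <- ord[!duplicated(key[ord])]
  out <- out[sort(keep)]
  ## deterministic order: descending combined score, then rule id
  out[order(-vapply(out, `[[`, numeric(1), "combined_score"),
            vapply(out, `[[`, character(1), "rule_id"))]
}

#' Biosensor-mode search from a source compound to sink metabolites
#'
#' Iterative best-first expansion of unexplored non-sink compounds, with
#' node priority equal to the combined (chemical x biological) score of the
#' transformation that produced the compound (ties broken by insertion
#' order).  A compound in the sink set is never expanded.  The search halts
#' at `itermax` expansions, when the time budget expires, or when the
#' frontier is exhausted, and returns the full scope.
#'
#' @param source structure row (`id`, `inchi`, `smiles`) of the source
#'   compound; an `input_error` is raised when it has no structure.
#' @param sinks character vector of sink InChI strings (metabolites of the
#'   known network).
#' @param rules rule table.
#' @param params a [search_params()].
#' @param structures structure lookup for template substrates.
#' @param net universal `metabolic_network` holding the template reactions
#'   (used to complete and balance accepted transformations).
#' @return object of class `retro_scope` with `nodes`, `edges`, completed
#'   `reaction_parts` and bookkeeping fields.
#' @export
search_biosensor <- function(source, sinks, rules, params, structures, net) {
  if (is.null(source$inchi) || is.na(source$inchi)) {
    pf_error(sprintf("source '%s' has no structure", source$id %||% "?"),
             "input_error")
  }
  if (length(sinks) == 0) pf_error("sink set is empty", "input_error")
  t0 <- Sys.time()

  nodes <- data.frame(key = source$inchi, id = source$id %||% "source",
                      smiles = source$smiles %||% NA_character_,
                      formula = source$formula %||% NA_character_,
                      charge = source$charge %||% 0L,
                      depth = 0L, is_sink = source$inchi %in% sinks,
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = character(0), substrate_key = character(0),
                      rule_id = character(0), template_reaction_id = character(0),
                      product_keys = character(0), chemical_score = numeric(0),
                      biological_score = numeric(0), combined_score = numeric(0),
                      reaction_id = character(0), balanced = logical(0),
                      stringsAsFactors = FALSE)
  scope <- structure(list(source_key = source$inchi, source_id = source$id %||% "source",
                          params = params, nodes = nodes, edges = edges,
                          reaction_parts = list(), iterations = 0L,
                          trivial = nodes$is_sink[1], discarded_unbalanced = 0L),
                     class = "retro_scope")
  if (scope$trivial || params$itermax == 0L) return(scope)

  frontier <- data.frame(key = source$inchi, priority = Inf, order = 0L,
                         depth = 0L, stringsAsFactors = FALSE)
  expanded <- character(0)
  iter <- 0L; edge_n <- 0L; insert_n <- 0L

  while (nrow(frontier) > 0 && iter < params$itermax &&
         as.numeric(difftime(Sys.time(), t0, units = "secs")) < params$time_budget) {
    o <- order(-frontier$priority, frontier$order)
    cur <- frontier[o[1], ]
    frontier <- frontier[-o[1], , drop = FALSE]
    if (cur$key %in% expanded) next
    expanded <- c(expanded, cur$key)
    iter <- iter + 1L
    nrow_ <- scope$nodes[match(cur$key, scope$nodes$key), ]
    node <- list(id = nrow_$id, inchi = nrow_$key, smiles = nrow_$smiles,
                 formula = nrow_$formula, charge = nrow_$charge)
    trans <- expand_node(node, rules, params, structures)
    for (t in trans) {
      edge_n <- edge_n + 1L
      eid <- sprintf("T%04d", edge_n)
      rid <- sprintf("%s_pred_%s", scope$source_id, eid)
      part <- tryCatch(
        complete_and_balance(t, t$template_reaction_id, net,
                             rule = list(rule_id = t$rule_id,
                                         smarts = rules$smarts[match(t$rule_id, rules$rule_id)],
                                         template_substrate_id =
                                           rules$template_substrate_id[match(t$rule_id, rules$rule_id)],
                                         taxa = rules$taxa[match(t$rule_id, rules$rule_id)]),
                             reaction_id = rid),
        phenoflux_error = function(e) {
          if (inherits(e, "balance_error")) NULL else stop(e)
        })
      if (is.null(part)) {
        scope$discarded_unbalanced <- scope$discarded_unbalanced + 1L
        next
      }
      scope$edges[nrow(scope$edges) + 1L, ] <-
        list(eid, cur$key, t$rule_id, t$template_reaction_id,
             paste(t$products$inchi, collapse = ";"), t$chemical_score,
             t$biological_score, t$combined_score, rid, TRUE)
      scope$reaction_parts[[eid]] <- part
      for (j in seq_len(nrow(t$products))) {
        pk <- t$products$inchi[j]
        if (!pk %in% scope$nodes$key) {
          scope$nodes[nrow(scope$nodes) + 1L, ] <-
            list(pk, inchi_met_id(pk), t$products$smiles[j],
                 t$products$formula[j], t$products$charge[j],
                 cur$depth + 1L, pk %in% sinks)
        }
        if (!pk %in% sinks && !pk %in% expanded && cur$depth + 1L < params$max_depth) {
          insert_n <- insert_n + 1L
          frontier[nrow(frontier) + 1L, ] <-
            list(pk, t$combined_score, insert_n, cur$depth + 1L)
        }
      }
    }
  }
  scope$iterations <- iter
  scope
}

#' Extract sink-connected pathways from a scope
#'
#' A pathway is an ordered chain of predicted reactions from the source
#' toward terminal metabolites; it is *connected* when every terminal
#' metabolite lies in the sink set.  Chains ending in a compound with no
#' outgoing transformation that is not a sink are counted as disconnected
#' (reported via the `"disconnected"` attribute, not returned).
#'
#' @param scope a `retro_scope`.
#' @param sinks character vector of sink InChI strings.
#' @param max_pathways enumeration cap (default 1000).
#' @return list of pathways, each a list with `edge_ids`, `reaction_ids` and
#'   `terminal_keys`; attribute `"disconnected"` holds the count of
#'   dangling chains.
#' @export
extract_connected_pathways <- function(scope, sinks, max_pathways = 1000L) {
  if (scope$trivial) {
    out <- list()
    attr(out, "disconnected") <- 0L
    attr(out, "trivially_connected") <- TRUE
    return(out)
  }
  edges_by_sub <- split(seq_len(nrow(scope$edges)), scope$edges$substrate_key)
  disconnected <- 0L
  pathways <- list()

  ## expand(u): list of sub-trees rooted at u, each = list(edge_rows, terminals, ok)
  expand_compound <- function(key, visited) {
    if (key %in% sinks) {
      return(list(list(edges = integer(0), terminals = key, ok = TRUE)))
    }
    rows <- edges_by_sub[[key]]
    rows <- rows[!is.na(rows)]
    if (is.null(rows) || length(rows) == 0 || key %in% visited) {
      return(list(list(edges = integer(0), terminals = key, ok = FALSE)))
    }
    out <- list()
    for (r in rows) {
      prods <- split_set(scope$edges$product_keys[r])
      branches <- lapply(prods, expand_compound, visited = c(visited, key))
      ## cartesian combination over product branches (bounded)
      combos <- list(list(edges = r, terminals = character(0), ok = TRUE))
      for (br in branches) {
        new_combos <- list()
        for (cmb in combos) {
          for (alt in br) {
            new_combos[[length(new_combos) + 1]] <-
              list(edges = c(cmb$edges, alt$edges),
                   terminals = c(cmb$terminals, alt$terminals),
                   ok = cmb$ok && alt$ok)
            if (length(new_combos) >= max_pathways) break
          }
          if (length(new_combos) >= max_pathways) break
        }
        combos <- new_combos
      }
      out <- c(out, combos)
      if (length(out) >= max_pathways) break
    }
    out
  }

  trees <- expand_compound(scope$source_key, character(0))
  for (tr in trees) {
    if (length(tr$edges) == 0) next
    if (tr$ok) {
      pathways[[length(pathways) + 1]] <-
        list(edge_ids = scope$edges$id[tr$edges],
             reaction_ids = scope$edges$reaction_id[tr$edges],
             terminal_keys = unique(tr$terminals))
    } else {
      disconnected <- disconnected + 1L
    }
  }
  attr(pathways, "disconnected") <- disconnected
  attr(pathways, "trivially_connected") <- FALSE
  pathways
}

#' Collect the predicted network fragment of connected pathways
#'
#' Gathers the completed, balanced reactions of the given pathways (deduped)
#' together with their new metabolites, ready for merging into a universal
#' network.
#'
#' @param scope a `retro_scope`.
#' @param pathways result of [extract_connected_pathways()].
#' @return list with `reactions`, `stoichiometry`, `metabolites` data frames
#'   (possibly empty).
#' @export
pathway_reactions <- function(scope, pathways) {
  eids <- unique(unlist(lapply(pathways, `[[`, "edge_ids")))
  parts <- scope$reaction_parts[eids]
  if (length(parts) == 0) {
    return(list(reactions = reaction_table(character(0)),
                stoichiometry = stoichiometry_table(character(0), character(0), numeric(0)),
                metabolites = metabolite_table(character(0))))
  }
  rxns <- do.call(rbind, lapply(parts, `[[`, "reactions"))
  stoi <- do.call(rbind, lapply(parts, `[[`, "stoichiometry"))
  mets <- do.call(rbind, lapply(parts, `[[`, "metabolites"))
  rownames(rxns) <- rownames(stoi) <- rownames(mets) <- NULL
  list(reactions = rxns[!duplicated(rxns$id), , drop = FALSE],
       stoichiometry = stoi[!duplicated(paste(stoi$reaction_id, stoi$metabolite_id)), , drop = FALSE],
       metabolites = mets[!duplicated(mets$id), , drop = FALSE])
}
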