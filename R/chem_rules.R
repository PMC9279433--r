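## Reaction rules: SMARTS transformations derived from annotated template
## reactions, applied to novel substrates under enzyme-promiscuity
## assumptions, scored, and completed into atomically balanced reactions.

#' Read a reaction-rule table
#'
#' @param path TSV with columns `rule_id`, `smarts`, `diameter`,
#'   `biological_score`, `template_reaction_id`, `taxa` and optionally
#'   `template_substrate_id`.
#' @return data frame of rules (one row per rule).
#' @export
read_rule_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("rule_id", "smarts", "diameter", "biological_score",
            "template_reaction_id", "taxa")
  if (!all(need %in% names(x))) {
    pf_error(sprintf("rule table missing columns: %s",
                     paste(setdiff(need, names(x)), collapse = ", ")),
             "parse_error")
  }
  if (!"template_substrate_id" %in% names(x)) x$template_substrate_id <- NA_character_
  x$taxa[is.na(x$taxa)] <- ""
  validate_rules(x)
  x
}

#' Validate rule-table invariants
#'
#' Rules admitted to search must have an even diameter in `[6, 16]` and a
#' biological score in `[0, 1]`.
#' @param rules rule data frame.
#' @export
validate_rules <- function(rules) {
  if (any(rules$biological_score < 0 | rules$biological_score > 1)) {
    pf_error("biological_score outside [0,1]", "validation_error")
  }
  bad <- rules$diameter < 6 | rules$diameter > 16 | rules$diameter %% 2 != 0
  if (any(bad)) {
    pf_error(sprintf("rule %s: diameter must be an even integer in [6,16]",
                     rules$rule_id[which(bad)[1]]), "validation_error")
  }
  invisible(rules)
}

#' Apply a reaction rule to a substrate
#'
#' Runs the rule's SMARTS transformation on the substrate structure.  One
#' transformation is returned per distinct product set (duplicates by
#' product InChI set are collapsed); an empty list means the substrate does
#' not match the rule's pattern.
#'
#' @param rule single-row rule data frame (or list) with `rule_id`, `smarts`.
#' @param substrate a structure row as from [standardize_structure()] (needs
#'   `inchi` or `smiles`).
#' @return list of transformations; each has `rule_id`, `substrate_inchi`,
#'   `products` (data frame with `inchi`, `smiles`, `formula`, `charge`) and
#'   a `chemical_score` slot filled by [score_match()] (NA here).
#' @export
apply_rule <- function(rule, substrate) {
  sub_str <- substrate$smiles %||% substrate$inchi
  if (is.null(sub_str) || is.na(sub_str)) {
    pf_error("substrate lacks a structure", "input_error")
  }
  res <- chem_apply_smarts(list(list(rule_id = as.character(rule$rule_id),
                                     smarts = as.character(rule$smarts),
                                     substrate = as.character(sub_str))))[[1]]
  if (!is.null(res$error)) {
    pf_error(sprintf("rule '%s': %s", rule$rule_id, res$error), "rule_error")
  }
  lapply(res$product_sets, function(ps) {
    prods <- do.call(rbind, lapply(ps, function(d) {
      data.frame(inchi = d$inchi, smiles = d$smiles,
                 formula = format_formula(unlist(d$formula)),
                 charge = as.integer(d$charge), stringsAsFactors = FALSE)
    }))
    list(rule_id = as.character(rule$rule_id),
         substrate_inchi = substrate$inchi %||% NA_character_,
         substrate_smiles = substrate$smiles %||% NA_character_,
         products = prods,
         chemical_score = NA_real_)
  })
}

#' Chemical similarity score of a transformation
#'
#' Tanimoto similarity (Morgan radius-2, 2048-bit fingerprints) between the
#' query substrate and the rule's template substrate.  Symmetric, in
#' `[0, 1]`, and 1 exactly on identical fingerprints.
#'
#' @param rule rule row with a resolvable template substrate structure.
#' @param substrate query structure (`smiles` or `inchi`).
#' @param structures structure lookup (data frame with `id` + `smiles`/`inchi`)
#'   used to resolve `rule$template_substrate_id`.
#' @return numeric scalar in `[0, 1]`.
#' @export
chemical_score <- function(rule, substrate, structures) {
  tmpl <- structures[structures$id == rule$template_substrate_id, , drop = FALSE]
  if (nrow(tmpl) == 0) {
    pf_error(sprintf("template substrate '%s' not in structure lookup",
                     rule$template_substrate_id), "input_error")
  }
  tanimoto_similarity(substrate$smiles %||% substrate$inchi,
                      tmpl$smiles[1] %||% tmpl$inchi[1])
}

#' Accept or reject a scored transformation
#'
#' A transformation is accepted iff its rule's biological score and its
#' chemical score both reach the cutoffs (inclusive).
#'
#' @param rule rule row (supplies `biological_score`).
#' @param transformation as from [apply_rule()], with `chemical_score` set.
#' @param params a [search_params()] list (supplies `bio_cutoff`, `chem_cutoff`).
#' @return logical scalar.
#' @export
score_match <- function(rule, transformation, params) {
  isTRUE(rule$biological_score >= params$bio_cutoff &&
           transformation$chemical_score >= params$chem_cutoff)
}

## ---- completion and atomic balancing --------------------------------------

#' Solve the elemental balance for a candidate species multiset
#'
#' Finds the smallest positive integer coefficients closing the per-element
#' and net-charge balance, allowing optional co-substrates/co-products with
#' zero or positive coefficients and protons as an implicit balancer.
#' @noRd
solve_balance <- function(sub_formulas, sub_charges, sub_fixed,
                          prod_formulas, prod_charges, prod_fixed,
                          max_coef = 4L) {
  ns <- length(sub_formulas); np <- length(prod_formulas)
  ranges_s <- lapply(seq_len(ns), function(i) if (sub_fixed[i]) 1:2 else 0:max_coef)
  ranges_p <- lapply(seq_len(np), function(i) if (prod_fixed[i]) 1:max_coef else 0:max_coef)
  grid <- expand.grid(c(ranges_s, ranges_p), KEEP.OUT.ATTRS = FALSE)
  ## deterministic preference: smallest total coefficient sum first
  grid <- grid[order(rowSums(grid), apply(grid, 1, max)), , drop = FALSE]
  for (r in seq_len(nrow(grid))) {
    cs <- as.integer(grid[r, seq_len(ns)])
    cp <- as.integer(grid[r, ns + seq_len(np)])
    lhs <- sum_formulas(sub_formulas, cs)
    rhs <- sum_formulas(prod_formulas, cp)
    els <- union(names(lhs), names(rhs))
    resid <- vapply(els, function(el) {
      (if (el %in% names(lhs)) lhs[[el]] else 0L) -
        (if (el %in% names(rhs)) rhs[[el]] else 0L)
    }, numeric(1))
    charge_resid <- sum(sub_charges * cs) - sum(prod_charges * cp)
    ## protons may absorb a joint hydrogen/charge imbalance
    h_res <- if ("H" %in% els) resid[["H"]] else 0
    other <- resid[setdiff(els, "H")]
    if (all(other == 0) && h_res == charge_resid) {
      return(list(sub_coefs = cs, prod_coefs = cp, protons = h_res))
    }
  }
  NULL
}

#' Complete and balance a predicted mono-substrate transformation
#'
#' The rule engine proposes only the main substrate and its products; the
#' template reaction supplies candidate co-substrates and co-products (water,
#' cofactor partners).  This operation copies those candidates, solves the
#' integer elemental-balance system jointly with net charge (protons act as
#' an implicit balancer species), and emits a `predicted` reaction whose
#' element and charge residuals are zero.
#'
#' @param transformation as from [apply_rule()].
#' @param template the template reaction: list with `id` and `stoichiometry`
#'   rows of the universal network, or a reaction id to look up in `net`.
#' @param net the `metabolic_network` holding the template reaction and the
#'   structures/formulas of its metabolites.
#' @param rule the rule row (taxa are inherited from it).
#' @param reaction_id id for the new reaction.
#' @param substrate_id,product_ids metabolite ids to use for the query
#'   substrate and the predicted products (defaults: derived from InChI).
#' @return list with `reactions` and `stoichiometry` rows plus `metabolites`
#'   rows for any newly introduced compounds.
#' @export
complete_and_balance <- function(transformation, template, net, rule,
                                 reaction_id,
                                 substrate_id = NULL, product_ids = NULL) {
  if (is.character(template)) {
    tid <- template
  } else {
    tid <- template$id
  }
  tstoi <- net$stoichiometry[net$stoichiometry$reaction_id == tid, , drop = FALSE]
  if (nrow(tstoi) == 0) {
    pf_error(sprintf("template reaction '%s' not found", tid), "input_error")
  }
  met_row <- function(id) net$metabolites[net$metabolites$id == id, , drop = FALSE]

  ## main template substrate: the one matching the rule's substrate pattern
  main_sub <- rule$template_substrate_id
  tsubs <- tstoi$metabolite_id[tstoi$coefficient < 0]
  if (is.na(main_sub) || !main_sub %in% tsubs) {
    patt <- strsplit(as.character(rule$smarts), ">>", fixed = TRUE)[[1]][1]
    hit <- vapply(tsubs, function(id) {
      m <- met_row(id)
      str <- m$smiles[1] %||% m$inchi[1]
      !is.na(str) && smarts_matches(patt, str)
    }, TRUE)
    if (!any(hit)) {
      pf_error(sprintf("rule '%s': no template substrate matches its pattern",
                       rule$rule_id), "rule_error")
    }
    main_sub <- tsubs[which(hit)[1]]
  }
  cosub_ids <- setdiff(tsubs, main_sub)

  q_formula <- parse_formula(transformation$substrate_formula %||% {
    std <- standardize_structure(data.frame(
      id = "query", smiles = transformation$substrate_smiles,
      inchi = transformation$substrate_inchi))
    std$formula[1]
  })
  q_charge <- transformation$substrate_charge %||% 0L
  prods <- transformation$products
  cos <- lapply(cosub_ids, function(id) met_row(id))

  ## candidate co-products: template products that are small currency species
  ## (not the template's structural product), offered with optional coefficients
  tprods <- tstoi$metabolite_id[tstoi$coefficient > 0]
  coprod_candidates <- Filter(function(id) {
    f <- parse_formula(met_row(id)$formula[1])
    length(f) > 0 && sum(f) <= 30   # small species only (water, CO2, methanol...)
  }, tprods)
  ## drop candidate co-products whose structure equals a predicted product
  coprod_candidates <- Filter(function(id) {
    !(met_row(id)$inchi[1] %||% "") %in% prods$inchi
  }, coprod_candidates)
  cop <- lapply(coprod_candidates, function(id) met_row(id))

  sub_formulas <- c(list(q_formula), lapply(cos, function(m) parse_formula(m$formula[1])))
  sub_charges <- c(q_charge, vapply(cos, function(m) m$charge[1] %||% 0L, 0L))
  sub_fixed <- c(TRUE, rep(FALSE, length(cos)))
  prod_formulas <- c(lapply(seq_len(nrow(prods)),
                            function(i) parse_formula(prods$formula[i])),
                     lapply(cop, function(m) parse_formula(m$formula[1])))
  prod_charges <- c(prods$charge, vapply(cop, function(m) m$charge[1] %||% 0L, 0L))
  prod_fixed <- c(rep(TRUE, nrow(prods)), rep(FALSE, length(cop)))

  sol <- solve_balance(sub_formulas, sub_charges, sub_fixed,
                       prod_formulas, prod_charges, prod_fixed)
  if (is.null(sol)) {
    pf_error(sprintf("reaction '%s': no nonnegative integer solution balances the equation",
                     reaction_id), "balance_error",
             data = list(reaction = reaction_id))
  }

  ## assemble metabolite ids
  substrate_id <- substrate_id %||% inchi_met_id(transformation$substrate_inchi)
  product_ids <- product_ids %||% vapply(prods$inchi, inchi_met_id, character(1),
                                         USE.NAMES = FALSE)
  new_mets <- data.frame(id = c(substrate_id, product_ids),
                         name = c(substrate_id, product_ids),
                         inchi = c(transformation$substrate_inchi, prods$inchi),
                         smiles = c(transformation$substrate_smiles, prods$smiles),
                         formula = c(format_formula(q_formula), prods$formula),
                         charge = as.integer(c(q_charge, prods$charge)),
                         compartment = "c", stringsAsFactors = FALSE)

  ids <- c(substrate_id, vapply(cos, function(m) m$id[1], ""),
           product_ids, vapply(cop, function(m) m$id[1], ""))
  coefs <- c(-sol$sub_coefs, sol$prod_coefs)
  if (sol$protons != 0) {
    ids <- c(ids, "h")
    coefs <- c(coefs, sol$protons)   # positive residual => protons produced
    if (!"h" %in% net$metabolites$id) {
      new_mets <- rbind(new_mets,
                        data.frame(id = "h", name = "H+", inchi = "InChI=1S/p+1",
                                   smiles = "[H+]", formula = "H", charge = 1L,
                                   compartment = "c", stringsAsFactors = FALSE))
    }
  }
  keep <- coefs != 0
  ids <- ids[keep]; coefs <- coefs[keep]
  ## merge duplicate metabolite entries (a species may appear on both sides)
  agg <- tapply(coefs, ids, sum)
  agg <- agg[agg != 0]

  list(reactions = reaction_table(reaction_id, reversible = FALSE,
                                  provenance = "predicted",
                                  taxa = rule$taxa %||% "",
                                  ec_numbers = ""),
       stoichiometry = stoichiometry_table(reaction_id, names(agg), as.numeric(agg)),
       metabolites = new_mets[!duplicated(new_mets$id), , drop = FALSE],
       template_reaction_id = tid,
       residuals = list(elements = 0, charge = 0))
}

#' Stable metabolite id derived from an InChI string
#' @noRd
inchi_met_id <- function(inchi) {
  body <- sub("^InChI=1S?/", "", inchi)
  frm <- strsplit(body, "/", fixed = TRUE)[[1]][1]
  codes <- utf8ToInt(inchi)
  hash <- sum(codes * seq_along(codes)) %% 999983L
  paste0("cpd_", frm, "_", hash)
}

#' Verify that a reaction is elementally and charge balanced
#'
#' @param stoi stoichiometry rows of one reaction.
#' @param metabolites metabolite table supplying `formula` and `charge`.
#' @return list with per-element residuals and the charge residual.
#' @export
balance_residuals <- function(stoi, metabolites) {
  idx <- match(stoi$metabolite_id, metabolites$id)
  if (anyNA(idx)) pf_error("metabolite missing from lookup", "input_error")
  formulas <- lapply(metabolites$formula[idx], parse_formula)
  elem <- sum_formulas(formulas, stoi$coefficient)
  ch <- metabolites$charge[idx]
  ch[is.na(ch)] <- 0L
  charge <- sum(ch * stoi$coefficient)
  list(elements = elem[elem != 0], charge = charge)
}
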