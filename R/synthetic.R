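## Synthetic study-condition generator with known planted ground truth.
##
## Universes are built from a curated library of phenolic-like scaffolds
## decorated with the modifications gut microbes reverse most often
## (O-methyl ethers, O-glucosides, O-glucuronides), so that hydrolysis and
## demethylation rules have realistic match semantics.  Hidden degradation
## pathways attach further decorations to universe scaffolds; the matching
## rule table is derived from structurally analogous annotated reactions so
## the biosensor search can rediscover the hidden chains.

## scaffold library: phenolic-like cores, each with >= 1 free aromatic OH
PHENOLIC_SCAFFOLDS <- c(
  phenol = "Oc1ccccc1",
  catechol = "Oc1ccccc1O",
  resorcinol = "Oc1cccc(O)c1",
  phloroglucinol = "Oc1cc(O)cc(O)c1",
  p_hydroxybenzoate = "O=C(O)c1ccc(O)cc1",
  protocatechuate = "O=C(O)c1ccc(O)c(O)c1",
  gallate = "O=C(O)c1cc(O)c(O)c(O)c1",
  p_coumarate = "O=C(O)/C=C/c1ccc(O)cc1",
  caffeate = "O=C(O)/C=C/c1ccc(O)c(O)c1",
  p_hydroxyphenylacetate = "O=C(O)Cc1ccc(O)cc1",
  phloretate = "O=C(O)CCc1ccc(O)cc1",
  tyrosol = "OCCc1ccc(O)cc1",
  daidzein = "O=c1c(-c2ccc(O)cc2)coc2cc(O)ccc12",
  genistein = "O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12",
  apigenin = "O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",
  luteolin = "O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",
  naringenin = "O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21",
  quercetin = "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12")

CURRENCY_SMILES <- c(
  water = "O",
  methanol = "CO",
  glucose = "OCC1OC(O)C(O)C(O)C1O",
  glucuronate = "O=C(O)C1OC(O)C(O)C(O)C1O")

## decoration operations: degradation rule SMARTS (mono-substrate), the
## synthesis direction used only by the generator, and the released species
DECORATION_OPS <- list(
  methyl = list(
    deg = "[c:1][OX2H0:2][CH3:3]>>[c:1][OX2H1:2].[CH3:3][OX2H1]",
    syn = "[c:1][OX2H1:2]>>[c:1][OX2H0:2][CH3]",
    released = "methanol", ec = "1.14.13.-", prefix = "Me"),
  glucoside = list(
    deg = paste0("[c:1][OX2:2][CH1:3]1[OX2:4][CH1:5]([CH2:6][OX2H1:7])",
                 "[CH1:8]([OX2H1:9])[CH1:10]([OX2H1:11])[CH1:12]1[OX2H1:13]",
                 ">>[c:1][OX2H1:2].[OX2H1][CH1:3]1[OX2:4][CH1:5]([CH2:6][OX2H1:7])",
                 "[CH1:8]([OX2H1:9])[CH1:10]([OX2H1:11])[CH1:12]1[OX2H1:13]"),
    syn = "[c:1][OX2H1:2]>>[c:1][OX2H0:2]C1OC(CO)C(O)C(O)C1O",
    released = "glucose", ec = "3.2.1.21", prefix = "Glc"),
  glucuronide = list(
    deg = paste0("[c:1][OX2:2][CH1:3]1[OX2:4][CH1:5]([CX3:6](=[OX1:7])[OX2H1:8])",
                 "[CH1:9]([OX2H1:10])[CH1:11]([OX2H1:12])[CH1:13]1[OX2H1:14]",
                 ">>[c:1][OX2H1:2].[OX2H1][CH1:3]1[OX2:4][CH1:5]([CX3:6](=[OX1:7])[OX2H1:8])",
                 "[CH1:9]([OX2H1:10])[CH1:11]([OX2H1:12])[CH1:13]1[OX2H1:14]"),
    syn = "[c:1][OX2H1:2]>>[c:1][OX2H0:2]C1OC(C(=O)O)C(O)C(O)C1O",
    released = "glucuronate", ec = "3.2.1.31", prefix = "GlcA"))

#' Apply a decoration operation in the synthesis direction
#'
#' Returns the standardized structure of the first (InChI-sorted) product,
#' which makes decoration deterministic.
#' @noRd
decorate_structure <- function(op_name, smiles) {
  op <- DECORATION_OPS[[op_name]]
  res <- chem_apply_smarts(list(list(rule_id = paste0("syn_", op_name),
                                     smarts = op$syn, substrate = smiles)))[[1]]
  if (!is.null(res$error) || length(res$product_sets) == 0) return(NULL)
  singles <- Filter(function(ps) length(ps) == 1, res$product_sets)
  if (length(singles) == 0) return(NULL)
  inchis <- vapply(singles, function(ps) ps[[1]]$inchi, character(1))
  d <- singles[[order(inchis)[1]]][[1]]
  list(inchi = d$inchi, smiles = d$smiles,
       formula = format_formula(unlist(d$formula)),
       charge = as.integer(d$charge))
}

#' Generate a synthetic universal network
#'
#' Builds a flux-consistent universal reaction database: phenolic scaffolds
#' and currency metabolites (water, methanol, glucose, glucuronate) with
#' real structures, decorated variants connected by annotated hydrolysis /
#' demethylation reactions, per-species transport reactions for every
#' metabolite a species touches, and reversible exchange reactions.  All
#' conversion reactions carry taxonomic annotations drawn over the species
#' set; the network is reproducible for a given seed.
#'
#' @param n_species number of species (labelled `s1`, `s2`, ...; >= 1).
#' @param n_metabolites target number of distinct compounds (scaffolds +
#'   currency + decorated variants; >= 8 so a consistent network exists).
#' @param connectivity expected number of decorated variants per scaffold
#'   (density of the annotated reaction layer, default 1.5).
#' @param seed integer seed.
#' @return a `metabolic_network`; decorated conversion reactions are the
#'   rule templates later searches draw on.
#' @export
generate_universe <- function(n_species, n_metabolites, connectivity = 1.5,
                              seed = 1L) {
  if (n_species < 1) pf_error("n_species must be >= 1", "generation_error")
  if (n_metabolites < 8) {
    pf_error("n_metabolites too small to build a consistent network (need >= 8)",
             "generation_error")
  }
  species <- paste0("s", seq_len(n_species))
  n_currency <- length(CURRENCY_SMILES)
  n_scaffolds <- min(length(PHENOLIC_SCAFFOLDS),
                     max(2L, ceiling((n_metabolites - n_currency) /
                                       (1 + connectivity))))
  n_decor <- max(1L, n_metabolites - n_currency - n_scaffolds)

  with_local_seed(split_seed(seed, "universe"), {
    scaffold_names <- names(PHENOLIC_SCAFFOLDS)[seq_len(n_scaffolds)]
    ## standardize scaffolds + currency in one batch
    base_records <- data.frame(
      id = c(scaffold_names, names(CURRENCY_SMILES)),
      smiles = c(unname(PHENOLIC_SCAFFOLDS[scaffold_names]),
                 unname(CURRENCY_SMILES)), stringsAsFactors = FALSE)
    std <- standardize_structure(base_records)

    ## decorated variants: cycle scaffolds, draw ops
    ops <- names(DECORATION_OPS)
    decor <- list()
    tries <- 0L
    while (length(decor) < n_decor && tries < n_decor * 5L) {
      tries <- tries + 1L
      sc <- scaffold_names[(tries - 1L) %% n_scaffolds + 1L]
      op <- sample(ops, 1L)
      did <- paste0(DECORATION_OPS[[op]]$prefix, "_", sc)
      if (did %in% names(decor)) next
      d <- decorate_structure(op, std$smiles[std$id == sc])
      if (is.null(d) || d$inchi %in% std$inchi) next
      decor[[did]] <- c(d, list(scaffold = sc, op = op))
    }
    if (length(decor) == 0) {
      pf_error("could not build any decorated compound", "generation_error")
    }

    met_ids <- c(std$id, names(decor))
    met_df <- metabolite_table(
      id = paste0(met_ids, "[c]"),
      name = met_ids,
      inchi = c(std$inchi, vapply(decor, `[[`, "", "inchi")),
      smiles = c(std$smiles, vapply(decor, `[[`, "", "smiles")),
      formula = c(std$formula, vapply(decor, `[[`, "", "formula")),
      charge = c(std$charge, vapply(decor, function(d) d$charge, 0L)),
      compartment = "c")

    rxn_rows <- list(); stoi_rows <- list()
    transport_taxa <- list()   # met id -> species set

    for (did in names(decor)) {
      d <- decor[[did]]
      op <- DECORATION_OPS[[d$op]]
      rid <- paste0("deg_", did)
      n_taxa <- sample(1:min(2L, n_species), 1L)
      taxa <- sort(sample(species, n_taxa))
      rxn_rows[[rid]] <- reaction_table(rid, reversible = FALSE,
                                        provenance = "annotated",
                                        taxa = collapse_set(taxa),
                                        ec_numbers = op$ec)
      mets <- c(paste0(did, "[c]"), "water[c]",
                paste0(d$scaffold, "[c]"), paste0(op$released, "[c]"))
      stoi_rows[[rid]] <- stoichiometry_table(rid, mets, c(-1, -1, 1, 1))
      for (m in mets) {
        transport_taxa[[m]] <- union(transport_taxa[[m]] %||% character(0), taxa)
      }
    }

    ## transports (per species per touched metabolite) and exchanges
    emet_rows <- list()
    for (m in names(transport_taxa)) {
      base <- strip_compartment(m)
      emet <- paste0(base, "[e]")
      row <- met_df[met_df$id == m, , drop = FALSE]
      row$id <- emet; row$compartment <- "e"
      emet_rows[[emet]] <- row
      for (sp in transport_taxa[[m]]) {
        tid <- paste0("T_", base, "_", sp)
        rxn_rows[[tid]] <- reaction_table(tid, reversible = TRUE,
                                          provenance = "transport", taxa = sp)
        stoi_rows[[tid]] <- stoichiometry_table(c(tid, tid), c(m, emet), c(-1, 1))
      }
      xid <- paste0("EX_", base)
      rxn_rows[[xid]] <- reaction_table(xid, reversible = TRUE,
                                        provenance = "exchange")
      stoi_rows[[xid]] <- stoichiometry_table(xid, emet, -1)
    }

    ## drop intracellular metabolites never used by a reaction
    all_stoi <- do.call(rbind, stoi_rows)
    met_all <- rbind(met_df, do.call(rbind, emet_rows))
    met_all <- met_all[met_all$id %in% all_stoi$metabolite_id, , drop = FALSE]
    rownames(met_all) <- NULL
    net <- metabolic_network(met_all, do.call(rbind, rxn_rows), all_stoi,
                             species_catalog = species)
    attr(net, "decorations") <- lapply(decor, function(d)
      list(scaffold = d$scaffold, op = d$op))
    net
  })
}

#' Plant hidden degradation pathways and derive a matching rule table
#'
#' Creates `n_sources` novel source compounds, each connected to a universe
#' scaffold by a chain of `depth` hidden hydrolysis/demethylation reactions.
#' Hidden reactions are *not* added to the universe; the returned rule table
#' holds rules derived from the universe's structurally analogous annotated
#' reactions (several diameters per template), sufficient for the biosensor
#' search to rediscover every hidden chain.
#'
#' @param universe a network from [generate_universe()].
#' @param n_sources number of source compounds.
#' @param depth hidden-chain length (>= 1).
#' @param seed integer seed.
#' @return list with `sources` (structure rows), `hidden` (reactions /
#'   stoichiometry / metabolites of the hidden chains),
#'   `rules` (rule table), and `truth` (per-source chain description).
#' @export
plant_pathways <- function(universe, n_sources, depth, seed = 1L) {
  if (depth < 1) pf_error("depth must be >= 1", "input_error")
  deco <- attr(universe, "decorations")
  if (is.null(deco) || length(deco) == 0) {
    pf_error("universe has no annotated decoration templates", "input_error")
  }
  ops_avail <- unique(vapply(deco, `[[`, "", "op"))
  anchors <- unique(vapply(deco, `[[`, "", "scaffold"))

  with_local_seed(split_seed(seed, "plant"), {
    sources <- list(); hidden_rxns <- list(); hidden_stoi <- list()
    hidden_mets <- list(); truth <- list()
    taken_inchis <- character(0)
    for (i in seq_len(n_sources)) {
      ## try anchors in rotating order until one supports a full-depth chain
      ## (a scaffold needs >= depth free aromatic hydroxyls)
      chain <- list()
      anchor <- NA_character_
      for (a_off in seq_along(anchors) - 1L) {
        anchor <- anchors[(i - 1L + a_off) %% length(anchors) + 1L]
        cur <- universe$metabolites[universe$metabolites$id == paste0(anchor, "[c]"), ]
        chain_ops <- sample(ops_avail, depth, replace = TRUE)
        chain <- list()
        for (k in seq_len(depth)) {
          ## preferred op first, remaining ops as fallback when the decorated
          ## structure collides with an existing compound
          d <- NULL
          for (op_try in unique(c(chain_ops[k], sample(ops_avail)))) {
            cand <- decorate_structure(op_try, cur$smiles)
            if (!is.null(cand) && !cand$inchi %in% universe$metabolites$inchi &&
                !cand$inchi %in% taken_inchis &&
                !cand$inchi %in% vapply(chain, function(s) s$inchi, "")) {
              d <- cand; chain_ops[k] <- op_try; break
            }
          }
          if (is.null(d)) break
          did <- sprintf("src%d_step%d", i, k)
          op <- DECORATION_OPS[[chain_ops[k]]]
          chain[[k]] <- list(id = did, op = chain_ops[k], parent = cur$id,
                             parent_inchi = cur$inchi,
                             inchi = d$inchi, smiles = d$smiles,
                             formula = d$formula, charge = d$charge,
                             released = op$released)
          cur <- data.frame(id = paste0(did, "[c]"), inchi = d$inchi,
                            smiles = d$smiles, formula = d$formula,
                            charge = d$charge, stringsAsFactors = FALSE)
        }
        if (length(chain) == depth) break
      }
      if (length(chain) < depth) next
      taken_inchis <- c(taken_inchis, vapply(chain, `[[`, "", "inchi"))
      src <- chain[[depth]]
      source_id <- sprintf("source_%d", i)
      sources[[source_id]] <- data.frame(
        id = source_id, inchi = src$inchi, smiles = src$smiles,
        formula = src$formula, charge = src$charge, anchor = anchor,
        stringsAsFactors = FALSE)
      ## hidden reactions run top-down: step k degrades chain[k] into its parent
      for (k in rev(seq_len(depth))) {
        st <- chain[[k]]
        rid <- sprintf("hidden_%d_%d", i, depth - k + 1L)
        hidden_rxns[[rid]] <- reaction_table(rid, reversible = FALSE,
                                             provenance = "predicted")
        hidden_stoi[[rid]] <- stoichiometry_table(
          rid,
          c(paste0(st$id, "[c]"), "water[c]", st$parent,
            paste0(st$released, "[c]")),
          c(-1, -1, 1, 1))
        hidden_mets[[st$id]] <- metabolite_table(
          paste0(st$id, "[c]"), st$id, inchi = st$inchi, smiles = st$smiles,
          formula = st$formula, charge = st$charge, compartment = "c")
      }
      truth[[source_id]] <- list(anchor = anchor, ops = chain_ops,
                                 steps = vapply(chain, `[[`, "", "inchi"))
    }

    ## rule table: for every decoration op used by the universe templates,
    ## rules at several diameters derived from the annotated analog reactions
    rule_rows <- list()
    for (did in names(deco)) {
      op_name <- deco[[did]]$op
      op <- DECORATION_OPS[[op_name]]
      diameters <- sort(sample(seq(6L, 16L, 2L), sample(2:3, 1L)))
      for (dm in diameters) {
        rule_rows[[length(rule_rows) + 1]] <- data.frame(
          rule_id = sprintf("rule_%s_d%d", did, dm),
          smarts = op$deg, diameter = dm,
          biological_score = round(stats::runif(1, 0.5, 1), 3),
          template_reaction_id = paste0("deg_", did),
          template_substrate_id = paste0(did, "[c]"),
          taxa = universe$reactions$taxa[match(paste0("deg_", did),
                                               universe$reactions$id)],
          stringsAsFactors = FALSE)
      }
    }
    rules <- do.call(rbind, rule_rows)
    rownames(rules) <- NULL
    validate_rules(rules)

    hidden <- list(
      reactions = do.call(rbind, hidden_rxns) %||% reaction_table(character(0)),
      stoichiometry = do.call(rbind, hidden_stoi) %||%
        stoichiometry_table(character(0), character(0), numeric(0)),
      metabolites = do.call(rbind, hidden_mets) %||% metabolite_table(character(0)))
    rownames(hidden$reactions) <- rownames(hidden$stoichiometry) <-
      rownames(hidden$metabolites) <- NULL
    list(sources = do.call(rbind, sources), hidden = hidden,
         rules = rules, truth = truth)
  })
}

#' Simulate untargeted-metabolomics presence calls
#'
#' Each true output metabolite is called present with probability
#' `sensitivity`; each other universe metabolite is called present with
#' probability `1 - specificity`.
#'
#' @param true_outputs named list: sample id -> character vector of truly
#'   producible metabolites.
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param universe character vector of measurable metabolites.
#' @param seed integer seed.
#' @return named list: sample id -> character vector of metabolites called
#'   present.
#' @export
simulate_metabolomics <- function(true_outputs, sensitivity, specificity,
                                  universe, seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  with_local_seed(split_seed(seed, "metabolomics"), {
    lapply(true_outputs, function(truth) {
      truth <- intersect(truth, universe)
      absent <- setdiff(universe, truth)
      called <- c(truth[stats::runif(length(truth)) <= sensitivity],
                  absent[stats::runif(length(absent)) <= 1 - specificity])
      sort(called)
    })
  })
}
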