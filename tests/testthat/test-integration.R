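## Sequential gap-filling, annotation pruning, single-species repair and
## version comparison.

## fixture: universal with a predicted reaction for compound X that needs a
## co-substrate supplied by one extra universal reaction
gapfill_fixture <- function() {
  mets <- metabolite_table(c("X", "co", "P", "pre"),
                           formula = c("C2", "C1", "C2", "C1"))
  rxns <- rbind(
    reaction_table("EX_X", reversible = TRUE, provenance = "exchange"),
    reaction_table("EX_pre", reversible = TRUE, provenance = "exchange"),
    reaction_table("EX_P", reversible = TRUE, provenance = "exchange"),
    reaction_table("supplier", taxa = "s1"),            # pre -> co
    reaction_table("pred_X", provenance = "predicted", taxa = "s1"),
    reaction_table("EX_co", reversible = TRUE, provenance = "exchange"))
  stoi <- rbind(
    stoichiometry_table("EX_X", "X", -1),
    stoichiometry_table("EX_pre", "pre", -1),
    stoichiometry_table("EX_P", "P", -1),
    stoichiometry_table(c("supplier", "supplier"), c("pre", "co"), c(-1, 1)),
    stoichiometry_table(c("pred_X", "pred_X", "pred_X"),
                        c("X", "co", "P"), c(-1, -1, 2)),
    stoichiometry_table("EX_co", "co", -1))
  metabolic_network(mets, rxns, stoi, species_catalog = "s1")
}

test_that("sequential gap-filling pulls in required universal support", {
  universal <- gapfill_fixture()
  base <- subset_network(universal, c("EX_pre", "EX_P"))
  out <- sequential_gapfill(universal, base, list(X = "pred_X"))
  expect_identical(out$integrated, "X")
  expect_length(out$skipped, 0)
  ## the co-substrate supplier (or the direct co exchange) must be included
  expect_true(any(c("supplier", "EX_co") %in% out$network$reactions$id))
  expect_true("pred_X" %in% out$network$reactions$id)
  ## base survives
  expect_true(all(base$reactions$id %in% out$network$reactions$id))
  ## integrated compound is flux-consistent in the result
  expect_false("pred_X" %in% blocked_reactions(as_flux_problem(out$network)))

  ## no predictions: base returned unchanged
  noop <- sequential_gapfill(universal, base, list())
  expect_identical(noop$network$reactions, base$reactions)

  ## base not contained in universal -> input error
  alien <- metabolic_network(metabolite_table("z"), reaction_table("rz"),
                             stoichiometry_table("rz", "z", -1))
  expect_error(sequential_gapfill(universal, alien, list(X = "pred_X")),
               class = "input_error")

  ## an unsupportable compound is skipped and reported, not fatal
  u2 <- universal
  u2$reactions <- rbind(u2$reactions,
                        reaction_table("pred_dead", provenance = "predicted"))
  u2$metabolites <- rbind(u2$metabolites, metabolite_table("D", formula = "C5"))
  u2$stoichiometry <- rbind(u2$stoichiometry,
                            stoichiometry_table(c("pred_dead", "pred_dead"),
                                                c("X", "D"), c(-1, 1)))
  out2 <- sequential_gapfill(u2, base, list(X = "pred_X", Y = "pred_dead"))
  expect_identical(out2$integrated, "X")
  expect_identical(out2$skipped, "Y")
})

test_that("pruning removes unannotated reactions and cascading blocks", {
  ## chain EX_a -> a -[linker, unannotated]-> b -[r_bc, annotated]-> c -> EX_c
  mets <- metabolite_table(c("a", "b", "c"))
  rxns <- rbind(
    reaction_table("EX_a", reversible = TRUE, provenance = "exchange"),
    reaction_table("linker", taxa = ""),
    reaction_table("r_bc", taxa = "s1"),
    reaction_table("EX_c", reversible = TRUE, provenance = "exchange"))
  stoi <- rbind(stoichiometry_table("EX_a", "a", -1),
                stoichiometry_table(c("linker", "linker"), c("a", "b"), c(-1, 1)),
                stoichiometry_table(c("r_bc", "r_bc"), c("b", "c"), c(-1, 1)),
                stoichiometry_table("EX_c", "c", -1))
  net <- metabolic_network(mets, rxns, stoi)
  pruned <- prune_and_consistency(net)
  ## removing the unannotated linker blocks the downstream annotated step too
  expect_false("linker" %in% pruned$reactions$id)
  expect_false("r_bc" %in% pruned$reactions$id)
  expect_length(blocked_reactions(as_flux_problem(pruned)), 0)

  ## a fully annotated consistent network passes through unchanged
  ok <- pipeline_fixture()$universe
  expect_identical(prune_and_consistency(ok)$reactions$id, ok$reactions$id)
})

test_that("single-species repair adds evidenced transports and strips the rest", {
  ## species s1 produces P intracellularly with no outlet
  mets <- metabolite_table(c("a[c]", "P[c]", "a[e]"),
                           compartment = c("c", "c", "e"))
  rxns <- rbind(
    reaction_table("r_aP", taxa = "s1"),
    reaction_table("T_a_s1", reversible = TRUE, provenance = "transport",
                   taxa = "s1"),
    reaction_table("EX_a", reversible = TRUE, provenance = "exchange"))
  stoi <- rbind(stoichiometry_table(c("r_aP", "r_aP"), c("a[c]", "P[c]"), c(-1, 1)),
                stoichiometry_table(c("T_a_s1", "T_a_s1"), c("a[c]", "a[e]"), c(-1, 1)),
                stoichiometry_table("EX_a", "a[e]", -1))
  net <- metabolic_network(mets, rxns, stoi, species_catalog = "s1")

  ## with evidence: transport + exchange added, P producible
  ev <- data.frame(species = "s1", metabolite = "P[c]", stringsAsFactors = FALSE)
  rep1 <- single_species_repair(net, ev)
  expect_true("T_P_s1" %in% rep1$reactions$id)
  expect_true("EX_P" %in% rep1$reactions$id)
  expect_true("r_aP" %in% rep1$reactions$id)
  expect_length(blocked_reactions(as_flux_problem(rep1)), 0)

  ## without evidence: the dead-end-producing reaction loses the species and
  ## is removed
  rep0 <- single_species_repair(net, ev[0, ])
  expect_false("r_aP" %in% rep0$reactions$id)

  ## a species without dead ends is untouched
  healthy <- pipeline_fixture()$universe
  rep2 <- single_species_repair(healthy, ev[0, ])
  expect_setequal(rep2$reactions$id, healthy$reactions$id)
})

test_that("coverage report reproduces printed catalogue differences exactly", {
  ## sub-class catalogues with the published covered counts:
  ## isoflavonoids 12 -> 36 of 86, anthocyanins 19 -> 38 of 49,
  ## hydroxycinnamic acids 13 -> 21 of 33
  specs <- list(iso = c(12, 36, 86), antho = c(19, 38, 49), hca = c(13, 21, 33))
  classes <- do.call(rbind, lapply(names(specs), function(sc) {
    data.frame(compound = paste0(sc, "_", seq_len(specs[[sc]][3])),
               subclass = sc, catalogue_size = specs[[sc]][3],
               stringsAsFactors = FALSE)
  }))
  covered <- function(version) {
    unlist(lapply(names(specs), function(sc) {
      n <- specs[[sc]][if (version == "old") 1 else 2]
      paste0(sc, "_", seq_len(n))
    }))
  }
  make_net <- function(ids) {
    metabolic_network(metabolite_table(c(ids, "x")), reaction_table("r"),
                      stoichiometry_table("r", "x", -1))
  }
  rep <- coverage_and_diff_report(make_net(covered("old")),
                                  make_net(covered("new")), classes)
  cov <- rep$coverage
  expect_equal(cov$coverage_diff_pct[cov$subclass == "iso"], 28)
  expect_equal(cov$coverage_diff_pct[cov$subclass == "antho"], 39)
  expect_equal(cov$coverage_diff_pct[cov$subclass == "hca"], 24)
  expect_equal(cov$covered_new[cov$subclass == "iso"], 36)

  ## identical networks: zero additions and zero differences
  same <- coverage_and_diff_report(make_net(covered("new")),
                                   make_net(covered("new")), classes)
  expect_length(same$added_reactions, 0)
  expect_true(all(same$coverage$coverage_diff_pct == 0))
})

test_that("the full update pipeline preserves the base and ends consistent", {
  fx <- pipeline_fixture()
  expect_setequal(fx$gapfill$integrated, names(fx$predictions))
  ## base preservation through gap-filling, pruning and repair
  expect_true(all(fx$universe$reactions$id %in% fx$net_new$reactions$id))
  ## no blocked reactions and no unannotated non-boundary reactions remain
  expect_length(blocked_reactions(as_flux_problem(fx$net_new)), 0)
  non_boundary <- !fx$net_new$reactions$provenance %in% c("exchange", "transport")
  expect_true(all(nzchar(fx$net_new$reactions$taxa[non_boundary])))
  ## determinism: a second run reproduces the same reaction set
  gf2 <- sequential_gapfill(fx$universal, fx$universe, fx$predictions)
  expect_identical(sort(gf2$network$reactions$id),
                   sort(fx$gapfill$network$reactions$id))
})
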