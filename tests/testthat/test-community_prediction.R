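## Compartmentalized community assembly and FVA-based output prediction.

## two species sharing a conversion a -> b, with transports and exchanges
two_species_net <- function() {
  mets <- metabolite_table(c("a[c]", "b[c]", "a[e]", "b[e]"),
                           compartment = c("c", "c", "e", "e"))
  rxns <- rbind(
    reaction_table("r_ab", taxa = "s1;s2"),
    reaction_table("T_a_s1", reversible = TRUE, provenance = "transport", taxa = "s1"),
    reaction_table("T_a_s2", reversible = TRUE, provenance = "transport", taxa = "s2"),
    reaction_table("T_b_s1", reversible = TRUE, provenance = "transport", taxa = "s1"),
    reaction_table("T_b_s2", reversible = TRUE, provenance = "transport", taxa = "s2"),
    reaction_table("EX_a", reversible = TRUE, provenance = "exchange"),
    reaction_table("EX_b", reversible = TRUE, provenance = "exchange"))
  stoi <- rbind(
    stoichiometry_table(c("r_ab", "r_ab"), c("a[c]", "b[c]"), c(-1, 1)),
    stoichiometry_table(c("T_a_s1", "T_a_s1"), c("a[c]", "a[e]"), c(-1, 1)),
    stoichiometry_table(c("T_a_s2", "T_a_s2"), c("a[c]", "a[e]"), c(-1, 1)),
    stoichiometry_table(c("T_b_s1", "T_b_s1"), c("b[c]", "b[e]"), c(-1, 1)),
    stoichiometry_table(c("T_b_s2", "T_b_s2"), c("b[c]", "b[e]"), c(-1, 1)),
    stoichiometry_table("EX_a", "a[e]", -1),
    stoichiometry_table("EX_b", "b[e]", -1))
  metabolic_network(mets, rxns, stoi, species_catalog = c("s1", "s2"))
}

test_that("community assembly builds one compartment per species plus a lumen", {
  net <- two_species_net()
  cm <- build_community(net, c("s1", "s2"))
  comps <- unique(cm$network$metabolites$compartment)
  expect_setequal(comps, c("s1", "s2", "lumen"))
  expect_length(comps, 3)                       # |species| + 1
  ## the shared conversion is replicated into both species compartments
  expect_true(all(c("r_ab[s1]", "r_ab[s2]") %in% cm$network$reactions$id))
  ## one lumen metabolite per extracellular compound, one exchange each
  lumen <- cm$network$metabolites$id[cm$network$metabolites$compartment == "lumen"]
  expect_setequal(lumen, c("a[lumen]", "b[lumen]"))
  exch <- grep("^EX_", cm$network$reactions$id, value = TRUE)
  expect_length(exch, 2)
  ## no reaction spans two species compartments
  comp_of <- function(mid) cm$network$metabolites$compartment[
    match(mid, cm$network$metabolites$id)]
  for (rid in cm$network$reactions$id) {
    comps_r <- unique(comp_of(cm$network$stoichiometry$metabolite_id[
      cm$network$stoichiometry$reaction_id == rid]))
    expect_lte(length(setdiff(comps_r, "lumen")), 1)
  }
  ## both species transport the shared metabolite into the same lumen pool
  expect_true(all(c("T_a_s1[s1]", "T_a_s2[s2]") %in% cm$network$reactions$id))

  expect_error(build_community(net, character(0)), class = "input_error")
  expect_warning(build_community(net, c("s1", "ghost")), "ghost")
})

test_that("contextualization opens only supplied uptakes and closes absent species", {
  net <- two_species_net()
  cm <- build_community(net, c("s1", "s2"))

  ## nothing in, nothing out
  empty <- contextualize(cm, community_context(character(0), c("s1", "s2")))
  v0 <- fva(empty, attr(empty, "exchange_ids"))
  expect_true(all(v0$max <= 1e-6))
  expect_length(predict_outputs(empty), 0)

  ## substrate supplied, converting species present: product secretable
  ctx <- community_context("a", c("s1", "s2"))
  p <- contextualize(cm, ctx)
  idx <- match("EX_a[lumen]", p$reaction_ids)
  expect_equal(p$lb[idx], -1000)
  ## b is producible; a itself is consumed only, so it cannot be net-secreted
  expect_setequal(predict_outputs(p), "b")

  ## converting species absent: downstream secretion stays closed
  p_off <- contextualize(cm, community_context("a", character(0)))
  expect_false("b" %in% predict_outputs(p_off))

  ## unknown ids are warnings, not errors
  p_w <- contextualize(cm, community_context("nonsense", "s1"))
  expect_match(attr(p_w, "context_warnings"), "unknown input compound",
               all = FALSE)
})

test_that("output sets are invariant to species order and grow monotonically", {
  fx <- pipeline_fixture()
  net_old <- fx$universe
  net_new <- fx$net_new
  inputs <- c(fx$src_met, "water")
  ctx <- community_context(inputs, c("s1", "s2", "s3"))
  out_a <- predict_outputs(contextualize(build_community(net_new,
                                                         c("s1", "s2", "s3")), ctx))
  out_b <- predict_outputs(contextualize(build_community(net_new,
                                                         c("s3", "s1", "s2")), ctx))
  expect_identical(out_a, out_b)

  ## the extended network strictly gains outputs on the source-only diet
  comp <- compare_outputs(net_old, net_new, list(ctx))
  expect_gt(comp$per_context$n_gained[1], 0)
  expect_true(all(comp$details[[1]]$outputs_old %in% comp$details[[1]]$outputs_new))

  ## closing a species never adds outputs
  ctx2 <- community_context(inputs, c("s1", "s2"))
  out_fewer <- predict_outputs(contextualize(build_community(net_new,
                                                             c("s1", "s2", "s3")),
                                             ctx2))
  expect_true(all(out_fewer %in% out_a))

  ## identical networks: counts of gained outputs are all zero
  same <- compare_outputs(net_new, net_new, list(ctx, ctx2))
  expect_true(all(same$per_context$n_gained == 0))
  expect_equal(same$summary[["mean"]], 0)
})
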