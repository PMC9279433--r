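test_that("tabular round-trip preserves network content and errors are located", {
  net <- toy_network()
  expect_equal(nrow(net$reactions), 5)
  expect_equal(nrow(net$metabolites), 3)

  stem <- file.path(tempdir(), "toy_net")
  write_network(net, stem, dialect = "tsv")
  back <- load_network(stem, dialect = "tsv")
  expect_identical(back$metabolites, net$metabolites)
  expect_identical(back$reactions, net$reactions)
  expect_equal(
    back$stoichiometry[order(back$stoichiometry$reaction_id,
                             back$stoichiometry$metabolite_id), ],
    net$stoichiometry[order(net$stoichiometry$reaction_id,
                            net$stoichiometry$metabolite_id), ],
    ignore_attr = TRUE)

  ## write(load(x)) == load(x)
  stem2 <- file.path(tempdir(), "toy_net2")
  write_network(back, stem2, dialect = "tsv")
  expect_identical(readLines(paste0(stem, ".reactions.tsv")),
                   readLines(paste0(stem2, ".reactions.tsv")))

  ## malformed stoichiometry names the record
  bad <- readLines(paste0(stem, ".reactions.tsv"))
  bad[2] <- sub("\ta=-1;?", "\tgarbage", bad[2])
  stem3 <- file.path(tempdir(), "toy_bad")
  writeLines(bad, paste0(stem3, ".reactions.tsv"))
  file.copy(paste0(stem, ".metabolites.tsv"), paste0(stem3, ".metabolites.tsv"),
            overwrite = TRUE)
  expect_error(load_network(stem3, "tsv"), class = "parse_error")
})

test_that("SBML round-trip preserves bounds, annotations and stoichiometry", {
  net <- toy_network()
  f <- tempfile(fileext = ".xml")
  write_network(net, f, dialect = "sbml")
  back <- load_network(f, dialect = "sbml")
  expect_identical(back$metabolites, net$metabolites)
  expect_identical(back$reactions, net$reactions)
  expect_equal(stoich_matrix(back)[net$metabolites$id, net$reactions$id],
               stoich_matrix(net))
})

test_that("dangling metabolite references are rejected at validation", {
  mets <- metabolite_table("a")
  rxns <- reaction_table("r1")
  stoi <- stoichiometry_table(c("r1", "r1"), c("a", "ghost"), c(-1, 1))
  expect_error(metabolic_network(mets, rxns, stoi), class = "validation_error")
  expect_error(
    metabolic_network(metabolite_table("a"), reaction_table("r1"),
                      stoichiometry_table("r1", "a", -1)[0, ]),
    class = "validation_error")
  ## reversibility flag must agree with bounds
  r <- reaction_table("r1", reversible = TRUE)
  r$lb <- 0
  expect_error(metabolic_network(mets, r, stoichiometry_table("r1", "a", -1)),
               class = "validation_error")
})

test_that("universal filtering keeps taxon-annotated, fully structured reactions", {
  net <- toy_network()
  ## r1 has taxon s1 and both metabolites carry InChI -> survives;
  ## r2 lacks taxa; EX_c touches the InChI-less metabolite c
  filtered <- filter_universal(net, "s1")
  expect_identical(filtered$reactions$id, "r1")
  expect_setequal(filtered$metabolites$id, c("a", "b"))

  ## idempotence
  twice <- filter_universal(filtered, "s1")
  expect_identical(twice$reactions, filtered$reactions)

  ## disjoint taxa -> empty result is permitted
  none <- filter_universal(net, "s99")
  expect_equal(nrow(none$reactions), 0)

  ## fully annotated + structured input is returned unchanged
  ok <- subset_network(net, c("r1"))
  expect_identical(filter_universal(ok, "s1")$reactions, ok$reactions)

  expect_error(filter_universal(net, character(0)), class = "input_error")
})

test_that("merge identifies metabolites by InChI and collapses duplicate reactions", {
  water_inchi <- "InChI=1S/H2O/h1H2"
  make_net <- function(wid, taxa) {
    mets <- metabolite_table(c(wid, "x"), inchi = c(water_inchi, NA),
                             formula = c("H2O", NA))
    rxns <- reaction_table(c("rx", "EX_w"), reversible = c(FALSE, TRUE),
                           provenance = c("annotated", "exchange"),
                           taxa = c(taxa, ""))
    stoi <- stoichiometry_table(c("rx", "rx", "EX_w"), c("x", wid, wid),
                                c(-1, 1, -1))
    metabolic_network(mets, rxns, stoi)
  }
  a <- make_net("water_a", "s1")
  b <- make_net("water_b", "s2")

  ## idempotence: merge(x, x) has the same counts as x
  aa <- merge_networks(a, a)
  expect_equal(nrow(aa$reactions), nrow(a$reactions))
  expect_equal(nrow(aa$metabolites), nrow(a$metabolites))

  m <- merge_networks(a, b)
  ## one water metabolite despite different ids
  expect_equal(sum(m$metabolites$inchi %in% water_inchi), 1)
  ## duplicate reaction collapsed with taxa unioned
  expect_equal(nrow(m$reactions), 2)
  expect_identical(m$reactions$taxa[m$reactions$id == "rx"], "s1;s2")

  ## commutative up to relabelling: same reaction count both ways
  m2 <- merge_networks(b, a)
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  expect_equal(nrow(m2$metabolites), nrow(m$metabolites))

  ## conflicting formulas for one structure are flagged, merge proceeds
  b2 <- make_net("water_b", "s2")
  b2$metabolites$formula[1] <- "H3O"
  mc <- merge_networks(a, b2)
  expect_match(attr(mc, "conflicts"), "conflicting formulas")
})

test_that("network summaries count provenance and phylum correctly", {
  empty <- metabolic_network(metabolite_table(character(0)),
                             reaction_table(character(0)),
                             stoichiometry_table(character(0), character(0),
                                                 numeric(0)))
  s0 <- network_summary(empty)
  expect_equal(s0$n_metabolites, 0)
  expect_equal(s0$n_reactions, 0)
  expect_true(all(s0$by_provenance == 0))

  mets <- metabolite_table(c("a", "b"))
  rxns <- reaction_table(paste0("r", 1:5),
                         provenance = c("predicted", "predicted", rep("annotated", 3)),
                         taxa = c("s1", "s2", "s1", "s3", ""))
  stoi <- stoichiometry_table(paste0("r", 1:5), rep(c("a", "b"), length.out = 5),
                              rep(-1, 5))
  net <- metabolic_network(mets, rxns, stoi)
  s <- network_summary(net, phylum_lookup = data.frame(
    species = c("s1", "s2"), phylum = c("Firmicutes", "Bacteroidetes"),
    stringsAsFactors = FALSE))
  expect_equal(s$by_provenance[["predicted"]], 2)
  expect_equal(s$by_provenance[["annotated"]], 3)
  expect_equal(s$by_phylum[["Firmicutes"]], 2)
  expect_equal(s$by_phylum[["Bacteroidetes"]], 1)
  ## species missing from the lookup fall under "unclassified"
  expect_equal(s$by_phylum[["unclassified"]], 1)
})
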