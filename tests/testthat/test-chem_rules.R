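## Structure standardization, SMARTS rule application, scoring and
## atomic balancing.

DAIDZEIN_SMILES <- "O=c1c(-c2ccc(O)cc2)coc2cc(O)ccc12"
DAIDZEIN_GLCA_SMILES <- "O=C(O)C1OC(Oc2ccc(-c3coc4cc(O)ccc4c3=O)cc2)C(O)C(O)C1O"
LUTEOLIN_SMILES <- "O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12"
LUTEOLIN_GLCA_SMILES <- "O=C(O)C1OC(Oc2cc(O)c3c(=O)cc(-c4ccc(O)c(O)c4)oc3c2)C(O)C(O)C1O"
GLCA_RULE <- phenoflux:::DECORATION_OPS$glucuronide$deg

test_that("standardization yields identical InChI across representations", {
  w <- standardize_structure(data.frame(id = "water", smiles = "O"))
  expect_identical(w$formula, "H2O")
  expect_identical(w$inchi, "InChI=1S/H2O/h1H2")
  expect_equal(w$charge, 0L)

  molblock <- paste(
    "", "     RDKit          2D", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "M  END", sep = "\n")
  from_mol <- standardize_structure(data.frame(id = "m", molblock = molblock))
  from_smi <- standardize_structure(data.frame(id = "s", smiles = "CO"))
  expect_identical(from_mol$inchi, from_smi$inchi)

  expect_error(standardize_structure(data.frame(id = "bad", smiles = "C1CC")),
               class = "structure_error")
})

test_that("an aryl-glucuronide hydrolysis rule transforms daidzein 4'-O-glucuronide", {
  rule <- list(rule_id = "glcA", smarts = GLCA_RULE)
  sub <- standardize_structure(data.frame(id = "dga", smiles = DAIDZEIN_GLCA_SMILES))
  trans <- apply_rule(rule, sub)
  expect_length(trans, 1)
  prods <- trans[[1]]$products
  expected <- standardize_structure(data.frame(
    id = c("daidzein", "glcA"),
    smiles = c(DAIDZEIN_SMILES, "O=C(O)C1OC(O)C(O)C(O)C1O")))
  expect_setequal(prods$inchi, expected$inchi)
  ## formulas carried through match the structures
  expect_setequal(prods$formula, c("C15H10O4", "C6H10O7"))

  ## the rule applied to its own template substrate reproduces the template
  tsub <- standardize_structure(data.frame(id = "lga", smiles = LUTEOLIN_GLCA_SMILES))
  tt <- apply_rule(rule, tsub)
  expect_length(tt, 1)
  lut <- standardize_structure(data.frame(id = "l", smiles = LUTEOLIN_SMILES))
  expect_true(lut$inchi %in% tt[[1]]$products$inchi)

  ## non-matching substrate -> empty list
  benz <- standardize_structure(data.frame(id = "bz", smiles = "c1ccccc1"))
  expect_length(apply_rule(rule, benz), 0)

  ## broken SMARTS -> rule error
  expect_error(apply_rule(list(rule_id = "x", smarts = ">>"), sub),
               class = "rule_error")
})

test_that("chemical score is a symmetric similarity with unit self-similarity", {
  s1 <- tanimoto_similarity(DAIDZEIN_SMILES, DAIDZEIN_SMILES)
  expect_equal(s1, 1)
  ab <- tanimoto_similarity(DAIDZEIN_SMILES, LUTEOLIN_SMILES)
  ba <- tanimoto_similarity(LUTEOLIN_SMILES, DAIDZEIN_SMILES)
  expect_equal(ab, ba)
  expect_gt(ab, 0); expect_lt(ab, 1)
})

test_that("cutoff acceptance is inclusive on both scores", {
  params <- search_params(bio_cutoff = 0.1, chem_cutoff = 0.6)
  tr <- list(chemical_score = 0.6)
  expect_true(score_match(list(biological_score = 0.1), tr, params))
  expect_false(score_match(list(biological_score = 0.05), tr, params))
  expect_false(score_match(list(biological_score = 0.5),
                           list(chemical_score = 0.599), params))
})

test_that("completion adds template co-substrates and balances every element", {
  ## template: luteolin 7-O-glucuronide + water -> luteolin + D-glucuronate
  std <- standardize_structure(data.frame(
    id = c("lut_glca", "water", "luteolin", "glucuronate"),
    smiles = c(LUTEOLIN_GLCA_SMILES, "O", LUTEOLIN_SMILES,
               "O=C(O)C1OC(O)C(O)C(O)C1O")))
  mets <- metabolite_table(std$id, inchi = std$inchi, smiles = std$smiles,
                           formula = std$formula, charge = std$charge)
  rxns <- reaction_table("tmpl", taxa = "s1")
  stoi <- stoichiometry_table(rep("tmpl", 4), std$id, c(-1, -1, 1, 1))
  net <- metabolic_network(mets, rxns, stoi)
  rule <- list(rule_id = "glcA", smarts = GLCA_RULE,
               template_substrate_id = "lut_glca", taxa = "s1")

  sub <- standardize_structure(data.frame(id = "dga", smiles = DAIDZEIN_GLCA_SMILES))
  trans <- apply_rule(rule, sub)[[1]]
  trans$substrate_formula <- sub$formula
  trans$substrate_charge <- sub$charge
  out <- complete_and_balance(trans, "tmpl", net, rule, reaction_id = "pred1")

  ## water copied in as co-substrate with unit coefficients
  expect_true("water" %in% out$stoichiometry$metabolite_id)
  expect_true(all(abs(out$stoichiometry$coefficient) == 1))
  expect_identical(out$reactions$provenance, "predicted")
  expect_identical(out$reactions$taxa, "s1")

  ## independent formula-summation oracle: C21H20O10 + H2O = C15H10O4 + C6H10O7
  lookup <- rbind(mets[, c("id", "formula", "charge")],
                  out$metabolites[, c("id", "formula", "charge")])
  lookup <- lookup[!duplicated(lookup$id), ]
  idx <- match(out$stoichiometry$metabolite_id, lookup$id)
  resid <- formula_sum_oracle(lookup$formula[idx], out$stoichiometry$coefficient)
  expect_true(all(resid == 0))
  ## and the package's own residual check agrees
  res <- balance_residuals(out$stoichiometry, lookup)
  expect_length(res$elements, 0)
  expect_equal(res$charge, 0)

  ## an already-balanced transformation needs no added species
  iso <- list(rule_id = "iso", substrate_inchi = std$inchi[std$id == "luteolin"],
              substrate_smiles = LUTEOLIN_SMILES,
              substrate_formula = "C15H10O6", substrate_charge = 0L,
              products = data.frame(inchi = "InChI=fake-iso", smiles = "X",
                                    formula = "C15H10O6", charge = 0L,
                                    stringsAsFactors = FALSE))
  mets2 <- metabolite_table(c("m1", "m2"), formula = c("C15H10O6", "C15H10O6"))
  net2 <- metabolic_network(mets2, reaction_table("t2"),
                            stoichiometry_table(c("t2", "t2"), c("m1", "m2"),
                                                c(-1, 1)))
  rule2 <- list(rule_id = "iso", smarts = GLCA_RULE,
                template_substrate_id = "m1", taxa = "")
  out2 <- complete_and_balance(iso, "t2", net2, rule2, reaction_id = "pred2")
  expect_equal(nrow(out2$stoichiometry), 2)
  expect_true(all(abs(out2$stoichiometry$coefficient) == 1))

  ## no co-substrate can close the balance -> balance error
  broken <- iso
  broken$products$formula <- "C20H10O6"   # five carbons appear from nowhere
  expect_error(complete_and_balance(broken, "t2", net2, rule2, "pred3"),
               class = "balance_error")
})

test_that("rule tables are validated on read", {
  f <- tempfile(fileext = ".tsv")
  rules <- data.frame(rule_id = c("a", "b"),
                      smarts = GLCA_RULE, diameter = c(8L, 12L),
                      biological_score = c(0.5, 0.9),
                      template_reaction_id = "tmpl", taxa = "s1",
                      stringsAsFactors = FALSE)
  utils::write.table(rules, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_rule_table(f)
  expect_equal(nrow(back), 2)
  expect_true("template_substrate_id" %in% names(back))

  rules$diameter[1] <- 7L
  utils::write.table(rules, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rule_table(f), class = "validation_error")
  rules$diameter[1] <- 18L
  utils::write.table(rules, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rule_table(f), class = "validation_error")
})
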