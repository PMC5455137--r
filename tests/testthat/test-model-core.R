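# Model structures, formula handling, balance checking, summaries and I/O.

test_that("formula parsing handles integer, fractional and pseudo elements", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("CH1.624O0.456"), c(C = 1, H = 1.624, O = 0.456))
  expect_equal(parse_formula("Fd"), c(Fd = 1))
  expect_equal(parse_formula("HO4P"), c(H = 1, O = 4, P = 1))
  expect_error(parse_formula("C6H12$"), "malformed")
  expect_length(parse_formula(NA_character_), 0)
  # round trip through the formatter
  f <- "CH1.624O0.456N0.216P0.033S0.0047"
  expect_equal(parse_formula(format_formula(parse_formula(f))), parse_formula(f))
})

test_that("model construction enforces invariants", {
  m <- toy_full()
  expect_s3_class(m, "metabolic_model")
  # exchanges touch exactly one metabolite
  per_rxn <- table(m$stoichiometry$reaction_id)
  expect_true(all(per_rxn[m$reactions$id[m$reactions$is_exchange]] == 1))
  # validation errors
  bad <- m; bad$reactions$lower_bound[3] <- 99; bad$reactions$upper_bound[3] <- -99
  expect_error(pdoflux:::validate_model(bad), "lower_bound")
  bad2 <- m; bad2$metabolites$charge[2] <- 0.5
  expect_error(pdoflux:::validate_model(bad2), "non-integer")
  expect_error(
    metabolic_model(m$metabolites, m$reactions, m$stoichiometry,
                    biomass_reaction_id = "NOT_THERE"),
    "biomass")
})

test_that("model_summary counts partition reactions", {
  s <- model_summary(toy_full())
  n <- function(k) s$n[s$feature == k]
  expect_equal(n("cytosolic_reactions") + n("transport_reactions") +
                 n("exchange_reactions"), n("total_reactions"))
  expect_equal(n("total_reactions"), 30)
  expect_equal(n("transport_reactions"), 1)
  expect_equal(n("exchange_reactions"), 13)
  # counts follow construction when branches are dropped
  m2 <- toy_glycerol_model(branches = c("acetate", "h2", "ferredoxin"))
  s2 <- model_summary(m2)
  expect_equal(s2$n[s2$feature == "total_reactions"], nrow(m2$reactions))
  expect_false("EX_pdo" %in% m2$reactions$id)
})

test_that("check_balance flags atom and charge imbalances and unverifiable reactions", {
  expect_equal(nrow(check_balance(toy_full())), 0)
  met <- tibble::tibble(id = c("a", "b", "x"), name = id,
                        formula = c("CH4", "CH3", NA), charge = c(0, 0, NA),
                        compartment = "c")
  rxn <- tibble::tibble(id = c("R1", "R2", "BIO"), name = id,
                        lower_bound = 0, upper_bound = 10, gpr = "",
                        ec = list(character(0)), kegg_id = NA_character_)
  sto <- tibble::tibble(reaction_id = c("R1", "R1", "R2", "R2", "BIO", "BIO"),
                        metabolite_id = c("a", "b", "a", "x", "a", "x"),
                        coefficient = c(-1, 1, -1, 1, -1, 1))
  m <- metabolic_model(met, rxn, sto, biomass_reaction_id = "BIO")
  out <- check_balance(m)
  r1 <- out[out$reaction_id == "R1", ]
  expect_equal(r1$imbalance[r1$element == "H"], -1)
  expect_true("unverifiable" %in% out$status[out$reaction_id == "R2"])
  # charge-only mismatch
  met2 <- tibble::tibble(id = c("p", "q"), name = id, formula = "C",
                         charge = c(0, 1), compartment = "c")
  rxn2 <- rxn[1, ]
  sto2 <- tibble::tibble(reaction_id = "R1", metabolite_id = c("p", "q"),
                         coefficient = c(-1, 1))
  m2 <- metabolic_model(met2, rxn2, sto2, biomass_reaction_id = "R1")
  # R1 is also the (exempt) biomass reaction here; give it a checkable product
  out2 <- check_balance(
    metabolic_model(met2, tibble::tibble(
      id = c("R1", "B"), name = id, lower_bound = 0, upper_bound = 1,
      gpr = "", ec = list(character(0)), kegg_id = NA_character_),
      dplyr::bind_rows(sto2, tibble::tibble(reaction_id = "B",
                                            metabolite_id = "q",
                                            coefficient = -1)),
      biomass_reaction_id = "B"))
  expect_equal(out2$element[out2$reaction_id == "R1"], "charge")
  expect_equal(out2$imbalance[out2$reaction_id == "R1"], 1)
})

test_that("biomass elemental composition sums consumed precursors per carbon", {
  # glucose-only biomass gives CH2O
  met <- tibble::tibble(id = c("glc", "bio"), name = id,
                        formula = c("C6H12O6", NA), charge = c(0, NA),
                        compartment = "c")
  rxn <- tibble::tibble(id = c("BIO", "EX_bio"), name = id, lower_bound = 0,
                        upper_bound = 10, gpr = "", ec = list(character(0)),
                        kegg_id = NA_character_)
  sto <- tibble::tibble(reaction_id = c("BIO", "BIO", "EX_bio"),
                        metabolite_id = c("glc", "bio", "bio"),
                        coefficient = c(-1, 1, -1))
  m <- metabolic_model(met, rxn, sto, biomass_reaction_id = "BIO")
  comp <- biomass_elemental_composition(m)
  expect_equal(comp[["C"]], 1)
  expect_equal(comp[["H"]], 2)
  expect_equal(comp[["O"]], 1)

  # two-precursor model: 1 x CH4 + 1 x C2H2O, hand-summed: C3 H6 O1 -> per C
  met2 <- tibble::tibble(id = c("p1", "p2", "bio"), name = id,
                         formula = c("CH4", "C2H2O", NA),
                         charge = c(0, 0, NA), compartment = "c")
  sto2 <- tibble::tibble(reaction_id = c("BIO", "BIO", "BIO", "EX_bio"),
                         metabolite_id = c("p1", "p2", "bio", "bio"),
                         coefficient = c(-1, -1, 1, -1))
  m2 <- metabolic_model(met2, rxn, sto2, biomass_reaction_id = "BIO")
  comp2 <- biomass_elemental_composition(m2)
  expect_equal(comp2[["H"]], 6 / 3)
  expect_equal(comp2[["O"]], 1 / 3)

  # atom conservation: per-C formula times total C returns the summed atoms
  m3 <- toy_full()
  comp3 <- biomass_elemental_composition(m3)
  sto3 <- m3$stoichiometry[m3$stoichiometry$reaction_id == "BIOMASS" &
                             m3$stoichiometry$coefficient < 0, ]
  tot <- Reduce(`+`, lapply(seq_len(nrow(sto3)), function(k) {
    f <- m3$metabolites$formula[m3$metabolites$id == sto3$metabolite_id[k]]
    a <- parse_formula(f) * abs(sto3$coefficient[k])
    full <- c(C = 0, H = 0, N = 0, O = 0, P = 0)
    full[names(a)] <- a
    full
  }))
  expect_equal(unname(comp3[names(tot)] * tot[["C"]]), unname(tot),
               tolerance = 1e-10)

  # no carbon -> error
  met4 <- tibble::tibble(id = c("w", "bio"), name = id,
                         formula = c("H2O", NA), charge = c(0, NA),
                         compartment = "c")
  sto4 <- tibble::tibble(reaction_id = c("BIO", "BIO", "EX_bio"),
                         metabolite_id = c("w", "bio", "bio"),
                         coefficient = c(-1, 1, -1))
  m4 <- metabolic_model(met4, rxn, sto4, biomass_reaction_id = "BIO")
  expect_error(biomass_elemental_composition(m4), "carbon")
})

test_that("SBML and tabular round trips preserve the model", {
  for (m in list(toy_full(), random_model(6, 9, seed = 4))) {
    S <- pdoflux:::stoich_matrix(m)
    p1 <- tempfile(fileext = ".xml")
    write_model(m, p1)
    m2 <- load_model(p1)
    expect_equal(pdoflux:::stoich_matrix(m2)[rownames(S), colnames(S)], S)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_identical(m2$reactions$ec, m$reactions$ec)
    expect_identical(m2$reactions$gpr, m$reactions$gpr)
    expect_equal(m2$metabolites$charge, m$metabolites$charge)
    expect_identical(m2$metabolites$formula, m$metabolites$formula)
    expect_equal(m2$gam, m$gam)
    expect_equal(m2$ngam, m$ngam)
    expect_identical(m2$atp_producing_ids, m$atp_producing_ids)
    p2 <- tempfile()
    write_model(m, p2, format = "table")
    m3 <- load_model(p2, format = "table")
    expect_equal(pdoflux:::stoich_matrix(m3)[rownames(S), colnames(S)], S)
    expect_identical(m3$reactions$gpr, m$reactions$gpr)
    unlink(c(p1, paste0(p2, c("_reactions.tsv", "_metabolites.tsv", "_model.tsv"))))
  }
})

test_that("round trips hold across random synthetic models", {
  for (seed in 1:10) {
    m <- random_model(5, 8, seed = seed)
    p <- tempfile(fileext = ".xml")
    write_model(m, p)
    m2 <- load_model(p)
    S <- pdoflux:::stoich_matrix(m)
    expect_equal(pdoflux:::stoich_matrix(m2)[rownames(S), colnames(S)], S)
    unlink(p)
  }
})

test_that("SBML reader reports parse and validation failures", {
  p <- tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?><sbml><model><listOfSpecies>', p)
  expect_error(load_model(p), "parse failure")
  writeLines(c('<?xml version="1.0"?>', "<sbml><model id=\"x\"></model></sbml>"), p)
  expect_error(load_model(p), "no <reaction>")
  expect_error(load_model(tempfile(fileext = ".xml")), "not found")
  unlink(p)
})

test_that("SBML reader tolerates kinetic-law bounds and note-encoded metadata", {
  p <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="legacy">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>BIOMASS_REACTION: vgrow</p></body></notes>',
    '<listOfSpecies>',
    '<species id="A" compartment="c"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>FORMULA: C2H4</p><p>CHARGE: -1</p></body></notes></species>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="vup" reversible="true">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters><parameter id="LOWER_BOUND" value="-7.5"/><parameter id="UPPER_BOUND" value="0"/></listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="vgrow" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: gA or gB</p><p>EC Number: 1.2.3.4</p></body></notes>',
    '<listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), p)
  m <- load_model(p)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "vup"], -7.5)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "vup"], 0)
  # undeclared bounds fall back to reversibility defaults
  expect_equal(m$reactions$lower_bound[m$reactions$id == "vgrow"], 0)
  expect_equal(m$biomass_reaction_id, "vgrow")
  expect_equal(m$reactions$ec[[which(m$reactions$id == "vgrow")]], "1.2.3.4")
  expect_equal(m$reactions$gpr[m$reactions$id == "vgrow"], "gA or gB")
  expect_equal(m$metabolites$formula, "C2H4")
  expect_equal(m$metabolites$charge, -1)
  unlink(p)
})

test_that("flux state JSON round trips", {
  f <- solve_fba(chain_model(0.1), culture_condition(c(EX_up = 10), fix_uptake = TRUE))
  p <- tempfile(fileext = ".json")
  write_flux_json(f, p)
  f2 <- read_flux_json(p)
  expect_equal(f2$fluxes, f$fluxes)
  expect_equal(f2$objective_value, f$objective_value)
  expect_equal(f2$status, f$status)
  unlink(p)
})

test_that("non-integer charge is rejected when writing", {
  m <- toy_full()
  m$metabolites$charge[1] <- 0.25
  expect_error(write_model(m, tempfile(fileext = ".xml")), "non-integer")
})
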