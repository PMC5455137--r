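# Blocked-metabolite/-reaction detection and flux-coupling classification.

test_that("open chains have no blocked metabolites; orphans are blocked", {
  # Aext -> A -> B -> Bext with open exchanges
  met <- tibble::tibble(id = c("Ae", "A", "B", "Be"), name = id, formula = "C",
                        charge = 0, compartment = c("e", "c", "c", "e"))
  rxn <- tibble::tibble(
    id = c("EX_A", "T_A", "R", "T_B", "EX_B"), name = id,
    lower_bound = c(-10, 0, 0, 0, 0), upper_bound = c(10, 10, 10, 10, 10),
    gpr = "", ec = list(character(0)), kegg_id = NA_character_)
  sto <- tibble::tibble(
    reaction_id = c("EX_A", "T_A", "T_A", "R", "R", "T_B", "T_B", "EX_B"),
    metabolite_id = c("Ae", "Ae", "A", "A", "B", "B", "Be", "Be"),
    coefficient = c(-1, -1, 1, -1, 1, -1, 1, -1))
  m <- metabolic_model(met, rxn, sto, biomass_reaction_id = "EX_B",
                       gam = 0, ngam = 0)
  expect_length(find_blocked_metabolites(m), 0)
  expect_length(find_blocked_reactions(m), 0)
  # a metabolite produced by no reaction is blocked, and so is the dead-end
  # branch feeding on it
  met2 <- dplyr::bind_rows(met, tibble::tibble(
    id = "orphan", name = "orphan", formula = "C", charge = 0, compartment = "c"))
  rxn2 <- dplyr::bind_rows(rxn, tibble::tibble(
    id = "DEAD", name = "DEAD", lower_bound = 0, upper_bound = 10, gpr = "",
    ec = list("9.9.9.9"), kegg_id = NA_character_))
  sto2 <- dplyr::bind_rows(sto, tibble::tibble(
    reaction_id = c("DEAD", "DEAD"), metabolite_id = c("orphan", "B"),
    coefficient = c(-1, 1)))
  m2 <- metabolic_model(met2, rxn2, sto2, biomass_reaction_id = "EX_B",
                        gam = 0, ngam = 0)
  expect_true("orphan" %in% find_blocked_metabolites(m2))
  expect_equal(find_blocked_reactions(m2), "DEAD")
})

test_that("toy blocked metabolites are exactly the conserved cofactor pools", {
  # the toy exchanges no phosphorus or carrier species, so every P-containing
  # metabolite and both ferredoxin states can never be net produced
  blocked <- find_blocked_metabolites(toy_full())
  expect_setequal(blocked, c("acp_c", "atp_c", "adp_c", "pi_c",
                             "nad_c", "nadh_c", "fdox_c", "fdred_c"))
})

test_that("two-reaction chains are fully coupled with ratio 1", {
  m <- chain_model(1)   # uptake -> A -> X -> out, all flux equal
  cp <- flux_coupling(m, target = "BIO")
  cls <- cp$reactions
  expect_equal(cls$class[cls$reaction == "EX_X"], "full")
  expect_equal(cls$rmin[cls$reaction == "EX_X"], 1, tolerance = 1e-6)
  expect_equal(cls$rmax[cls$reaction == "EX_X"], 1, tolerance = 1e-6)
})

test_that("branch points are directionally coupled to their source", {
  y <- y_network(10)
  # relative to the uptake-side reaction, each branch can be off but can
  # never run without it
  cp <- flux_coupling(y, target = "EX_B")
  cls <- stats::setNames(cp$reactions$class, cp$reactions$reaction)
  expect_equal(unname(cls["R1"]), "full")      # R1 == EX_B by stoichiometry
  expect_equal(unname(cls["R2"]), "uncoupled") # R2 can run while EX_B off
  # vertex-enumeration oracle: enumerate the polytope and derive the classes
  S <- pdoflux:::stoich_matrix(y)
  V <- enumerate_vertices(S, y$reactions$lower_bound, y$reactions$upper_bound)
  it <- match("EX_B", colnames(S)); j2 <- match("R2", colnames(S))
  # some vertex runs R2 without the target -> not directionally coupled
  expect_true(any(abs(V[, j2]) > 1e-6 & abs(V[, it]) < 1e-6))
})

test_that("coupling report agrees with sampled-polytope evidence on random models", {
  for (seed in c(1, 2, 3, 5, 8)) {
    m <- random_model(6, 9, seed = seed)
    tgt <- m$biomass_reaction_id
    cp <- tryCatch(flux_coupling(m, target = tgt), error = function(e) NULL)
    if (is.null(cp)) next   # target blocked in this draw
    S <- pdoflux:::stoich_matrix(m)
    verts <- pdoflux:::random_vertices(S, m$reactions$lower_bound,
                                       m$reactions$upper_bound, 40, seed)
    V <- do.call(rbind, verts)
    it <- match(tgt, colnames(S))
    for (j in seq_len(ncol(S))) {
      row <- cp$reactions[cp$reactions$reaction == colnames(S)[j], ]
      if (row$class == "blocked") {
        expect_lt(max(abs(V[, j])), 1e-6)
        next
      }
      on <- abs(V[, it]) > 1e-6
      if (any(on)) {
        ratios <- V[on, j] / V[on, it]
        # sampled ratios always fall inside the reported bounds
        expect_true(all(ratios >= row$rmin - 1e-5 & ratios <= row$rmax + 1e-5))
        if (row$class == "full") {
          expect_lt(max(abs(ratios)) - min(abs(ratios)), 1e-5)
        }
      }
      if (row$class == "directional") {
        # reaction never observed running while the target is off (the
        # one-way implication defining directional coupling; full/partial
        # classes constrain the ratio, not the target-off fibre)
        expect_false(any(abs(V[!on, j]) > 1e-6))
      }
    }
  }
})

test_that("full coupling behaves as an equivalence relation on the toy", {
  cp <- toy_coupling()
  full_set <- cp$reactions$reaction[cp$reactions$class == "full"]
  expect_true(all(c("PC", "ALA", "LIP", "BIOMASS", "EX_biomass") %in% full_set))
  # re-targeting onto another member of the class preserves the class
  cp2 <- flux_coupling(toy_full(), target = "PC")
  full2 <- cp2$reactions$reaction[cp2$reactions$class == "full"]
  expect_true(all(setdiff(full_set, "PC") %in% full2))
})

test_that("enzyme classes aggregate reaction classes by strongest coupling", {
  report <- list(reactions = tibble::tibble(
    reaction = c("r1", "r2", "r3", "r4"),
    rmin = 0, rmax = 1,
    class = c("full", "blocked", "blocked", "directional"),
    ec = list("1.1.1.1", c("1.1.1.1", "2.2.2.2"), "2.2.2.2", "3.3.3.3")))
  model <- list(reactions = tibble::tibble(
    id = c("r1", "r2", "r3", "r4"),
    ec = list("1.1.1.1", c("1.1.1.1", "2.2.2.2"), "2.2.2.2", "3.3.3.3")))
  out <- classify_enzymes(report, model)
  cls <- stats::setNames(out$class, out$ec)
  expect_equal(unname(cls["1.1.1.1"]), "full")      # full beats blocked
  expect_equal(unname(cls["2.2.2.2"]), "blocked")   # all reactions blocked
  expect_equal(unname(cls["3.3.3.3"]), "directional")
})

test_that("coupling requires an unblocked target", {
  m <- random_model(5, 7, seed = 1)
  m$reactions$lower_bound[m$reactions$id == "EX_sink"] <- 0
  m$reactions$upper_bound[m$reactions$id == "EX_sink"] <- 0
  expect_error(flux_coupling(m, target = "EX_sink"), "blocked")
})
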